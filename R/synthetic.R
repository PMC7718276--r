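# Synthetic-data generators. Every downstream stage of the package can be
# exercised on data with known ground truth: a regulatory network with a
# planted active TF, expression matrices with a planted gene-set shift,
# paired-caller somatic call sets with known true somatics, and coverage
# tracks with promoter-localised depletion. All generators are pure
# functions of (config, seed): a single master seed is expanded into
# per-component substreams (see substream_seed) so outputs are reproducible
# and independent across components.

#' Configuration for the regulatory-network simulator
#'
#' @param n_tfs number of transcription factors (>= 1).
#' @param n_target_genes number of non-TF target genes (>= n_tfs).
#' @param tf_dna_out_degree_mean mean Poisson out-degree of TF-DNA edges
#'   per TF.
#' @param ppi_degree_mean mean protein-protein interaction degree per node.
#' @param confidence_range length-2 numeric in (0, 1], low <= high; edge
#'   confidences are uniform in this range.
#' @param seed integer master seed.
#' @return list of class `network_sim_config`.
#' @export
network_sim_config <- function(n_tfs = 50L, n_target_genes = 1000L,
                               tf_dna_out_degree_mean = 20,
                               ppi_degree_mean = 4,
                               confidence_range = c(0.5, 1),
                               seed = 1L) {
  check_count(n_tfs, "n_tfs", min = 1L)
  check_count(n_target_genes, "n_target_genes", min = 1L)
  if (n_target_genes < n_tfs)
    stop_config("n_target_genes", "must be >= n_tfs")
  check_positive(tf_dna_out_degree_mean, "tf_dna_out_degree_mean")
  check_positive(ppi_degree_mean, "ppi_degree_mean")
  if (length(confidence_range) != 2L || confidence_range[1] > confidence_range[2] ||
      any(confidence_range <= 0) || any(confidence_range > 1))
    stop_config("confidence_range", "must be (low, high) with 0 < low <= high <= 1")
  structure(list(n_tfs = as.integer(n_tfs),
                 n_target_genes = as.integer(n_target_genes),
                 tf_dna_out_degree_mean = tf_dna_out_degree_mean,
                 ppi_degree_mean = ppi_degree_mean,
                 confidence_range = as.numeric(confidence_range),
                 seed = as.integer(seed)),
            class = "network_sim_config")
}

#' Simulate a TF-DNA + PPI regulatory network
#'
#' TF-DNA edges are directed TF -> gene edges with Poisson out-degrees;
#' targets are drawn uniformly from all other nodes (so TFs also regulate
#' other TFs, giving the TF-DNA graph depth beyond 1). PPI edges are
#' undirected pairs stored as two directed edges sharing one confidence.
#' Confidences are uniform in the configured range. Deterministic given the
#' config seed.
#'
#' @param config a [network_sim_config()].
#' @return edge data frame (`source`, `target`, `kind`, `confidence`).
#' @export
simulate_network <- function(config = network_sim_config()) {
  stopifnot(inherits(config, "network_sim_config"))
  tfs <- sprintf("TF%03d", seq_len(config$n_tfs))
  genes <- sprintf("G%05d", seq_len(config$n_target_genes))
  nodes <- c(tfs, genes)
  with_seed(substream_seed(config$seed, "network"), {
    runif_conf <- function(n)
      stats::runif(n, config$confidence_range[1], config$confidence_range[2])
    tf_edges <- lapply(tfs, function(tf) {
      k <- min(stats::rpois(1, config$tf_dna_out_degree_mean), length(nodes) - 1L)
      if (k == 0L) return(NULL)
      data.frame(source = tf,
                 target = sample(setdiff(nodes, tf), k),
                 kind = "tf_dna", stringsAsFactors = FALSE)
    })
    tf_edges <- do.call(rbind, tf_edges[!vapply(tf_edges, is.null, logical(1))])
    n_pairs <- round(length(nodes) * config$ppi_degree_mean / 2)
    ppi <- NULL
    if (n_pairs > 0) {
      a <- sample(nodes, n_pairs, replace = TRUE)
      b <- sample(nodes, n_pairs, replace = TRUE)
      keep <- a != b
      a <- a[keep]; b <- b[keep]
      lo <- pmin(a, b); hi <- pmax(a, b)
      dup <- duplicated(paste0(lo, "\r", hi))
      lo <- lo[!dup]; hi <- hi[!dup]
      conf <- runif_conf(length(lo))
      ppi <- data.frame(source = c(lo, hi), target = c(hi, lo),
                        kind = "ppi", confidence = rep(conf, 2),
                        stringsAsFactors = FALSE)
    }
    if (!is.null(tf_edges)) tf_edges$confidence <- runif_conf(nrow(tf_edges))
    edges <- rbind(tf_edges, ppi)
    if (is.null(edges))
      edges <- data.frame(source = character(), target = character(),
                          kind = character(), confidence = numeric(),
                          stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    validate_edges(edges)
  })
}

#' Configuration for planting an active regulator
#'
#' @param planted_tf identifier of the TF whose subnetwork carries the
#'   signal; must be a TF-DNA source in the network.
#' @param effect_mean mean shift of planted-gene z-scores at depth 1, in
#'   units of the signed -log10(adjusted p)-weighted log2FC score.
#' @param noise_sd standard deviation of the per-gene noise (> 0).
#' @param depth_decay multiplicative attenuation of the effect per extra
#'   depth, in (0, 1].
#' @param seed integer master seed.
#' @return list of class `plant_config`.
#' @export
plant_config <- function(planted_tf = "TF001", effect_mean = 2,
                         noise_sd = 1, depth_decay = 0.5, seed = 1L) {
  check_positive(noise_sd, "noise_sd")
  if (depth_decay <= 0 || depth_decay > 1)
    stop_config("depth_decay", "must lie in (0, 1]")
  structure(list(planted_tf = planted_tf, effect_mean = effect_mean,
                 noise_sd = noise_sd, depth_decay = depth_decay,
                 seed = as.integer(seed)),
            class = "plant_config")
}

#' Plant an active regulator and emit a DE table
#'
#' Genes in the planted TF's depth-<=3 subnetwork (over both edge kinds)
#' draw z ~ Normal(effect_mean * depth_decay^(D-1), noise_sd); all other
#' genes draw z ~ Normal(0, noise_sd). The DE table reports log2_fc = z,
#' a two-sided normal tail p-value for z/noise_sd, and BH-adjusted p.
#'
#' @param edges edge data frame from [simulate_network()].
#' @param plant a [plant_config()].
#' @param max_depth subnetwork depth carrying the planted effect.
#' @return list with `de` (DE table data frame) and `truth` (list:
#'   `planted_tf`, `members` data frame of gene/distance).
#' @export
plant_regulator <- function(edges, plant = plant_config(), max_depth = 3L) {
  stopifnot(inherits(plant, "plant_config"))
  edges <- validate_edges(edges)
  if (!plant$planted_tf %in% edges$source[edges$kind == "tf_dna"])
    stop(sprintf("planted TF '%s' is not a TF-DNA source in the network",
                 plant$planted_tf), call. = FALSE)
  sub <- build_subnetwork(plant$planted_tf, edges, max_depth = max_depth)
  genes <- sort(unique(c(edges$source, edges$target)))
  mu <- stats::setNames(rep(0, length(genes)), genes)
  mu[sub$nodes$gene_id] <- plant$effect_mean *
    plant$depth_decay^(sub$nodes$distance - 1)
  z <- with_seed(substream_seed(plant$seed, "plant"),
                 stats::rnorm(length(genes), mu, plant$noise_sd))
  p <- 2 * stats::pnorm(-abs(z / plant$noise_sd))
  de <- data.frame(gene = genes, log2_fc = z, p_value = p,
                   adj_p_value = benjamini_hochberg(p),
                   stringsAsFactors = FALSE)
  list(de = de,
       truth = list(planted_tf = plant$planted_tf,
                    members = sub$nodes[c("gene_id", "distance")]))
}

#' Simulate an FPKM-like expression matrix with a planted set shift
#'
#' Each gene gets a log-normal baseline (meanlog 1, sdlog 1); per-sample
#' values multiply the baseline by log-normal noise. Genes of `shifted_set`
#' are multiplied by 2^shift in group 2. All values are nonnegative by
#' construction.
#'
#' @param n_samples_per_group samples per group (two groups).
#' @param gene_sets named list of gene-identifier vectors.
#' @param shifted_set name of the set to shift (must be in `gene_sets`).
#' @param shift log2 shift applied to the set in group 2.
#' @param seed integer master seed.
#' @param n_background extra background genes beyond the union of the sets.
#' @param noise_sdlog per-sample log-normal noise (sdlog).
#' @return numeric matrix genes x samples; columns `grp1_*`, `grp2_*`;
#'   attribute `group` gives the group of each column.
#' @export
simulate_expression_matrix <- function(n_samples_per_group, gene_sets,
                                       shifted_set, shift, seed = 1L,
                                       n_background = 500L,
                                       noise_sdlog = 0.5) {
  check_count(n_samples_per_group, "n_samples_per_group", min = 1L)
  if (!shifted_set %in% names(gene_sets))
    stop(sprintf("unknown gene set '%s'", shifted_set), call. = FALSE)
  genes <- unique(c(unlist(gene_sets), sprintf("BG%05d", seq_len(n_background))))
  n <- length(genes)
  k <- 2L * n_samples_per_group
  with_seed(substream_seed(seed, "expression"), {
    baseline <- stats::rlnorm(n, meanlog = 1, sdlog = 1)
    m <- baseline * matrix(stats::rlnorm(n * k, 0, noise_sdlog), n, k)
    grp <- rep(c("grp1", "grp2"), each = n_samples_per_group)
    colnames(m) <- paste0(grp, "_S", rep(seq_len(n_samples_per_group), 2))
    rownames(m) <- genes
    in_set <- genes %in% gene_sets[[shifted_set]]
    m[in_set, grp == "grp2"] <- m[in_set, grp == "grp2"] * 2^shift
    attr(m, "group") <- grp
    m
  })
}

#' Configuration for the variant-call simulator
#'
#' Emulates an unmatched tumour design with a panel of normals: true
#' somatics are called by both callers against every normal; each caller
#' also produces private false positives; strain polymorphisms are called
#' by both callers but appear on a blacklist.
#'
#' @param n_true_somatic,n_fp_per_caller,n_strain_variants counts (>= 0).
#' @param n_normals number of normals in the panel (>= 1).
#' @param vaf_true expected tumour VAF of true somatics, in (0, 1).
#' @param coverage_mean mean Poisson sequencing depth.
#' @param seed integer master seed.
#' @return list of class `variant_sim_config`.
#' @export
variant_sim_config <- function(n_true_somatic = 20L, n_fp_per_caller = 30L,
                               n_strain_variants = 10L, n_normals = 2L,
                               vaf_true = 0.4, coverage_mean = 60,
                               seed = 1L) {
  check_count(n_true_somatic, "n_true_somatic")
  check_count(n_fp_per_caller, "n_fp_per_caller")
  check_count(n_strain_variants, "n_strain_variants")
  check_count(n_normals, "n_normals", min = 1L)
  if (vaf_true <= 0 || vaf_true >= 1)
    stop_config("vaf_true", "must lie strictly in (0, 1)")
  check_positive(coverage_mean, "coverage_mean")
  structure(list(n_true_somatic = as.integer(n_true_somatic),
                 n_fp_per_caller = as.integer(n_fp_per_caller),
                 n_strain_variants = as.integer(n_strain_variants),
                 n_normals = as.integer(n_normals),
                 vaf_true = vaf_true, coverage_mean = coverage_mean,
                 seed = as.integer(seed)),
            class = "variant_sim_config")
}

# Draw n distinct variant sites with annotation.
random_variants <- function(n, offset = 0L) {
  if (n == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(), effect = character(),
                      stringsAsFactors = FALSE))
  bases <- c("A", "C", "G", "T")
  chrom <- paste0("chr", sample(1:19, n, replace = TRUE))
  pos <- sample.int(1e6L, n) + offset
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
             gene = sprintf("GENE%04d", sample.int(500L, n, replace = TRUE)),
             effect = sample(ALL_EFFECTS, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate paired-caller, panel-of-normals variant call sets
#'
#' @param config a [variant_sim_config()].
#' @param callers names of the two callers.
#' @return list with `calls` (nested list `calls[[caller]][[normal]]` of
#'   variant data frames), `blacklist` (strain variants) and `truth`
#'   (the true somatic records).
#' @export
simulate_variant_calls <- function(config = variant_sim_config(),
                                   callers = c("callerA", "callerB")) {
  stopifnot(inherits(config, "variant_sim_config"), length(callers) == 2L)
  normals <- sprintf("normal%d", seq_len(config$n_normals))
  with_seed(substream_seed(config$seed, "variants"), {
    annotate <- function(v, vaf, germline = FALSE) {
      n <- nrow(v)
      if (!n) {
        v[c("tumour_depth", "tumour_vaf", "normal_depth", "normal_vaf")] <-
          list(integer(), numeric(), integer(), numeric())
        return(v)
      }
      td <- pmax(1L, stats::rpois(n, config$coverage_mean))
      nd <- pmax(1L, stats::rpois(n, config$coverage_mean))
      v$tumour_depth <- td
      v$tumour_vaf <- stats::rbinom(n, td, vaf) / td
      v$normal_depth <- nd
      v$normal_vaf <- if (germline) stats::rbinom(n, nd, vaf) / nd else 0
      v
    }
    truth <- annotate(random_variants(config$n_true_somatic), config$vaf_true)
    strain <- annotate(random_variants(config$n_strain_variants, offset = 2e6L),
                       0.5, germline = FALSE)
    fps <- lapply(seq_along(callers), function(i)
      annotate(random_variants(config$n_fp_per_caller, offset = (2L + i) * 2e6L),
               config$vaf_true))
    names(fps) <- callers
    calls <- lapply(callers, function(cl) {
      per_normal <- lapply(normals, function(nm) {
        v <- rbind(truth, strain, fps[[cl]])
        if (nrow(v)) v$caller <- cl
        v
      })
      stats::setNames(per_normal, normals)
    })
    names(calls) <- callers
    truth$caller <- rep("truth", nrow(truth))
    list(calls = calls,
         blacklist = strain[c("chrom", "pos", "ref", "alt")],
         truth = truth)
  })
}

#' Simulate a coverage track with promoter-localised depletion
#'
#' A piecewise-constant bedGraph track: baseline coverage with mild
#' multiplicative log-normal noise per segment, where promoter windows
#' (`TSS +/- promoter_flank`, strand-aware) of the depleted gene set are
#' multiplied by `depletion_factor`.
#'
#' @param annotations gene annotation data frame (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param depleted_set character vector of gene identifiers (subset of the
#'   annotation).
#' @param depletion_factor multiplier on promoter coverage, in [0, 1).
#' @param promoter_flank half-width of the depleted promoter window in bp.
#' @param baseline baseline coverage level.
#' @param segment_bp width of constant-coverage segments.
#' @param noise_sdlog log-normal noise per segment (0 disables noise).
#' @param seed integer master seed.
#' @return bedGraph data frame (`chrom`, `start`, `end`, `score`).
#' @export
simulate_coverage <- function(annotations, depleted_set, depletion_factor = 0.2,
                              promoter_flank = 2000L, baseline = 10,
                              segment_bp = 200L, noise_sdlog = 0.1, seed = 1L) {
  if (depletion_factor < 0 || depletion_factor >= 1)
    stop_config("depletion_factor", "must lie in [0, 1)")
  missing <- setdiff(depleted_set, annotations$gene_id)
  if (length(missing))
    stop("depleted gene(s) absent from annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  prom <- tss_windows(annotations, depleted_set, flank = promoter_flank)
  with_seed(substream_seed(seed, "coverage"), {
    out <- lapply(unique(annotations$chrom), function(chr) {
      chr_end <- max(annotations$end[annotations$chrom == chr]) + 20000L
      starts <- seq(0L, chr_end - 1L, by = segment_bp)
      ends <- pmin(starts + segment_bp, chr_end)
      score <- baseline * if (noise_sdlog > 0)
        stats::rlnorm(length(starts), 0, noise_sdlog) else rep(1, length(starts))
      p <- prom[prom$chrom == chr, , drop = FALSE]
      if (nrow(p)) {
        depleted <- rep(FALSE, length(starts))
        for (j in seq_len(nrow(p)))
          depleted <- depleted | (starts < p$end[j] & ends > max(0L, p$start[j]))
        score[depleted] <- score[depleted] * depletion_factor
      }
      data.frame(chrom = chr, start = starts, end = ends, score = score,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a BED-style gene annotation
#'
#' Convenience generator: `n_genes` non-overlapping genes laid out along one
#' or more chromosomes with alternating strands.
#'
#' @param n_genes number of genes.
#' @param gene_length gene body length in bp.
#' @param spacing gap between consecutive genes in bp.
#' @param chroms chromosome names to cycle through.
#' @param first_start start coordinate of the first gene on each chromosome.
#' @return annotation data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
simulate_annotations <- function(n_genes = 50L, gene_length = 10000L,
                                 spacing = 50000L, chroms = c("chr1", "chr2"),
                                 first_start = 40000L) {
  chrom <- rep(chroms, length.out = n_genes)
  idx <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along) - 1L
  start <- first_start + idx * (gene_length + spacing)
  data.frame(gene_id = sprintf("GENE%04d", seq_len(n_genes)),
             chrom = chrom, start = start, end = start + gene_length,
             strand = rep(c("+", "-"), length.out = n_genes),
             stringsAsFactors = FALSE)
}
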
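# Somatic-variant consensus and filtering: two-caller intersection, the
# unmatched-tumour every-normal rule with a strain blacklist, depth/VAF
# gates, and RAS/MAPK/PI3K / MYC pathway mutant classification.

DAMAGING_EFFECTS <- c("missense", "frameshift", "nonsense", "splice_site")
ALL_EFFECTS <- c(DAMAGING_EFFECTS, "synonymous", "other")

variant_columns <- c("chrom", "pos", "ref", "alt", "tumour_depth", "tumour_vaf",
                     "normal_depth", "normal_vaf", "effect", "gene", "caller")

validate_variants <- function(v) {
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(v))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(v) && any(v$ref == v$alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  v
}

#' Normalise variant representation
#'
#' Reduces each variant to its minimal left-aligned representation: the
#' shared allele suffix is trimmed first (keeping at least one base), then
#' the shared prefix, advancing `pos` accordingly. Two callers reporting the
#' same indel with different padding then share a (chrom, pos, ref, alt) key.
#'
#' @param v variant data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return the data frame with normalised `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(v) {
  v <- validate_variants(v)
  if (!nrow(v)) return(v)
  for (i in seq_len(nrow(v))) {
    r <- strsplit(v$ref[i], "")[[1]]
    a <- strsplit(v$alt[i], "")[[1]]
    # trim shared suffix, keep >= 1 base each
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    # trim shared prefix, advancing pos
    while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; v$pos[i] <- v$pos[i] + 1L
    }
    v$ref[i] <- paste(r, collapse = "")
    v$alt[i] <- paste(a, collapse = "")
  }
  v
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Two-caller consensus
#'
#' Retains variants identified by both callers: records whose normalised
#' (chrom, pos, ref, alt) key appears in both call sets. Record fields are
#' taken from `calls_a`; the `caller` field is set to `"consensus"`.
#'
#' @param calls_a,calls_b variant data frames from the two callers.
#' @return the intersecting records.
#' @export
consensus_variants <- function(calls_a, calls_b) {
  calls_a <- normalize_variants(calls_a)
  calls_b <- normalize_variants(calls_b)
  out <- calls_a[variant_key(calls_a) %in% variant_key(calls_b), , drop = FALSE]
  if ("caller" %in% names(out)) out$caller <- rep("consensus", nrow(out))
  rownames(out) <- NULL
  out
}

#' Unmatched-tumour consensus against a panel of normals
#'
#' For tumours without a matched normal, a variant is retained only if it was
#' called by every caller against every normal, and its key is absent from
#' the strain-polymorphism blacklist (variants known in other strains cannot
#' be excluded as germline).
#'
#' @param calls nested list: `calls[[caller]][[normal]]` is a variant data
#'   frame; at least two callers and one normal, with every caller covering
#'   every normal.
#' @param blacklist data frame with `chrom`, `pos`, `ref`, `alt` (or `NULL`).
#' @return retained variant records (fields from the first caller/normal),
#'   `caller` set to `"consensus"`.
#' @export
unmatched_consensus <- function(calls, blacklist = NULL) {
  if (length(calls) < 2L)
    stop("unmatched consensus requires both callers", call. = FALSE)
  normals <- sort(unique(unlist(lapply(calls, names))))
  if (!length(normals)) stop("at least one normal is required", call. = FALSE)
  missing_pairs <- unlist(lapply(names(calls), function(cl)
    paste(cl, setdiff(normals, names(calls[[cl]])), sep = "/")))
  missing_pairs <- missing_pairs[!endsWith(missing_pairs, "/")]
  if (length(missing_pairs))
    stop("missing caller/normal call set(s): ",
         paste(missing_pairs, collapse = ", "), call. = FALSE)
  sets <- lapply(calls, function(per_caller)
    lapply(per_caller, normalize_variants))
  keys <- lapply(unlist(sets, recursive = FALSE), variant_key)
  shared <- Reduce(intersect, keys)
  if (!is.null(blacklist) && nrow(blacklist))
    shared <- setdiff(shared, variant_key(normalize_variants(blacklist)))
  first <- sets[[1L]][[1L]]
  out <- first[variant_key(first) %in% shared, , drop = FALSE]
  if ("caller" %in% names(out)) out$caller <- rep("consensus", nrow(out))
  rownames(out) <- NULL
  out
}

#' Somatic filter configuration
#'
#' Thresholds for [somatic_filter()] and [classify_pathway_status()]:
#' coverage gates are strict (`depth > min_coverage`), the tumour VAF gate is
#' inclusive (`>=`), the normal VAF gate is inclusive (`<=`).
#'
#' @param min_coverage minimum depth in tumour and normal (strict >).
#' @param min_tumour_vaf minimum tumour variant allele frequency.
#' @param max_normal_vaf maximum normal variant allele frequency.
#' @param pathway_min_vaf VAF gate for pathway classification (strict >).
#' @param pathway_min_coverage depth gate for pathway classification (strict >).
#' @param amplification_copies copy number at or above which a gain counts.
#' @param deletion_copies copy number at or below which a loss counts.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 10L, min_tumour_vaf = 0.05,
                          max_normal_vaf = 0.01, pathway_min_vaf = 0.2,
                          pathway_min_coverage = 20L,
                          amplification_copies = 5L, deletion_copies = 0L) {
  cfg <- list(min_coverage = min_coverage, min_tumour_vaf = min_tumour_vaf,
              max_normal_vaf = max_normal_vaf, pathway_min_vaf = pathway_min_vaf,
              pathway_min_coverage = pathway_min_coverage,
              amplification_copies = amplification_copies,
              deletion_copies = deletion_copies)
  for (nm in names(cfg))
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0)
      stop_config(nm, "must be a single nonnegative number")
  if (min_tumour_vaf <= max_normal_vaf)
    stop_config("min_tumour_vaf", "must exceed max_normal_vaf")
  structure(cfg, class = "filter_config")
}

#' Depth and VAF somatic filter
#'
#' Keeps variants with tumour and normal depth strictly above
#' `min_coverage`, tumour VAF at least `min_tumour_vaf` and normal VAF at
#' most `max_normal_vaf`.
#'
#' @param variants variant data frame with depth and VAF columns.
#' @param config a [filter_config()].
#' @return the surviving records.
#' @export
somatic_filter <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  need <- c("tumour_depth", "tumour_vaf", "normal_depth", "normal_vaf")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants lack annotation column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!stats::complete.cases(variants[need]))
  if (length(bad))
    stop("missing depth/VAF annotation for record(s): ",
         paste(variant_key(variants[bad, , drop = FALSE]), collapse = ", "),
         call. = FALSE)
  keep <- variants$tumour_depth > config$min_coverage &
    variants$normal_depth > config$min_coverage &
    variants$tumour_vaf >= config$min_tumour_vaf &
    variants$normal_vaf <= config$max_normal_vaf
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a sample's pathway mutation status
#'
#' A sample is `mutant` for a pathway if any pathway gene carries an
#' SNV/indel with a damaging effect (missense, frameshift, nonsense or
#' splice-site) at tumour VAF strictly above `pathway_min_vaf` and depth
#' strictly above `pathway_min_coverage`, or overlaps a copy-number segment
#' with an amplification (copies >= `amplification_copies`) or homozygous
#' deletion (copies <= `deletion_copies`). It is `wild_type` only if every
#' pathway gene is free of SNV/indels of any effect and of copy-number
#' change (copy-neutral = 2); anything in between is `indeterminate`.
#'
#' @param variants the sample's variant data frame.
#' @param cna data frame of copy-number segments with columns `chrom`,
#'   `start`, `end`, `copy_number`, `gene_overlaps` (comma-separated gene
#'   identifiers), or `NULL`.
#' @param pathway_genes non-empty character vector of pathway genes.
#' @param config a [filter_config()].
#' @param sample_id label carried into the result.
#' @param pathway pathway label carried into the result.
#' @return list of class `pathway_call` with `sample_id`, `pathway`,
#'   `status` and `evidence` (list of qualifying variant/CNA rows).
#' @export
classify_pathway_status <- function(variants, cna, pathway_genes,
                                    config = filter_config(),
                                    sample_id = "sample",
                                    pathway = "ras_mapk_pi3k") {
  stopifnot(inherits(config, "filter_config"))
  if (!length(pathway_genes)) stop("pathway gene set is empty", call. = FALSE)
  v <- variants[variants$gene %in% pathway_genes, , drop = FALSE]
  qual_v <- v[v$effect %in% DAMAGING_EFFECTS &
                v$tumour_vaf > config$pathway_min_vaf &
                v$tumour_depth > config$pathway_min_coverage, , drop = FALSE]
  seg_genes <- function(seg) strsplit(seg, ",")[[1]]
  qual_c <- NULL
  any_cna_change <- FALSE
  if (!is.null(cna) && nrow(cna)) {
    hits <- vapply(cna$gene_overlaps, function(g)
      any(seg_genes(g) %in% pathway_genes), logical(1))
    seg <- cna[hits, , drop = FALSE]
    any_cna_change <- nrow(seg) > 0 && any(seg$copy_number != 2L)
    qual_c <- seg[seg$copy_number >= config$amplification_copies |
                    seg$copy_number <= config$deletion_copies, , drop = FALSE]
  }
  evidence <- c(
    if (nrow(qual_v)) split(qual_v, seq_len(nrow(qual_v))),
    if (!is.null(qual_c) && nrow(qual_c)) split(qual_c, seq_len(nrow(qual_c)))
  )
  status <- if (length(evidence)) "mutant"
  else if (nrow(v) == 0L && !any_cna_change) "wild_type"
  else "indeterminate"
  structure(list(sample_id = sample_id, pathway = pathway, status = status,
                 evidence = evidence %||% list()),
            class = "pathway_call")
}

#' @export
print.pathway_call <- function(x, ...) {
  cat(sprintf("%s | %s: %s (%d piece(s) of evidence)\n",
              x$sample_id, x$pathway, x$status, length(x$evidence)))
  invisible(x)
}

#' Read / write a strain-variant blacklist
#'
#' Tab-separated with header `chrom pos ref alt`.
#' @param path file path.
#' @param blacklist data frame to write.
#' @export
read_blacklist <- function(path) {
  validate_variants(utils::read.delim(path, stringsAsFactors = FALSE,
                                      colClasses = c(pos = "integer")))
}

#' @rdname read_blacklist
#' @export
write_blacklist <- function(blacklist, path) {
  utils::write.table(blacklist[c("chrom", "pos", "ref", "alt")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write copy-number segments
#'
#' Tab-separated, 0-based half-open, with header
#' `chrom start end copy_number gene_overlaps`.
#' @param path file path.
#' @param cna data frame to write.
#' @export
read_cna <- function(path) {
  cna <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(cna$start >= cna$end))
    stop("CNA segments must satisfy start < end", call. = FALSE)
  cna
}

#' @rdname read_cna
#' @export
write_cna <- function(cna, path) {
  utils::write.table(cna[c("chrom", "start", "end", "copy_number", "gene_overlaps")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
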
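# Independent brute-force oracles used to validate the package's
# implementations. These deliberately re-derive each quantity from first
# principles (path enumeration, explicit walks, per-base expansion,
# combinatorial sums) rather than calling the code under test.

# --- network score oracle: enumerate all simple paths from the root -------

# Shortest-path distances via exhaustive simple-path enumeration.
oracle_distances <- function(edges, root, max_depth) {
  dist <- c()
  walk <- function(node, d, seen) {
    if (d > 0) {
      cur <- dist[node]
      if (is.na(cur) || d < cur) dist[node] <<- d
    }
    if (d == max_depth) return()
    nxt <- unique(edges$target[edges$source == node])
    for (t in setdiff(nxt, seen)) walk(t, d + 1L, c(seen, t))
  }
  dist <- stats::setNames(rep(NA_integer_, 0), character(0))
  walk(root, 0L, root)
  dist
}

# Network score re-derived from path enumeration plus the stated
# parent-selection rule (shortest distance, then max confidence, then
# lexicographic parent), with out-degree counted on the full selected graph.
oracle_network_score <- function(root, edges, gene_scores, max_depth = 3L,
                                 kinds = c("tf_dna", "ppi")) {
  e <- edges[edges$kind %in% kinds, , drop = FALSE]
  if (!nrow(e)) return(0)
  # collapse parallel edges to the max-confidence one
  key <- paste(e$source, e$target)
  e <- do.call(rbind, lapply(split(e, key), function(g)
    g[which.max(g$confidence), , drop = FALSE]))
  dist <- oracle_distances(e, root, max_depth)
  if (!length(dist)) return(0)
  outdeg <- table(e$source)
  total <- 0
  for (node in names(dist)) {
    d <- dist[[node]]
    parents <- e[e$target == node, , drop = FALSE]
    parents$pd <- ifelse(parents$source == root, 0L,
                         as.integer(dist[parents$source]))
    parents <- parents[!is.na(parents$pd) & parents$pd == d - 1L, , drop = FALSE]
    parents <- parents[order(-parents$confidence, parents$source), , drop = FALSE]
    best <- parents[1L, ]
    s_r <- unname(gene_scores[node])
    if (is.na(s_r)) s_r <- 0
    total <- total + s_r * best$confidence /
      (d * as.integer(outdeg[[best$source]]))
  }
  total
}

# Random small graph for oracle comparisons.
random_small_graph <- function(seed, n_nodes = NULL) {
  set.seed(seed)
  n <- n_nodes %||% sample(4:20, 1)
  nodes <- sprintf("n%02d", seq_len(n))
  m <- sample(n:(3 * n), 1)
  src <- sample(nodes, m, replace = TRUE)
  tgt <- sample(nodes, m, replace = TRUE)
  keep <- src != tgt
  edges <- data.frame(source = c("n01", src[keep]),
                      target = c("n02", tgt[keep]),
                      kind = sample(c("tf_dna", "ppi"), sum(keep) + 1, replace = TRUE),
                      confidence = round(runif(sum(keep) + 1, 0.1, 1), 3),
                      stringsAsFactors = FALSE)
  scores <- stats::setNames(round(rnorm(n), 3), nodes)
  list(edges = edges, scores = scores, root = "n01")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- GSEA enrichment-score oracle: explicit walk ---------------------------

oracle_es <- function(scores, inset, weight = 1) {
  n <- length(scores)
  nh <- sum(inset)
  nr <- sum(abs(scores[inset])^weight)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    running <- running + if (inset[i]) {
      if (nr > 0) abs(scores[i])^weight / nr else 1 / nh
    } else -1 / (n - nh)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# --- ssGSEA oracle: direct summation of the ECDF difference ---------------

oracle_ssgsea_es <- function(x, genes, set, alpha) {
  n <- length(x)
  ord <- order(-x, genes)
  g <- genes[ord]
  rank_val <- n:1
  inset <- g %in% set
  denom_in <- sum(rank_val[inset]^alpha)
  total <- 0
  for (i in seq_len(n)) {
    p_in <- sum((rank_val[seq_len(i)][inset[seq_len(i)]])^alpha) / denom_in
    p_out <- sum(!inset[seq_len(i)]) / (n - sum(inset))
    total <- total + (p_in - p_out)
  }
  total
}

# --- hypergeometric upper tail by combinatorial enumeration ----------------

oracle_hyper_upper <- function(k, n_universe, n_a, n_b) {
  js <- k:min(n_a, n_b)
  sum(choose(n_a, js) * choose(n_universe - n_a, n_b - js)) /
    choose(n_universe, n_b)
}

# --- per-base TSS profile oracle -------------------------------------------

# Expand a bedGraph to per-base values over [0, chrom_end), slice the
# window, reverse for minus strand, average per bin.
oracle_window_bins <- function(coverage, chrom, start, end, strand, bin_size) {
  span <- end - start
  vals <- rep(NA_real_, span)
  for (p in seq(start, end - 1L)) {
    if (p < 0) next
    row <- coverage[coverage$chrom == chrom & coverage$start <= p &
                      coverage$end > p, , drop = FALSE]
    vals[p - start + 1L] <- if (nrow(row)) row$score[1] else 0
  }
  if (strand == "-") vals <- rev(vals)
  sapply(seq_len(span / bin_size), function(b)
    mean(vals[((b - 1) * bin_size + 1):(b * bin_size)], na.rm = TRUE))
}

# --- small shared fixtures -------------------------------------------------

make_variants <- function(chrom, pos, ref, alt, tumour_depth = 50L,
                          tumour_vaf = 0.3, normal_depth = 50L,
                          normal_vaf = 0, effect = "missense",
                          gene = "GENE0001", caller = "callerA") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             tumour_depth = as.integer(tumour_depth), tumour_vaf = tumour_vaf,
             normal_depth = as.integer(normal_depth), normal_vaf = normal_vaf,
             effect = effect, gene = gene, caller = caller,
             stringsAsFactors = FALSE)
}
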
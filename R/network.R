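# Master-regulator inference: depth-bounded TF subnetworks over TF-DNA and
# protein-protein interaction edges, the distance/out-degree-weighted network
# score, direct-target enrichment, and aggregate ranking of candidate TFs.

EDGE_KINDS <- c("tf_dna", "ppi")

#' Validate a regulatory edge list
#'
#' Edges are directed `source -> target` rows with a `kind` of `"tf_dna"`
#' (TF-DNA regulatory edge) or `"ppi"` (protein-protein interaction, stored
#' as two directed edges), and a `confidence` in (0, 1] (the MARA/String-style
#' relationship score). Self-loops are rejected.
#'
#' @param edges data frame with columns `source`, `target`, `kind`,
#'   `confidence`.
#' @return the validated data frame.
#' @export
validate_edges <- function(edges) {
  need <- c("source", "target", "kind", "confidence")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop("edge list lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(edges$kind %in% EDGE_KINDS))
    stop("edge kind must be one of: ", paste(EDGE_KINDS, collapse = ", "), call. = FALSE)
  if (any(edges$confidence <= 0 | edges$confidence > 1))
    stop("edge confidence must lie in (0, 1]", call. = FALSE)
  if (any(edges$source == edges$target))
    stop("self-loop edges are not allowed", call. = FALSE)
  edges
}

# Out-degree (number of distinct targets) per source over the selected kinds,
# computed on the full network.
out_degrees <- function(edges, kinds = EDGE_KINDS) {
  e <- edges[edges$kind %in% kinds, , drop = FALSE]
  e <- e[!duplicated(paste0(e$source, "\r", e$target)), , drop = FALSE]
  tab <- table(e$source)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a depth-bounded TF-rooted subnetwork
#'
#' Breadth-first expansion from `root_tf` over edges of the selected kinds, up
#' to `max_depth` steps. Each gene is recorded once at its minimum distance
#' `D` from the root, together with the parent it was first reached from, the
#' parent's out-degree `L` (over the selected kinds, on the full network) and
#' the confidence of the traversed edge. Among equal-distance parents the
#' highest edge confidence wins, then the lexicographically smallest parent.
#'
#' @param root_tf identifier of the root transcription factor.
#' @param edges validated edge list (see [validate_edges()]).
#' @param max_depth maximum edge distance from the root (default 3).
#' @param kinds which edge kinds to traverse.
#' @return list of class `tf_subnetwork` with `root_tf` and a `nodes` data
#'   frame (`gene_id`, `distance`, `parent`, `parent_out_degree`,
#'   `edge_confidence`). The root is never among the nodes.
#' @export
build_subnetwork <- function(root_tf, edges, max_depth = 3L,
                             kinds = EDGE_KINDS) {
  edges <- validate_edges(edges)
  check_count(max_depth, "max_depth", min = 1L)
  e <- edges[edges$kind %in% kinds, , drop = FALSE]
  if (!root_tf %in% c(e$source, e$target))
    stop(sprintf("root TF '%s' is absent from the selected network", root_tf),
         call. = FALSE)
  # best (highest-confidence) directed edge per (source, target) pair
  o <- order(e$source, e$target, -e$confidence, method = "radix")
  e <- e[o, , drop = FALSE]
  e <- e[!duplicated(paste0(e$source, "\r", e$target)), , drop = FALSE]
  deg <- out_degrees(edges, kinds)
  by_source <- split(seq_len(nrow(e)), e$source)

  visited <- root_tf
  frontier <- root_tf
  nodes <- vector("list", max_depth)
  for (d in seq_len(max_depth)) {
    idx <- unlist(by_source[intersect(frontier, names(by_source))], use.names = FALSE)
    if (!length(idx)) break
    cand <- e[idx, , drop = FALSE]
    cand <- cand[!(cand$target %in% visited), , drop = FALSE]
    if (!nrow(cand)) break
    # tie-break among same-depth parents: confidence desc, then parent id asc
    co <- order(cand$target, -cand$confidence, cand$source, method = "radix")
    cand <- cand[co, , drop = FALSE]
    cand <- cand[!duplicated(cand$target), , drop = FALSE]
    nodes[[d]] <- data.frame(gene_id = cand$target,
                             distance = d,
                             parent = cand$source,
                             parent_out_degree = as.integer(deg[cand$source]),
                             edge_confidence = cand$confidence,
                             stringsAsFactors = FALSE)
    visited <- c(visited, cand$target)
    frontier <- cand$target
  }
  nodes <- do.call(rbind, nodes[!vapply(nodes, is.null, logical(1))])
  if (is.null(nodes))
    nodes <- data.frame(gene_id = character(), distance = integer(),
                        parent = character(), parent_out_degree = integer(),
                        edge_confidence = numeric(), stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(root_tf = root_tf, nodes = nodes), class = "tf_subnetwork")
}

#' TF network score
#'
#' The candidate master-regulator score of a TF subnetwork:
#' \deqn{N_t = \sum_{r \in V_t} \frac{S_r \, S_n}{D_r \, L_r}}
#' where the sum runs over subnetwork genes r, S_r is the signed gene
#' significance score, S_n the confidence of the edge the gene was reached
#' through, D_r its BFS distance from the root and L_r the out-degree of its
#' parent. Genes absent from the score table contribute S_r = 0. An empty
#' subnetwork scores 0.
#'
#' @param subnetwork a `tf_subnetwork` from [build_subnetwork()].
#' @param gene_scores named numeric vector of signed scores (names are gene
#'   identifiers), or a data frame with columns `gene` and `score`.
#' @param use_abs if `TRUE`, |S_r| enters the sum instead of the signed score
#'   (off by default: down-regulated genes subtract).
#' @return a single numeric score.
#' @export
network_score <- function(subnetwork, gene_scores, use_abs = FALSE) {
  stopifnot(inherits(subnetwork, "tf_subnetwork"))
  if (is.data.frame(gene_scores))
    gene_scores <- stats::setNames(gene_scores$score, gene_scores$gene)
  nd <- subnetwork$nodes
  if (!nrow(nd)) return(0)
  if (any(nd$parent_out_degree < 1L))
    stop("internal consistency error: zero parent out-degree", call. = FALSE)
  s_r <- unname(gene_scores[nd$gene_id])
  s_r[is.na(s_r)] <- 0
  if (use_abs) s_r <- abs(s_r)
  sum(s_r * nd$edge_confidence / (nd$distance * nd$parent_out_degree))
}

#' Hypergeometric enrichment of a TF's direct targets in DE genes
#'
#' Upper-tail hypergeometric probability of the overlap between the TF's
#' depth-1 TF-DNA targets and a set of differentially expressed genes, in a
#' stated gene universe, returned as -log10(p).
#'
#' @param tf TF identifier.
#' @param edges validated edge list.
#' @param de_genes character vector of DE genes (subset of `universe`).
#' @param universe character vector: the gene universe.
#' @return -log10 upper-tail hypergeometric p-value.
#' @export
direct_target_enrichment <- function(tf, edges, de_genes, universe) {
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe", call. = FALSE)
  e <- edges[edges$kind == "tf_dna" & edges$source == tf, , drop = FALSE]
  targets <- intersect(unique(e$target), universe)
  p <- hypergeometric_overlap(targets, de_genes, universe)
  -log10(p)
}

#' Rank candidate regulators by aggregate sub-score rank
#'
#' Each of the three sub-scores is ranked descending across TFs (rank 1 =
#' largest, ties receive the average rank); the aggregate rank is the sum of
#' the three metric ranks, and TFs are ordered ascending by aggregate rank
#' (smallest = strongest candidate), ties broken by identifier.
#'
#' @param sub_scores data frame with columns `tf`, `m1`, `m2`, `m3`.
#' @return data frame sorted strongest-first with added `rank1`, `rank2`,
#'   `rank3` and `aggregate_rank` columns.
#' @export
rank_regulators <- function(sub_scores) {
  need <- c("tf", "m1", "m2", "m3")
  miss <- setdiff(need, names(sub_scores))
  if (length(miss))
    stop("sub_scores lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(sub_scores[c("m1", "m2", "m3")]))
    stop("every TF needs all three sub-scores", call. = FALSE)
  out <- sub_scores
  out$rank1 <- rank(-out$m1, ties.method = "average")
  out$rank2 <- rank(-out$m2, ties.method = "average")
  out$rank3 <- rank(-out$m3, ties.method = "average")
  out$aggregate_rank <- out$rank1 + out$rank2 + out$rank3
  out <- out[order(out$aggregate_rank, out$tf, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer candidate master regulators from a DE table and a network
#'
#' End-to-end master-regulator inference: genes are scored by sign(log2FC) x
#' -log10(adjusted p), every TF appearing as a TF-DNA source is scored on
#' three metrics — (m1) the network score over its TF-DNA-only subnetwork,
#' (m2) the network score over the combined TF-DNA + PPI subnetwork, (m3)
#' -log10 hypergeometric enrichment of its direct targets among DE-called
#' genes — and TFs are ordered by the aggregate of their per-metric ranks.
#'
#' @param de DE data frame (`gene`, `log2_fc`, `p_value`, `adj_p_value`).
#' @param edges regulatory edge list (see [validate_edges()]).
#' @param max_depth maximum subnetwork depth (default 3).
#' @param fc_threshold,q_threshold thresholds for the DE call feeding m3.
#' @param use_abs use |S_r| in the network score (default signed).
#' @return an object of class `mr_ranking`: the [rank_regulators()] table
#'   plus metadata, with `print` and `summary` methods.
#' @export
master_regulators <- function(de, edges, max_depth = 3L,
                              fc_threshold = 1, q_threshold = 0.05,
                              use_abs = FALSE) {
  de <- score_de_table(de)
  edges <- validate_edges(edges)
  scores <- stats::setNames(de$score, de$gene)
  universe <- de$gene
  calls <- call_differential(de, fc_threshold, q_threshold)
  de_genes <- intersect(c(calls$up, calls$down), universe)
  tfs <- sort(unique(edges$source[edges$kind == "tf_dna"]))
  sub <- lapply(tfs, function(tf) {
    m1 <- network_score(build_subnetwork(tf, edges, max_depth, kinds = "tf_dna"),
                        scores, use_abs)
    m2 <- network_score(build_subnetwork(tf, edges, max_depth, kinds = EDGE_KINDS),
                        scores, use_abs)
    m3 <- direct_target_enrichment(tf, edges, de_genes, universe)
    c(m1 = m1, m2 = m2, m3 = m3)
  })
  tab <- data.frame(tf = tfs, do.call(rbind, sub), stringsAsFactors = FALSE)
  ranking <- rank_regulators(tab)
  structure(list(ranking = ranking,
                 n_tfs = length(tfs),
                 n_de_genes = length(de_genes),
                 n_genes = length(universe),
                 max_depth = max_depth,
                 use_abs = use_abs),
            class = "mr_ranking")
}

#' @export
print.mr_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Master-regulator ranking: %d TFs scored against %d genes (%d DE)\n",
              x$n_tfs, x$n_genes, x$n_de_genes))
  cat(sprintf("Subnetwork depth <= %d; gene scores %s\n\n",
              x$max_depth, if (x$use_abs) "absolute" else "signed"))
  print(utils::head(x$ranking, n), digits = 4)
  if (nrow(x$ranking) > n)
    cat(sprintf("... and %d more TFs\n", nrow(x$ranking) - n))
  invisible(x)
}

#' @export
summary.mr_ranking <- function(object, ...) {
  top <- object$ranking[1L, ]
  cat("Top candidate:", top$tf,
      sprintf("(aggregate rank %.1f; m1=%.3g, m2=%.3g, m3=%.3g)\n",
              top$aggregate_rank, top$m1, top$m2, top$m3))
  invisible(object$ranking)
}

#' Read / write a regulatory edge list
#'
#' Tab-separated with header `source target kind confidence`.
#' @param path file path.
#' @param edges edge data frame.
#' @export
read_edges <- function(path) {
  validate_edges(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_edges
#' @export
write_edges <- function(edges, path) {
  validate_edges(edges)
  utils::write.table(edges[c("source", "target", "kind", "confidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
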
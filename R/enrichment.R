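# Gene-set enrichment: weighted-KS pre-ranked GSEA with a gene-label
# permutation null, single-sample GSEA (rank-weighted ECDF difference),
# hypergeometric overlap and Pearson correlation of pathway scores.

# Running-sum enrichment statistic on an ordered score vector.
# `inset` marks gene-set membership along the ranking (strongest first).
running_es <- function(scores, inset, weight = 1) {
  n <- length(scores)
  nh <- sum(inset)
  w <- abs(scores[inset])^weight
  denom <- sum(w)
  step <- numeric(n)
  # degenerate all-zero in-set scores: fall back to equal hit increments
  step[inset] <- if (denom > 0) w / denom else 1 / nh
  step[!inset] <- -1 / (n - nh)
  cs <- cumsum(step)
  cs[which.max(abs(cs))]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running sum over a ranked gene list:
#' genes in the set increment the sum by |score|^weight (normalised by the
#' in-set total), genes outside decrement by 1/(N - Nh); the enrichment score
#' (ES) is the signed maximum deviation. The null distribution comes from
#' gene-label permutations; NES is the ES divided by the mean |null ES| of
#' matching sign, and the p-value is empirical over same-sign null scores.
#'
#' @param ranked data frame with columns `gene` and `score`, ordered
#'   strongest-upregulated first (see [rank_genes()]).
#' @param gene_set character vector of gene identifiers.
#' @param n_perm number of label permutations (default 1000).
#' @param weight running-sum exponent on |score| (default 1; 0 gives the
#'   unweighted KS statistic).
#' @param seed integer seed for the permutation null.
#' @param set_name label carried into the result.
#' @return data frame with one row: `set_name`, `es`, `nes`, `p_value`,
#'   `fdr_q` (equal to `p_value` for a single set), `n_genes`, `n_hits`.
#' @export
preranked_gsea <- function(ranked, gene_set, n_perm = 1000L, weight = 1,
                           seed = 1L, set_name = "gene_set") {
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  inset <- ranked$gene %in% gene_set
  nh <- sum(inset)
  n <- nrow(ranked)
  if (nh == 0L) stop("gene set has no overlap with the ranked list", call. = FALSE)
  if (nh == n) stop("gene set covers the entire ranked list (degenerate)", call. = FALSE)
  es <- running_es(ranked$score, inset, weight)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- logical(n)
    perm[sample.int(n, nh)] <- TRUE
    running_es(ranked$score, perm, weight)
  }, numeric(1)))
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else {
    warning("no same-sign permutation scores; NES unavailable")
    NA_real_
  }
  data.frame(set_name = set_name, es = es, nes = nes, p_value = p,
             fdr_q = p, n_genes = n, n_hits = nh, stringsAsFactors = FALSE)
}

#' Pre-ranked GSEA over a gene-set collection
#'
#' Runs [preranked_gsea()] for every set and attaches an FDR across sets:
#' either the standard GSEA NES-based procedure (for each set, the fraction
#' of pooled null NES at least as extreme, divided by the fraction of
#' observed NES at least as extreme, capped at 1) or Benjamini-Hochberg on
#' the nominal p-values.
#'
#' @param ranked ranked gene data frame.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param fdr_method `"gsea"` (NES-based) or `"BH"`.
#' @inheritParams preranked_gsea
#' @return data frame with one row per usable set.
#' @export
preranked_gsea_collection <- function(ranked, sets, n_perm = 1000L, weight = 1,
                                      seed = 1L, fdr_method = c("gsea", "BH")) {
  fdr_method <- match.arg(fdr_method)
  res <- vector("list", length(sets))
  nulls <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    inset <- ranked$gene %in% sets[[i]]
    if (sum(inset) < 1L || sum(inset) == nrow(ranked)) {
      warning(sprintf("skipping degenerate set '%s'", nm))
      next
    }
    r <- preranked_gsea(ranked, sets[[i]], n_perm, weight,
                        seed = substream_seed(seed, nm), set_name = nm)
    # reconstruct the same null for the pooled NES-based FDR
    null_es <- with_seed(substream_seed(seed, nm), vapply(seq_len(n_perm), function(j) {
      perm <- logical(nrow(ranked))
      perm[sample.int(nrow(ranked), sum(inset))] <- TRUE
      running_es(ranked$score, perm, weight)
    }, numeric(1)))
    pos <- mean(null_es[null_es >= 0])
    neg <- mean(abs(null_es[null_es < 0]))
    nulls[[i]] <- ifelse(null_es >= 0, null_es / pos, null_es / neg)
    res[[i]] <- r
  }
  keep <- !vapply(res, is.null, logical(1))
  out <- do.call(rbind, res[keep])
  if (is.null(out)) return(out)
  if (fdr_method == "BH") {
    out$fdr_q <- benjamini_hochberg(out$p_value)
  } else {
    pooled <- unlist(nulls[keep])
    pooled <- pooled[is.finite(pooled)]
    out$fdr_q <- vapply(out$nes, function(nes) {
      if (is.na(nes)) return(NA_real_)
      if (nes >= 0) {
        num <- mean(pooled >= nes)
        den <- mean(out$nes >= nes, na.rm = TRUE)
      } else {
        num <- mean(pooled <= nes)
        den <- mean(out$nes <= nes, na.rm = TRUE)
      }
      min(1, if (den > 0) num / den else 1)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Filter an expression matrix for single-sample GSEA
#'
#' Drops genes whose mean FPKM across samples is below 1 and, among rows
#' sharing a gene name, keeps the row with the largest total expression.
#'
#' @param fpkm numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns; values must be nonnegative.
#' @param min_mean minimum row mean to keep a gene (default 1).
#' @return the filtered matrix.
#' @export
prep_expression <- function(fpkm, min_mean = 1) {
  stopifnot(is.matrix(fpkm), !is.null(rownames(fpkm)))
  if (any(fpkm < 0)) stop("expression values must be nonnegative", call. = FALSE)
  fpkm <- fpkm[rowMeans(fpkm) >= min_mean, , drop = FALSE]
  if (anyDuplicated(rownames(fpkm))) {
    tot <- rowSums(fpkm)
    keep <- unlist(tapply(seq_len(nrow(fpkm)), rownames(fpkm),
                          function(ii) ii[which.max(tot[ii])]))
    fpkm <- fpkm[sort(unname(keep)), , drop = FALSE]
  }
  fpkm
}

# ssGSEA statistic for one sample: integrated difference between the
# rank^alpha-weighted in-set ECDF and the unweighted out-set ECDF.
ssgsea_sample_es <- function(x, genes, set, alpha) {
  n <- length(x)
  ord <- order(-x, genes, method = "radix")
  inset <- genes[ord] %in% set
  nh <- sum(inset)
  r <- n:1  # expression rank: highest-expressed gene gets rank n
  w <- r^alpha
  p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  p_out <- cumsum(!inset) / (n - nh)
  sum(p_in - p_out)
}

#' Single-sample GSEA
#'
#' Per-sample pathway activity scores: within each sample genes are ranked by
#' expression and the enrichment score is the integrated difference between
#' the rank^alpha-weighted ECDF of in-set genes and the unweighted ECDF of
#' out-set genes. Raw scores are then min-max normalised across the whole
#' sample-by-set score matrix (unless `normalize = "none"`).
#'
#' @param expr numeric expression matrix (genes x samples) as returned by
#'   [prep_expression()].
#' @param sets named list of gene-identifier vectors.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize `"minmax"` (default) or `"none"`.
#' @return data frame with columns `sample_id`, `set_name`, `es`.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = c("minmax", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  genes <- rownames(expr)
  usable <- vapply(sets, function(s) sum(genes %in% s) >= 2L, logical(1))
  if (any(!usable))
    warning("skipping set(s) with < 2 matrix genes: ",
            paste(names(sets)[!usable], collapse = ", "))
  sets <- sets[usable]
  if (!length(sets)) return(data.frame(sample_id = character(),
                                       set_name = character(), es = numeric()))
  es <- sapply(colnames(expr), function(j)
    vapply(sets, function(s) ssgsea_sample_es(expr[, j], genes, s, alpha),
           numeric(1)))
  es <- matrix(es, nrow = length(sets),
               dimnames = list(names(sets), colnames(expr)))
  if (normalize == "minmax") {
    rng <- range(es)
    if (diff(rng) > 0) es <- (es - rng[1]) / diff(rng)
  }
  data.frame(sample_id = rep(colnames(es), each = nrow(es)),
             set_name = rep(rownames(es), times = ncol(es)),
             es = as.vector(es), stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least the given overlap between two gene sets
#' drawn from a common universe: P(X >= |A intersect B|) with |universe|
#' elements, |A| successes and |B| draws. Symmetric in A and B.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return the upper-tail p-value.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe", call. = FALSE)
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                length(set_b), lower.tail = FALSE)
}

#' Pearson correlation with t-based p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with elements `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Read / write gene sets in GMT format
#'
#' Reading delegates to `fgsea::gmtPathways`; writing emits the standard
#' tab-separated `name  description  gene...` rows.
#'
#' @param path file path.
#' @param sets named list of gene-identifier vectors.
#' @param description description field written for every set.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in GMT", call. = FALSE)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
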
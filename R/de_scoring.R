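# Differential-expression scoring: BH adjustment, signed gene scores,
# significance calling, ranking and mouse->human homolog translation.

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false discovery rate adjustment: p-values are sorted
#' ascending, each multiplied by m/i, a running minimum is taken from the
#' largest rank downwards, and the result capped at 1 and returned in the
#' input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted p-values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Signed gene significance score
#'
#' Computes S = sign(log2 fold-change) * -log10(BH-adjusted p), the signed
#' score used both for ranking genes and for weighting the master-regulator
#' network score. An adjusted p of zero is capped at the smallest positive
#' double before the log, and a zero fold-change yields a score of exactly 0.
#'
#' @param log2_fc numeric vector of log2 fold-changes.
#' @param adj_p numeric vector of BH-adjusted p-values in [0, 1].
#' @return numeric vector of signed scores.
#' @examples
#' gene_score(2, 0.01)    #  2
#' gene_score(-3, 0.001)  # -3
#' @export
gene_score <- function(log2_fc, adj_p) {
  stopifnot(length(log2_fc) == length(adj_p))
  if (anyNA(adj_p) || any(adj_p < 0 | adj_p > 1))
    stop("adjusted p-values must all lie in [0, 1]", call. = FALSE)
  p <- pmax(adj_p, .Machine$double.xmin)
  sign(log2_fc) * -log10(p)
}

#' Score a differential-expression table
#'
#' @param de data frame with columns `gene`, `log2_fc`, `p_value`,
#'   `adj_p_value` (the shape written by [write_de_table()]).
#' @return the table with an added numeric `score` column.
#' @export
score_de_table <- function(de) {
  de <- validate_de_table(de)
  de$score <- gene_score(de$log2_fc, de$adj_p_value)
  de
}

validate_de_table <- function(de) {
  need <- c("gene", "log2_fc", "p_value", "adj_p_value")
  miss <- setdiff(need, names(de))
  if (length(miss))
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(de$gene))
    stop("duplicate gene_id in DE table: ",
         paste(unique(de$gene[duplicated(de$gene)]), collapse = ", "), call. = FALSE)
  de
}

#' Call differentially expressed genes
#'
#' Partitions a DE table into up, down and unchanged gene sets using strict
#' thresholds: |log2 fold-change| > `fc_threshold` and adjusted p <
#' `q_threshold`. The defaults reproduce the usual |log2FC| > 1, q < 0.05
#' calling convention.
#'
#' @param de DE data frame (see [score_de_table()]).
#' @param fc_threshold positive log2 fold-change threshold (strict >).
#' @param q_threshold adjusted-p threshold (strict <).
#' @return list with character vectors `up`, `down`, `unchanged`.
#' @export
call_differential <- function(de, fc_threshold = 1, q_threshold = 0.05) {
  check_positive(fc_threshold, "fc_threshold")
  check_positive(q_threshold, "q_threshold")
  de <- validate_de_table(de)
  up <- de$log2_fc > fc_threshold & de$adj_p_value < q_threshold
  down <- de$log2_fc < -fc_threshold & de$adj_p_value < q_threshold
  list(up = de$gene[up],
       down = de$gene[down],
       unchanged = de$gene[!(up | down)])
}

#' Rank genes by signed score
#'
#' Stable descending order by score; ties are broken lexicographically by
#' gene identifier so the ranking is fully reproducible.
#'
#' @param genes character vector of unique gene identifiers.
#' @param scores numeric scores, parallel to `genes`.
#' @return data frame with columns `gene`, `score`, ordered for pre-ranked
#'   GSEA (strongest up-regulation first).
#' @export
rank_genes <- function(genes, scores) {
  stopifnot(length(genes) == length(scores))
  if (anyDuplicated(genes)) stop("gene identifiers must be unique", call. = FALSE)
  o <- order(-scores, genes, method = "radix")
  data.frame(gene = genes[o], score = scores[o], stringsAsFactors = FALSE)
}

#' Translate gene identifiers through a homolog map
#'
#' Maps (typically mouse) gene identifiers to their (human) homologues using a
#' two-column table. Genes absent from the map are dropped and counted.
#' One-to-many mappings emit every target, flagged in the output; when scores
#' are supplied, many-to-one collisions on the target identifier keep the
#' entry with the largest absolute score.
#'
#' @param genes character vector of source identifiers.
#' @param mapping data frame with columns `mouse_gene`, `human_gene`.
#' @param scores optional numeric vector parallel to `genes`, carried through
#'   and used to resolve collisions.
#' @return list with `translated` (data frame gene/score/one_to_many) and
#'   `n_dropped` (genes without a mapping).
#' @export
map_homologs <- function(genes, mapping, scores = NULL) {
  if (!all(c("mouse_gene", "human_gene") %in% names(mapping)))
    stop("mapping must have columns mouse_gene and human_gene", call. = FALSE)
  if (!is.null(scores)) stopifnot(length(scores) == length(genes))
  hit <- genes %in% mapping$mouse_gene
  n_dropped <- sum(!hit)
  idx <- which(hit)
  rows <- lapply(idx, function(i) {
    targets <- mapping$human_gene[mapping$mouse_gene == genes[i]]
    data.frame(gene = targets,
               score = if (is.null(scores)) NA_real_ else scores[i],
               one_to_many = length(targets) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), score = numeric(), one_to_many = logical())
  if (!is.null(scores) && anyDuplicated(out$gene)) {
    # many-to-one collision: keep the largest |score| per human gene
    keep <- tapply(seq_len(nrow(out)), out$gene, function(ii)
      ii[which.max(abs(out$score[ii]))])
    out <- out[sort(unlist(keep)), , drop = FALSE]
    rownames(out) <- NULL
  }
  list(translated = out, n_dropped = n_dropped)
}

#' Read / write a differential-expression table
#'
#' Tab-separated with header `gene log2_fc p_value adj_p_value`.
#' @param path file path.
#' @param de data frame to write.
#' @return `read_de_table` returns the validated data frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_de_table(de)
}

#' @rdname read_de_table
#' @export
write_de_table <- function(de, path) {
  validate_de_table(de)
  utils::write.table(de[c("gene", "log2_fc", "p_value", "adj_p_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
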
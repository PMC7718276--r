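# Strand-oriented TSS metagene profiles: binned mean ChIP coverage in
# +/- flank windows around the transcription start sites of a gene set.
# All genomic inputs are 0-based half-open (BED/bedGraph convention);
# the TSS of a minus-strand gene is its annotation end.

#' Read / write BED6 gene annotations
#'
#' BED6 (0-based half-open) via rtracklayer; the `name` column holds the
#' gene identifier.
#'
#' @param path file path.
#' @param annotations data frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_bed_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed_annotations
#' @export
write_bed_annotations <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    annotations$chrom,
    IRanges::IRanges(annotations$start + 1L, annotations$end),
    strand = annotations$strand)
  gr$name <- annotations$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write bedGraph coverage
#'
#' 4-column bedGraph (0-based half-open) via rtracklayer. Reading rejects
#' unsorted or overlapping intervals.
#'
#' @param path file path.
#' @param coverage data frame with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    score = gr$score, stringsAsFactors = FALSE)
  validate_bedgraph(cov)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(coverage, path) {
  validate_bedgraph(coverage)
  gr <- GenomicRanges::GRanges(
    coverage$chrom, IRanges::IRanges(coverage$start + 1L, coverage$end),
    score = coverage$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

validate_bedgraph <- function(cov) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(cov)))
  for (chr in unique(cov$chrom)) {
    x <- cov[cov$chrom == chr, , drop = FALSE]
    if (is.unsorted(x$start) || any(x$start[-1] < x$end[-nrow(x)]))
      stop(sprintf("bedGraph intervals on %s are unsorted or overlapping", chr),
           call. = FALSE)
  }
  cov
}

#' Oriented TSS windows for a gene set
#'
#' For each gene the TSS is the annotation start (+ strand) or end
#' (- strand); the window spans `[TSS - flank, TSS + flank)` in genomic
#' coordinates with an orientation flag for minus-strand genes. Genes
#' missing from the annotation are skipped with a warning and counted.
#' Windows may overhang position 0; the overhang is masked during
#' profiling rather than dropped.
#'
#' @param annotations annotation data frame (see [read_bed_annotations()]).
#' @param gene_set character vector of gene identifiers.
#' @param flank half-width of the window in bp (default 15000).
#' @return data frame `gene_id`, `chrom`, `start`, `end`, `strand` with
#'   attribute `n_missing`.
#' @export
tss_windows <- function(annotations, gene_set, flank = 15000L) {
  check_count(flank, "flank", min = 1L)
  hit <- gene_set %in% annotations$gene_id
  if (any(!hit))
    warning(sprintf("%d gene(s) missing from annotation: %s", sum(!hit),
                    paste(gene_set[!hit], collapse = ", ")))
  ann <- annotations[match(gene_set[hit], annotations$gene_id), , drop = FALSE]
  tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  out <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                    start = tss - flank, end = tss + flank,
                    strand = ann$strand, stringsAsFactors = FALSE)
  attr(out, "n_missing") <- sum(!hit)
  rownames(out) <- NULL
  out
}

# Per-base coverage over genomic [start, end), 0-based half-open.
# Positions before 0 are NA (masked); positions past the track end are 0.
window_values <- function(rle_by_chrom, chrom, start, end) {
  n <- end - start
  vals <- rep(NA_real_, n)
  rle <- rle_by_chrom[[chrom]]
  len <- if (is.null(rle)) 0L else length(rle)
  lo <- max(start, 0L)          # first unmasked genomic position
  if (lo >= end) return(vals)
  idx <- (lo - start + 1L):n    # slots for [lo, end)
  v <- numeric(end - lo)        # gaps and overhang past track end are 0
  hi <- min(end, len)
  if (!is.null(rle) && hi > lo)
    v[seq_len(hi - lo)] <- as.numeric(S4Vectors::window(rle, lo + 1L, hi))
  vals[idx] <- v
  vals
}

#' Binned mean coverage profile around TSSs
#'
#' Computes, for each window, per-bin mean coverage (interval-overlap
#' weighted, i.e. exact per-base averaging of the step function), reverses
#' minus-strand windows so every profile reads 5' to 3' of the gene, and
#' averages across genes ignoring masked (chromosome-overhang) positions.
#'
#' @param coverage bedGraph data frame (see [read_bedgraph()]).
#' @param windows window data frame from [tss_windows()].
#' @param bin_size bin width in bp; must divide the window width
#'   (default 300, giving 100 bins across a +/- 15 kb window).
#' @param keep_per_gene keep the per-gene bin matrix in the result.
#' @return object of class `tss_profile`: `offset_bp` (bin start offsets
#'   relative to the TSS, oriented), `mean_density`, `n_genes`, and
#'   optionally `per_gene`.
#' @export
profile_density <- function(coverage, windows, bin_size = 300L,
                            keep_per_gene = FALSE) {
  validate_bedgraph(coverage)
  if (!nrow(windows)) stop("no TSS windows to profile", call. = FALSE)
  width <- unique(windows$end - windows$start)
  stopifnot(length(width) == 1L)
  if (width %% bin_size != 0)
    stop("bin_size must divide the window width", call. = FALSE)
  nbins <- width %/% bin_size
  gr <- GenomicRanges::GRanges(
    coverage$chrom, IRanges::IRanges(coverage$start + 1L, coverage$end))
  cov_rle <- GenomicRanges::coverage(gr, weight = coverage$score)
  per_gene <- matrix(NA_real_, nrow = nrow(windows), ncol = nbins,
                     dimnames = list(windows$gene_id, NULL))
  for (i in seq_len(nrow(windows))) {
    v <- window_values(cov_rle, windows$chrom[i], windows$start[i],
                       windows$end[i])
    if (windows$strand[i] == "-") v <- rev(v)
    per_gene[i, ] <- colMeans(matrix(v, nrow = bin_size), na.rm = TRUE)
  }
  mean_density <- colMeans(per_gene, na.rm = TRUE)
  structure(list(offset_bp = seq(-width / 2, width / 2 - bin_size, by = bin_size),
                 mean_density = mean_density,
                 n_genes = nrow(windows),
                 bin_size = bin_size,
                 per_gene = if (keep_per_gene) per_gene else NULL),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("TSS metagene profile: %d genes, %d bins of %d bp spanning [%d, %d)\n",
              x$n_genes, length(x$offset_bp), x$bin_size,
              min(x$offset_bp), max(x$offset_bp) + x$bin_size))
  cat(sprintf("mean density: min %.3g at %+d bp, max %.3g at %+d bp\n",
              min(x$mean_density), x$offset_bp[which.min(x$mean_density)],
              max(x$mean_density), x$offset_bp[which.max(x$mean_density)]))
  invisible(x)
}

#' @export
plot.tss_profile <- function(x, ..., xlab = "Distance from TSS (bp)",
                             ylab = "Mean coverage", type = "l") {
  graphics::plot(x$offset_bp + x$bin_size / 2, x$mean_density,
                 type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Write a TSS profile as TSV
#'
#' Columns `offset_bp`, `mean_density`, `n_genes`.
#' @param profile a `tss_profile`.
#' @param path output path.
#' @export
write_tss_profile <- function(profile, path) {
  stopifnot(inherits(profile, "tss_profile"))
  utils::write.table(
    data.frame(offset_bp = profile$offset_bp,
               mean_density = profile$mean_density,
               n_genes = profile$n_genes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
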
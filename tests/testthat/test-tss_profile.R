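flat_cov <- function(score = 1, end = 200000L)
  data.frame(chrom = c("chr1", "chr2"), start = 0L, end = end, score = score)

test_that("TSS windows follow strand convention and may overhang zero", {
  ann <- data.frame(gene_id = c("gp", "gm", "near"),
                    chrom = "chr1",
                    start = c(100000L, 40000L, 5000L),
                    end = c(110000L, 50000L, 9000L),
                    strand = c("+", "-", "+"))
  win <- tss_windows(ann, c("gp", "gm", "near"), flank = 15000)
  expect_equal(win$start[win$gene_id == "gp"], 85000)
  expect_equal(win$end[win$gene_id == "gp"], 115000)
  # minus strand: TSS is the annotation end
  expect_equal(win$start[win$gene_id == "gm"], 35000)
  expect_equal(win$end[win$gene_id == "gm"], 65000)
  # window overhanging the chromosome start is kept (masked later)
  expect_equal(win$start[win$gene_id == "near"], -10000)
  expect_warning(w2 <- tss_windows(ann, c("gp", "ghost")), "missing")
  expect_equal(attr(w2, "n_missing"), 1)
})

test_that("uniform coverage gives an exactly flat profile", {
  ann <- simulate_annotations(6)
  win <- tss_windows(ann, ann$gene_id, flank = 15000)
  prof <- profile_density(flat_cov(2.5, end = 500000L), win, bin_size = 300)
  expect_equal(unname(prof$mean_density), rep(2.5, 100))
  expect_equal(prof$n_genes, 6)
})

test_that("half-window coverage is oriented by strand", {
  # coverage 2 on [0, 100000), 0 beyond; windows centred at 100000
  cov <- data.frame(chrom = "chr1", start = 0L, end = 100000L, score = 2)
  ann <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                    start = c(100000L, 90000L), end = c(110000L, 100000L),
                    strand = c("+", "-"))
  win_p <- tss_windows(ann, "plus", flank = 1000)
  prof_p <- profile_density(cov, win_p, bin_size = 100)
  expect_equal(unname(prof_p$mean_density), c(rep(2, 10), rep(0, 10)))
  # same genomic pattern, minus strand: profile mirrored
  win_m <- tss_windows(ann, "minus", flank = 1000)
  prof_m <- profile_density(cov, win_m, bin_size = 100)
  expect_equal(unname(prof_m$mean_density), c(rep(0, 10), rep(2, 10)))
})

test_that("the profile is the per-bin mean across genes", {
  cov <- data.frame(chrom = "chr1",
                    start = c(0L, 100000L), end = c(100000L, 500000L),
                    score = c(4, 8))
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    start = c(50000L, 200000L), end = c(60000L, 210000L),
                    strand = "+")
  win <- tss_windows(ann, c("g1", "g2"), flank = 2000)
  prof <- profile_density(cov, win, bin_size = 200)
  p1 <- profile_density(cov, win[1, ], bin_size = 200)
  p2 <- profile_density(cov, win[2, ], bin_size = 200)
  expect_equal(prof$mean_density, (p1$mean_density + p2$mean_density) / 2)
})

test_that("reversing a gene's strand reverses its bin vector exactly", {
  set.seed(13)
  cov <- data.frame(chrom = "chr1", start = seq(0L, 99800L, 200L),
                    end = seq(200L, 100000L, 200L),
                    score = round(runif(500, 0, 10), 2))
  ann <- data.frame(gene_id = "g", chrom = "chr1", start = 50000L,
                    end = 60000L, strand = "+")
  win_p <- tss_windows(ann, "g", flank = 2000)
  ann$strand <- "-"
  ann$end <- 50000L  # keep the TSS at the same genomic position
  ann$start <- 40000L
  win_m <- tss_windows(ann, "g", flank = 2000)
  p <- profile_density(cov, win_p, bin_size = 100)$mean_density
  m <- profile_density(cov, win_m, bin_size = 100)$mean_density
  expect_equal(unname(m), rev(unname(p)))
})

test_that("profiles scale linearly with the coverage track", {
  set.seed(17)
  cov <- data.frame(chrom = "chr1", start = seq(0L, 99000L, 1000L),
                    end = seq(1000L, 100000L, 1000L),
                    score = round(runif(100, 0, 5), 2))
  ann <- data.frame(gene_id = "g", chrom = "chr1", start = 50000L,
                    end = 51000L, strand = "+")
  win <- tss_windows(ann, "g", flank = 1000)
  base <- profile_density(cov, win, bin_size = 100)$mean_density
  cov3 <- cov; cov3$score <- 3 * cov3$score
  expect_equal(profile_density(cov3, win, bin_size = 100)$mean_density, 3 * base)
})

test_that("interval-weighted bin means match the per-base oracle", {
  set.seed(23)
  for (i in 1:5) {
    breaks <- sort(sample(100:2900, 7))
    cov <- data.frame(chrom = "chr1",
                      start = c(0L, breaks), end = c(breaks, 3000L),
                      score = round(runif(8, 0, 10), 2))
    strand <- sample(c("+", "-"), 1)
    ann <- data.frame(gene_id = "g", chrom = "chr1", start = 1200L,
                      end = 2000L, strand = strand)
    win <- tss_windows(ann, "g", flank = 800)
    got <- profile_density(cov, win, bin_size = 100)$mean_density
    want <- oracle_window_bins(cov, "chr1", win$start, win$end, strand, 100)
    expect_equal(unname(got), want)
  }
})

test_that("windows clipped at the chromosome start are masked, not dropped", {
  cov <- flat_cov(5, end = 50000L)
  ann <- data.frame(gene_id = "g", chrom = "chr1", start = 500L,
                    end = 2000L, strand = "+")
  win <- tss_windows(ann, "g", flank = 1000)
  prof <- profile_density(cov, win, bin_size = 100)
  # first five bins lie entirely before position 0 -> no data
  expect_true(all(is.nan(prof$mean_density[1:5])))
  expect_equal(unname(prof$mean_density[6:20]), rep(5, 15))
  want <- oracle_window_bins(cov, "chr1", -500, 1500, "+", 100)
  expect_equal(unname(prof$mean_density), want)
})

test_that("gaps in the bedGraph count as zero coverage", {
  cov <- data.frame(chrom = "chr1", start = 1000L, end = 1500L, score = 4)
  ann <- data.frame(gene_id = "g", chrom = "chr1", start = 1000L,
                    end = 3000L, strand = "+")
  win <- tss_windows(ann, "g", flank = 500)
  prof <- profile_density(cov, win, bin_size = 500)
  expect_equal(unname(prof$mean_density), c(0, 4))
})

test_that("unsorted or overlapping bedGraph intervals are rejected", {
  bad <- data.frame(chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L),
                    score = 1)
  expect_error(mraxis:::validate_bedgraph(bad), "unsorted or overlapping")
  win <- data.frame(gene_id = "g", chrom = "chr1", start = 0L, end = 600L,
                    strand = "+")
  expect_error(profile_density(bad, win, bin_size = 100), "unsorted")
})

test_that("annotations and coverage round-trip through BED and bedGraph", {
  ann <- simulate_annotations(4)
  cov <- data.frame(chrom = "chr1", start = c(0L, 300L), end = c(300L, 900L),
                    score = c(1.5, 2.25))
  fb <- withr::local_tempfile(fileext = ".bed")
  fg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bed_annotations(ann, fb)
  write_bedgraph(cov, fg)
  expect_equal(read_bed_annotations(fb), ann)
  expect_equal(read_bedgraph(fg), cov)
})
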
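test_that("variant normalisation left-aligns and minimises alleles", {
  v <- make_variants("chr1", 100, "CTT", "CT")
  out <- normalize_variants(v)
  expect_equal(out$ref, "CT")
  expect_equal(out$alt, "C")
  expect_equal(out$pos, 100)
  # shared prefix advances the position
  v <- make_variants("chr1", 200, "AC", "AG")
  out <- normalize_variants(v)
  expect_equal(out[c("pos", "ref", "alt")],
               data.frame(pos = 201, ref = "C", alt = "G"))
  # SNVs are untouched
  v <- make_variants("chr1", 10, "A", "T")
  expect_equal(normalize_variants(v), v)
  expect_error(normalize_variants(make_variants("chr1", 1, "A", "A")), "differ")
})

test_that("two-caller consensus keeps exactly the shared keys", {
  a <- make_variants("chr1", c(100, 200), c("A", "C"), c("T", "G"))
  b <- make_variants("chr1", c(200, 300), c("C", "G"), c("G", "A"),
                     caller = "callerB")
  cons <- consensus_variants(a, b)
  expect_equal(cons$pos, 200)
  expect_equal(cons$caller, "consensus")
  expect_equal(nrow(consensus_variants(a[1, ], b)), 0)        # disjoint
  expect_equal(nrow(consensus_variants(a, a)), 2)             # identical
  # symmetric as key sets and contained in both inputs
  k1 <- mraxis:::variant_key(consensus_variants(a, b))
  k2 <- mraxis:::variant_key(consensus_variants(b, a))
  expect_setequal(k1, k2)
  # representation differences vanish after normalisation
  a2 <- make_variants("chr1", 100, "TGA", "TG")
  b2 <- make_variants("chr1", 100, "TGAC", "TGC", caller = "callerB")
  expect_equal(nrow(consensus_variants(a2, b2)), 1)
})

test_that("unmatched consensus requires every caller/normal pair and the blacklist", {
  v1 <- make_variants("chr1", 100, "A", "T")
  v2 <- make_variants("chr1", 200, "C", "G")
  v3 <- make_variants("chr1", 300, "G", "A")
  both <- rbind(v1, v2, v3)
  calls <- list(
    callerA = list(normal1 = both, normal2 = both),
    callerB = list(normal1 = both, normal2 = rbind(v1, v2)))
  # v3 missing from callerB/normal2 -> dropped; blacklist removes v2
  out <- unmatched_consensus(calls, blacklist = v2[c("chrom", "pos", "ref", "alt")])
  expect_equal(out$pos, 100)
  # without a blacklist v2 survives
  expect_setequal(unmatched_consensus(calls)$pos, c(100, 200))
  # a missing caller/normal combination is a validation error naming the pair
  broken <- calls
  broken$callerB$normal2 <- NULL
  expect_error(unmatched_consensus(broken), "callerB/normal2")
  expect_error(unmatched_consensus(calls["callerA"]), "both callers")
})

test_that("adding normals can only shrink the unmatched consensus", {
  sim <- simulate_variant_calls(variant_sim_config(n_normals = 3, seed = 11))
  sub2 <- lapply(sim$calls, function(x) x[c("normal1", "normal2")])
  sub3 <- sim$calls
  k2 <- mraxis:::variant_key(unmatched_consensus(sub2, sim$blacklist))
  k3 <- mraxis:::variant_key(unmatched_consensus(sub3, sim$blacklist))
  expect_true(all(k3 %in% k2))
})

test_that("somatic filter applies strict coverage and VAF gates", {
  keep <- make_variants("chr1", 1, "A", "T", tumour_depth = 30,
                        tumour_vaf = 0.20, normal_depth = 30, normal_vaf = 0)
  expect_equal(nrow(somatic_filter(keep)), 1)
  # depth exactly 10 fails the strict > gate
  edge <- make_variants("chr1", 1, "A", "T", tumour_depth = 10,
                        tumour_vaf = 0.2, normal_depth = 30, normal_vaf = 0)
  expect_equal(nrow(somatic_filter(edge)), 0)
  # normal VAF above 0.01 fails
  germ <- make_variants("chr1", 1, "A", "T", tumour_depth = 30,
                        tumour_vaf = 0.2, normal_depth = 30, normal_vaf = 0.02)
  expect_equal(nrow(somatic_filter(germ)), 0)
  # tumour VAF gate is inclusive at 0.05
  low <- make_variants("chr1", 1, "A", "T", tumour_depth = 30,
                       tumour_vaf = 0.05, normal_depth = 30, normal_vaf = 0)
  expect_equal(nrow(somatic_filter(low)), 1)
  miss <- keep
  miss$tumour_vaf <- NA
  expect_error(somatic_filter(miss), "chr1:1:A:T")
  expect_error(filter_config(min_tumour_vaf = 0.01, max_normal_vaf = 0.05),
               "max_normal_vaf")
})

test_that("pathway classification distinguishes mutant, wild-type, indeterminate", {
  genes <- c("KRAS", "NF1")
  # damaging variant above both gates -> mutant
  mut <- classify_pathway_status(
    make_variants("chr1", 1, "A", "T", tumour_vaf = 0.3, tumour_depth = 50,
                  gene = "KRAS"), NULL, genes)
  expect_equal(mut$status, "mutant")
  expect_length(mut$evidence, 1)
  # amplification (copies >= 5) -> mutant even without SNVs
  cna <- data.frame(chrom = "chr1", start = 0, end = 1e6, copy_number = 5,
                    gene_overlaps = "KRAS")
  amp <- classify_pathway_status(make_variants("chr9", 5, "A", "T",
                                               gene = "OTHER"), cna, genes)
  expect_equal(amp$status, "mutant")
  # homozygous deletion -> mutant
  del <- cna; del$copy_number <- 0
  expect_equal(classify_pathway_status(make_variants("chr9", 5, "A", "T",
                                                     gene = "OTHER"),
                                       del, genes)$status, "mutant")
  # only a synonymous pathway variant: neither mutant nor variant-free
  syn <- classify_pathway_status(
    make_variants("chr1", 1, "A", "T", tumour_vaf = 0.3, tumour_depth = 50,
                  gene = "KRAS", effect = "synonymous"), NULL, genes)
  expect_equal(syn$status, "indeterminate")
  # sub-threshold damaging variant is likewise indeterminate
  weak <- classify_pathway_status(
    make_variants("chr1", 1, "A", "T", tumour_vaf = 0.1, tumour_depth = 50,
                  gene = "KRAS"), NULL, genes)
  expect_equal(weak$status, "indeterminate")
  # no pathway variants, all copy-neutral -> wild type
  wt <- classify_pathway_status(
    make_variants("chr9", 5, "A", "T", gene = "OTHER"),
    data.frame(chrom = "chr1", start = 0, end = 1e6, copy_number = 2,
               gene_overlaps = "KRAS"), genes)
  expect_equal(wt$status, "wild_type")
  # monotone: adding qualifying evidence never leaves mutant
  more <- classify_pathway_status(
    rbind(make_variants("chr1", 1, "A", "T", tumour_vaf = 0.3,
                        tumour_depth = 50, gene = "KRAS"),
          make_variants("chr2", 2, "C", "G", tumour_vaf = 0.4,
                        tumour_depth = 60, gene = "NF1",
                        effect = "nonsense")), cna, genes)
  expect_equal(more$status, "mutant")
  expect_length(more$evidence, 3)
  expect_error(classify_pathway_status(mut, NULL, character(0)), "empty")
})

test_that("variant records round-trip through VCF v4.2", {
  v <- make_variants("chr3", c(150, 9000), c("A", "CT"), c("G", "C"),
                     tumour_depth = c(55, 80), tumour_vaf = c(0.35, 0.5),
                     normal_depth = c(60, 70), normal_vaf = c(0, 0.01),
                     effect = c("missense", "frameshift"),
                     gene = c("KRAS", "NF1"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(v, f)
  back <- read_variant_vcf(f)
  expect_equal(back[c("chrom", "pos", "ref", "alt", "tumour_depth",
                      "normal_depth", "effect", "gene")],
               v[c("chrom", "pos", "ref", "alt", "tumour_depth",
                   "normal_depth", "effect", "gene")])
  expect_equal(back$tumour_vaf, v$tumour_vaf, tolerance = 1e-4)
  # empty call set round-trips to an empty frame
  write_variant_vcf(v[0, ], f)
  expect_equal(nrow(read_variant_vcf(f)), 0)
})
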
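test_that("network simulation is deterministic and honours its config", {
  cfg <- network_sim_config(n_tfs = 5, n_target_genes = 50, seed = 3)
  e1 <- simulate_network(cfg)
  e2 <- simulate_network(cfg)
  expect_identical(e1, e2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_edges(e1, f1); write_edges(e2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical on disk
  # degenerate confidence range pins every confidence at 1
  cfg1 <- network_sim_config(n_tfs = 5, n_target_genes = 50,
                             confidence_range = c(1, 1), seed = 3)
  expect_true(all(simulate_network(cfg1)$confidence == 1))
  # ppi edges come in mirrored pairs
  ppi <- e1[e1$kind == "ppi", ]
  key <- paste(pmin(ppi$source, ppi$target), pmax(ppi$source, ppi$target))
  expect_true(all(table(key) == 2))
  expect_error(network_sim_config(n_tfs = 0), "n_tfs")
  expect_error(network_sim_config(n_tfs = 10, n_target_genes = 5),
               "n_target_genes")
  expect_error(network_sim_config(confidence_range = c(0.5, 1.2)),
               "confidence_range")
})

test_that("tf-dna edge counts follow the configured Poisson out-degree", {
  # 1 TF, 1 target: the only possible TF-DNA edge is TF001 -> G00001,
  # present with probability 1 - exp(-1) under a Poisson(1) out-degree
  counts <- vapply(1:400, function(s) {
    cfg <- network_sim_config(n_tfs = 1, n_target_genes = 1,
                              tf_dna_out_degree_mean = 1,
                              ppi_degree_mean = 1e-6, seed = s)
    e <- simulate_network(cfg)
    sum(e$kind == "tf_dna")
  }, numeric(1))
  expect_true(all(counts %in% 0:1))
  p_hat <- mean(counts)
  p_true <- 1 - exp(-1)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 400))
})

test_that("planting a null effect leaves planted and background scores alike", {
  cfg <- network_sim_config(n_tfs = 20, n_target_genes = 1000, seed = 5)
  edges <- simulate_network(cfg)
  pl <- plant_regulator(edges, plant_config("TF001", effect_mean = 0, seed = 5))
  planted <- pl$de$gene %in% pl$truth$members$gene_id
  ks <- suppressWarnings(ks.test(pl$de$log2_fc[planted],
                                 pl$de$log2_fc[!planted]))
  expect_gt(ks$p.value, 0.01)
  # p-values are uniform under the null
  ks_u <- suppressWarnings(ks.test(pl$de$p_value, "punif"))
  expect_gt(ks_u$p.value, 0.01)
})

test_that("a strong planted effect separates depth-1 targets from background", {
  diffs <- vapply(1:10, function(s) {
    edges <- simulate_network(network_sim_config(n_tfs = 20,
                                                 n_target_genes = 500,
                                                 seed = s))
    pl <- plant_regulator(edges, plant_config("TF001", effect_mean = 5,
                                              noise_sd = 1, seed = s))
    sc <- score_de_table(pl$de)
    d1 <- pl$truth$members$gene_id[pl$truth$members$distance == 1]
    mean(sc$score[sc$gene %in% d1]) -
      mean(sc$score[!sc$gene %in% pl$truth$members$gene_id])
  }, numeric(1))
  expect_gt(mean(diffs), 3)
})

test_that("planted DE tables are reproducible for a fixed seed", {
  edges <- simulate_network(network_sim_config(n_tfs = 5, n_target_genes = 40,
                                               seed = 2))
  p1 <- plant_regulator(edges, plant_config("TF002", seed = 9))
  p2 <- plant_regulator(edges, plant_config("TF002", seed = 9))
  expect_identical(p1, p2)
  expect_error(plant_regulator(edges, plant_config("NOPE", seed = 9)),
               "not a TF-DNA source")
})

test_that("expression simulation plants a detectable set shift", {
  sets <- list(sig = sprintf("S%02d", 1:20), other = sprintf("O%02d", 1:15))
  m0 <- simulate_expression_matrix(5, sets, "sig", shift = 0, seed = 4)
  expect_true(all(m0 >= 0))
  expect_identical(m0, simulate_expression_matrix(5, sets, "sig", 0, seed = 4))
  grp <- attr(m0, "group")
  t0 <- apply(m0[sets$sig, ], 1, function(x)
    t.test(x[grp == "grp2"], x[grp == "grp1"])$statistic)
  expect_lt(abs(mean(t0)), 1)  # no systematic group difference at shift 0
  # shift 3: ssGSEA scores of the shifted set are higher in group 2
  m3 <- simulate_expression_matrix(5, sets, "sig", shift = 3, seed = 4)
  es <- ssgsea(prep_expression(m3), sets["sig"])
  g <- attr(m3, "group")[match(es$sample_id, colnames(m3))]
  expect_gt(min(es$es[g == "grp2"]), max(es$es[g == "grp1"]))
  expect_error(simulate_expression_matrix(5, sets, "nope", 1), "unknown")
})

test_that("variant simulation places truth, FPs and strain variants as designed", {
  sim <- simulate_variant_calls(variant_sim_config(seed = 21))
  truth_keys <- mraxis:::variant_key(sim$truth)
  all_sets <- unlist(sim$calls, recursive = FALSE)
  # truth is in the intersection of every caller/normal set
  inter <- Reduce(intersect, lapply(all_sets, mraxis:::variant_key))
  expect_true(all(truth_keys %in% inter))
  # blacklist keys are shared too (they mimic strain polymorphisms)
  bl <- mraxis:::variant_key(sim$blacklist)
  expect_true(all(bl %in% inter))
  expect_length(intersect(truth_keys, bl), 0)
  # caller-private false positives are absent from the other caller
  kA <- mraxis:::variant_key(sim$calls$callerA$normal1)
  kB <- mraxis:::variant_key(sim$calls$callerB$normal1)
  expect_length(setdiff(intersect(kA, kB), c(truth_keys, bl)), 0)
  # no confounders: the filter chain returns exactly the truth
  clean <- simulate_variant_calls(variant_sim_config(n_fp_per_caller = 0,
                                                     n_strain_variants = 0,
                                                     seed = 8))
  out <- somatic_filter(unmatched_consensus(clean$calls, clean$blacklist))
  expect_setequal(mraxis:::variant_key(out), mraxis:::variant_key(clean$truth))
  # no true somatics: empty consensus
  none <- simulate_variant_calls(variant_sim_config(n_true_somatic = 0, seed = 8))
  expect_equal(nrow(unmatched_consensus(none$calls, none$blacklist)), 0)
})

test_that("coverage simulation depletes promoters by the configured factor", {
  ann <- simulate_annotations(20)
  depleted <- ann$gene_id[1:10]
  cov <- simulate_coverage(ann, depleted, depletion_factor = 0.2, seed = 6)
  expect_identical(cov, simulate_coverage(ann, depleted, 0.2, seed = 6))
  win_d <- tss_windows(ann, depleted, flank = 1000)
  win_n <- tss_windows(ann, setdiff(ann$gene_id, depleted), flank = 1000)
  mean_d <- mean(profile_density(cov, win_d, 200)$mean_density)
  mean_n <- mean(profile_density(cov, win_n, 200)$mean_density)
  expect_lt(abs(mean_d / mean_n - 0.2), 0.1 * 0.2 + 0.02)
  # depletion factor 0 zeroes the promoter bins entirely
  cov0 <- simulate_coverage(ann, depleted, depletion_factor = 0,
                            noise_sdlog = 0, seed = 6)
  prof0 <- profile_density(cov0, win_d, 200)
  centre <- abs(prof0$offset_bp) < 800
  expect_true(all(prof0$mean_density[centre] == 0))
  expect_error(simulate_coverage(ann, "GHOST", 0.2), "absent")
  expect_error(simulate_coverage(ann, depleted, 1), "depletion_factor")
})
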
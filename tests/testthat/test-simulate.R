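test_that("simulated manifests plant tight CpG clusters and are reproducible", {
  cfg <- sim_config(n_probes = 1200, n_signature_probes = 40, n_clusters = 3,
                    cluster_size = 6, cluster_gap = 150, seed = 3)
  man <- simulate_manifest(cfg)
  expect_equal(nrow(man), 1200)
  cl <- attr(man, "clusters")
  expect_equal(nrow(cl), 3)
  expect_equal(cl$n_cpgs, rep(6, 3))
  expect_true(all(cl$end - cl$start == 750))
  man2 <- simulate_manifest(cfg)
  attr(man, "clusters") <- attr(man2, "clusters") <- NULL
  attr(man, "signature_probes") <- attr(man2, "signature_probes") <- NULL
  expect_identical(man, man2)

  cfg0 <- sim_config(n_probes = 1000, n_signature_probes = 0, n_clusters = 0,
                     cluster_size = 0, n_ref_probes = 100, seed = 1)
  man0 <- simulate_manifest(cfg0)
  expect_equal(nrow(man0), 1000)
  expect_length(attr(man0, "signature_probes"), 0)
})

test_that("cohorts are deterministic, bounded in (0,1), and null at zero effect", {
  cfg <- sim_config(n_probes = 5000, n_signature_probes = 60, effect_bi = 0,
                    n_case_bi = 8, n_case_mono = 8, n_control = 64,
                    n_clusters = 2, cluster_size = 5, seed = 11)
  man <- simulate_manifest(cfg)
  coh <- simulate_cohort(cfg, man)
  coh2 <- simulate_cohort(cfg, man)
  expect_identical(coh$beta, coh2$beta)
  expect_identical(coh$detection_p, coh2$detection_p)
  expect_true(all(coh$beta > 0 & coh$beta < 1))
  d <- mean_beta_difference(coh$beta, coh$samples)
  expect_lt(median(abs(d)), 0.01)
})

test_that("the planted dose structure follows effect_bi and dose_factor", {
  sc <- shared_cohort()
  coh <- sc$cohort
  truth <- coh$truth
  s <- coh$samples
  hyper <- truth$signature_probes[truth$direction == "hyper"]
  bi <- rowMeans(coh$beta[hyper, s$sample_id[s$group == "case_biallelic"]])
  mono <- rowMeans(coh$beta[hyper, s$sample_id[s$group == "case_monoallelic"]])
  ctl <- rowMeans(coh$beta[hyper, s$sample_id[s$group == "control"]])
  # planted beta-scale shifts recovered in the group means (Monte-Carlo)
  expect_lt(abs(mean(bi - ctl) - sc$cfg$effect_bi), 0.02)
  expect_lt(abs(mean(mono - ctl) - sc$cfg$effect_bi * sc$cfg$dose_factor), 0.02)
  # dose_factor = 1 makes the two planted shifts equal in expectation
  cfg1 <- sim_config(n_probes = 3000, n_signature_probes = 100,
                     dose_factor = 1, n_case_bi = 10, n_case_mono = 10,
                     n_control = 20, seed = 5)
  coh1 <- simulate_cohort(cfg1, simulate_manifest(cfg1))
  s1 <- coh1$samples
  hy <- coh1$truth$signature_probes[coh1$truth$direction == "hyper"]
  d_bi <- rowMeans(coh1$beta[hy, s1$sample_id[s1$group == "case_biallelic"]]) -
    rowMeans(coh1$beta[hy, s1$sample_id[s1$group == "control"]])
  d_mono <- rowMeans(coh1$beta[hy, s1$sample_id[s1$group == "case_monoallelic"]]) -
    rowMeans(coh1$beta[hy, s1$sample_id[s1$group == "control"]])
  expect_lt(abs(mean(d_bi) - mean(d_mono)), 0.02)
})

test_that("expected planted shift increases monotonically with effect_bi", {
  shifts <- vapply(c(0.05, 0.10, 0.15, 0.20), function(e) {
    cfg <- sim_config(n_probes = 2000, n_signature_probes = 80, effect_bi = e,
                      n_case_bi = 8, n_case_mono = 0, n_control = 16, seed = 9)
    coh <- simulate_cohort(cfg, simulate_manifest(cfg))
    s <- coh$samples
    hy <- coh$truth$signature_probes[coh$truth$direction == "hyper"]
    mean(rowMeans(coh$beta[hy, s$sample_id[s$group == "case_biallelic"]]) -
           rowMeans(coh$beta[hy, s$sample_id[s$group == "control"]]))
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("simulated expression behaves as a calibrated null and gains power with enrichment", {
  # null: one-tailed rank-sum rejection rate compatible with alpha = 0.05
  rej <- vapply(1:200, function(s) {
    ex <- simulate_expression(paste0("D", 1:40), 200, enrichment = 0, seed = s)
    dg <- unique(ex$gene[ex$is_dmr])
    bg <- unique(ex$gene[!ex$is_dmr])
    compare_expression(dg, bg, ex, "excitatory_neurons")$p_one_tailed < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  # power: strong enrichment detected in nearly all replicates
  pow <- vapply(1:100, function(s) {
    ex <- simulate_expression(paste0("D", 1:40), 200, enrichment = 2, seed = s)
    dg <- unique(ex$gene[ex$is_dmr])
    bg <- unique(ex$gene[!ex$is_dmr])
    compare_expression(dg, bg, ex, "excitatory_neurons")$p_one_tailed < 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.95)
  expect_error(simulate_expression("D1", 0), "background")
})

test_that("disorder cohorts share baselines with the original cohort", {
  sc <- shared_cohort()
  half <- sc$cohort$truth$signature_probes[1:60]
  dis <- simulate_disorder_cohort(sc$cfg, sc$cohort, half, n_cases = 6,
                                  n_controls = 12, effect = 0.15, seed = 4)
  expect_true(all(dis$beta > 0 & dis$beta < 1))
  # control means track the shared per-probe baselines
  base <- beta_unlogit2(sc$cohort$truth$mu)
  ctl <- rowMeans(dis$beta[, dis$samples$group == "control"])
  keep <- setdiff(names(base), sc$cohort$truth$ref_probes)
  expect_gt(cor(base[keep], ctl[keep]), 0.95)
})
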
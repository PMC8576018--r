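test_that("QC removes probes by first matching criterion without double counting", {
  probes <- paste0("cg", 1:8)
  man <- tiny_manifest(probes)
  man$chrom <- c("chr1", "chrX", "chr2", "chrY", "chr3", "chr4", "chr5", "chr6")
  man$snp_flag <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  man$cross_reactive_flag <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  b <- matrix(0.5, 8, 3, dimnames = list(probes, c("a", "b", "c")))
  dp <- matrix(0.001, 8, 3, dimnames = dimnames(b))
  dp["cg2", 2] <- 0.02  # fails detection AND is on chrX: counts as detection
  dp["cg1", 1] <- 0.02
  out <- qc_filter_probes(b, man, dp)
  expect_identical(rownames(out), c("cg3", "cg7", "cg8"))
  rep <- qc_report(out)
  expect_equal(rep$n_removed[rep$criterion == "detection_p"], 2)
  expect_equal(rep$n_removed[rep$criterion == "sex_chromosome"], 1)  # chrY only
  expect_equal(rep$n_removed[rep$criterion == "snp"], 1)
  expect_equal(rep$n_removed[rep$criterion == "cross_reactive"], 1)
  expect_equal(sum(rep$n_removed), 8 - nrow(out))
  # brute-force recount on a random flag matrix
  set.seed(1)
  n <- 1000
  man2 <- tiny_manifest(sprintf("p%04d", 1:n))
  man2$chrom <- sample(c(paste0("chr", 1:5), "chrX"), n, replace = TRUE)
  man2$snp_flag <- runif(n) < 0.05
  man2$cross_reactive_flag <- runif(n) < 0.05
  b2 <- matrix(0.5, n, 2, dimnames = list(man2$probe_id, c("a", "b")))
  dp2 <- matrix(ifelse(runif(2 * n) < 0.03, 0.05, 0.001), n, 2,
                dimnames = dimnames(b2))
  out2 <- qc_filter_probes(b2, man2, dp2)
  keep_oracle <- !(apply(dp2 > 0.01, 1, any) | man2$chrom == "chrX" |
                     man2$snp_flag | man2$cross_reactive_flag)
  expect_identical(rownames(out2), man2$probe_id[keep_oracle])
  expect_equal(sum(qc_report(out2)$n_removed), sum(!keep_oracle))
})

test_that("incomplete probes are dropped and QC/drop order does not matter", {
  probes <- paste0("cg", 1:4)
  b <- tiny_beta(c(0.1, 0.2, NA, 0.4, 0.5, 0.6, 0.7, 0.8), probes[1:4],
                 c("a", "b"))
  out <- drop_incomplete(b)
  expect_identical(rownames(out), c("cg1", "cg3", "cg4"))
  expect_identical(drop_incomplete(out), out)
  expect_warning(drop_incomplete(b[2, , drop = FALSE] * NA), "missing")

  man <- tiny_manifest(probes)
  man$chrom[2] <- "chrX"
  a1 <- drop_incomplete(qc_filter_probes(b, man))
  a2 <- qc_filter_probes(drop_incomplete(b), man)
  expect_identical(rownames(a1), rownames(a2))
})

test_that("beta/M transform matches the clipped logit and inverts exactly", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0), -9.964341, tolerance = 1e-6)
  x <- seq(0.002, 0.998, length.out = 101)
  expect_equal(m_to_beta(beta_to_m(x)), x, tolerance = 1e-12)
  expect_true(is.na(beta_to_m(NA)))
})

test_that("control matching is greedy nearest-age with deterministic tie-breaks", {
  cases <- tibble::tibble(sample_id = "case1", group = "case_biallelic",
                          age_years = 30, sex = "F", batch = "b")
  pool <- tibble::tibble(
    sample_id = c("F30", "F31", "F50", "M30"),
    group = "control", age_years = c(30, 31, 50, 30),
    sex = c("F", "F", "F", "M"), batch = "b")
  expect_setequal(match_controls(cases, pool, ratio = 2), c("F30", "F31"))
  expect_error(match_controls(cases, pool, ratio = 5), "case1")
  expect_error(suppressWarnings(
    match_controls(cases, pool[pool$sex == "M", ], ratio = 1)), "case1")
  # equal ages: tie broken by id, stable across runs
  pool2 <- tibble::tibble(sample_id = c("c3", "c1", "c2"), group = "control",
                          age_years = 30, sex = "F", batch = "b")
  expect_identical(match_controls(cases, pool2, ratio = 2), c("c1", "c2"))
  expect_identical(match_controls(cases, pool2, ratio = 2),
                   match_controls(cases, pool2, ratio = 2))
  # age gap beyond the limit warns
  expect_warning(match_controls(cases, pool, ratio = 3, max_age_gap = 10),
                 "age gap")
})

test_that("PCA screening flags a far-shifted sample and only that sample", {
  set.seed(21)
  m <- matrix(rnorm(50 * 21), 50, 21,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:21)))
  m[, 21] <- m[, 21] + 10
  flags <- pca_outlier_check(m)
  expect_identical(flags$sample_id[flags$outlier], "s21")
  m0 <- matrix(0.3, 10, 5, dimnames = list(paste0("p", 1:10), paste0("s", 1:5)))
  expect_false(any(pca_outlier_check(m0)$outlier))
  expect_false(any(pca_outlier_check(m, z_cut = Inf)$outlier))
})

test_that("deconvolution recovers exact mixtures and stays on the simplex", {
  set.seed(7)
  ref <- matrix(runif(200 * 4, 0.05, 0.95), 200, 4,
                dimnames = list(sprintf("p%03d", 1:200), paste0("ct", 1:4)))
  b <- cbind(pure2 = ref[, 2], mix = 0.6 * ref[, 1] + 0.4 * ref[, 2])
  rownames(b) <- rownames(ref)
  est <- estimate_cell_proportions(b, ref)
  expect_equal(unlist(est[1, paste0("ct", 1:4)]), c(ct1 = 0, ct2 = 1, ct3 = 0, ct4 = 0),
               tolerance = 1e-6)
  expect_equal(unlist(est[2, paste0("ct", 1:4)]), c(ct1 = 0.6, ct2 = 0.4, ct3 = 0, ct4 = 0),
               tolerance = 1e-6)
  # noisy mixtures: proportions recovered within 0.05 and on the simplex
  w <- matrix(c(0.5, 0.2, 0.2, 0.1, 0.25, 0.25, 0.25, 0.25), 2, byrow = TRUE)
  noisy <- t(w %*% t(ref)) + matrix(rnorm(400, 0, 0.02), 200, 2)
  colnames(noisy) <- c("m1", "m2")
  est2 <- estimate_cell_proportions(pmin(pmax(noisy, 0), 1), ref)
  p <- as.matrix(est2[, paste0("ct", 1:4)])
  expect_lt(max(abs(p - w)), 0.05)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)
  expect_error(estimate_cell_proportions(b[1:3, ], ref[1:3, ]), "shared|common|probes")
})

test_that("global statistics reproduce medians, KS D and perfect-identity cases", {
  probes <- paste0("cg", 1:3)
  s <- tiny_samples(1, 1, 1)
  b <- tiny_beta(c(0.9, 0.9, 0.5,
                   0.7, 0.6, 0.5,
                   0.2, 0.3, 0.1), probes, s$sample_id)
  gs <- global_methylation_stats(b, s)
  expect_equal(gs$group_summary$median_beta,
               c(median(b[, 1]), median(b[, 2]), median(b[, 3])))
  # identical difference vectors give D = 0
  b2 <- b; b2[, 2] <- b2[, 1]
  gs2 <- global_methylation_stats(b2, s)
  expect_equal(gs2$ks_D, 0)
  # bi equal to control gives equal summaries and r = 1 within bi vs ctrl
  b3 <- b; b3[, 1] <- b3[, 3]
  gs3 <- global_methylation_stats(b3, s)
  sm <- gs3$group_summary
  expect_equal(sm$median_beta[sm$group == "case_biallelic"],
               sm$median_beta[sm$group == "control"])
  expect_error(global_methylation_stats(b, s[s$group != "control", ]),
               "control")
})

test_that("KS D equals the ECDF-step enumeration oracle on random instances", {
  expect_equal(ks_oracle(c(1, 3), c(2, 4)), 0.5)
  set.seed(33)
  for (i in 1:100) {
    a <- rnorm(sample(3:15, 1))
    b <- rnorm(sample(3:15, 1), mean = runif(1, -1, 1))
    D <- suppressWarnings(ks.test(a, b)$statistic)
    expect_equal(unname(D), ks_oracle(a, b), tolerance = 1e-9)
  }
})
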
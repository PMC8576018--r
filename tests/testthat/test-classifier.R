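test_that("MVP training separates a separable cohort and is a pure function", {
  sc <- shared_cohort()
  coh <- sc$cohort
  sig <- discover_signature(coh$beta, coh$samples)
  model <- train_mvp(coh$beta, coh$samples, sig)
  tr <- model$training_scores
  expect_true(all(tr$mvp[tr$group != "control"] > 0.5))
  expect_true(all(tr$mvp[tr$group == "control"] < 0.5))
  # scoring the training set reproduces the training-time scores exactly
  sc1 <- score_mvp(model, coh$beta[, tr$sample_id])
  expect_equal(sc1$mvp, tr$mvp, tolerance = 1e-12)
  # duplicated sample gets an identical score; order does not matter
  dup <- coh$beta[, c(tr$sample_id[3], tr$sample_id)]
  colnames(dup)[1] <- "copy"
  sc2 <- score_mvp(model, dup)
  expect_equal(sc2$mvp[1], sc1$mvp[3], tolerance = 1e-12)
  perm <- sample(ncol(coh$beta))
  sc3 <- score_mvp(model, coh$beta[, perm])
  expect_equal(sc3$mvp[match(sc1$sample_id, sc3$sample_id)], sc1$mvp,
               tolerance = 1e-12)
  # missing probes are an error naming them
  expect_error(score_mvp(model, coh$beta[-match(model$probes[1], rownames(coh$beta)), ]),
               model$probes[1])
})

test_that("dose ordering is recovered across a dose_factor grid", {
  meds <- purrr::map_dfr(c(0.3, 0.5, 0.7), function(dose) {
    purrr::map_dfr(1:2, function(rep) {
      cfg <- sim_config(n_probes = 1500, n_signature_probes = 80,
                        dose_factor = dose, n_case_bi = 6, n_case_mono = 6,
                        n_control = 24, n_ref_probes = 100,
                        seed = 100 * rep + round(10 * dose))
      coh <- simulate_cohort(cfg, simulate_manifest(cfg))
      sig <- discover_signature(coh$beta, coh$samples)
      model <- train_mvp(coh$beta, coh$samples, sig)
      sc <- dplyr::left_join(score_mvp(model, coh$beta), coh$samples,
                             by = "sample_id")
      out <- dplyr::summarise(dplyr::group_by(sc, group),
                              med = median(mvp), .groups = "drop")
      out$dose <- dose; out$rep <- rep
      out
    })
  })
  wide <- tidyr::pivot_wider(meds, names_from = "group", values_from = "med")
  expect_true(all(wide$case_biallelic > wide$case_monoallelic))
  expect_true(all(wide$case_monoallelic > wide$control))
})

test_that("randomly relabelled cohorts produce uninformative held-out scores", {
  set.seed(19)
  reps <- purrr::map_dbl(1:20, function(r) {
    n <- 40
    x <- matrix(rnorm(n * 20), n, 20)
    rownames(x) <- paste0("s", 1:n)
    is_case <- rep(c(TRUE, FALSE), each = n / 2)
    train <- c(sample(which(is_case), 15), sample(which(!is_case), 15))
    fit <- episignr:::fit_binary_mvp(x[train, ], is_case[train])
    f <- episignr:::decision_values(fit$svm, x[-train, ])
    mean(episignr:::mvp_sigmoid(f, fit$A, fit$B))
  })
  expect_gt(mean(reps), 0.35)
  expect_lt(mean(reps), 0.65)
})

test_that("one-against-all models separate syndromes and self-score highest", {
  sc <- shared_cohort()
  coh <- sc$cohort
  sig_probes <- coh$truth$signature_probes
  other <- simulate_disorder_cohort(sc$cfg, coh, setdiff(rownames(coh$beta),
                                                         c(sig_probes, coh$truth$ref_probes))[1:120],
                                    n_cases = 8, n_controls = 0,
                                    effect = 0.15, seed = 23)
  beta_all <- cbind(coh$beta, other$beta)
  cohorts <- tibble::tibble(
    sample_id = c(coh$samples$sample_id, other$samples$sample_id),
    cohort = c(ifelse(coh$samples$group == "control", "control", "TET3"),
               rep("OTHER", nrow(other$samples)))
  )
  mm <- train_multiclass(beta_all, cohorts, sig_probes, seed = 2)
  ho <- mm$held_out
  tet3_model <- ho[ho$class == "TET3", ]
  expect_lt(max(tet3_model$mvp[tet3_model$cohort == "OTHER"]), 0.2)
  expect_lt(max(tet3_model$mvp[tet3_model$cohort == "control"]), 0.2)
  expect_gt(min(tet3_model$mvp[tet3_model$cohort == "TET3"]), 0.5)
  # each model scores its own training cases at least as high as any other cohort
  for (cl in names(mm$models)) {
    tr <- mm$training_scores[mm$training_scores$class == cl, ]
    own <- mean(tr$mvp[tr$cohort == cl])
    rest <- tapply(tr$mvp[tr$cohort != cl], tr$cohort[tr$cohort != cl], mean)
    expect_true(all(own >= rest))
  }
  # split bookkeeping and the degenerate train_frac guard
  expect_error(train_multiclass(beta_all, cohorts, sig_probes, train_frac = 1),
               "test sample")
  small <- cohorts[c(1:3, which(cohorts$cohort == "control")[1:8]), ]
  expect_error(train_multiclass(beta_all, small, sig_probes), "too small")
})

test_that("classical MDS reproduces exact 2-D geometry deterministically", {
  # 3 points with pairwise distances 3-4-5 are exactly 2-D embeddable
  b <- matrix(c(0, 0, 3, 0, 0, 4), nrow = 2,
              dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  emb <- mds_embed(b, c("f1", "f2"))
  pts <- as.matrix(emb$points[, c("MDS1", "MDS2")])
  d <- as.numeric(dist(pts))
  expect_equal(sort(d), c(3, 4, 5), tolerance = 1e-9)
  # coordinates centered at the origin
  expect_equal(colSums(pts), c(MDS1 = 0, MDS2 = 0), tolerance = 1e-9)
  # identical samples land on identical coordinates; reruns are identical
  b2 <- cbind(b, d = b[, "a"])
  emb2 <- mds_embed(b2, c("f1", "f2"))
  p2 <- as.matrix(emb2$points[, c("MDS1", "MDS2")])
  expect_equal(p2[1, ], p2[4, ], tolerance = 1e-12)
  expect_identical(mds_embed(b2, c("f1", "f2"))$points, emb2$points)
})

test_that("Ward clustering separates planted groups and has n-1 merges", {
  sc <- shared_cohort()
  coh <- sc$cohort
  s <- coh$samples
  ids <- s$sample_id[s$group %in% c("case_biallelic", "control")]
  hc <- hcluster(coh$beta[, ids], coh$truth$signature_probes)
  expect_equal(nrow(hc$tree$merge), length(ids) - 1)
  part <- cut_clusters(hc, 2)
  grp <- s$group[match(ids, s$sample_id)]
  tab <- table(part, grp)
  # one cluster is exactly the bi-allelic cases
  expect_true(any(tab["1", ] == 0) || any(tab["2", ] == 0))
  agree <- max(sum(diag(tab)), sum(diag(tab[2:1, ])))
  expect_equal(agree, length(ids))
  expect_setequal(hc$leaf_order, ids)
})
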
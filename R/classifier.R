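# Supervised MVP (methylation variant pathogenicity) scoring with a
# linear-kernel SVM and deterministic sigmoid (Platt) calibration, plus the
# unsupervised structure checks: classical MDS and Ward clustering.

# Platt sigmoid calibration (Newton iterations with backtracking, using
# prior-corrected targets). Deterministic: fitted on the training decision
# values, no resampling.
platt_scale <- function(f, y) {
  prior1 <- sum(y); prior0 <- sum(!y)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  Fv <- fval(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p                     # dF/dz per point
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newF <- fval(newA, newB)
      if (newF < Fv + 1e-4 * step * (g1 * dA + g2 * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    Fv <- fval(A, B)
  }
  list(A = A, B = B)
}

# Linear-kernel SVM with inverse-frequency class weights; returns the model
# plus the sigmoid calibration fitted on the oriented training decision
# values (positive = case).
fit_binary_mvp <- function(x, is_case, cost = 1) {
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    abort("need at least 2 samples in each class")
  }
  y <- factor(ifelse(is_case, "case", "control"), levels = c("case", "control"))
  n <- length(y)
  cw <- c(case = n / (2 * sum(is_case)), control = n / (2 * sum(!is_case)))
  model <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                      scale = FALSE, class.weights = cw)
  f <- decision_values(model, x)
  cal <- platt_scale(f, is_case)
  list(svm = model, A = cal$A, B = cal$B)
}

# Decision values oriented so that larger means more case-like.
decision_values <- function(model, x) {
  dv <- attr(stats::predict(model, x, decision.values = TRUE),
             "decision.values")
  f <- as.numeric(dv[, 1])
  # e1071 names the column "<positive>/<negative>"; flip if the positive
  # side is the control class
  if (startsWith(colnames(dv)[1], "control/")) f <- -f
  f
}

mvp_sigmoid <- function(f, A, B) 1 / (1 + exp(A * f + B))

#' Train an MVP scoring model
#'
#' Fits a linear-kernel support vector machine on the beta values of the
#' signature probes (cases versus controls, inverse-frequency class
#' weights) and calibrates its decision values to `[0, 1]` MVP scores with
#' a Platt sigmoid. The fit is deterministic: no resampling is involved.
#'
#' @param beta Probes-by-samples beta matrix containing the training
#'   samples.
#' @param samples Sample sheet for the training samples.
#' @param signature An `episignature` (or character vector of probe ids).
#' @param case_groups Group labels forming the positive class.
#' @param cost SVM cost parameter.
#' @return An object of class `mvp_model`, carrying the signature probes,
#'   the fitted machine, calibration constants and the training scores.
#' @export
train_mvp <- function(beta, samples, signature,
                      case_groups = case_groups_default, cost = 1) {
  probes <- if (inherits(signature, "episignature"))
    signature$probes$probe_id else signature
  miss <- setdiff(probes, rownames(beta))
  if (length(miss) > 0) {
    abort(sprintf("signature probe(s) missing from beta matrix: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  ids <- samples$sample_id[samples$group %in% c(case_groups, "control")]
  x <- t(beta[probes, ids, drop = FALSE])
  if (anyNA(x)) abort("missing beta values among signature probes for training samples")
  is_case <- samples$group[match(ids, samples$sample_id)] %in% case_groups
  fit <- fit_binary_mvp(x, is_case, cost)
  f <- decision_values(fit$svm, x)
  training_scores <- tibble(
    sample_id = ids,
    group = samples$group[match(ids, samples$sample_id)],
    mvp = mvp_sigmoid(f, fit$A, fit$B)
  )
  structure(list(probes = probes, svm = fit$svm, A = fit$A, B = fit$B,
                 cost = cost, case_groups = case_groups,
                 training_scores = training_scores),
            class = "mvp_model")
}

#' Score samples with an MVP model
#'
#' Applies a trained [train_mvp()] model to new samples, returning the
#' calibrated pathogenicity score in `[0, 1]` and an interpretation band.
#' The default bands are reporting conventions, not fitted thresholds:
#' below `bands[1]` the sample is signature-negative, at or above
#' `bands[2]` signature-positive, in between intermediate.
#'
#' @param model An `mvp_model`.
#' @param beta Probes-by-samples beta matrix; every signature probe must be
#'   present and non-missing for every sample scored.
#' @param bands Two interpretation cut points.
#' @return Tibble with `sample_id`, `mvp`, `band`.
#' @export
score_mvp <- function(model, beta, bands = c(0.2, 0.5)) {
  miss <- setdiff(model$probes, rownames(beta))
  if (length(miss) > 0) {
    abort(sprintf("signature probe(s) missing from beta matrix: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  x <- t(beta[model$probes, , drop = FALSE])
  if (anyNA(x)) {
    bad <- model$probes[colSums(is.na(t(x))) > 0]
    abort(sprintf("missing beta values at signature probe(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  f <- decision_values(model$svm, x)
  mvp <- mvp_sigmoid(f, model$A, model$B)
  tibble(
    sample_id = colnames(beta),
    mvp = mvp,
    band = case_when(
      mvp < bands[1] ~ "signature_negative",
      mvp >= bands[2] ~ "signature_positive",
      TRUE ~ "intermediate"
    )
  )
}

#' Train one-against-all multi-syndrome MVP models
#'
#' For each syndrome cohort, trains a binary model of that cohort against
#' every other sample (other syndromes plus controls) on the signature
#' probes, using a stratified 75/25 train/test split per cohort, and scores
#' the held-out samples with every model.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param cohorts Tibble with `sample_id` and `cohort` (controls labelled
#'   `"control"`); every cohort needs at least 4 samples so the split
#'   leaves a test sample.
#' @param signature An `episignature` or probe-id vector.
#' @param train_frac Fraction of each cohort used for training; must leave
#'   at least one test sample per cohort.
#' @param seed Integer seed driving the stratified split.
#' @param cost SVM cost parameter.
#' @return An object of class `multiclass_mvp`: per-class models, the
#'   train/test assignment, and held-out scores (`sample_id`, `cohort`,
#'   `class`, `mvp`).
#' @export
train_multiclass <- function(beta, cohorts, signature, train_frac = 0.75,
                             seed = 1, cost = 1) {
  probes <- if (inherits(signature, "episignature"))
    signature$probes$probe_id else signature
  counts <- table(cohorts$cohort)
  if (any(counts < 4)) {
    abort(sprintf("cohort(s) too small for a %d%%/%d%% split: %s",
                  round(train_frac * 100), round((1 - train_frac) * 100),
                  paste(names(counts)[counts < 4], collapse = ", ")))
  }
  split <- with_seed(seed, {
    purrr::map_dfr(names(counts), function(co) {
      ids <- cohorts$sample_id[cohorts$cohort == co]
      n_train <- floor(train_frac * length(ids))
      if (n_train >= length(ids)) {
        abort(sprintf("train_frac = %g leaves no test sample for cohort '%s'",
                      train_frac, co))
      }
      train_ids <- sample(ids, n_train)
      tibble(sample_id = ids, cohort = co,
             role = ifelse(ids %in% train_ids, "train", "test"))
    })
  })
  train <- split[split$role == "train", ]
  test <- split[split$role == "test", ]
  x_train <- t(beta[probes, train$sample_id, drop = FALSE])
  x_test <- t(beta[probes, test$sample_id, drop = FALSE])
  classes <- setdiff(names(counts), "control")
  models <- lapply(setNames(classes, classes), function(cl) {
    fit_binary_mvp(x_train, train$cohort == cl, cost)
  })
  held_out <- purrr::map_dfr(classes, function(cl) {
    fit <- models[[cl]]
    f <- decision_values(fit$svm, x_test)
    tibble(sample_id = test$sample_id, cohort = test$cohort, class = cl,
           mvp = mvp_sigmoid(f, fit$A, fit$B))
  })
  training_scores <- purrr::map_dfr(classes, function(cl) {
    fit <- models[[cl]]
    f <- decision_values(fit$svm, x_train)
    tibble(sample_id = train$sample_id, cohort = train$cohort, class = cl,
           mvp = mvp_sigmoid(f, fit$A, fit$B))
  })
  structure(list(models = models, probes = probes, split = split,
                 held_out = held_out, training_scores = training_scores,
                 seed = seed),
            class = "multiclass_mvp")
}

#' Classical MDS embedding of samples
#'
#' Torgerson metric multidimensional scaling of the pairwise Euclidean
#' distances between samples over the signature probes. Coordinates are
#' centered at the origin; the sign of each axis is fixed by forcing its
#' largest-magnitude coordinate positive, so the embedding is fully
#' deterministic.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param probes Signature probe ids.
#' @param k Number of dimensions (default 2).
#' @return List of class `epi_mds` with `points` (tibble `sample_id`,
#'   `MDS1`, `MDS2`, ...) and the eigenvalues.
#' @export
mds_embed <- function(beta, probes, k = 2) {
  if (ncol(beta) < 3) abort("need at least 3 samples for MDS")
  d <- dist(t(beta[probes, , drop = FALSE]))
  fit <- cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  points <- as_tibble(pts, .name_repair = ~ paste0("MDS", seq_len(k)))
  points <- dplyr::bind_cols(tibble(sample_id = colnames(beta)), points)
  structure(list(points = points, eig = fit$eig), class = "epi_mds")
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distances over the
#' signature probes with Ward linkage (the `ward.D2` criterion, which
#' applies Ward's minimum-variance rule to Euclidean distances).
#'
#' @param beta Probes-by-samples beta matrix.
#' @param probes Signature probe ids.
#' @param linkage `"ward"` (default), `"complete"` or `"average"`.
#' @return List of class `epi_hclust` with the `hclust` tree, the leaf
#'   order (sample ids left to right) and a `cut(k)` helper via
#'   [stats::cutree()].
#' @export
hcluster <- function(beta, probes, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  if (ncol(beta) < 2) abort("need at least 2 samples to cluster")
  method <- c(ward = "ward.D2", complete = "complete", average = "average")[linkage]
  d <- dist(t(beta[probes, , drop = FALSE]))
  tree <- hclust(d, method = method)
  structure(list(tree = tree, leaf_order = tree$labels[tree$order],
                 linkage = linkage),
            class = "epi_hclust")
}

#' Cut a sample dendrogram into k clusters
#' @param x An `epi_hclust`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster assignments.
#' @export
cut_clusters <- function(x, k = 2) cutree(x$tree, k = k)
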
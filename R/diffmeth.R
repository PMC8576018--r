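# Per-probe linear modelling on M-values with composition covariates,
# empirical-Bayes variance moderation, BH adjustment and beta-scale effect
# sizes.

case_groups_default <- c("case_biallelic", "case_monoallelic")

# Build the per-sample design matrix: intercept, pooled case indicator,
# and k-1 composition columns (the last cell type is dropped because
# proportions sum to one).
build_design <- function(samples, sample_ids, covariates = NULL,
                         case_groups = case_groups_default) {
  idx <- match(sample_ids, samples$sample_id)
  if (anyNA(idx)) abort("sample(s) in the matrix missing from the sample sheet")
  grp <- as.numeric(samples$group[idx] %in% case_groups)
  X <- cbind(intercept = 1, group = grp)
  if (!is.null(covariates)) {
    if (is_tibble(covariates) || is.data.frame(covariates)) {
      ci <- match(sample_ids, covariates$sample_id)
      if (anyNA(ci)) abort("covariate rows missing for some samples")
      cols <- setdiff(names(covariates), c("sample_id", "residual_norm"))
      cov_mat <- as.matrix(covariates[ci, cols, drop = FALSE])
    } else {
      cov_mat <- as.matrix(covariates)[sample_ids, , drop = FALSE]
    }
    # drop one column: simplex-constrained proportions are collinear with
    # the intercept
    if (ncol(cov_mat) > 1) cov_mat <- cov_mat[, -ncol(cov_mat), drop = FALSE]
    X <- cbind(X, cov_mat)
  }
  X
}

#' Fit per-probe linear models on M-values
#'
#' Ordinary least squares of each probe's M-values on an intercept, a
#' pooled case indicator (bi- and mono-allelic carriers coded 1, controls
#' 0) and optional cell-composition covariates (one column dropped to avoid
#' collinearity with the intercept). Returns the per-probe quantities the
#' empirical-Bayes moderation needs.
#'
#' @param m Probes-by-samples M-value matrix without missing values.
#' @param samples Sample sheet covering the matrix columns.
#' @param covariates Optional per-sample covariates: the tibble returned by
#'   [estimate_cell_proportions()] or a sample-by-covariate matrix.
#' @param case_groups Group labels pooled as "case".
#' @return A list of class `probe_fit`: tibble `stats` (`probe_id`, `coef`,
#'   `s2`, `df`, `std_unscaled`), the design matrix, and bookkeeping.
#' @export
fit_probe_models <- function(m, samples, covariates = NULL,
                             case_groups = case_groups_default) {
  if (anyNA(m)) abort("M-value matrix contains missing values; run drop_incomplete() first")
  X <- build_design(samples, colnames(m), covariates, case_groups)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  n <- nrow(X)
  df <- n - ncol(X)
  if (df < 1) abort("no residual degrees of freedom")
  Y <- t(m)
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  stdu <- sqrt(xtx_inv[2, 2])
  structure(list(
    stats = tibble(probe_id = rownames(m),
                   coef = unname(coefs["group", ]),
                   s2 = unname(s2),
                   df = df,
                   std_unscaled = stdu),
    design = X,
    case_groups = case_groups
  ), class = "probe_fit")
}

#' Moderate per-probe statistics by empirical Bayes
#'
#' Shrinks per-probe residual variances toward a pooled prior estimated by
#' moment matching on the log variances: with prior degrees of freedom `d0`
#' and prior variance `s0^2`, the posterior variance is
#' `(d0 * s0^2 + df * s2) / (d0 + df)` and the moderated t-statistic uses
#' `d0 + df` degrees of freedom (`d0 = Inf` gives a normal reference).
#'
#' @param fit A `probe_fit` from [fit_probe_models()].
#' @param d0_override Optional forced prior df: `0` recovers the ordinary
#'   t-statistic, `Inf` the pooled-variance z-statistic.
#' @return Tibble with `probe_id`, `coef`, `t_mod`, `p_raw`; the estimated
#'   `d0` and `s0_sq` are attached as attributes.
#' @export
moderate_statistics <- function(fit, d0_override = NULL) {
  st <- fit$stats
  if (nrow(st) < 10 && is.null(d0_override)) {
    abort("need at least 10 probes to estimate the variance prior")
  }
  s2 <- st$s2
  if (all(s2 == 0)) abort("all residual variances are zero; nothing to moderate")
  if (any(s2 <= 0)) {
    warn("nonpositive residual variances floored at 1e-300 for prior estimation")
    s2 <- pmax(s2, 1e-300)
  }
  df <- st$df
  if (is.null(d0_override)) {
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      warn("log-variance moments admit no positive prior df; using d0 = Inf")
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  } else {
    d0 <- d0_override
    s0_sq <- if (is.finite(d0) && d0 > 0) exp(mean(log(s2))) else
      if (is.infinite(d0)) exp(mean(log(s2))) else NA_real_
  }
  if (d0 == 0) {
    s2_tilde <- s2
    df_total <- df
  } else if (is.infinite(d0)) {
    s2_tilde <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_tilde <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  t_mod <- st$coef / (sqrt(s2_tilde) * st$std_unscaled)
  p_raw <- ifelse(is.infinite(df_total),
                  2 * pnorm(-abs(t_mod)),
                  2 * pt(-abs(t_mod), df_total))
  out <- tibble(probe_id = st$probe_id, coef = st$coef,
                t_mod = t_mod, p_raw = p_raw)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values; Bonferroni and
#' Holm are available as alternatives.
#'
#' @param p_raw Vector of p-values in `[0, 1]`.
#' @param method Adjustment procedure.
#' @return Adjusted p-values, same order as input.
#' @export
adjust_bh <- function(p_raw, method = c("BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p_raw, method = method)
}

#' Per-probe mean beta difference
#'
#' Mean beta over case samples minus mean over controls, computed on the
#' beta scale (the effect-size threshold of the selection cascade is stated
#' in methylation-fraction units). Missing values are excluded per probe; a
#' probe with no case or no control measurement gets `NA`.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet.
#' @param case_groups Group labels pooled as "case".
#' @return Named numeric vector of differences, one per probe.
#' @export
mean_beta_difference <- function(beta, samples,
                                 case_groups = case_groups_default) {
  case_ids <- samples$sample_id[samples$group %in% case_groups]
  ctl_ids <- samples$sample_id[samples$group == "control"]
  if (length(case_ids) == 0 || length(ctl_ids) == 0) {
    abort("both case and control groups must be non-empty")
  }
  cm <- rowMeans(beta[, case_ids, drop = FALSE], na.rm = TRUE)
  km <- rowMeans(beta[, ctl_ids, drop = FALSE], na.rm = TRUE)
  d <- cm - km
  d[is.nan(cm) | is.nan(km)] <- NA_real_
  d
}

#' Per-probe differential methylation statistics
#'
#' Convenience pipeline: M-value transform, per-probe linear model with
#' optional composition covariates, empirical-Bayes moderation, BH
#' adjustment and beta-scale effect sizes.
#'
#' @inheritParams fit_probe_models
#' @param beta Probes-by-samples beta matrix without missing values.
#' @param clip_eps Clipping margin for the logit transform.
#' @param d0_override See [moderate_statistics()].
#' @return Tibble with `probe_id`, `delta_beta`, `coef`, `t_mod`, `p_raw`,
#'   `p_adj` and a placeholder `auc` column filled by [roc_filter()].
#' @export
probe_statistics <- function(beta, samples, covariates = NULL,
                             case_groups = case_groups_default,
                             clip_eps = 0.001, d0_override = NULL) {
  m <- beta_to_m(beta, clip_eps)
  fit <- fit_probe_models(m, samples, covariates, case_groups)
  mod <- moderate_statistics(fit, d0_override)
  mod$p_adj <- adjust_bh(mod$p_raw)
  mod$delta_beta <- unname(mean_beta_difference(beta, samples, case_groups))
  mod$auc <- NA_real_
  out <- mod[, c("probe_id", "delta_beta", "coef", "t_mod", "p_raw", "p_adj", "auc")]
  attr(out, "d0") <- attr(mod, "d0", exact = TRUE)
  attr(out, "s0_sq") <- attr(mod, "s0_sq", exact = TRUE)
  out
}
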
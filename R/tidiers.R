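# broom-style accessors for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an episignature
#'
#' @param x An `episignature`.
#' @param ... Unused.
#' @return The per-probe tibble: id, direction, group mean betas, effect
#'   size and (when available) adjusted p and AUC.
#' @export
tidy.episignature <- function(x, ...) x$probes

#' One-row summary of an episignature
#'
#' @param x An `episignature`.
#' @param ... Unused.
#' @return Tibble with probe counts by direction, cohort sizes and the
#'   cascade thresholds.
#' @export
glance.episignature <- function(x, ...) {
  th <- x$provenance$thresholds
  tibble(
    n_probes = nrow(x$probes),
    n_hyper = sum(x$probes$direction == "hyper"),
    n_hypo = sum(x$probes$direction == "hypo"),
    n_cases = x$provenance$n_cases %||% NA_integer_,
    n_controls = x$provenance$n_controls %||% NA_integer_,
    delta_min = th$delta_min %||% NA_real_,
    p_adj_max = th$p_adj_max %||% NA_real_,
    auc_min = th$auc_min %||% NA_real_,
    r_max = th$r_max %||% NA_real_
  )
}

#' @export
tidy.mvp_model <- function(x, ...) x$training_scores

#' @export
glance.mvp_model <- function(x, ...) {
  tibble(n_probes = length(x$probes),
         n_train = nrow(x$training_scores),
         n_cases = sum(x$training_scores$group %in% x$case_groups),
         cost = x$cost,
         platt_A = x$A, platt_B = x$B)
}

#' @export
tidy.multiclass_mvp <- function(x, ...) x$held_out

#' @export
glance.multiclass_mvp <- function(x, ...) {
  tibble(n_classes = length(x$models),
         n_train = sum(x$split$role == "train"),
         n_test = sum(x$split$role == "test"),
         seed = x$seed)
}

#' @export
tidy.global_stats <- function(x, ...) x$differences

#' @export
glance.global_stats <- function(x, ...) {
  gs <- x$group_summary
  tibble(
    median_beta_bi = gs$median_beta[gs$group == "case_biallelic"],
    median_beta_mono = gs$median_beta[gs$group == "case_monoallelic"],
    median_beta_control = gs$median_beta[gs$group == "control"],
    ks_D = x$ks_D, ks_p = x$ks_p,
    pearson_r = x$pearson_r, r_squared = x$pearson_r^2,
    n_probes = x$n_probes
  )
}

#' @export
tidy.epi_mds <- function(x, ...) x$points

`%||%` <- function(a, b) if (is.null(a)) b else a
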
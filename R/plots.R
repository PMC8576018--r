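# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_segment
#'   scale_fill_gradientn labs theme_minimal facet_wrap geom_jitter
#'   geom_boxplot geom_abline
#' @export
ggplot2::autoplot

#' Heatmap of signature-probe methylation
#'
#' Samples as columns, probes as rows, beta color scale from 0 to 1,
#' following the conventions of episignature heatmaps.
#'
#' @param object An `episignature`.
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet (used to order samples by group).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episignature <- function(object, beta, samples, ...) {
  probes <- object$probes$probe_id
  ord <- order(match(samples$group,
                     c("case_biallelic", "case_monoallelic", "control", "query")))
  ids <- samples$sample_id[ord]
  df <- as_tibble(beta[probes, ids, drop = FALSE], rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "beta") %>%
    mutate(sample_id = factor(.data$sample_id, levels = ids),
           probe_id = factor(.data$probe_id, levels = rev(probes)))
  ggplot(df, aes(x = .data$sample_id, y = .data$probe_id, fill = .data$beta)) +
    geom_tile() +
    scale_fill_gradientn(colors = c("#2166AC", "#F7F7F7", "#B2182B"),
                         limits = c(0, 1), name = "beta") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' MDS scatter of samples
#'
#' @param object An `epi_mds`.
#' @param samples Optional sample sheet to color points by group.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_mds <- function(object, samples = NULL, ...) {
  df <- object$points
  if (!is.null(samples)) {
    df <- left_join(df, samples[, c("sample_id", "group")], by = "sample_id")
    p <- ggplot(df, aes(x = .data$MDS1, y = .data$MDS2, color = .data$group))
  } else {
    p <- ggplot(df, aes(x = .data$MDS1, y = .data$MDS2))
  }
  p + geom_point(size = 2) + theme_minimal() +
    labs(x = "MDS 1", y = "MDS 2")
}

#' MVP score strip chart by group
#'
#' @param scores Tibble from [score_mvp()] joined with a `group` column, or
#'   the `training_scores` of an [train_mvp()] model.
#' @param bands Interpretation band cut points drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_mvp_scores <- function(scores, bands = c(0.2, 0.5)) {
  stopifnot(all(c("group", "mvp") %in% names(scores)))
  ggplot(scores, aes(x = .data$group, y = .data$mvp, color = .data$group)) +
    geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = bands, linetype = "dashed",
                        color = "grey40") +
    ggplot2::ylim(0, 1) +
    labs(x = NULL, y = "MVP score") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Case-versus-control mean methylation scatter
#'
#' Per-probe mean beta in cases against controls with the identity line,
#' the global concordance view that accompanies the distribution
#' statistics.
#'
#' @param beta Probes-by-samples beta matrix (complete cases).
#' @param samples Sample sheet.
#' @param case_groups Group labels pooled as case.
#' @return A ggplot object.
#' @export
plot_mean_scatter <- function(beta, samples,
                              case_groups = case_groups_default) {
  beta <- drop_incomplete(beta)
  case_ids <- samples$sample_id[samples$group %in% case_groups]
  ctl_ids <- samples$sample_id[samples$group == "control"]
  df <- tibble(control = rowMeans(beta[, ctl_ids, drop = FALSE]),
               case = rowMeans(beta[, case_ids, drop = FALSE]))
  ggplot(df, aes(x = .data$control, y = .data$case)) +
    geom_point(alpha = 0.2, size = 0.4) +
    geom_abline(slope = 1, intercept = 0, color = "red") +
    labs(x = "Mean beta (controls)", y = "Mean beta (cases)") +
    theme_minimal()
}
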
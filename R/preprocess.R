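# Probe QC, beta/M transforms, matched-control selection, reference-based
# cell deconvolution and cohort-level distribution statistics.

#' Quality-control filter for array probes
#'
#' Removes probes that fail detection in at least one sample (detection
#' p-value above `detection_threshold`), probes on the sex chromosomes, and
#' probes flagged as overlapping a SNP or as cross-reactive. Each removed
#' probe is attributed to the first criterion it matches, in that order, so
#' the per-criterion counts sum to the total removed.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param manifest Manifest tibble covering all probes.
#' @param detection_p Optional detection p-value matrix aligned to `beta`.
#' @param detection_threshold Detection p-value above which a measurement is
#'   considered failed (default 0.01).
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return The filtered beta matrix with a `qc_report` attribute (a tibble
#'   of per-criterion removal counts; see [qc_report()]).
#' @export
qc_filter_probes <- function(beta, manifest, detection_p = NULL,
                             detection_threshold = 0.01,
                             sex_chroms = c("chrX", "chrY")) {
  idx <- match(rownames(beta), manifest$probe_id)
  if (anyNA(idx)) {
    abort(sprintf("probe(s) absent from manifest: %s",
                  paste(head(rownames(beta)[is.na(idx)], 5), collapse = ", ")))
  }
  man <- manifest[idx, ]
  fail_det <- if (is.null(detection_p)) rep(FALSE, nrow(beta)) else {
    stopifnot(identical(dim(detection_p), dim(beta)))
    rowSums(detection_p > detection_threshold, na.rm = TRUE) > 0
  }
  on_sex <- man$chrom %in% sex_chroms
  snp <- man$snp_flag
  cross <- man$cross_reactive_flag

  reason <- rep(NA_character_, nrow(beta))
  reason[cross] <- "cross_reactive"
  reason[snp] <- "snp"
  reason[on_sex] <- "sex_chromosome"
  reason[fail_det] <- "detection_p"
  keep <- is.na(reason)
  if (!any(keep)) abort("no probes survive QC")

  report <- tibble(
    criterion = c("detection_p", "sex_chromosome", "snp", "cross_reactive"),
    n_removed = c(sum(reason == "detection_p", na.rm = TRUE),
                  sum(reason == "sex_chromosome", na.rm = TRUE),
                  sum(reason == "snp", na.rm = TRUE),
                  sum(reason == "cross_reactive", na.rm = TRUE))
  )
  out <- beta[keep, , drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_filter_probes
#' @export
qc_report <- function(beta) {
  rep <- attr(beta, "qc_report")
  if (is.null(rep)) abort("no qc_report attribute; run qc_filter_probes() first")
  rep
}

#' Drop probes with missing values
#'
#' Retains only probes measured in every sample (complete cases), the rule
#' applied before distribution-level comparisons.
#'
#' @param beta Probes-by-samples beta matrix.
#' @return The complete-case submatrix; a warning is raised if nothing
#'   survives.
#' @export
drop_incomplete <- function(beta) {
  keep <- rowSums(is.na(beta)) == 0
  if (!any(keep)) warn("all probes have missing values; returning empty matrix")
  beta[keep, , drop = FALSE]
}

#' Beta to M-value transform
#'
#' `M = log2(beta' / (1 - beta'))` with beta clipped into
#' `[clip_eps, 1 - clip_eps]` so M stays finite; missing values stay
#' missing. [m_to_beta()] inverts the transform (exactly, away from the
#' clipping boundary).
#'
#' @param beta Beta matrix or vector in `[0, 1]`.
#' @param clip_eps Clipping margin (default 0.001, bounding |M| near 10).
#' @return M-values of the same shape.
#' @export
beta_to_m <- function(beta, clip_eps = 0.001) {
  b <- pmin(pmax(beta, clip_eps), 1 - clip_eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m M-value matrix or vector.
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Select age- and sex-matched controls
#'
#' For each case, greedily selects `ratio` controls of the same sex with
#' nearest age, without replacement across cases. Ties on age distance are
#' broken in favor of the younger control, then by lexicographic sample id,
#' making the selection deterministic. A warning is issued when a selected
#' control exceeds `max_age_gap` years from its case.
#'
#' @param cases Sample sheet rows of the cases, matched in row order.
#' @param pool Sample sheet rows of candidate controls (disjoint from
#'   cases).
#' @param ratio Controls selected per case (default 5).
#' @param max_age_gap Age gap in years above which a warning is raised.
#' @return Character vector of selected control sample ids (union over
#'   cases, in selection order).
#' @export
match_controls <- function(cases, pool, ratio = 5, max_age_gap = 10) {
  if (length(intersect(cases$sample_id, pool$sample_id)) > 0) {
    abort("control pool must be disjoint from cases")
  }
  available <- pool
  chosen <- character(0)
  for (i in seq_len(nrow(cases))) {
    cand <- available[available$sex == cases$sex[i], ]
    if (nrow(cand) < ratio) {
      abort(sprintf("control pool exhausted for case '%s' (sex %s): %d of %d needed available",
                    cases$sample_id[i], cases$sex[i], nrow(cand), ratio))
    }
    ord <- order(abs(cand$age_years - cases$age_years[i]),
                 cand$age_years, cand$sample_id)
    pick <- cand$sample_id[ord[seq_len(ratio)]]
    gaps <- abs(cand$age_years[ord[seq_len(ratio)]] - cases$age_years[i])
    if (any(gaps > max_age_gap)) {
      warn(sprintf("case '%s': matched control(s) exceed the %g-year age gap (max gap %.1f)",
                   cases$sample_id[i], max_age_gap, max(gaps)))
    }
    chosen <- c(chosen, pick)
    available <- available[!available$sample_id %in% pick, ]
  }
  chosen
}

#' Flag PCA outlier samples
#'
#' Projects samples onto the top `k` principal components of the M-value
#' matrix and flags any sample whose score on one of them exceeds `z_cut`
#' robust z-scores (median/MAD).
#'
#' @param m Probes-by-samples M-value matrix (complete rows are used).
#' @param k Number of leading components inspected.
#' @param z_cut Robust z-score threshold.
#' @return Tibble with `sample_id`, the component scores and an `outlier`
#'   flag.
#' @export
pca_outlier_check <- function(m, k = 2, z_cut = 3) {
  if (ncol(m) < 3) abort("need at least 3 samples for PCA outlier screening")
  m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  z <- apply(scores, 2, function(x) {
    s <- mad(x)
    dev <- x - median(x)
    if (s == 0) ifelse(dev == 0, 0, Inf) else dev / s
  })
  z <- matrix(z, ncol = k)
  out <- as_tibble(scores)
  names(out) <- paste0("PC", seq_len(k))
  out$sample_id <- colnames(m)
  out$outlier <- apply(abs(z) > z_cut, 1, any)
  out[, c("sample_id", paste0("PC", seq_len(k)), "outlier")]
}

#' Estimate blood cell proportions by constrained least squares
#'
#' Regresses each sample's beta values at the reference probes on the
#' cell-type reference profiles under nonnegativity and a sum-to-one
#' constraint, the standard reference-based deconvolution used to supply
#' composition covariates to the probe-level model.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param ref Reference beta matrix, probes by cell types (rownames are
#'   probe ids resolvable against `beta`).
#' @return Tibble with `sample_id`, one column per cell type (proportions on
#'   the simplex) and `residual_norm`.
#' @export
estimate_cell_proportions <- function(beta, ref) {
  common <- intersect(rownames(beta), rownames(ref))
  if (length(common) < ncol(ref)) {
    abort(sprintf("only %d probes shared with the reference; need at least %d",
                  length(common), ncol(ref)))
  }
  A0 <- ref[common, , drop = FALSE]
  lambda <- 1000  # weight enforcing the sum-to-one row
  res <- purrr::map_dfr(colnames(beta), function(s) {
    y <- beta[common, s]
    ok <- !is.na(y)
    A <- rbind(A0[ok, , drop = FALSE], lambda)
    b <- c(y[ok], lambda)
    fit <- pracma::lsqnonneg(A, b)
    x <- fit$x
    if (sum(x) > 0) x <- x / sum(x)
    rn <- sqrt(sum((A0[ok, , drop = FALSE] %*% x - y[ok])^2))
    out <- as.list(setNames(x, colnames(ref)))
    out$sample_id <- s
    out$residual_norm <- rn
    as_tibble(out)
  })
  res[, c("sample_id", colnames(ref), "residual_norm")]
}

#' Cohort-level methylation distribution statistics
#'
#' Computes the global summaries used to compare bi-allelic and
#' mono-allelic carriers against controls: per-group median and mean beta
#' over all complete-case entries, per-probe group mean differences
#' (bi-allelic minus control, mono-allelic minus control), a two-sample
#' Kolmogorov-Smirnov test between those two difference distributions
#' (asymptotic p-value), and the Pearson correlation between per-probe case
#' and control means.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet with groups `case_biallelic`,
#'   `case_monoallelic` and `control` all present.
#' @return A list of class `global_stats`; see [glance.global_stats()] for
#'   the one-row summary and [tidy.global_stats()] for per-probe
#'   differences.
#' @export
global_methylation_stats <- function(beta, samples) {
  for (g in c("case_biallelic", "case_monoallelic", "control")) {
    if (!any(samples$group == g)) abort(sprintf("required group '%s' absent", g))
  }
  beta <- drop_incomplete(beta)
  sid <- function(g) samples$sample_id[samples$group == g]
  bi <- beta[, sid("case_biallelic"), drop = FALSE]
  mono <- beta[, sid("case_monoallelic"), drop = FALSE]
  ctl <- beta[, sid("control"), drop = FALSE]

  d_bi <- rowMeans(bi) - rowMeans(ctl)
  d_mono <- rowMeans(mono) - rowMeans(ctl)
  ks <- suppressWarnings(ks.test(d_bi, d_mono))
  case <- beta[, samples$sample_id[samples$group %in%
                                     c("case_biallelic", "case_monoallelic")],
               drop = FALSE]
  r <- cor(rowMeans(case), rowMeans(ctl))

  structure(list(
    group_summary = tibble(
      group = c("case_biallelic", "case_monoallelic", "control"),
      median_beta = c(median(bi), median(mono), median(ctl)),
      mean_beta = c(mean(bi), mean(mono), mean(ctl)),
      n_samples = c(ncol(bi), ncol(mono), ncol(ctl))
    ),
    differences = tibble(probe_id = rownames(beta),
                         delta_bi = d_bi, delta_mono = d_mono),
    ks_D = unname(ks$statistic),
    ks_p = ks$p.value,
    pearson_r = r,
    n_probes = nrow(beta)
  ), class = "global_stats")
}

#' @export
print.global_stats <- function(x, ...) {
  cat("Global methylation statistics over", x$n_probes, "complete-case probes\n")
  print(x$group_summary)
  cat(sprintf("KS D = %.4g (p = %.3g); Pearson r = %.4f (r^2 = %.4f)\n",
              x$ks_D, x$ks_p, x$pearson_r, x$pearson_r^2))
  invisible(x)
}
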
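# The four-stage probe-selection cascade producing an episignature:
# effect-size threshold, adjusted-p threshold, ROC AUC filter, and greedy
# correlation pruning.

#' Effect-size and significance candidate selection
#'
#' Returns the probes with `|delta_beta| >= delta_min` ("at least 10%" is
#' inclusive), the probes with `p_adj < p_adj_max` (strict), and their
#' intersection ordered by ascending adjusted p-value. All three
#' cardinalities are reported, mirroring the triplet bookkeeping of
#' signature discovery.
#'
#' @param stats Probe statistics tibble from [probe_statistics()].
#' @param delta_min Minimum absolute mean beta difference (default 0.10).
#' @param p_adj_max Strict upper bound on the adjusted p-value
#'   (default 0.001).
#' @return List with `delta_probes`, `p_probes`, `candidates` (intersection,
#'   ordered by ascending `p_adj`) and a `counts` tibble.
#' @export
select_candidates <- function(stats, delta_min = 0.10, p_adj_max = 0.001) {
  ok <- !is.na(stats$delta_beta) & !is.na(stats$p_adj)
  delta_probes <- stats$probe_id[ok & abs(stats$delta_beta) >= delta_min]
  p_probes <- stats$probe_id[ok & stats$p_adj < p_adj_max]
  both <- stats[ok & abs(stats$delta_beta) >= delta_min &
                  stats$p_adj < p_adj_max, ]
  both <- both[order(both$p_adj, both$probe_id), ]
  list(
    delta_probes = delta_probes,
    p_probes = p_probes,
    candidates = both$probe_id,
    counts = tibble(
      stage = c("delta_beta", "p_adj", "intersection"),
      n = c(length(delta_probes), length(p_probes), nrow(both))
    )
  )
}

#' Per-probe ROC AUC
#'
#' Directional AUC: the fraction of (case, control) sample pairs where the
#' case beta exceeds the control beta, ties counted one half (the
#' Mann-Whitney U identity, computed via mid-ranks).
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples Sample sheet.
#' @param probes Probe ids to evaluate.
#' @param case_groups Group labels pooled as "case".
#' @return Named numeric vector of AUC values in `[0, 1]`.
#' @export
probe_auc <- function(beta, samples, probes,
                      case_groups = case_groups_default) {
  case_ids <- samples$sample_id[samples$group %in% case_groups]
  ctl_ids <- samples$sample_id[samples$group == "control"]
  if (length(case_ids) == 0 || length(ctl_ids) == 0) {
    abort("both case and control groups must be non-empty")
  }
  n1 <- length(case_ids); n2 <- length(ctl_ids)
  sub <- beta[probes, c(case_ids, ctl_ids), drop = FALSE]
  apply(sub, 1, function(x) {
    r <- rank(x)
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
}

#' ROC AUC filter of the selection cascade
#'
#' Keeps probes whose discriminative ability exceeds `auc_min` in either
#' direction (`max(AUC, 1 - AUC) > auc_min`), so the occasional
#' hypomethylated signature probe is not discarded.
#'
#' @inheritParams probe_auc
#' @param auc_min Strict AUC threshold (default 0.9).
#' @return Tibble with `probe_id`, the directional `auc`, and `keep`.
#' @export
roc_filter <- function(beta, samples, probes, auc_min = 0.9,
                       case_groups = case_groups_default) {
  auc <- probe_auc(beta, samples, probes, case_groups)
  tibble(probe_id = probes, auc = unname(auc),
         keep = pmax(auc, 1 - auc) > auc_min)
}

#' Correlation pruning of the selection cascade
#'
#' Greedy sweep over probes ordered by ascending adjusted p-value, keeping
#' the most significant representative of each redundant block;
#' deterministic given the ordering. Pearson correlations are computed
#' separately within the case-only and control-only sample sets: pooling
#' the groups would make every differential probe correlate with every
#' other through the case/control separation itself, which is group
#' structure, not redundancy. For the same reason the default rule treats
#' a probe as redundant only when its correlation with an already-kept
#' probe exceeds `r_max` in absolute value in BOTH sample sets —
#' correlation that appears only among cases typically reflects shared
#' biology (for instance a methylation dose gradient), whereas genuine
#' probe redundancy replicates in controls. `rule = "either"` gives the
#' stricter variant that removes on a single-group excess. Zero-variance
#' probes (correlation undefined) are kept with a warning.
#'
#' @inheritParams probe_auc
#' @param probes Candidate probe ids, ordered by ascending `p_adj`.
#' @param r_max Maximum tolerated absolute correlation (default 0.8).
#' @param rule `"replicated"` (default): remove when the excess correlation
#'   shows in both sample sets; `"either"`: remove on one set alone.
#' @return Character vector of kept probe ids, in input order.
#' @export
correlation_filter <- function(beta, samples, probes, r_max = 0.8,
                               case_groups = case_groups_default,
                               rule = c("replicated", "either")) {
  rule <- match.arg(rule)
  if (length(probes) <= 1) return(probes)
  case_ids <- samples$sample_id[samples$group %in% case_groups]
  ctl_ids <- samples$sample_id[samples$group == "control"]
  norm_rows <- function(ids) {
    x <- beta[probes, ids, drop = FALSE]
    x <- x - rowMeans(x)
    ss <- sqrt(rowSums(x^2))
    list(x = x, ss = ss)
  }
  ca <- norm_rows(case_ids)
  ct <- norm_rows(ctl_ids)
  degenerate <- ca$ss == 0 | ct$ss == 0
  if (any(degenerate)) {
    warn(sprintf("%d probe(s) have zero variance within a group; correlation undefined, kept",
                 sum(degenerate)))
  }
  kept <- integer(0)
  for (i in seq_along(probes)) {
    if (degenerate[i]) { kept <- c(kept, i); next }
    ok <- TRUE
    for (j in kept) {
      if (degenerate[j]) next
      r1 <- sum(ca$x[i, ] * ca$x[j, ]) / (ca$ss[i] * ca$ss[j])
      if (rule == "either" && abs(r1) > r_max) { ok <- FALSE; break }
      r2 <- sum(ct$x[i, ] * ct$x[j, ]) / (ct$ss[i] * ct$ss[j])
      if (rule == "either" && abs(r2) > r_max) { ok <- FALSE; break }
      if (rule == "replicated" && abs(r1) > r_max && abs(r2) > r_max) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  probes[kept]
}

#' Assemble an episignature object
#'
#' Records the surviving probes with per-probe direction (sign of the mean
#' beta difference), group mean betas and full provenance (thresholds,
#' cohort sizes, counts surviving each cascade stage).
#'
#' @inheritParams probe_auc
#' @param probes Final probe ids (cascade survivors), ordered by ascending
#'   adjusted p-value.
#' @param stats Optional probe statistics tibble; `p_adj` and `auc` are
#'   carried into the signature when present.
#' @param provenance Optional list of thresholds and stage counts.
#' @return An object of class `episignature`.
#' @export
build_signature <- function(beta, samples, probes, stats = NULL,
                            provenance = list(),
                            case_groups = case_groups_default) {
  if (length(probes) == 0) abort("no signature probes")
  if (anyDuplicated(probes)) abort("signature probe list contains duplicates")
  case_ids <- samples$sample_id[samples$group %in% case_groups]
  ctl_ids <- samples$sample_id[samples$group == "control"]
  mc <- rowMeans(beta[probes, case_ids, drop = FALSE], na.rm = TRUE)
  mk <- rowMeans(beta[probes, ctl_ids, drop = FALSE], na.rm = TRUE)
  tab <- tibble(
    probe_id = probes,
    direction = unname(ifelse(mc >= mk, "hyper", "hypo")),
    mean_beta_case = unname(mc),
    mean_beta_control = unname(mk),
    delta_beta = unname(mc - mk)
  )
  if (!is.null(stats)) {
    tab <- left_join(tab, stats[, intersect(c("probe_id", "p_adj", "auc"),
                                            names(stats))], by = "probe_id")
  }
  provenance$n_cases <- length(case_ids)
  provenance$n_controls <- length(ctl_ids)
  structure(list(probes = tab, provenance = provenance),
            class = "episignature")
}

#' Discover an episignature from a cohort
#'
#' Runs the full discovery cascade: per-probe moderated statistics
#' ([probe_statistics()]), then the effect-size/significance intersection
#' ([select_candidates()]), ROC AUC filter ([roc_filter()]) and correlation
#' pruning ([correlation_filter()]).
#'
#' @inheritParams probe_statistics
#' @param delta_min,p_adj_max,auc_min,r_max Cascade thresholds.
#' @return An `episignature`; the full probe statistics (with AUC filled in
#'   for candidates) are attached as attribute `"stats"`, and stage counts
#'   live in `$provenance$stage_counts`.
#' @export
discover_signature <- function(beta, samples, covariates = NULL,
                               delta_min = 0.10, p_adj_max = 0.001,
                               auc_min = 0.9, r_max = 0.8,
                               case_groups = case_groups_default,
                               clip_eps = 0.001,
                               cor_rule = c("replicated", "either")) {
  cor_rule <- match.arg(cor_rule)
  stats <- probe_statistics(beta, samples, covariates, case_groups, clip_eps)
  cand <- select_candidates(stats, delta_min, p_adj_max)
  roc <- roc_filter(beta, samples, cand$candidates, auc_min, case_groups)
  stats$auc[match(roc$probe_id, stats$probe_id)] <- roc$auc
  after_roc <- roc$probe_id[roc$keep]
  final <- correlation_filter(beta, samples, after_roc, r_max, case_groups,
                              rule = cor_rule)
  counts <- bind_rows(
    cand$counts,
    tibble(stage = c("roc_auc", "correlation"),
           n = c(length(after_roc), length(final)))
  )
  prov <- list(
    thresholds = list(delta_min = delta_min, p_adj_max = p_adj_max,
                      auc_min = auc_min, r_max = r_max),
    stage_counts = counts
  )
  if (length(final) == 0) {
    # a cohort without a methylation signature is a legitimate outcome
    prov$n_cases <- sum(samples$group %in% case_groups)
    prov$n_controls <- sum(samples$group == "control")
    sig <- structure(list(
      probes = tibble(probe_id = character(), direction = character(),
                      mean_beta_case = numeric(), mean_beta_control = numeric(),
                      delta_beta = numeric(), p_adj = numeric(), auc = numeric()),
      provenance = prov
    ), class = "episignature")
  } else {
    sig <- build_signature(beta, samples, final, stats, prov, case_groups)
  }
  attr(sig, "stats") <- stats
  sig
}

#' Overlap between two episignatures
#'
#' @param sig_a,sig_b `episignature` objects (or probe-id vectors).
#' @return Integer count of shared probes.
#' @export
signature_overlap <- function(sig_a, sig_b) {
  pa <- if (inherits(sig_a, "episignature")) sig_a$probes$probe_id else sig_a
  pb <- if (inherits(sig_b, "episignature")) sig_b$probes$probe_id else sig_b
  length(intersect(pa, pb))
}

#' @export
print.episignature <- function(x, ...) {
  n_hyper <- sum(x$probes$direction == "hyper")
  cat(sprintf("Episignature: %d probes (%d hypermethylated, %d hypomethylated)\n",
              nrow(x$probes), n_hyper, nrow(x$probes) - n_hyper))
  if (!is.null(x$provenance$stage_counts)) {
    cat("Cascade stage counts:\n")
    print(x$provenance$stage_counts)
  }
  invisible(x)
}
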
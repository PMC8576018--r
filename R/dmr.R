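# Rule-based DMR calling: chained significant CpGs, regional effect size,
# Fisher-combined p-values, annotation and cross-cohort direction checks.

#' Fisher's method for combining p-values
#'
#' `X^2 = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom. Zero p-values are clipped to 1e-300 with a warning.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return List with `chi2`, `df`, `combined_p`.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) abort("no p-values to combine")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warn("zero p-value(s) clipped to 1e-300 before Fisher combination")
    p <- pmax(p, 1e-300)
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df, combined_p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Call differentially methylated regions
#'
#' Within each chromosome, significant CpGs (`p_adj < sig_p`) are chained:
#' consecutive significant CpGs at most `max_gap` bp apart join one
#' cluster. Clusters with at least `min_cpgs` significant CpGs become
#' candidate regions spanning the first to last significant CpG. The
#' regional mean beta difference averages over ALL array CpGs inside the
#' span, and the Fisher-combined p-value pools the raw p-values of all
#' span CpGs. A region is reported when `|mean_delta_beta| >= delta_min`
#' and `combined_p < fisher_p_max`; results are sorted by combined p.
#'
#' In `mode = "window"` the proximity rule instead requires the whole run
#' of significant CpGs to span at most `max_gap` bp.
#'
#' @param stats Probe statistics tibble (needs `probe_id`, `p_raw`,
#'   `p_adj`, `delta_beta`).
#' @param manifest Manifest tibble with positions for every probe in
#'   `stats`.
#' @param sig_p Per-CpG adjusted-p threshold defining "significant".
#' @param min_cpgs Minimum significant CpGs per region (default 5).
#' @param max_gap Proximity threshold in bp (default 1000).
#' @param delta_min Minimum absolute regional mean beta difference
#'   (default 0.10).
#' @param fisher_p_max Strict bound on the Fisher-combined p (default
#'   0.01).
#' @param mode Proximity interpretation: `"chain"` (consecutive gaps) or
#'   `"window"` (total span).
#' @return Tibble of regions: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_cpgs_total`, `n_cpgs_significant`, `mean_delta_beta`, `direction`,
#'   `fisher_chi2`, `fisher_df`, `combined_p`.
#' @export
find_dmrs <- function(stats, manifest, sig_p = 0.001, min_cpgs = 5,
                      max_gap = 1000, delta_min = 0.10, fisher_p_max = 0.01,
                      mode = c("chain", "window")) {
  mode <- match.arg(mode)
  idx <- match(stats$probe_id, manifest$probe_id)
  if (anyNA(idx)) {
    abort(sprintf("probe(s) missing from manifest: %s",
                  paste(head(stats$probe_id[is.na(idx)], 5), collapse = ", ")))
  }
  df <- tibble(
    probe_id = stats$probe_id,
    chrom = manifest$chrom[idx],
    pos = manifest$pos[idx],
    p_raw = stats$p_raw,
    p_adj = stats$p_adj,
    delta_beta = stats$delta_beta
  )
  df <- df[order(df$chrom, df$pos), ]
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    sig <- sub[!is.na(sub$p_adj) & sub$p_adj < sig_p, ]
    if (nrow(sig) < min_cpgs) next
    cluster_id <- if (mode == "chain") {
      cumsum(c(1, diff(sig$pos) > max_gap))
    } else {
      # window mode: greedy maximal runs whose total span fits max_gap
      cid <- integer(nrow(sig)); cur <- 1; anchor <- sig$pos[1]
      cid[1] <- 1
      for (i in seq_len(nrow(sig))[-1]) {
        if (sig$pos[i] - anchor > max_gap) { cur <- cur + 1; anchor <- sig$pos[i] }
        cid[i] <- cur
      }
      cid
    }
    for (cl in unique(cluster_id)) {
      members <- sig[cluster_id == cl, ]
      if (nrow(members) < min_cpgs) next
      start <- min(members$pos); end <- max(members$pos)
      span <- sub[sub$pos >= start & sub$pos <= end, ]
      mean_delta <- mean(span$delta_beta, na.rm = TRUE)
      fc <- fisher_combine(pmax(span$p_raw, 1e-300))
      if (abs(mean_delta) < delta_min) next
      if (fc$combined_p >= fisher_p_max) next
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start = start, end = end,
        n_cpgs_total = nrow(span),
        n_cpgs_significant = nrow(members),
        mean_delta_beta = mean_delta,
        direction = ifelse(mean_delta >= 0, "hyper", "hypo"),
        fisher_chi2 = fc$chi2, fisher_df = fc$df, combined_p = fc$combined_p
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_cpgs_total = integer(), n_cpgs_significant = integer(),
                  mean_delta_beta = numeric(), direction = character(),
                  fisher_chi2 = numeric(), fisher_df = integer(),
                  combined_p = numeric()))
  }
  res <- bind_rows(out)
  res[order(res$combined_p, res$chrom, res$start), ]
}

#' Annotate DMRs with gene context
#'
#' Attaches the union of manifest gene annotations over all CpGs inside
#' each region, flags regions whose span covers a TSS-annotated CpG, and
#' labels unannotated regions intergenic.
#'
#' @param dmrs Tibble from [find_dmrs()].
#' @param manifest Manifest tibble with gene annotations.
#' @return `dmrs` with added columns `genes` (semicolon-separated
#'   `symbol:region` pairs, `"intergenic"` when none) and `tss_overlap`.
#' @export
annotate_dmrs <- function(dmrs, manifest) {
  gm <- manifest_gene_map(manifest)
  gm$chrom <- manifest$chrom[match(gm$probe_id, manifest$probe_id)]
  gm$pos <- manifest$pos[match(gm$probe_id, manifest$probe_id)]
  genes <- character(nrow(dmrs)); tss <- logical(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    hits <- gm[gm$chrom == dmrs$chrom[i] & gm$pos >= dmrs$start[i] &
                 gm$pos <= dmrs$end[i], ]
    hits <- distinct(hits[, c("gene", "region")])
    genes[i] <- if (nrow(hits) == 0) "intergenic" else
      paste(sprintf("%s:%s", hits$gene, hits$region), collapse = ";")
    tss[i] <- any(hits$region == "TSS")
  }
  dmrs$genes <- genes
  dmrs$tss_overlap <- tss
  dmrs
}

#' Compare DMR directions against another cohort
#'
#' For each DMR, computes the sign of the regional case-minus-control mean
#' beta difference in a second cohort and counts how many regions agree
#' with the DMR's direction (the cross-disorder overlap check).
#'
#' @param dmrs Annotated or raw DMR tibble.
#' @param manifest Manifest tibble (defines CpG positions).
#' @param beta_other Beta matrix of the other cohort (platform-intersected
#'   beforehand if needed).
#' @param samples_other Sample sheet of the other cohort.
#' @param case_groups Group labels treated as cases in the other cohort.
#' @return List with `per_dmr` (tibble: region, other-cohort delta, sign
#'   agreement) and `n_agree` / `n_compared`.
#' @export
dmr_cohort_compare <- function(dmrs, manifest, beta_other, samples_other,
                               case_groups = case_groups_default) {
  case_ids <- samples_other$sample_id[samples_other$group %in% case_groups]
  ctl_ids <- samples_other$sample_id[samples_other$group == "control"]
  if (length(case_ids) == 0 || length(ctl_ids) == 0) {
    abort("other cohort needs both case and control samples")
  }
  rows <- list()
  n_skipped <- 0
  for (i in seq_len(nrow(dmrs))) {
    in_span <- manifest$chrom == dmrs$chrom[i] &
      manifest$pos >= dmrs$start[i] & manifest$pos <= dmrs$end[i]
    probes <- intersect(manifest$probe_id[in_span], rownames(beta_other))
    if (length(probes) == 0) { n_skipped <- n_skipped + 1; next }
    cm <- mean(beta_other[probes, case_ids, drop = FALSE], na.rm = TRUE)
    km <- mean(beta_other[probes, ctl_ids, drop = FALSE], na.rm = TRUE)
    delta <- cm - km
    rows[[length(rows) + 1]] <- tibble(
      chrom = dmrs$chrom[i], start = dmrs$start[i], end = dmrs$end[i],
      direction = dmrs$direction[i],
      delta_other = delta,
      agrees = (delta >= 0) == (dmrs$direction[i] == "hyper")
    )
  }
  if (n_skipped > 0) {
    inform(sprintf("%d DMR(s) had no covered CpGs in the other cohort and were excluded",
                   n_skipped))
  }
  per_dmr <- if (length(rows) > 0) bind_rows(rows) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           direction = character(), delta_other = numeric(),
           agrees = logical())
  list(per_dmr = per_dmr, n_agree = sum(per_dmr$agrees),
       n_compared = nrow(per_dmr))
}
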
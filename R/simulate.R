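# Synthetic methylation cohorts with the statistical structure the
# discovery pipeline assumes: logit-normal beta noise, a planted set of
# (mostly hypermethylated) signature probes with a larger effect in
# bi-allelic than mono-allelic carriers, cell-composition confounding,
# age/sex covariates, and co-located CpG clusters for DMR calling.

# Autosomal genome dictionary used for probe placement (approximate
# chromosome lengths in bp).
sim_genome <- function() {
  tibble(
    chrom = paste0("chr", 1:22),
    length = round(seq(248e6, 50e6, length.out = 22))
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults describe
#' the discovery-scale study design the package is tested against: 8
#' bi-allelic and 8 mono-allelic cases versus a pool of 64 controls, 20,000
#' probes with 300 planted signature probes, a planted bi-allelic beta shift
#' of 0.15 halved in mono-allelic carriers, and moderate logit-scale noise.
#'
#' @param n_probes Total probes on the simulated array.
#' @param n_signature_probes Planted differential probes (includes the
#'   clustered CpGs).
#' @param n_case_bi,n_case_mono,n_control Cohort sizes per group.
#' @param effect_bi Planted mean beta-scale shift in bi-allelic cases.
#' @param dose_factor Multiplier in `(0, 1]` for the mono-allelic shift.
#' @param frac_hyper Fraction of signature probes shifted upward
#'   (hypermethylated); the remainder are hypomethylated.
#' @param baseline_mu,baseline_sd Mean and sd of the per-probe baseline on
#'   the M scale (background probes). The defaults place the global median
#'   beta near 0.79 — the level reported for whole blood — with a
#'   between-probe spread wide enough to reproduce the strongly U-shaped
#'   beta distribution of real arrays.
#' @param noise_sd Per-entry Gaussian noise sd on the M scale.
#' @param n_clusters,cluster_size,cluster_gap Number of co-located signature
#'   CpG clusters, CpGs per cluster, and inter-CpG gap in bp (kept well
#'   under the 1 kb DMR chaining threshold).
#' @param n_cell_types,dirichlet_conc Cell types and Dirichlet concentration
#'   for per-sample blood composition.
#' @param n_ref_probes Cell-type-informative probes forming the
#'   deconvolution reference.
#' @param ref_noise_sd Beta-scale noise sd added on the reference probes.
#' @param confound_frac,confounding_strength Fraction of background probes
#'   whose M value depends on composition, and the size of that dependence.
#' @param age_range,sex_ratio Age range (years) and probability of female.
#' @param det_fail_frac Fraction of probe-by-sample entries with a failed
#'   detection p-value (> 0.01).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 20000,
                       n_signature_probes = 300,
                       n_case_bi = 8,
                       n_case_mono = 8,
                       n_control = 64,
                       effect_bi = 0.15,
                       dose_factor = 0.5,
                       frac_hyper = 0.99,
                       baseline_mu = 1.9,
                       baseline_sd = 3,
                       noise_sd = 0.5,
                       n_clusters = 5,
                       cluster_size = 6,
                       cluster_gap = 150,
                       n_cell_types = 6,
                       dirichlet_conc = 10,
                       n_ref_probes = 200,
                       ref_noise_sd = 0.02,
                       confound_frac = 0.025,
                       confounding_strength = 1,
                       age_range = c(2, 60),
                       sex_ratio = 0.5,
                       det_fail_frac = 1e-4,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$effect_bi >= 0, cfg$effect_bi <= 0.8,
    cfg$dose_factor > 0, cfg$dose_factor <= 1,
    cfg$n_probes >= cfg$n_signature_probes + cfg$n_ref_probes,
    cfg$n_signature_probes >= cfg$n_clusters * cfg$cluster_size,
    cfg$frac_hyper >= 0, cfg$frac_hyper <= 1
  )
  structure(cfg, class = "sim_config")
}

cell_type_names <- function(k) {
  std <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")
  if (k <= length(std)) std[seq_len(k)] else paste0("cell", seq_len(k))
}

#' Simulate a probe manifest
#'
#' Places background probes uniformly over an autosomal genome dictionary
#' and plants `n_clusters` co-located CpG clusters (consecutive gaps of
#' `cluster_gap` bp, so each cluster satisfies the DMR proximity rule by
#' construction). Cluster probes are annotated to a synthetic gene at its
#' TSS; roughly half of all probes are flagged as present on the 450K array.
#'
#' The planted signature probe ids (clustered CpGs first, then scattered
#' probes) are attached as attribute `"signature_probes"`, and the cluster
#' intervals as attribute `"clusters"`; [simulate_cohort()] reads both.
#'
#' @param config A [sim_config()].
#' @return A manifest tibble (see [read_manifest()]).
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genome <- sim_genome()
    n_clustered <- config$n_clusters * config$cluster_size
    n_bg <- config$n_probes - n_clustered

    bg_chrom <- sample(genome$chrom, n_bg, replace = TRUE,
                       prob = genome$length / sum(genome$length))
    bg_pos <- floor(runif(n_bg, 1, genome$length[match(bg_chrom, genome$chrom)])) + 1

    clusters <- vector("list", config$n_clusters)
    used <- tibble(chrom = character(), start = numeric(), end = numeric())
    for (k in seq_len(max(config$n_clusters, 0))) {
      placed <- FALSE
      for (try in 1:100) {
        ch <- sample(genome$chrom, 1)
        span <- (config$cluster_size - 1) * config$cluster_gap
        start <- floor(runif(1, 1e4, genome$length[genome$chrom == ch] - span - 1e4))
        end <- start + span
        clash <- any(used$chrom == ch & used$start <= end + 2000 & used$end >= start - 2000)
        if (!clash) {
          used <- bind_rows(used, tibble(chrom = ch, start = start, end = end))
          clusters[[k]] <- tibble(
            chrom = ch,
            pos = seq(start, by = config$cluster_gap, length.out = config$cluster_size),
            cluster = k
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("could not place a CpG cluster without overlap after 100 tries")
    }
    clust_df <- if (config$n_clusters > 0) bind_rows(clusters) else
      tibble(chrom = character(), pos = numeric(), cluster = integer())

    manifest <- tibble(
      probe_id = sprintf("cg%06d", seq_len(config$n_probes)),
      chrom = c(clust_df$chrom, bg_chrom),
      pos = c(clust_df$pos, bg_pos),
      on_450k = runif(config$n_probes) < 0.5,
      snp_flag = FALSE,
      cross_reactive_flag = FALSE,
      genes = ""
    )
    if (nrow(clust_df) > 0) {
      manifest$genes[seq_len(nrow(clust_df))] <-
        sprintf("GENE%03d:TSS", clust_df$cluster)
    }

    n_scatter <- config$n_signature_probes - n_clustered
    scatter_ids <- manifest$probe_id[n_clustered + seq_len(n_scatter)]
    sig_ids <- c(manifest$probe_id[seq_len(n_clustered)], scatter_ids)

    cluster_regions <- if (nrow(clust_df) > 0) {
      clust_df %>%
        mutate(probe_id = manifest$probe_id[seq_len(nrow(clust_df))]) %>%
        group_by(.data$cluster, .data$chrom) %>%
        summarise(start = min(.data$pos), end = max(.data$pos),
                  n_cpgs = dplyr::n(), .groups = "drop")
    } else {
      tibble(cluster = integer(), chrom = character(), start = numeric(),
             end = numeric(), n_cpgs = integer())
    }

    attr(manifest, "signature_probes") <- sig_ids
    attr(manifest, "clusters") <- cluster_regions
    manifest
  })
}

#' Simulate a methylation cohort
#'
#' Generates beta values as `M = mu_p + delta(group) + confounding + noise`
#' back-transformed to the beta scale, where the planted logit-scale offset
#' is chosen so the mean beta-scale shift at the probe baseline equals
#' `effect_bi` in bi-allelic cases and `effect_bi * dose_factor` in
#' mono-allelic cases. A disjoint block of cell-type-informative probes is
#' generated as a noisy linear mixture of a reference panel, providing
#' ground truth for deconvolution.
#'
#' @param config A [sim_config()].
#' @param manifest Manifest from [simulate_manifest()] (carries the planted
#'   probe ids as an attribute).
#' @return A list of class `epi_cohort` with elements `beta` (probes x
#'   samples matrix), `detection_p` (same shape), `samples` (sample sheet
#'   tibble), `cell_reference` (reference beta matrix, probes x cell types),
#'   `proportions` (true per-sample composition) and `truth` (planted
#'   signature probes, per-probe beta shifts by group, cluster intervals).
#' @export
simulate_cohort <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"))
  sig_ids <- attr(manifest, "signature_probes")
  if (is.null(sig_ids)) abort("manifest lacks planted-probe bookkeeping; use simulate_manifest()")

  with_seed(config$seed + 1L, {
    n_bi <- config$n_case_bi; n_mono <- config$n_case_mono; n_ctl <- config$n_control
    n <- n_bi + n_mono + n_ctl
    samples <- tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = c(rep("case_biallelic", n_bi), rep("case_monoallelic", n_mono),
                rep("control", n_ctl)),
      age_years = round(runif(n, config$age_range[1], config$age_range[2]), 1),
      sex = ifelse(runif(n) < config$sex_ratio, "F", "M"),
      batch = "batch1"
    )

    probes <- manifest$probe_id
    p <- length(probes)
    sig_idx <- match(sig_ids, probes)
    nonsig <- setdiff(seq_len(p), sig_idx)
    ref_idx <- nonsig[seq_len(config$n_ref_probes)]
    pool <- setdiff(nonsig, ref_idx)
    n_conf <- round(config$confound_frac * p)
    conf_idx <- sample(pool, min(n_conf, length(pool)))

    # Baselines: background probes from the configured M-scale normal.
    # Signature probes emulate regulatory CpG-island sites: essentially
    # unmethylated in controls when the planted change is a methylation
    # gain (the TSS-hypermethylation pattern), and near-fully methylated
    # when it is a loss.
    mu <- rnorm(p, config$baseline_mu, config$baseline_sd)
    hyper <- runif(length(sig_idx)) < config$frac_hyper
    base_sig <- ifelse(hyper, runif(length(sig_idx), 0.03, 0.12),
                       runif(length(sig_idx), 0.88, 0.97))
    mu[sig_idx] <- beta_logit2(base_sig)

    effect <- ifelse(hyper, config$effect_bi, -config$effect_bi)
    delta_bi <- beta_logit2(base_sig + effect) - mu[sig_idx]
    delta_mono <- beta_logit2(base_sig + effect * config$dose_factor) - mu[sig_idx]

    K <- config$n_cell_types
    comp <- rdirichlet(n, rep(config$dirichlet_conc, K))
    rownames(comp) <- samples$sample_id
    colnames(comp) <- cell_type_names(K)
    w <- matrix(rnorm(length(conf_idx) * K), ncol = K)

    M <- matrix(rep(mu, n), nrow = p, ncol = n,
                dimnames = list(probes, samples$sample_id))
    is_bi <- samples$group == "case_biallelic"
    is_mono <- samples$group == "case_monoallelic"
    M[sig_idx, is_bi] <- M[sig_idx, is_bi] + delta_bi
    M[sig_idx, is_mono] <- M[sig_idx, is_mono] + delta_mono
    if (length(conf_idx) > 0) {
      M[conf_idx, ] <- M[conf_idx, ] +
        config$confounding_strength * (w %*% t(comp))
    }
    M <- M + matrix(rnorm(p * n, 0, config$noise_sd), nrow = p)
    beta <- beta_unlogit2(M)

    # Cell-type-informative probes: noisy linear mixture of the reference.
    ref_beta <- matrix(runif(config$n_ref_probes * K, 0.05, 0.95),
                       nrow = config$n_ref_probes,
                       dimnames = list(probes[ref_idx], colnames(comp)))
    mix <- ref_beta %*% t(comp) +
      matrix(rnorm(config$n_ref_probes * n, 0, config$ref_noise_sd),
             nrow = config$n_ref_probes)
    beta[ref_idx, ] <- pmin(pmax(mix, 1e-6), 1 - 1e-6)

    detection_p <- matrix(runif(p * n, 0, 0.005), nrow = p,
                          dimnames = dimnames(beta))
    fail <- runif(p * n) < config$det_fail_frac
    detection_p[fail] <- runif(sum(fail), 0.011, 0.1)

    truth <- list(
      signature_probes = sig_ids,
      direction = ifelse(hyper, "hyper", "hypo"),
      delta_beta_bi = setNames(effect, sig_ids),
      delta_beta_mono = setNames(effect * config$dose_factor, sig_ids),
      clusters = attr(manifest, "clusters"),
      ref_probes = probes[ref_idx],
      confounded_probes = probes[conf_idx],
      mu = setNames(mu, probes),
      ref_beta = ref_beta
    )

    structure(
      list(beta = beta, detection_p = detection_p, samples = samples,
           cell_reference = ref_beta, proportions = comp, truth = truth),
      class = "epi_cohort"
    )
  })
}

#' Simulate a cohort of a second disorder on shared probe baselines
#'
#' Generates case and control samples for another syndrome on the SAME
#' per-probe baselines as an existing cohort (required for any
#' cross-cohort comparison: scoring its samples with a trained MVP model,
#' joint MDS/clustering, or DMR direction checks). The disorder shifts
#' `affected_probes` toward the direction planted in the original truth
#' set (falling back to hypermethylation for probes outside it), with a
#' beta-scale mean shift of `effect` at the baseline.
#'
#' @param config The [sim_config()] used for the original cohort (noise
#'   and cell-composition settings are reused).
#' @param cohort The `epi_cohort` whose baselines are shared.
#' @param affected_probes Probe ids shifted in the new disorder (may
#'   overlap the original signature fully, partially or not at all).
#' @param n_cases,n_controls Sample counts for the new cohort.
#' @param effect Beta-scale mean shift in the new disorder's cases.
#' @param label Group label given to the new cases.
#' @param seed Integer seed.
#' @return An `epi_cohort` (no detection failures are injected).
#' @export
simulate_disorder_cohort <- function(config, cohort, affected_probes,
                                     n_cases, n_controls, effect,
                                     label = "case_biallelic", seed = 99) {
  truth <- cohort$truth
  mu <- truth$mu
  probes <- names(mu)
  bad <- setdiff(affected_probes, probes)
  if (length(bad) > 0) abort("affected_probes must exist in the original cohort")
  with_seed(seed, {
    n <- n_cases + n_controls
    samples <- tibble(
      sample_id = sprintf("T%03d", seq_len(n)),
      group = c(rep(label, n_cases), rep("control", n_controls)),
      age_years = round(runif(n, config$age_range[1], config$age_range[2]), 1),
      sex = ifelse(runif(n) < config$sex_ratio, "F", "M"),
      batch = "batch2"
    )
    dir <- setNames(rep("hyper", length(affected_probes)), affected_probes)
    known <- intersect(affected_probes, truth$signature_probes)
    dir[known] <- truth$direction[match(known, truth$signature_probes)]
    base <- beta_unlogit2(mu[affected_probes])
    signed <- ifelse(dir == "hyper", effect, -effect)
    target <- pmin(pmax(base + signed, 1e-4), 1 - 1e-4)
    delta <- beta_logit2(target) - mu[affected_probes]

    M <- matrix(rep(mu, n), nrow = length(probes),
                dimnames = list(probes, samples$sample_id))
    is_case <- samples$group == label
    M[affected_probes, is_case] <- M[affected_probes, is_case] + delta
    M <- M + matrix(rnorm(length(probes) * n, 0, config$noise_sd),
                    nrow = length(probes))
    beta <- beta_unlogit2(M)

    K <- ncol(cohort$cell_reference)
    comp <- rdirichlet(n, rep(config$dirichlet_conc, K))
    dimnames(comp) <- list(samples$sample_id, colnames(cohort$cell_reference))
    ref_idx <- truth$ref_probes
    mix <- truth$ref_beta %*% t(comp) +
      matrix(rnorm(length(ref_idx) * n, 0, config$ref_noise_sd),
             nrow = length(ref_idx))
    beta[ref_idx, ] <- pmin(pmax(mix, 1e-6), 1 - 1e-6)

    structure(
      list(beta = beta, detection_p = NULL, samples = samples,
           cell_reference = cohort$cell_reference, proportions = comp,
           truth = list(signature_probes = affected_probes,
                        direction = unname(dir), mu = mu,
                        ref_probes = ref_idx, ref_beta = truth$ref_beta)),
      class = "epi_cohort"
    )
  })
}

#' Simulate a gene-by-cell-type expression matrix
#'
#' TPM values are log-normal per cell type; DMR-associated genes receive a
#' location shift of `enrichment` on the natural-log scale. The
#' proportion-expressed column is a fixed monotone transform of TPM, so
#' rank-based comparisons agree between the two metrics.
#'
#' @param dmr_genes Character vector of DMR-associated gene symbols.
#' @param n_background Number of background (autosomal protein-coding)
#'   genes; must be positive.
#' @param enrichment Nonnegative log-scale expression shift for DMR genes.
#' @param cell_types Cell type names.
#' @param seed Integer seed.
#' @return A tibble with columns `gene`, `cell_type`, `tpm`,
#'   `prop_expressed`, `is_dmr`.
#' @export
simulate_expression <- function(dmr_genes, n_background, enrichment = 0,
                                cell_types = c("excitatory_neurons",
                                               "inhibitory_neurons"),
                                seed = 1) {
  if (n_background <= 0) abort("n_background must be positive: comparison undefined without background genes")
  if (enrichment < 0) abort("enrichment must be nonnegative")
  with_seed(seed, {
    genes <- c(dmr_genes, sprintf("BG%05d", seq_len(n_background)))
    is_dmr <- c(rep(TRUE, length(dmr_genes)), rep(FALSE, n_background))
    out <- purrr::map_dfr(cell_types, function(ct) {
      lt <- rnorm(length(genes), mean = 1, sd = 1.5) + enrichment * is_dmr
      tpm <- exp(lt)
      tibble(gene = genes, cell_type = ct, tpm = tpm,
             prop_expressed = tpm / (tpm + 50), is_dmr = is_dmr)
    })
    out
  })
}
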
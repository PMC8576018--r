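# Small in-code fixtures shared across tests.

# Minimal sample sheet: n_bi/n_mono cases and n_ctl controls.
tiny_samples <- function(n_bi = 2, n_mono = 2, n_ctl = 4) {
  n <- n_bi + n_mono + n_ctl
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = c(rep("case_biallelic", n_bi), rep("case_monoallelic", n_mono),
              rep("control", n_ctl)),
    age_years = seq(10, 50, length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    batch = "b1"
  )
}

# Beta matrix with named dims from a vector (row-major probes x samples).
tiny_beta <- function(values, probes, samples) {
  matrix(values, nrow = length(probes), byrow = TRUE,
         dimnames = list(probes, samples))
}

# A small manifest on one chromosome with evenly spaced probes.
tiny_manifest <- function(probe_ids, chrom = "chr1", start = 1000, gap = 500,
                          genes = "") {
  tibble::tibble(
    probe_id = probe_ids,
    chrom = chrom,
    pos = seq(start, by = gap, length.out = length(probe_ids)),
    on_450k = TRUE, snp_flag = FALSE, cross_reactive_flag = FALSE,
    genes = genes
  )
}

# A fully simulated mid-size cohort used by several test files (cached per
# session to keep the suite fast).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_probes = 4000, n_signature_probes = 120,
                        n_case_bi = 8, n_case_mono = 8, n_control = 40,
                        seed = 42)
      man <- simulate_manifest(cfg)
      coh <- simulate_cohort(cfg, man)
      cache <<- list(cfg = cfg, manifest = man, cohort = coh)
    }
    cache
  }
})

# Independent brute-force BH definition: p_adj_i over sorted p is
# min_{j >= rank(i)} ( m * p_(j) / j ), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Independent KS D by ECDF-step enumeration at all pooled points.
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Independent AUC by explicit concordant-pair counting.
auc_oracle <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(cases) * length(controls))
}

# Independent OLS via Moore-Penrose pseudoinverse.
ols_oracle <- function(X, y) {
  b <- MASS::ginv(X) %*% y
  res <- y - X %*% b
  df <- nrow(X) - qr(X)$rank
  list(coef = as.numeric(b), s2 = sum(res^2) / df, df = df)
}

# Independent DMR caller: enumerate maximal chains of significant CpGs and
# apply the three filters directly.
dmr_oracle <- function(stats, manifest, sig_p = 0.001, min_cpgs = 5,
                       max_gap = 1000, delta_min = 0.10, fisher_p_max = 0.01) {
  df <- merge(as.data.frame(stats), as.data.frame(manifest), by = "probe_id")
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    sig <- sub[sub$p_adj < sig_p, ]
    if (nrow(sig) == 0) next
    # maximal chains: split where consecutive significant gaps exceed max_gap
    grp <- cumsum(c(1, diff(sig$pos) > max_gap))
    for (g in unique(grp)) {
      mem <- sig[grp == g, ]
      if (nrow(mem) < min_cpgs) next
      span <- sub[sub$pos >= min(mem$pos) & sub$pos <= max(mem$pos), ]
      md <- mean(span$delta_beta)
      chi2 <- -2 * sum(log(pmax(span$p_raw, 1e-300)))
      cp <- pchisq(chi2, 2 * nrow(span), lower.tail = FALSE)
      if (abs(md) >= delta_min && cp < fisher_p_max) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = min(mem$pos), end = max(mem$pos),
          n_sig = nrow(mem), combined_p = cp)
      }
    }
  }
  if (length(out) == 0) return(data.frame(chrom = character(), start = numeric(),
                                          end = numeric(), n_sig = integer(),
                                          combined_p = numeric()))
  do.call(rbind, out)
}

# Full-permutation one-tailed rank-sum p-value (oracle for small n).
ranksum_perm_oracle <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(N, n1)
  stats <- apply(sets, 2, function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
  mean(stats >= U_obs - 1e-12)
}
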
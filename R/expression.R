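# Expression of DMR-associated genes versus background protein-coding
# genes, per cell type, by one-tailed Wilcoxon rank-sum.

#' Map DMRs to representative genes
#'
#' Resolves each annotated DMR to a single gene: among its annotated genes
#' present in the expression matrix, the one with the highest expression in
#' the evaluated cell type. DMRs with no expressed annotation are dropped
#' (logged), and genes hit by several DMRs are counted once.
#'
#' @param dmrs Annotated DMR tibble (from [annotate_dmrs()]).
#' @param expr Expression tibble from [simulate_expression()] or with the
#'   same columns (`gene`, `cell_type`, `tpm`, `prop_expressed`).
#' @param cell_type Cell type in which expression is evaluated.
#' @return Character vector of unique gene symbols.
#' @export
map_dmr_genes <- function(dmrs, expr, cell_type) {
  ex <- expr[expr$cell_type == cell_type, ]
  if (nrow(ex) == 0) abort(sprintf("cell type '%s' absent from expression matrix", cell_type))
  picked <- character(0)
  n_dropped <- 0
  for (i in seq_len(nrow(dmrs))) {
    if (dmrs$genes[i] %in% c("", "intergenic")) { n_dropped <- n_dropped + 1; next }
    syms <- unique(stringr::str_split_fixed(
      strsplit(dmrs$genes[i], ";", fixed = TRUE)[[1]], ":", 2)[, 1])
    cand <- ex[ex$gene %in% syms, ]
    if (nrow(cand) == 0) { n_dropped <- n_dropped + 1; next }
    picked <- c(picked, cand$gene[which.max(cand$tpm)])
  }
  if (n_dropped > 0) {
    inform(sprintf("%d DMR(s) had no expressed gene annotation and were dropped",
                   n_dropped))
  }
  unique(picked)
}

#' One-tailed Wilcoxon rank-sum test (first sample greater)
#'
#' Mann-Whitney U computed from mid-ranks. The p-value is exact (full
#' enumeration of group assignments) when the combined sample size is at
#' most `exact_max`, and otherwise uses the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param a,b Numeric vectors; the alternative is that `a` is
#'   stochastically greater than `b`.
#' @param exact_max Combined-size cutoff for exact enumeration
#'   (default 12).
#' @return List with `U` (rank-sum statistic for `a`), `p` and `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  x <- c(a, b)
  r <- rank(x)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (N <= exact_max) {
    idx_sets <- combn(N, n1)
    stats <- apply(idx_sets, 2, function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
    p <- mean(stats >= U - 1e-12)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- n1 * n2 / 2
    ties <- table(x)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - 0.5) / sqrt(sigma2)
    list(U = U, p = pnorm(z, lower.tail = FALSE), method = "normal_approx")
  }
}

#' Compare DMR-gene expression to background genes
#'
#' One-tailed Wilcoxon rank-sum test of the hypothesis that DMR-associated
#' genes have higher expression than background (autosomal protein-coding)
#' genes in a given cell type, on either the TPM or the
#' proportion-of-cells-expressing metric.
#'
#' @param dmr_genes,background Disjoint character vectors of gene symbols.
#' @param expr Expression tibble (`gene`, `cell_type`, `tpm`,
#'   `prop_expressed`).
#' @param cell_type Cell type evaluated.
#' @param metric `"tpm"` or `"prop_expressed"`.
#' @param exact_max See [rank_sum_test()].
#' @return One-row tibble: `cell_type`, `metric`, `n_dmr_genes`,
#'   `n_background_genes`, `wilcoxon_W`, `p_one_tailed`, `method`.
#' @export
compare_expression <- function(dmr_genes, background, expr, cell_type,
                               metric = c("tpm", "prop_expressed"),
                               exact_max = 12) {
  metric <- match.arg(metric)
  if (length(dmr_genes) == 0 || length(background) == 0) {
    abort("both gene lists must be non-empty")
  }
  if (length(intersect(dmr_genes, background)) > 0) {
    abort("DMR and background gene lists must be disjoint")
  }
  ex <- expr[expr$cell_type == cell_type, ]
  val <- function(g) {
    v <- ex[[metric]][match(g, ex$gene)]
    miss <- g[is.na(v)]
    if (length(miss) > 0) {
      inform(sprintf("%d gene(s) absent from expression matrix dropped: %s",
                     length(miss), paste(head(miss, 3), collapse = ", ")))
    }
    v[!is.na(v)]
  }
  a <- val(dmr_genes); b <- val(background)
  if (length(a) == 0 || length(b) == 0) abort("no expressed genes left to compare")
  ts <- rank_sum_test(a, b, exact_max)
  tibble(cell_type = cell_type, metric = metric,
         n_dmr_genes = length(a), n_background_genes = length(b),
         wilcoxon_W = ts$U, p_one_tailed = ts$p, method = ts$method)
}
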
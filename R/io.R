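#' Read a beta-value matrix from TSV
#'
#' Reads a probes-by-samples table of methylation beta values. The first
#' column holds probe ids, the header row holds sample ids, and empty cells
#' denote missing measurements (never zero: 0 is a legal beta). Probe and
#' sample order are preserved exactly as in the file.
#'
#' @param path Path to a tab-separated file.
#' @param range Allowed value range; beta values must lie in `[0, 1]`.
#'   Detection p-value matrices share the same layout and range.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames; missing cells are `NA`.
#' @export
read_beta_matrix <- function(path, range = c(0, 1)) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) abort("beta matrix file needs a probe-id column and at least one sample")
  probe_ids <- df[[1]]
  sample_ids <- names(df)[-1]
  mat <- matrix(NA_real_, nrow = length(probe_ids), ncol = length(sample_ids),
                dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    raw <- df[[j + 1]]
    filled <- !is.na(raw) & raw != ""
    vals <- suppressWarnings(as.numeric(raw[filled]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      i <- which(filled)[bad[1]]
      abort(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                    raw[i], probe_ids[i], sample_ids[j]))
    }
    oob <- which(vals < range[1] | vals > range[2])
    if (length(oob) > 0) {
      i <- which(filled)[oob[1]]
      abort(sprintf("value %s outside [%g, %g] at probe '%s', sample '%s'",
                    raw[i], range[1], range[2], probe_ids[i], sample_ids[j]))
    }
    mat[filled, j] <- vals
  }
  if (anyDuplicated(probe_ids)) {
    abort(sprintf("duplicate probe id(s): %s",
                  paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")))
  }
  mat
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()]: values are written with six decimal
#' places and missing entries as empty cells, so a write/read round trip
#' reproduces values to 1e-6 and key order exactly.
#'
#' @param beta Numeric matrix, probes as rows.
#' @param path Output path.
#' @param digits Decimal places written.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, digits = 6) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
  lines <- c(
    paste(c("probe_id", colnames(beta)), collapse = "\t"),
    vapply(seq_len(nrow(beta)), function(i) {
      paste(c(rownames(beta)[i], fmt(beta[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe manifest from CSV
#'
#' The manifest declares the probe universe: genomic position, platform
#' membership (450K subset of EPIC), SNP / cross-reactive flags and gene
#' annotations. Gene annotations are semicolon-separated `symbol:region`
#' pairs with region one of TSS, body, intergenic or lncRNA.
#'
#' @param path Path to a CSV with columns `probe_id`, `chrom`, `pos`,
#'   `on_450k`, `snp_flag`, `cross_reactive_flag`, `genes`.
#' @return A tibble, one row per probe; `genes` is kept as the raw string
#'   (empty when unannotated). Use [manifest_gene_map()] to expand it.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_double(),
    on_450k = readr::col_logical(),
    snp_flag = readr::col_logical(),
    cross_reactive_flag = readr::col_logical(),
    genes = readr::col_character()
  ), progress = FALSE)
  df$genes[is.na(df$genes)] <- ""
  validate_manifest(as_tibble(df))
}

#' @rdname read_manifest
#' @param manifest A manifest tibble to validate (duplicate ids and
#'   non-positive coordinates are errors).
#' @export
validate_manifest <- function(manifest) {
  needed <- c("probe_id", "chrom", "pos", "on_450k", "snp_flag",
              "cross_reactive_flag", "genes")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(manifest$probe_id[duplicated(manifest$probe_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate probe id(s) in manifest: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (any(manifest$pos < 1)) abort("manifest positions must be >= 1 (1-based)")
  manifest
}

#' Write a probe manifest to CSV
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Expand manifest gene annotations
#'
#' @param manifest Manifest tibble.
#' @return Tibble with one row per (probe, gene) pair: `probe_id`, `gene`,
#'   `region`. Probes without annotation are absent.
#' @export
manifest_gene_map <- function(manifest) {
  ann <- manifest[manifest$genes != "", c("probe_id", "genes")]
  if (nrow(ann) == 0) {
    return(tibble(probe_id = character(), gene = character(), region = character()))
  }
  pairs <- strsplit(ann$genes, ";", fixed = TRUE)
  out <- tibble(
    probe_id = rep(ann$probe_id, lengths(pairs)),
    pair = unlist(pairs)
  )
  parts <- stringr::str_split_fixed(out$pair, ":", 2)
  tibble(probe_id = out$probe_id, gene = parts[, 1], region = parts[, 2])
}

#' Read a sample sheet from CSV
#'
#' @param path CSV with columns `sample_id`, `group` (one of
#'   `case_biallelic`, `case_monoallelic`, `control`, `query`), `age_years`,
#'   `sex` (`F`/`M`) and `batch`.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    age_years = readr::col_double(),
    sex = readr::col_character(),
    batch = readr::col_character()
  ), progress = FALSE)
  validate_sample_sheet(as_tibble(df))
}

#' @rdname read_sample_sheet
#' @param samples Sample sheet tibble to validate.
#' @export
validate_sample_sheet <- function(samples) {
  groups <- c("case_biallelic", "case_monoallelic", "control", "query")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(samples$group), groups)
  if (length(bad) > 0) {
    abort(sprintf("unknown group label(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "), paste(groups, collapse = ", ")))
  }
  if (any(!samples$sex %in% c("F", "M"))) abort("sex must be 'F' or 'M'")
  if (any(samples$age_years < 0)) abort("age_years must be nonnegative")
  samples
}

#' Restrict a probe list to an array platform
#'
#' Signatures discovered on the EPIC array can only be applied to 450K data
#' through the probes shared by both platforms; this drops probes absent
#' from the requested platform while preserving input order.
#'
#' @param signature_probes Character vector of probe ids.
#' @param manifest Manifest tibble; every probe must be present.
#' @param platform `"EPIC"` (identity) or `"K450"` (keep `on_450k` probes).
#' @return The retained probe ids, in input order.
#' @export
restrict_to_platform <- function(signature_probes, manifest, platform = c("EPIC", "K450")) {
  platform <- match.arg(platform)
  idx <- match(signature_probes, manifest$probe_id)
  if (anyNA(idx)) {
    abort(sprintf("probe id(s) not in manifest: %s",
                  paste(head(signature_probes[is.na(idx)], 5), collapse = ", ")))
  }
  if (platform == "EPIC") return(signature_probes)
  signature_probes[manifest$on_450k[idx]]
}

#' Write a DMR set as BED6
#'
#' Internal coordinates are 1-based inclusive; BED uses 0-based half-open,
#' so `start` is decremented on export. The score column is
#' `-10 * log10(combined_p)` clamped to `[0, 1000]`; name is the DMR rank.
#'
#' @param dmrs DMR tibble from [find_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  header <- "# chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(dmrs) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- round(pmin(pmax(-10 * log10(dmrs$combined_p), 0), 1000))
  lines <- sprintf("%s\t%d\t%d\tDMR_%d\t%d\t.",
                   dmrs$chrom, as.integer(dmrs$start - 1L), as.integer(dmrs$end),
                   seq_len(nrow(dmrs)), as.integer(score))
  writeLines(c(header, lines), path)
  invisible(path)
}
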
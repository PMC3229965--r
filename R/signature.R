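#' The published epigenetic aging signature
#'
#' Returns the frozen five-CpG aging signature — four CpG sites
#' hypermethylated with donor age (TRIM58, KCNQ1DN, NPTX2, GRIA2) plus one
#' hypomethylated site (BIRC4BP) — or its three-CpG variant restricted to
#' the most significant hypermethylated sites (KCNQ1DN, NPTX2, GRIA2).
#'
#' @param variant `"five"` (default) or `"three"`.
#' @return A signature tibble with columns `cpg_id`, `role`
#'   (`"hyper"`/`"hypo"`), `gene_label`.
#' @export
#' @examples
#' published_signature("five")
published_signature <- function(variant = c("five", "three")) {
  variant <- match.arg(variant)
  five <- tibble::tibble(
    cpg_id = c("cg07533148", "cg01530101", "cg12799895", "cg25148589",
               "cg23571857"),
    role = c("hyper", "hyper", "hyper", "hyper", "hypo"),
    gene_label = c("TRIM58", "KCNQ1DN", "NPTX2", "GRIA2", "BIRC4BP")
  )
  if (variant == "five") {
    five
  } else {
    five[five$gene_label %in% c("KCNQ1DN", "NPTX2", "GRIA2"), , drop = FALSE]
  }
}

#' Validate a signature tibble
#'
#' @param spec A data frame with columns `cpg_id` and `role`; an optional
#'   `gene_label` column is filled with `NA` when absent.
#' @return A validated signature tibble.
#' @export
validate_signature <- function(spec) {
  if (!is.data.frame(spec) || !all(c("cpg_id", "role") %in% names(spec))) {
    stop("signature: need columns 'cpg_id' and 'role'", call. = FALSE)
  }
  if (nrow(spec) < 1L) {
    stop("signature: need at least one CpG", call. = FALSE)
  }
  if (anyDuplicated(spec$cpg_id)) {
    stop("signature: duplicate probe ID '",
         spec$cpg_id[duplicated(spec$cpg_id)][1L], "'", call. = FALSE)
  }
  if (!all(spec$role %in% c("hyper", "hypo"))) {
    stop("signature: role must be 'hyper' or 'hypo'", call. = FALSE)
  }
  spec <- tibble::as_tibble(spec)
  if (!"gene_label" %in% names(spec)) spec$gene_label <- NA_character_
  spec[, c("cpg_id", "role", "gene_label")]
}

#' Methylation dynamic range over the observed age span
#'
#' The absolute change in fitted beta between the youngest and oldest
#' donor, from the ordinary least-squares line of beta on age. Larger
#' dynamic range means the age trend is less easily swamped by technical
#' noise, so it is one of the signature-selection filters.
#'
#' @param betas,ages Paired numeric vectors; pairs with missing values are
#'   dropped.
#' @return The absolute fitted beta change (unitless, in beta units).
#' @export
dynamic_range <- function(betas, ages) {
  keep <- !is.na(betas) & !is.na(ages)
  betas <- betas[keep]
  ages <- ages[keep]
  if (length(betas) < 3L) {
    stop("dynamic_range: fewer than 3 complete pairs", call. = FALSE)
  }
  if (length(unique(ages)) < 2L) {
    stop("dynamic_range: constant ages", call. = FALSE)
  }
  slope <- stats::cov(betas, ages) / stats::var(ages)
  abs(slope) * (max(ages) - min(ages))
}

#' Select signature CpGs from screening results
#'
#' Encodes a reproducible version of the published selection logic: a CpG
#' is eligible if (1) it appears in the combined-cohort screening results
#' with the requested direction, (2) its per-dataset correlation clears
#' `min_per_dataset_r` (with the sign of its direction) in at least
#' `min_datasets` datasets, and (3) its methylation dynamic range over the
#' combined age span is at least `min_range`. Eligible hypermethylated
#' candidates are ranked by combined correlation (descending, ties by
#' probe ID) and the top `k_hyper` are taken; hypomethylated candidates
#' analogously with the sign flipped.
#'
#' @param combined Screening tibble from [run_ptm()] (columns `cpg_id`,
#'   `r`, and `direction`).
#' @param per_dataset Wide per-dataset correlation table from
#'   [per_dataset_ptm()] covering at least the combined candidates.
#' @param beta Combined beta-value tibble (for dynamic range).
#' @param annotations Annotation tibble for the combined samples.
#' @param k_hyper Number of hypermethylated CpGs to select.
#' @param k_hypo Number of hypomethylated CpGs to select.
#' @param min_per_dataset_r Per-dataset correlation floor (default 0.3).
#' @param min_range Dynamic-range floor in beta units (default 0.05).
#' @param min_datasets Number of datasets that must clear the per-dataset
#'   floor; default is a majority, `ceiling(n_datasets / 2)`.
#' @return A signature tibble (`cpg_id`, `role`, `gene_label`).
#' @export
select_signature <- function(combined, per_dataset, beta, annotations,
                             k_hyper = 4L, k_hypo = 1L,
                             min_per_dataset_r = 0.3, min_range = 0.05,
                             min_datasets = NULL) {
  if (k_hyper + k_hypo < 1L) {
    stop("select_signature: k_hyper + k_hypo must be at least 1",
         call. = FALSE)
  }
  if (nrow(combined) == 0L) {
    stop("select_signature: empty screening results", call. = FALSE)
  }
  validate_beta_matrix(beta)
  ann <- validate_annotations(annotations)
  ds_cols <- setdiff(names(per_dataset), "cpg_id")
  if (is.null(min_datasets)) {
    min_datasets <- ceiling(length(ds_cols) / 2)
  }
  ages <- ann$age[match(names(beta)[-1L], ann$sample_id)]

  eligible <- function(cand, sign) {
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      id <- cand$cpg_id[i]
      row <- per_dataset[per_dataset$cpg_id == id, ds_cols, drop = FALSE]
      rs <- sign * as.numeric(row[1L, ])
      n_ok <- sum(!is.na(rs) & rs >= min_per_dataset_r)
      if (n_ok < min_datasets) next
      b <- as.numeric(beta[beta$cpg_id == id, -1L])
      if (dynamic_range(b, ages) < min_range) next
      keep[i] <- TRUE
    }
    cand[keep, , drop = FALSE]
  }

  pick <- function(dir, k, sign) {
    if (k == 0L) return(NULL)
    cand <- combined[combined$direction == dir, , drop = FALSE]
    cand <- cand[order(-sign * cand$r, cand$cpg_id), , drop = FALSE]
    cand <- eligible(cand, sign)
    if (nrow(cand) < k) {
      stop("select_signature: only ", nrow(cand), " eligible ", dir,
           "methylated candidate(s) for the ", k, " requested",
           call. = FALSE)
    }
    tibble::tibble(cpg_id = cand$cpg_id[seq_len(k)], role = dir,
                   gene_label = NA_character_)
  }

  validate_signature(dplyr::bind_rows(pick("hyper", k_hyper, 1),
                                      pick("hypo", k_hypo, -1)))
}

#' Write / read a signature as structured text
#'
#' A small versioned TSV: comment header carrying the format version,
#' then one row per probe (`cpg_id`, `role`, `gene_label`).
#'
#' @param spec A signature tibble.
#' @param path File path.
#' @return `path` invisibly (write) or the signature tibble (read).
#' @export
write_signature <- function(spec, path) {
  spec <- validate_signature(spec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# methylage signature format 1", con)
  writeLines(paste(c("cpg_id", "role", "gene_label"), collapse = "\t"), con)
  writeLines(paste(spec$cpg_id, spec$role,
                   ifelse(is.na(spec$gene_label), "NA", spec$gene_label),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) {
    stop("signature file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          sep = "\t", na.strings = "NA",
                          colClasses = "character")
  validate_signature(df)
}
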
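#' Beta-value matrices as tibbles
#'
#' Throughout the package a beta matrix is a tibble whose first column,
#' `cpg_id`, holds Illumina probe identifiers (one row per CpG site) and
#' whose remaining columns are numeric per-sample methylation fractions
#' (beta values) in \[0, 1\], with `NA` as the explicit missing marker.
#' This mirrors how Infinium series matrices ship: probes in rows, samples
#' in columns. Sample annotations are a companion tibble with one row per
#' sample (`sample_id`, `age` in years, `dataset`, optional `sex`).
#'
#' @name beta-matrix
#' @keywords internal
NULL

#' Validate a beta-value tibble
#'
#' Checks the structural contract of a beta matrix: a `cpg_id` character
#' column first, numeric sample columns after it, unique probe and sample
#' identifiers, and all non-missing values within \[0, 1\].
#'
#' @param beta A beta-value tibble (see [beta-matrix]).
#' @param what Label used in error messages.
#' @return `beta`, invisibly, if valid. Otherwise an error naming the
#'   offending probe or sample.
#' @export
validate_beta_matrix <- function(beta, what = "beta matrix") {
  if (!is.data.frame(beta) || ncol(beta) < 2L) {
    stop(what, ": expected a data frame with a 'cpg_id' column followed by ",
         "at least one sample column", call. = FALSE)
  }
  if (names(beta)[1L] != "cpg_id") {
    stop(what, ": first column must be 'cpg_id', found '", names(beta)[1L],
         "'", call. = FALSE)
  }
  if (anyDuplicated(beta$cpg_id)) {
    dup <- beta$cpg_id[duplicated(beta$cpg_id)][1L]
    stop(what, ": duplicate probe ID '", dup, "'", call. = FALSE)
  }
  if (anyDuplicated(names(beta))) {
    dup <- names(beta)[duplicated(names(beta))][1L]
    stop(what, ": duplicate sample ID '", dup, "'", call. = FALSE)
  }
  for (s in names(beta)[-1L]) {
    v <- beta[[s]]
    if (!is.numeric(v)) {
      stop(what, ": sample column '", s, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop(what, ": beta value ", format(v[bad[1L]]), " outside [0, 1] at ",
           "probe '", beta$cpg_id[bad[1L]], "', sample '", s, "'",
           call. = FALSE)
    }
  }
  invisible(beta)
}

#' Read a beta-value matrix from tab-separated text
#'
#' Expects a header row `cpg_id<TAB>sample...` followed by one row per
#' probe; cells are numeric beta values or `NA`. Missing cells are carried
#' through as `NA`, never dropped.
#'
#' @param path Path to a TSV file.
#' @return A validated beta-value tibble.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("cpg_id\tS1\tS2", "cg0001\t0.1\t0.5", "cg0002\t0.9\tNA"), tf)
#' read_beta_matrix(tf)
read_beta_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("beta matrix file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stop("beta matrix file is empty: ", path, call. = FALSE)
  }
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 2L || cols[1L] != "cpg_id") {
    stop("malformed beta matrix header (line 1) in ", path,
         ": expected 'cpg_id' followed by sample IDs", call. = FALSE)
  }
  # base strtod parsing is correctly rounded, so serialized doubles
  # round-trip bit-exactly
  df <- utils::read.delim(
    path, sep = "\t", header = TRUE, check.names = FALSE, quote = "",
    na.strings = "NA",
    colClasses = c("character", rep("numeric", length(cols) - 1L))
  )
  beta <- tibble::as_tibble(df)
  validate_beta_matrix(beta, what = paste0("beta matrix '", path, "'"))
}

#' Write a beta-value matrix to tab-separated text
#'
#' Values are serialized with 17 significant digits so a read/write/read
#' round trip reproduces every non-missing double bit-exactly; missing
#' cells are written as `NA`.
#'
#' @param beta A beta-value tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  out <- beta
  for (s in names(out)[-1L]) {
    v <- sprintf("%.17g", out[[s]])
    v[is.na(out[[s]])] <- "NA"
    out[[s]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read per-sample annotations
#'
#' Expects tab-separated text with header columns `sample_id`, `age`,
#' `dataset` and optionally `sex`. Ages are parsed as real years; age 0
#' is valid (cord blood donors).
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  validate_annotations(ann)
}

#' Validate a sample-annotation tibble
#'
#' @param ann A data frame with columns `sample_id`, `age`, `dataset`
#'   (optional `sex`).
#' @return A tibble with `age` numeric, or an error for negative ages,
#'   missing columns, or duplicate sample IDs.
#' @export
validate_annotations <- function(ann) {
  need <- c("sample_id", "age", "dataset")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotations: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann <- tibble::as_tibble(ann)
  ann$age <- as.numeric(ann$age)
  if (anyNA(ann$age)) {
    stop("annotations: non-numeric or missing age for sample '",
         ann$sample_id[which(is.na(ann$age))[1L]], "'", call. = FALSE)
  }
  if (any(ann$age < 0)) {
    stop("annotations: negative age for sample '",
         ann$sample_id[which(ann$age < 0)[1L]], "'", call. = FALSE)
  }
  if (any(!nzchar(ann$sample_id) | is.na(ann$sample_id))) {
    stop("annotations: empty sample_id", call. = FALSE)
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("annotations: duplicate sample_id '",
         ann$sample_id[duplicated(ann$sample_id)][1L], "'", call. = FALSE)
  }
  ann
}

#' Write per-sample annotations
#'
#' @param ann An annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(validate_annotations(ann), path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Combine beta matrices from several datasets
#'
#' Joins datasets on the probe reference ID: the combined matrix keeps the
#' intersection of all input probe sets, in the order of the first matrix,
#' and concatenates samples in input order. No normalization of any kind is
#' applied — datasets are combined on raw beta values so genuine
#' between-tissue methylation differences are not masked.
#'
#' @param matrices A list of beta-value tibbles with disjoint sample IDs.
#' @return A combined beta-value tibble.
#' @export
combine_datasets <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("combine_datasets: need at least one beta matrix", call. = FALSE)
  }
  purrr::walk(matrices, validate_beta_matrix)
  if (length(matrices) == 1L) {
    return(tibble::as_tibble(matrices[[1L]]))
  }
  samples <- unlist(purrr::map(matrices, ~ names(.x)[-1L]))
  if (anyDuplicated(samples)) {
    stop("combine_datasets: duplicate sample ID '",
         samples[duplicated(samples)][1L], "' across inputs", call. = FALSE)
  }
  shared <- purrr::reduce(purrr::map(matrices, "cpg_id"), intersect)
  if (length(shared) == 0L) {
    stop("combine_datasets: no probe ID shared by all inputs",
         call. = FALSE)
  }
  # keep the first matrix's probe order
  shared <- matrices[[1L]]$cpg_id[matrices[[1L]]$cpg_id %in% shared]
  aligned <- purrr::imap(matrices, function(m, i) {
    m <- m[match(shared, m$cpg_id), , drop = FALSE]
    if (i == 1L) m else m[, -1L, drop = FALSE]
  })
  dplyr::bind_cols(aligned)
}

#' Per-sample quantile summary of beta values
#'
#' Computes empirical quantiles of the non-missing beta values of each
#' sample, using linear interpolation between order statistics. Used to
#' inspect whether the global methylation distribution differs across
#' samples or datasets before any screening.
#'
#' @param beta A beta-value tibble.
#' @param levels Quantile levels, probabilities in \[0, 1\].
#' @return A long tibble with columns `sample_id`, `level`, `value`.
#' @export
quantile_summary <- function(beta, levels = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  validate_beta_matrix(beta)
  if (any(levels < 0 | levels > 1) || anyNA(levels)) {
    stop("quantile_summary: levels must be probabilities in [0, 1]",
         call. = FALSE)
  }
  purrr::map_dfr(names(beta)[-1L], function(s) {
    v <- beta[[s]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop("quantile_summary: sample '", s, "' has no non-missing values",
           call. = FALSE)
    }
    tibble::tibble(
      sample_id = s,
      level = as.numeric(levels),
      value = unname(stats::quantile(v, probs = levels, type = 7))
    )
  })
}

#' Plot per-sample beta-value quantiles
#'
#' @param quantiles Output of [quantile_summary()].
#' @param annotations Optional annotation tibble; when given, lines are
#'   coloured by dataset.
#' @return A ggplot object.
#' @export
plot_quantile_summary <- function(quantiles, annotations = NULL) {
  df <- quantiles
  if (!is.null(annotations)) {
    df <- dplyr::left_join(df,
                           dplyr::select(validate_annotations(annotations),
                                         "sample_id", "dataset"),
                           by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$level, y = .data$value,
      group = .data$sample_id, colour = .data$dataset))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$level, y = .data$value, group = .data$sample_id))
  }
  p +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "quantile level", y = expression(beta)) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
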
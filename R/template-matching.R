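#' Build an age template for template matching
#'
#' Rescales donor ages to relative values in \[0, 1\] by min–max scaling,
#' one template value per sample. Pearson correlation is invariant under
#' this positive affine rescaling, so the scaled template ranks CpGs
#' identically to raw ages; the scaling is kept because the template is
#' also a convenient display axis.
#'
#' @param annotations Annotation tibble (`sample_id`, `age`, `dataset`).
#' @return A tibble with columns `sample_id`, `age`, `template`.
#' @export
#' @examples
#' ann <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                       age = c(20, 45, 70), dataset = "d")
#' build_age_template(ann)
build_age_template <- function(annotations) {
  ann <- validate_annotations(annotations)
  if (nrow(ann) < 2L) {
    stop("build_age_template: need at least two samples", call. = FALSE)
  }
  rng <- range(ann$age)
  if (rng[1L] == rng[2L]) {
    stop("build_age_template: all donor ages are equal (",
         rng[1L], " yrs); a constant template has no correlation",
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = ann$sample_id,
    age = ann$age,
    template = (ann$age - rng[1L]) / (rng[2L] - rng[1L])
  )
}

#' Pearson product-moment correlation with pairwise-complete filtering
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   in either vector are dropped before the computation.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pearson_r: x and y must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) {
    stop("pearson_r: fewer than 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: correlation undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of the sample correlation for
#' independent normal errors: `t = |r| * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom, doubled for a two-sided test.
#'
#' @param r Correlation coefficient, `|r| <= 1`.
#' @param n Number of sample pairs, at least 3.
#' @return A p-value in (0, 1]. `|r| = 1` returns the smallest positive
#'   double with a warning, since the t statistic is infinite there.
#' @export
#' @examples
#' correlation_p_value(0.6, 130) # far below 1e-13
correlation_p_value <- function(r, n) {
  if (any(n < 3L)) {
    stop("correlation_p_value: need n >= 3", call. = FALSE)
  }
  if (any(abs(r) > 1)) {
    stop("correlation_p_value: |r| must not exceed 1", call. = FALSE)
  }
  p <- rep(NA_real_, length(r))
  exact <- abs(r) >= 1
  if (any(exact)) {
    warning("correlation_p_value: |r| = 1, returning smallest positive value")
    p[exact] <- .Machine$double.xmin
  }
  ok <- !exact
  if (any(ok)) {
    nn <- rep_len(n, length(r))[ok]
    tt <- abs(r[ok]) * sqrt((nn - 2) / (1 - r[ok]^2))
    p[ok] <- pmax(2 * stats::pt(tt, df = nn - 2, lower.tail = FALSE),
                  .Machine$double.xmin)
    p[ok] <- pmin(p[ok], 1)
  }
  p
}

#' Screen CpG sites by template matching
#'
#' Correlates each CpG's beta values against the age template (Pearson
#' correlation over pairwise-complete samples) and retains the sites whose
#' correlation passes the threshold in the requested direction:
#' hypermethylated with age (`r >= r_threshold`), hypomethylated
#' (`r <= -r_threshold`), or both (`|r| >= r_threshold`). Results are
#' ordered by `|r|` descending, ties broken by probe ID.
#'
#' A Bonferroni-adjusted p-value over the number of CpGs tested is
#' reported for information only; the retained set is thresholded on raw
#' `r`, not on adjusted significance.
#'
#' @param beta A beta-value tibble.
#' @param template Output of [build_age_template()]; its samples must all
#'   be present in `beta`.
#' @param r_threshold Correlation threshold in \[0, 1\] (default 0.6).
#' @param direction `"hyper"`, `"hypo"`, or `"both"`.
#' @param min_n Minimum pairwise-complete sample count per CpG (default 8);
#'   guards against spurious perfect correlations on tiny subsets.
#' @return A tibble with columns `cpg_id`, `r`, `p`, `n_used`, `direction`,
#'   `p_bonferroni`, one row per retained CpG.
#' @export
run_ptm <- function(beta, template, r_threshold = 0.6,
                    direction = c("hyper", "hypo", "both"), min_n = 8L) {
  direction <- match.arg(direction)
  validate_beta_matrix(beta)
  if (!is.numeric(r_threshold) || r_threshold < 0 || r_threshold > 1) {
    stop("run_ptm: r_threshold must be in [0, 1]", call. = FALSE)
  }
  present <- intersect(template$sample_id, names(beta)[-1L])
  if (length(present) == 0L) {
    stop("run_ptm: no template sample is present in the beta matrix",
         call. = FALSE)
  }
  tv <- template$template[match(present, template$sample_id)]
  mat <- as.matrix(beta[, present, drop = FALSE])
  rownames(mat) <- beta$cpg_id

  stats_tbl <- cpg_template_correlations(mat, tv)
  n_tested <- sum(!is.na(stats_tbl$r))

  keep <- switch(direction,
    hyper = !is.na(stats_tbl$r) & stats_tbl$r >= r_threshold,
    hypo  = !is.na(stats_tbl$r) & stats_tbl$r <= -r_threshold,
    both  = !is.na(stats_tbl$r) & abs(stats_tbl$r) >= r_threshold
  )
  keep <- keep & stats_tbl$n_used >= min_n
  out <- stats_tbl[keep, , drop = FALSE]
  out$direction <- ifelse(out$r > 0, "hyper", "hypo")
  out$p_bonferroni <- pmin(out$p * n_tested, 1)
  out[order(-abs(out$r), out$cpg_id), , drop = FALSE]
}

# Vectorized per-CpG Pearson r and p against one template vector.
# Constant or under-sampled CpGs get NA r rather than an error: screening
# over thousands of probes must not abort on a degenerate row.
cpg_template_correlations <- function(mat, tv) {
  ok <- !is.na(mat)
  n_used <- as.integer(rowSums(ok))
  x <- ifelse(ok, mat, 0)
  tvm <- matrix(tv, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE)
  sum_t <- rowSums(ifelse(ok, tvm, 0))
  sum_t2 <- rowSums(ifelse(ok, tvm^2, 0))
  sum_x <- rowSums(x)
  sum_x2 <- rowSums(x^2)
  sum_xt <- rowSums(x * tvm)
  num <- n_used * sum_xt - sum_x * sum_t
  den2 <- (n_used * sum_x2 - sum_x^2) * (n_used * sum_t2 - sum_t^2)
  r <- ifelse(n_used >= 3L & den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  # exact |r| = 1 (noiseless data) gets the smallest positive double
  # without the scalar API's warning: screening must stay quiet
  ex <- !is.na(r) & abs(r) >= 1
  p[ex] <- .Machine$double.xmin
  comp <- !is.na(r) & !ex
  if (any(comp)) {
    p[comp] <- correlation_p_value(r[comp], n_used[comp])
  }
  tibble::tibble(cpg_id = rownames(mat), r = unname(r), p = unname(p),
                 n_used = unname(n_used))
}

#' Per-dataset template-matching correlations for named CpGs
#'
#' Recomputes the Pearson correlation of each named CpG against a
#' dataset-specific age template, one value per (CpG, dataset) cell.
#' Datasets in which the correlation is not computable — fewer than three
#' samples, constant ages, or a constant beta vector — yield an explicit
#' `NA` cell rather than being dropped.
#'
#' @param beta A beta-value tibble.
#' @param annotations Annotation tibble covering the matrix samples.
#' @param cpg_ids Probes to evaluate; all must be present in `beta`.
#' @return A wide tibble: one row per `cpg_id`, one column per dataset
#'   label, `NA` for not-computable cells.
#' @export
per_dataset_ptm <- function(beta, annotations, cpg_ids) {
  validate_beta_matrix(beta)
  ann <- validate_annotations(annotations)
  missing_cpg <- setdiff(cpg_ids, beta$cpg_id)
  if (length(missing_cpg)) {
    stop("per_dataset_ptm: probe '", missing_cpg[1L],
         "' absent from the beta matrix", call. = FALSE)
  }
  ann <- ann[ann$sample_id %in% names(beta)[-1L], , drop = FALSE]
  sub <- beta[match(cpg_ids, beta$cpg_id), , drop = FALSE]
  out <- tibble::tibble(cpg_id = cpg_ids)
  for (ds in unique(ann$dataset)) {
    ids <- ann$sample_id[ann$dataset == ds]
    ages <- ann$age[ann$dataset == ds]
    col <- rep(NA_real_, length(cpg_ids))
    if (length(ids) >= 3L && length(unique(ages)) >= 2L) {
      tv <- (ages - min(ages)) / (max(ages) - min(ages))
      mat <- as.matrix(sub[, ids, drop = FALSE])
      rownames(mat) <- cpg_ids
      col <- cpg_template_correlations(mat, tv)$r
    }
    out[[ds]] <- col
  }
  out
}
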
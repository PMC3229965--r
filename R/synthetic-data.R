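#' Specify a synthetic multi-dataset methylation cohort
#'
#' Describes a cohort of several datasets (tissues/cell types) with
#' distinct sample sizes and age ranges, a handful of planted
#' age-associated "signature" CpGs whose beta values drift linearly with
#' donor age, and a background of null CpGs with no age trend. Planted
#' slopes are drawn from `slope_range` (beta units per year; negated for
#' hypomethylated CpGs) and intercepts from `baseline_range`
#' (hypomethylated intercepts are mirrored to `1 - baseline_range`), so
#' that with the defaults every planted line stays well inside \[0, 1\]
#' over the cohort's age span. Each dataset applies a per-CpG constant
#' tissue offset (Gaussian, `tissue_offset_sd`), emulating tissue-specific
#' baseline methylation, and i.i.d. Gaussian measurement noise
#' (`noise_sd`) is added to every cell before clipping to \[0, 1\].
#'
#' @param datasets A tibble with columns `label`, `n_samples`, `age_min`,
#'   `age_max` (years), `tissue_offset_sd` (beta units).
#' @param n_signature_hyper,n_signature_hypo Planted CpG counts.
#' @param n_null_cpgs Background CpGs with no age trend.
#' @param slope_range Interval of planted slope magnitudes (beta/yr).
#' @param baseline_range Interval of planted intercepts (beta units).
#' @param noise_sd Measurement noise SD (beta units).
#' @param seed Master integer seed; every random draw flows from it via a
#'   per-dataset counter, so adding a dataset never perturbs the draws of
#'   the others.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(datasets,
                        n_signature_hyper = 4L, n_signature_hypo = 1L,
                        n_null_cpgs = 500L,
                        slope_range = c(0.002, 0.006),
                        baseline_range = c(0.1, 0.3),
                        noise_sd = 0.03, seed = 1L) {
  datasets <- tibble::as_tibble(datasets)
  need <- c("label", "n_samples", "age_min", "age_max", "tissue_offset_sd")
  miss <- setdiff(need, names(datasets))
  if (length(miss)) {
    stop("cohort_spec: datasets missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(datasets$age_min > datasets$age_max)) {
    stop("cohort_spec: age_min > age_max", call. = FALSE)
  }
  if (any(datasets$n_samples < 0) || any(datasets$tissue_offset_sd < 0) ||
      n_signature_hyper < 0 || n_signature_hypo < 0 || n_null_cpgs < 0 ||
      noise_sd < 0) {
    stop("cohort_spec: counts and standard deviations must be >= 0",
         call. = FALSE)
  }
  if (length(slope_range) != 2L || any(slope_range <= 0) ||
      slope_range[1L] > slope_range[2L]) {
    stop("cohort_spec: slope_range must be a positive increasing interval",
         call. = FALSE)
  }
  if (length(baseline_range) != 2L ||
      any(baseline_range < 0 | baseline_range > 1) ||
      baseline_range[1L] > baseline_range[2L]) {
    stop("cohort_spec: baseline_range must be an increasing interval in ",
         "[0, 1]", call. = FALSE)
  }
  if (n_signature_hyper + n_signature_hypo + n_null_cpgs < 1L) {
    stop("cohort_spec: need at least one CpG", call. = FALSE)
  }
  if (sum(datasets$n_samples) < 2L) {
    stop("cohort_spec: need at least two samples in total", call. = FALSE)
  }
  structure(list(
    datasets = datasets,
    n_signature_hyper = as.integer(n_signature_hyper),
    n_signature_hypo = as.integer(n_signature_hypo),
    n_null_cpgs = as.integer(n_null_cpgs),
    slope_range = as.numeric(slope_range),
    baseline_range = as.numeric(baseline_range),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' The frozen training-cohort specification
#'
#' Mirrors the structure of the five published training cohorts: dermis
#' (n = 20, ages 18-72), epidermis (n = 30, 19-72), cervical smear
#' (n = 30, 26-43), CD4 T-cells (n = 24, 16-69) and CD14 monocytes
#' (n = 26, 16-69) — 130 samples in total — with 4 planted
#' hypermethylated and 1 hypomethylated CpG among 500 null CpGs,
#' measurement noise SD 0.03 and tissue offset SD 0.01.
#'
#' @param seed Master seed (default 1).
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
training_cohort_spec <- function(seed = 1L, ...) {
  datasets <- tibble::tibble(
    label = c("dermis", "epidermis", "cervical smear", "CD4 T-cells",
              "CD14 monocytes"),
    n_samples = c(20L, 30L, 30L, 24L, 26L),
    age_min = c(18, 19, 26, 16, 16),
    age_max = c(72, 72, 43, 69, 69),
    tissue_offset_sd = 0.01
  )
  cohort_spec(datasets, seed = seed, ...)
}

# Deterministic sub-seed for component `i` of master seed `seed`;
# stays within the 32-bit signed integer range.
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic cohort with planted age-associated CpGs
#'
#' Draws donor ages uniformly within each dataset's range and emits a
#' beta matrix where planted CpGs follow
#' `clip(intercept + slope * age + tissue_offset + noise, 0, 1)` and null
#' CpGs follow the same recipe with zero slope. Fully deterministic given
#' the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param truth Optional ground truth from a previous call (its `cpgs`
#'   table); reusing it generates an independent cohort — new donors,
#'   offsets and noise — from the same underlying planted CpG model, e.g.
#'   a validation cohort for a model trained on the original one.
#' @return A list with `beta` (beta-value tibble), `annotations`
#'   (sample annotations) and `truth` (list: `cpgs` tibble with
#'   `cpg_id`, `role`, `true_intercept`, `true_slope`).
#' @export
generate_cohort <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(truth)) {
    truth <- list(cpgs = draw_ground_truth(spec))
  }
  cpgs <- truth$cpgs
  n_cpg <- nrow(cpgs)
  mats <- vector("list", nrow(spec$datasets))
  anns <- vector("list", nrow(spec$datasets))
  for (i in seq_len(nrow(spec$datasets))) {
    ds <- spec$datasets[i, ]
    set.seed(sub_seed(spec$seed, i))
    n <- ds$n_samples
    if (n == 0L) next
    ages <- stats::runif(n, ds$age_min, ds$age_max)
    offsets <- stats::rnorm(n_cpg, 0, ds$tissue_offset_sd)
    noise <- matrix(stats::rnorm(n_cpg * n, 0, spec$noise_sd),
                    nrow = n_cpg, ncol = n)
    line <- outer(cpgs$true_slope, ages) + cpgs$true_intercept + offsets
    vals <- pmin(pmax(line + noise, 0), 1)
    ids <- sprintf("%s_s%03d", gsub("[^A-Za-z0-9]+", "_", ds$label),
                   seq_len(n))
    m <- tibble::as_tibble(vals, .name_repair = "minimal")
    names(m) <- ids
    mats[[i]] <- dplyr::bind_cols(tibble::tibble(cpg_id = cpgs$cpg_id), m)
    anns[[i]] <- tibble::tibble(sample_id = ids, age = ages,
                                dataset = ds$label)
  }
  beta <- combine_datasets(purrr::compact(mats))
  annotations <- dplyr::bind_rows(anns)
  validate_beta_matrix(beta)
  list(beta = beta, annotations = annotations, truth = truth)
}

# Draw planted and null CpG parameters from the spec's master seed.
draw_ground_truth <- function(spec) {
  set.seed(sub_seed(spec$seed, 0L))
  n_hyper <- spec$n_signature_hyper
  n_hypo <- spec$n_signature_hypo
  n_null <- spec$n_null_cpgs
  total <- n_hyper + n_hypo + n_null
  ids <- sprintf("cg%08d", seq_len(total))
  role <- c(rep("hyper", n_hyper), rep("hypo", n_hypo),
            rep("null", n_null))
  slope <- numeric(total)
  intercept <- numeric(total)
  if (n_hyper > 0) {
    slope[role == "hyper"] <- stats::runif(n_hyper, spec$slope_range[1L],
                                           spec$slope_range[2L])
    intercept[role == "hyper"] <- stats::runif(n_hyper,
                                               spec$baseline_range[1L],
                                               spec$baseline_range[2L])
  }
  if (n_hypo > 0) {
    slope[role == "hypo"] <- -stats::runif(n_hypo, spec$slope_range[1L],
                                           spec$slope_range[2L])
    intercept[role == "hypo"] <- 1 - stats::runif(n_hypo,
                                                  spec$baseline_range[1L],
                                                  spec$baseline_range[2L])
  }
  if (n_null > 0) {
    intercept[role == "null"] <- stats::runif(n_null, 0.1, 0.9)
  }
  tibble::tibble(cpg_id = ids, role = role, true_intercept = intercept,
                 true_slope = slope)
}

#' Write the planted-CpG ground truth as tab-separated text
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth$cpgs, path, na = "NA", progress = FALSE)
  invisible(path)
}
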
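#' Fit a per-CpG linear calibration of beta against age
#'
#' Ordinary least squares of beta (response) on donor age (predictor),
#' `beta ~ A + B * age` — the classical-calibration direction: the line is
#' fitted response-on-covariate and later inverted to read age off a new
#' beta value. Calibrations with `|B|` below `1e-4` beta units per year
#' are flagged degenerate: inverting a near-flat line produces explosive
#' age estimates, so such CpGs are excluded from prediction.
#'
#' @param betas,ages Paired numeric vectors; incomplete pairs are dropped.
#' @param cpg_id Probe identifier recorded in the result.
#' @return A one-row tibble: `cpg_id`, `intercept` (A, beta at age 0),
#'   `slope` (B, beta units per year), `slope_se`, `r_squared`, `n_train`,
#'   `degenerate`.
#' @export
#' @examples
#' fit_cpg_calibration(c(0.1, 0.3, 0.5), c(0, 50, 100), "cg0001")
fit_cpg_calibration <- function(betas, ages, cpg_id = "cpg") {
  keep <- !is.na(betas) & !is.na(ages)
  betas <- betas[keep]
  ages <- ages[keep]
  if (length(betas) < 3L) {
    stop("fit_cpg_calibration: fewer than 3 complete pairs for '",
         cpg_id, "'", call. = FALSE)
  }
  if (length(unique(ages)) < 2L) {
    stop("fit_cpg_calibration: constant ages for '", cpg_id, "'",
         call. = FALSE)
  }
  fit <- stats::lm(betas ~ ages)
  co <- stats::coef(fit)
  # summary.lm warns on exact fits; noiseless calibration data are valid
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(betas) == 0) 0 else sm$r.squared
  tibble::tibble(
    cpg_id = cpg_id,
    intercept = unname(co[1L]),
    slope = unname(co[2L]),
    slope_se = unname(sm$coefficients[2L, "Std. Error"]),
    r_squared = r2,
    n_train = length(betas),
    degenerate = abs(unname(co[2L])) < slope_floor()
  )
}

# Slope magnitude below which a calibration is unusable for inversion.
slope_floor <- function() 1e-4

#' Fit the signature age model on a training cohort
#'
#' Fits one beta-versus-age calibration per signature CpG over all
#' training samples and bundles them into a `signature_model` object used
#' by [predict_age()].
#'
#' @param beta Training beta-value tibble; all signature probes must be
#'   present.
#' @param annotations Training annotation tibble.
#' @param spec Signature tibble ([published_signature()] or
#'   [select_signature()] output).
#' @param drop_degenerate Drop near-flat calibrations with a warning
#'   instead of erroring (default `FALSE`).
#' @param training_label Provenance string stored with the model.
#' @return A `signature_model`: list with `calibrations` (tibble) and
#'   `training_label`.
#' @export
fit_signature_model <- function(beta, annotations, spec,
                                drop_degenerate = FALSE,
                                training_label = "training") {
  validate_beta_matrix(beta)
  ann <- validate_annotations(annotations)
  spec <- validate_signature(spec)
  missing_cpg <- setdiff(spec$cpg_id, beta$cpg_id)
  if (length(missing_cpg)) {
    stop("fit_signature_model: probe '", missing_cpg[1L],
         "' absent from the training matrix", call. = FALSE)
  }
  sample_ids <- names(beta)[-1L]
  ages <- ann$age[match(sample_ids, ann$sample_id)]
  if (anyNA(ages)) {
    stop("fit_signature_model: sample '",
         sample_ids[which(is.na(ages))[1L]], "' has no annotation",
         call. = FALSE)
  }
  cal <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    b <- as.numeric(beta[beta$cpg_id == spec$cpg_id[i], -1L])
    fit_cpg_calibration(b, ages, spec$cpg_id[i])
  })
  cal <- dplyr::left_join(cal, spec, by = "cpg_id")
  if (any(cal$degenerate)) {
    bad <- cal$cpg_id[cal$degenerate]
    if (drop_degenerate) {
      warning("dropping degenerate calibration(s): ",
              paste(bad, collapse = ", "))
      cal <- cal[!cal$degenerate, , drop = FALSE]
      if (nrow(cal) == 0L) {
        stop("fit_signature_model: all calibrations degenerate",
             call. = FALSE)
      }
    } else {
      stop("fit_signature_model: degenerate (near-flat) calibration for ",
           paste(bad, collapse = ", "),
           "; use drop_degenerate = TRUE to drop", call. = FALSE)
    }
  }
  structure(list(calibrations = cal, training_label = training_label),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> ", nrow(x$calibrations), " CpG calibration(s), ",
      "trained on '", x$training_label, "'\n", sep = "")
  print(x$calibrations, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signature model into its per-CpG calibrations
#'
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return The calibration tibble (one row per CpG).
#' @method tidy signature_model
#' @export
tidy.signature_model <- function(x, ...) {
  x$calibrations
}

#' One-row model summary for a signature model
#'
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return A one-row tibble: number of CpGs, training size, median
#'   calibration r-squared.
#' @method glance signature_model
#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(
    n_cpgs = nrow(x$calibrations),
    n_train = as.integer(stats::median(x$calibrations$n_train)),
    median_r_squared = stats::median(x$calibrations$r_squared),
    training_label = x$training_label
  )
}

#' Invert a single calibration: age from one beta value
#'
#' The calibration line `beta = A + B * age` is solved for age:
#' `age = (beta - A) / B`. The estimate is returned raw — it may be
#' negative or exceed the human lifespan; clamping is the caller's choice
#' (see `clamp` in [predict_age()]).
#'
#' @param beta Beta value(s).
#' @param intercept,slope Calibration coefficients A and B.
#' @return Predicted age(s) in years.
#' @export
#' @examples
#' predict_age_single(0.3, intercept = 0.1, slope = 0.004) # 50 years
predict_age_single <- function(beta, intercept, slope) {
  if (any(abs(slope) < slope_floor())) {
    stop("predict_age_single: degenerate calibration (|slope| < ",
         format(slope_floor()), ")", call. = FALSE)
  }
  (beta - intercept) / slope
}

#' Predict donor age for every sample of a beta matrix
#'
#' For each sample, every non-missing signature beta is inverted through
#' its calibration line and the per-CpG age estimates are averaged with
#' equal weights. Samples missing some signature probes are averaged over
#' the available ones (recorded in `n_cpgs_used`); a sample missing all of
#' them is an error.
#'
#' @param model A `signature_model`.
#' @param beta Beta-value tibble to predict on; all model probes must be
#'   present as rows.
#' @param subset Optional probe subset (must be within the model's CpGs),
#'   e.g. the three-CpG variant.
#' @param clamp If `TRUE`, clamp predictions to \[0, 120\] years
#'   (default `FALSE`: raw estimates are returned).
#' @return A tibble with one row per sample: `sample_id`, `predicted_age`,
#'   `n_cpgs_used`, then one `Ni` column per signature probe (named by its
#'   probe ID).
#' @export
predict_age <- function(model, beta, subset = NULL, clamp = FALSE) {
  stopifnot(inherits(model, "signature_model"))
  validate_beta_matrix(beta)
  cal <- model$calibrations
  if (!is.null(subset)) {
    extra <- setdiff(subset, cal$cpg_id)
    if (length(extra)) {
      stop("predict_age: subset probe '", extra[1L],
           "' is not in the model", call. = FALSE)
    }
    cal <- cal[cal$cpg_id %in% subset, , drop = FALSE]
  }
  missing_cpg <- setdiff(cal$cpg_id, beta$cpg_id)
  if (length(missing_cpg)) {
    stop("predict_age: probe '", missing_cpg[1L],
         "' absent from the beta matrix", call. = FALSE)
  }
  sample_ids <- names(beta)[-1L]
  mat <- as.matrix(beta[match(cal$cpg_id, beta$cpg_id), -1L, drop = FALSE])
  # per-CpG inverse predictions: rows CpGs, columns samples
  ni <- (mat - cal$intercept) / cal$slope
  if (clamp) ni <- pmin(pmax(ni, 0), 120)
  n_used <- colSums(!is.na(ni))
  if (any(n_used == 0L)) {
    stop("predict_age: all signature betas missing for sample(s) ",
         paste(sample_ids[n_used == 0L], collapse = ", "), call. = FALSE)
  }
  pred <- colMeans(ni, na.rm = TRUE)
  out <- tibble::tibble(
    sample_id = sample_ids,
    predicted_age = unname(pred),
    n_cpgs_used = as.integer(n_used)
  )
  rownames(ni) <- cal$cpg_id
  per_cpg <- tibble::as_tibble(t(ni))
  dplyr::bind_cols(out, per_cpg)
}

#' Evaluate age predictions against chronological age
#'
#' Precision is reported as the mean absolute difference between predicted
#' and chronological age in years, alongside the squared Pearson
#' correlation of predicted versus actual age across samples.
#'
#' @param predictions Output of [predict_age()].
#' @param annotations Annotation tibble; every predicted sample must be
#'   annotated.
#' @return A `precision_report`: list with `summary` (one-row tibble:
#'   `mean_abs_diff`, `r_squared`, `n_samples`) and `per_sample` (tibble
#'   with signed errors in years).
#' @export
evaluate_predictions <- function(predictions, annotations) {
  ann <- validate_annotations(annotations)
  idx <- match(predictions$sample_id, ann$sample_id)
  if (anyNA(idx)) {
    stop("evaluate_predictions: no annotation for sample '",
         predictions$sample_id[which(is.na(idx))[1L]], "'", call. = FALSE)
  }
  actual <- ann$age[idx]
  err <- predictions$predicted_age - actual
  r2 <- if (length(err) >= 3L &&
            stats::sd(actual) > 0 && stats::sd(predictions$predicted_age) > 0) {
    stats::cor(predictions$predicted_age, actual)^2
  } else {
    NA_real_
  }
  structure(list(
    summary = tibble::tibble(
      mean_abs_diff = mean(abs(err)),
      r_squared = r2,
      n_samples = length(err)
    ),
    per_sample = tibble::tibble(
      sample_id = predictions$sample_id,
      predicted_age = predictions$predicted_age,
      actual_age = actual,
      error = err
    )
  ), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report> n =", x$summary$n_samples,
      " mean |error| =", format(x$summary$mean_abs_diff, digits = 4),
      "yrs  r^2 =", format(x$summary$r_squared, digits = 3), "\n")
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x A `precision_report`.
#' @param ... Unused.
#' @method tidy precision_report
#' @export
tidy.precision_report <- function(x, ...) x$per_sample

#' @rdname evaluate_predictions
#' @method glance precision_report
#' @export
glance.precision_report <- function(x, ...) x$summary

#' Plot predicted versus chronological age
#'
#' @param report A `precision_report`.
#' @return A ggplot object: one point per sample with the identity line.
#' @export
plot_predictions <- function(report) {
  stopifnot(inherits(report, "precision_report"))
  ggplot2::ggplot(report$per_sample,
                  ggplot2::aes(x = .data$actual_age,
                               y = .data$predicted_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "chronological age (yrs)", y = "predicted age (yrs)")
}

#' Plot signature calibration lines over the training data
#'
#' @param object A `signature_model`.
#' @param beta Optional beta-value tibble to overlay as points.
#' @param annotations Annotation tibble (required when `beta` is given).
#' @param ... Unused.
#' @return A ggplot object, one facet per signature CpG.
#' @method autoplot signature_model
#' @export
autoplot.signature_model <- function(object, beta = NULL,
                                     annotations = NULL, ...) {
  cal <- object$calibrations
  p <- ggplot2::ggplot()
  if (!is.null(beta)) {
    ann <- validate_annotations(annotations)
    pts <- beta[beta$cpg_id %in% cal$cpg_id, , drop = FALSE] |>
      tidyr::pivot_longer(-"cpg_id", names_to = "sample_id",
                          values_to = "beta") |>
      dplyr::left_join(dplyr::select(ann, "sample_id", "age"),
                       by = "sample_id")
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$age, y = .data$beta), alpha = 0.5)
  }
  p +
    ggplot2::geom_abline(
      data = cal,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cpg_id)) +
    ggplot2::labs(x = "age (yrs)", y = expression(beta)) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write / read a fitted signature model as structured text
#'
#' A versioned TSV with a comment header carrying the format version and
#' training provenance, then one row per calibration. Coefficients are
#' serialized with 17 significant digits so the round trip is bit-exact.
#'
#' @param model A `signature_model`.
#' @param path File path.
#' @return `path` invisibly (write) or a `signature_model` (read).
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  cal <- model$calibrations
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# methylage signature_model format 1", con)
  writeLines(paste0("# training_label\t", model$training_label), con)
  writeLines(paste(c("cpg_id", "intercept", "slope", "slope_se",
                     "r_squared", "n_train", "degenerate", "role",
                     "gene_label"), collapse = "\t"), con)
  writeLines(paste(
    cal$cpg_id,
    sprintf("%.17g", cal$intercept),
    sprintf("%.17g", cal$slope),
    sprintf("%.17g", cal$slope_se),
    sprintf("%.17g", cal$r_squared),
    cal$n_train,
    cal$degenerate,
    if (!"role" %in% names(cal)) "NA" else cal$role,
    ifelse(is.na(cal$gene_label), "NA", cal$gene_label),
    sep = "\t"), con)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  label_line <- grep("^# training_label\t", lines, value = TRUE)
  training_label <- if (length(label_line)) {
    sub("^# training_label\t", "", label_line[1L])
  } else {
    "unknown"
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                          na.strings = "NA", stringsAsFactors = FALSE)
  cal <- tibble::tibble(
    cpg_id = as.character(df$cpg_id),
    intercept = as.numeric(df$intercept),
    slope = as.numeric(df$slope),
    slope_se = as.numeric(df$slope_se),
    r_squared = as.numeric(df$r_squared),
    n_train = as.integer(df$n_train),
    degenerate = as.logical(df$degenerate),
    role = as.character(df$role),
    gene_label = as.character(df$gene_label)
  )
  structure(list(calibrations = cal, training_label = training_label),
            class = "signature_model")
}
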
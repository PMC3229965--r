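#' Screening workflow: combined and per-dataset template matching
#'
#' Runs the discovery half of the pipeline on one cohort: builds the age
#' template, screens all CpGs at a stringent and a less stringent
#' correlation threshold, recomputes per-dataset correlations for the
#' stringent hits, and writes all reports to `out_dir`. Inputs may be
#' tibbles or paths to the package's TSV dialects; input files are never
#' modified.
#'
#' @param beta Beta-value tibble or path to a beta-matrix TSV.
#' @param annotations Annotation tibble or path to an annotation TSV.
#' @param out_dir Output directory (created if absent).
#' @param r_threshold Stringent correlation threshold (default 0.6).
#' @param secondary_threshold Less stringent threshold (default 0.4).
#' @param direction Screening direction for the reports (default
#'   `"both"`).
#' @param min_n Minimum pairwise-complete samples per CpG.
#' @return Invisibly, a list with the primary and secondary screening
#'   tibbles, the per-dataset table, and the written file paths.
#' @export
run_screen <- function(beta, annotations, out_dir,
                       r_threshold = 0.6, secondary_threshold = 0.4,
                       direction = "both", min_n = 8L) {
  for (thr in c(r_threshold, secondary_threshold)) {
    if (!is.numeric(thr) || is.na(thr) || thr < 0 || thr > 1) {
      stop("run_screen: thresholds must be in [0, 1]", call. = FALSE)
    }
  }
  beta <- resolve_beta(beta)
  ann <- resolve_annotations(annotations)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  template <- build_age_template(ann)
  primary <- run_ptm(beta, template, r_threshold, direction, min_n)
  secondary <- run_ptm(beta, template, secondary_threshold, direction,
                       min_n)
  per_ds <- if (nrow(primary) > 0L) {
    per_dataset_ptm(beta, ann, primary$cpg_id)
  } else {
    tibble::tibble(cpg_id = character())
  }

  paths <- list(
    primary = file.path(out_dir, "ptm_primary.tsv"),
    secondary = file.path(out_dir, "ptm_secondary.tsv"),
    per_dataset = file.path(out_dir, "ptm_per_dataset.tsv"),
    manifest = file.path(out_dir, "screen_manifest.json")
  )
  readr::write_tsv(primary, paths$primary, na = "NA", progress = FALSE)
  readr::write_tsv(secondary, paths$secondary, na = "NA", progress = FALSE)
  readr::write_tsv(per_ds, paths$per_dataset, na = "NA", progress = FALSE)
  write_manifest(paths$manifest, list(
    step = "screen", r_threshold = r_threshold,
    secondary_threshold = secondary_threshold, direction = direction,
    min_n = min_n, n_cpgs = nrow(beta), n_samples = ncol(beta) - 1L
  ))
  invisible(list(primary = primary, secondary = secondary,
                 per_dataset = per_ds, paths = paths))
}

#' Fit / predict / evaluate workflow with a strict train-test split
#'
#' Fits the signature calibrations on the training cohort only, predicts
#' ages for the test cohort with those training calibrations (never
#' refitting on test data), evaluates precision against the test
#' annotations, and writes the model, the predictions and the precision
#' report to `out_dir`.
#'
#' @param train_beta,train_annotations Training cohort (tibbles or paths).
#' @param test_beta,test_annotations Test cohort (tibbles or paths).
#' @param signature A signature tibble, a path to a signature file, or a
#'   variant name (`"five"`/`"three"`) resolved via
#'   [published_signature()].
#' @param subset Optional probe subset for prediction (e.g.
#'   `published_signature("three")$cpg_id`).
#' @param clamp Clamp predictions to \[0, 120\] years (default `FALSE`).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the fitted `model`, `predictions`
#'   tibble, `report` (`precision_report`) and written file paths.
#' @export
run_fit_predict_evaluate <- function(train_beta, train_annotations,
                                     test_beta, test_annotations,
                                     signature = "five", subset = NULL,
                                     clamp = FALSE, out_dir) {
  spec <- resolve_signature(signature)
  train_beta <- resolve_beta(train_beta)
  train_ann <- resolve_annotations(train_annotations)
  test_beta <- resolve_beta(test_beta)
  test_ann <- resolve_annotations(test_annotations)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  model <- fit_signature_model(train_beta, train_ann, spec,
                               training_label = "training input")
  predictions <- predict_age(model, test_beta, subset = subset,
                             clamp = clamp)
  report <- evaluate_predictions(predictions, test_ann)

  paths <- list(
    model = file.path(out_dir, "signature_model.tsv"),
    predictions = file.path(out_dir, "predictions.tsv"),
    precision = file.path(out_dir, "precision.tsv"),
    per_sample = file.path(out_dir, "per_sample_errors.tsv"),
    manifest = file.path(out_dir, "fit_manifest.json")
  )
  write_signature_model(model, paths$model)
  readr::write_tsv(predictions, paths$predictions, na = "NA",
                   progress = FALSE)
  readr::write_tsv(report$summary, paths$precision, na = "NA",
                   progress = FALSE)
  readr::write_tsv(report$per_sample, paths$per_sample, na = "NA",
                   progress = FALSE)
  write_manifest(paths$manifest, list(
    step = "fit_predict_evaluate",
    signature = spec$cpg_id, subset = subset, clamp = clamp,
    n_train = ncol(train_beta) - 1L, n_test = ncol(test_beta) - 1L
  ))
  invisible(list(model = model, predictions = predictions,
                 report = report, paths = paths))
}

resolve_beta <- function(x) {
  if (is.character(x) && length(x) == 1L) read_beta_matrix(x)
  else validate_beta_matrix(tibble::as_tibble(x))
}

resolve_annotations <- function(x) {
  if (is.character(x) && length(x) == 1L) read_annotations(x)
  else validate_annotations(x)
}

resolve_signature <- function(x) {
  if (is.data.frame(x)) {
    validate_signature(x)
  } else if (is.character(x) && length(x) == 1L) {
    if (x %in% c("five", "three")) published_signature(x)
    else read_signature(x)
  } else {
    stop("signature must be a tibble, a variant name, or a file path",
         call. = FALSE)
  }
}

# Machine-readable run manifest beside the outputs; timestamps are kept
# out of the tabular artifacts so identical configs give identical files.
write_manifest <- function(path, fields) {
  fields$package_version <- as.character(utils::packageVersion("methylage"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, null = "null")
  } else {
    writeLines(utils::capture.output(utils::str(fields)), path)
  }
  invisible(path)
}
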
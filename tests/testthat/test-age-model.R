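test_that("calibration recovers an exact line and matches the
           normal-equations oracle", {
  cal <- fit_cpg_calibration(c(0.1, 0.3, 0.5), c(0, 50, 100), "cg1")
  expect_equal(cal$intercept, 0.1)
  expect_equal(cal$slope, 0.004)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$n_train, 3L)
  expect_false(cal$degenerate)

  # constant beta: slope 0, flagged degenerate
  flat <- fit_cpg_calibration(rep(0.3, 5), c(10, 20, 30, 40, 50))
  expect_equal(flat$intercept, 0.3)
  expect_equal(flat$slope, 0)
  expect_true(flat$degenerate)

  expect_error(fit_cpg_calibration(c(0.1, 0.2), c(10, 20)), "3 complete")
  expect_error(fit_cpg_calibration(runif(5), rep(30, 5)), "constant ages")

  # random pairs against explicit normal equations
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    ages <- runif(n, 0, 90)
    betas <- runif(n)
    X <- cbind(1, ages)
    ab <- solve(t(X) %*% X, t(X) %*% betas)
    cal <- fit_cpg_calibration(betas, ages)
    expect_equal(cal$intercept, ab[1L], tolerance = 1e-10)
    expect_equal(cal$slope, ab[2L], tolerance = 1e-10)
  }
})

test_that("signature model fitting recovers noiseless coefficients and
           errors on missing probes", {
  ages <- seq(5, 85, length.out = 20)
  truth <- tibble::tibble(
    cpg_id = c("cgA", "cgB", "cgC"),
    intercept = c(0.1, 0.25, 0.9),
    slope = c(0.004, 0.006, -0.005))
  vals <- with(truth, outer(slope, ages) + intercept)
  beta <- tiny_beta(vals, cpg_ids = truth$cpg_id)
  ann <- tiny_annotations(names(beta)[-1L], ages)
  spec <- tibble::tibble(cpg_id = truth$cpg_id,
                         role = c("hyper", "hyper", "hypo"))
  model <- fit_signature_model(beta, ann, spec)
  expect_s3_class(model, "signature_model")
  expect_equal(model$calibrations$intercept, truth$intercept,
               tolerance = 1e-10)
  expect_equal(model$calibrations$slope, truth$slope, tolerance = 1e-10)

  expect_error(
    fit_signature_model(beta, ann,
                        tibble::tibble(cpg_id = "cgZ", role = "hyper")),
    "cgZ")

  # degenerate calibration blocks fitting unless explicitly dropped
  flatbeta <- beta
  flatbeta[2, -1L] <- as.list(rep(0.5, 20))
  expect_error(fit_signature_model(flatbeta, ann, spec), "degenerate")
  expect_warning(
    m2 <- fit_signature_model(flatbeta, ann, spec, drop_degenerate = TRUE),
    "dropping")
  expect_equal(nrow(m2$calibrations), 2L)
})

test_that("fitted slopes fall within 3 standard errors of truth", {
  # OLS sampling-distribution check at the training-cohort scale
  set.seed(2024)
  n <- 130
  ages <- runif(n, 16, 72)
  hits <- 0L
  total <- 0L
  for (rep in 1:100) {
    slope <- runif(1, 0.002, 0.006)
    intercept <- runif(1, 0.1, 0.3)
    betas <- intercept + slope * ages + rnorm(n, 0, 0.03)
    cal <- fit_cpg_calibration(betas, ages)
    total <- total + 1L
    if (abs(cal$slope - slope) <= 3 * cal$slope_se) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.99)
})

test_that("single-CpG inversion is the algebraic inverse of the line", {
  expect_equal(predict_age_single(0.1, 0.1, 0.004), 0)
  expect_equal(predict_age_single(0.3, 0.1, 0.004), 50)
  # hypomethylated CpG: negative slope handled by the same formula
  expect_equal(predict_age_single(0.4, 0.5, -0.002), 50)
  expect_error(predict_age_single(0.4, 0.5, 1e-6), "degenerate")
  # round trip through the line for arbitrary ages
  for (a in c(-5, 0, 33.3, 90, 140)) {
    b <- 0.22 + 0.0031 * a
    expect_equal(predict_age_single(b, 0.22, 0.0031), a,
                 tolerance = 1e-10)
  }
})

test_that("predict_age averages per-CpG inversions with equal weights", {
  ages <- seq(10, 80, length.out = 15)
  truth <- tibble::tibble(cpg_id = c("cgA", "cgB", "cgC"),
                          intercept = c(0.1, 0.3, 0.85),
                          slope = c(0.005, 0.003, -0.004))
  beta <- tiny_beta(with(truth, outer(slope, ages) + intercept),
                    cpg_ids = truth$cpg_id)
  ann <- tiny_annotations(names(beta)[-1L], ages)
  spec <- tibble::tibble(cpg_id = truth$cpg_id,
                         role = c("hyper", "hyper", "hypo"))
  model <- fit_signature_model(beta, ann, spec)

  # consistency: betas on every line at age 33 predict exactly 33
  probe <- tiny_beta(matrix(truth$intercept + truth$slope * 33, ncol = 1),
                     cpg_ids = truth$cpg_id, sample_ids = "q")
  expect_equal(predict_age(model, probe)$predicted_age, 33,
               tolerance = 1e-8)

  # hand mean: per-CpG predictions {40, 60} average to 50
  two <- tiny_beta(matrix(c(0.1 + 0.005 * 40, 0.3 + 0.003 * 60, NA),
                          ncol = 1),
                   cpg_ids = truth$cpg_id, sample_ids = "h")
  got <- predict_age(model, two)
  expect_equal(got$predicted_age, 50, tolerance = 1e-8)
  expect_equal(got$n_cpgs_used, 2L)

  # subset restricted to two named probes uses exactly those
  sub <- predict_age(model, probe, subset = c("cgA", "cgC"))
  expect_equal(sub$n_cpgs_used, 2L)
  expect_equal(sub$predicted_age,
               mean(c((probe[[2]][1] - 0.1) / 0.005,
                      (probe[[2]][3] - 0.85) / -0.004)),
               tolerance = 1e-8)
  expect_error(predict_age(model, probe, subset = "cgZ"), "cgZ")

  # all signature betas missing is an error naming the sample
  gone <- tiny_beta(matrix(NA_real_, nrow = 3, ncol = 1),
                    cpg_ids = truth$cpg_id, sample_ids = "empty")
  expect_error(predict_age(model, gone), "empty")

  # clamping bounds raw estimates to a plausible lifespan
  weird <- tiny_beta(matrix(c(0.95, 0.9, 0.05), ncol = 1),
                     cpg_ids = truth$cpg_id, sample_ids = "w")
  raw <- predict_age(model, weird)
  clamped <- predict_age(model, weird, clamp = TRUE)
  expect_true(any(raw[, truth$cpg_id] > 120))
  expect_true(all(clamped[, truth$cpg_id] <= 120 &
                    clamped[, truth$cpg_id] >= 0))
})

test_that("evaluation reports mean absolute error and r-squared", {
  preds <- tibble::tibble(sample_id = c("a", "b", "c"),
                          predicted_age = c(30, 40, 50),
                          n_cpgs_used = 3L)
  ann <- tiny_annotations(c("a", "b", "c"), c(30, 40, 50))
  rep0 <- evaluate_predictions(preds, ann)
  expect_equal(rep0$summary$mean_abs_diff, 0)
  expect_equal(rep0$summary$r_squared, 1)

  # signed errors {+4, -6} -> mean |error| 5
  preds2 <- tibble::tibble(sample_id = c("a", "b"),
                           predicted_age = c(34, 34), n_cpgs_used = 3L)
  ann2 <- tiny_annotations(c("a", "b"), c(30, 40))
  rep2 <- evaluate_predictions(preds2, ann2)
  expect_equal(rep2$summary$mean_abs_diff, 5)
  expect_equal(rep2$per_sample$error, c(4, -6))

  expect_error(
    evaluate_predictions(preds, tiny_annotations(c("a", "b"), c(30, 40))),
    "no annotation")

  # permutation invariance of the summary
  set.seed(3)
  predsN <- tibble::tibble(sample_id = sprintf("s%d", 1:20),
                           predicted_age = runif(20, 10, 80),
                           n_cpgs_used = 5L)
  annN <- tiny_annotations(predsN$sample_id, runif(20, 10, 80))
  shuf <- predsN[sample(20), ]
  expect_equal(evaluate_predictions(shuf, annN)$summary,
               evaluate_predictions(predsN, annN)$summary)
})

test_that("tidy and glance expose calibrations and summaries", {
  ages <- seq(10, 80, length.out = 12)
  beta <- tiny_beta(matrix(0.1 + 0.004 * ages, nrow = 1),
                    cpg_ids = "cgA")
  ann <- tiny_annotations(names(beta)[-1L], ages)
  model <- fit_signature_model(
    beta, ann, tibble::tibble(cpg_id = "cgA", role = "hyper"))
  td <- generics::tidy(model)
  expect_equal(td$cpg_id, "cgA")
  gl <- generics::glance(model)
  expect_equal(gl$n_cpgs, 1L)

  preds <- predict_age(model, beta)
  ev <- evaluate_predictions(preds, ann)
  expect_equal(nrow(generics::tidy(ev)), 12L)
  expect_equal(generics::glance(ev), ev$summary)
})

test_that("model serialization round-trips bit-exactly", {
  ages <- seq(5, 85, length.out = 25)
  truth <- tibble::tibble(cpg_id = c("cgA", "cgB"),
                          intercept = c(0.11, 0.87),
                          slope = c(0.0043, -0.0051))
  set.seed(8)
  beta <- tiny_beta(with(truth, outer(slope, ages) + intercept) +
                      matrix(rnorm(50, 0, 0.01), nrow = 2),
                    cpg_ids = truth$cpg_id)
  ann <- tiny_annotations(names(beta)[-1L], ages)
  model <- fit_signature_model(
    beta, ann,
    tibble::tibble(cpg_id = truth$cpg_id, role = c("hyper", "hypo")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_signature_model(model, tf)
  back <- read_signature_model(tf)
  expect_identical(back$calibrations$intercept,
                   model$calibrations$intercept)
  expect_identical(back$calibrations$slope, model$calibrations$slope)
  expect_equal(back$training_label, model$training_label)
  # identical predictions from the deserialized model
  expect_equal(predict_age(back, beta), predict_age(model, beta))
})

test_that("averaging over CpGs beats every single CpG under
           independent noise", {
  # error of a single-CpG inverse prediction is noise/B; averaging k
  # independent such errors shrinks the absolute error
  set.seed(99)
  ages <- runif(300, 10, 80)
  truth <- tibble::tibble(cpg_id = sprintf("cg%d", 1:4),
                          intercept = c(0.1, 0.2, 0.3, 0.8),
                          slope = c(0.004, 0.005, 0.003, -0.004))
  train <- tiny_beta(with(truth, outer(slope, seq(0, 100, 5)) + intercept),
                     cpg_ids = truth$cpg_id)
  ann_train <- tiny_annotations(names(train)[-1L], seq(0, 100, 5))
  model <- fit_signature_model(
    train, ann_train,
    tibble::tibble(cpg_id = truth$cpg_id,
                   role = c("hyper", "hyper", "hyper", "hypo")))
  noisy <- with(truth, outer(slope, ages) + intercept) +
    matrix(rnorm(4 * 300, 0, 0.02), nrow = 4)
  beta_val <- tiny_beta(noisy, cpg_ids = truth$cpg_id)
  preds <- predict_age(model, beta_val)
  mae_avg <- mean(abs(preds$predicted_age - ages))
  mae_single <- vapply(truth$cpg_id,
                       function(id) mean(abs(preds[[id]] - ages)), 0)
  expect_true(all(mae_avg < mae_single))
})
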
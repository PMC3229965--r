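# Small in-code fixtures and independent oracles shared across tests.

# A tiny beta tibble from a plain matrix (rows = CpGs, cols = samples).
tiny_beta <- function(values, cpg_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(cpg_ids)) cpg_ids <- sprintf("cg%08d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(values)))
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  names(out) <- sample_ids
  dplyr::bind_cols(tibble::tibble(cpg_id = cpg_ids), out)
}

tiny_annotations <- function(sample_ids, ages, dataset = "d1") {
  tibble::tibble(sample_id = sample_ids, age = ages,
                 dataset = rep_len(dataset, length(sample_ids)))
}

# Brute-force Pearson correlation over pairwise-complete pairs: the
# independent oracle for the vectorized screening path.
brute_pearson <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force screening loop mirroring the run_ptm contract.
brute_ptm <- function(beta, template, r_threshold, direction, min_n) {
  rows <- lapply(seq_len(nrow(beta)), function(i) {
    b <- as.numeric(beta[i, -1L])
    tv <- template$template[match(names(beta)[-1L], template$sample_id)]
    keep <- !is.na(b) & !is.na(tv)
    n <- sum(keep)
    if (n < 3L || stats::sd(b[keep]) == 0) return(NULL)
    r <- brute_pearson(b, tv)
    data.frame(cpg_id = beta$cpg_id[i], r = r, n_used = n)
  })
  df <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(df)) return(df)
  keep <- switch(direction,
                 hyper = df$r >= r_threshold,
                 hypo = df$r <= -r_threshold,
                 both = abs(df$r) >= r_threshold)
  df <- df[keep & df$n_used >= min_n, , drop = FALSE]
  df[order(-abs(df$r), df$cpg_id), , drop = FALSE]
}

# All permutations of a vector (for the exact permutation p-value oracle).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# A minimal noiseless cohort spec: two datasets, no offsets, no noise.
noiseless_spec <- function(seed = 7L, n_null = 20L) {
  cohort_spec(
    datasets = tibble::tibble(
      label = c("tissue A", "tissue B"),
      n_samples = c(12L, 10L),
      age_min = c(5, 20), age_max = c(80, 70),
      tissue_offset_sd = 0
    ),
    n_signature_hyper = 3L, n_signature_hypo = 1L, n_null_cpgs = n_null,
    noise_sd = 0, seed = seed
  )
}
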
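#' Ground truth for a synthetic label-free omics experiment
#'
#' Defines a two-group feature-by-sample experiment with known spiked
#' log2 fold changes and intensity-dependent (missing-not-at-random)
#' dropout. Defaults emulate a quantified liver proteome: ~2000 features,
#' 6 animals per group, log2 ion-count intensities around 25 with
#' replicate-level SD 0.3, and ~10% left-censored missingness.
#'
#' @param n_features number of features.
#' @param n_per_group samples per group (two groups).
#' @param spiked_features named numeric vector mapping feature ids (or a
#'   bare numeric vector with indices as names taken from feature order)
#'   to true log2 fold changes; empty for a null experiment.
#' @param base_mean baseline log2 intensity; scalar, or length-`n_features`
#'   vector for a realistic dynamic range.
#' @param base_sd replicate-level SD of log2 intensity.
#' @param mnar_shift center of the dropout sigmoid, in SDs below the grand
#'   mean intensity: lower-intensity measurements are more likely missing.
#' @param missing_rate overall expected fraction of missing cells in
#'   `[0, 1)`; the dropout sigmoid is calibrated so the expected overall
#'   missingness equals this rate.
#' @param seed integer seed.
#' @return object of class `omics_truth`.
#' @export
omics_truth <- function(n_features = 2000L, n_per_group = 6L,
                        spiked_features = numeric(0), base_mean = 25,
                        base_sd = 0.3, mnar_shift = 1.8,
                        missing_rate = 0.1, seed = 1L) {
  if (n_per_group < 2L) stop("need >= 2 samples per group")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!length(base_mean) %in% c(1L, n_features))
    stop("base_mean must be scalar or length n_features")
  feature_ids <- paste0("feature_", seq_len(n_features))
  if (length(spiked_features)) {
    if (is.null(names(spiked_features)))
      stop("spiked_features must be named by feature id")
    if (!all(names(spiked_features) %in% feature_ids))
      stop("spiked feature ids outside the feature set")
  }
  structure(list(n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group),
                 spiked_features = spiked_features,
                 base_mean = base_mean, base_sd = base_sd,
                 mnar_shift = mnar_shift, missing_rate = missing_rate,
                 feature_ids = feature_ids, seed = as.integer(seed)),
            class = "omics_truth")
}

#' Generate a two-group abundance matrix with MNAR dropout
#'
#' Log2 intensities are drawn per feature as
#' `Normal(base_mean + group * log2FC, base_sd)`; the table is returned on
#' the raw intensity scale (2^log2) so the standard pipeline
#' (log2-normalize, impute, test) applies. Dropout follows a logistic
#' probability decreasing with log2 intensity, centered `mnar_shift` SDs
#' below the grand mean with scale `0.5 * base_sd`, with the center offset
#' calibrated so the expected overall missingness equals `missing_rate`.
#'
#' @param truth an [omics_truth()].
#' @return list with `table` (an [abundance_table()], scale `"raw"`),
#'   `design` (a [group_design()]) and `truth` record listing the spiked
#'   features.
#' @export
gen_omics_dataset <- function(truth) {
  stopifnot(inherits(truth, "omics_truth"))
  nf <- truth$n_features; np <- truth$n_per_group
  fc <- stats::setNames(numeric(nf), truth$feature_ids)
  fc[names(truth$spiked_features)] <- truth$spiked_features
  mu <- matrix(truth$base_mean, nf, 2 * np)
  mu[, np + seq_len(np)] <- mu[, np + seq_len(np)] + fc
  out <- withr::with_seed(truth$seed, {
    x <- mu + matrix(stats::rnorm(nf * 2 * np, 0, truth$base_sd), nf, 2 * np)
    if (truth$missing_rate > 0) {
      scale <- 0.5 * truth$base_sd
      center0 <- mean(x) - truth$mnar_shift * stats::sd(x)
      # calibrate the sigmoid center so E[missing] = missing_rate
      f <- function(d) mean(stats::plogis((center0 + d - x) / scale)) -
        truth$missing_rate
      d <- stats::uniroot(f, lower = -50 * scale - diff(range(x)),
                          upper = 50 * scale + diff(range(x)),
                          extendInt = "yes", tol = 1e-10)$root
      p_miss <- stats::plogis((center0 + d - x) / scale)
      x[stats::runif(length(x)) < p_miss] <- NA_real_
    }
    x
  })
  vals <- 2^out
  colnames(vals) <- c(paste0("ctrl_", seq_len(np)), paste0("cond_", seq_len(np)))
  rownames(vals) <- truth$feature_ids
  design <- group_design(colnames(vals),
                         rep(c("ctrl", "cond"), each = np))
  list(table = abundance_table(vals, scale = "raw"),
       design = design,
       truth = truth_record("gen_omics_dataset",
                            spiked_features = truth$spiked_features,
                            log2fc = fc, missing_rate = truth$missing_rate))
}
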
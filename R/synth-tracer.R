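#' Ground truth for a synthetic isotopomer experiment
#'
#' @param fragment a [fragment_spec()] for the measured ion.
#' @param true_mid true (pre-natural-abundance) fractional labeling
#'   distribution m+0 ... m+n; renormalized to sum to 1.
#' @param n_replicates number of observed replicate MIDs to draw.
#' @param noise_sd SD of additive fractional noise on the observed MID.
#' @param seed integer seed.
#' @return object of class `tracer_truth`.
#' @export
tracer_truth <- function(fragment, true_mid, n_replicates = 3L,
                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(fragment, "fragment_spec"))
  true_mid <- check_mid(true_mid)
  if (length(true_mid) > fragment$n_labelable + 1L)
    stop("MID longer than n_labelable + 1")
  if (n_replicates < 1L) stop("need >= 1 replicate")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(fragment = fragment, true_mid = true_mid,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tracer_truth")
}

#' Generate observed mass-isotopomer distributions
#'
#' Forward-convolves a true labeling distribution with the natural isotope
#' abundance of the measured fragment (the exact inverse of
#' [correct_mid()]), then adds seeded Gaussian noise per replicate, clips
#' at zero and renormalizes.
#'
#' @param truth a [tracer_truth()].
#' @param iso an [isotope_table()].
#' @return list with `observed` (replicates x isotopologues matrix) and
#'   `truth` record carrying `true_mid`.
#' @export
gen_mid_dataset <- function(truth, iso = isotope_table()) {
  stopifnot(inherits(truth, "tracer_truth"))
  size <- length(truth$true_mid)
  M <- build_correction_matrix(truth$fragment, iso, size)
  clean <- as.vector(M %*% truth$true_mid)
  clean <- clean / sum(clean)
  obs <- withr::with_seed(truth$seed, {
    t(vapply(seq_len(truth$n_replicates), function(r) {
      v <- clean
      if (truth$noise_sd > 0)
        v <- pmax(v + stats::rnorm(size, 0, truth$noise_sd), 0)
      v / sum(v)
    }, numeric(size)))
  })
  colnames(obs) <- paste0("m", seq_len(size) - 1L)
  list(observed = obs,
       truth = truth_record("gen_mid_dataset", true_mid = truth$true_mid,
                            fragment = truth$fragment))
}
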
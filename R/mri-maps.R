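#' Average a frame range of a cine
#'
#' Cine acquisitions reach signal steady state after an initial transient;
#' averaging late frames improves SNR before parameter fitting. The range
#' is a closed interval in the 1-based frame numbering of the acquisition.
#'
#' @param cine an [image_stack()] with multiple frames.
#' @param frame_range integer vector `c(first, last)`, 1-based, inclusive.
#' @return single-frame [image_stack()] with metadata preserved.
#' @export
average_frames <- function(cine, frame_range) {
  stopifnot(inherits(cine, "image_stack"), length(frame_range) == 2L)
  first <- frame_range[1]; last <- frame_range[2]
  if (first > last) stop("empty range")
  if (first < 1L || last > n_frames(cine)) stop("frame range out of bounds")
  avg <- apply(cine$pixels[, , first:last, drop = FALSE], c(1, 2), mean)
  out <- cine
  out$pixels <- array(avg, dim = c(dim(avg), 1L))
  out
}

#' Two-point variable-flip-angle T1 map
#'
#' Estimates apparent T1 (uncorrected for B1 inhomogeneity) from two
#' spoiled-gradient-echo images at distinct flip angles using the
#' small-flip-angle linearization S/alpha = const - (T1/(2 TR)) S alpha,
#' giving the closed form T1app = -2 TR (y1 - y2)/(x1 - x2) with
#' y = S/alpha, x = S alpha (alpha in radians).
#'
#' Pixels where the design is locally degenerate (x1 = x2), the estimate is
#' non-positive or non-finite, or exceeds `t1_max_ms` are marked invalid.
#'
#' @param stack_a1,stack_a2 single-frame [image_stack()]s at two distinct
#'   flip angles (degrees in metadata).
#' @param tr_ms repetition time, ms.
#' @param t1_max_ms validity ceiling on T1app, ms.
#' @return [param_map()] of T1app in ms.
#' @export
fit_t1_vfa <- function(stack_a1, stack_a2, tr_ms,
                       t1_max_ms = 10000) {
  stopifnot(inherits(stack_a1, "image_stack"), inherits(stack_a2, "image_stack"))
  if (tr_ms <= 0) stop("tr_ms must be positive")
  a1 <- stack_a1$meta$flip_angle_deg
  a2 <- stack_a2$meta$flip_angle_deg
  if (is.null(a1) || is.null(a2)) stop("flip_angle_deg missing from metadata")
  if (isTRUE(all.equal(a1, a2))) stop("degenerate design: identical flip angles")
  if (n_frames(stack_a1) > 1L || n_frames(stack_a2) > 1L)
    stop("expected single-frame stacks; use average_frames() first")
  s1 <- frame_matrix(stack_a1); s2 <- frame_matrix(stack_a2)
  if (!all(dim(s1) == dim(s2))) stop("mismatched geometry")
  a1 <- a1 * pi / 180; a2 <- a2 * pi / 180
  y1 <- s1 / a1; y2 <- s2 / a2
  x1 <- s1 * a1; x2 <- s2 * a2
  dx <- x1 - x2
  t1 <- -2 * tr_ms * (y1 - y2) / dx
  valid <- dx != 0 & is.finite(t1) & t1 > 0 & t1 <= t1_max_ms
  param_map(t1, valid, units = "ms")
}

# Log-linear starting values for the offset exponential fit: subtract the
# last-echo signal as a crude offset estimate, then regress log of the
# positive remainder on TE over the early echoes.
t2star_start <- function(s, te) {
  c0 <- s[length(s)]
  d <- s - c0
  n_early <- max(4L, ceiling(length(s) / 2))
  idx <- which(d[seq_len(n_early)] > 0)
  if (length(idx) >= 2L) {
    fit <- stats::lm.fit(cbind(1, te[idx]), log(d[idx]))
    b0 <- -fit$coefficients[2]
    a0 <- exp(fit$coefficients[1])
    if (!is.finite(b0) || b0 <= 0) b0 <- 1 / stats::median(te)
    if (!is.finite(a0) || a0 <= 0) a0 <- max(s) - min(s)
  } else {
    b0 <- 1 / stats::median(te)
    a0 <- max(s) - min(s)
  }
  list(A = unname(a0), B = unname(min(max(b0, 1e-5), 9)), C = unname(c0))
}

#' Per-pixel T2* map from a multi-echo gradient-echo stack
#'
#' Fits the offset exponential `s(TE) = A exp(-B TE) + C` per pixel by
#' bounded nonlinear least squares (Levenberg-Marquardt, B constrained to
#' (1e-6, 10) /ms) and stores T2* = 1/B in ms. Starting values come from a
#' log-linear fit to the early echoes after subtracting the last-echo
#' signal. Pixels whose fit fails to converge, whose signal carries no
#' decay information (zero variance), or whose relative residual exceeds
#' `max_rel_residual` are marked invalid rather than extrapolated.
#'
#' @param mge [image_stack()] with >= 4 echoes and `te_ms` metadata.
#' @param max_rel_residual validity ceiling on RMSE / mean absolute signal.
#' @param max_iter maximum Levenberg-Marquardt iterations per pixel.
#' @return [param_map()] of T2* in ms, with per-pixel `A` and `C` estimates
#'   attached as attributes `amplitude` and `offset`.
#' @export
fit_t2star_map <- function(mge, max_rel_residual = 0.5, max_iter = 200) {
  stopifnot(inherits(mge, "image_stack"))
  te <- mge$meta$te_ms
  if (is.null(te)) stop("te_ms missing from metadata")
  if (length(te) < 4L) stop("insufficient echoes for 3-parameter fit")
  if (any(diff(te) <= 0)) stop("te_ms must be strictly increasing")
  if (n_frames(mge) != length(te)) stop("echo count does not match te_ms")
  d <- dim(mge$pixels)[1:2]
  t2 <- matrix(NA_real_, d[1], d[2])
  Aout <- matrix(NA_real_, d[1], d[2])
  Cout <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                     ptol = 1e-12)
  resid_fn <- function(par, s) par[1] * exp(-par[2] * te) + par[3] - s
  jac_fn <- function(par, s) {
    e <- exp(-par[2] * te)
    cbind(e, -par[1] * te * e, 1)
  }
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      s <- mge$pixels[i, j, ]
      if (stats::sd(s) == 0) next  # A = 0: decay rate unidentifiable
      st <- t2star_start(s, te)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(st$A, st$B, st$C),
                           lower = c(-Inf, 1e-6, -Inf),
                           upper = c(Inf, 10, Inf),
                           fn = resid_fn, jac = jac_fn, s = s,
                           control = ctrl),
        error = function(e) NULL)
      # info codes 1-3 signal convergence in ftol/ptol/both
      if (is.null(fit) || !fit$info %in% 1:3) next
      cf <- fit$par
      rel <- sqrt(mean(resid_fn(cf, s)^2)) / mean(abs(s))
      if (!is.finite(rel) || rel > max_rel_residual) next
      t2[i, j] <- 1 / cf[2]
      Aout[i, j] <- cf[1]
      Cout[i, j] <- cf[3]
      valid[i, j] <- TRUE
    }
  }
  out <- param_map(t2, valid, units = "ms")
  attr(out, "amplitude") <- Aout
  attr(out, "offset") <- Cout
  out
}

#' Relative change map between two challenges
#'
#' Per-pixel percent change `100 (p_challenge - p_baseline)/p_baseline`,
#' e.g. the oxygen-challenge delta-T1 map
#' `100 (T1_O2 - T1_air)/T1_air`. The maps are assumed co-registered; the
#' valid mask of the result is the intersection of the inputs', minus
#' pixels where the baseline is zero.
#'
#' @param map_air baseline [param_map()] (medical air).
#' @param map_o2 challenge [param_map()] (100\% oxygen).
#' @return [param_map()] in percent.
#' @export
relative_delta_map <- function(map_air, map_o2) {
  stopifnot(inherits(map_air, "param_map"), inherits(map_o2, "param_map"))
  if (!all(dim(map_air$values) == dim(map_o2$values)))
    stop("mismatched geometry")
  valid <- map_air$valid & map_o2$valid & map_air$values != 0
  valid[is.na(valid)] <- FALSE
  delta <- 100 * (map_o2$values - map_air$values) / map_air$values
  param_map(delta, valid, units = "%")
}

#' Exclude vessel-like outlier pixels from an ROI
#'
#' Blood has a much longer T1 than liver tissue, so vessel pixels appear as
#' outliers in the ROI's T1 distribution. The ROI mean and standard
#' deviation are computed once over valid ROI pixels (single pass), and
#' pixels outside `[mean - k_sd SD, mean + k_sd SD]` (boundary inclusive)
#' are removed from the mask. Re-running on the result with the same frozen
#' statistics is idempotent.
#'
#' @param t1_map [param_map()] of T1 in ms.
#' @param roi [roi_mask()] of the manually segmented organ region.
#' @param k_sd width of the retention interval in SDs (default 2).
#' @return [roi_mask()] with outliers removed.
#' @export
exclude_vessels <- function(t1_map, roi, k_sd = 2) {
  stopifnot(inherits(t1_map, "param_map"), inherits(roi, "roi_mask"))
  if (!any(roi$pixels)) stop("roi is empty")
  sel <- roi$pixels & t1_map$valid
  vals <- t1_map$values[sel]
  if (length(vals) < 2L) stop("cannot estimate spread: <2 valid roi pixels")
  m <- mean(vals); s <- stats::sd(vals)
  keep <- roi$pixels & t1_map$valid &
    t1_map$values >= m - k_sd * s & t1_map$values <= m + k_sd * s
  keep[is.na(keep)] <- FALSE
  roi_mask(keep, label = paste0(roi$label, "_no_vessels"))
}

#' Mean, SD and count over a masked parameter map
#'
#' @param map a [param_map()].
#' @param mask a [roi_mask()].
#' @return list with `mean`, `sd` (`NA` when a single pixel), `n`.
#' @export
masked_mean <- function(map, mask) {
  stopifnot(inherits(map, "param_map"), inherits(mask, "roi_mask"))
  sel <- mask$pixels & map$valid
  if (!any(sel)) stop("no valid pixels inside mask")
  vals <- map$values[sel]
  list(mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
       n = length(vals))
}

#' FAIR perfusion index map
#'
#' Quantifies perfusion from a FAIR experiment with a two-compartment
#' tissue model at a single inversion time. The apparent longitudinal rate
#' of each inverted image is `R1app(s) = -log((1 - s/M0)/2)/TI` with M0
#' taken from the reference image; the perfusion index is
#' `f = lambda (R1_selective - R1_global)`, reported in institutional units
#' (I.U.). Pixels where the reference is non-positive or the log argument
#' is non-positive (s/M0 >= 1) are marked invalid.
#'
#' @param sel slice-selective inversion [image_stack()].
#' @param glob global inversion [image_stack()].
#' @param ref reference (no inversion) [image_stack()].
#' @param ti_ms inversion time, ms.
#' @param partition_coeff blood-tissue partition coefficient lambda, mL/g.
#' @return [param_map()] of the perfusion index in I.U.
#' @export
fit_fair_perfusion <- function(sel, glob, ref, ti_ms = 2000,
                               partition_coeff = 0.9) {
  stopifnot(inherits(sel, "image_stack"), inherits(glob, "image_stack"),
            inherits(ref, "image_stack"))
  if (ti_ms <= 0) stop("ti_ms must be positive")
  s <- frame_matrix(sel); g <- frame_matrix(glob); m0 <- frame_matrix(ref)
  if (!all(dim(s) == dim(g)) || !all(dim(s) == dim(m0)))
    stop("mismatched geometry")
  arg_s <- (1 - s / m0) / 2
  arg_g <- (1 - g / m0) / 2
  valid <- m0 > 0 & arg_s > 0 & arg_g > 0
  valid[is.na(valid)] <- FALSE
  arg_s[!valid] <- NA_real_  # keep log() off non-positive arguments
  arg_g[!valid] <- NA_real_
  r1s <- -log(arg_s) / ti_ms
  r1g <- -log(arg_g) / ti_ms
  f <- partition_coeff * (r1s - r1g)
  param_map(f, valid, units = "I.U.")
}
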
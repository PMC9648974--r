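#' Digital phantom specification
#'
#' Describes the ground-truth parameter fields from which the MR phantom
#' generators synthesize signal. Scalar fields are expanded to the full
#' grid. All generators are pure functions of (spec, seed): identical
#' inputs give bit-identical output.
#'
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param t1_field true longitudinal relaxation time T1 in ms; scalar or
#'   matrix.
#' @param t2star_field true T2* in ms; scalar or matrix.
#' @param perfusion_field true perfusion index f (institutional units, the
#'   quantity recovered by [fit_fair_perfusion()]); scalar or matrix.
#' @param proton_density equilibrium magnetization M0 (a.u.); scalar or matrix.
#' @param roi logical matrix of pixels belonging to the object (default all).
#' @param vessel_pixels optional integer indices (into the grid) of pixels
#'   emulating blood vessels; must lie inside `roi`.
#' @param vessel_t1 T1 (ms) assigned to `vessel_pixels`; blood T1 at 7 T is
#'   much longer than liver tissue T1, which is what the vessel-exclusion
#'   step detects.
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.).
#'   Magnitude-signal noise is modelled as Gaussian; at the signal-to-noise
#'   ratios used here the difference from Rician noise is negligible, and a
#'   Gaussian model keeps noiseless round trips exact.
#' @param seed integer seed used by the generators.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, t1_field = 1000, t2star_field = 20,
                         perfusion_field = 0, proton_density = 1000,
                         roi = NULL, vessel_pixels = NULL, vessel_t1 = 2400,
                         noise_sd = 0, seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1))
  expand <- function(x, what) {
    if (length(x) == 1L) x <- matrix(x, grid_shape[1], grid_shape[2])
    if (!is.matrix(x) || !all(dim(x) == grid_shape))
      stop(what, " must be scalar or a matrix matching grid_shape")
    x
  }
  t1_field <- expand(t1_field, "t1_field")
  t2star_field <- expand(t2star_field, "t2star_field")
  perfusion_field <- expand(perfusion_field, "perfusion_field")
  proton_density <- expand(proton_density, "proton_density")
  if (is.null(roi)) roi <- matrix(TRUE, grid_shape[1], grid_shape[2])
  stopifnot(is.matrix(roi), is.logical(roi), all(dim(roi) == grid_shape))
  if (!is.null(vessel_pixels)) {
    if (!all(roi[vessel_pixels])) stop("vessel_pixels must lie inside roi")
    t1_field[vessel_pixels] <- vessel_t1
  }
  for (f in list(t1_field, t2star_field, proton_density))
    if (any(f[roi] <= 0)) stop("parameter fields must be positive inside roi")
  if (any(perfusion_field[roi] < 0))
    stop("perfusion_field must be non-negative inside roi")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape), t1_field = t1_field,
                 t2star_field = t2star_field,
                 perfusion_field = perfusion_field,
                 proton_density = proton_density, roi = roi,
                 vessel_pixels = vessel_pixels, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Full spoiled-gradient-echo steady-state signal. alpha in radians.
spgr_signal <- function(m0, alpha, tr_ms, t1_ms) {
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(alpha) * (1 - e1) / (1 - e1 * cos(alpha))
}

# Small-flip-angle linearization of the SPGR signal; exactly invertible by
# the two-point estimator in fit_t1_vfa.
spgr_linearized <- function(m0, alpha, tr_ms, t1_ms) {
  m0 * alpha / (1 + alpha^2 * t1_ms / (2 * tr_ms))
}

#' Generate variable-flip-angle cine phantoms
#'
#' Synthesizes one spoiled-gradient-echo cine per flip angle over a known
#' T1 field, for testing variable-flip-angle T1 mapping. The `linearized`
#' model is the exact forward model of the two-point estimator; `full_spgr`
#' is the complete steady-state signal equation, so fitting it with the
#' linearized estimator exposes the small-angle approximation bias.
#'
#' @param spec a [phantom_spec()].
#' @param flip_angles_deg at least two distinct flip angles, degrees.
#' @param tr_ms repetition time, ms.
#' @param model `"linearized"` or `"full_spgr"` forward model.
#' @param frames number of cine frames per angle (each with independent
#'   noise; the signal itself is at steady state in every frame).
#'
#' @return list with `stacks` (one [image_stack()] per flip angle) and
#'   `truth` (a truth record carrying `t1_field` and `m0`).
#' @export
gen_vfa_phantom <- function(spec, flip_angles_deg = c(5, 20), tr_ms = 10,
                            model = c("linearized", "full_spgr"),
                            frames = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "phantom_spec"))
  flip_angles_deg <- unique(flip_angles_deg)
  if (length(flip_angles_deg) < 2L)
    stop("underdetermined: need >= 2 distinct flip angles")
  if (tr_ms <= 0) stop("tr_ms must be positive")
  fwd <- if (model == "linearized") spgr_linearized else spgr_signal
  d <- spec$grid_shape
  stacks <- withr::with_seed(spec$seed, {
    lapply(flip_angles_deg, function(a_deg) {
      s <- fwd(spec$proton_density, a_deg * pi / 180, tr_ms, spec$t1_field)
      px <- array(s, dim = c(d, frames))
      if (spec$noise_sd > 0)
        px <- px + array(stats::rnorm(prod(d) * frames, 0, spec$noise_sd),
                         dim = c(d, frames))
      image_stack(px, flip_angle_deg = a_deg, tr_ms = tr_ms)
    })
  })
  names(stacks) <- paste0("fa", flip_angles_deg)
  list(stacks = stacks,
       truth = truth_record("gen_vfa_phantom", t1_field = spec$t1_field,
                            m0 = spec$proton_density, model = model,
                            tr_ms = tr_ms, flip_angles_deg = flip_angles_deg))
}

#' Generate a multi-echo gradient-echo phantom
#'
#' Signal decays as `A * exp(-TE/T2*) + C` over a known T2* field, the
#' forward model inverted by [fit_t2star_map()].
#'
#' @param spec a [phantom_spec()].
#' @param te_ms strictly increasing echo times, ms; at least 4 echoes are
#'   required for a stable 3-parameter fit.
#' @param amplitude decay amplitude A (a.u.); scalar or matrix.
#' @param offset baseline offset C (a.u.); scalar or matrix.
#'
#' @return list with `stack` (an [image_stack()] with one frame per echo)
#'   and `truth` (carries `t2star_field`, `amplitude`, `offset`).
#' @export
gen_mge_phantom <- function(spec, te_ms = seq(2.5, 47.5, by = 2.5),
                            amplitude = 100, offset = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(te_ms) < 4L) stop("insufficient echoes for 3-parameter fit")
  if (any(diff(te_ms) <= 0)) stop("te_ms must be strictly increasing")
  d <- spec$grid_shape
  A <- if (length(amplitude) == 1L) matrix(amplitude, d[1], d[2]) else amplitude
  C <- if (length(offset) == 1L) matrix(offset, d[1], d[2]) else offset
  px <- array(0, dim = c(d, length(te_ms)))
  for (k in seq_along(te_ms))
    px[, , k] <- A * exp(-te_ms[k] / spec$t2star_field) + C
  px <- withr::with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      px + array(stats::rnorm(length(px), 0, spec$noise_sd), dim = dim(px))
    else px
  })
  list(stack = image_stack(px, te_ms = te_ms),
       truth = truth_record("gen_mge_phantom", t2star_field = spec$t2star_field,
                            amplitude = A, offset = C, te_ms = te_ms))
}

#' Generate FAIR arterial-spin-labeling phantoms
#'
#' Produces the slice-selective, global-inversion and reference (no
#' inversion) images of a FAIR experiment at a single inversion time over a
#' known perfusion field, assuming perfect inversion:
#' reference = M0; global = M0 (1 - 2 exp(-TI R1));
#' selective = M0 (1 - 2 exp(-TI (R1 + f/lambda))), with R1 = 1/T1 in 1/ms
#' and lambda the blood-tissue partition coefficient.
#'
#' @param spec a [phantom_spec()]; `perfusion_field` holds the true f.
#' @param ti_ms inversion time, ms.
#' @param partition_coeff blood-tissue partition coefficient lambda, mL/g.
#'
#' @return list with `selective`, `global_inv`, `reference` image stacks and
#'   `truth` (carries `perfusion_field`).
#' @export
gen_fair_phantom <- function(spec, ti_ms = 2000, partition_coeff = 0.9) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (ti_ms <= 0) stop("ti_ms must be positive")
  m0 <- spec$proton_density
  r1 <- 1 / spec$t1_field
  dr1 <- spec$perfusion_field / partition_coeff
  imgs <- list(selective = m0 * (1 - 2 * exp(-ti_ms * (r1 + dr1))),
               global_inv = m0 * (1 - 2 * exp(-ti_ms * r1)),
               reference = m0)
  imgs <- withr::with_seed(spec$seed, {
    lapply(imgs, function(s) {
      if (spec$noise_sd > 0)
        s <- s + matrix(stats::rnorm(length(s), 0, spec$noise_sd),
                        nrow(s), ncol(s))
      s
    })
  })
  c(lapply(imgs, image_stack, ti_ms = ti_ms),
    list(truth = truth_record("gen_fair_phantom",
                              perfusion_field = spec$perfusion_field,
                              ti_ms = ti_ms,
                              partition_coeff = partition_coeff)))
}
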
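#' Natural isotope abundance table
#'
#' Per-element natural abundances of the stable isotopes, indexed by mass
#' shift (position 1 = monoisotopic, position 2 = +1 Da, ...). Defaults are
#' the standard terrestrial values for the elements present in
#' methoxime-TBDMS derivatized metabolite fragments (C, H, N, O, Si, S).
#' Any element can be overridden; each vector is renormalized to sum to 1.
#'
#' @param ... named numeric vectors overriding individual elements, e.g.
#'   `C = c(0.99, 0.01)`.
#' @return named list of abundance vectors, class `isotope_table`.
#' @export
isotope_table <- function(...) {
  tab <- list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.9223, 0.0468, 0.0309),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  over <- list(...)
  for (nm in names(over)) {
    v <- over[[nm]]
    if (!is.numeric(v) || any(v < 0) || sum(v) <= 0)
      stop("invalid abundance vector for element ", nm)
    tab[[nm]] <- v
  }
  tab <- lapply(tab, function(v) v / sum(v))
  structure(tab, class = "isotope_table")
}

#' Measured-fragment elemental composition
#'
#' The elemental composition of the ion actually measured by GC-MS,
#' including all derivatization atoms (methoxime and TBDMS groups carry C,
#' H, N, O and Si that contribute natural-abundance mass shifts), together
#' with the number of tracer-labelable backbone carbons.
#'
#' @param element_counts named integer vector of atom counts, e.g.
#'   `c(C = 11, H = 25, O = 3, Si = 2)`.
#' @param n_labelable number of backbone carbons that can carry tracer
#'   label (MID length minus one); must not exceed the carbon count.
#' @return object of class `fragment_spec`.
#' @export
fragment_spec <- function(element_counts, n_labelable) {
  element_counts <- element_counts[element_counts > 0]
  if (any(element_counts < 0)) stop("atom counts must be >= 0")
  n_c <- if ("C" %in% names(element_counts)) element_counts[["C"]] else 0L
  if (n_labelable > n_c)
    stop("n_labelable (", n_labelable, ") exceeds carbon count (", n_c, ")")
  if (n_labelable < 0) stop("n_labelable must be >= 0")
  structure(list(element_counts = element_counts,
                 n_labelable = as.integer(n_labelable)),
            class = "fragment_spec")
}

#' Packaged fragment library
#'
#' Loads the elemental compositions of the methoxime-TBDMS fragments used
#' for glucose and lactate GC-MS isotopomer measurements, shipped with the
#' package (compositions follow standard derivatization chemistry:
#' glucose methoxime-penta-TBDMS [M-57]+, lactate di-TBDMS [M-57]+).
#'
#' @param path optional path to a JSON fragment library; defaults to the
#'   packaged file.
#' @return named list of [fragment_spec()] objects.
#' @export
fragment_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fragments.json", package = "hepatoxim")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(f)
    fragment_spec(unlist(f$element_counts), f$n_labelable))
}

# Mass-shift distribution of n atoms of one element: n-fold convolution of
# the single-atom isotope-shift distribution.
element_shift_dist <- function(abund, n) {
  out <- 1
  for (k in seq_len(n)) out <- convolve_full(out, abund)
  out
}

convolve_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Natural-abundance correction matrix
#'
#' Builds the matrix mapping a true tracer-labeling distribution to the
#' mass-isotopomer distribution observed by the spectrometer. Column j
#' (0-based labeling index) is the predicted observed mass distribution of
#' a molecule with exactly j tracer carbons labeled: the natural-abundance
#' mass-shift distributions of all atoms except the j labeled carbons are
#' convolved, the result shifted up by j, truncated to `size` and
#' renormalized.
#'
#' @param frag a [fragment_spec()].
#' @param iso an [isotope_table()].
#' @param size number of measured isotopologues (MID length, m+0 ... m+n).
#' @return `size` x `size` column-stochastic matrix.
#' @export
build_correction_matrix <- function(frag, iso = isotope_table(),
                                    size = frag$n_labelable + 1L) {
  stopifnot(inherits(frag, "fragment_spec"))
  if (size > frag$n_labelable + 1L)
    stop("size exceeds theoretically possible labeled shifts (",
         frag$n_labelable + 1L, ")")
  counts <- frag$element_counts
  unknown <- setdiff(names(counts), names(iso))
  if (length(unknown))
    stop("no abundance data for element(s): ", paste(unknown, collapse = ", "))
  M <- matrix(0, size, size)
  for (j in seq_len(size) - 1L) {
    dist <- 1
    for (el in names(counts)) {
      n_at <- counts[[el]] - if (el == "C") j else 0L
      if (n_at > 0) dist <- convolve_full(dist, element_shift_dist(iso[[el]], n_at))
    }
    col <- numeric(size)
    avail <- seq_len(min(length(dist), size - j)) # shifts j, j+1, ...
    col[j + avail] <- dist[avail]
    M[, j + 1L] <- col / sum(col)
  }
  M
}

#' Correct an observed MID for natural abundance
#'
#' Solves `M x = observed` by non-negative least squares and renormalizes
#' the solution to a fractional distribution. Small negative observed
#' entries (noise) are clipped to zero before the solve.
#'
#' @param observed numeric vector, observed fractional MID (m+0 ... m+n).
#' @param matrix correction matrix from [build_correction_matrix()].
#' @param max_condition reject matrices with 2-norm condition number above
#'   this threshold.
#' @return corrected MID, non-negative and summing to 1.
#' @export
correct_mid <- function(observed, matrix, max_condition = 1e8) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("correction matrix must be square")
  if (length(observed) != nrow(matrix))
    stop("observed MID length does not match matrix size")
  csums <- colSums(matrix)
  if (any(abs(csums - 1) > 1e-6))
    stop("correction matrix is not column-stochastic")
  d <- svd(matrix)$d
  kap <- if (min(d) == 0) Inf else max(d) / min(d)
  if (kap > max_condition)
    stop(sprintf("correction matrix ill-conditioned (condition number %.3g > %.3g)",
                 kap, max_condition))
  obs <- pmax(observed, 0)
  x <- pracma::lsqnonneg(matrix, obs)$x
  if (sum(x) <= 0) stop("correction produced an all-zero distribution")
  x / sum(x)
}

#' Total labeled fraction of a MID
#'
#' The fraction of molecules carrying any tracer label, `1 - (m+0)`.
#'
#' @param mid fractional MID (m+0 first).
#' @return labeled fraction in `[0, 1]`.
#' @export
labeled_fraction <- function(mid) {
  mid <- check_mid(mid)
  1 - mid[1]
}

#' Precursor-normalized enrichment
#'
#' Labeled fraction of a downstream metabolite relative to the enrichment
#' of its labeled precursor pool (e.g. liver metabolite labeling relative
#' to liver glucose m+6 during a uniformly labeled glucose infusion).
#'
#' @param labeled labeled fraction of the metabolite.
#' @param precursor_enrichment enrichment of the precursor pool (> 0).
#' @return normalized enrichment.
#' @export
normalize_enrichment <- function(labeled, precursor_enrichment) {
  if (precursor_enrichment == 0) stop("undefined normalization: precursor enrichment is zero")
  labeled / precursor_enrichment
}

#' Fractional gluconeogenesis from a labeled lactate/pyruvate bolus
#'
#' Fraction of circulating glucose newly synthesized from the labeled
#' three-carbon pool, computed from natural-abundance-corrected glucose
#' and lactate MIDs as
#' `(M1g + M2g + M3g) / (2 M0lac (M1lac + M2lac + M3lac))`:
#' glucose made from two labeled three-carbon units acquires m+1..m+3
#' label from each half, the factor 2 accounting for the two halves, and
#' the lactate terms normalizing to the precursor pool enrichment.
#'
#' @param glucose_mid corrected glucose MID, length >= 4 (m+0 ... m+6 for
#'   the full fragment).
#' @param lactate_mid corrected lactate MID, length 4 (m+0 ... m+3).
#' @return fractional gluconeogenesis (dimensionless).
#' @export
fractional_gng <- function(glucose_mid, lactate_mid) {
  check_fractions <- function(mid, what) {
    if (!is.numeric(mid) || any(!is.finite(mid)) || any(mid < 0))
      stop(what, " MID must be non-negative and finite")
    if (sum(mid) > 1 + 1e-6)
      stop(what, " MID fractions sum above 1; normalize intensities first")
    mid
  }
  # fractions are consumed as given: a truncated MID (e.g. m+0..m+3 of a
  # 6-carbon fragment) legitimately sums below 1
  glucose_mid <- check_fractions(glucose_mid, "glucose")
  lactate_mid <- check_fractions(lactate_mid, "lactate")
  if (length(glucose_mid) < 4L) stop("glucose MID must cover m+0 ... m+3")
  if (length(lactate_mid) != 4L) stop("lactate MID must be m+0 ... m+3")
  num <- sum(glucose_mid[2:4])
  lab_lac <- sum(lactate_mid[2:4])
  den <- 2 * lactate_mid[1] * lab_lac
  if (lab_lac == 0) stop("zero labeled lactate")
  if (den == 0) stop("zero denominator: unlabeled or empty lactate pool")
  num / den
}

# Validate and renormalize a fractional MID.
check_mid <- function(mid) {
  if (!is.numeric(mid) || length(mid) < 1L) stop("MID must be numeric")
  if (any(!is.finite(mid))) stop("MID entries must be finite")
  if (any(mid < -1e-9)) stop("MID entries must be non-negative")
  mid <- pmax(mid, 0)
  s <- sum(mid)
  if (s <= 0) stop("MID sums to zero")
  mid / s
}
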
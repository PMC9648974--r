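#' Image stack with acquisition metadata
#'
#' A 2-D image or a 3-D stack of frames/echoes plus the acquisition
#' parameters the fitters need. Frames are indexed along the third axis.
#'
#' @param pixels numeric matrix (rows x cols) or 3-D array
#'   (rows x cols x frames) of signal intensities (a.u.).
#' @param flip_angle_deg flip angle(s) in degrees, or `NULL`.
#' @param tr_ms repetition time in ms, or `NULL`.
#' @param te_ms echo times in ms (one per frame for multi-echo data), or `NULL`.
#' @param ti_ms inversion time in ms, or `NULL`.
#'
#' @return An object of class `image_stack` with elements `pixels` and `meta`.
#' @export
image_stack <- function(pixels, flip_angle_deg = NULL, tr_ms = NULL,
                        te_ms = NULL, ti_ms = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be a matrix or a rows x cols x frames array")
  if (!all(is.finite(pixels))) stop("image intensities must be finite")
  n_frames <- dim(pixels)[3L]
  if (!is.null(te_ms) && length(te_ms) > 1L && length(te_ms) != n_frames)
    stop("te_ms length (", length(te_ms), ") does not match frame count (",
         n_frames, ")")
  if (!is.null(tr_ms) && tr_ms <= 0) stop("tr_ms must be positive")
  if (!is.null(ti_ms) && ti_ms <= 0) stop("ti_ms must be positive")
  structure(list(
    pixels = pixels,
    meta = list(flip_angle_deg = flip_angle_deg, tr_ms = tr_ms,
                te_ms = te_ms, ti_ms = ti_ms),
    frame_axis = 3L
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d x %d, %d frame(s)\n", d[1], d[2], d[3]))
  m <- x$meta[!vapply(x$meta, is.null, logical(1))]
  for (nm in names(m))
    cat(sprintf("  %s: %s\n", nm, paste(signif(m[[nm]], 5), collapse = ", ")))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[3L]

#' Extract a single frame as a matrix
#' @param stack an [image_stack()].
#' @param i frame index (1-based).
#' @return numeric matrix.
#' @export
frame_matrix <- function(stack, i = 1L) {
  stopifnot(inherits(stack, "image_stack"), i >= 1L, i <= n_frames(stack))
  stack$pixels[, , i]
}

#' Per-pixel fitted parameter map
#'
#' @param values numeric matrix of per-pixel parameter estimates; entries at
#'   invalid pixels are stored as `NA`.
#' @param valid logical matrix marking pixels where the fit succeeded.
#' @param units unit label (e.g. `"ms"`, `"I.U."`, `"%"`).
#'
#' @return An object of class `param_map`.
#' @export
param_map <- function(values, valid = is.finite(values), units = "") {
  stopifnot(is.matrix(values), is.matrix(valid),
            all(dim(values) == dim(valid)))
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, units = units),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map> %d x %d [%s], %d/%d valid\n",
              nrow(x$values), ncol(x$values), x$units,
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param pixels logical matrix, `TRUE` inside the region.
#' @param label text label for the region.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, label = "roi") {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, label = label), class = "roi_mask")
}

#' Feature-by-sample abundance table
#'
#' The container for label-free omics intensity data. Missing measurements
#' are stored as `NA`; `scale` tracks which transformations have been
#' applied so operations can enforce their preconditions.
#'
#' @param values numeric matrix, features as rows, samples as columns.
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to rownames).
#' @param scale one of `"raw"`, `"log2"`, `"normalized"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, feature_ids = rownames(values),
                            scale = c("raw", "log2", "normalized")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values))
  if (is.null(feature_ids))
    feature_ids <- paste0("feature_", seq_len(nrow(values)))
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length must match row count")
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw intensities must be non-negative")
  rownames(values) <- feature_ids
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  structure(list(values = values, feature_ids = feature_ids, scale = scale),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d features x %d samples [%s], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Two-group sample design
#'
#' @param sample character vector of sample names (column names of the
#'   abundance table).
#' @param group group label per sample; exactly two distinct labels. Fold
#'   changes are reported as second group minus first group, in the order
#'   the labels first appear.
#' @return An object of class `group_design`.
#' @export
group_design <- function(sample, group) {
  stopifnot(length(sample) == length(group))
  if (anyDuplicated(sample)) stop("duplicate sample names in design")
  lv <- unique(as.character(group))
  if (length(lv) != 2L)
    stop("differential testing requires exactly two groups, got ", length(lv))
  group <- factor(as.character(group), levels = lv)
  if (any(table(group) < 2L)) stop("need >= 2 samples per group")
  structure(list(sample = as.character(sample), group = group, levels = lv),
            class = "group_design")
}

# Ground truth emitted by every synthetic generator, consumed by recovery
# tests. A tagged list; contents depend on the generator.
truth_record <- function(generator, ...) {
  structure(list(generator = generator, ...), class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> from %s: %s\n", x$generator,
              paste(setdiff(names(x), "generator"), collapse = ", ")))
  invisible(x)
}
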
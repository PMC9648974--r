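#' Log2-transform and column-normalize an abundance table
#'
#' Each sample (column) is log2-transformed and standardized by its own
#' mean and standard deviation ("average abundance and data distribution
#' width"), then rescaled by the grand mean and pooled SD across columns so
#' values remain in log2-intensity units. After normalization every column
#' has identical mean and SD. Missing cells stay missing.
#'
#' @param table [abundance_table()] on the raw scale with positive values.
#' @param width one of `"sd"` (default) or `"mad"`: the distribution-width
#'   estimate used for standardization.
#' @return normalized [abundance_table()] (scale `"normalized"`).
#' @export
log2_normalize <- function(table, width = c("sd", "mad")) {
  width <- match.arg(width)
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale != "raw") stop("expected a raw-scale table")
  x <- table$values
  if (any(x <= 0, na.rm = TRUE)) stop("present raw values must be positive")
  lg <- log2(x)
  n_present <- colSums(!is.na(lg))
  if (any(n_present < 2L))
    stop("column(s) with <2 present values: ",
         paste(colnames(lg)[n_present < 2L], collapse = ", "))
  mu <- colMeans(lg, na.rm = TRUE)
  wfun <- if (width == "sd") function(v) stats::sd(v, na.rm = TRUE)
          else function(v) stats::mad(v, na.rm = TRUE)
  sg <- apply(lg, 2, wfun)
  if (any(sg == 0)) stop("column(s) with zero spread")
  grand_mu <- mean(mu)
  grand_sg <- mean(sg)
  z <- sweep(sweep(lg, 2, mu, "-"), 2, sg, "/")
  out <- z * grand_sg + grand_mu
  res <- table
  res$values <- out
  res$scale <- "normalized"
  res
}

#' Impute missing values from a left-shifted Gaussian
#'
#' Missing-not-at-random cells (detection-limit censoring) are filled per
#' sample with random draws centered `shift_sd` standard deviations below
#' that sample's mean abundance, with width `width_sd` of the sample SD;
#' mean and SD are computed from the present values. Present values are
#' never altered.
#'
#' @param table normalized [abundance_table()].
#' @param shift_sd downshift of the imputation distribution, in column SDs.
#' @param width_sd width of the imputation distribution, in column SDs.
#' @param seed integer seed; imputation is deterministic given the seed.
#' @return complete [abundance_table()] with attribute `imputed` (logical
#'   matrix marking imputed cells).
#' @export
impute_mnar <- function(table, shift_sd = 2.5, width_sd = 0.3, seed) {
  stopifnot(inherits(table, "abundance_table"))
  if (!table$scale %in% c("normalized", "log2"))
    stop("imputation expects log2-scale (normalized) data")
  if (missing(seed)) stop("an explicit seed is required")
  x <- table$values
  miss <- is.na(x)
  if (!any(miss)) {
    attr(table, "imputed") <- miss
    return(table)
  }
  if (any(colSums(!miss) == 0)) stop("column(s) fully missing")
  x <- withr::with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      mj <- miss[, j]
      if (!any(mj)) next
      m <- mean(x[!mj, j]); s <- stats::sd(x[!mj, j])
      x[mj, j] <- stats::rnorm(sum(mj), m - shift_sd * s, width_sd * s)
    }
    x
  })
  res <- table
  res$values <- x
  attr(res, "imputed") <- miss
  res
}

#' Normality-gated two-group test
#'
#' The adaptive test applied per feature: when both groups have more than 4
#' replicates, each group is screened with a Shapiro-Wilk normality test;
#' if either looks non-normal (p < `alpha_gates`) a two-sided Mann-Whitney
#' test is used (normal approximation with continuity correction, which at
#' these group sizes makes the same accept/reject decisions as the exact
#' test and tolerates ties). Otherwise an F-test of equal variances decides
#' between the pooled two-sample t-test and Welch's heteroscedastic t-test.
#' Groups of 4 or fewer replicates skip the normality gate (the screen has
#' no power there) and go directly to the F-test branch.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param alpha_gates significance level of the Shapiro-Wilk and F gates.
#' @return list with `p`, `test_used` (`"t_homo"`, `"t_hetero"` or
#'   `"mann_whitney"`) and `degenerate` (TRUE when both groups are a single
#'   shared constant, in which case p = 1 by convention).
#' @export
adaptive_test <- function(group_a, group_b, alpha_gates = 0.05) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (length(unique(c(a, b))) == 1L)
    return(list(p = 1, test_used = "t_homo", degenerate = TRUE))
  if (length(a) > 4L && length(b) > 4L) {
    swp <- function(v) {
      if (length(unique(v)) == 1L) return(0)  # constant: certainly non-normal
      stats::shapiro.test(v)$p.value
    }
    if (swp(a) < alpha_gates || swp(b) < alpha_gates) {
      p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
      return(list(p = p, test_used = "mann_whitney", degenerate = FALSE))
    }
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  f_p <- if (va == 0 || vb == 0) 0 else {
    r <- stats::pf(va / vb, na - 1, nb - 1)
    2 * min(r, 1 - r)
  }
  if (f_p < alpha_gates) {
    se2 <- va / na + vb / nb
    if (se2 == 0) return(list(p = 0, test_used = "t_hetero", degenerate = FALSE))
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    list(p = 2 * stats::pt(-abs(tt), df), test_used = "t_hetero",
         degenerate = FALSE)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    if (se2 == 0) return(list(p = 0, test_used = "t_homo", degenerate = FALSE))
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    list(p = 2 * stats::pt(-abs(tt), na + nb - 2), test_used = "t_homo",
         degenerate = FALSE)
  }
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)` with `m` the number of tested features.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method only `"bonferroni"` is provided, matching the study
#'   design; the family is all features tested in the run.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = "bonferroni") {
  method <- match.arg(method, "bonferroni")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  pmin(1, p * length(p))
}

#' Volcano-style significance call
#'
#' `"up"` when `log2fc > fc_thresh` and `p_adj < p_thresh`; `"down"` when
#' `log2fc < -fc_thresh` and `p_adj < p_thresh`; otherwise `"ns"`.
#' Inequalities are strict: boundary values are not significant.
#'
#' @param log2fc log2 fold change(s).
#' @param p_adj adjusted p-value(s).
#' @param fc_thresh absolute log2-fold-change threshold.
#' @param p_thresh adjusted-p threshold.
#' @return character vector of calls.
#' @export
call_significant <- function(log2fc, p_adj, fc_thresh = 1, p_thresh = 0.05) {
  if (any(!is.finite(log2fc)) || any(!is.finite(p_adj)))
    stop("inputs must be finite")
  ifelse(p_adj < p_thresh & log2fc > fc_thresh, "up",
         ifelse(p_adj < p_thresh & log2fc < -fc_thresh, "down", "ns"))
}

#' Row-wise z-score transform
#'
#' Standardizes each feature row to mean 0 and SD 1 for clustering and
#' heat-map display. Rows with zero spread carry no clustering information
#' and are excluded with a warning (ids in attribute `excluded`).
#'
#' @param table complete [abundance_table()] (no missing values).
#' @return numeric matrix of z-scores.
#' @export
zscore_rows <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$values else table
  if (any(is.na(x))) stop("z-scoring requires a complete table; impute first")
  sds <- apply(x, 1, stats::sd)
  bad <- sds == 0
  if (any(bad))
    warning(sum(bad), " constant row(s) excluded from z-scoring")
  z <- (x[!bad, , drop = FALSE] - rowMeans(x[!bad, , drop = FALSE])) /
    sds[!bad]
  attr(z, "excluded") <- rownames(x)[bad]
  z
}

#' Hierarchical clustering of z-scored features
#'
#' Deterministic agglomerative clustering of feature rows (average linkage
#' on Euclidean distance by default), as used for unsupervised heat maps.
#'
#' @param z numeric matrix, typically from [zscore_rows()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param metric distance metric passed to [stats::dist()].
#' @return list with `order` (leaf ordering), `merge`, `height` and the
#'   underlying `hclust` object.
#' @export
cluster_rows <- function(z, linkage = "average", metric = "euclidean") {
  if (!is.matrix(z) || nrow(z) < 2L) stop("need >= 2 rows to cluster")
  if (any(!is.finite(z))) stop("non-finite entries")
  hc <- stats::hclust(stats::dist(z, method = metric), method = linkage)
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc)
}

#' Total-ion-count normalization
#'
#' Scales each sample so all column sums equal the grand mean of the
#' original column sums, removing differences in total loaded material.
#'
#' @param table raw-scale [abundance_table()] with non-negative values.
#' @return normalized [abundance_table()] (values rescaled, scale stays
#'   `"raw"` since units remain raw intensities).
#' @export
tic_normalize <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale != "raw") stop("expected a raw-scale table")
  sums <- colSums(table$values, na.rm = TRUE)
  if (any(sums == 0))
    stop("zero total ion count in sample(s): ",
         paste(colnames(table$values)[sums == 0], collapse = ", "))
  target <- mean(sums)
  res <- table
  res$values <- sweep(table$values, 2, target / sums, "*")
  res
}

#' Redox-indicator metabolite ratio panels
#'
#' Per-sample ratios of metabolite pairs whose equilibrium reflects
#' compartment redox state (e.g. pyruvate/lactate for the cytosolic and
#' acetoacetate/beta-hydroxybutyrate for the mitochondrial NAD+/NADH
#' ratio). Samples with a zero denominator are flagged `NA` and excluded
#' from any control-group normalization.
#'
#' @param table [abundance_table()] of metabolite intensities.
#' @param pairs list of `c(numerator_id, denominator_id)` pairs.
#' @param design optional [group_design()]; with `control_group`, each
#'   ratio is divided by its control-group mean so the control mean is 1.
#' @param control_group label of the reference group in `design`.
#' @return matrix of ratios, one row per pair, one column per sample.
#' @export
redox_ratios <- function(table, pairs, design = NULL, control_group = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$values
  out <- matrix(NA_real_, length(pairs), ncol(x),
                dimnames = list(NULL, colnames(x)))
  rn <- character(length(pairs))
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    for (id in pr)
      if (!id %in% rownames(x)) stop("metabolite not found: ", id)
    num <- x[pr[1], ]; den <- x[pr[2], ]
    r <- num / den
    r[!is.finite(r) | den == 0] <- NA_real_
    out[k, ] <- r
    rn[k] <- paste0(pr[1], "/", pr[2])
  }
  rownames(out) <- rn
  if (!is.null(design) && !is.null(control_group)) {
    if (!control_group %in% design$levels)
      stop("control group not in design: ", control_group)
    ctrl <- design$sample[design$group == control_group]
    cm <- rowMeans(out[, ctrl, drop = FALSE], na.rm = TRUE)
    out <- out / cm
  }
  out
}

#' Flag mitochondrially localized features
#'
#' Marks features present in a mitochondrial annotation set (a packaged
#' list of canonical mouse mitochondrial gene symbols standing in for a
#' full localization database). Matching is case-insensitive; unmatched
#' ids are flagged `FALSE`.
#'
#' @param diff data frame with a `feature_id` column (e.g. from
#'   [diff_abundance()]).
#' @param ann character vector of mitochondrial feature ids; defaults to
#'   the packaged annotation fixture.
#' @return `diff` with a logical `mito` column.
#' @export
annotate_mito <- function(diff, ann = mito_annotations()) {
  stopifnot(is.data.frame(diff), "feature_id" %in% names(diff))
  diff$mito <- toupper(diff$feature_id) %in% toupper(ann)
  diff
}

#' Packaged mitochondrial annotation fixture
#'
#' A small curated list of canonical mouse mitochondrial gene symbols
#' (electron-transport-chain subunits, assembly factors and matrix
#' enzymes) shipped as a synthetic stand-in for a full mitochondrial
#' protein inventory.
#'
#' @param path optional path to a plain-text id list (one per line).
#' @return character vector of feature ids.
#' @export
mito_annotations <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mito_annotations.txt",
                        package = "hepatoxim")
  ids <- readLines(path)
  ids <- trimws(ids[nzchar(trimws(ids)) & !startsWith(trimws(ids), "#")])
  if (anyDuplicated(toupper(ids))) stop("duplicate annotation ids")
  ids
}

#' Two-group differential-abundance pipeline
#'
#' Runs the full label-free pipeline on a raw abundance table:
#' log2-normalization, left-shifted Gaussian imputation of MNAR cells,
#' per-feature normality-gated testing, Bonferroni adjustment over all
#' tested features, and volcano-style significance calls. Fold changes are
#' computed on the normalized log2 values (second design group minus
#' first); `used_imputed` records whether any cell of a feature was
#' imputed.
#'
#' @param table raw-scale [abundance_table()].
#' @param design a [group_design()] covering the table's columns.
#' @param seed integer seed for the imputation draws.
#' @param shift_sd,width_sd imputation parameters, see [impute_mnar()].
#' @param fc_thresh,p_thresh significance-call thresholds, see
#'   [call_significant()].
#' @param annotations optional mitochondrial id set for [annotate_mito()];
#'   `NULL` skips annotation.
#' @return data frame with one row per feature: `feature_id`, `log2fc`,
#'   `p_value`, `p_adj`, `test_used`, `call`, `degenerate`, `used_imputed`
#'   and optionally `mito`.
#' @export
diff_abundance <- function(table, design, seed, shift_sd = 2.5,
                           width_sd = 0.3, fc_thresh = 1, p_thresh = 0.05,
                           annotations = NULL) {
  stopifnot(inherits(table, "abundance_table"), inherits(design, "group_design"))
  if (!all(design$sample %in% colnames(table$values)))
    stop("design samples missing from table")
  norm <- log2_normalize(table)
  imp <- impute_mnar(norm, shift_sd = shift_sd, width_sd = width_sd,
                     seed = seed)
  x <- imp$values[, design$sample, drop = FALSE]
  imputed <- attr(imp, "imputed")[, design$sample, drop = FALSE]
  ia <- design$group == design$levels[1]
  ib <- design$group == design$levels[2]
  n <- nrow(x)
  p <- numeric(n); test_used <- character(n); degen <- logical(n)
  for (i in seq_len(n)) {
    r <- adaptive_test(x[i, ia], x[i, ib])
    p[i] <- r$p; test_used[i] <- r$test_used; degen[i] <- r$degenerate
  }
  log2fc <- rowMeans(x[, ib, drop = FALSE]) - rowMeans(x[, ia, drop = FALSE])
  p_adj <- adjust_pvalues(p)
  out <- data.frame(feature_id = table$feature_ids,
                    log2fc = log2fc,
                    p_value = p,
                    p_adj = p_adj,
                    test_used = test_used,
                    call = call_significant(log2fc, p_adj, fc_thresh, p_thresh),
                    degenerate = degen,
                    used_imputed = rowSums(imputed) > 0,
                    row.names = NULL)
  if (!is.null(annotations)) out <- annotate_mito(out, annotations)
  out
}
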
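#' Read an abundance matrix from CSV/TSV
#'
#' Features as rows (first column = feature id), samples as columns.
#' Empty cells and `NA` both parse as missing; numbers must use dot
#' decimals regardless of locale.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"` (default inferred from the extension).
#' @param scale abundance scale of the stored values.
#' @return an [abundance_table()].
#' @export
read_abundance_csv <- function(path, format = NULL,
                               scale = c("raw", "log2", "normalized")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- infer_sep(path, format)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), colClasses = "character")
  if (ncol(df) < 2L) stop("need a feature-id column plus >= 1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d (feature %s), column %s",
                 bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  rownames(num) <- ids
  abundance_table(num, scale = scale)
}

#' Read a wide-format MID table from CSV/TSV
#'
#' One row per (metabolite, sample) with `m0, m1, ...` columns; each row is
#' renormalized to a fractional distribution.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @return data frame with `metabolite`, `sample` and a `mid` list-column
#'   of fractional vectors.
#' @export
read_mid_csv <- function(path, format = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- infer_sep(path, format)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("metabolite", "sample")
  if (!all(need %in% names(df)))
    stop("MID table must have 'metabolite' and 'sample' columns")
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  if (length(mcols) < 2L) stop("need >= 2 isotopologue columns (m0, m1, ...)")
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  df$mid <- lapply(seq_len(nrow(df)), function(i)
    check_mid(as.numeric(df[i, mcols])))
  df[c("metabolite", "sample", "mid")]
}

#' Read a sample-design CSV
#'
#' @param path CSV with `sample` and `group` columns.
#' @return a [group_design()].
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("design file must have 'sample' and 'group' columns")
  group_design(df$sample, df$group)
}

infer_sep <- function(path, format) {
  if (is.null(format))
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  switch(match.arg(format, c("csv", "tsv")), csv = ",", tsv = "\t")
}

#' Write an image stack with a JSON metadata sidecar
#'
#' NIfTI (`.nii` / `.nii.gz`) stores the voxel data losslessly; TIFF
#' stores data scaled to `[0, 1]` with the scale recorded in the sidecar.
#' Acquisition metadata (flip angle, TR, TE list, TI) goes to
#' `<path>.json`.
#'
#' @param stack an [image_stack()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  meta <- stack$meta[!vapply(stack$meta, is.null, logical(1))]
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(stack$pixels), path)
  } else if (grepl("\\.tiff?$", path)) {
    rng <- max(abs(stack$pixels), 1e-300)
    meta$tiff_scale <- rng
    pages <- lapply(seq_len(n_frames(stack)),
                    function(k) (stack$pixels[, , k] / rng + 1) / 2)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else stop("unsupported image format: ", path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path image path; the `<path>.json` sidecar supplies metadata.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  if (grepl("\\.nii(\\.gz)?$", path)) {
    nii <- RNifti::readNifti(path)
    px <- array(as.numeric(nii), dim = dim(nii))
  } else if (grepl("\\.tiff?$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    rng <- if (!is.null(meta$tiff_scale)) meta$tiff_scale else 1
    px <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) px[, , k] <- (2 * pages[[k]] - 1) * rng
  } else stop("unsupported image format: ", path)
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  image_stack(px,
              flip_angle_deg = meta$flip_angle_deg,
              tr_ms = meta$tr_ms,
              te_ms = meta$te_ms,
              ti_ms = meta$ti_ms)
}

#' Write a parameter map and its ROI statistics
#'
#' @param map a [param_map()].
#' @param path image output path (`.nii`, `.nii.gz`).
#' @param roi optional [roi_mask()]; when given, a `<path>_stats.csv` with
#'   mean, sd and n over the masked map is written alongside.
#' @return `path`, invisibly.
#' @export
write_param_map <- function(map, path, roi = NULL) {
  stopifnot(inherits(map, "param_map"))
  vals <- map$values
  vals[!map$valid] <- NA_real_
  RNifti::writeNifti(RNifti::asNifti(vals), path)
  if (!is.null(roi)) {
    st <- masked_mean(map, roi)
    utils::write.csv(data.frame(label = roi$label, mean = st$mean,
                                sd = st$sd, n = st$n, units = map$units),
                     sub("\\.nii(\\.gz)?$", "_stats.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

# ---- pipeline orchestration --------------------------------------------

stage_schemas <- function() {
  common <- c("stage", "seed", "out_dir", "log_level")
  list(
    synth = c(common, "what", "grid_shape", "t1_ms", "t2star_ms",
              "perfusion", "proton_density", "noise_sd", "flip_angles_deg",
              "tr_ms", "te_start_ms", "te_step_ms", "n_echoes", "ti_ms",
              "lambda_ml_g", "model", "n_features", "n_per_group",
              "missing_rate", "spike_log2fc", "n_spiked"),
    mri = c(common, "what", "air", "o2", "selective", "global_inv",
            "reference", "roi", "tr_ms", "ti_ms", "lambda_ml_g", "k_sd",
            "frame_range"),
    tracer = c(common, "what", "mids", "fragments", "fragment",
               "glucose_metabolite", "lactate_metabolite"),
    omics = c(common, "matrix", "design", "shift_sd", "width_sd",
              "fc_thresh", "p_thresh", "annotate"))
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$stage)) stop("config must name a stage")
  schemas <- stage_schemas()
  if (!config$stage %in% names(schemas))
    stop("unknown stage: ", config$stage)
  unknown <- setdiff(names(config), schemas[[config$stage]])
  if (length(unknown))
    stop("unknown config key(s) for stage ", config$stage, ": ",
         paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("an explicit seed is required")
  if (is.null(config$out_dir)) stop("out_dir is required")
  config
}

log_msg <- function(level, stage, ...) {
  if (identical(level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run one pipeline stage from a validated configuration
#'
#' Executes a stage (`synth`, `mri`, `tracer` or `omics`) described by a
#' configuration list or YAML file, writes its outputs under
#' `config$out_dir`, and emits a JSON run report recording the package
#' version, seed, parameters, MD5 hashes of all inputs and a per-stage
#' summary. Identical configuration and inputs produce byte-identical
#' outputs. Unknown configuration keys are rejected before any
#' computation; log lines go to stderr, never to stdout.
#'
#' @param config named list or path to a YAML file. Required keys:
#'   `stage`, `seed`, `out_dir`; remaining keys are stage-specific (see
#'   the stage functions' arguments, with units in the key names, e.g.
#'   `tr_ms`, `ti_ms`).
#' @return the run report, invisibly (also written to
#'   `<out_dir>/run_report.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  level <- config$log_level %||% "info"
  t0 <- Sys.time()
  inputs <- character(0)
  summary <- switch(config$stage,
    synth = stage_synth(config, level),
    mri = { inputs <- unlist(config[c("air", "o2", "selective",
                                      "global_inv", "reference", "roi")])
            stage_mri(config, level) },
    tracer = { inputs <- unlist(config[c("mids", "fragments")])
               stage_tracer(config, level) },
    omics = { inputs <- unlist(config[c("matrix", "design")])
              stage_omics(config, level) })
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  report <- list(
    stage = config$stage,
    package_version = as.character(utils::packageVersion("hepatoxim")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("stage", "seed", "out_dir",
                                                 "log_level"))],
    input_md5 = as.list(tools::md5sum(inputs)),
    summary = summary,
    elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_msg(level, config$stage, "done in ", report$elapsed_s, " s")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_synth <- function(cfg, level) {
  what <- cfg$what %||% "vfa"
  gs <- cfg$grid_shape %||% c(32L, 32L)
  spec <- phantom_spec(gs, t1_field = cfg$t1_ms %||% 1000,
                       t2star_field = cfg$t2star_ms %||% 20,
                       perfusion_field = cfg$perfusion %||% 0,
                       proton_density = cfg$proton_density %||% 1000,
                       noise_sd = cfg$noise_sd %||% 0, seed = cfg$seed)
  od <- cfg$out_dir
  if (what == "vfa") {
    g <- gen_vfa_phantom(spec, cfg$flip_angles_deg %||% c(5, 20),
                         cfg$tr_ms %||% 10, cfg$model %||% "linearized")
    for (nm in names(g$stacks))
      write_image_stack(g$stacks[[nm]], file.path(od, paste0(nm, ".nii.gz")))
    jsonlite::write_json(list(t1_field = g$truth$t1_field),
                         file.path(od, "truth.json"), digits = NA)
    log_msg(level, "synth", "wrote VFA phantom (", paste(gs, collapse = "x"), ")")
    list(what = what, files = paste0(names(g$stacks), ".nii.gz"))
  } else if (what == "mge") {
    te <- (cfg$te_start_ms %||% 2.5) +
      (cfg$te_step_ms %||% 2.5) * (seq_len(cfg$n_echoes %||% 16L) - 1L)
    g <- gen_mge_phantom(spec, te)
    write_image_stack(g$stack, file.path(od, "mge.nii.gz"))
    jsonlite::write_json(list(t2star_field = g$truth$t2star_field),
                         file.path(od, "truth.json"), digits = NA)
    list(what = what, files = "mge.nii.gz")
  } else if (what == "fair") {
    g <- gen_fair_phantom(spec, cfg$ti_ms %||% 2000, cfg$lambda_ml_g %||% 0.9)
    for (nm in c("selective", "global_inv", "reference"))
      write_image_stack(g[[nm]], file.path(od, paste0(nm, ".nii.gz")))
    jsonlite::write_json(list(perfusion_field = g$truth$perfusion_field),
                         file.path(od, "truth.json"), digits = NA)
    list(what = what, files = c("selective.nii.gz", "global_inv.nii.gz",
                                "reference.nii.gz"))
  } else if (what == "omics") {
    nsp <- cfg$n_spiked %||% 0L
    spiked <- if (nsp > 0)
      stats::setNames(rep(cfg$spike_log2fc %||% 2, nsp),
                      paste0("feature_", seq_len(nsp)))
    else numeric(0)
    tr <- omics_truth(n_features = cfg$n_features %||% 2000L,
                      n_per_group = cfg$n_per_group %||% 6L,
                      spiked_features = spiked,
                      missing_rate = cfg$missing_rate %||% 0.1,
                      seed = cfg$seed)
    g <- gen_omics_dataset(tr)
    write_abundance_csv(g$table, file.path(od, "matrix.csv"))
    utils::write.csv(data.frame(sample = g$design$sample,
                                group = as.character(g$design$group)),
                     file.path(od, "design.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(g$truth$spiked_features),
                         file.path(od, "truth.json"), digits = NA)
    list(what = what, files = c("matrix.csv", "design.csv"))
  } else stop("unknown synth target: ", what)
}

stage_mri <- function(cfg, level) {
  what <- cfg$what %||% "t1"
  od <- cfg$out_dir
  prep <- function(path) {
    st <- read_image_stack(path)
    if (n_frames(st) > 1L)
      st <- average_frames(st, cfg$frame_range %||% c(55L, min(65L, n_frames(st))))
    st
  }
  roi <- if (!is.null(cfg$roi)) {
    r <- read_image_stack(cfg$roi)
    roi_mask(frame_matrix(r) > 0.5, "liver")
  }
  if (what == "t1") {
    air <- lapply(cfg$air, prep); o2 <- lapply(cfg$o2, prep)
    m_air <- fit_t1_vfa(air[[1]], air[[2]], cfg$tr_ms %||% 10)
    m_o2 <- fit_t1_vfa(o2[[1]], o2[[2]], cfg$tr_ms %||% 10)
    delta <- relative_delta_map(m_air, m_o2)
    roi2 <- if (!is.null(roi)) exclude_vessels(m_air, roi, cfg$k_sd %||% 2)
    write_param_map(m_air, file.path(od, "t1_air.nii.gz"), roi2)
    write_param_map(m_o2, file.path(od, "t1_o2.nii.gz"), roi2)
    write_param_map(delta, file.path(od, "delta_t1.nii.gz"), roi2)
    s <- if (!is.null(roi2)) masked_mean(delta, roi2)
         else list(mean = mean(delta$values[delta$valid]), n = sum(delta$valid))
    log_msg(level, "mri", sprintf("mean delta-T1 %.2f%% over %d px", s$mean, s$n))
    list(what = what, mean_delta_pct = s$mean, n = s$n)
  } else if (what == "t2star") {
    m <- fit_t2star_map(read_image_stack(cfg$air))
    write_param_map(m, file.path(od, "t2star.nii.gz"), roi)
    list(what = what, n_valid = sum(m$valid))
  } else if (what == "perfusion") {
    m <- fit_fair_perfusion(read_image_stack(cfg$selective),
                            read_image_stack(cfg$global_inv),
                            read_image_stack(cfg$reference),
                            cfg$ti_ms %||% 2000, cfg$lambda_ml_g %||% 0.9)
    write_param_map(m, file.path(od, "perfusion.nii.gz"), roi)
    list(what = what, n_valid = sum(m$valid))
  } else stop("unknown mri target: ", what)
}

stage_tracer <- function(cfg, level) {
  frags <- fragment_library(cfg$fragments)
  mids <- read_mid_csv(cfg$mids)
  what <- cfg$what %||% "correct"
  corrected <- lapply(seq_len(nrow(mids)), function(i) {
    met <- mids$metabolite[i]
    if (!met %in% names(frags)) stop("no fragment spec for metabolite: ", met)
    # wide files shared across metabolites may pad short MIDs with zeros
    size <- min(length(mids$mid[[i]]), frags[[met]]$n_labelable + 1L)
    mid <- check_mid(mids$mid[[i]][seq_len(size)])
    M <- build_correction_matrix(frags[[met]], size = size)
    correct_mid(mid, M)
  })
  size_max <- max(lengths(corrected))
  wide <- t(vapply(corrected, function(v) c(v, rep(NA, size_max - length(v))),
                   numeric(size_max)))
  colnames(wide) <- paste0("m", seq_len(size_max) - 1L)
  out_df <- cbind(mids[c("metabolite", "sample")], as.data.frame(wide))
  utils::write.csv(out_df, file.path(cfg$out_dir, "corrected_mids.csv"),
                   row.names = FALSE)
  summary <- list(what = what, n_rows = nrow(out_df))
  if (what == "gng") {
    glu <- cfg$glucose_metabolite %||% "glucose"
    lac <- cfg$lactate_metabolite %||% "lactate"
    samples <- intersect(mids$sample[mids$metabolite == glu],
                         mids$sample[mids$metabolite == lac])
    gng <- vapply(samples, function(s) {
      fractional_gng(corrected[[which(mids$metabolite == glu & mids$sample == s)]],
                     corrected[[which(mids$metabolite == lac & mids$sample == s)]][1:4])
    }, numeric(1))
    utils::write.csv(data.frame(sample = samples, fractional_gng = gng),
                     file.path(cfg$out_dir, "gng.csv"), row.names = FALSE)
    summary$mean_gng <- mean(gng)
  }
  summary
}

stage_omics <- function(cfg, level) {
  tab <- read_abundance_csv(cfg$matrix)
  design <- read_design_csv(cfg$design)
  ann <- if (isTRUE(cfg$annotate)) mito_annotations()
  diff <- diff_abundance(tab, design, seed = cfg$seed,
                         shift_sd = cfg$shift_sd %||% 2.5,
                         width_sd = cfg$width_sd %||% 0.3,
                         fc_thresh = cfg$fc_thresh %||% 1,
                         p_thresh = cfg$p_thresh %||% 0.05,
                         annotations = ann)
  utils::write.csv(diff, file.path(cfg$out_dir, "diff_table.csv"),
                   row.names = FALSE)
  imp <- impute_mnar(log2_normalize(tab), shift_sd = cfg$shift_sd %||% 2.5,
                     width_sd = cfg$width_sd %||% 0.3, seed = cfg$seed)
  z <- zscore_rows(imp)
  utils::write.csv(as.data.frame(z), file.path(cfg$out_dir, "zscores.csv"))
  cl <- cluster_rows(z)
  jsonlite::write_json(list(order = cl$order, height = cl$height),
                       file.path(cfg$out_dir, "clusters.json"), digits = NA)
  log_msg(level, "omics", sum(diff$call == "up"), " up, ",
          sum(diff$call == "down"), " down of ", nrow(diff))
  list(n_features = nrow(diff), n_up = sum(diff$call == "up"),
       n_down = sum(diff$call == "down"))
}

#' Write an abundance table to CSV
#'
#' Missing cells are written as `NA`; the first column holds feature ids.
#'
#' @param table an [abundance_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(feature_id = table$feature_ids,
                   as.data.frame(table$values), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
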
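#' Pipeline configuration
#'
#' All stage parameters of the detector, with defaults encoding the
#' canonical operating point: an 8-line SE bank in a 15 x 15 array (0.75 mm
#' at 0.05 mm/px), a four-level symlet-2 decomposition zeroing the
#' approximation and the finest detail triplet, segmentation by a fixed
#' threshold on the denoised scale, and the 10 mm overlapping-block rule
#' requiring at least four components. `block_px` is derived from the
#' physical `block_mm` and the pixel spacing (200 px at 0.05 mm/px);
#' `step_px` is `step_fraction * block_px`.
#'
#' @param se List: `footprint_px`, `n_orientations`, `border`.
#' @param wavelet List: `name`, `levels`, `mode`, `zero_approx`,
#'   `zero_finest_detail`.
#' @param segment List: `method` (`"fixed"`, `"otsu"`, `"quantile"`,
#'   `"sigma"`), `t`, `q`, `k`, `connectivity`, `min_size_px`.
#' @param cluster List: `block_mm`, `step_fraction`, `min_count`.
#' @param io List: `pixel_spacing_mm`.
#' @param seed Integer seed (used only by phantom-generating callers).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(se = list(), wavelet = list(), segment = list(),
                            cluster = list(), io = list(), seed = 1L) {
  defaults <- list(
    se = list(footprint_px = 15L, n_orientations = 8L, border = "reflect"),
    wavelet = list(name = "sym2", levels = 4L, mode = "symmetric",
                   zero_approx = TRUE, zero_finest_detail = TRUE),
    segment = list(method = "fixed", t = 0.14, q = 0.999, k = 4,
                   connectivity = 8L, min_size_px = 0L),
    cluster = list(block_mm = 10, step_fraction = 0.5, min_count = 4L),
    io = list(pixel_spacing_mm = 0.05))
  cfg <- defaults
  for (sec in names(defaults)) {
    user <- get(sec)
    bad <- setdiff(names(user), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown ", sec, " option(s): ", paste(bad, collapse = ", "))
    cfg[[sec]][names(user)] <- user
  }
  cfg$seed <- as.integer(seed)
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    if (se$footprint_px %% 2L == 0L) stop("se$footprint_px must be odd")
    if (!se$border %in% c("reflect", "replicate", "constant"))
      stop("unknown border policy: ", se$border)
    if (!segment$method %in% c("fixed", "otsu", "quantile", "sigma"))
      stop("unknown segmentation method: ", segment$method)
    if (cluster$step_fraction <= 0 || cluster$step_fraction > 1)
      stop("cluster$step_fraction must lie in (0, 1]")
    if (io$pixel_spacing_mm <= 0) stop("io$pixel_spacing_mm must be positive")
  })
  cfg
}

#' Effective block geometry of a configuration
#' @param config A [pipeline_config()].
#' @param pixel_spacing_mm Spacing override; default the config's own.
#' @return List with `block_px`, `step_px`, `block_mm`.
#' @export
block_geometry <- function(config, pixel_spacing_mm = NULL) {
  sp <- if (is.null(pixel_spacing_mm)) config$io$pixel_spacing_mm
        else pixel_spacing_mm
  block_px <- as.integer(round(config$cluster$block_mm / sp))
  list(block_px = block_px,
       step_px = max(1L, as.integer(round(block_px * config$cluster$step_fraction))),
       block_mm = block_px * sp)
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as YAML with one section per stage; every
#' omitted key takes its default, so a file containing only overrides is
#' valid.
#'
#' @param path Path to a `.yaml`/`.yml` file.
#' @return [read_config()] returns a `pipeline_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  pipeline_config(se = y[["se"]] %||% list(),
                  wavelet = y[["wavelet"]] %||% list(),
                  segment = y[["segment"]] %||% list(),
                  cluster = y[["cluster"]] %||% list(),
                  io = y[["io"]] %||% list(),
                  seed = y[["seed"]] %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full microcalcification-cluster detection pipeline
#'
#' Enhance (multi-SE top-hat), denoise (wavelet subband zeroing), segment
#' (threshold + connected components), and apply the overlapping-block
#' cluster rule, returning merged detections. Deterministic for a fixed
#' image and configuration.
#'
#' @param image A [gray_image] or numeric matrix in `[0, 1]`.
#' @param config A [pipeline_config()] (default configuration if omitted).
#' @param keep_stages If `TRUE`, intermediate stage outputs (`enhanced`,
#'   `denoised`, `mask`, `components`, `raw_detections`) are returned.
#' @param verbose If `TRUE`, log stage parameters and timings to stderr.
#' @return A list with `detections` (merged detection data frame) and, if
#'   requested, `stages`.
#' @export
run_pipeline <- function(image, config = pipeline_config(),
                         keep_stages = FALSE, verbose = FALSE) {
  image <- as_gray_image(image,
                         spacing = config$io$pixel_spacing_mm)
  say <- function(...) if (verbose) message(sprintf(...))
  sp <- image$pixel_spacing_mm
  ses <- generate_line_ses(config$se$footprint_px, config$se$n_orientations)
  say("enhance: %d line SEs, footprint %d px (%.2f mm), border %s",
      length(ses$elements), ses$footprint_px, ses$footprint_px * sp,
      config$se$border)
  enhanced <- multi_se_enhance(image, ses, border = config$se$border)
  say("denoise: %s, %d levels, mode %s, zero approx=%s finest=%s",
      config$wavelet$name, config$wavelet$levels, config$wavelet$mode,
      config$wavelet$zero_approx, config$wavelet$zero_finest_detail)
  sel <- subband_selector(
    zero_approx = config$wavelet$zero_approx,
    zero_detail_levels = if (config$wavelet$zero_finest_detail)
      config$wavelet$levels else integer(),
    n_levels = config$wavelet$levels)
  denoised <- denoise(enhanced, sel, wavelet_name = config$wavelet$name,
                      n_levels = config$wavelet$levels,
                      extension_mode = config$wavelet$mode)
  mask <- threshold_image(denoised, method = config$segment$method,
                          t = config$segment$t, q = config$segment$q,
                          k = config$segment$k)
  say("segment: method %s, threshold %.5g, %d foreground px",
      mask$method, mask$threshold, sum(mask$pixels))
  comps <- extract_components(mask, connectivity = config$segment$connectivity,
                              pixel_spacing_mm = sp,
                              min_size_px = config$segment$min_size_px)
  geom <- block_geometry(config, sp)
  grid <- make_grid(dim(image), geom$block_px, geom$step_px)
  say("cluster: %d components; blocks %d px (%.1f mm), step %d px, min count %d",
      nrow(comps$components), geom$block_px, geom$block_mm, geom$step_px,
      config$cluster$min_count)
  raw <- detect_clusters(comps, grid, min_count = config$cluster$min_count)
  det <- merge_detections(raw)
  say("detections: %d block hits -> %d merged clusters", nrow(raw), nrow(det))
  out <- list(detections = det)
  if (keep_stages)
    out$stages <- list(enhanced = enhanced, denoised = denoised, mask = mask,
                       components = comps, raw_detections = raw, grid = grid)
  out
}

#' Sweep the segmentation threshold over a phantom suite
#'
#' Computes the enhanced + denoised image once per suite image, then scores
#' the pipeline at each fixed threshold: a simple operating-curve (FROC-style)
#' helper for choosing the segmentation threshold.
#'
#' @param suite A list from [default_benchmark_suite()].
#' @param thresholds Numeric vector of fixed thresholds to evaluate.
#' @param config A [pipeline_config()]; its segmentation method is ignored
#'   (each sweep point uses `fixed(t)`).
#' @return A data frame with one row per threshold: `threshold`,
#'   `tpr_percent`, `fp_per_image`, `n_true_clusters`.
#' @export
threshold_sweep <- function(suite, thresholds, config = pipeline_config()) {
  ses <- generate_line_ses(config$se$footprint_px, config$se$n_orientations)
  sel <- subband_selector(
    zero_approx = config$wavelet$zero_approx,
    zero_detail_levels = if (config$wavelet$zero_finest_detail)
      config$wavelet$levels else integer(),
    n_levels = config$wavelet$levels)
  dens <- lapply(suite, function(s)
    denoise(multi_se_enhance(s$image, ses, border = config$se$border), sel,
            wavelet_name = config$wavelet$name,
            n_levels = config$wavelet$levels,
            extension_mode = config$wavelet$mode))
  truths <- lapply(suite, function(s) s$truth$cluster_boxes_px)
  rows <- lapply(thresholds, function(t) {
    dets <- lapply(dens, function(d) {
      sp <- d$pixel_spacing_mm
      comps <- extract_components(threshold_image(d, "fixed", t = t),
                                  connectivity = config$segment$connectivity,
                                  pixel_spacing_mm = sp,
                                  min_size_px = config$segment$min_size_px)
      geom <- block_geometry(config, sp)
      grid <- make_grid(dim(d), geom$block_px, geom$step_px)
      merge_detections(detect_clusters(comps, grid, config$cluster$min_count))
    })
    e <- match_and_score(dets, truths)
    data.frame(threshold = t, tpr_percent = e$tpr_percent,
               fp_per_image = e$fp_per_image,
               n_true_clusters = e$n_true_clusters)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the pipeline over a phantom suite and score it
#'
#' @param suite A list from [default_benchmark_suite()].
#' @param config A [pipeline_config()].
#' @param match_rule Passed to [match_and_score()].
#' @return List with `eval` (an `mc_eval`) and `detections_per_image`.
#' @export
evaluate_pipeline <- function(suite, config = pipeline_config(),
                              match_rule = "center_in_box") {
  dets <- lapply(suite, function(s)
    run_pipeline(s$image, config)$detections)
  truths <- lapply(suite, function(s) s$truth$cluster_boxes_px)
  list(eval = match_and_score(dets, truths, match_rule = match_rule),
       detections_per_image = dets)
}
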
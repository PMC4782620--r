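#' Grayscale image with physical pixel spacing
#'
#' The pipeline's working container: a numeric matrix of intensities indexed
#' `[row, col]` (origin top-left, 0-based coordinates in all reported tables),
#' together with the physical size of a pixel side in millimetres. Images read
#' from disk are normalized to `[0, 1]`; intermediate stage outputs (e.g. the
#' wavelet-denoised image) may be signed and are not clipped.
#'
#' @param pixels Numeric matrix of finite intensities.
#' @param pixel_spacing_mm Positive scalar, millimetres per pixel side.
#'   Default 0.05, the spacing of full-resolution digitized mammograms.
#' @return An object of class `gray_image`: a list with elements `pixels`,
#'   `height_px`, `width_px`, `pixel_spacing_mm`.
#' @export
gray_image <- function(pixels, pixel_spacing_mm = 0.05) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite")
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("`pixel_spacing_mm` must be a positive scalar")
  structure(
    list(pixels = pixels,
         height_px = nrow(pixels),
         width_px = ncol(pixels),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm)),
    class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g mm/px (%.1f x %.1f mm), range [%.4g, %.4g]\n",
              x$height_px, x$width_px, x$pixel_spacing_mm,
              x$height_px * x$pixel_spacing_mm, x$width_px * x$pixel_spacing_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_gray_image <- function(x, spacing = 0.05) {
  if (inherits(x, "gray_image")) x else gray_image(x, spacing)
}

#' Read a grayscale image from disk
#'
#' Reads an 8- or 16-bit single-channel TIFF or PNG and normalizes intensities
#' to `[0, 1]` by dividing by the integer type maximum (the underlying readers
#' perform this division, so the mapping is monotone and exact). Multi-channel
#' images are rejected.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param spacing_override Optional positive scalar overriding the default
#'   pixel spacing of 0.05 mm/px.
#' @return A [gray_image].
#' @export
read_image <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    dcm = , dicom = stop("DICOM input is not supported by this build; ",
                         "convert to 16-bit TIFF or PNG"),
    stop("unsupported image format: .", ext, " (expected TIFF or PNG)"))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    else stop("expected a single-channel image, got ", dim(px)[3], " channels")
  }
  spacing <- if (is.null(spacing_override)) 0.05 else spacing_override
  gray_image(px, spacing)
}

#' Write a grayscale image to disk
#'
#' Intensities are clipped to `[0, 1]` and written as 16-bit TIFF or PNG
#' (by file extension).
#'
#' @param image A [gray_image] or numeric matrix.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_image <- function(image, path) {
  image <- as_gray_image(image)
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stop("unsupported output format: .", ext))
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask A `binary_mask` (see [threshold_image]) or logical matrix.
#' @param path Output `.png` path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  png::writePNG(ifelse(m, 1, 0), path)
  invisible(path)
}

det_cols <- c("block_row", "block_col", "r0", "r1", "c0", "c1",
              "y0_mm", "y1_mm", "x0_mm", "x1_mm",
              "component_count", "member_labels")

#' Write cluster detections to CSV or JSON
#'
#' One record per detection: block indices, half-open pixel bounding box
#' `[r0, r1) x [c0, c1)`, the same box in millimetres, the number of member
#' components and their labels (`;`-joined in CSV). The written file
#' round-trips losslessly through [read_detections()].
#'
#' @param detections A detection data frame as returned by [detect_clusters()]
#'   or [merge_detections()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @export
write_detections <- function(detections, path,
                             format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  d <- as.data.frame(detections)[, det_cols, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    jsonlite::write_json(d, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read cluster detections written by [write_detections()]
#' @param path Path to a `.csv` or `.json` detection file.
#' @return A detection data frame.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("cannot read detections: no such file: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    d <- jsonlite::fromJSON(path)
    if (length(d) == 0L || is.null(dim(d)))
      d <- utils::read.csv(text = paste(det_cols, collapse = ","))
  } else {
    d <- utils::read.csv(path, colClasses = c(member_labels = "character"))
  }
  d <- as.data.frame(d)[, det_cols, drop = FALSE]
  num <- setdiff(det_cols, "member_labels")
  d[num] <- lapply(d[num], as.numeric)
  ints <- c("block_row", "block_col", "r0", "r1", "c0", "c1", "component_count")
  d[ints] <- lapply(d[ints], as.integer)
  d$member_labels <- as.character(d$member_labels)
  d
}

empty_detections <- function() {
  d <- data.frame(block_row = integer(), block_col = integer(),
                  r0 = integer(), r1 = integer(),
                  c0 = integer(), c1 = integer(),
                  y0_mm = numeric(), y1_mm = numeric(),
                  x0_mm = numeric(), x1_mm = numeric(),
                  component_count = integer(),
                  member_labels = character(),
                  stringsAsFactors = FALSE)
  d
}
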
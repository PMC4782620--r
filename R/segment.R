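#' Threshold an image into a binary mask
#'
#' Foreground is `pixel > threshold`. Methods:
#' \describe{
#'   \item{`fixed`}{a fixed threshold `t` on the working intensity scale.}
#'   \item{`otsu`}{Otsu's between-class-variance criterion over 256 bins
#'     (via `EBImage::otsu`); a constant image yields an empty mask with a
#'     warning, since no foreground is distinguishable.}
#'   \item{`quantile`}{the empirical `q`-quantile of all pixels, so a fixed
#'     fraction `1 - q` of pixels is marked foreground.}
#'   \item{`sigma`}{`mean + k * sd` of all pixels: an outlier rule that
#'     adapts to the residual-noise level of the denoised image.}
#' }
#'
#' @param image A [gray_image] or numeric matrix.
#' @param method One of `"fixed"`, `"otsu"`, `"quantile"`, `"sigma"`.
#' @param t Threshold value for `fixed` (default 0.14).
#' @param q Quantile for `quantile` (default 0.999), in (0, 1).
#' @param k Multiplier for `sigma` (default 4).
#' @return An object of class `binary_mask`: list with logical matrix
#'   `pixels`, the `threshold` used, and the `method` name.
#' @export
threshold_image <- function(image, method = c("fixed", "otsu", "quantile", "sigma"),
                            t = 0.14, q = 0.999, k = 4) {
  method <- match.arg(method)
  image <- as_gray_image(image)
  px <- image$pixels
  thr <- switch(method,
    fixed = {
      if (!is.finite(t)) stop("`t` must be finite")
      t
    },
    otsu = {
      if (max(px) - min(px) < .Machine$double.eps * 4) {
        warning("constant image: Otsu threshold undefined, returning empty mask")
        Inf
      } else {
        # otsu expects intensities in `range`; work on the image's own range
        rg <- range(px)
        EBImage::otsu(EBImage::Image(t(px)), range = rg, levels = 256L)
      }
    },
    quantile = {
      if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)")
      stats::quantile(px, q, names = FALSE)
    },
    sigma = mean(px) + k * stats::sd(px))
  structure(list(pixels = px > thr, threshold = as.numeric(thr),
                 method = method),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px (method %s, threshold %.5g)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$method,
              x$threshold))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' Maximal connected foreground regions under 4- or 8-connectivity, labeled
#' deterministically in raster-scan order (row-major) of each component's
#' first pixel. Centroids and bounding boxes are reported in 0-based
#' `(row, col)` pixel coordinates with half-open boxes, plus physical
#' centroids in millimetres.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param pixel_spacing_mm Millimetres per pixel (default 0.05).
#' @param min_size_px Drop components smaller than this many pixels
#'   (default 0 = keep all); survivors are relabeled contiguously.
#' @return An object of class `component_set`: list with `components` (a
#'   data frame: `label`, `pixel_count`, `centroid_r`, `centroid_c`,
#'   `r0`, `r1`, `c0`, `c1`, `centroid_y_mm`, `centroid_x_mm`), `labels`
#'   (integer matrix, 0 = background), `source_shape`, `connectivity`,
#'   `pixel_spacing_mm`.
#' @export
extract_components <- function(mask, connectivity = 8L,
                               pixel_spacing_mm = 0.05, min_size_px = 0L) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  if (!is.matrix(m)) stop("`mask` must be a matrix")
  if (!is.logical(m)) m <- m > 0
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  n <- nrow(m); w <- ncol(m)
  fg <- which(m)                    # column-major linear indices
  labmat <- matrix(0L, n, w)
  comp_df <- data.frame(label = integer(), pixel_count = integer(),
                        centroid_r = numeric(), centroid_c = numeric(),
                        r0 = integer(), r1 = integer(),
                        c0 = integer(), c1 = integer(),
                        centroid_y_mm = numeric(), centroid_x_mm = numeric())
  if (length(fg)) {
    r <- (fg - 1L) %% n
    c_ <- (fg - 1L) %/% n           # 0-based coords
    pos <- integer(n * w); pos[fg] <- seq_along(fg)
    offs <- list(c(1L, 0L), c(0L, 1L))                 # down, right
    if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
    efrom <- integer(0); eto <- integer(0)
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c_ + o[2]
      ok <- r2 >= 0L & r2 < n & c2 >= 0L & c2 < w
      nb <- pos[c2[ok] * n + r2[ok] + 1L]
      sel <- nb > 0L
      efrom <- c(efrom, which(ok)[sel])
      eto <- c(eto, nb[sel])
    }
    g <- igraph::make_graph(c(rbind(efrom, eto)), n = length(fg),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
    # relabel by raster (row-major) order of each component's first pixel
    raster <- r * w + c_
    first_px <- tapply(raster, memb, min)
    relab <- integer(length(first_px))
    relab[order(first_px)] <- seq_along(first_px)
    lab <- relab[memb]
    if (min_size_px > 0L) {
      sizes <- tabulate(lab)
      keep <- which(sizes >= min_size_px)
      if (length(keep) < length(sizes)) {
        sel <- lab %in% keep
        fg <- fg[sel]; r <- r[sel]; c_ <- c_[sel]; lab <- lab[sel]
        if (length(keep)) {
          relab2 <- integer(max(keep)); relab2[sort(keep)] <- seq_along(keep)
          lab <- relab2[lab]
        }
      }
    }
    if (length(fg)) {
      labmat[fg] <- lab
      comp_df <- data.frame(
        label = sort(unique(lab)),
        pixel_count = as.integer(tabulate(lab)),
        centroid_r = as.numeric(tapply(r, lab, mean)),
        centroid_c = as.numeric(tapply(c_, lab, mean)),
        r0 = as.integer(tapply(r, lab, min)),
        r1 = as.integer(tapply(r, lab, max)) + 1L,
        c0 = as.integer(tapply(c_, lab, min)),
        c1 = as.integer(tapply(c_, lab, max)) + 1L)
      comp_df$centroid_y_mm <- comp_df$centroid_r * pixel_spacing_mm
      comp_df$centroid_x_mm <- comp_df$centroid_c * pixel_spacing_mm
      rownames(comp_df) <- NULL
    }
  }
  structure(list(components = comp_df, labels = labmat,
                 source_shape = c(n, w), connectivity = as.integer(connectivity),
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, %d x %d image, %d-connectivity\n",
              nrow(x$components), x$source_shape[1], x$source_shape[2],
              x$connectivity))
  invisible(x)
}
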
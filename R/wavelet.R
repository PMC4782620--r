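#' @name wavelet
#' @title Multilevel 2-D discrete wavelet transform
#' @description
#' A separable multilevel 2-D DWT with orthogonal filters, used by the
#' denoising stage. The default wavelet is symlet-2 (the least-asymmetric
#' orthogonal wavelet with two vanishing moments). Signal extension is
#' half-point symmetric by default; decomposition keeps the slightly
#' redundant `floor((n + filter_len - 1)/2)` coefficients per axis so that
#' the inverse, cropped to the recorded input shape at each level, is exact
#' to machine precision for every extension mode.
NULL

wav_filters <- function(name = "sym2") {
  s3 <- sqrt(3)
  dec_lo <- switch(name,
    sym2 = , db2 = c(1 - s3, 3 - s3, 3 + s3, 1 + s3) / (4 * sqrt(2)),
    haar = , db1 = c(1, 1) / sqrt(2),
    stop("unknown wavelet: ", name, " (supported: sym2/db2, haar/db1)"))
  n <- length(dec_lo)
  # quadrature mirror: dec_hi[k] = (-1)^k dec_lo[n+1-k]; rec_* = rev(dec_*)
  dec_hi <- rev(dec_lo) * (-1)^seq_len(n)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), flen = n)
}

# extension indices for positions (1-p)..(n+p), with repeated reflection
ext_idx <- function(n, p, mode) {
  i <- c(seq.int(1L - p, 0L), seq_len(n), seq.int(n + 1L, n + p))
  switch(mode,
    symmetric = {            # half-point: ... x2 x1 | x1 x2 ... xn | xn ...
      j <- (i - 1L) %% (2L * n)
      ifelse(j < n, j + 1L, 2L * n - j)
    },
    reflect = {              # whole-point: ... x3 x2 | x1 x2 ... | x(n-1) ...
      if (n == 1L) rep(1L, length(i))
      else {
        j <- (i - 1L) %% (2L * n - 2L)
        ifelse(j < n, j + 1L, 2L * n - 1L - j)
      }
    },
    periodic = (i - 1L) %% n + 1L,
    stop("unknown extension mode: ", mode))
}

extend_rows <- function(m, p, mode) {
  if (mode == "zero") {
    z <- matrix(0, p, ncol(m))
    return(rbind(z, m, z))
  }
  m[ext_idx(nrow(m), p, mode), , drop = FALSE]
}

# single-level DWT along rows (each column transformed); returns list(a, d)
dwt_step <- function(m, f, mode) {
  p <- f$flen - 1L
  xe <- extend_rows(m, p, mode)
  n <- nrow(m)
  L <- (n + f$flen - 1L) %/% 2L
  starts <- 2L * seq_len(L)
  a <- matrix(0, L, ncol(m)); d <- matrix(0, L, ncol(m))
  rlo <- rev(f$dec_lo); rhi <- rev(f$dec_hi)
  for (k in seq_len(f$flen)) {
    rows <- starts + k - 1L
    a <- a + rlo[k] * xe[rows, , drop = FALSE]
    d <- d + rhi[k] * xe[rows, , drop = FALSE]
  }
  list(a = a, d = d)
}

# inverse of dwt_step, cropped to n_orig rows
idwt_step <- function(a, d, f, n_orig) {
  L <- nrow(a)
  if (!identical(dim(a), dim(d)))
    stop("approximation and detail blocks must share a shape")
  pz <- f$flen - 1L                       # leading zeros before the upsample
  u_a <- matrix(0, 2L * L + pz, ncol(a))
  u_d <- u_a
  u_a[pz + 2L * seq_len(L) - 1L, ] <- a
  u_d[pz + 2L * seq_len(L) - 1L, ] <- d
  out_len <- 2L * L - f$flen + 2L
  if (n_orig > out_len)
    stop("inconsistent pyramid: cannot reconstruct ", n_orig,
         " rows from ", L, " coefficients")
  r <- seq_len(out_len)
  y <- matrix(0, out_len, ncol(a))
  for (k in seq_len(f$flen)) {
    rows <- r + 2L * f$flen - 2L - k      # full conv, first flen-2 dropped
    y <- y + f$rec_lo[k] * u_a[rows, , drop = FALSE] +
         f$rec_hi[k] * u_d[rows, , drop = FALSE]
  }
  y[seq_len(n_orig), , drop = FALSE]
}

dwt2_step <- function(m, f, mode) {
  cols <- dwt_step(m, f, mode)                       # along rows of each column
  lo <- dwt_step(t(cols$a), f, mode)                 # then along the other axis
  hi <- dwt_step(t(cols$d), f, mode)
  list(a = t(lo$a),   # LL
       h = t(hi$a),   # rows high-pass, cols low-pass: horizontal-edge detail
       v = t(lo$d),   # vertical-edge detail
       d = t(hi$d))   # diagonal detail
}

idwt2_step <- function(a, h, v, d, f, shape) {
  lo <- t(idwt_step(t(a), t(v), f, shape[2]))
  hi <- t(idwt_step(t(h), t(d), f, shape[2]))
  idwt_step(lo, hi, f, shape[1])
}

#' Decompose an image into a multilevel wavelet pyramid
#'
#' Standard separable multilevel 2-D DWT. Detail triplets are stored
#' coarsest-to-finest: `details[[1]]` is the coarsest triplet (same scale as
#' the retained approximation), `details[[n_levels]]` the finest
#' (half-resolution) one. Shapes are recorded per level so [reconstruct()]
#' inverts exactly for odd as well as even sides.
#'
#' @param image A [gray_image] or numeric matrix.
#' @param wavelet_name `"sym2"` (default) or `"haar"`.
#' @param n_levels Number of decomposition levels (default 4).
#' @param extension_mode `"symmetric"` (default), `"reflect"`, `"periodic"`
#'   or `"zero"`.
#' @return An object of class `wavelet_pyramid`: list with `approx`,
#'   `details` (list of `list(h, v, d)` triplets, coarsest first),
#'   `wavelet_name`, `n_levels`, `extension_mode`, `shapes`,
#'   `original_shape`, `pixel_spacing_mm`.
#' @export
decompose <- function(image, wavelet_name = "sym2", n_levels = 4L,
                      extension_mode = "symmetric") {
  image <- as_gray_image(image)
  if (n_levels < 1L) stop("`n_levels` must be >= 1")
  min_side <- 2L^n_levels
  if (min(dim(image)) < min_side)
    stop("image sides must be >= ", min_side, " for ", n_levels,
         " decomposition levels")
  f <- wav_filters(wavelet_name)
  a <- image$pixels
  details <- vector("list", n_levels)
  shapes <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    shapes[[n_levels - j + 1L]] <- dim(a)
    s <- dwt2_step(a, f, extension_mode)
    details[[n_levels - j + 1L]] <- list(h = s$h, v = s$v, d = s$d)
    a <- s$a
  }
  structure(
    list(approx = a, details = details, wavelet_name = wavelet_name,
         n_levels = as.integer(n_levels), extension_mode = extension_mode,
         shapes = shapes, original_shape = dim(image$pixels),
         pixel_spacing_mm = image$pixel_spacing_mm),
    class = "wavelet_pyramid")
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf("<wavelet_pyramid> %s, %d levels, mode %s, image %d x %d\n",
              x$wavelet_name, x$n_levels, x$extension_mode,
              x$original_shape[1], x$original_shape[2]))
  cat(sprintf("  approx %d x %d; finest detail %d x %d\n",
              nrow(x$approx), ncol(x$approx),
              nrow(x$details[[x$n_levels]]$h), ncol(x$details[[x$n_levels]]$h)))
  invisible(x)
}

#' Subband selector
#'
#' Chooses which subbands [zero_subbands()] replaces with zeros. Detail
#' levels use the pyramid's coarsest-to-finest numbering: level 1 is the
#' coarsest detail triplet, level `n_levels` the finest. The default —
#' zero the retained approximation and the finest detail triplet — keeps a
#' zero-mean mid-band: it removes the smooth background carried by the
#' approximation and the finest-scale structure (pixel noise and 1-2 px wide
#' gland/vessel ridges) while preserving the compact blobs, a few pixels
#' across, that microcalcifications produce after top-hat enhancement.
#'
#' @param zero_approx Zero the coarsest approximation (default `TRUE`).
#' @param zero_detail_levels Integer vector of detail levels to zero,
#'   coarsest-to-finest numbering; `NULL` (default) means the finest level
#'   only once attached to a pyramid.
#' @param n_levels Pyramid depth the selector is meant for (default 4).
#' @return An object of class `subband_selector`.
#' @export
subband_selector <- function(zero_approx = TRUE, zero_detail_levels = NULL,
                             n_levels = 4L) {
  if (is.null(zero_detail_levels)) zero_detail_levels <- as.integer(n_levels)
  zero_detail_levels <- as.integer(zero_detail_levels)
  if (length(zero_detail_levels) &&
      (any(zero_detail_levels < 1L) || any(zero_detail_levels > n_levels)))
    stop("detail levels must lie in [1, ", n_levels, "]")
  structure(list(zero_approx = isTRUE(zero_approx),
                 zero_detail_levels = sort(unique(zero_detail_levels)),
                 n_levels = as.integer(n_levels)),
            class = "subband_selector")
}

empty_selector <- function(n_levels = 4L)
  subband_selector(FALSE, integer(), n_levels)

#' Zero selected subbands of a pyramid
#'
#' Returns a new pyramid in which every selected array is replaced by zeros;
#' unselected arrays are untouched and the input pyramid is not modified.
#'
#' @param pyr A `wavelet_pyramid`.
#' @param sel A [subband_selector].
#' @return A `wavelet_pyramid`.
#' @export
zero_subbands <- function(pyr, sel) {
  stopifnot(inherits(pyr, "wavelet_pyramid"), inherits(sel, "subband_selector"))
  if (length(sel$zero_detail_levels) &&
      max(sel$zero_detail_levels) > pyr$n_levels)
    stop("selector refers to detail level ", max(sel$zero_detail_levels),
         " but the pyramid has ", pyr$n_levels, " levels")
  out <- pyr
  if (sel$zero_approx) out$approx <- array(0, dim(pyr$approx))
  for (lvl in sel$zero_detail_levels) {
    out$details[[lvl]] <- lapply(pyr$details[[lvl]],
                                 function(b) array(0, dim(b)))
  }
  out
}

#' Reconstruct an image from a wavelet pyramid
#'
#' Inverse multilevel transform, cropped at every level to the shape recorded
#' during decomposition, so `reconstruct(decompose(f))` returns `f` exactly
#' (to machine precision). The output is signed: no clipping is applied, so
#' thresholds downstream act on the true reconstruction values.
#'
#' @param pyr A `wavelet_pyramid`.
#' @return A [gray_image] (possibly with negative pixels).
#' @export
reconstruct <- function(pyr) {
  stopifnot(inherits(pyr, "wavelet_pyramid"))
  f <- wav_filters(pyr$wavelet_name)
  a <- pyr$approx
  for (lvl in seq_len(pyr$n_levels)) {
    d <- pyr$details[[lvl]]
    if (!identical(dim(d$h), dim(d$v)) || !identical(dim(d$h), dim(d$d)))
      stop("inconsistent pyramid: detail triplet at level ", lvl,
           " has mismatched shapes")
    a <- idwt2_step(a, d$h, d$v, d$d, f, pyr$shapes[[lvl]])
  }
  gray_image(a, pyr$pixel_spacing_mm)
}

#' Wavelet subband-zeroing denoiser
#'
#' Decompose, zero the selected subbands, reconstruct. With the default
#' selector this suppresses finest-scale curvilinear structures (mammary
#' glands, vessels) far more than the compact few-pixel blobs produced by
#' microcalcifications, which is the separation the segmentation threshold
#' relies on.
#'
#' @inheritParams decompose
#' @param sel A [subband_selector]; default zeroes the approximation and the
#'   finest detail triplet.
#' @return A [gray_image] (signed; not clipped).
#' @export
denoise <- function(image, sel = NULL, wavelet_name = "sym2", n_levels = 4L,
                    extension_mode = "symmetric") {
  if (is.null(sel)) sel <- subband_selector(n_levels = n_levels)
  pyr <- decompose(image, wavelet_name, n_levels, extension_mode)
  reconstruct(zero_subbands(pyr, sel))
}
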
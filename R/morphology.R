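#' Bank of rotated line structuring elements
#'
#' Builds the flat line structuring elements (SEs) used by the multi-SE
#' top-hat enhancement: digital line segments of length `footprint_px`
#' revolving around their common centre inside a `footprint_px` x
#' `footprint_px` array, at angles `k * 180 / n_orientations` degrees for
#' `k = 0 .. n_orientations - 1`. Each line is rasterized by stepping along
#' its dominant axis and mirroring every pixel through the anchor, so all
#' SEs are point-symmetric and contain the centre pixel. At the default
#' spacing of 0.05 mm/px the default 15 px footprint spans 0.75 mm: any
#' bright structure larger than 0.75 x 0.75 mm is removed by the opening
#' with at least one SE and therefore suppressed in the enhancement.
#'
#' @param footprint_px Odd positive integer, side of the square array
#'   (default 15).
#' @param n_orientations Number of line orientations (default 8).
#' @return An object of class `se_bank`: list with `elements` (each a
#'   `struct_elem` with fields `mask`, `anchor`, `orientation_deg`,
#'   `offsets`) and `footprint_px`.
#' @export
generate_line_ses <- function(footprint_px = 15L, n_orientations = 8L) {
  if (footprint_px < 1L || footprint_px %% 2L == 0L)
    stop("`footprint_px` must be an odd positive integer")
  if (n_orientations < 1L)
    stop("`n_orientations` must be a positive integer")
  half <- (footprint_px - 1L) %/% 2L
  angles <- (seq_len(n_orientations) - 1L) * 180 / n_orientations
  elems <- lapply(angles, function(a) make_line_se(footprint_px, half, a))
  keys <- vapply(elems, function(e) paste(which(e$mask), collapse = ","), "")
  if (anyDuplicated(keys)) {
    if (footprint_px == 1L) {
      elems <- elems[!duplicated(keys)]
    } else {
      stop("n_orientations = ", n_orientations, " yields duplicate line SEs ",
           "at footprint ", footprint_px, "; reduce the orientation count")
    }
  }
  structure(list(elements = elems, footprint_px = as.integer(footprint_px)),
            class = "se_bank")
}

make_line_se <- function(footprint, half, angle_deg) {
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  if (half > 0L) {
    if (abs(co) >= abs(si)) {
      dc <- seq_len(half)
      dr <- round(dc * si / co)
    } else {
      dr <- seq_len(half)
      dc <- round(dr * co / si)
    }
    offs <- cbind(c(0L, dr, -dr), c(0L, dc, -dc))
  } else {
    offs <- cbind(0L, 0L)
  }
  storage.mode(offs) <- "integer"
  colnames(offs) <- c("dr", "dc")
  mask <- matrix(FALSE, footprint, footprint)
  mask[cbind(offs[, 1] + half + 1L, offs[, 2] + half + 1L)] <- TRUE
  structure(list(mask = mask, anchor = c(half, half),
                 orientation_deg = angle_deg %% 180, offsets = offs),
            class = "struct_elem")
}

#' @export
print.se_bank <- function(x, ...) {
  cat(sprintf("<se_bank> %d line SEs in a %d x %d array\n",
              length(x$elements), x$footprint_px, x$footprint_px))
  invisible(x)
}

#' Dump a structuring-element bank to a JSON description
#'
#' Writes footprint, orientations and the set-pixel offsets of every SE, for
#' inspection or use outside R.
#'
#' @param bank An `se_bank`.
#' @param path Output `.json` path.
#' @export
dump_se_bank <- function(bank, path) {
  desc <- list(
    footprint_px = bank$footprint_px,
    n_elements = length(bank$elements),
    elements = lapply(bank$elements, function(e)
      list(orientation_deg = e$orientation_deg,
           offsets = apply(e$offsets, 1, function(o) c(dr = o[1], dc = o[2]),
                           simplify = FALSE))))
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pad_matrix <- function(m, p, border = "reflect", constant_value = 0) {
  if (p == 0L) return(m)
  n <- nrow(m); w <- ncol(m)
  if (border == "constant") {
    out <- matrix(constant_value, n + 2L * p, w + 2L * p)
    out[p + seq_len(n), p + seq_len(w)] <- m
    return(out)
  }
  mode <- switch(border,
    reflect = "symmetric",          # mirror with edge duplication, rebounding
    replicate = NA_character_,
    stop("unknown border policy: ", border))
  side <- function(len) {
    if (border == "replicate")
      c(rep(1L, p), seq_len(len), rep(len, p))
    else
      ext_idx(len, p, mode)
  }
  m[side(n), side(w), drop = FALSE]
}

#' Grayscale opening by a flat structuring element
#'
#' Erosion followed by dilation with the same SE. Flat (binary) SEs only; the
#' image is padded by the chosen border policy so the result is exact up to
#' the boundary.
#'
#' @param image A [gray_image] or numeric matrix.
#' @param se A `struct_elem` from [generate_line_ses()].
#' @param border Border policy: `"reflect"` (default), `"replicate"` or
#'   `"constant"`.
#' @param constant_value Pad value when `border = "constant"`.
#' @return A [gray_image] of the same shape and spacing.
#' @export
grayscale_opening <- function(image, se, border = "reflect", constant_value = 0) {
  image <- as_gray_image(image)
  px <- opening_matrix(image$pixels, se, border, constant_value)
  gray_image(px, image$pixel_spacing_mm)
}

# flat erosion/dilation on the valid region of a padded matrix: each output
# pixel is the min/max of the input over the SE offsets
shift_reduce <- function(M, offs, p, op) {
  n <- nrow(M) - 2L * p; w <- ncol(M) - 2L * p
  out <- NULL
  for (k in seq_len(nrow(offs))) {
    s <- M[p + offs[k, 1] + seq_len(n), p + offs[k, 2] + seq_len(w),
           drop = FALSE]
    out <- if (is.null(out)) s else op(out, s)
  }
  out
}

opening_matrix <- function(m, se, border, constant_value = 0) {
  p <- (nrow(se$mask) - 1L) %/% 2L
  if (p == 0L) return(m)
  # pad 2p: the opening at a pixel depends on input up to 2p away
  mp <- pad_matrix(m, 2L * p, border, constant_value)
  er <- shift_reduce(mp, se$offsets, p, pmin)
  shift_reduce(er, se$offsets, p, pmax)
}

#' Top-hat transform
#'
#' The image minus its grayscale opening: isolates bright structures that
#' cannot contain the SE. Always nonnegative (opening is anti-extensive).
#'
#' @inheritParams grayscale_opening
#' @return A [gray_image] with `pixels = image - opening(image)`.
#' @export
tophat <- function(image, se, border = "reflect", constant_value = 0) {
  image <- as_gray_image(image)
  t <- image$pixels - opening_matrix(image$pixels, se, border, constant_value)
  gray_image(pmax(t, 0), image$pixel_spacing_mm)
}

#' Multi-structuring-element top-hat enhancement
#'
#' Computes `E = f - max_i (f opened by b_i)` over the SE bank: the pixelwise
#' maximum of the openings keeps any bright structure that fits at least one
#' line SE, so the residual `E` enhances exactly the compact bright spots
#' (candidate microcalcifications) that no line of the bank fits, whatever
#' their orientation. Equivalently `E` is the pixelwise minimum of the eight
#' single-SE top-hats.
#'
#' @param image A [gray_image] or numeric matrix.
#' @param ses An `se_bank` from [generate_line_ses()].
#' @param border Border policy passed to the openings.
#' @param constant_value Pad value when `border = "constant"`.
#' @return A [gray_image]; nonnegative everywhere.
#' @export
multi_se_enhance <- function(image, ses, border = "reflect", constant_value = 0) {
  if (!inherits(ses, "se_bank") || length(ses$elements) == 0L)
    stop("`ses` must be a non-empty se_bank")
  image <- as_gray_image(image)
  m <- image$pixels
  mx <- NULL
  for (se in ses$elements) {
    op <- opening_matrix(m, se, border, constant_value)
    mx <- if (is.null(mx)) op else pmax(mx, op)
  }
  gray_image(pmax(m - mx, 0), image$pixel_spacing_mm)
}
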
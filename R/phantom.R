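#' Synthetic mammogram phantom specification
#'
#' Describes a phantom image: a smooth low-contrast background, optional
#' clusters of small bright quasi-Gaussian spots (the microcalcification
#' model), optional curvilinear bright ridges with nonhomogeneous intensity
#' (the gland/vessel confounder model) and additive Gaussian noise, all on
#' the `[0, 1]` working intensity scale. Rendering is fully determined by
#' `seed`; each structural layer (background, spots, lines, noise) draws
#' from its own RNG stream derived from the master seed, so one layer can be
#' changed without perturbing the others.
#'
#' @param image_px Integer `(height, width)`, default `c(1024, 1024)`.
#' @param pixel_spacing_mm Millimetres per pixel, default 0.05.
#' @param background List: `base` level, low-frequency `amplitude`, and
#'   `scale_px` (correlation length of the smooth field).
#' @param clusters List of [cluster_spec()] objects.
#' @param lines List of [line_spec()] objects.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param psf_sigma_px Standard deviation (pixels) of the Gaussian
#'   acquisition point-spread function applied to the noiseless scene
#'   (default 0.7). Real digitized mammograms are band-limited; without a
#'   PSF, rasterized curvilinear ridges carry single-pixel staircase
#'   artifacts that are indistinguishable in principle from true 1 px spots.
#'   Set to 0 for exact-arithmetic tests.
#' @param seed Integer master seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_px = c(1024L, 1024L), pixel_spacing_mm = 0.05,
                         background = list(base = 0.3, amplitude = 0.1,
                                           scale_px = 64),
                         clusters = list(), lines = list(),
                         noise_sigma = 0.01, psf_sigma_px = 0.7, seed = 1L) {
  image_px <- as.integer(image_px)
  if (min(image_px) < 16L)
    stop("image sides must be >= 16 px (decomposable at 4 wavelet levels)")
  struct_amp <- max(c(0,
    vapply(clusters, function(cl) max(cl$spot_amplitude), 0),
    vapply(lines, function(l) l$amplitude, 0)))
  if (background$base + background$amplitude + struct_amp > 1 + 1e-9)
    stop("background base plus structure amplitudes must not exceed 1")
  structure(list(image_px = image_px, pixel_spacing_mm = pixel_spacing_mm,
                 background = background, clusters = clusters, lines = lines,
                 noise_sigma = noise_sigma, psf_sigma_px = psf_sigma_px,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Cluster specification for the phantom generator
#'
#' A group of `n_spots` bright spots scattered uniformly within a square of
#' side `extent_mm` centred at `center_mm`. Spots are isotropic Gaussians
#' truncated at three standard deviations, with the standard deviation set
#' to a quarter of the spot diameter (so the stated diameter spans roughly
#' the central 95% of the profile); a `"square"` profile of constant
#' amplitude is available for exact-arithmetic tests.
#'
#' @param center_mm Numeric `(y, x)` cluster centre in millimetres.
#' @param extent_mm Side of the square the spots fall in (default 10, the
#'   area a clinical cluster occupies).
#' @param n_spots Number of spots; `NULL` (default) draws 4-10.
#' @param spot_diameter_mm Range the per-spot diameter is drawn from
#'   (default 0.2-0.5 mm, within the 0.05-1 mm span of real
#'   microcalcifications).
#' @param spot_amplitude Range of per-spot contrast above background
#'   (default 0.2-0.4: the phantom's positive images model *reported*
#'   clusters, i.e. calcifications conspicuous enough for a radiologist to
#'   see against glandular texture of contrast up to ~0.25).
#' @param profile `"gaussian"` (default) or `"square"`.
#' @param scatter How spot centres are placed inside the extent box:
#'   `"gaussian"` (default) scatters them around the centre with standard
#'   deviation `extent_mm / 5` truncated to the box, matching the
#'   concentrated appearance of clinical clusters whose quoted 10 x 10 mm
#'   area is an upper bound; `"uniform"` spreads them uniformly over the
#'   whole box.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(center_mm, extent_mm = 10, n_spots = NULL,
                         spot_diameter_mm = c(0.2, 0.5),
                         spot_amplitude = c(0.2, 0.4),
                         profile = c("gaussian", "square"),
                         scatter = c("gaussian", "uniform")) {
  profile <- match.arg(profile)
  scatter <- match.arg(scatter)
  spot_diameter_mm <- range(spot_diameter_mm)
  spot_amplitude <- range(spot_amplitude)
  if (!is.null(n_spots) && n_spots < 1L) stop("`n_spots` must be >= 1")
  structure(list(center_mm = as.numeric(center_mm), extent_mm = extent_mm,
                 n_spots = if (is.null(n_spots)) NULL else as.integer(n_spots),
                 spot_diameter_mm = spot_diameter_mm,
                 spot_amplitude = spot_amplitude, profile = profile,
                 scatter = scatter),
            class = "cluster_spec")
}

#' Curvilinear ridge specification for the phantom generator
#'
#' A bright ridge following a quadratic Bezier curve, `width_px` wide, with
#' per-pixel multiplicative intensity jitter emulating the nonhomogeneous
#' intensity of mammary glands and vessels. With the default width of 1-2 px
#' the ridge is far narrower than the 15 px SE footprint, so the top-hat
#' stage passes it through and the wavelet stage must suppress it —
#' mirroring the premise that a microcalcification is about twice the size
#' of a gland cross-section.
#'
#' @param control_points_mm 3 x 2 matrix of `(y, x)` Bezier control points in
#'   millimetres, or `NULL` (default) to draw them at generation time.
#' @param width_px Ridge width in pixels (default 1).
#' @param amplitude Peak contrast above background (default 0.15).
#' @param jitter Multiplicative jitter fraction in `[0, 1)` (default 0.2):
#'   each ridge pixel's intensity is scaled by `U(1 - jitter, 1 + jitter)`,
#'   clamped so the amplitude bound still holds.
#' @return An object of class `line_spec`.
#' @export
line_spec <- function(control_points_mm = NULL, width_px = 1L,
                      amplitude = 0.15, jitter = 0.2) {
  if (jitter < 0 || jitter >= 1) stop("`jitter` must lie in [0, 1)")
  structure(list(control_points_mm = control_points_mm,
                 width_px = as.integer(width_px),
                 amplitude = amplitude, jitter = jitter),
            class = "line_spec")
}

substream_seeds <- function(seed, n = 4L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

smooth_background <- function(shape, base, amplitude, scale_px) {
  if (amplitude <= 0) return(matrix(base, shape[1], shape[2]))
  gr <- pmax(2L, ceiling(shape / scale_px) + 1L)
  coarse <- matrix(stats::runif(prod(gr), -1, 1), gr[1], gr[2])
  up <- EBImage::resize(coarse, w = shape[1], h = shape[2],
                        filter = "bilinear")
  up <- up / max(abs(up), 1e-12) * amplitude
  base + matrix(up, shape[1], shape[2])
}

render_spot <- function(img, r, c_, diam_px, amp, profile) {
  n <- nrow(img); w <- ncol(img)
  if (profile == "square") {
    half <- max(0L, floor(diam_px / 2))
    rr <- max(1L, round(r) + 1L - half):min(n, round(r) + 1L + half)
    cc <- max(1L, round(c_) + 1L - half):min(w, round(c_) + 1L + half)
    img[rr, cc] <- img[rr, cc] + amp
    return(img)
  }
  sigma <- diam_px / 4
  rad <- max(1L, ceiling(3 * sigma))
  rr <- max(1L, floor(r) + 1L - rad):min(n, ceiling(r) + 1L + rad)
  cc <- max(1L, floor(c_) + 1L - rad):min(w, ceiling(c_) + 1L + rad)
  d2 <- outer((rr - 1L - r)^2, (cc - 1L - c_)^2, "+")
  g <- amp * exp(-d2 / (2 * sigma^2))
  g[d2 > (3 * sigma)^2] <- 0
  img[rr, cc] <- img[rr, cc] + g
  img
}

bezier_points <- function(p, n_steps) {
  t <- seq(0, 1, length.out = n_steps)
  cbind((1 - t)^2 * p[1, 1] + 2 * t * (1 - t) * p[2, 1] + t^2 * p[3, 1],
        (1 - t)^2 * p[1, 2] + 2 * t * (1 - t) * p[2, 2] + t^2 * p[3, 2])
}

render_line <- function(layer, lspec, spacing) {
  n <- nrow(layer); w <- ncol(layer)
  p_mm <- lspec$control_points_mm
  if (is.null(p_mm)) {
    p_px <- cbind(stats::runif(3, 0.05 * n, 0.95 * n),
                  stats::runif(3, 0.05 * w, 0.95 * w))
  } else {
    p_px <- p_mm / spacing
  }
  len <- sum(sqrt(rowSums(diff(p_px)^2)))
  pts <- bezier_points(p_px, max(16L, ceiling(3 * len)))
  hw <- lspec$width_px / 2
  rad <- ceiling(hw)
  offs <- expand.grid(dr = seq.int(-rad, rad), dc = seq.int(-rad, rad))
  offs <- offs[offs$dr^2 + offs$dc^2 <= hw^2 + 1e-9, , drop = FALSE]
  rr <- round(pts[, 1]); cc <- round(pts[, 2])
  idx <- unique(unlist(lapply(seq_len(nrow(offs)), function(k) {
    r2 <- rr + offs$dr[k]; c2 <- cc + offs$dc[k]
    ok <- r2 >= 0 & r2 < n & c2 >= 0 & c2 < w
    c2[ok] * n + r2[ok] + 1
  })))
  jit <- stats::runif(length(idx), 1 - lspec$jitter, 1 + lspec$jitter)
  val <- pmin(lspec$amplitude * jit, lspec$amplitude)
  layer[idx] <- pmax(layer[idx], val)
  layer
}

#' Generate a phantom image with ground truth
#'
#' Renders `clip(psf * (background + spots + ridges) + noise, 0, 1)` (where
#' `psf *` denotes the optional acquisition blur) and records the realized
#' structures: per-cluster spot centres (0-based pixel coordinates), one
#' half-open cluster bounding box per cluster, and the binary mask of
#' confounder ridges.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (a [gray_image]) and `truth` (list:
#'   `spot_centers_px`, `cluster_boxes_px`, `line_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$image_px
  sp <- spec$pixel_spacing_mm
  seeds <- substream_seeds(spec$seed, 4L)
  img <- with_seed(seeds[1],
    smooth_background(shape, spec$background$base,
                      spec$background$amplitude, spec$background$scale_px))
  spot_centers <- list()
  boxes <- data.frame(r0 = integer(), r1 = integer(),
                      c0 = integer(), c1 = integer())
  if (length(spec$clusters)) {
    res <- with_seed(seeds[2], {
      lapply(seq_along(spec$clusters), function(ci) {
        cl <- spec$clusters[[ci]]
        k <- if (is.null(cl$n_spots)) sample(4:10, 1L) else cl$n_spots
        ctr_px <- cl$center_mm / sp
        half_px <- cl$extent_mm / sp / 2
        if (identical(cl$scatter, "uniform")) {
          r <- stats::runif(k, ctr_px[1] - half_px, ctr_px[1] + half_px)
          c_ <- stats::runif(k, ctr_px[2] - half_px, ctr_px[2] + half_px)
        } else {
          sd_px <- cl$extent_mm / 5 / sp
          draw_trunc <- function(mu) {
            x <- stats::rnorm(k, mu, sd_px)
            for (it in 1:20) {
              bad <- abs(x - mu) > half_px
              if (!any(bad)) break
              x[bad] <- stats::rnorm(sum(bad), mu, sd_px)
            }
            pmin(pmax(x, mu - half_px), mu + half_px)
          }
          r <- draw_trunc(ctr_px[1])
          c_ <- draw_trunc(ctr_px[2])
        }
        diam <- stats::runif(k, cl$spot_diameter_mm[1], cl$spot_diameter_mm[2]) / sp
        amp <- stats::runif(k, cl$spot_amplitude[1], cl$spot_amplitude[2])
        if (any(r - diam / 2 < 0) || any(r + diam / 2 > shape[1] - 1) ||
            any(c_ - diam / 2 < 0) || any(c_ + diam / 2 > shape[2] - 1))
          stop("cluster ", ci, " places spots outside the image")
        list(r = r, c = c_, diam = diam, amp = amp, profile = cl$profile)
      })
    })
    for (ci in seq_along(res)) {
      cl <- res[[ci]]
      for (k in seq_along(cl$r))
        img <- render_spot(img, cl$r[k], cl$c[k], cl$diam[k], cl$amp[k],
                           cl$profile)
      spot_centers[[ci]] <- cbind(r = cl$r, c = cl$c)
      pad <- cl$diam / 2 + 1
      boxes <- rbind(boxes, data.frame(
        r0 = max(0L, floor(min(cl$r - pad))),
        r1 = min(shape[1], ceiling(max(cl$r + pad)) + 1L),
        c0 = max(0L, floor(min(cl$c - pad))),
        c1 = min(shape[2], ceiling(max(cl$c + pad)) + 1L)))
    }
  }
  line_layer <- matrix(0, shape[1], shape[2])
  if (length(spec$lines)) {
    line_layer <- with_seed(seeds[3], {
      ll <- line_layer
      for (l in spec$lines) ll <- render_line(ll, l, sp)
      ll
    })
    img <- img + line_layer
  }
  if (spec$psf_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = spec$psf_sigma_px))
  if (spec$noise_sigma > 0) {
    img <- img + with_seed(seeds[4],
      matrix(stats::rnorm(prod(shape), 0, spec$noise_sigma),
             shape[1], shape[2]))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = gray_image(img, sp),
       truth = list(spot_centers_px = spot_centers,
                    cluster_boxes_px = boxes,
                    line_mask = line_layer > 0))
}

#' Default phantom benchmark suite
#'
#' A reproducible mix of phantom images emulating a screening set: a fixed
#' fraction of images (default 10%, rounded, at least one) contain 1-2 spot
#' clusters, every image contains 2-6 gland-like curvilinear confounders,
#' and all structural parameters are drawn from the package defaults.
#'
#' @param n_images Number of images.
#' @param seed Integer master seed.
#' @param positive_fraction Fraction of images containing clusters
#'   (default 0.1).
#' @param image_px Image shape, default `c(1024, 1024)`.
#' @param pixel_spacing_mm Pixel spacing, default 0.05.
#' @return A list of `n_images` elements, each `list(image, truth, spec)`.
#' @export
default_benchmark_suite <- function(n_images, seed = 1L,
                                    positive_fraction = 0.1,
                                    image_px = c(1024L, 1024L),
                                    pixel_spacing_mm = 0.05) {
  if (n_images < 1L) stop("`n_images` must be >= 1")
  fov_mm <- image_px * pixel_spacing_mm
  n_pos <- max(1L, round(positive_fraction * n_images))
  plan <- with_seed(seed, {
    pos_idx <- sort(sample.int(n_images, min(n_pos, n_images)))
    seeds <- sample.int(.Machine$integer.max - 1L, n_images)
    list(pos_idx = pos_idx, seeds = seeds)
  })
  lapply(seq_len(n_images), function(i) {
    s <- plan$seeds[i]
    layout <- with_seed(s + 1L, {
      n_lines <- sample(2:6, 1L)
      lines <- replicate(n_lines, line_spec(width_px = sample(1:2, 1L),
                                            amplitude = stats::runif(1, 0.1, 0.25),
                                            jitter = 0.2),
                         simplify = FALSE)
      clusters <- list()
      if (i %in% plan$pos_idx) {
        n_cl <- sample(1:2, 1L)
        margin <- 8
        span <- fov_mm - 2 * margin
        if (min(span) <= 0)
          stop("image too small for the default cluster layout")
        # keep clusters apart, capped by what the field of view allows
        min_sep <- min(15, 0.7 * sqrt(sum(span^2)))
        ctrs <- matrix(NA_real_, 0, 2)
        tries <- 0L
        while (nrow(ctrs) < n_cl && tries < 200L) {
          tries <- tries + 1L
          cand <- c(stats::runif(1, margin, fov_mm[1] - margin),
                    stats::runif(1, margin, fov_mm[2] - margin))
          if (nrow(ctrs) == 0 ||
              all(sqrt(rowSums(sweep(ctrs, 2, cand)^2)) > min_sep))
            ctrs <- rbind(ctrs, cand)
        }
        clusters <- lapply(seq_len(nrow(ctrs)), function(j)
          cluster_spec(center_mm = ctrs[j, ]))
      }
      list(lines = lines, clusters = clusters)
    })
    spec <- phantom_spec(image_px = image_px,
                         pixel_spacing_mm = pixel_spacing_mm,
                         clusters = layout$clusters, lines = layout$lines,
                         seed = s)
    c(generate_phantom(spec), list(spec = spec))
  })
}
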
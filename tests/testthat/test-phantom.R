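test_that("phantom generation is deterministic and bookkeeping is exact", {
  spec <- phantom_spec(image_px = c(128, 128),
                       clusters = list(cluster_spec(center_mm = c(3.2, 3.2),
                                                    extent_mm = 4, n_spots = 5)),
                       lines = list(line_spec(amplitude = 0.2)),
                       noise_sigma = 0.01, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_equal(nrow(a$truth$cluster_boxes_px), 1)
  expect_equal(nrow(a$truth$spot_centers_px[[1]]), 5)
  expect_true(all(a$image$pixels >= 0 & a$image$pixels <= 1))
})

test_that("a structure-free noiseless phantom equals its smooth background", {
  spec <- phantom_spec(image_px = c(64, 64), noise_sigma = 0, psf_sigma_px = 0,
                       seed = 3)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$truth$cluster_boxes_px), 0)
  expect_false(any(ph$truth$line_mask))
  # smooth background only: bounded by base +/- amplitude
  expect_true(all(abs(ph$image$pixels - 0.3) <= 0.1 + 1e-12))
  # flat background option: exactly the base level
  flat <- generate_phantom(phantom_spec(image_px = c(32, 32),
                                        background = list(base = 0.25,
                                                          amplitude = 0,
                                                          scale_px = 16),
                                        noise_sigma = 0, psf_sigma_px = 0,
                                        seed = 1))
  expect_true(all(flat$image$pixels == 0.25))
})

test_that("spot peaks reach background + amplitude without blur or noise", {
  spec <- phantom_spec(image_px = c(96, 96),
                       background = list(base = 0.2, amplitude = 0, scale_px = 16),
                       clusters = list(cluster_spec(center_mm = c(2.4, 2.4),
                                                    extent_mm = 2, n_spots = 4,
                                                    spot_diameter_mm = c(0.3, 0.3),
                                                    spot_amplitude = c(0.3, 0.3))),
                       noise_sigma = 0, psf_sigma_px = 0, seed = 8)
  ph <- generate_phantom(spec)
  sc <- ph$truth$spot_centers_px[[1]]
  for (k in seq_len(nrow(sc))) {
    r <- round(sc[k, 1]) + 1; c_ <- round(sc[k, 2]) + 1
    peak <- max(ph$image$pixels[max(1, r - 2):min(96, r + 2),
                                max(1, c_ - 2):min(96, c_ + 2)])
    expect_equal(peak, 0.5, tolerance = 0.1)   # profile discretization slack
  }
  # spots stay within the cluster extent box
  ctr_px <- c(2.4, 2.4) / 0.05
  expect_true(all(abs(sc[, 1] - ctr_px[1]) <= 2 / 0.05 / 2 + 1e-9))
  expect_true(all(abs(sc[, 2] - ctr_px[2]) <= 2 / 0.05 / 2 + 1e-9))
})

test_that("square spots add exactly their amplitude", {
  spec <- phantom_spec(image_px = c(64, 64),
                       background = list(base = 0.1, amplitude = 0, scale_px = 8),
                       clusters = list(cluster_spec(center_mm = c(1.6, 1.6),
                                                    extent_mm = 1, n_spots = 2,
                                                    spot_diameter_mm = c(0.2, 0.2),
                                                    spot_amplitude = c(0.25, 0.25),
                                                    profile = "square")),
                       noise_sigma = 0, psf_sigma_px = 0, seed = 5)
  ph <- generate_phantom(spec)
  expect_true(all(sort(unique(round(ph$image$pixels, 10))) %in%
                    c(0.1, 0.35, 0.6)))
})

test_that("gland-like ridges are narrow, jittered and recorded in the truth", {
  spec <- phantom_spec(image_px = c(128, 128),
                       background = list(base = 0.2, amplitude = 0, scale_px = 16),
                       lines = list(line_spec(width_px = 1, amplitude = 0.2,
                                              jitter = 0.2)),
                       noise_sigma = 0, psf_sigma_px = 0, seed = 14)
  ph <- generate_phantom(spec)
  lm <- ph$truth$line_mask
  expect_gt(sum(lm), 50)
  # ridge intensities carry multiplicative jitter, bounded by the amplitude
  vals <- ph$image$pixels[lm] - 0.2
  expect_true(all(vals > 0.2 * 0.8 - 1e-9 & vals <= 0.2 + 1e-9))
  expect_gt(stats::sd(vals), 0)
  # width 1: the mask is a thin curve, area ~ its length
  expect_lt(mean(lm), 0.03)
})

test_that("amplitude budget and geometry are validated", {
  expect_error(phantom_spec(background = list(base = 0.8, amplitude = 0.1,
                                              scale_px = 16),
                            lines = list(line_spec(amplitude = 0.3))),
               "exceed 1")
  expect_error(phantom_spec(image_px = c(8, 8)), ">= 16")
  expect_error(generate_phantom(
    phantom_spec(image_px = c(64, 64),
                 clusters = list(cluster_spec(center_mm = c(0.2, 0.2),
                                              extent_mm = 8, n_spots = 10)),
                 seed = 2)),
    "outside the image")
})

test_that("benchmark suites are reproducible with the stated composition", {
  s1 <- default_benchmark_suite(6, seed = 5, image_px = c(384, 384))
  s2 <- default_benchmark_suite(6, seed = 5, image_px = c(384, 384))
  expect_length(s1, 6)
  expect_identical(s1[[3]]$image$pixels, s2[[3]]$image$pixels)
  n_cl <- vapply(s1, function(s) nrow(s$truth$cluster_boxes_px), 0L)
  expect_equal(sum(n_cl > 0), 1)          # 10% of 6, at least one positive
  for (s in s1) {
    expect_identical(length(s$truth$spot_centers_px) > 0,
                     nrow(s$truth$cluster_boxes_px) > 0)
    expect_gte(length(s$spec$lines), 2)
    expect_lte(length(s$spec$lines), 6)
  }
  # positive-count rule at the screening-set scale: round(14/138 * 138) = 14
  pos_planned <- function(n, frac) max(1L, round(frac * n))
  expect_equal(pos_planned(138, 14 / 138), 14)
  expect_equal(pos_planned(30, 0.1), 3)
})
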
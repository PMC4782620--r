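test_that("decompose/reconstruct is a perfect-reconstruction pair", {
  set.seed(21)
  for (shape in list(c(64, 64), c(33, 47), c(50, 31), c(17, 64))) {
    m <- matrix(runif(prod(shape)), shape[1], shape[2])
    for (mode in c("symmetric", "reflect", "periodic", "zero")) {
      pyr <- decompose(gray_image(m), n_levels = 4, extension_mode = mode)
      rec <- reconstruct(pyr)
      expect_lt(max(abs(rec$pixels - m)), 1e-8)
    }
  }
})

test_that("constant images put all energy into the approximation", {
  flat <- gray_image(matrix(0.37, 48, 48))
  pyr <- decompose(flat, n_levels = 4)
  for (d in pyr$details) {
    expect_lt(max(abs(d$h)), 1e-10)
    expect_lt(max(abs(d$v)), 1e-10)
    expect_lt(max(abs(d$d)), 1e-10)
  }
  # zeroing the approximation reconstructs to ~0
  z <- zero_subbands(pyr, subband_selector(TRUE, integer(), 4))
  expect_lt(max(abs(reconstruct(z)$pixels)), 1e-8)
})

test_that("subband shapes follow the dyadic halving of the input", {
  pyr <- decompose(gray_image(matrix(0, 64, 64)), n_levels = 4)
  fin <- pyr$details[[4]]$h
  expect_true(all(dim(fin) >= 32) && all(dim(fin) <= 34))
  expect_length(pyr$details, 4)
  expect_identical(dim(pyr$details[[1]]$h), dim(pyr$approx))
  expect_error(decompose(gray_image(matrix(0, 8, 8)), n_levels = 4), ">= 16")
})

test_that("multilevel coefficients match an independent reference", {
  # fixture computed with PyWavelets 1.9 (wavedec2, sym2, symmetric, 2 levels)
  x <- matrix((7 * (0:63)) %% 23, 8, 8, byrow = TRUE)
  pyr <- decompose(gray_image(x), wavelet_name = "sym2", n_levels = 2,
                   extension_mode = "symmetric")
  expect_equal(dim(pyr$approx), c(4L, 4L))
  expect_equal(sum(pyr$approx), 613.369061579326, tolerance = 1e-10)
  expect_equal(pyr$approx[1, 1], 23.783735279210, tolerance = 1e-10)
  expect_equal(pyr$approx[2, 3], 51.788490796958, tolerance = 1e-10)
  expect_equal(sum(pyr$details[[1]]$h), -8.043697202708, tolerance = 1e-9)
  expect_equal(pyr$details[[1]]$v[2, 3], -4.878303620348, tolerance = 1e-10)
  expect_equal(pyr$details[[1]]$d[1, 1], -1.655890446176, tolerance = 1e-10)
  expect_equal(dim(pyr$details[[2]]$h), c(5L, 5L))
  expect_equal(sum(pyr$details[[2]]$h), 7.008738748841, tolerance = 1e-9)
  expect_equal(sum(pyr$details[[2]]$d), 20.406969107630, tolerance = 1e-9)
})

test_that("zero_subbands zeroes exactly the selected arrays and nothing else", {
  img <- toy_image(32, seed = 9)
  pyr <- decompose(img, n_levels = 3)
  sel <- subband_selector(TRUE, 3L, 3L)       # default shape: approx + finest
  z <- zero_subbands(pyr, sel)
  expect_true(all(z$approx == 0))
  expect_true(all(z$details[[3]]$h == 0) && all(z$details[[3]]$v == 0) &&
                all(z$details[[3]]$d == 0))
  for (lvl in 1:2) expect_identical(z$details[[lvl]], pyr$details[[lvl]])
  expect_false(all(pyr$approx == 0))          # input not mutated
  # empty selector is the identity; zeroing is a projection
  expect_identical(zero_subbands(pyr, subband_selector(FALSE, integer(), 3)), pyr)
  expect_identical(zero_subbands(z, sel), z)
  expect_error(subband_selector(TRUE, 5L, 4L), "\\[1, 4\\]")
  expect_error(zero_subbands(decompose(img, n_levels = 2),
                             subband_selector(TRUE, 3L, 3L)), "levels")
})

test_that("zeroing never increases coefficient energy", {
  img <- toy_image(40, seed = 13)
  pyr <- decompose(img, n_levels = 4)
  e0 <- pyramid_energy(pyr)
  for (sel in list(subband_selector(TRUE, integer(), 4),
                   subband_selector(FALSE, c(1L, 4L), 4),
                   subband_selector(TRUE, 1:4, 4))) {
    expect_lte(pyramid_energy(zero_subbands(pyr, sel)), e0)
  }
})

test_that("denoise is linear and reduces a constant image to ~0", {
  sel <- subband_selector(n_levels = 3)
  set.seed(31)
  a <- matrix(runif(32 * 32), 32); b <- matrix(runif(32 * 32), 32)
  da <- denoise(gray_image(a), sel, n_levels = 3)$pixels
  db <- denoise(gray_image(b), sel, n_levels = 3)$pixels
  dab <- denoise(gray_image(2 * a + 0.5 * b), sel, n_levels = 3)$pixels
  expect_equal(dab, 2 * da + 0.5 * db, tolerance = 1e-10)
  # identity selector recovers the input
  did <- denoise(gray_image(a), subband_selector(FALSE, integer(), 3),
                 n_levels = 3)$pixels
  expect_lt(max(abs(did - a)), 1e-8)
  # constant image: everything lives in the zeroed approximation
  dc <- denoise(gray_image(matrix(0.6, 32, 32)), sel, n_levels = 3)$pixels
  expect_lt(max(abs(dc)), 1e-8)
})

test_that("default denoiser attenuates a thin ridge more than a compact blob", {
  set.seed(77)
  m <- matrix(rnorm(128 * 128, 0, 0.002), 128, 128)
  m[30, 10:118] <- m[30, 10:118] + 0.4          # 1-px-wide line
  m[80:84, 60:64] <- m[80:84, 60:64] + 0.4      # 5x5 blob
  den <- denoise(gray_image(m), subband_selector(n_levels = 4))$pixels
  line_peak <- max(den[28:32, 10:118])
  blob_peak <- max(den[78:86, 58:66])
  expect_lt(line_peak, blob_peak)
})
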
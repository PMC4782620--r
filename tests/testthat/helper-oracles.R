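# Independent brute-force oracles used across the test files.

# reflect-pad (mirror with edge duplication), replicating the package's
# documented border convention but written independently
oracle_pad <- function(m, p) {
  idx <- function(n) {
    i <- seq.int(1L - p, n + p)
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  m[idx(nrow(m)), idx(ncol(m)), drop = FALSE]
}

# per-pixel sliding-window grayscale opening: erosion then dilation, each a
# scalar min/max over the SE offsets at every pixel
oracle_opening <- function(m, offs, pad = oracle_pad) {
  h <- max(abs(offs))
  p <- 2L * h
  mp <- pad(m, p)
  n <- nrow(m); w <- ncol(m)
  er <- matrix(NA_real_, n + 2L * h, w + 2L * h)
  for (i in seq_len(nrow(er))) for (j in seq_len(ncol(er)))
    er[i, j] <- min(mp[cbind(i + h + offs[, 1], j + h + offs[, 2])])
  op <- matrix(NA_real_, n, w)
  for (i in seq_len(n)) for (j in seq_len(w))
    op[i, j] <- max(er[cbind(i + h + offs[, 1], j + h + offs[, 2])])
  op
}

oracle_tophat <- function(m, offs) pmax(m - oracle_opening(m, offs), 0)

oracle_multi_se <- function(m, ses) {
  mx <- NULL
  for (se in ses$elements) {
    op <- oracle_opening(m, se$offsets)
    mx <- if (is.null(mx)) op else pmax(mx, op)
  }
  pmax(m - mx, 0)
}

# exhaustive Otsu: scan every distinct value as a candidate threshold and
# maximize the between-class variance
oracle_otsu <- function(x) {
  vals <- sort(unique(as.vector(x)))
  cand <- vals[-length(vals)]
  bcv <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, 0)
  cand[which.max(bcv)]
}

# tiny deterministic gray image
toy_image <- function(n = 12, w = n, seed = 1, spacing = 0.05) {
  set.seed(seed)
  gray_image(matrix(runif(n * w), n, w), spacing)
}

# one cluster of k point spots placed at given 0-based pixel coords, as a
# component_set-compatible mask
mask_with_points <- function(shape, coords) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[coords + 1L] <- TRUE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pyramid_energy <- function(pyr) {
  sum(pyr$approx^2) + sum(vapply(pyr$details, function(d)
    sum(d$h^2) + sum(d$v^2) + sum(d$d^2), 0))
}
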
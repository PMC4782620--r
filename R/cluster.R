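#' Overlapping block grid
#'
#' Tiles an image with square blocks of side `block_px` whose anchors advance
#' by `step_px` along each axis (default: 200 px blocks stepping 100 px, i.e.
#' adjacent blocks overlap by a 100 px wide band; at 0.05 mm/px a block spans
#' the 10 x 10 mm area a microcalcification cluster occupies). The last
#' anchor in each axis is clamped so the final block abuts the image edge:
#' every pixel is covered by at least one block.
#'
#' @param image_shape Integer `(height, width)` in pixels.
#' @param block_px Block side in pixels (default 200).
#' @param step_px Anchor step in pixels (default 100); must satisfy
#'   `1 <= step_px <= block_px`.
#' @return An object of class `block_grid`: list with `row_anchors`,
#'   `col_anchors` (0-based), `block_px`, `step_px`, `image_shape`.
#' @export
make_grid <- function(image_shape, block_px = 200L, step_px = 100L) {
  image_shape <- as.integer(image_shape)
  block_px <- as.integer(block_px); step_px <- as.integer(step_px)
  if (block_px > min(image_shape))
    stop("block side ", block_px, " px exceeds the image (",
         image_shape[1], " x ", image_shape[2], ")")
  if (step_px < 1L || step_px > block_px)
    stop("`step_px` must satisfy 1 <= step_px <= block_px")
  anchors <- function(n) {
    a <- seq.int(0L, max(0L, n - block_px), by = step_px)
    last <- n - block_px
    if (a[length(a)] != last) a <- c(a, last)
    a
  }
  structure(list(row_anchors = anchors(image_shape[1]),
                 col_anchors = anchors(image_shape[2]),
                 block_px = block_px, step_px = step_px,
                 image_shape = image_shape),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> %d x %d blocks of %d px, step %d px, image %d x %d\n",
              length(x$row_anchors), length(x$col_anchors), x$block_px,
              x$step_px, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Detect microcalcification clusters by the block counting rule
#'
#' A component belongs to a block iff its centroid lies inside the block's
#' half-open box; a block containing at least `min_count` components
#' (default 4, i.e. "more than three") is emitted as a cluster detection.
#' Because blocks overlap, a tight cluster is typically reported by several
#' neighbouring blocks; use [merge_detections()] to consolidate them.
#'
#' @param components A `component_set` from [extract_components()].
#' @param grid A `block_grid` from [make_grid()].
#' @param min_count Minimum number of components for a block to be labeled a
#'   cluster (default 4).
#' @return A detection data frame, one row per qualifying block:
#'   `block_row`, `block_col` (0-based block indices), half-open pixel box
#'   `r0`, `r1`, `c0`, `c1`, the same box in mm, `component_count` and
#'   `member_labels` (`;`-joined component labels).
#' @export
detect_clusters <- function(components, grid, min_count = 4L) {
  stopifnot(inherits(components, "component_set"), inherits(grid, "block_grid"))
  if (!identical(as.integer(components$source_shape),
                 as.integer(grid$image_shape)))
    stop("components and grid refer to different image shapes")
  if (min_count < 1L) stop("`min_count` must be >= 1")
  sp <- components$pixel_spacing_mm
  out <- empty_detections()
  comp <- components$components
  if (nrow(comp) == 0L) return(out)
  b <- grid$block_px
  rows <- list()
  for (i in seq_along(grid$row_anchors)) {
    r0 <- grid$row_anchors[i]
    inr <- comp$centroid_r >= r0 & comp$centroid_r < r0 + b
    if (!any(inr)) next
    for (j in seq_along(grid$col_anchors)) {
      c0 <- grid$col_anchors[j]
      sel <- inr & comp$centroid_c >= c0 & comp$centroid_c < c0 + b
      cnt <- sum(sel)
      if (cnt >= min_count) {
        rows[[length(rows) + 1L]] <- data.frame(
          block_row = i - 1L, block_col = j - 1L,
          r0 = r0, r1 = r0 + b, c0 = c0, c1 = c0 + b,
          y0_mm = r0 * sp, y1_mm = (r0 + b) * sp,
          x0_mm = c0 * sp, x1_mm = (c0 + b) * sp,
          component_count = cnt,
          member_labels = paste(comp$label[sel], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

split_labels <- function(s) {
  if (is.na(s) || !nzchar(s)) integer(0)
  else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Merge overlapping block detections
#'
#' Block detections that share at least one member component are transitively
#' grouped (connected components of the block-sharing graph) and each group
#' is collapsed into one detection: union of member labels, union bounding
#' box, block indices of the group's first block. Idempotent.
#'
#' @param raw A detection data frame from [detect_clusters()].
#' @return A detection data frame with one row per merged cluster.
#' @export
merge_detections <- function(raw) {
  raw <- as.data.frame(raw)
  n <- nrow(raw)
  if (n <= 1L) return(raw)
  members <- lapply(raw$member_labels, split_labels)
  all_lab <- sort(unique(unlist(members)))
  # bipartite trick: connect detections through shared labels
  edges <- integer(0)
  for (i in seq_len(n)) {
    li <- match(members[[i]], all_lab) + n
    edges <- c(edges, rbind(i, li))
  }
  g <- igraph::make_graph(edges, n = n + length(all_lab), directed = FALSE)
  memb <- igraph::components(g)$membership[seq_len(n)]
  groups <- split(seq_len(n), memb)
  groups <- groups[order(vapply(groups, min, 1L))]
  rows <- lapply(groups, function(idx) {
    d <- raw[idx, , drop = FALSE]
    labs <- sort(unique(unlist(members[idx])))
    data.frame(
      block_row = d$block_row[1], block_col = d$block_col[1],
      r0 = min(d$r0), r1 = max(d$r1), c0 = min(d$c0), c1 = max(d$c1),
      y0_mm = min(d$y0_mm), y1_mm = max(d$y1_mm),
      x0_mm = min(d$x0_mm), x1_mm = max(d$x1_mm),
      component_count = length(labs),
      member_labels = paste(labs, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
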
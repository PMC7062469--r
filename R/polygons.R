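#' Spine-head region of interest
#'
#' A spine-head ROI is a simple polygon drawn in the single plane where the
#' head appears brightest, with 0-based pixel-center coordinates (`x` runs
#' along columns, `y` along rows). A pixel belongs to the ROI when its
#' center lies inside the polygon (even-odd rule).
#'
#' @param spine_id Identifier, coerced to character.
#' @param class Either `"mushroom"` (bright head wider than the neck) or
#'   `"filopodial"` (headless protrusion).
#' @param x,y Numeric vertex coordinates (0-based pixel units), not closed.
#' @param plane_index Index of the imaging plane the polygon was drawn in.
#' @return An object of class `spine_roi`.
#' @examples
#' roi <- spine_roi("s1", "mushroom", x = c(2, 8, 8, 2), y = c(2, 2, 8, 8))
#' roi$area_px
#' @export
spine_roi <- function(spine_id, class = c("mushroom", "filopodial"),
                      x, y, plane_index = 1L) {
  class <- match.arg(class)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("polygon needs >= 3 (x, y) vertex pairs", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("polygon vertices must be finite", call. = FALSE)
  if (polygon_self_intersects(x, y)) {
    stop("polygon is not simple (self-intersecting)", call. = FALSE)
  }
  area_px <- nrow(polygon_pixels(x, y))
  if (area_px < 1L) stop("polygon encloses no pixel centers", call. = FALSE)
  structure(
    list(spine_id = as.character(spine_id), class = class,
         x = as.numeric(x), y = as.numeric(y),
         plane_index = as.integer(plane_index), area_px = area_px),
    class = "spine_roi"
  )
}

# Even-odd (ray crossing) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# All 0-based (x, y) pixel centers inside the polygon, as a 2-column matrix.
polygon_pixels <- function(vx, vy) {
  xr <- floor(min(vx)):ceiling(max(vx))
  yr <- floor(min(vy)):ceiling(max(vy))
  g <- expand.grid(x = xr, y = yr)
  keep <- point_in_polygon(g$x, g$y, vx, vy)
  as.matrix(g[keep, , drop = FALSE])
}

# Linear (column-major) indices of a spine polygon's pixels inside an
# nrow x ncol image; errors if any pixel falls outside the image.
rasterize_spine <- function(spine, nrow, ncol) {
  px <- polygon_pixels(spine$x, spine$y)
  if (nrow(px) == 0L) stop("empty polygon raster", call. = FALSE)
  col1 <- px[, "x"] + 1L  # 0-based x -> 1-based column
  row1 <- px[, "y"] + 1L
  if (any(col1 < 1L | col1 > ncol | row1 < 1L | row1 > nrow)) {
    stop(sprintf("spine '%s' extends outside the %d x %d image",
                 spine$spine_id, nrow, ncol), call. = FALSE)
  }
  as.integer((col1 - 1L) * nrow + row1)
}

# O(n^2) proper-crossing check between non-adjacent edges.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  nx <- c(x, x[1]); ny <- c(y, y[1])
  seg <- function(i) c(nx[i], ny[i], nx[i + 1], ny[i + 1])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      a <- seg(i); b <- seg(j)
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && all(c(o1, o2, o3, o4) != 0)) return(TRUE)
    }
  }
  FALSE
}

# Regular-polygon approximation of a disk, with slight radial jitter so no
# vertex lands exactly on a pixel-center boundary.
disk_polygon <- function(cx, cy, radius, n_vertices = 12L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)] +
    pi / (7 * n_vertices)
  list(x = cx + radius * cos(th), y = cy + radius * sin(th))
}
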
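#' Polygon utilities
#'
#' Polygons are given in pixel coordinates as a two-column object (columns
#' `x`, `y`) describing one closed ring, or as a list of such rings. Multiple
#' rings are combined under the even-odd rule, so an annulus can be expressed
#' as an outer ring plus an inner ring. Pixel centers fall on integer
#' coordinates; a pixel belongs to the polygon when its center is inside.
#'
#' @name polygons
#' @keywords internal
NULL

as_rings <- function(polygon) {
  if (is.data.frame(polygon) || is.matrix(polygon)) polygon <- list(polygon)
  lapply(polygon, function(ring) {
    ring <- as.matrix(as.data.frame(ring)[, c("x", "y")])
    storage.mode(ring) <- "double"
    if (nrow(ring) < 3L) stop("polygon ring needs at least 3 vertices")
    ring
  })
}

# Edges of all rings as a matrix with columns x1, y1, x2, y2.
ring_edges <- function(rings) {
  do.call(rbind, lapply(rings, function(r) {
    nxt <- c(seq_len(nrow(r))[-1L], 1L)
    cbind(r[, 1L], r[, 2L], r[nxt, 1L], r[nxt, 2L])
  }))
}

#' Test points against a polygon (even-odd rule)
#'
#' @param x,y numeric vectors of point coordinates.
#' @param polygon a ring or list of rings (see [polygons]).
#' @return logical vector, `TRUE` where the point lies inside.
#' @export
point_in_polygon <- function(x, y, polygon) {
  e <- ring_edges(as_rings(polygon))
  inside <- logical(length(x))
  for (k in seq_len(nrow(e))) {
    x1 <- e[k, 1L]; y1 <- e[k, 2L]; x2 <- e[k, 3L]; y2 <- e[k, 4L]
    crosses <- (y1 <= y) != (y2 <= y)
    if (any(crosses)) {
      xc <- x1 + (y[crosses] - y1) * (x2 - x1) / (y2 - y1)
      inside[crosses] <- xor(inside[crosses], xc < x[crosses])
    }
  }
  inside
}

#' Rasterize a polygon to a logical mask
#'
#' Scanline even-odd fill: a pixel is set when its center (integer column =
#' x, integer row = y) lies inside the polygon.
#'
#' @param polygon a ring or list of rings.
#' @param shape integer vector `c(nrow, ncol)` of the target mask.
#' @return logical matrix of dimension `shape`.
#' @export
rasterize_polygon <- function(polygon, shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("shape must be c(nrow, ncol)")
  e <- ring_edges(as_rings(polygon))
  mask <- matrix(FALSE, shape[1L], shape[2L])
  cols <- seq_len(shape[2L])
  for (row in seq_len(shape[1L])) {
    y <- as.numeric(row)
    crosses <- (e[, 2L] <= y) != (e[, 4L] <= y)
    if (!any(crosses)) next
    xc <- e[crosses, 1L] +
      (y - e[crosses, 2L]) * (e[crosses, 3L] - e[crosses, 1L]) /
        (e[crosses, 4L] - e[crosses, 2L])
    mask[row, ] <- (findInterval(cols, sort(xc), left.open = TRUE) %% 2L) == 1L
  }
  mask
}

# TRUE if any two non-adjacent edges of a single ring properly intersect.
ring_self_intersects <- function(ring) {
  e <- ring_edges(list(ring))
  n <- nrow(e)
  seg_int <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (seg_int(e[i, ], e[j, ])) return(TRUE)
    }
  }
  FALSE
}

validate_polygon <- function(polygon, name = "polygon") {
  rings <- as_rings(polygon)
  for (r in rings) {
    if (ring_self_intersects(r)) stop(name, " is self-intersecting")
  }
  invisible(rings)
}
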
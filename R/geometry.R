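# Planar geometry helpers shared by the tessellation and oxygen modules.
# Polygons are plain data frames / matrices with columns x, y, vertices in
# order (either orientation), implicitly closed.

#' Polygon area by the shoelace formula
#'
#' @param x,y Numeric vectors of vertex coordinates (polygon implicitly
#'   closed; either orientation).
#' @return Absolute area in the square of the coordinate unit.
#' @keywords internal
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Clip a convex polygon to the half-plane {p : (p - m) . nrm <= 0}
# (Sutherland-Hodgman against a single edge). Returns a list(x, y);
# empty vectors when the polygon is entirely outside.
clip_halfplane <- function(px, py, mx, my, nx, ny) {
  n <- length(px)
  d <- (px - mx) * nx + (py - my) * ny
  if (all(d <= 0)) return(list(x = px, y = py))
  if (all(d > 0)) return(list(x = numeric(0), y = numeric(0)))
  outx <- numeric(2L * n)
  outy <- numeric(2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 0
    djn <- d[j] <= 0
    if (din) {
      k <- k + 1L; outx[k] <- px[i]; outy[k] <- py[i]
    }
    if (din != djn) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      outx[k] <- px[i] + t * (px[j] - px[i])
      outy[k] <- py[i] + t * (py[j] - py[i])
    }
  }
  list(x = outx[seq_len(k)], y = outy[seq_len(k)])
}

# Points-in-polygon test (TRUE when inside), vectorised over points.
# mgcv::in.out expects the boundary as a two-column matrix.
points_in_polygon <- function(px, py, poly_x, poly_y) {
  bnd <- cbind(c(poly_x, poly_x[1L]), c(poly_y, poly_y[1L]))
  as.logical(mgcv::in.out(bnd, cbind(px, py)))
}

# Regular closed polygon approximating a circle (for disk-geometry solves).
circle_polygon <- function(cx, cy, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  tibble(x = cx + r * cos(th), y = cy + r * sin(th))
}
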
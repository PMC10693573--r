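# Closed-polygon geometry helpers. Polygons are n x 2 matrices of (x, y)
# vertices, implicitly closed (last vertex joins the first), vertices in
# order along the boundary.

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(poly) {
  d <- poly[c(2:nrow(poly), 1L), , drop = FALSE] - poly
  sum(sqrt(rowSums(d^2)))
}

convex_hull_perimeter <- function(poly) {
  h <- grDevices::chull(poly[, 1], poly[, 2])
  polygon_perimeter(poly[h, , drop = FALSE])
}

# maximum Feret diameter = largest pairwise vertex distance (attained on the
# convex hull, so compute there)
max_feret <- function(poly) {
  h <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
  if (nrow(h) < 2L) return(0)
  d2 <- as.matrix(stats::dist(h))
  max(d2)
}

# TRUE when no two non-adjacent edges properly intersect (simple polygon).
# O(n^2) pairs but vectorized over the inner index.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  cross <- function(ax, ay, bx, by, cx, cy) {
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  }
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    j <- j[j != i %% n + 1L & i != j %% n + 1L]
    if (length(j) == 0L) next
    d1 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d2 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    d3 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d4 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    hit <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
    if (any(hit)) return(FALSE)
  }
  TRUE
}

# Resample a closed boundary to n points equally spaced in arc length.
resample_closed <- function(poly, n = 128L) {
  closed <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  t_out <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(s, closed[, 1], xout = t_out, ties = "ordered")$y
  y <- stats::approx(s, closed[, 2], xout = t_out, ties = "ordered")$y
  cbind(x, y)
}

# circular moving-average smoothing of a closed boundary; window in points
smooth_closed <- function(poly, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(poly)
  n <- nrow(poly)
  h <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, k) ((i + k - 1L) %% n) + 1L)
  cbind(rowMeans(matrix(poly[idx, 1], n)), rowMeans(matrix(poly[idx, 2], n)))
}

# mean absolute discrete curvature of a closed, equally-spaced boundary
mean_abs_curvature <- function(poly) {
  n <- nrow(poly)
  ip <- c(n, 1:(n - 1L)); inx <- c(2:n, 1L)
  dx <- (poly[inx, 1] - poly[ip, 1]) / 2
  dy <- (poly[inx, 2] - poly[ip, 2]) / 2
  ddx <- poly[inx, 1] - 2 * poly[, 1] + poly[ip, 1]
  ddy <- poly[inx, 2] - 2 * poly[, 2] + poly[ip, 2]
  denom <- (dx^2 + dy^2)^1.5
  k <- abs(dx * ddy - dy * ddx) / pmax(denom, .Machine$double.eps)
  mean(k)
}

# vectorized even-odd point-in-polygon test
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}
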
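# Independent brute-force oracles used across the suite. Each one states the
# defining property directly and is kept separate from the implementation
# path it checks.

# nearest-rank percentile as "smallest observed z whose empirical CDF reaches
# the level" — scans candidate values instead of indexing a sorted vector
oracle_percentile <- function(z, level) {
  cand <- sort(unique(z))
  n <- length(z)
  for (v in cand) {
    # epsilon guards the comparison when level * n is an exact integer
    if (sum(z <= v) >= level * n - 1e-9) return(v)
  }
  cand[length(cand)]
}

# exhaustive per-point max-height scan for one raster cell
oracle_cell_max <- function(cloud, origin, cell_size, ix, iy) {
  in_cell <- floor((cloud$x - origin[1]) / cell_size) == (ix - 1) &
    floor((cloud$y - origin[2]) / cell_size) == (iy - 1)
  if (!any(in_cell)) return(NA_real_)
  max(cloud$z[in_cell])
}

# crossing-number point-in-polygon (scalar, boundary-inclusive via explicit
# on-segment test with exact arithmetic on the test polygons)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    if (abs(cross) < 1e-12 &&
        px >= min(ax, bx) - 1e-12 && px <= max(ax, bx) + 1e-12 &&
        py >= min(ay, by) - 1e-12 && py <= max(ay, by) + 1e-12)
      return(TRUE)
  }
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ay <- poly[i, 2]; by <- poly[j, 2]
    if ((ay > py) != (by > py)) {
      xint <- poly[i, 1] + (py - ay) / (by - ay) * (poly[j, 1] - poly[i, 1])
      if (px < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# O(n^2) max pairwise horizontal distance
oracle_max_pairwise_xy <- function(cloud) {
  xy <- cbind(cloud$x, cloud$y)
  best <- 0
  for (i in seq_len(nrow(xy) - 1)) {
    d2 <- (xy[-(1:i), 1] - xy[i, 1])^2 + (xy[-(1:i), 2] - xy[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# quadratic-scan extrema + prominence: for each interior strict extremum,
# walk outward to the nearest strictly higher (for maxima) sample on each
# side and take the in-between minima as bases
oracle_extrema <- function(times, values, min_prominence) {
  n <- length(values)
  res <- NULL
  for (i in 2:(n - 1)) {
    kind <- if (values[i] > values[i - 1] && values[i] > values[i + 1]) "max"
    else if (values[i] < values[i - 1] && values[i] < values[i + 1]) "min"
    else next
    v <- if (kind == "max") values else -values
    li <- i
    while (li > 1 && v[li - 1] <= v[i]) li <- li - 1
    ri <- i
    while (ri < n && v[ri + 1] <= v[i]) ri <- ri + 1
    prom <- v[i] - max(min(v[li:i]), min(v[i:ri]))
    if (prom >= min_prominence)
      res <- rbind(res, data.frame(index = i, kind = kind, prominence = prom))
  }
  res
}

# coarse grid-search minimizer of the geometric sphere objective
oracle_sphere_grid <- function(cloud, center0, halfwidth = 1e-3, step = 1e-4) {
  m <- cbind(cloud$x, cloud$y, cloud$z)
  offs <- seq(-halfwidth, halfwidth, by = step)
  best <- list(obj = Inf)
  for (dx in offs) for (dy in offs) for (dz in offs) {
    c0 <- center0 + c(dx, dy, dz)
    rho <- sqrt((m[, 1] - c0[1])^2 + (m[, 2] - c0[2])^2 + (m[, 3] - c0[3])^2)
    r <- mean(rho)  # optimal radius for fixed center
    obj <- sum((rho - r)^2)
    if (obj < best$obj) best <- list(obj = obj, center = c0, radius = r)
  }
  best
}

random_rotation <- function(max_angle_rad) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_angle_rad)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

random_cloud <- function(n, xr = c(-1, 1), yr = c(-1, 1), zr = c(0, 3)) {
  point_cloud(stats::runif(n, xr[1], xr[2]), stats::runif(n, yr[1], yr[2]),
              stats::runif(n, zr[1], zr[2]))
}
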
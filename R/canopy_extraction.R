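## Canopy isolation: 2D max-height rasters for frame definition, frame
## clipping with trunk exclusion, and horizontal crown extent.

#' Rasterize maximum height
#'
#' Builds a 2D grid over the cloud's xy bounding box whose cells hold the
#' maximum z of the points they contain (a simple canopy height model).
#' Cells are half-open: a point on a cell's upper x/y boundary belongs to
#' the next cell, and the grid is padded so the maximum point is strictly
#' covered. Empty cells carry NA.
#'
#' @param cloud a non-empty \code{point_cloud}.
#' @param cell_size cell edge length in meters (default 0.10).
#' @return a \code{height_raster}: list with \code{origin} (xy of the min
#'   corner), \code{cell_size}, and \code{grid} (matrix, rows = x index,
#'   cols = y index, NA = no data).
#' @export
rasterize_max_height <- function(cloud, cell_size = 0.10) {
  cloud <- as_point_cloud(cloud)
  stop_if_empty(cloud, "rasterize_max_height")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be positive", call. = FALSE)
  ox <- min(cloud$x); oy <- min(cloud$y)
  ix <- floor((cloud$x - ox) / cell_size) + 1L
  iy <- floor((cloud$y - oy) / cell_size) + 1L
  nx <- max(ix); ny <- max(iy)
  grid <- matrix(NA_real_, nrow = nx, ncol = ny)
  key <- (iy - 1L) * nx + ix
  mx <- tapply(cloud$z, key, max)
  grid[as.integer(names(mx))] <- mx
  structure(list(origin = c(x = ox, y = oy), cell_size = cell_size,
                 grid = grid),
            class = "height_raster")
}

#' Export a height raster as an ESRI ASCII grid
#' @param raster a \code{height_raster}.
#' @param path output path.
#' @param nodata no-data value written for empty cells (default -9999).
#' @export
write_esri_ascii <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  nx <- nrow(g); ny <- ncol(g)
  hdr <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
           sprintf("xllcorner %.6f", raster$origin[["x"]]),
           sprintf("yllcorner %.6f", raster$origin[["y"]]),
           sprintf("cellsize %.6f", raster$cell_size),
           sprintf("NODATA_value %s", format(nodata)))
  g[is.na(g)] <- nodata
  # ESRI rows run north -> south: highest y index first
  rows <- vapply(rev(seq_len(ny)), function(j)
    paste(sprintf("%.4f", g[, j]), collapse = " "), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Construct a canopy frame
#'
#' A canopy frame isolates one tree's crown: a simple (non-self-intersecting)
#' 2D outline polygon plus vertical limits. \code{z_min} implements the
#' trunk-exclusion floor; the identical frame is applied to every scan epoch
#' so that height-percentile changes reflect movement, not windowing.
#'
#' @param outline n x 2 matrix (or data frame with x, y) of polygon vertices
#'   in order, meters; the closing vertex may be repeated or omitted.
#' @param z_min,z_max vertical limits in meters, \code{z_min < z_max}.
#' @param tree_id optional tree identifier.
#' @return a \code{canopy_frame}.
#' @export
canopy_frame <- function(outline, z_min, z_max, tree_id = "tree") {
  outline <- as.matrix(outline)[, 1:2, drop = FALSE]
  storage.mode(outline) <- "double"
  # drop a repeated closing vertex
  n <- nrow(outline)
  if (n >= 2 && all(outline[1, ] == outline[n, ]))
    outline <- outline[-n, , drop = FALSE]
  if (nrow(outline) < 3)
    stop("outline polygon needs at least 3 distinct vertices", call. = FALSE)
  if (!polygon_is_simple(outline))
    stop("outline polygon is self-intersecting", call. = FALSE)
  if (!(z_min < z_max))
    stop("z_min must be strictly below z_max", call. = FALSE)
  structure(list(tree_id = as.character(tree_id), outline = outline,
                 z_min = as.numeric(z_min), z_max = as.numeric(z_max)),
            class = "canopy_frame")
}

# segment-intersection test over all non-adjacent edge pairs (small polygons)
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
      q <- seg[j, 1:2]; s <- seg[j, 3:4] - q
      denom <- cross2(r[1], r[2], s[1], s[2])
      qp <- q - p
      if (abs(denom) < 1e-300) next  # parallel; overlap ignored for frames
      t <- cross2(qp[1], qp[2], s[1], s[2]) / denom
      u <- cross2(qp[1], qp[2], r[1], r[2]) / denom
      if (t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12)
        return(FALSE)
    }
  }
  TRUE
}

# Boundary-inclusive point-in-polygon, vectorized over points.
# Crossing-number parity with an explicit on-segment test.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # point on segment (i,j)?
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tpar <- ((px - xi) * dx + (py - yi) * dy) / len2
      tpar <- pmin(1, pmax(0, tpar))
      ex <- xi + tpar * dx - px
      ey <- yi + tpar * dy - py
      on_edge <- on_edge | (ex * ex + ey * ey <= (1e-12)^2)
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Clip a scan to a canopy frame
#'
#' Retains exactly the points whose xy falls inside or on the outline and
#' whose z lies in \code{[z_min, z_max]} (both boundaries inclusive).
#' Applying the same frame to every epoch implements the constant-window
#' requirement of percentile-displacement analysis.
#'
#' @param cloud a \code{point_cloud}.
#' @param frame a \code{canopy_frame}.
#' @param scan_id optional id used in the empty-result warning.
#' @return the clipped \code{point_cloud} (possibly empty, with a warning).
#' @export
clip_to_frame <- function(cloud, frame, scan_id = NULL) {
  cloud <- as_point_cloud(cloud)
  keep <- cloud$z >= frame$z_min & cloud$z <= frame$z_max
  keep[keep] <- points_in_polygon(cloud$x[keep], cloud$y[keep], frame$outline)
  out <- cloud[keep, , drop = FALSE]
  class(out) <- c("point_cloud", "data.frame")
  if (nrow(out) == 0)
    warning(sprintf("canopy frame '%s' clipped scan%s to an empty cloud",
                    frame$tree_id,
                    if (is.null(scan_id)) "" else sprintf(" '%s'", scan_id)),
            call. = FALSE)
  out
}

#' Maximum crown diameter
#'
#' Maximum horizontal (xy) extent of a cloud: the diameter of its xy convex
#' hull. Exact pairwise maximum for n <= 2000 points; above that the hull is
#' taken first (via \code{grDevices::chull}) and the pairwise maximum is
#' computed over hull vertices only, which is exact for the hull diameter.
#'
#' @param cloud a \code{point_cloud} with >= 2 points.
#' @return diameter in meters.
#' @export
max_crown_diameter <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 2)
    stop("crown diameter needs at least 2 points", call. = FALSE)
  xy <- cbind(cloud$x, cloud$y)
  if (nrow(xy) > 2000) {
    h <- grDevices::chull(xy[, 1], xy[, 2])
    xy <- xy[h, , drop = FALSE]
  }
  if (nrow(xy) == 2) return(sqrt(sum((xy[1, ] - xy[2, ])^2)))
  max(stats::dist(xy))
}

## -- frame serialization ----------------------------------------------------

#' Format a canopy frame outline as WKT POLYGON
#' @param frame a \code{canopy_frame}.
#' @return WKT string.
#' @export
frame_to_wkt <- function(frame) {
  v <- rbind(frame$outline, frame$outline[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", v[, 1], v[, 2]), collapse = ", "))
}

parse_wkt_polygon <- function(wkt) {
  m <- regmatches(wkt, regexec("POLYGON\\s*\\(\\(([^)]*)\\)\\)", wkt))[[1]]
  if (length(m) < 2)
    stop(sprintf("cannot parse WKT POLYGON: %s", wkt), call. = FALSE)
  pairs <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
  do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
}

#' Read a canopy frame from JSON
#'
#' Expects \code{{tree_id, outline: "POLYGON ((...))", z_min, z_max}}.
#' @param path JSON path.
#' @return a \code{canopy_frame}.
#' @export
read_canopy_frame <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  canopy_frame(parse_wkt_polygon(j$outline), j$z_min, j$z_max,
               tree_id = if (is.null(j$tree_id)) "tree" else j$tree_id)
}

#' Write a canopy frame to JSON
#' @param frame a \code{canopy_frame}.
#' @param path output JSON path.
#' @export
write_canopy_frame <- function(frame, path) {
  jsonlite::write_json(list(tree_id = frame$tree_id,
                            outline = frame_to_wkt(frame),
                            z_min = frame$z_min, z_max = frame$z_max),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
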
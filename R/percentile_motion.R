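## Height-percentile thresholds, the first-scan displacement baseline, the
## narrow-slab (<50% of max crown diameter) validity rule, and the mean
## displacement series.

#' Default percentile levels (deciles 0.1 ... 0.9)
#' @return numeric vector of levels.
#' @export
default_levels <- function() seq(0.1, 0.9, by = 0.1)

#' Height-percentile thresholds of a cloud
#'
#' Nearest-rank convention: the threshold for level l is the z of the point
#' at ascending rank ceiling(l * n). For n a multiple of 1/spacing this makes
#' the inter-threshold slabs hold exactly equal point counts (e.g. 10% each
#' for deciles); in general counts are within 1 of l * n. Thresholds are
#' non-decreasing in level by construction, and well-defined under ties.
#'
#' @param cloud a non-empty \code{point_cloud}.
#' @param levels strictly increasing fractions in (0, 1).
#' @return a \code{percentile_heights}: list with \code{levels} and
#'   \code{heights} (named numeric, meters).
#' @export
percentile_heights <- function(cloud, levels = default_levels()) {
  cloud <- as_point_cloud(cloud)
  stop_if_empty(cloud, "percentile_heights")
  check_levels(levels)
  zs <- sort(cloud$z)
  n <- length(zs)
  # guard the ceiling against floating error when l * n is an exact integer
  ranks <- pmax(1L, pmin(n, as.integer(ceiling(levels * n * (1 - 1e-12)))))
  h <- zs[ranks]
  structure(list(levels = levels,
                 heights = stats::setNames(h, format_level(levels))),
            class = "percentile_heights")
}

check_levels <- function(levels) {
  if (length(levels) == 0 || any(levels <= 0) || any(levels >= 1) ||
      any(diff(levels) <= 0))
    stop("levels must be strictly increasing fractions in (0, 1)",
         call. = FALSE)
  invisible(levels)
}

format_level <- function(levels) sprintf("p%02d", round(levels * 100))

#' Horizontal extent of a height slab
#'
#' \code{\link{max_crown_diameter}} applied to the points with
#' \code{z_lo <= z < z_hi}. A slab with fewer than 2 points is reported as
#' zero extent (treated as narrow by the validity rule).
#'
#' @param cloud a \code{point_cloud}.
#' @param z_lo,z_hi slab bounds in meters, \code{z_lo < z_hi}.
#' @return slab extent in meters.
#' @export
slab_extent <- function(cloud, z_lo, z_hi) {
  if (!(z_lo < z_hi)) stop("z_lo must be below z_hi", call. = FALSE)
  cloud <- as_point_cloud(cloud)
  sel <- cloud$z >= z_lo & cloud$z < z_hi
  if (sum(sel) < 2) return(0)
  sub <- cloud[sel, , drop = FALSE]
  class(sub) <- c("point_cloud", "data.frame")
  max_crown_diameter(sub)
}

#' Percentile validity flags from the baseline scan
#'
#' A level is invalid when its slab — the height interval between the
#' previous threshold (or the cloud minimum for the first level) and its own
#' threshold, half-open above — is narrower across than 50% of the baseline
#' cloud's maximum crown diameter. This excludes trunk and crown-apex slabs,
#' whose equal point counts spread over a wide height interval and amplify
#' displacement artifacts. Flags are computed once on the baseline and held
#' fixed for the whole series.
#'
#' @param baseline_cloud the clipped first-scan \code{point_cloud}.
#' @param levels percentile levels.
#' @param width_fraction narrowness cutoff as a fraction of the maximum crown
#'   diameter (default 0.5).
#' @return named logical vector, TRUE = valid.
#' @export
percentile_validity <- function(baseline_cloud, levels = default_levels(),
                                width_fraction = 0.5) {
  baseline_cloud <- as_point_cloud(baseline_cloud)
  stop_if_empty(baseline_cloud, "percentile_validity")
  check_levels(levels)
  ph <- percentile_heights(baseline_cloud, levels)$heights
  dmax <- max_crown_diameter(baseline_cloud)
  lo <- c(min(baseline_cloud$z), ph[-length(ph)])
  valid <- vapply(seq_along(levels), function(i) {
    hi <- ph[i]
    if (!(lo[i] < hi)) {
      ext <- 0  # degenerate slab (ties): treat as narrow
    } else {
      # half-open (lo, hi]; include the lower bound for the lowest slab so the
      # bottom point is not orphaned
      sel <- if (i == 1)
        baseline_cloud$z >= lo[i] & baseline_cloud$z <= hi
      else
        baseline_cloud$z > lo[i] & baseline_cloud$z <= hi
      if (sum(sel) < 2) return(FALSE)
      sub <- baseline_cloud[sel, , drop = FALSE]
      class(sub) <- c("point_cloud", "data.frame")
      ext <- max_crown_diameter(sub)
    }
    ext >= width_fraction * dmax
  }, TRUE)
  names(valid) <- format_level(levels)
  if (!any(valid))
    stop("all percentile levels invalid: canopy frame is likely wrong",
         call. = FALSE)
  valid
}

#' Percentile displacement series relative to the first scan
#'
#' Clips every epoch to the same canopy frame, computes nearest-rank
#' percentile heights per epoch, and subtracts the first-scan baseline.
#' Upward movement is positive. The mean displacement per epoch averages
#' the levels flagged valid on the baseline (invalid-level curves are
#' retained for plotting but excluded from the mean).
#'
#' @param series a registered \code{scan_series} with >= 2 scans.
#' @param frame the tree's \code{canopy_frame}.
#' @param levels percentile levels.
#' @param width_fraction narrowness cutoff passed to
#'   \code{\link{percentile_validity}}.
#' @return a \code{displacement_series}: list with \code{tree_id},
#'   \code{scan_ids}, \code{times_h} (hours since first scan),
#'   \code{displacement} (epoch x level matrix, meters),
#'   \code{valid_levels} (named logical), and \code{mean_displacement}
#'   (numeric per epoch, meters).
#' @export
displacement_series <- function(series, frame, levels = default_levels(),
                                width_fraction = 0.5) {
  if (length(series) < 2)
    stop("displacement analysis needs at least 2 scans", call. = FALSE)
  check_levels(levels)
  ids <- series_ids(series)
  clipped <- lapply(seq_along(ids), function(i) {
    cl <- suppressWarnings(clip_to_frame(series$records[[i]]$cloud, frame, ids[i]))
    if (nrow(cl) == 0)
      stop(sprintf("scan '%s': canopy frame '%s' yields an empty cloud",
                   ids[i], frame$tree_id), call. = FALSE)
    cl
  })
  hmat <- t(vapply(clipped, function(cl) percentile_heights(cl, levels)$heights,
                   numeric(length(levels))))
  disp <- sweep(hmat, 2, hmat[1, ])
  disp[1, ] <- 0  # baseline epoch is exactly zero by definition
  valid <- percentile_validity(clipped[[1]], levels, width_fraction)
  rownames(disp) <- ids
  mean_disp <- rowMeans(disp[, valid, drop = FALSE])
  structure(list(tree_id = frame$tree_id, scan_ids = ids,
                 times_h = series_hours(series), levels = levels,
                 displacement = disp, valid_levels = valid,
                 mean_displacement = mean_disp),
            class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf(
    "displacement_series '%s': %d epochs over %.2f h, %d/%d valid levels\n",
    x$tree_id, length(x$times_h), max(x$times_h),
    sum(x$valid_levels), length(x$valid_levels)))
  cat(sprintf("  mean displacement range: [%.2f, %.2f] cm\n",
              min(x$mean_displacement) * 100, max(x$mean_displacement) * 100))
  invisible(x)
}

#' Long-format table of a displacement series
#'
#' One row per (epoch, level): \code{tree_id, scan_id, time_h, level,
#' displacement_m, valid, mean_displacement_m} (the mean repeats across
#' levels within an epoch).
#'
#' @param dseries a \code{displacement_series}.
#' @return data frame in long format.
#' @export
displacement_table <- function(dseries) {
  nl <- length(dseries$levels); ne <- length(dseries$times_h)
  data.frame(
    tree_id = dseries$tree_id,
    scan_id = rep(dseries$scan_ids, times = nl),
    time_h = rep(dseries$times_h, times = nl),
    level = rep(dseries$levels, each = ne),
    displacement_m = as.vector(dseries$displacement),
    valid = rep(unname(dseries$valid_levels), each = ne),
    mean_displacement_m = rep(dseries$mean_displacement, times = nl),
    stringsAsFactors = FALSE)
}

#' Write a displacement series as long-format CSV
#' @param dseries a \code{displacement_series}.
#' @param path output CSV path.
#' @export
write_displacement_csv <- function(dseries, path) {
  utils::write.csv(displacement_table(dseries), path, row.names = FALSE)
  invisible(path)
}
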
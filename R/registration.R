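## Sphere-target rigid registration against a fixed first scan.
## All lengths in meters.

#' Fit a sphere to a point cloud
#'
#' Two-stage fit: an algebraic linear initialization followed by geometric
#' (orthogonal-distance) Gauss-Newton refinement of the objective
#' sum((||p - c|| - r)^2). Iteration stops when the parameter step drops
#' below 1e-10 m or after 100 iterations.
#'
#' @param points a \code{point_cloud} with >= 4 non-coplanar points.
#' @param initial optional list with \code{center} (length-3) and
#'   \code{radius} to seed the refinement; defaults to the algebraic fit.
#' @return a \code{sphere_fit}: list with \code{center}, \code{radius},
#'   \code{rms_residual}, \code{n_points}.
#' @export
fit_sphere <- function(points, initial = NULL) {
  m <- xyz_matrix(as_point_cloud(points))
  n <- nrow(m)
  if (n < 4)
    stop("sphere fit needs at least 4 points", call. = FALSE)
  ctr <- sweep(m, 2, colMeans(m))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-12 * max(sv[1], 1e-300))
    stop("sphere fit: points are (near-)coplanar, geometry degenerate",
         call. = FALSE)
  if (is.null(initial)) {
    # algebraic: ||p||^2 = 2 p.c + (r^2 - ||c||^2)
    A <- cbind(2 * m, 1)
    b <- rowSums(m^2)
    beta <- qr.solve(A, b)
    c0 <- beta[1:3]
    r0 <- sqrt(max(beta[4] + sum(c0^2), .Machine$double.eps))
  } else {
    c0 <- as.numeric(initial$center); r0 <- as.numeric(initial$radius)
  }
  par <- c(c0, r0)
  for (it in seq_len(100)) {
    d <- sweep(m, 2, par[1:3])
    rho <- sqrt(rowSums(d^2))
    rho[rho < 1e-300] <- 1e-300
    res <- rho - par[4]
    J <- cbind(-d / rho, -1)
    step <- tryCatch(qr.solve(crossprod(J), -crossprod(J, res)),
                     error = function(e) rep(0, 4))
    par <- par + as.numeric(step)
    if (sqrt(sum(step^2)) < 1e-10) break
  }
  d <- sweep(m, 2, par[1:3])
  res <- sqrt(rowSums(d^2)) - par[4]
  structure(list(center = unname(par[1:3]), radius = unname(par[4]),
                 rms_residual = sqrt(mean(res^2)), n_points = n),
            class = "sphere_fit")
}

#' Least-squares rigid transform between corresponding 3D points
#'
#' Estimates rotation R (proper, det +1) and translation t minimizing
#' sum(||R s_i + t - d_i||^2) over paired source/target centers, via the
#' SVD of the cross-covariance (Kabsch). No scale is fitted.
#'
#' @param source_centers,target_centers n x 3 matrices (or data frames with
#'   x, y, z) of corresponding points, n >= 3, not collinear.
#' @return a \code{rigid_transform}: list with \code{rotation} (3 x 3) and
#'   \code{translation} (length 3).
#' @export
estimate_rigid_transform <- function(source_centers, target_centers) {
  S <- as_center_matrix(source_centers)
  D <- as_center_matrix(target_centers)
  if (nrow(S) != nrow(D))
    stop("source and target center lists differ in length", call. = FALSE)
  if (nrow(S) < 3)
    stop("rigid transform needs at least 3 correspondences", call. = FALSE)
  cs <- colMeans(S); cd <- colMeans(D)
  S0 <- sweep(S, 2, cs); D0 <- sweep(D, 2, cd)
  sv <- svd(S0, nu = 0, nv = 0)$d
  if (sv[2] < 1e-12 * max(sv[1], 1e-300))
    stop("rigid transform: centers are (near-)collinear, geometry degenerate",
         call. = FALSE)
  H <- crossprod(S0, D0)
  dec <- svd(H)
  sgn <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, sgn)) %*% t(dec$u)
  t <- cd - as.numeric(R %*% cs)
  rigid_transform(R, t)
}

#' Construct a rigid transform
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 numeric, meters.
#' @return a \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a \code{rigid_transform}.
#' @param x a \code{point_cloud} or n x 3 matrix.
#' @return same type as the input.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "point_cloud")) {
    m <- xyz_matrix(x) %*% t(transform$rotation)
    m <- sweep(m, 2, transform$translation, `+`)
    out <- x
    out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
    return(out)
  }
  m <- as_center_matrix(x) %*% t(transform$rotation)
  sweep(m, 2, transform$translation, `+`)
}

#' Invert a rigid transform
#' @param transform a \code{rigid_transform}.
#' @return the inverse \code{rigid_transform}.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms (a then b)
#' @param a,b \code{rigid_transform}s; the result applies \code{a} first.
#' @return a \code{rigid_transform}.
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

as_center_matrix <- function(x) {
  if (is.matrix(x)) return(x[, 1:3, drop = FALSE])
  if (inherits(x, "point_cloud") || is.data.frame(x))
    return(cbind(x$x, x$y, x$z))
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  stop("cannot interpret centers", call. = FALSE)
}

#' Registration tension between aligned target sets
#'
#' Mean Euclidean distance between transformed source centers and their
#' target counterparts — the residual "tension" left after rigid alignment.
#'
#' @param transform a \code{rigid_transform} mapping source into the target
#'   frame.
#' @param source_centers,target_centers corresponding centers (n x 3).
#' @return mean residual distance in meters.
#' @export
registration_tension <- function(transform, source_centers, target_centers) {
  S <- apply_transform(transform, as_center_matrix(source_centers))
  D <- as_center_matrix(target_centers)
  mean(sqrt(rowSums((S - D)^2)))
}

#' Register a scan series to its fixed first scan
#'
#' The first scan is held fixed; every later scan is rigidly aligned onto it
#' using reference-target centers matched by label. Targets present in a scan
#' but absent from the first scan (or vice versa) are dropped; fewer than 3
#' shared labels is an error naming the scan.
#'
#' @param series a \code{scan_series}.
#' @param targets_per_scan data frame with columns
#'   \code{scan_id,label,x,y,z} (meters), or a named list (by scan_id) of
#'   such frames.
#' @return list with \code{series} (registered \code{scan_series}),
#'   \code{report} (a \code{registration_report} with per-scan tension and
#'   its maximum), and \code{transforms} (named list of the applied
#'   \code{rigid_transform}s; identity for the first scan).
#' @export
register_series <- function(series, targets_per_scan) {
  tg <- normalize_targets(targets_per_scan)
  ids <- series_ids(series)
  ref_id <- ids[1]
  ref <- tg[tg$scan_id == ref_id, , drop = FALSE]
  if (nrow(ref) < 3)
    stop(sprintf("reference scan '%s' has %d targets; need >= 3",
                 ref_id, nrow(ref)), call. = FALSE)
  tension <- stats::setNames(numeric(length(ids)), ids)
  transforms <- stats::setNames(vector("list", length(ids)), ids)
  out_records <- series$records
  transforms[[ref_id]] <- rigid_transform()
  for (i in seq_along(ids)[-1]) {
    id <- ids[i]
    cur <- tg[tg$scan_id == id, , drop = FALSE]
    shared <- intersect(ref$label, cur$label)
    missing <- setdiff(ref$label, cur$label)
    if (length(shared) < 3)
      stop(sprintf(
        "scan '%s': only %d target label(s) shared with reference (missing: %s)",
        id, length(shared), paste(missing, collapse = ", ")), call. = FALSE)
    S <- as.matrix(cur[match(shared, cur$label), c("x", "y", "z")])
    D <- as.matrix(ref[match(shared, ref$label), c("x", "y", "z")])
    tr <- estimate_rigid_transform(S, D)
    transforms[[id]] <- tr
    tension[id] <- registration_tension(tr, S, D)
    out_records[[i]]$cloud <- apply_transform(tr, out_records[[i]]$cloud)
  }
  reg <- scan_series(out_records, frame_of_reference = ref_id)
  report <- structure(list(per_scan_tension = tension,
                           max_mean_tension = max(tension)),
                      class = "registration_report")
  list(series = reg, report = report, transforms = transforms)
}

normalize_targets <- function(targets_per_scan) {
  if (is.data.frame(targets_per_scan)) {
    need <- c("scan_id", "label", "x", "y", "z")
    if (!all(need %in% names(targets_per_scan)))
      stop(sprintf("targets need columns %s", paste(need, collapse = ", ")),
           call. = FALSE)
    return(targets_per_scan)
  }
  do.call(rbind, lapply(names(targets_per_scan), function(id) {
    d <- targets_per_scan[[id]]
    d$scan_id <- id
    d
  }))
}

#' Read a targets CSV (scan_id,label,x,y,z in meters)
#' @param path CSV path.
#' @return data frame of targets.
#' @export
read_targets <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a registration report as JSON (tensions in mm)
#' @param report a \code{registration_report}.
#' @param path output JSON path.
#' @export
write_registration_report <- function(report, path) {
  jsonlite::write_json(
    list(per_scan_tension_mm = as.list(report$per_scan_tension * 1000),
         max_mean_tension_mm = report$max_mean_tension * 1000),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("registration_report: %d scans, max mean tension %.3f mm\n",
              length(x$per_scan_tension), x$max_mean_tension * 1000))
  invisible(x)
}
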
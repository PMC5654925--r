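## Seeded simulator for TLS scan series of parametric tree crowns with known
## movement, scanner ranging noise, ghost-point count fluctuation, per-scan
## rigid registration offsets, and reference-sphere targets. Defaults follow
## the study conditions: 18 scans over 12.5 h at mixed 30-min/1-h intervals,
## crowns 0.7-2.3 m wide and 1.35-3.8 m tall, 0.95 mm ranging noise,
## <= 2.3 mm per-scan registration offsets, +/- 1% ghost-point fluctuation.

#' Parametric crown specification
#'
#' @param tree_id identifier.
#' @param crown_shape one of \code{"cylinder"}, \code{"cone"},
#'   \code{"ellipsoid"}, \code{"pendulous"}. Cone tapers to an apex at the
#'   top; pendulous is widest near the top with drooping sides (weeping
#'   habit).
#' @param height total tree height, m (crown top).
#' @param crown_diameter maximum crown diameter, m.
#' @param crown_base_height height of the crown base, m
#'   (\code{< height}).
#' @param point_count number of points (>= 1000).
#' @param point_density_profile \code{"uniform"} fills the crown solid;
#'   \code{"shell"} concentrates points in the outer 15% radial shell
#'   (a scanner sees surfaces, not volumes).
#' @return a \code{tree_spec}.
#' @export
tree_spec <- function(tree_id = "tree", crown_shape = "cylinder",
                      height = 3, crown_diameter = 1.5,
                      crown_base_height = 0.6, point_count = 10000,
                      point_density_profile = "uniform") {
  crown_shape <- match.arg(crown_shape,
                           c("cylinder", "cone", "ellipsoid", "pendulous"))
  point_density_profile <- match.arg(point_density_profile,
                                     c("uniform", "shell"))
  if (!(crown_diameter > 0)) stop("crown_diameter must be > 0", call. = FALSE)
  if (!(crown_base_height < height))
    stop("crown_base_height must be below height", call. = FALSE)
  if (point_count < 1000)
    stop("point_count must be at least 1000", call. = FALSE)
  structure(list(tree_id = as.character(tree_id), crown_shape = crown_shape,
                 height = height, crown_diameter = crown_diameter,
                 crown_base_height = crown_base_height,
                 point_count = as.integer(point_count),
                 point_density_profile = point_density_profile),
            class = "tree_spec")
}

#' Generative movement model
#'
#' Vertical displacement field
#' \deqn{d(t) = a t + A_c \sin(2\pi (t - \phi_c)/P_c)
#'            + A_o \sin(2\pi (t - \phi_o)/P_o)}
#' (meters; t in hours since the first scan). \code{spatial_mode}
#' \code{"uniform"} applies d(t) to every crown point; \code{"lever_arm"}
#' scales it linearly from 0 at the crown base to 1 at the crown top
#' (branches hinged near the trunk).
#'
#' @param drift_rate m/h.
#' @param circadian_amplitude,circadian_period,circadian_phase m, h, h.
#' @param oscillation_amplitude,oscillation_period,oscillation_phase m, h, h.
#' @param spatial_mode \code{"uniform"} or \code{"lever_arm"}.
#' @return a \code{motion_model}.
#' @export
motion_model <- function(drift_rate = 0,
                         circadian_amplitude = 0, circadian_period = 10,
                         circadian_phase = 0,
                         oscillation_amplitude = 0, oscillation_period = 3,
                         oscillation_phase = 0,
                         spatial_mode = "uniform") {
  spatial_mode <- match.arg(spatial_mode, c("uniform", "lever_arm"))
  stopifnot(circadian_amplitude >= 0, oscillation_amplitude >= 0,
            circadian_period > 0, oscillation_period > 0)
  structure(list(drift_rate = drift_rate,
                 circadian_amplitude = circadian_amplitude,
                 circadian_period = circadian_period,
                 circadian_phase = circadian_phase,
                 oscillation_amplitude = oscillation_amplitude,
                 oscillation_period = oscillation_period,
                 oscillation_phase = oscillation_phase,
                 spatial_mode = spatial_mode),
            class = "motion_model")
}

#' Evaluate the scalar displacement field of a motion model
#' @param model a \code{motion_model}.
#' @param t_h hours since the first scan (vectorized).
#' @return displacement in meters at the crown top (uniform mode: at every
#'   point).
#' @export
motion_field <- function(model, t_h) {
  model$drift_rate * t_h +
    model$circadian_amplitude *
      sin(2 * pi * (t_h - model$circadian_phase) / model$circadian_period) +
    model$oscillation_amplitude *
      sin(2 * pi * (t_h - model$oscillation_phase) / model$oscillation_period)
}

#' Scanner noise model
#'
#' @param ranging_sigma per-point isotropic noise standard deviation per
#'   axis, m (default 0.00095 — sub-millimeter phase-shift ranging).
#' @param registration_sigma per-scan rigid offset budget, m: each scan's
#'   residual misregistration (rotation + translation combined, measured at
#'   scene radius) is at most this (default 0.0023).
#' @param ghost_fraction relative point-count fluctuation from ghost points
#'   (default 0.01, i.e. +/- 1%; must be < 0.05).
#' @param seed integer RNG seed.
#' @return a \code{noise_model}.
#' @export
noise_model <- function(ranging_sigma = 0.00095, registration_sigma = 0.0023,
                        ghost_fraction = 0.01, seed = 1L) {
  stopifnot(ranging_sigma >= 0, registration_sigma >= 0, ghost_fraction >= 0,
            ghost_fraction < 0.05)
  structure(list(ranging_sigma = ranging_sigma,
                 registration_sigma = registration_sigma,
                 ghost_fraction = ghost_fraction, seed = as.integer(seed)),
            class = "noise_model")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a parametric crown point cloud
#'
#' Deterministic given (spec, seed); the achieved point count equals
#' \code{spec$point_count} exactly and all points lie inside the crown solid.
#' The crown axis is the z axis through (0, 0).
#'
#' @param spec a \code{\link{tree_spec}}.
#' @param seed integer seed.
#' @return a \code{point_cloud}.
#' @export
generate_tree <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "tree_spec"))
  with_seed(seed, {
    n <- spec$point_count
    R <- spec$crown_diameter / 2
    zb <- spec$crown_base_height; zt <- spec$height
    u <- stats::runif(n)            # vertical coordinate in [0, 1]
    th <- stats::runif(n, 0, 2 * pi)
    v <- stats::runif(n)            # radial coordinate
    rel_r <- switch(spec$crown_shape,
      cylinder = rep(1, n),
      cone = 1 - u,                 # apex at top
      ellipsoid = sqrt(pmax(0, 1 - (2 * u - 1)^2)),
      pendulous = u^0.3)            # widest near the top, drooping sides
    rad_frac <- if (spec$point_density_profile == "uniform")
      sqrt(v) else 0.85 + 0.15 * v
    r <- R * rel_r * rad_frac
    point_cloud(r * cos(th), r * sin(th), zb + u * (zt - zb))
  })
}

#' Displace a crown by a motion model at time t
#'
#' Applies the vertical displacement field of \code{\link{motion_model}}:
#' uniform mode shifts every point by d(t); lever-arm mode scales the shift
#' linearly from 0 at \code{crown_base} to 1 at the crown top (the cloud's
#' max z at t = 0). Deterministic.
#'
#' @param cloud crown \code{point_cloud}.
#' @param model a \code{motion_model}.
#' @param t_h hours since the first scan (scalar).
#' @param crown_base crown base height, m (hinge of the lever arm).
#' @return displaced \code{point_cloud}.
#' @export
displace_canopy <- function(cloud, model, t_h, crown_base = 0) {
  stopifnot(t_h >= 0)
  cloud <- as_point_cloud(cloud)
  d <- motion_field(model, t_h)
  if (model$spatial_mode == "uniform") {
    cloud$z <- cloud$z + d
  } else {
    top <- max(cloud$z)
    lever <- (cloud$z - crown_base) / max(top - crown_base, 1e-12)
    cloud$z <- cloud$z + d * pmin(1, pmax(0, lever))
  }
  cloud
}

#' The 18-epoch overnight scan schedule
#'
#' Half-hourly from 6:30 p.m. to 8:00 p.m., hourly from 9:00 p.m. to
#' 4:00 a.m., then half-hourly from 4:30 a.m. to 7:00 a.m. — 18 scans
#' spanning 12.5 h.
#'
#' @param start POSIXct (or string) of the first scan.
#' @return POSIXct vector of length 18.
#' @export
default_scan_schedule <- function(start = "2016-09-16 18:30:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  offsets_h <- c(seq(0, 1.5, by = 0.5),      # 18:30 .. 20:00
                 seq(2.5, 9.5, by = 1),      # 21:00 .. 04:00
                 seq(10, 12.5, by = 0.5))    # 04:30 .. 07:00
  t0 + offsets_h * 3600
}

#' Default reference-sphere target layout
#'
#' Four spheres of radius 0.0725 m at fixed positions around the scene,
#' outside any crown, at staggered heights.
#'
#' @return data frame with \code{label, x, y, z, radius}.
#' @export
default_sphere_targets <- function() {
  data.frame(label = c("S1", "S2", "S3", "S4"),
             x = c(3, 0, -3, 0), y = c(0, 3, 0, -3),
             z = c(0.5, 1.0, 1.5, 2.0), radius = 0.0725,
             stringsAsFactors = FALSE)
}

#' Sample points on a sphere surface
#' @param center length-3 numeric, m.
#' @param radius sphere radius, m.
#' @param n number of surface points.
#' @param sigma per-axis noise sd added to each point, m.
#' @return a \code{point_cloud}.
#' @export
sample_sphere_points <- function(center, radius, n = 200, sigma = 0) {
  d <- matrix(stats::rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  m <- sweep(d * radius, 2, as.numeric(center), `+`)
  if (sigma > 0) m <- m + matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
  point_cloud(m[, 1], m[, 2], m[, 3])
}

# random small rigid offset with displacement <= budget at scene_radius
random_rigid_offset <- function(budget, scene_radius = 5) {
  if (budget <= 0) return(rigid_transform())
  m <- stats::runif(1, 0, budget)     # total offset magnitude at scene radius
  s <- stats::runif(1)                # split between rotation and translation
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- s * m / scene_radius
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  rigid_transform(Rm, (1 - s) * m * dir)
}

#' Simulate a full TLS scan series with ground truth
#'
#' Per epoch: displaces the crown by the motion model, adds isotropic
#' per-point ranging noise, perturbs the point count by up to
#' \code{ghost_fraction} (near-duplicate insertions with 3 mm jitter, or
#' random deletions), applies a random small rigid offset (budget
#' \code{registration_sigma} at scene radius) to the whole scan, and emits
#' reference-sphere target centers transformed consistently (noiseless), plus
#' optionally per-sphere surface point clouds sampled with ranging noise.
#' Fully deterministic given the seed in \code{noise}.
#'
#' @param spec a \code{\link{tree_spec}}.
#' @param model a \code{\link{motion_model}}.
#' @param noise a \code{\link{noise_model}} (its \code{seed} drives all
#'   randomness).
#' @param schedule POSIXct scan times (default the 18-epoch schedule).
#' @param sample_targets also sample \code{target_points} noisy surface
#'   points per sphere per scan (for registration from raw target scans).
#' @param target_points surface points per sphere when sampling.
#' @return list with \code{series} (a \code{scan_series}), \code{targets}
#'   (data frame \code{scan_id,label,x,y,z} of transformed noiseless
#'   centers), \code{target_clouds} (named list by scan_id of named lists by
#'   label of \code{point_cloud}s; NULL unless \code{sample_targets}), and
#'   \code{truth} (generative parameters, per-epoch rigid offsets, and the
#'   displacement field values d(t)).
#' @export
simulate_series <- function(spec, model, noise, schedule = default_scan_schedule(),
                            sample_targets = FALSE, target_points = 200) {
  stopifnot(inherits(spec, "tree_spec"), inherits(model, "motion_model"),
            inherits(noise, "noise_model"))
  schedule <- as.POSIXct(schedule, tz = "UTC")
  if (any(diff(as.numeric(schedule)) <= 0))
    stop("schedule must be strictly increasing", call. = FALSE)
  ne <- length(schedule)
  t_h <- (as.numeric(schedule) - as.numeric(schedule[1])) / 3600
  spheres <- default_sphere_targets()
  with_seed(noise$seed, {
    base <- generate_tree(spec, seed = stats::runif(1, 1, 2^30))
    records <- vector("list", ne)
    transforms <- vector("list", ne)
    target_rows <- vector("list", ne)
    target_clouds <- if (sample_targets)
      stats::setNames(vector("list", ne), sprintf("scan%02d", seq_len(ne)))
    for (i in seq_len(ne)) {
      id <- sprintf("scan%02d", i)
      cl <- displace_canopy(base, model, t_h[i], spec$crown_base_height)
      n <- nrow(cl)
      if (noise$ranging_sigma > 0) {
        cl$x <- cl$x + stats::rnorm(n, sd = noise$ranging_sigma)
        cl$y <- cl$y + stats::rnorm(n, sd = noise$ranging_sigma)
        cl$z <- cl$z + stats::rnorm(n, sd = noise$ranging_sigma)
      }
      if (noise$ghost_fraction > 0) {
        n_tgt <- round(n * (1 + stats::runif(1, -noise$ghost_fraction,
                                             noise$ghost_fraction)))
        if (n_tgt > n) {
          idx <- sample.int(n, n_tgt - n, replace = TRUE)
          ghosts <- cl[idx, , drop = FALSE]
          ghosts$x <- ghosts$x + stats::rnorm(n_tgt - n, sd = 0.003)
          ghosts$y <- ghosts$y + stats::rnorm(n_tgt - n, sd = 0.003)
          ghosts$z <- ghosts$z + stats::rnorm(n_tgt - n, sd = 0.003)
          cl <- rbind(cl, ghosts)
        } else if (n_tgt < n) {
          cl <- cl[sort(sample.int(n, n_tgt)), , drop = FALSE]
        }
        class(cl) <- c("point_cloud", "data.frame")
      }
      tr <- if (i == 1) rigid_transform() else
        random_rigid_offset(noise$registration_sigma)
      transforms[[i]] <- tr
      cl <- apply_transform(tr, cl)
      ctr <- apply_transform(tr, as.matrix(spheres[, c("x", "y", "z")]))
      target_rows[[i]] <- data.frame(scan_id = id, label = spheres$label,
                                     x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                                     stringsAsFactors = FALSE)
      if (sample_targets) {
        target_clouds[[id]] <- stats::setNames(lapply(seq_len(nrow(spheres)),
          function(k) sample_sphere_points(ctr[k, ], spheres$radius[k],
                                           n = target_points,
                                           sigma = noise$ranging_sigma)),
          spheres$label)
      }
      records[[i]] <- scan_record(id, schedule[i], cl)
    }
    names(transforms) <- sprintf("scan%02d", seq_len(ne))
    list(series = scan_series(records, frame_of_reference = "simulated"),
         targets = do.call(rbind, target_rows),
         target_clouds = if (sample_targets) target_clouds else NULL,
         truth = list(spec = spec, model = model, noise = noise,
                      times_h = t_h, field = motion_field(model, t_h),
                      transforms = transforms))
  })
}

#' Default canopy frame for a simulated crown
#'
#' Square outline around the crown with the stated margin (>= 10 cm, as
#' frames are digitized with), vertical limits from just below the crown base
#' to above the crown top with headroom for movement.
#'
#' @param spec a \code{\link{tree_spec}}.
#' @param margin horizontal margin, m (default 0.15).
#' @param headroom vertical slack above/below the crown, m (default 0.2).
#' @return a \code{canopy_frame}.
#' @export
default_canopy_frame <- function(spec, margin = 0.15, headroom = 0.2) {
  R <- spec$crown_diameter / 2 + margin
  canopy_frame(outline = cbind(c(-R, R, R, -R), c(-R, -R, R, R)),
               z_min = spec$crown_base_height - headroom,
               z_max = spec$height + headroom,
               tree_id = spec$tree_id)
}
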
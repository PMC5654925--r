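## Seeded measurement experiments over the simulator + pipeline: registration
## tension under scanner noise, the static-tree noise floor, per-class
## classification recovery, and decomposition recovery. These are the
## computations the numbered analysis scripts drive and the validation
## checks re-run.

#' One registration-tension trial under scanner noise
#'
#' Simulates the reference-sphere registration of one scan pair: the four
#' default spheres are each sampled with \code{points_per_sphere} surface
#' points at per-point noise \code{ranging_sigma}; one scan is displaced by a
#' random rigid transform (rotation up to \code{max_rot_deg}, translation up
#' to \code{max_trans}); sphere centers are fitted independently in both
#' scans, the rigid alignment back onto the reference is estimated from the
#' fitted centers, and the mean residual distance over centers (the
#' registration tension) is returned.
#'
#' @param seed integer seed.
#' @param points_per_sphere surface points per sphere (default 200).
#' @param ranging_sigma per-axis point noise, m (default 0.00095).
#' @param max_rot_deg,max_trans bounds of the random offset (default 5 deg,
#'   0.005 m).
#' @return mean tension in meters.
#' @export
registration_tension_trial <- function(seed, points_per_sphere = 200,
                                       ranging_sigma = 0.00095,
                                       max_rot_deg = 5, max_trans = 0.005) {
  with_seed(seed, {
    spheres <- default_sphere_targets()
    ctrs <- as.matrix(spheres[, c("x", "y", "z")])
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- stats::runif(1, 0, max_rot_deg * pi / 180)
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    offset <- rigid_transform(Rm, stats::runif(1, 0, max_trans) * dir)
    moved_ctrs <- apply_transform(offset, ctrs)
    fit_centers <- function(centers) {
      t(vapply(seq_len(nrow(centers)), function(k) {
        fit_sphere(sample_sphere_points(centers[k, ], spheres$radius[k],
                                        n = points_per_sphere,
                                        sigma = ranging_sigma))$center
      }, numeric(3)))
    }
    ref_fit <- fit_centers(ctrs)
    mov_fit <- fit_centers(moved_ctrs)
    tr <- estimate_rigid_transform(mov_fit, ref_fit)
    registration_tension(tr, mov_fit, ref_fit)
  })
}

#' One static-tree noise-floor trial
#'
#' Simulates a non-moving crown scanned on the 18-epoch overnight schedule
#' under the full noise model (ranging noise, ghost-point count fluctuation,
#' per-scan rigid offsets), registers every scan back onto the first via
#' sphere targets, runs the percentile-displacement pipeline, and returns the
#' maximum absolute mean displacement across epochs — the apparent movement
#' of a tree that did not move.
#'
#' @param seed integer seed.
#' @param spec crown \code{\link{tree_spec}} (default: cylinder, height 3 m,
#'   diameter 1.5 m, 50,000 points).
#' @param noise a \code{\link{noise_model}} template; its seed is replaced by
#'   \code{seed}.
#' @param register_from \code{"sphere_clouds"} fits sphere centers from
#'   noisy sampled target scans (realistic residual registration error);
#'   \code{"centers"} uses the noiseless transformed centers.
#' @return max |mean displacement| over epochs, meters.
#' @export
noise_floor_trial <- function(seed,
                              spec = tree_spec(crown_shape = "cylinder",
                                               height = 3, crown_diameter = 1.5,
                                               crown_base_height = 0.6,
                                               point_count = 50000),
                              noise = noise_model(),
                              register_from = c("sphere_clouds", "centers")) {
  register_from <- match.arg(register_from)
  noise$seed <- as.integer(seed)
  sim <- simulate_series(spec, motion_model(), noise,
                         sample_targets = register_from == "sphere_clouds")
  targets <- if (register_from == "centers") sim$targets else {
    do.call(rbind, lapply(names(sim$target_clouds), function(id) {
      tc <- sim$target_clouds[[id]]
      ctr <- t(vapply(tc, function(cl) fit_sphere(cl)$center, numeric(3)))
      data.frame(scan_id = id, label = names(tc),
                 x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                 stringsAsFactors = FALSE)
    }))
  }
  reg <- register_series(sim$series, targets)
  ds <- displacement_series(reg$series, default_canopy_frame(spec))
  max(abs(ds$mean_displacement))
}

#' Generative motion model for one movement class
#'
#' Study-condition models: sleep — 2 cm circadian amplitude, period drawn in
#' 10--12 h; drift — 5 cm over the 12.5 h window; oscillation — 0.75 cm
#' amplitude, 3 h period; noise — no movement. Phases (and the direction,
#' up/down) are drawn at random; spatial mode is uniform.
#'
#' @param class one of \code{"sleep"}, \code{"drift"}, \code{"oscillation"},
#'   \code{"noise"}.
#' @return a \code{\link{motion_model}} (draws from the current RNG stream).
#' @export
class_motion_model <- function(class) {
  sgn <- sample(c(-1, 1), 1)
  switch(match.arg(class, c("sleep", "drift", "oscillation", "noise")),
    sleep = {
      P <- stats::runif(1, 10, 12)
      motion_model(circadian_amplitude = 0.02, circadian_period = P,
                   circadian_phase = stats::runif(1, 0, P)) |>
        flip_direction(sgn)
    },
    drift = motion_model(drift_rate = sgn * 0.05 / 12.5),
    oscillation = motion_model(oscillation_amplitude = 0.0075,
                               oscillation_period = 3,
                               oscillation_phase = stats::runif(1, 0, 3)) |>
      flip_direction(sgn),
    noise = motion_model())
}

flip_direction <- function(model, sgn) {
  if (sgn >= 0) return(model)
  model$drift_rate <- -model$drift_rate
  # a sign flip is a half-period phase shift
  model$circadian_phase <- model$circadian_phase + model$circadian_period / 2
  model$oscillation_phase <- model$oscillation_phase +
    model$oscillation_period / 2
  model
}

#' One classification-recovery trial
#'
#' Simulates a crown moving per \code{\link{class_motion_model}} under the
#' full noise model, registers the series from its (noiseless) sphere-target
#' centers, extracts the mean-displacement series, classifies it, and
#' returns the primary label.
#'
#' @param class generative movement class.
#' @param seed integer seed.
#' @param point_count crown points (default 8000).
#' @return character primary label.
#' @export
classification_trial <- function(class, seed, point_count = 8000) {
  model <- with_seed(seed * 7 + 1, class_motion_model(class))
  spec <- tree_spec(crown_shape = "cylinder", height = 3,
                    crown_diameter = 1.5, crown_base_height = 0.6,
                    point_count = point_count)
  sim <- simulate_series(spec, model, noise_model(seed = seed))
  reg <- register_series(sim$series, sim$targets)
  ds <- displacement_series(reg$series, default_canopy_frame(spec))
  classify_movement(ds, decompose = FALSE)$primary_label
}

#' Classification recovery rates over seeded simulations
#'
#' @param n_per_class simulations per movement class.
#' @param base_seed offset added to the per-trial seeds.
#' @param point_count crown points per simulation.
#' @param classes classes to evaluate.
#' @return data frame with columns \code{class, n, n_correct, accuracy}.
#' @export
classification_recovery <- function(n_per_class = 100, base_seed = 0,
                                    point_count = 8000,
                                    classes = c("sleep", "drift",
                                                "oscillation", "noise")) {
  rows <- lapply(classes, function(cl) {
    labels <- vapply(seq_len(n_per_class), function(i)
      classification_trial(cl, seed = base_seed + i,
                           point_count = point_count), "")
    data.frame(class = cl, n = n_per_class, n_correct = sum(labels == cl),
               accuracy = mean(labels == cl), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One decomposition-recovery trial
#'
#' Generates a drift + circadian + oscillation mean-displacement series on
#' the 18-epoch schedule (drift 0.002 m/h, 1.5 cm circadian at 10 h, 0.6 cm
#' oscillation at 3 h, random phases), adds measurement noise of 1 mm, fits
#' \code{\link{decompose_movement}}, and returns fitted versus true
#' parameters.
#'
#' @param seed integer seed.
#' @param noise_sd measurement noise on the series, m (default 0.001).
#' @return one-row data frame with true and fitted drift rate, amplitudes
#'   and periods.
#' @export
decomposition_trial <- function(seed, noise_sd = 0.001) {
  with_seed(seed, {
    sched <- default_scan_schedule()
    t <- (as.numeric(sched) - as.numeric(sched[1])) / 3600
    true <- motion_model(drift_rate = 0.002,
                         circadian_amplitude = 0.015, circadian_period = 10,
                         circadian_phase = stats::runif(1, 0, 10),
                         oscillation_amplitude = 0.006, oscillation_period = 3,
                         oscillation_phase = stats::runif(1, 0, 3))
    d <- motion_field(true, t)
    v <- (d - d[1]) + stats::rnorm(length(t), sd = noise_sd)
    comp <- decompose_movement(list(times_h = t, mean_displacement = v))
    data.frame(seed = seed,
               drift_true = true$drift_rate, drift_fit = comp$drift_rate,
               A_c_true = true$circadian_amplitude,
               A_c_fit = comp$circadian_amplitude,
               P_c_true = true$circadian_period, P_c_fit = comp$circadian_period,
               A_o_true = true$oscillation_amplitude,
               A_o_fit = comp$oscillation_amplitude,
               P_o_true = true$oscillation_period, P_o_fit = comp$oscillation_period)
  })
}
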
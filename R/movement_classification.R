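## Four-type movement classification (sleep / drift / oscillation / noise)
## on a mean-displacement time series, plus an additive
## drift + circadian + short-period sinusoid decomposition.

#' Classification thresholds
#'
#' One config object holds every rule threshold, each with its field default:
#' \itemize{
#'   \item \code{noise_gate_m}: 0.005 m — displacement magnitudes at or below
#'     this are indistinguishable from measurement noise.
#'   \item \code{sleep_window_h}: c(8, 12) — a sleeping crown returns to its
#'     starting position 8--12 h after the first scan.
#'   \item \code{sleep_max_extrema}: 2 — sleep shows one or two clear
#'     minimum/maximum positions.
#'   \item \code{min_oscillation_extrema}: 3 — oscillation needs at least
#'     three local extrema.
#'   \item \code{comparable_factor}: 3 — extremum prominences count as
#'     "comparable" when max/min prominence <= this factor.
#'   \item \code{drift_last_n}: 2 — drift requires the position farthest from
#'     start to occur in one of the last scans (final two epochs, ~30 min
#'     apart on the half-hourly morning tail).
#' }
#'
#' @param noise_gate_m,sleep_window_h,sleep_max_extrema,min_oscillation_extrema,comparable_factor,drift_last_n see above.
#' @return a \code{classification_config} list.
#' @export
classification_config <- function(noise_gate_m = 0.005,
                                  sleep_window_h = c(8, 12),
                                  sleep_max_extrema = 2,
                                  min_oscillation_extrema = 3,
                                  comparable_factor = 3,
                                  drift_last_n = 2) {
  stopifnot(noise_gate_m > 0, length(sleep_window_h) == 2,
            sleep_window_h[1] < sleep_window_h[2],
            sleep_max_extrema >= 1, min_oscillation_extrema >= 3,
            comparable_factor >= 1, drift_last_n >= 1)
  structure(list(noise_gate_m = noise_gate_m, sleep_window_h = sleep_window_h,
                 sleep_max_extrema = sleep_max_extrema,
                 min_oscillation_extrema = min_oscillation_extrema,
                 comparable_factor = comparable_factor,
                 drift_last_n = drift_last_n),
            class = "classification_config")
}

#' Local extrema with prominence gating
#'
#' Interior samples that strictly exceed both neighbors (maxima) or fall
#' strictly below both (minima); endpoints are never extrema. Prominence of
#' a maximum is its value minus the higher of the two "base" levels, where
#' each base is the minimum of the series between the extremum and the
#' nearest sample on that side exceeding it (or the series edge); minima are
#' handled by negation. Extrema with prominence below \code{min_prominence}
#' are dropped. Irregular sampling is allowed; prominence depends on values
#' only.
#'
#' @param times_h strictly increasing sample times, hours.
#' @param values_m displacement values, meters.
#' @param min_prominence prominence gate in meters (default 0.005, the
#'   movement-detection threshold).
#' @return data frame with columns \code{time_h, value_m, kind
#'   ("min"/"max"), prominence_m, index}.
#' @export
find_local_extrema <- function(times_h, values_m, min_prominence = 0.005) {
  n <- length(values_m)
  stopifnot(length(times_h) == n, n >= 3, all(diff(times_h) > 0))
  out <- list()
  for (i in 2:(n - 1)) {
    is_max <- values_m[i] > values_m[i - 1] && values_m[i] > values_m[i + 1]
    is_min <- values_m[i] < values_m[i - 1] && values_m[i] < values_m[i + 1]
    if (!is_max && !is_min) next
    v <- if (is_max) values_m else -values_m
    prom <- extremum_prominence(v, i)
    if (prom >= min_prominence)
      out[[length(out) + 1]] <- data.frame(
        time_h = times_h[i], value_m = values_m[i],
        kind = if (is_max) "max" else "min",
        prominence_m = prom, index = i, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(time_h = numeric(0), value_m = numeric(0),
                      kind = character(0), prominence_m = numeric(0),
                      index = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# prominence of a local maximum at index i of v
extremum_prominence <- function(v, i) {
  n <- length(v)
  left <- 1
  for (k in seq(i - 1, 1)) if (v[k] > v[i]) { left <- k + 1; break }
  right <- n
  if (i + 1 <= n)
    for (k in seq(i + 1, n)) if (v[k] > v[i]) { right <- k - 1; break }
  base_left <- min(v[left:i])
  base_right <- min(v[i:right])
  v[i] - max(base_left, base_right)
}

#' Classify a mean-displacement series into the four-type framework
#'
#' Decision rules (all thresholds from \code{config}):
#' \itemize{
#'   \item \strong{noise} (exclusive): max |mean displacement| never exceeds
#'     the noise gate.
#'   \item \strong{sleep}: some epoch 8--12 h after the start lies within the
#'     noise gate of the starting position, and 1--2 prominent extrema exist.
#'     Reported "not evaluable" when the series spans less than 8 h.
#'   \item \strong{drift}: no prominent extrema, and the position farthest
#'     from start occurs in one of the last \code{drift_last_n} epochs.
#'   \item \strong{oscillation}: at least 3 prominent extrema with comparable
#'     prominences (max/min <= \code{comparable_factor}).
#' }
#' When several rules fire, the primary label is the one with the largest
#' associated amplitude (sleep: max |displacement|; drift: |end - start|;
#' oscillation: mean prominence) and the rest become secondary — superposed
#' movement forms. When the series exceeds the gate but no rule fires, the
#' largest-amplitude rule is assigned as primary with \code{fallback = TRUE}
#' in the evidence.
#'
#' @param series a \code{displacement_series} (or any list with
#'   \code{times_h} and \code{mean_displacement}).
#' @param config a \code{\link{classification_config}}.
#' @param decompose also fit \code{\link{decompose_movement}} components
#'   (default TRUE; requires >= 8 epochs).
#' @return a \code{movement_classification}: list with \code{primary_label},
#'   \code{secondary_labels}, \code{evidence} (rule booleans and the numbers
#'   that fired them), \code{extrema}, and \code{components}
#'   (\code{\link{decompose_movement}} fit, when >= 8 epochs).
#' @export
classify_movement <- function(series, config = classification_config(),
                              decompose = TRUE) {
  t <- unname(series$times_h)
  v <- unname(series$mean_displacement)
  n <- length(v)
  stopifnot(length(t) == n, n >= 3)
  gate <- config$noise_gate_m
  span_h <- max(t) - min(t)
  max_abs <- max(abs(v))

  if (max_abs <= gate) {
    return(new_classification("noise", character(0),
      evidence = list(rule_noise = TRUE, rule_sleep = FALSE,
                      rule_drift = FALSE, rule_oscillation = FALSE,
                      max_abs_displacement_m = max_abs,
                      noise_gate_m = gate, span_h = span_h),
      extrema = NULL, series = series, config = config,
      decompose = decompose))
  }

  ex <- find_local_extrema(t, v, min_prominence = gate)
  n_ex <- nrow(ex)

  sleep_evaluable <- span_h >= config$sleep_window_h[1]
  in_window <- t >= config$sleep_window_h[1] & t <= config$sleep_window_h[2]
  returned <- sleep_evaluable && any(in_window & abs(v - v[1]) <= gate)
  rule_sleep <- isTRUE(returned) && n_ex >= 1 && n_ex <= config$sleep_max_extrema

  last_idx <- seq(max(1, n - config$drift_last_n + 1), n)
  farthest_last <- which.max(abs(v)) %in% last_idx
  rule_drift <- n_ex == 0 && farthest_last

  comparable <- n_ex >= config$min_oscillation_extrema &&
    max(ex$prominence_m) <= config$comparable_factor * min(ex$prominence_m)
  rule_osc <- isTRUE(comparable)

  amp <- c(sleep = if (rule_sleep) max_abs else NA_real_,
           drift = if (rule_drift) abs(v[n] - v[1]) else NA_real_,
           oscillation = if (rule_osc) mean(ex$prominence_m) else NA_real_)
  fired <- names(amp)[!is.na(amp)]
  fallback <- length(fired) == 0
  if (fallback) {
    # nothing fires though movement exceeds the gate: assign the rule whose
    # amplitude measure is largest, so every series gets a label
    amp_all <- c(sleep = max_abs, drift = abs(v[n] - v[1]),
                 oscillation = if (n_ex > 0) mean(ex$prominence_m) else 0)
    fired <- names(which.max(amp_all))
    amp[fired] <- amp_all[fired]
  }
  primary <- names(which.max(amp[fired]))
  secondary <- setdiff(fired, primary)

  new_classification(primary, secondary,
    evidence = list(rule_noise = FALSE, rule_sleep = rule_sleep,
                    rule_drift = rule_drift, rule_oscillation = rule_osc,
                    sleep_evaluable = sleep_evaluable,
                    returned_to_start = isTRUE(returned),
                    n_prominent_extrema = n_ex,
                    farthest_in_last_epochs = farthest_last,
                    comparable_prominences = isTRUE(comparable),
                    sleep_amplitude_m = unname(amp["sleep"]),
                    drift_amplitude_m = unname(amp["drift"]),
                    oscillation_amplitude_m = unname(amp["oscillation"]),
                    max_abs_displacement_m = max_abs,
                    noise_gate_m = gate, span_h = span_h,
                    fallback = fallback),
    extrema = ex, series = series, config = config,
    decompose = decompose)
}

new_classification <- function(primary, secondary, evidence, extrema,
                               series, config, decompose = TRUE) {
  comp <- if (decompose && length(series$times_h) >= 8)
    decompose_movement(series) else NULL
  structure(list(tree_id = series$tree_id, primary_label = primary,
                 secondary_labels = secondary, evidence = evidence,
                 extrema = extrema, components = comp, config = config),
            class = "movement_classification")
}

#' @export
print.movement_classification <- function(x, ...) {
  cat(sprintf("movement_classification%s: %s%s\n",
              if (is.null(x$tree_id)) "" else sprintf(" '%s'", x$tree_id),
              x$primary_label,
              if (length(x$secondary_labels))
                sprintf(" (+ %s)", paste(x$secondary_labels, collapse = ", "))
              else ""))
  invisible(x)
}

#' Additive decomposition of a displacement series
#'
#' Least-squares fit of
#' \deqn{v(t) = c + a t + A_c \sin(2\pi (t - \phi_c)/P_c)
#'            + A_o \sin(2\pi (t - \phi_o)/P_o)}
#' with the circadian period P_c searched over [8, 12] h and the oscillation
#' period P_o over [2, 6] h. For fixed periods the model is linear in
#' (c, a, and the sine/cosine pairs), so the search is an exhaustive period
#' grid (step 0.25 h) with linear least squares at each node, followed by
#' local refinement of the two periods (L-BFGS-B on the profile residual).
#' The intercept c absorbs the baseline subtraction (a displacement series is
#' zero at t = 0, so a generative field d(t) appears as d(t) - d(0)).
#' Amplitudes are reported non-negative; the fit is deterministic.
#'
#' @param series a \code{displacement_series} (or list with \code{times_h}
#'   and \code{mean_displacement}), >= 8 epochs.
#' @param circadian_range,oscillation_range period search bounds, hours.
#' @param grid_step_h period grid step, hours.
#' @return a \code{movement_components}: list with \code{drift_rate} (m/h),
#'   \code{circadian_amplitude}/\code{_period}/\code{_phase},
#'   \code{oscillation_amplitude}/\code{_period}/\code{_phase},
#'   \code{intercept}, \code{residual_rms} (m), \code{converged}.
#' @export
decompose_movement <- function(series, circadian_range = c(8, 12),
                               oscillation_range = c(2, 6),
                               grid_step_h = 0.25) {
  t <- series$times_h
  v <- series$mean_displacement
  stopifnot(length(t) == length(v), length(t) >= 8)

  fit_fixed <- function(pc, po) {
    X <- cbind(1, t,
               sin(2 * pi * t / pc), cos(2 * pi * t / pc),
               sin(2 * pi * t / po), cos(2 * pi * t / po))
    fit <- stats::lm.fit(X, v)
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }
  pcs <- seq(circadian_range[1], circadian_range[2], by = grid_step_h)
  pos <- seq(oscillation_range[1], oscillation_range[2], by = grid_step_h)
  grid <- expand.grid(pc = pcs, po = pos)
  rss <- mapply(function(pc, po) fit_fixed(pc, po)$rss, grid$pc, grid$po)
  best <- grid[which.min(rss), ]

  obj <- function(p) fit_fixed(p[1], p[2])$rss
  opt <- tryCatch(
    stats::optim(c(best$pc, best$po), obj, method = "L-BFGS-B",
                 lower = c(circadian_range[1], oscillation_range[1]),
                 upper = c(circadian_range[2], oscillation_range[2])),
    error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0 &&
    opt$value <= min(rss) + 1e-18
  if (!is.null(opt) && opt$value <= min(rss)) {
    pc <- opt$par[1]; po <- opt$par[2]
  } else {
    pc <- best$pc; po <- best$po
  }
  ff <- fit_fixed(pc, po)
  cf <- ff$coef
  amp_phase <- function(bs, bc, period) {
    A <- sqrt(bs^2 + bc^2)
    # bs sin(wt) + bc cos(wt) = A sin(w (t - phi)) with phi below
    phi <- (-atan2(bc, bs) * period / (2 * pi)) %% period
    c(A, phi)
  }
  circ <- amp_phase(cf[3], cf[4], pc)
  osc <- amp_phase(cf[5], cf[6], po)
  structure(list(intercept = unname(cf[1]), drift_rate = unname(cf[2]),
                 circadian_amplitude = circ[1], circadian_period = pc,
                 circadian_phase = circ[2],
                 oscillation_amplitude = osc[1], oscillation_period = po,
                 oscillation_phase = osc[2],
                 residual_rms = sqrt(ff$rss / length(v)),
                 converged = converged),
            class = "movement_components")
}

#' @export
print.movement_components <- function(x, ...) {
  cat(sprintf(
    paste0("movement_components: drift %.4f m/h; circadian %.4f m @ %.2f h; ",
           "oscillation %.4f m @ %.2f h; residual rms %.4f m\n"),
    x$drift_rate, x$circadian_amplitude, x$circadian_period,
    x$oscillation_amplitude, x$oscillation_period, x$residual_rms))
  invisible(x)
}

#' Write a movement classification as JSON
#' @param cls a \code{movement_classification}.
#' @param path output JSON path.
#' @export
write_classification_json <- function(cls, path) {
  comp <- cls$components
  jsonlite::write_json(
    list(tree_id = cls$tree_id,
         primary_label = cls$primary_label,
         secondary_labels = as.list(cls$secondary_labels),
         evidence = cls$evidence,
         components = if (is.null(comp)) NULL else unclass(comp)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
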
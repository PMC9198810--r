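#' Piecewise-constant intervention schedule
#'
#' Interventions are parameter switches applied instantaneously at given
#' times: the new values hold from the switch time onward
#' (right-continuous), the state is continuous across the switch, and the
#' integrator restarts exactly at each switch time. `NA` entries leave a
#' parameter unchanged in that segment.
#'
#' @param time Strictly increasing vector of switch times (days, all > 0).
#' @param ... Named parameter overrides (any [sewir_params()] field), each
#'   a vector recycled to `length(time)`; use `NA` for "no change at this
#'   switch".
#' @return A tibble of class `sewir_schedule` with a `time` column plus one
#'   column per overridden parameter.
#' @examples
#' sewir_schedule(time = 220, m = 0.8)                 # raise vaccination
#' sewir_schedule(time = 220, m = 0.8, k1 = 0.6)       # raise both controls
#' @export
sewir_schedule <- function(time, ...) {
  overrides <- list(...)
  if (length(time) == 0 || !is.numeric(time)) {
    abort("schedule needs at least one numeric switch time",
          class = "sewir_validation_error")
  }
  if (any(time <= 0) || is.unsorted(time, strictly = TRUE)) {
    abort("switch times must be strictly increasing and > 0",
          class = "sewir_validation_error")
  }
  unknown <- setdiff(names(overrides), .param_names)
  if (length(unknown) || is.null(names(overrides)) ||
      any(names(overrides) == "")) {
    abort(paste0("overrides must be named model parameters; offending: ",
                 paste(unknown, collapse = ", ")),
          class = "sewir_validation_error")
  }
  out <- tibble(time = time)
  for (nm in names(overrides)) {
    v <- rep_len(overrides[[nm]], length(time))
    live <- v[!is.na(v)]
    bad <- any(!is.finite(live)) ||
      (nm == "m" && any(live < 0 | live > 1)) ||
      (nm == "mu" && any(live <= 0)) ||
      (nm != "m" && any(live < 0))
    if (bad) {
      abort(paste0("override values for ", nm, " violate parameter ranges"),
            class = "sewir_validation_error")
    }
    out[[nm]] <- v
  }
  class(out) <- c("sewir_schedule", class(out))
  out
}

# effective parameter set per segment; segment i covers
# [boundaries[i], boundaries[i+1])
segment_params <- function(params, schedule) {
  if (is.null(schedule)) return(list(params))
  segs <- list(params)
  cur <- params
  for (i in seq_len(nrow(schedule))) {
    over <- as.list(schedule[i, setdiff(names(schedule), "time")])
    over <- over[!vapply(over, is.na, logical(1))]
    cur[names(over)] <- over
    validate_params(cur)
    segs[[i + 1L]] <- cur
  }
  segs
}

#' Integrate the SEWIR system forward in time
#'
#' Deterministic integration of the five-compartment system with optional
#' piecewise-constant parameter switches. The default integrator is the
#' adaptive Dormand-Prince 4(5) pair (`method = "ode45"`, rtol `1e-8`,
#' atol `1e-10`); a fixed-step classical RK4 (`method = "rk4"`, internal
#' step `step`) is available for bit-reproducible comparison runs. The
#' integration restarts exactly at every switch time. Output components in
#' `(-10*atol, 0)` (adaptive-integrator noise on the invariant boundary)
#' are clipped to zero; anything more negative is an error, since the
#' nonnegative orthant is forward-invariant for the exact flow.
#'
#' @param params A [sewir_params()] object (the segment-0 parameters).
#' @param init A [sewir_state()] initial condition.
#' @param t_end Integration horizon (days, > 0).
#' @param schedule Optional [sewir_schedule()] of interventions.
#' @param output_step Spacing of the output grid (days, default 0.1).
#' @param method `"ode45"` (adaptive, default) or `"rk4"` (fixed step).
#' @param rtol,atol Adaptive-integrator tolerances.
#' @param step Fixed internal step for `method = "rk4"` (days).
#' @return A tibble of class `sewir_trajectory` with columns
#'   `t, S, E, W, I, R`; the effective per-segment parameter sets are in
#'   `attr(, "params_used")` and the segment boundaries in
#'   `attr(, "boundaries")`.
#' @examples
#' p <- sewir_params(m = 0.8, k1 = 0.6)
#' traj <- sewir_simulate(p, sewir_state(120, 0, 15, 1, 0), t_end = 100)
#' summarise_trajectory(traj)
#' @export
sewir_simulate <- function(params, init, t_end, schedule = NULL,
                           output_step = 0.1,
                           method = c("ode45", "rk4"),
                           rtol = 1e-8, atol = 1e-10, step = 0.05) {
  method <- match.arg(method)
  validate_params(params)
  validate_state(init)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    abort("t_end must be a positive number",
          class = "sewir_validation_error")
  }
  switch_times <- numeric(0)
  if (!is.null(schedule)) {
    if (!inherits(schedule, "sewir_schedule")) {
      abort("schedule must be built with sewir_schedule()",
            class = "sewir_validation_error")
    }
    switch_times <- schedule$time[schedule$time < t_end]
    schedule <- schedule[schedule$time < t_end, , drop = FALSE]
  }
  segs <- segment_params(params, if (length(switch_times)) schedule else NULL)
  boundaries <- c(0, switch_times, t_end)

  grid <- seq(0, t_end, by = output_step)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  grid <- sort(unique(c(grid, switch_times)))

  # unvalidated vector field: the integrator may probe transiently
  # (and harmlessly) negative states, which strict validation would reject
  deriv <- function(t, y, p) {
    S <- y[1]; E <- y[2]; W <- y[3]; I <- y[4]; R <- y[5]
    list(c(
      -p$beta * I * S + p$Lambda * (1 - p$m) + p$k2 * W - p$m * S - p$mu * S,
      p$beta * I * S - (p$k1 + p$epsilon + p$mu) * E,
      p$k1 * E - (p$vartheta + p$k2 + p$mu) * W,
      p$epsilon * E - (p$vartheta + p$gamma + p$mu) * I,
      p$vartheta * W + p$vartheta * I + p$m * (p$Lambda + S) - p$mu * R
    ))
  }

  rows <- list()
  y <- unname(init)
  for (i in seq_along(segs)) {
    t0 <- boundaries[i]; t1 <- boundaries[i + 1]
    seg_times <- grid[grid >= t0 & grid <= t1]
    if (seg_times[1] > t0) seg_times <- c(t0, seg_times)
    if (seg_times[length(seg_times)] < t1) seg_times <- c(seg_times, t1)
    out <- if (method == "ode45") {
      deSolve::ode(y = y, times = seg_times, func = deriv, parms = segs[[i]],
                   method = "ode45", rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y = y, times = seg_times, func = deriv, parms = segs[[i]],
                   method = "rk4", hini = step)
    }
    m <- unclass(out)
    if (anyNA(m)) {
      abort(sprintf("integration failed in segment starting at t = %g", t0),
            class = "sewir_integration_error")
    }
    vals <- m[, -1, drop = FALSE]
    too_negative <- vals < -10 * atol
    if (any(too_negative)) {
      bad_t <- m[which(rowSums(too_negative) > 0)[1], 1]
      abort(sprintf("negative compartment beyond tolerance at t = %g", bad_t),
            class = "sewir_integration_error")
    }
    vals[vals < 0] <- 0
    # drop the duplicated segment-start row except for the first segment
    keep <- if (i == 1L) seq_len(nrow(m)) else -1L
    rows[[i]] <- cbind(t = m[keep, 1], vals[keep, , drop = FALSE])
    y <- vals[nrow(vals), ]
  }
  res <- as_tibble(as.data.frame(do.call(rbind, rows)))
  names(res) <- c("t", .compartments)
  res <- res[res$t %in% grid | seq_len(nrow(res)) == nrow(res), ]
  structure(res,
            class = c("sewir_trajectory", class(tibble())),
            params_used = segs,
            boundaries = boundaries)
}

#' Summarise a trajectory: peaks, threshold crossings, terminal state
#'
#' For each compartment reports the global maximum on the output grid
#' (`peak`, with first-grid-point tie-break), the outbreak peak
#' (`outbreak_peak`: the largest interior local maximum, i.e. the crest of
#' an epidemic wave, which differs from `peak` when a compartment starts
#' at a high initial value and declines before the wave; falls back to the
#' global maximum for monotone trajectories), the first time after
#' `control_start` the compartment drops below `threshold` (linear
#' interpolation between the bracketing grid points; `NA` if it never
#' does), the terminal value, and, when `reference` is given, the maximum
#' absolute deviation from that reference state over the final
#' `final_window` days.
#'
#' @param traj A [sewir_simulate()] trajectory.
#' @param threshold Threshold for the below-threshold crossing time
#'   (individuals, default 1).
#' @param control_start Crossings are only sought at `t >= control_start`
#'   (days, default 0).
#' @param reference Optional named state (e.g. an equilibrium) for the
#'   final-window deviation column.
#' @param final_window Length of the terminal window (days, default 50).
#' @return A tibble with one row per compartment.
#' @export
summarise_trajectory <- function(traj, threshold = 1, control_start = 0,
                                 reference = NULL, final_window = 50) {
  if (!nrow(traj)) abort("empty trajectory",
                         class = "sewir_validation_error")
  tt <- traj$t
  purrr::map_dfr(.compartments, function(comp) {
    v <- traj[[comp]]
    i_peak <- which.max(v)
    # interior local maxima (plateau-tolerant)
    n <- length(v)
    is_locmax <- if (n >= 3) {
      idx <- 2:(n - 1)
      idx[v[idx] >= v[idx - 1] & v[idx] >= v[idx + 1]]
    } else integer(0)
    if (length(is_locmax)) {
      i_out <- is_locmax[which.max(v[is_locmax])]
    } else {
      i_out <- i_peak
    }
    # first below-threshold time after control_start, interpolated
    sel <- which(tt >= control_start)
    cross <- NA_real_
    if (length(sel)) {
      below <- sel[v[sel] < threshold]
      if (length(below)) {
        i <- below[1]
        if (i == sel[1] || v[i - 1] < threshold) {
          cross <- tt[i]
        } else {
          cross <- tt[i - 1] + (v[i - 1] - threshold) /
            (v[i - 1] - v[i]) * (tt[i] - tt[i - 1])
        }
      }
    }
    row <- tibble(compartment = comp,
                  peak = v[i_peak], peak_time = tt[i_peak],
                  outbreak_peak = v[i_out], outbreak_peak_time = tt[i_out],
                  time_below_threshold = cross,
                  terminal = v[n])
    if (!is.null(reference)) {
      win <- tt >= (tt[n] - final_window)
      row$max_dev_final <- max(abs(v[win] - reference[[comp]]))
    }
    row
  })
}

#' @describeIn sewir_simulate Plot all five compartments against time.
#' @param object A `sewir_trajectory`.
#' @param ... Unused.
#' @method autoplot sewir_trajectory
#' @export
autoplot.sewir_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t",
                              names_to = "compartment", values_to = "size")
  long$compartment <- factor(long$compartment, levels = .compartments)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$size,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "individuals",
                  colour = "compartment") +
    ggplot2::theme_minimal()
}
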
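#' Packaged simulation scenarios
#'
#' Six ready-made scenario configurations exercising the model under
#' different control intensities, all sharing the baseline constants and
#' the initial state `(S, E, W, I, R) = (120, 0, 15, 1, 0)`:
#'
#' * `case1` — strong controls from the start (m = 0.8, k1 = 0.6, R0 < 1):
#'   the epidemic dies out and the system converges to the disease-free
#'   equilibrium.
#' * `case2` — weak controls (m = 0.35, k1 = 0.3, R0 > 1): convergence to
#'   the endemic equilibrium.
#' * `case3` — m = 0.35, k1 = 0.6 initially; on day 220 vaccination is
#'   raised to m = 0.8, pushing R0 below 1 and driving extinction.
#' * `case4` — as case3 but with weaker early quarantine (k1 = 0.2); on
#'   day 220 both controls rise to (m, k1) = (0.8, 0.6).
#' * `case5` — k1 fixed at 0.8, vaccination varied over representative
#'   values keeping R0 < 1 (a family of three runs).
#' * `case6` — m fixed at 0.8, quarantine rate varied (family of three).
#'
#' The case5/case6 per-curve values are illustrative choices within the
#' R0 < 1 constraint, not canonical constants.
#'
#' @param name One of `"case1" ... "case6"`.
#' @param init Optional initial state overriding the default; named so the
#'   compartment mapping is explicit.
#' @return An object of class `sewir_scenario`: a list with `name`,
#'   `params`, `init`, `t_end`, `schedule`, `threshold`, `control_start`,
#'   and for the two families a `varied` element
#'   (`list(param =, values =)`).
#' @examples
#' cfg <- sewir_case("case1")
#' res <- run_case(cfg, output_step = 0.5)
#' glance(res$equilibria)
#' @export
sewir_case <- function(name = c("case1", "case2", "case3", "case4",
                                "case5", "case6"),
                       init = sewir_state(S = 120, E = 0, W = 15, I = 1,
                                          R = 0)) {
  name <- match.arg(name)
  validate_state(init)
  base <- switch(name,
    case1 = list(params = sewir_params(m = 0.8, k1 = 0.6), t_end = 500,
                 schedule = NULL),
    case2 = list(params = sewir_params(m = 0.35, k1 = 0.3), t_end = 500,
                 schedule = NULL),
    case3 = list(params = sewir_params(m = 0.35, k1 = 0.6), t_end = 400,
                 schedule = sewir_schedule(time = 220, m = 0.8)),
    case4 = list(params = sewir_params(m = 0.35, k1 = 0.2), t_end = 400,
                 schedule = sewir_schedule(time = 220, m = 0.8, k1 = 0.6)),
    case5 = list(params = sewir_params(m = 0.78, k1 = 0.8), t_end = 200,
                 schedule = NULL,
                 varied = list(param = "m", values = c(0.78, 0.85, 0.92))),
    case6 = list(params = sewir_params(m = 0.8, k1 = 0.6), t_end = 200,
                 schedule = NULL,
                 varied = list(param = "k1", values = c(0.6, 0.8, 1.0)))
  )
  structure(c(list(name = name, init = init, threshold = 1,
                   control_start = if (name %in% c("case3", "case4")) 220
                                   else 0),
              base),
            class = "sewir_scenario")
}

#' Run a scenario end to end
#'
#' Simulates the scenario, summarises the trajectory, and attaches the
#' equilibrium and stability reports for the scenario's initial parameter
#' set (and, for scheduled scenarios, the post-switch parameter set).
#' For the curve families (case5/case6) the member scenarios are run
#' individually and returned together with a combined trajectory table.
#'
#' @param config A [sewir_case()] scenario (or a hand-built list with the
#'   same fields).
#' @param output_step,method Passed to [sewir_simulate()].
#' @return For a single scenario, a list of class `sewir_case_result` with
#'   `trajectory`, `summary`, `equilibria`, `stability` (list with `dfe`
#'   and, when R0 > 1, `endemic`), and for scheduled runs
#'   `post_equilibria`/`post_stability` for the final segment's parameters.
#'   For a family, a list of class `sewir_case_family` with `results` (one
#'   `sewir_case_result` per value) and `trajectories` (a long tibble with
#'   a `curve` column).
#' @export
run_case <- function(config, output_step = 0.1, method = "ode45") {
  if (!is.null(config$varied)) {
    vals <- config$varied$values
    results <- lapply(vals, function(v) {
      cfg <- config
      cfg$params[[config$varied$param]] <- v
      validate_params(cfg$params)
      cfg$varied <- NULL
      run_case(cfg, output_step = output_step, method = method)
    })
    names(results) <- paste0(config$varied$param, "=", vals)
    trajs <- purrr::map2_dfr(results, names(results), function(r, nm) {
      dplyr::mutate(as_tibble(r$trajectory), curve = nm)
    })
    return(structure(list(name = config$name, results = results,
                          trajectories = trajs),
                     class = "sewir_case_family"))
  }
  traj <- sewir_simulate(config$params, config$init, config$t_end,
                         schedule = config$schedule,
                         output_step = output_step, method = method)
  eq <- equilibria(config$params)
  stab <- list(dfe = classify_stability(config$params, "dfe"))
  if (!is.null(eq$Pstar)) {
    stab$endemic <- classify_stability(config$params, "endemic")
  }
  out <- list(name = config$name,
              config = config,
              trajectory = traj,
              summary = summarise_trajectory(
                traj, threshold = config$threshold %||% 1,
                control_start = config$control_start %||% 0),
              equilibria = eq,
              stability = stab)
  if (!is.null(config$schedule)) {
    post <- attr(traj, "params_used")
    post <- post[[length(post)]]
    out$post_equilibria <- equilibria(post)
    out$post_stability <- list(dfe = classify_stability(post, "dfe"))
    if (!is.null(out$post_equilibria$Pstar)) {
      out$post_stability$endemic <- classify_stability(post, "endemic")
    }
  }
  structure(out, class = "sewir_case_result")
}

#' @export
print.sewir_case_result <- function(x, ...) {
  cat(sprintf("<sewir_case_result> %s: R0 = %.4f (%s)\n", x$name,
              x$equilibria$R0, x$stability$dfe$classification))
  print(x$summary)
  invisible(x)
}

#' Compare outbreak peaks between two scenarios
#'
#' Runs both scenarios (which must share the initial state and horizon)
#' and reports the percent change `100 * (peak_a - peak_b) / peak_b` of
#' the chosen compartment's peak. The comparison uses outbreak peaks (the
#' crest of the epidemic wave, i.e. the largest interior local maximum)
#' by default: a compartment that starts above its wave crest and declines
#' first would otherwise report its initial value as the "peak". Set
#' `peak = "global"` for the raw grid maximum.
#'
#' @param case_a,case_b [sewir_case()] scenarios (a is the numerator).
#' @param compartment One of `"S", "E", "W", "I", "R"`.
#' @param peak `"outbreak"` (default) or `"global"`.
#' @param output_step Output grid spacing (days); the default 0.05 resolves
#'   the sharp early wave crests.
#' @return A one-row tibble with `compartment`, `peak_a`, `peak_b`,
#'   `percent_change` (`NA` when the reference peak is zero).
#' @export
compare_peaks <- function(case_a, case_b, compartment,
                          peak = c("outbreak", "global"),
                          output_step = 0.05) {
  peak <- match.arg(peak)
  compartment <- match.arg(compartment, .compartments)
  if (!isTRUE(all.equal(case_a$init, case_b$init)) ||
      !identical(case_a$t_end, case_b$t_end)) {
    abort("compared scenarios must share the initial state and horizon",
          class = "sewir_validation_error")
  }
  col <- if (peak == "outbreak") "outbreak_peak" else "peak"
  get_peak <- function(cfg) {
    res <- run_case(cfg, output_step = output_step)
    s <- res$summary
    s[[col]][s$compartment == compartment]
  }
  pa <- get_peak(case_a)
  pb <- get_peak(case_b)
  tibble(compartment = compartment, peak_a = pa, peak_b = pb,
         percent_change = if (pb == 0) NA_real_ else 100 * (pa - pb) / pb)
}

#' Reproduction-number surface over the two control parameters
#'
#' Evaluates the closed-form R0 over a Cartesian grid of vaccination
#' success rate `m` and government control rate `k1`, holding the other
#' parameters at `params`' values. R0 is strictly decreasing in both
#' controls.
#'
#' @param params A [sewir_params()] object supplying the fixed rates (its
#'   own `m`, `k1` are ignored).
#' @param m_grid,k1_grid Grid values (defaults: 0 to 1 in steps of 0.01).
#' @return A long tibble of class `sewir_surface` with columns
#'   `m`, `k1`, `R0`.
#' @export
r0_surface <- function(params, m_grid = seq(0, 1, by = 0.01),
                       k1_grid = seq(0, 1, by = 0.01)) {
  validate_params(params)
  if (!length(m_grid) || !length(k1_grid) ||
      any(m_grid < 0 | m_grid > 1) || any(k1_grid < 0)) {
    abort("grids must be non-empty and within parameter ranges",
          class = "sewir_validation_error")
  }
  grid <- tidyr::expand_grid(m = m_grid, k1 = k1_grid)
  grid$R0 <- purrr::map2_dbl(grid$m, grid$k1, function(m, k1) {
    p <- params; p$m <- m; p$k1 <- k1
    r0_closed_form(p)
  })
  structure(grid, class = c("sewir_surface", class(tibble())))
}

#' Local sensitivity of R0 to the two control parameters
#'
#' Central-difference estimates of `dR0/dm` and `dR0/dk1` at the
#' parameter set's own `(m, k1)`. Both derivatives are negative; the
#' comparison of their magnitudes says which control gives more leverage
#' per unit increase at that operating point.
#'
#' @param params A [sewir_params()] object.
#' @param h Finite-difference step (default `1e-5`).
#' @return A one-row tibble with `m`, `k1`, `dR0_dm`, `dR0_dk1`, and
#'   `more_sensitive_to` (`"m"` or `"k1"` by absolute magnitude).
#' @export
r0_sensitivity <- function(params, h = 1e-5) {
  validate_params(params)
  shift <- function(field, delta) {
    p <- params; p[[field]] <- p[[field]] + delta
    r0_closed_form(p)
  }
  dm <- (shift("m", h) - shift("m", -h)) / (2 * h)
  dk1 <- (shift("k1", h) - shift("k1", -h)) / (2 * h)
  tibble(m = params$m, k1 = params$k1, dR0_dm = dm, dR0_dk1 = dk1,
         more_sensitive_to = if (abs(dm) >= abs(dk1)) "m" else "k1")
}

#' @describeIn r0_surface Filled-contour plot of the surface with the
#'   `R0 = 1` threshold contour drawn on top.
#' @param object A `sewir_surface`.
#' @param ... Unused.
#' @method autoplot sewir_surface
#' @export
autoplot.sewir_surface <- function(object, ...) {
  gg <- ggplot2::ggplot(as_tibble(object),
                        ggplot2::aes(x = .data$m, y = .data$k1,
                                     fill = .data$R0)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "vaccination success rate m",
                  y = expression("government control rate " * k[1])) +
    ggplot2::theme_minimal()
  if (min(object$R0) < 1 && max(object$R0) > 1) {
    gg <- gg + ggplot2::geom_contour(
      ggplot2::aes(z = .data$R0), breaks = 1, colour = "white")
  }
  gg
}
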
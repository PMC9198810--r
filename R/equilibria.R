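#' Disease-free equilibrium
#'
#' With no infection (E = W = I = 0) the susceptible class settles at
#' `S0 = Lambda*(1-m)/(m+mu)`: unvaccinated inflow balanced against
#' vaccination and mortality. The recovered coordinate follows from
#' `dR/dt = 0` as `m*(Lambda+S0)/mu`.
#'
#' @param params A [sewir_params()] object.
#' @return A list with `S0`, `P0` (named vector in the reporting order
#'   `(E, I, S, W)`), and `R0_comp`, the recovered coordinate of the full
#'   five-compartment equilibrium.
#' @export
disease_free_equilibrium <- function(params) {
  validate_params(params)
  S0 <- params$Lambda * (1 - params$m) / (params$m + params$mu)
  list(S0 = S0,
       P0 = c(E = 0, I = 0, S = S0, W = 0),
       R0_comp = params$m * (params$Lambda + S0) / params$mu)
}

#' Basic reproduction number, closed form
#'
#' `R0 = beta * epsilon * S0 / (T1 * T2)` with `S0 = Lambda(1-m)/(m+mu)`,
#' `T1 = mu+k1+epsilon`, `T2 = mu+vartheta+gamma`: the expected number of
#' secondary infections seeded by one infected individual at the
#' disease-free equilibrium. Only the E -> I route contributes because the
#' quarantined exposed class W does not transmit.
#'
#' @param params A [sewir_params()] object.
#' @return A single number; the epidemic threshold sits at 1.
#' @export
r0_closed_form <- function(params) {
  d <- derived_rates(params)
  S0 <- disease_free_equilibrium(params)$S0
  params$beta * params$epsilon * S0 / (d$T1 * d$T2)
}

#' Basic reproduction number via the next-generation matrix
#'
#' Builds the 2x2 new-infection matrix `F = [[0, beta*S0], [0, 0]]` and
#' transition matrix `V = [[T1, 0], [-epsilon, T2]]` of the infected
#' subsystem (E, I) linearized at the disease-free equilibrium, and returns
#' the spectral radius of `F V^-1` computed numerically by eigendecomposition
#' (an independent route to the closed form, used as an internal
#' cross-check).
#'
#' @param params A [sewir_params()] object.
#' @return A list with matrices `F`, `V`, the next-generation matrix `K`,
#'   and its spectral radius `rho`.
#' @export
r0_ngm <- function(params) {
  d <- derived_rates(params)
  S0 <- disease_free_equilibrium(params)$S0
  Fm <- matrix(c(0, params$beta * S0,
                 0, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("E", "I"), c("E", "I")))
  Vm <- matrix(c(d$T1, 0,
                 -params$epsilon, d$T2), nrow = 2, byrow = TRUE,
               dimnames = list(c("E", "I"), c("E", "I")))
  if (abs(det(Vm)) < .Machine$double.eps) {
    abort("transition matrix V is singular (degenerate parameters)",
          class = "sewir_validation_error")
  }
  K <- Fm %*% solve(Vm)
  rho <- max(Mod(eigen(K, only.values = TRUE)$values))
  list(F = Fm, V = Vm, K = K, rho = rho)
}

#' Endemic equilibrium
#'
#' When `R0 > 1` the system admits a unique interior steady state:
#' \deqn{S^* = T_1 T_2 / (\beta\varepsilon), \quad
#'       E^* = \frac{T_3 T_1 T_2 \theta (1 - R_0)}{\beta\varepsilon (k_1 k_2 - T_1 T_3)}, \quad
#'       I^* = \frac{\varepsilon}{T_2} E^*, \quad
#'       W^* = \frac{k_1}{T_3} E^*}
#' Both `(1 - R0)` and `(k1 k2 - T1 T3)` are negative when `R0 > 1`, so all
#' components are positive; the expression is evaluated in exactly this form
#' (not algebraically rearranged). At `R0 <= 1` (the threshold included) no
#' endemic equilibrium exists and `NULL` is returned.
#'
#' @param params A [sewir_params()] object.
#' @return `NULL` if `R0 <= 1`; otherwise a named vector
#'   `(E, I, S, W)` plus `R`, the recovered coordinate from `dR/dt = 0`.
#' @export
endemic_equilibrium <- function(params) {
  d <- derived_rates(params)
  R0 <- r0_closed_form(params)
  if (R0 <= 1) return(NULL)
  be <- params$beta * params$epsilon
  stopifnot(be > 0)  # R0 > 1 forces beta*epsilon > 0
  Sstar <- d$T1 * d$T2 / be
  Estar <- d$T3 * d$T1 * d$T2 * d$theta * (1 - R0) /
    (be * (params$k1 * params$k2 - d$T1 * d$T3))
  Istar <- (params$epsilon / d$T2) * Estar
  Wstar <- (params$k1 / d$T3) * Estar
  Rstar <- (params$vartheta * Wstar + params$vartheta * Istar +
              params$m * (params$Lambda + Sstar)) / params$mu
  out <- c(E = Estar, I = Istar, S = Sstar, W = Wstar, R = Rstar)
  if (any(out[c("E", "I", "S", "W")] <= 0)) {
    abort("endemic equilibrium components must be positive when R0 > 1",
          class = "sewir_internal_error")
  }
  out
}

#' Full equilibrium report
#'
#' Bundles the disease-free equilibrium, the basic reproduction number by
#' both routes, the endemic equilibrium when it exists, and the derived
#' compound rates.
#'
#' @param params A [sewir_params()] object.
#' @return An object of class `sewir_equilibria` with elements `params`,
#'   `derived`, `S0`, `R0` (closed form), `ngm`, `P0`, `Pstar` (or `NULL`).
#' @examples
#' eq <- equilibria(sewir_params(m = 0.35, k1 = 0.3))
#' glance(eq)
#' tidy(eq)
#' @export
equilibria <- function(params) {
  dfe <- disease_free_equilibrium(params)
  structure(list(params = params,
                 derived = derived_rates(params),
                 S0 = dfe$S0,
                 R0 = r0_closed_form(params),
                 ngm = r0_ngm(params),
                 P0 = dfe$P0,
                 P0_R = dfe$R0_comp,
                 Pstar = endemic_equilibrium(params)),
            class = "sewir_equilibria")
}

#' @export
print.sewir_equilibria <- function(x, ...) {
  cat("<sewir_equilibria>\n")
  cat(sprintf("  S0 = %.4f   R0 = %.4f (%s)\n", x$S0, x$R0,
              if (x$R0 > 1) "endemic equilibrium exists" else
                "disease-free only"))
  if (!is.null(x$Pstar)) {
    cat(sprintf("  P* (E, I, S, W) = (%.4f, %.4f, %.4f, %.4f)\n",
                x$Pstar["E"], x$Pstar["I"], x$Pstar["S"], x$Pstar["W"]))
  }
  invisible(x)
}

#' @describeIn equilibria One row per equilibrium point and compartment.
#' @param x A `sewir_equilibria` object.
#' @param ... Unused.
#' @method tidy sewir_equilibria
#' @export
tidy.sewir_equilibria <- function(x, ...) {
  rows <- tibble(point = "disease_free",
                 compartment = names(x$P0),
                 value = unname(x$P0))
  if (!is.null(x$Pstar)) {
    rows <- dplyr::bind_rows(rows,
      tibble(point = "endemic",
             compartment = names(x$Pstar),
             value = unname(x$Pstar)))
  }
  rows
}

#' @describeIn equilibria One-row summary: S0, R0 by both routes, existence
#'   flag and the derived compound rates.
#' @method glance sewir_equilibria
#' @export
glance.sewir_equilibria <- function(x, ...) {
  tibble(S0 = x$S0, R0 = x$R0, R0_ngm = x$ngm$rho,
         endemic_exists = !is.null(x$Pstar),
         T1 = x$derived$T1, T2 = x$derived$T2, T3 = x$derived$T3,
         theta = x$derived$theta)
}

# equilibrium in internal (S, E, W, I, R) order, for residual checks and
# simulation starts
as_state <- function(pt) {
  sewir_state(S = pt[["S"]], E = pt[["E"]], W = pt[["W"]], I = pt[["I"]],
              R = if ("R" %in% names(pt)) pt[["R"]] else 0)
}
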
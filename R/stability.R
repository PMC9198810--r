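#' Jacobian of the reduced system at the disease-free equilibrium
#'
#' The four-compartment system (R decouples) linearized at
#' `P0 = (0, 0, S0, 0)`, in `(E, I, S, W)` row/column order:
#' \preformatted{
#'   [ -T1   beta*S0    0      0  ]
#'   [ eps   -T2        0      0  ]
#'   [ 0     -beta*S0  -theta  k2 ]
#'   [ k1    0          0     -T3 ]
#' }
#' Its spectrum always contains `-theta` and `-T3` exactly; the remaining
#' pair are the roots of `lambda^2 + (T1+T2) lambda + T1*T2*(1-R0)`, so the
#' disease-free state is locally stable precisely when `R0 < 1`.
#'
#' @param params A [sewir_params()] object.
#' @return A 4x4 matrix with dimnames `(E, I, S, W)`.
#' @export
jacobian_dfe <- function(params) {
  d <- derived_rates(params)
  S0 <- disease_free_equilibrium(params)$S0
  b <- params$beta
  matrix(c(-d$T1, b * S0, 0, 0,
           params$epsilon, -d$T2, 0, 0,
           0, -b * S0, -d$theta, params$k2,
           params$k1, 0, 0, -d$T3),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("E", "I", "S", "W"), c("E", "I", "S", "W")))
}

#' Jacobian of the reduced system at the endemic equilibrium
#'
#' Linearization at `P* = (E*, I*, S*, W*)` in `(E, I, S, W)` order:
#' \preformatted{
#'   [ -T1   beta*S*    beta*I*        0  ]
#'   [ eps   -T2        0              0  ]
#'   [ 0     -beta*S*  -beta*I*-theta  k2 ]
#'   [ k1    0          0             -T3 ]
#' }
#'
#' @param params A [sewir_params()] object with `r0_closed_form(params) > 1`.
#' @return A 4x4 matrix with dimnames `(E, I, S, W)`.
#' @export
jacobian_endemic <- function(params) {
  d <- derived_rates(params)
  pstar <- endemic_equilibrium(params)
  if (is.null(pstar)) {
    abort("no endemic equilibrium: R0 <= 1", class = "sewir_no_endemic_error")
  }
  b <- params$beta
  Ss <- pstar[["S"]]; Is <- pstar[["I"]]
  matrix(c(-d$T1, b * Ss, b * Is, 0,
           params$epsilon, -d$T2, 0, 0,
           0, -b * Ss, -b * Is - d$theta, params$k2,
           params$k1, 0, 0, -d$T3),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("E", "I", "S", "W"), c("E", "I", "S", "W")))
}

#' Closed-form characteristic coefficients at the endemic equilibrium
#'
#' Coefficients `(b1, b2, b3, b4)` of the monic quartic
#' `lambda^4 + b1 lambda^3 + b2 lambda^2 + b3 lambda + b4` of the Jacobian
#' at `P*`:
#' \deqn{b_1 = T_1 + T_2 + T_3 + \beta I^* + \theta}
#' \deqn{b_2 = T_1 T_3 + T_2 T_3 + (\beta I^* + \theta)(T_1 + T_2 + T_3)}
#' \deqn{b_3 = \beta I^*(T_1 T_2 + T_2 T_3) + \theta(T_1 T_3 + T_2 T_3) +
#'   \beta I^*(T_1 T_3 - k_1 k_2)}
#' \deqn{b_4 = \beta I^* T_2 (T_1 T_3 - k_1 k_2)}
#' All four are positive whenever `R0 > 1`, since `T1 T3 > k1 k2` always.
#'
#' @param params A [sewir_params()] object with `R0 > 1`.
#' @return Named numeric vector `c(b1, b2, b3, b4)`.
#' @export
char_coeffs_endemic <- function(params) {
  d <- derived_rates(params)
  pstar <- endemic_equilibrium(params)
  if (is.null(pstar)) {
    abort("no endemic equilibrium: R0 <= 1", class = "sewir_no_endemic_error")
  }
  bI <- params$beta * pstar[["I"]]
  k1k2 <- params$k1 * params$k2
  with(d, c(
    b1 = T1 + T2 + T3 + bI + theta,
    b2 = T1 * T3 + T2 * T3 + (bI + theta) * (T1 + T2 + T3),
    b3 = bI * (T1 * T2 + T2 * T3) + theta * (T1 * T3 + T2 * T3) +
      bI * (T1 * T3 - k1k2),
    b4 = bI * T2 * (T1 * T3 - k1k2)
  ))
}

#' Hurwitz matrix and its leading principal minors
#'
#' For the monic polynomial
#' `lambda^n + b1 lambda^(n-1) + ... + bn`, builds the n x n Hurwitz matrix
#' with rows alternating `(b1, b3, b5, ...)` and `(1, b2, b4, ...)`
#' (entry `H[i, j] = b[2j - i]`, with `b0 = 1` and `b_k = 0` outside
#' `0..n`), and returns the leading principal minors `Phi_1 ... Phi_n`.
#' By the Routh-Hurwitz criterion all roots have negative real part iff
#' every minor is positive.
#'
#' @param coeffs Numeric vector `(b1, ..., bn)` of the non-leading
#'   coefficients of a monic real polynomial, `n >= 1`.
#' @return Named numeric vector of the `n` minors, with the Hurwitz matrix
#'   attached as attribute `"hurwitz_matrix"`.
#' @examples
#' hurwitz_minors(c(3, 2))  # lambda^2 + 3 lambda + 2: both minors positive
#' @export
hurwitz_minors <- function(coeffs) {
  n <- length(coeffs)
  if (n < 1L) abort("need at least one coefficient",
                    class = "sewir_validation_error")
  if (!is.numeric(coeffs) || anyNA(coeffs) || any(!is.finite(coeffs))) {
    abort("coefficients must be finite numbers",
          class = "sewir_validation_error")
  }
  b <- function(k) {
    if (k == 0) 1 else if (k >= 1 && k <= n) coeffs[k] else 0
  }
  H <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) b(2 * j - i)))
  minors <- vapply(seq_len(n),
                   function(k) det(H[seq_len(k), seq_len(k), drop = FALSE]),
                   numeric(1))
  structure(setNames(minors, paste0("Phi", seq_len(n))),
            hurwitz_matrix = H)
}

#' Classify local stability at an equilibrium
#'
#' Computes the Jacobian at the requested equilibrium, its eigenvalues, the
#' characteristic-polynomial coefficients, and the Routh-Hurwitz minors, and
#' classifies the point as `"stable"`, `"unstable"` or `"marginal"`. The
#' eigenvalue verdict and the Hurwitz verdict are cross-checked and must
#' agree (away from the marginal band); disagreement raises an internal
#' consistency error. An eigenvalue real part within `tol` of zero yields
#' `"marginal"`, never a silent `"stable"`.
#'
#' @param params A [sewir_params()] object.
#' @param point `"dfe"` (disease-free) or `"endemic"`.
#' @param tol Half-width of the marginal band on eigenvalue real parts
#'   (default `1e-9`).
#' @return An object of class `sewir_stability`: a list with `point`,
#'   `jacobian`, `eigenvalues`, `char_coeffs`, `hurwitz_minors`,
#'   `classification`.
#' @examples
#' classify_stability(sewir_params(m = 0.8, k1 = 0.6), "dfe")
#' @export
classify_stability <- function(params, point = c("dfe", "endemic"),
                               tol = 1e-9) {
  point <- match.arg(point)
  J <- if (point == "dfe") jacobian_dfe(params) else jacobian_endemic(params)
  ev <- eigen(J, only.values = TRUE)$values
  # monic characteristic coefficients from the matrix itself
  cp <- char_poly_coeffs(J)
  minors <- hurwitz_minors(cp)
  re <- Re(ev)
  classification <-
    if (any(abs(re) <= tol)) "marginal"
    else if (all(re < 0)) "stable"
    else "unstable"
  hurwitz_stable <- all(minors > 0)
  if (classification != "marginal" &&
      hurwitz_stable != (classification == "stable")) {
    abort("Hurwitz and eigenvalue stability verdicts disagree",
          class = "sewir_internal_error")
  }
  structure(list(point = point,
                 jacobian = J,
                 eigenvalues = ev,
                 char_coeffs = cp,
                 hurwitz_minors = minors,
                 hurwitz_stable = hurwitz_stable,
                 classification = classification),
            class = "sewir_stability")
}

# non-leading coefficients (b1..bn) of the monic characteristic polynomial
# of a real matrix, via the eigenvalue product expansion
char_poly_coeffs <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  co <- 1
  for (r in ev) co <- c(co, 0) - c(0, r * co)  # multiply by (lambda - r)
  out <- Re(co[-1])
  setNames(out, paste0("b", seq_along(out)))
}

#' @export
print.sewir_stability <- function(x, ...) {
  cat(sprintf("<sewir_stability> %s equilibrium: %s\n",
              if (x$point == "dfe") "disease-free" else "endemic",
              x$classification))
  cat("  eigenvalue real parts:",
      paste(sprintf("%.4g", Re(x$eigenvalues)), collapse = ", "), "\n")
  cat("  Hurwitz minors:",
      paste(sprintf("%.4g", x$hurwitz_minors), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn classify_stability One row per eigenvalue, with the matching
#'   Hurwitz minor alongside.
#' @param x A `sewir_stability` object.
#' @param ... Unused.
#' @method tidy sewir_stability
#' @export
tidy.sewir_stability <- function(x, ...) {
  tibble(eigenvalue = seq_along(x$eigenvalues),
         real = Re(x$eigenvalues),
         imag = Im(x$eigenvalues),
         hurwitz_minor = unname(x$hurwitz_minors))
}

#' @describeIn classify_stability One-row verdict summary.
#' @method glance sewir_stability
#' @export
glance.sewir_stability <- function(x, ...) {
  tibble(point = x$point,
         classification = x$classification,
         max_re_eigenvalue = max(Re(x$eigenvalues)),
         all_minors_positive = x$hurwitz_stable)
}

#' Lyapunov diagnostic for global stability of the disease-free state
#'
#' The scalar function `L = epsilon*E + T1*I` (with `T1 = mu+k1+epsilon`)
#' is nonnegative, vanishes only when `E = I = 0`, and along the flow has
#' exact derivative `dL/dt = I * (beta*epsilon*S - T1*T2)`. Inside the
#' feasible region with `S <= S0` this equals
#' `I * T1 * T2 * (beta*epsilon*S/(T1*T2) - 1) <= I * T1 * T2 * (R0 - 1)`,
#' which is nonpositive when `R0 < 1`; combined with LaSalle's invariance
#' principle that certifies global convergence to the disease-free
#' equilibrium. The derivative sign guarantee uses `S <= S0`, so the
#' returned record flags states violating it rather than assuming it.
#'
#' @param state A [sewir_state()] vector.
#' @param params A [sewir_params()] object.
#' @return A list with `value`, `derivative`, and `s_exceeds_s0` (logical).
#' @export
lyapunov <- function(state, params) {
  d <- derived_rates(params)
  validate_state(state)
  S0 <- disease_free_equilibrium(params)$S0
  list(value = params$epsilon * state[["E"]] + d$T1 * state[["I"]],
       derivative = state[["I"]] *
         (params$beta * params$epsilon * state[["S"]] - d$T1 * d$T2),
       s_exceeds_s0 = state[["S"]] > S0)
}

#' Evaluate the Lyapunov diagnostic along a trajectory
#'
#' @param traj A trajectory tibble from [sewir_simulate()].
#' @param params The [sewir_params()] object the trajectory was run under
#'   (for scheduled runs, pass the segment parameters of interest).
#' @return A tibble with columns `t`, `value`, `derivative`,
#'   `s_exceeds_s0`.
#' @export
lyapunov_along <- function(traj, params) {
  d <- derived_rates(params)
  S0 <- disease_free_equilibrium(params)$S0
  tibble(t = traj$t,
         value = params$epsilon * traj$E + d$T1 * traj$I,
         derivative = traj$I *
           (params$beta * params$epsilon * traj$S - d$T1 * d$T2),
         s_exceeds_s0 = traj$S > S0)
}
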
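#' Construct a compartment state vector
#'
#' @param S,E,W,I,R Compartment sizes (individuals, continuous, each >= 0):
#'   susceptible, unquarantined exposed, quarantined exposed, infected,
#'   recovered.
#' @return A named numeric vector of length 5 in `(S, E, W, I, R)` order.
#' @export
sewir_state <- function(S, E, W, I, R) {
  x <- c(S = S, E = E, W = W, I = I, R = R)
  validate_state(x)
  x
}

validate_state <- function(x) {
  if (!is.numeric(x) || length(x) != 5L || anyNA(x) || any(!is.finite(x))) {
    abort("state must be 5 finite numbers (S, E, W, I, R)",
          class = "sewir_validation_error")
  }
  if (is.null(names(x)) || !identical(names(x), .compartments)) {
    names(x) <- .compartments
  }
  if (any(x < 0)) {
    abort("compartment sizes must be >= 0",
          class = "sewir_validation_error")
  }
  invisible(x)
}

#' SEWIR vector field
#'
#' Right-hand side of the five-compartment system
#' \deqn{S' = -\beta I S + \Lambda(1-m) + k_2 W - mS - \mu S}
#' \deqn{E' = \beta I S - (k_1+\varepsilon+\mu)E}
#' \deqn{W' = k_1 E - (\vartheta+k_2+\mu)W}
#' \deqn{I' = \varepsilon E - (\vartheta+\gamma+\mu)I}
#' \deqn{R' = \vartheta W + \vartheta I + m(\Lambda+S) - \mu R}
#' Vaccination removes susceptibles (and diverts a fraction m of new
#' entrants) directly into R, so the recovery inflow is `m*(Lambda + S)`;
#' under this reading total population obeys
#' `dN/dt = Lambda - gamma*I - mu*N` exactly, which the return value
#' satisfies to machine precision.
#'
#' @param state A [sewir_state()] vector (or any named numeric with
#'   components S, E, W, I, R).
#' @param params A [sewir_params()] object.
#' @return Named numeric vector of the five time-derivatives
#'   (individuals/day).
#' @export
sewir_rhs <- function(state, params) {
  validate_params(params)
  validate_state(state)
  with(c(as.list(state), params), c(
    S = -beta * I * S + Lambda * (1 - m) + k2 * W - m * S - mu * S,
    E = beta * I * S - (k1 + epsilon + mu) * E,
    W = k1 * E - (vartheta + k2 + mu) * W,
    I = epsilon * E - (vartheta + gamma + mu) * I,
    R = vartheta * W + vartheta * I + m * (Lambda + S) - mu * R
  ))
}

#' Biologically feasible region
#'
#' The flow is studied on the closed, forward-invariant set
#' `Omega = { S,E,W,I >= 0, S + E + W + I <= Lambda(1-m)/mu }`:
#' the living non-recovered population can never asymptotically exceed the
#' unvaccinated inflow divided by the mortality rate.
#'
#' @param state A [sewir_state()] vector (R is ignored by the bound).
#' @param params A [sewir_params()] object.
#' @return `feasible_bound()`: the scalar `Lambda*(1-m)/mu`.
#'   `in_feasible_region()`: `TRUE` iff the state lies in Omega (boundary
#'   included).
#' @export
feasible_bound <- function(params) {
  validate_params(params)
  params$Lambda * (1 - params$m) / params$mu
}

#' @rdname feasible_bound
#' @export
in_feasible_region <- function(state, params) {
  validate_state(state)
  all(state[c("S", "E", "W", "I")] >= 0) &&
    sum(state[c("S", "E", "W", "I")]) <= feasible_bound(params)
}
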
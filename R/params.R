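#' Construct a validated SEWIR parameter set
#'
#' The SEWIR model tracks susceptible (S), unquarantined exposed (E),
#' quarantined exposed (W), infected (I) and recovered (R) individuals.
#' All rates are per day; compartment sizes are individuals. The defaults
#' for the seven demographic/epidemiological constants are the baseline
#' estimates used throughout the package's worked scenarios; the two control
#' variables `m` (vaccination success rate, a probability) and `k1`
#' (government control rate, the per-day rate at which unquarantined exposed
#' individuals are moved into medical quarantine) have no defaults and must
#' be supplied by the caller.
#'
#' @param m Vaccination success rate, in `[0, 1]` (dimensionless probability).
#' @param k1 Government control rate (1/day), >= 0.
#' @param Lambda Population replenishment rate (individuals/day): newborns
#'   plus net in-migration.
#' @param beta Transmission rate per infected-susceptible contact
#'   (1/(individuals x day)).
#' @param mu Natural mortality rate (1/day), must be > 0.
#' @param epsilon Conversion rate from unquarantined exposed to infected
#'   (1/day).
#' @param gamma Disease-induced mortality rate (1/day).
#' @param vartheta Recovery rate (1/day), applied identically to W and I.
#' @param k2 Autoimmune clearance rate returning quarantined exposed
#'   individuals to the susceptible class (1/day).
#'
#' @return An object of class `sewir_params`: a named list of the nine rates.
#' @examples
#' p <- sewir_params(m = 0.8, k1 = 0.6)
#' r0_closed_form(p)
#' @export
sewir_params <- function(m, k1, Lambda = 15, beta = 0.5, mu = 0.08,
                         epsilon = 0.8, gamma = 0.06, vartheta = 0.8,
                         k2 = 0.01) {
  p <- list(Lambda = Lambda, beta = beta, mu = mu, epsilon = epsilon,
            gamma = gamma, m = m, k1 = k1, vartheta = vartheta, k2 = k2)
  validate_params(p)
  structure(p, class = "sewir_params")
}

validate_params <- function(p) {
  vals <- unlist(p[.param_names])
  if (length(vals) != 9L || !is.numeric(vals) || anyNA(vals) ||
      any(!is.finite(vals))) {
    abort("all nine SEWIR parameters must be finite numbers",
          class = "sewir_validation_error")
  }
  nonneg <- c("Lambda", "beta", "epsilon", "gamma", "vartheta", "k1", "k2")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) {
    abort(paste0("parameters must be >= 0: ", paste(bad, collapse = ", ")),
          class = "sewir_validation_error")
  }
  if (p$mu <= 0) {
    abort("mu (natural mortality) must be > 0",
          class = "sewir_validation_error")
  }
  if (p$m < 0 || p$m > 1) {
    abort("m (vaccination success rate) must lie in [0, 1]",
          class = "sewir_validation_error")
  }
  invisible(p)
}

#' @export
print.sewir_params <- function(x, ...) {
  cat("<sewir_params>\n")
  vals <- unlist(x[.param_names])
  cat(paste0("  ", format(names(vals), width = 8), " = ", format(vals)),
      sep = "\n")
  invisible(x)
}

#' Compound rates derived from an SEWIR parameter set
#'
#' The total per-capita outflow rates of the E, I and W compartments and of
#' the susceptible class:
#' `T1 = mu + k1 + epsilon`, `T2 = mu + vartheta + gamma`,
#' `T3 = mu + vartheta + k2`, `theta = m + mu`. These four compounds appear
#' in every closed form (R0, the endemic equilibrium, the characteristic
#' polynomials). The combination `k1*k2 - T1*T3` is algebraically negative
#' for every admissible parameter set; this is asserted, as several endemic
#' formulas divide by it.
#'
#' @param params A [sewir_params()] object.
#' @return A named list with `T1`, `T2`, `T3`, `theta`.
#' @export
derived_rates <- function(params) {
  validate_params(params)
  d <- list(T1 = params$mu + params$k1 + params$epsilon,
            T2 = params$mu + params$vartheta + params$gamma,
            T3 = params$mu + params$vartheta + params$k2,
            theta = params$m + params$mu)
  stopifnot(d$T1 > 0, d$T2 > 0, d$T3 > 0, d$theta > 0)
  # k1*k2 - T1*T3 = -(mu+eps)(mu+vth) - k1(mu+vth) - k2(mu+eps) < 0
  if (params$k1 * params$k2 - d$T1 * d$T3 >= 0) {
    abort("internal invariant violated: k1*k2 - T1*T3 must be negative",
          class = "sewir_internal_error")
  }
  d
}

#' @describeIn sewir_params Tidy a parameter set into a two-column tibble.
#' @param x A `sewir_params` object.
#' @param ... Unused.
#' @method tidy sewir_params
#' @export
tidy.sewir_params <- function(x, ...) {
  tibble(parameter = .param_names, value = unlist(x[.param_names]))
}

#' Read or write an SEWIR parameter set as a flat YAML mapping
#'
#' The file holds a flat mapping of the ASCII parameter names
#' (`Lambda`, `beta`, `mu`, `epsilon`, `gamma`, `m`, `k1`, `vartheta`, `k2`).
#' A file may omit `m` and `k1` (scenario-level variables); supply them via
#' `...` in that case. The packaged baseline constants live at
#' `system.file("extdata", "params_table1.yaml", package = "sewir")`.
#'
#' @param path Path to a YAML file.
#' @param ... Named overrides (typically `m` and `k1`) merged over the file's
#'   values before validation.
#' @return A [sewir_params()] object.
#' @export
read_params <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  unknown <- setdiff(names(raw), .param_names)
  if (length(unknown)) {
    abort(paste0("unknown parameter fields: ", paste(unknown, collapse = ", ")),
          class = "sewir_validation_error")
  }
  missing <- setdiff(.param_names, names(raw))
  if (length(missing)) {
    abort(paste0("missing parameter fields: ", paste(missing, collapse = ", ")),
          class = "sewir_validation_error")
  }
  do.call(sewir_params, raw)
}

#' @rdname read_params
#' @param params A [sewir_params()] object to serialize.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(lapply(params[.param_names], as.numeric), path)
  invisible(path)
}
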
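# shared fixtures: baseline parameter sets and randomized generators

table1_params <- function(m, k1) sewir_params(m = m, k1 = k1)

params_case1 <- function() table1_params(m = 0.8, k1 = 0.6)   # R0 < 1
params_case2 <- function() table1_params(m = 0.35, k1 = 0.3)  # R0 > 1

default_init <- function() sewir_state(S = 120, E = 0, W = 15, I = 1, R = 0)

# a random admissible parameter set
random_params <- function() {
  sewir_params(Lambda = runif(1, 0.5, 30), beta = runif(1, 0.01, 1),
               mu = runif(1, 0.01, 0.5), epsilon = runif(1, 0.01, 1.5),
               gamma = runif(1, 0, 0.5), m = runif(1, 0, 0.99),
               k1 = runif(1, 0, 1.5), vartheta = runif(1, 0, 1.5),
               k2 = runif(1, 0, 0.5))
}

# a random parameter set conditioned on R0 > 1 (rejection sampling biased
# toward low vaccination and high transmission so acceptance is quick)
random_endemic_params <- function() {
  repeat {
    p <- sewir_params(Lambda = runif(1, 5, 30), beta = runif(1, 0.2, 1),
                      mu = runif(1, 0.01, 0.2), epsilon = runif(1, 0.3, 1.5),
                      gamma = runif(1, 0, 0.3), m = runif(1, 0, 0.5),
                      k1 = runif(1, 0, 1), vartheta = runif(1, 0, 1),
                      k2 = runif(1, 0, 0.3))
    if (r0_closed_form(p) > 1) return(p)
  }
}

# a random state inside the feasible region Omega
random_omega_state <- function(params, max_R = 50) {
  bound <- feasible_bound(params)
  raw <- runif(4)
  raw <- raw / sum(raw) * runif(1, 0, bound)
  sewir_state(S = raw[1], E = raw[2], W = raw[3], I = raw[4],
              R = runif(1, 0, max_R))
}

# rescale beta so the parameter set hits a prescribed R0 (R0 is linear
# in beta)
with_r0 <- function(params, target) {
  p <- unclass(params)
  p$beta <- p$beta * target / r0_closed_form(params)
  do.call(sewir_params, p)
}

# reorder an (E, I, S, W[, R]) equilibrium into internal (S,E,W,I,R) order
as_state_helper <- function(pt) {
  sewir_state(S = pt[["S"]], E = pt[["E"]], W = pt[["W"]], I = pt[["I"]],
              R = if ("R" %in% names(pt)) pt[["R"]] else 0)
}

# elementwise relative difference with a one-individual floor, used for
# integrator-convergence contracts
rel_diff <- function(a, b) max(abs(a - b) / pmax(abs(b), 1))
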
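test_that("an equilibrium initial condition is a fixed point of the flow", {
  p <- params_case2()
  ps <- endemic_equilibrium(p)
  traj <- sewir_simulate(p, as_state_helper(ps), t_end = 100,
                         output_step = 1)
  for (comp in c("S", "E", "W", "I", "R")) {
    expect_lt(max(abs(traj[[comp]] - ps[[comp]])), 1e-6 * max(1, ps[[comp]]))
  }
})

test_that("a subthreshold epidemic converges to the disease-free state", {
  p <- params_case1()
  traj <- sewir_simulate(p, default_init(), t_end = 500, output_step = 1)
  last <- traj[nrow(traj), ]
  expect_equal(last$S, 3.4091, tolerance = 1e-3)
  expect_lt(last$E + last$W + last$I, 1e-3)
})

test_that("distinct initial conditions converge to the same endemic state", {
  p <- params_case2()
  ps <- endemic_equilibrium(p)
  inits <- list(sewir_state(120, 0, 15, 1, 0),
                sewir_state(70, 0, 15, 1, 50),
                sewir_state(20, 0, 15, 1, 100))
  for (init in inits) {
    traj <- sewir_simulate(p, init, t_end = 500, output_step = 1)
    last <- unlist(traj[nrow(traj), c("E", "I", "S", "W")])
    expect_equal(unname(last), unname(ps[c("E", "I", "S", "W")]),
                 tolerance = 1e-3)
  }
})

test_that("intervention switches restart exactly and keep the state continuous", {
  p <- table1_params(m = 0.35, k1 = 0.6)
  sched <- sewir_schedule(time = 220, m = 0.8)
  traj <- sewir_simulate(p, default_init(), t_end = 300, schedule = sched,
                         output_step = 0.5)
  expect_true(220 %in% traj$t)
  expect_equal(sum(traj$t == 220), 1L)  # no duplicated switch row
  segs <- attr(traj, "params_used")
  expect_length(segs, 2L)
  expect_equal(segs[[1]]$m, 0.35)
  expect_equal(segs[[2]]$m, 0.8)
  expect_equal(segs[[2]]$k1, 0.6)      # untouched fields carry over
  # state continuity: no jump bigger than one step's worth of motion
  i <- which(traj$t == 220)
  step_move <- abs(traj$S[i + 1] - traj$S[i])
  expect_lt(step_move, 10)

  # schedules are validated strictly
  expect_error(sewir_schedule(time = c(30, 20), m = 0.5),
               class = "sewir_validation_error")
  expect_error(sewir_schedule(time = 10, nonsense = 1),
               class = "sewir_validation_error")
  expect_error(sewir_schedule(time = 10, m = 2),  # invalid merged params
               class = "sewir_validation_error")
})

test_that("halving integrator tolerances leaves trajectories unchanged to 1e-6", {
  p <- params_case1()
  a <- sewir_simulate(p, default_init(), t_end = 150, output_step = 1,
                      rtol = 1e-8, atol = 1e-10)
  b <- sewir_simulate(p, default_init(), t_end = 150, output_step = 1,
                      rtol = 5e-9, atol = 5e-11)
  for (comp in c("S", "E", "W", "I", "R")) {
    expect_lt(rel_diff(a[[comp]], b[[comp]]), 1e-6)
  }
})

test_that("adaptive and fixed-step integrators agree", {
  p <- params_case2()
  a <- sewir_simulate(p, default_init(), t_end = 100, output_step = 1)
  b <- sewir_simulate(p, default_init(), t_end = 100, output_step = 1,
                      method = "rk4", step = 0.02)
  for (comp in c("S", "E", "W", "I", "R")) {
    expect_lt(rel_diff(a[[comp]], b[[comp]]), 1e-4)
  }
})

test_that("trajectories started in Omega stay in Omega", {
  set.seed(301)
  p <- params_case1()
  bound <- feasible_bound(p)
  for (i in 1:5) {
    init <- random_omega_state(p)
    traj <- sewir_simulate(p, init, t_end = 300, output_step = 1)
    mass <- traj$S + traj$E + traj$W + traj$I
    expect_lte(max(mass), bound + 1e-6 * bound)
    expect_true(all(traj[c("S", "E", "W", "I", "R")] >= 0))
  }
})

test_that("randomized initial conditions reach the attractor by t = 500", {
  set.seed(302)
  inits <- replicate(10, random_omega_state(params_case1(), max_R = 30),
                     simplify = FALSE)
  # subthreshold parameters: global extinction of the infected compartments
  for (init in inits) {
    traj <- sewir_simulate(params_case1(), init, t_end = 500,
                           output_step = 5)
    last <- traj[nrow(traj), ]
    expect_lt(max(last$E, last$W, last$I), 1e-3)
  }
  # above-threshold parameters: global convergence to the endemic state
  ps <- endemic_equilibrium(params_case2())
  for (init in inits) {
    init["I"] <- max(init[["I"]], 0.1)  # seed the epidemic
    traj <- sewir_simulate(params_case2(), init, t_end = 500,
                           output_step = 5)
    last <- unlist(traj[nrow(traj), c("E", "I", "S", "W")])
    expect_equal(unname(last), unname(ps[c("E", "I", "S", "W")]),
                 tolerance = 1e-3)
  }
})

test_that("trajectory summaries report peaks, crossings and tie-breaks", {
  # constant trajectory: peak equals the constant, at the first grid point
  traj_const <- tibble::tibble(t = seq(0, 10, 0.5), S = 2, E = 1, W = 1,
                               I = 1, R = 0)
  s <- summarise_trajectory(traj_const)
  expect_equal(s$peak, c(2, 1, 1, 1, 0))
  expect_true(all(s$peak_time == 0))
  expect_equal(s$outbreak_peak, s$peak)

  # decaying epidemic: I crosses the threshold with interpolation
  traj <- sewir_simulate(params_case1(), default_init(), t_end = 300,
                         output_step = 0.5)
  s <- summarise_trajectory(traj, threshold = 1, control_start = 2)
  i_row <- s[s$compartment == "I", ]
  expect_false(is.na(i_row$time_below_threshold))
  expect_gt(i_row$time_below_threshold, 2)
  # interpolated crossing actually brackets the threshold
  tb <- i_row$time_below_threshold
  before <- max(traj$t[traj$t <= tb]); after <- min(traj$t[traj$t > tb])
  expect_gte(traj$I[traj$t == before], 1 - 1e-6)
  expect_lt(traj$I[traj$t == after], 1)
  # peaked-and-declined compartment: peak >= terminal
  expect_gte(i_row$peak, i_row$terminal)
  # never-below-threshold compartment is absent, not an error
  expect_true(is.na(s$time_below_threshold[s$compartment == "R"]))

  # reference deviation over the terminal window
  dfe <- disease_free_equilibrium(params_case1())
  ref <- c(S = dfe$S0, E = 0, W = 0, I = 0, R = dfe$R0_comp)
  s2 <- summarise_trajectory(traj, reference = ref, final_window = 50)
  expect_lt(max(s2$max_dev_final[s2$compartment %in% c("E", "W", "I")]),
            0.05)
})

test_that("integration inputs are validated and failures are explicit", {
  p <- params_case1()
  expect_error(sewir_simulate(p, default_init(), t_end = -5),
               class = "sewir_validation_error")
  expect_error(sewir_simulate(p, c(1, 2, 3), t_end = 10),
               class = "sewir_validation_error")
  expect_error(summarise_trajectory(tibble::tibble()),
               class = "sewir_validation_error")
})
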
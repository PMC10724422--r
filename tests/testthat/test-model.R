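test_that("resting state is an exact flux balance at c = n = 1", {
  p <- model_parameters()
  st <- resting_state(p)
  expect_equal(unname(st[["c"]]), 1)
  expect_equal(unname(st[["n"]]), 1)
  f <- model_fluxes(st, p, NULL, 0)
  expect_lt(abs(sum(f[c("J_theta", "J_cru", "J_pump", "J_leak", "J_ncx")])),
            1e-10)
  expect_lt(abs(sum(f[c("J_theta_star", "J_pump_star", "J_leak_star")])),
            1e-10)
  # randomized parameter sweep: the balance is solved at construction
  set.seed(42)
  for (i in 1:10) {
    pr <- model_parameters(V_pump = runif(1, 0.1, 1), K_pump = runif(1, 0.5, 2),
                           V_cru = runif(1, 0, 0.3), K_cru = runif(1, 1, 2.5),
                           m_cru = sample(2:6, 1), K_h = runif(1, 1, 3),
                           tau_h = runif(1, 5, 60), V_ncx = runif(1, 0.01, 0.5),
                           K_ncx = runif(1, 0.3, 2), q_ncx = runif(1, 0, 5),
                           k_na = runif(1, 0.001, 0.05))
    fr <- model_fluxes(resting_state(pr), pr, NULL, 0)
    expect_lt(abs(sum(fr[1:5])), 1e-10)
    expect_lt(abs(sum(fr[6:8])), 1e-10)
  }
})

test_that("a hand-edited leak is rejected as a configuration error", {
  p <- model_parameters()
  p$k_leak <- p$k_leak * 1.1
  expect_error(resting_state(p), "resting balance violated")
})

test_that("parameter invariants are enforced at construction", {
  expect_error(model_parameters(V_pump = -0.1), "strictly positive")
  expect_error(model_parameters(m_cru = 0.5), "m_cru")
  expect_error(model_parameters(q_ncx = -1), "q_ncx")
  # CRU release dominating extrusion at rest has no non-negative leak
  expect_error(model_parameters(V_cru = 50), "negative Ca2\\+ leak")
})

test_that("stimulus window is half-open and Na coupling follows the group", {
  p <- model_parameters()
  st <- resting_state(p)
  stim <- stimulus_influx(t_on = 10, duration = 3, intensity = 0.25,
                          na_coupled = TRUE)
  # before onset: both balances at zero
  f0 <- model_fluxes(st, p, stim, t = 9.99)
  expect_lt(abs(sum(f0[1:5])), 1e-10)
  # inside the pulse: both sums equal the intensity (Na+ coupled)
  f1 <- model_fluxes(st, p, stim, t = 10)
  expect_equal(unname(sum(f1[1:5])), 0.25, tolerance = 1e-9)
  expect_equal(unname(sum(f1[6:8])), 0.25, tolerance = 1e-9)
  # the window excludes its right edge
  f2 <- model_fluxes(st, p, stim, t = 13)
  expect_equal(unname(f2[["J_theta"]]), 0)
  # neighbor cells get calcium but no sodium
  stim_n <- stimulus_influx(10, 3, 0.25, na_coupled = FALSE)
  f3 <- model_fluxes(st, p, stim_n, t = 11)
  expect_equal(unname(f3[["J_theta"]]), 0.25)
  expect_equal(unname(f3[["J_theta_star"]]), 0)
})

test_that("flux signs follow their physiological direction", {
  p <- model_parameters()
  set.seed(7)
  for (i in 1:20) {
    st <- c(c = runif(1, 0.2, 4), n = runif(1, 0.5, 3), h = runif(1, 0, 1))
    f <- model_fluxes(st, p, NULL, 0)
    expect_lte(f[["J_pump"]], 0)
    expect_lte(f[["J_ncx"]], 0)
    expect_lte(f[["J_pump_star"]], 0)
    expect_gte(f[["J_cru"]], 0)
    expect_gte(f[["J_leak"]], 0)
    expect_gte(f[["J_leak_star"]], 0)
  }
})

test_that("raising cytosolic Na slows the exchanger only when q_ncx > 0", {
  p <- model_parameters(q_ncx = 3)
  f1 <- model_fluxes(c(c = 2, n = 1, h = 0.5), p, NULL, 0)
  f2 <- model_fluxes(c(c = 2, n = 2, h = 0.5), p, NULL, 0)
  expect_lt(abs(f2[["J_ncx"]]), abs(f1[["J_ncx"]]))
  p0 <- model_parameters(q_ncx = 0)
  g1 <- model_fluxes(c(c = 2, n = 1, h = 0.5), p0, NULL, 0)
  g2 <- model_fluxes(c(c = 2, n = 2, h = 0.5), p0, NULL, 0)
  expect_equal(g1[["J_ncx"]], g2[["J_ncx"]])
})

test_that("non-positive state variables raise a domain error naming them", {
  p <- model_parameters()
  expect_error(model_fluxes(c(c = -1, n = 1, h = 0.5), p), "c must be > 0")
  expect_error(model_fluxes(c(c = 1, n = 0, h = 0.5), p), "n must be > 0")
})

test_that("an unstimulated simulation stays at rest", {
  p <- model_parameters()
  stim <- stimulus_influx(10, 3, intensity = 0, na_coupled = TRUE)
  traj <- simulate_model(p, stim, t_end = 100, dt_out = 1)
  expect_lt(max(abs(traj$states$c - 1)), 1e-6)
  expect_lt(max(abs(traj$states$n - 1)), 1e-6)
})

test_that("concentrations stay positive across a random parameter sweep", {
  set.seed(11)
  for (i in 1:8) {
    pr <- model_parameters(V_pump = runif(1, 0.1, 0.8),
                           K_pump = runif(1, 0.8, 2.5),
                           V_cru = runif(1, 0, 0.4), K_cru = runif(1, 1.2, 2.5),
                           m_cru = sample(2:5, 1), K_h = runif(1, 1, 2.5),
                           tau_h = runif(1, 5, 40),
                           V_ncx = runif(1, 0.01, 0.3),
                           K_ncx = runif(1, 0.3, 1.5), q_ncx = runif(1, 0, 4),
                           k_na = runif(1, 0.001, 0.03))
    stim <- stimulus_influx(5, runif(1, 0.5, 5), runif(1, 0, 0.5))
    traj <- simulate_model(pr, stim, t_end = 120, dt_out = 1,
                           keep_fluxes = FALSE)
    expect_true(all(traj$states$c > 0))
    expect_true(all(traj$states$n > 0))
    expect_true(all(traj$states$h >= 0 & traj$states$h <= 1))
  }
})

test_that("Na coupling raises late-time calcium exactly when q_ncx > 0", {
  run_pair <- function(p) {
    s_t <- stimulus_influx(12.3, 2.7, 0.2, na_coupled = TRUE)
    s_n <- stimulus_influx(12.3, 2.7, 0.2, na_coupled = FALSE)
    list(t = simulate_model(p, s_t, 160, 1.23, keep_fluxes = FALSE),
         n = simulate_model(p, s_n, 160, 1.23, keep_fluxes = FALSE))
  }
  pq <- model_parameters()   # q_ncx > 0
  tr <- run_pair(pq)
  late <- tr$t$times > 40
  expect_true(all(tr$t$states$c[late] >= tr$n$states$c[late] - 1e-8))
  expect_gt(max(tr$t$states$c[late] - tr$n$states$c[late]), 0.01)
  p0 <- model_parameters(q_ncx = 0)
  tr0 <- run_pair(p0)
  expect_lt(max(abs(tr0$t$states$c - tr0$n$states$c)), 1e-6)
})

test_that("peak amplitude is non-decreasing in stimulus intensity", {
  p <- model_parameters()
  peaks <- vapply(seq(0, 0.4, length.out = 11), function(I) {
    stim <- stimulus_influx(12.3, 2.7, I)
    max(simulate_model(p, stim, 130, 1.23, keep_fluxes = FALSE)$states$c)
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-8))
})

test_that("calcium returns to rest after a finite pulse", {
  p <- model_parameters()
  stim <- stimulus_influx(12.3, 2.7, 0.2, na_coupled = TRUE)
  traj <- simulate_model(p, stim, t_end = 9000, dt_out = 30,
                         keep_fluxes = FALSE)
  expect_lt(abs(traj$states$c[length(traj$times)] - 1), 0.01)
})

test_that("adaptive integration matches a fixed-step RK4 reference", {
  p <- model_parameters()
  stim <- stimulus_influx(t_on = 5, duration = 2, intensity = 0.25)
  traj <- simulate_model(p, stim, t_end = 40, dt_out = 1, keep_fluxes = FALSE)
  ref <- rk4_reference(p, stim, t_end = 40, dt = 1e-3)
  ref_c <- ref$c[match(traj$times, ref$t)]
  expect_true(all(is.finite(ref_c)))
  expect_lt(max(abs(traj$states$c - ref_c) / ref_c), 1e-4)
})

test_that("simulation preconditions are enforced", {
  p <- model_parameters()
  stim <- stimulus_influx(10, 5, 0.1)
  expect_error(simulate_model(p, stim, t_end = 12, dt_out = 1),
               "t_end must exceed")
  expect_error(simulate_model(p, stim, t_end = 100, dt_out = 0), "dt_out")
})

test_that("trajectory-to-trace aligns the frame grid on the stimulus", {
  p <- model_parameters()
  stim <- stimulus_influx(12.3, 2.7, 0.2)
  traj <- simulate_model(p, stim, t_end = 162, dt_out = 1.23,
                         keep_fluxes = FALSE)
  tr <- trajectory_to_trace(traj, frame_interval = 1.23,
                            n_baseline_frames = 10, n_post_frames = 121)
  expect_equal(tr$stim_frame, 10L)
  expect_equal(length(tr$intensity), 131L)
  expect_equal(tr$time[11], 12.3)        # first post-stimulus frame at t_on
  expect_lt(max(abs(tr$intensity[1:10] - 1)), 1e-9)
  # subsampling cannot beat the dense trajectory maximum
  dense <- simulate_model(p, stim, t_end = 162, dt_out = 0.05,
                          keep_fluxes = FALSE)
  expect_lte(max(tr$intensity), max(dense$states$c) + 1e-9)
  # unstimulated trajectory maps to a flat unit trace
  traj0 <- simulate_model(p, stimulus_influx(12.3, 2.7, 0), 162, 1.23,
                          keep_fluxes = FALSE)
  tr0 <- trajectory_to_trace(traj0)
  expect_lt(max(abs(tr0$intensity - 1)), 1e-6)
  # insufficient pre-stimulus span is a precondition error
  traj_short <- simulate_model(p, stimulus_influx(2, 1, 0.1), 60, 0.5)
  expect_error(trajectory_to_trace(traj_short, 1.23, 10, 30),
               "pre-stimulus")
})
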
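# Four-state filter scheme: loading equilibrium, generator structure,
# propagation, steady states, and simulated currents.

symk <- bath_conditions(c(K = 120), c(K = 120))

test_that("loading equilibrium is the Boltzmann of the driving force", {
  p <- gating_params(z = 2.2, dmu_half = -10, k_act = 0.25, k_inact = 0.25)
  expect_equal(loading_equilibrium(-10, p), 0.5)
  # one slope unit above the midpoint: s = 25.33/2.2 = 11.52 mV
  expect_equal(loading_equilibrium(-10 + 11.5, p), 0.731, tolerance = 2e-3)
  expect_lt(loading_equilibrium(-500, p), 1e-9)
  expect_gt(loading_equilibrium(500, p), 1 - 1e-9)
})

test_that("generator columns sum to zero and loading obeys detailed balance", {
  p <- gating_params(z = 2.55, dmu_half = -20, k_act = 0.23, k_inact = 0.25)
  for (vm in c(-60, -20, 0, 15, 40, 80)) {
    Q <- rate_matrix(vm, symk, p)
    expect_lt(max(abs(colSums(Q))), 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
    pl <- loading_equilibrium(vm, p)  # symmetric K+: dmu = vm
    expect_equal(Q["IO", "ID"] / Q["ID", "IO"], pl / (1 - pl),
                 tolerance = 1e-9)
  }
})

test_that("the conformational activation rate is voltage independent", {
  p <- gating_params(z = 2.55, dmu_half = -20, k_act = 0.23, k_inact = 0.25)
  q20 <- rate_matrix(20, symk, p)["AO", "IO"]
  q100 <- rate_matrix(100, symk, p)["AO", "IO"]
  expect_identical(q20, q100)
  expect_identical(q20, p$k_act)
})

test_that("state vectors must be normalised probabilities", {
  expect_error(state_vector(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(state_vector(c(1.2, -0.2, 0, 0)), "sum to 1|\\[0, 1\\]")
  expect_silent(state_vector(c(ID = 1, IO = 0, AO = 0, AI = 0)))
})

test_that("a zero generator leaves the state unchanged", {
  p0 <- c(0.4, 0.3, 0.2, 0.1)
  res <- fluxgate:::.propagate_const(matrix(0, 4, 4), p0,
                                     times = seq(0, 5, 0.5), t_end = 5)
  expect_equal(res$states, matrix(p0, 4, 11), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(res$p_end, p0, tolerance = 1e-12)
})

test_that("matrix-exponential propagation matches a fine-step Euler oracle", {
  # slow-rate regime where the first-order Euler error at dt/1000 is < 1e-6
  par <- gating_params(z = 2, dmu_half = 0, k_load0 = 0.05, k_act = 0.02,
                       k_deact = 0.01, k_inact = 0.03, k_switch = 0.04)
  seg <- data.frame(ms = c(2, 2), mV = c(-20, 20))
  prot <- voltage_protocol(seg, dt = 0.1)
  p0 <- state_vector(c(ID = 0.4, IO = 0.3, AO = 0.2, AI = 0.1))
  res <- propagate(p0, prot, symk, par)
  oracle <- euler_oracle(p0, seg, symk, par, res$time, h = 0.1 / 1000)
  expect_lt(max(abs(res$states - oracle)), 1e-6)
  expect_lt(max(abs(rowSums(res$states) - 1)), 1e-9)
})

test_that("a long hold converges to the stationary distribution", {
  pr <- get_preset("traak_wt_symK")
  p0 <- state_vector(c(ID = 0.25, IO = 0.25, AO = 0.25, AI = 0.25))
  for (vm in c(-40, 20, 80)) {
    prot <- voltage_protocol(data.frame(ms = 400, mV = vm), dt = 1)
    res <- propagate(p0, prot, pr$conditions, pr$params)
    ss <- steady_state(vm, pr$conditions, pr$params)
    expect_equal(unname(res$states[nrow(res$states), ]), unname(unclass(ss)),
                 tolerance = 1e-8)
  }
})

test_that("the holding potential leaves TRAAK ion-depleted", {
  pr <- get_preset("traak_wt_symK")
  ss <- steady_state(-80, pr$conditions, pr$params)
  expect_gt(ss["ID"], 0.9)
})

test_that("simulated current scales with channel count and vanishes at n = 0", {
  pr <- get_preset("traak_wt_symK")
  par0 <- pr$params
  par0$n_channels <- 0
  prot <- voltage_protocol(data.frame(ms = c(20, 80, 40),
                                      mV = c(-80, 60, -80)), dt = 0.1)
  tr0 <- simulate_current(prot, pr$conditions, par0)
  expect_true(all(tr0$current_pA == 0))
})

test_that("flux-gated tails decay with the inactivation time constant", {
  fam <- quick_family("traak_wt_symK", prepulse_mV = c(-80, 100))
  tau <- tail_tau(fam)
  k_inact <- get_preset("traak_wt_symK")$params$k_inact
  expect_equal(tau, 1 / k_inact, tolerance = 0.02)
})

test_that("check valve: no steady-state current for any voltage below Erev", {
  pr <- get_preset("traak_wt_symK")
  par <- pr$params
  par$po_floor <- 0
  for (vm in c(-120, -60, -10, -1)) {
    ss <- steady_state(vm, pr$conditions, par)
    expect_lt(ss["AO"] + ss["AI"], 1e-12)
  }
  # transient inward current exists only after a depolarised pre-pulse
  fam <- quick_family("traak_wt_symK", prepulse_mV = c(-80, 100),
                      params = par)
  tail_of <- function(tr) {
    sel <- tr$time_ms >= 20 + 120 + 0.5
    min(tr$current_pA[sel])
  }
  expect_lt(tail_of(fam$traces[["100mV"]]), -100)   # large inward tail
  expect_gt(tail_of(fam$traces[["-80mV"]]), -1e-9)  # none without pre-pulse
})

test_that("leak mode gives a linear, history-free I-V", {
  fam <- quick_family("twik1_leak",
                      prepulse_mV = seq(-100, 100, 20))
  iv <- vapply(seq_along(fam$step_mV), function(i)
    end_of_step_current(fam$traces[[i]], fam$step_start_ms,
                        fam$tail_start_ms), numeric(1))
  expect_gt(suppressWarnings(
    summary(stats::lm(iv ~ fam$step_mV))$r.squared), 0.999)
  amps <- vapply(fam$traces, function(tr)
    extract_tail_amplitude(tr, fam$tail_start_ms)$amplitude, numeric(1))
  expect_lt(diff(range(amps)), 1e-6 * max(abs(amps)))
})

test_that("protocol validation enforces sane segments", {
  expect_error(voltage_protocol(data.frame(ms = -5, mV = 0)), "> 0")
  expect_error(voltage_protocol(data.frame(ms = 1, mV = 0), dt = 2),
               "shortest")
  expect_error(
    propagate(state_vector(c(ID = 1, IO = 0, AO = 0, AI = 0)),
              list(), symk, get_preset("traak_wt_symK")$params))
})
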
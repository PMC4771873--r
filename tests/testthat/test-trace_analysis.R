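# Exponential, Boltzmann and Hill fitting; tails, rectification, coupling.

test_that("exponential fit recovers a noise-free time constant exactly", {
  tr <- make_exp_trace(tau = 4, a = 120, b = 10)
  fit <- fit_exponential(tr, c(0, 40))
  expect_equal(fit$tau, 4, tolerance = 1e-6)
  expect_equal(fit$amplitude, 120, tolerance = 1e-4)
  expect_equal(fit$baseline, 10, tolerance = 1e-4)
})

test_that("exponential fit is unbiased under 5% noise", {
  set.seed(42)
  taus <- replicate(100, {
    tr <- make_exp_trace(tau = 4, a = 120, b = 10)
    tr$current_pA <- tr$current_pA + stats::rnorm(nrow(tr), 0, 0.05 * 120)
    fit_exponential(tr, c(0, 40))$tau
  })
  expect_lt(abs(mean(taus) - 4) / 4, 0.02)
})

test_that("a flat trace is rejected with a diagnostic", {
  t <- seq(0, 20, 0.05)
  tr <- current_trace(t, rep(0, length(t)), rep(7, length(t)))
  expect_error(fit_exponential(tr, c(0, 20)), "flat")
})

test_that("tail extrapolation recovers the instantaneous amplitude", {
  # step ends at t = 10; tail decays from a known instantaneous value
  t <- seq(0, 60, 0.05)
  a0 <- -500
  b <- -12
  i <- ifelse(t < 10, 300, a0 * exp(-(t - 10) / 4) + b)
  tr <- current_trace(t, ifelse(t < 10, 100, -80), i)
  tf <- extract_tail_amplitude(tr, 10)
  expect_equal(tf$amplitude, a0 + b, tolerance = 0.01 * abs(a0))
  expect_equal(tf$tau, 4, tolerance = 1e-3)
  expect_error(extract_tail_amplitude(tr, 58), "5 ms")
})

test_that("tail amplitudes rise monotonically with the pre-pulse", {
  fam <- quick_family("traak_wt_symK", prepulse_mV = seq(-20, 100, 20))
  amps <- vapply(fam$traces, function(tr)
    abs(extract_tail_amplitude(tr, fam$tail_start_ms)$amplitude), numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("Boltzmann fit recovers noise-free parameters exactly", {
  gv <- make_boltzmann_gv(z = 2.2, v_half = -15, amp = 1, offset = 0.02)
  fit <- fit_boltzmann(gv)
  expect_lt(abs(fit$z - 2.2) / 2.2, 1e-3)
  expect_equal(fit$v_half, -15, tolerance = 0.01)
  expect_true(fit$saturated)
})

test_that("gating charge from the slope is temperature consistent", {
  for (tk in c(284, 304)) {
    gv <- make_boltzmann_gv(z = 2.4, v_half = 0, temperature = tk)
    expect_lt(abs(fit_boltzmann(gv, temperature = tk)$z - 2.4) / 2.4, 1e-3)
  }
})

test_that("non-saturating curves are flagged", {
  # plateau far above the sampled range
  gv <- make_boltzmann_gv(z = 1.5, v_half = 150, v = seq(-100, 100, 20))
  fit <- fit_boltzmann(gv)
  expect_false(fit$saturated)
  expect_error(fit_boltzmann(gv[1:3, ]), "at least 5")
})

test_that("simulate -> analyze recovers preset z and kinetics end to end", {
  pr <- get_preset("traak_rb")
  fam <- generate_family(pr, prepulse_mV = seq(-40, 160, 20))
  fit <- fit_gv_family(fam)$fit
  expect_lt(abs(fit$z - pr$params$z) / pr$params$z, 0.02)
  # activation relaxes at p_load * k_act + k_deact (analytic oracle, loading
  # pre-equilibrated); tail decays at k_inact
  pk <- get_preset("traak_wt_symK")$params
  fam2 <- generate_family("traak_wt_symK", prepulse_mV = c(60, 100))
  tau <- activation_tau(fam2, step_mV = 60)$tau_ms
  tau_true <- 1 / (loading_equilibrium(60, pk) * pk$k_act + pk$k_deact)
  expect_lt(abs(tau - tau_true) / tau_true, 0.05)
  expect_equal(tail_tau(fam2), 1 / pk$k_inact, tolerance = 0.05)
})

test_that("rectification coefficient is 1 for a leak and errs on silence", {
  leak <- quick_family("twik1_leak", prepulse_mV = c(-100, 0, 100))
  expect_equal(rectification_coefficient(leak), 1, tolerance = 0.01)
  dead <- leak
  dead$traces <- lapply(dead$traces, function(tr) {
    tr$current_pA <- tr$current_pA * 0
    tr
  })
  expect_error(rectification_coefficient(dead), "noise floor")
})

test_that("tail fold change distinguishes leak from flux-gated channels", {
  leak <- quick_family("twik1_leak", prepulse_mV = c(-100, -80, 0, 100))
  expect_equal(tail_fold_change(leak), 1, tolerance = 1e-6)
  gated <- quick_family("traak_wt_symK", prepulse_mV = c(-100, -80, 0, 100))
  expect_gt(tail_fold_change(gated), 10)
})

test_that("Hill fit recovers noise-free dose-response parameters", {
  cc <- 10^seq(-1.5, 2, length.out = 8)
  y <- 1 + 49 / (1 + (3.5 / cc)^1.4)
  fit <- fit_hill(data.frame(concentration_uM = cc, fold_activation = y))
  expect_equal(fit$ec50, 3.5, tolerance = 1e-4)
  expect_equal(fit$n, 1.4, tolerance = 1e-4)
  expect_equal(fit$fmax, 50, tolerance = 1e-3)
  flat <- data.frame(concentration_uM = cc, fold_activation = rep(1, 8))
  expect_error(fit_hill(flat), "flat")
  wobble <- data.frame(concentration_uM = cc,
                       fold_activation = c(5, 1, 4, 2, 3, 2, 4, 1))
  expect_error(fit_hill(wobble), "monoton")
})

test_that("V1/2 regression detects both coupled and uncoupled sensors", {
  # erev-independent synthetic: fixed V1/2 -> slope 0
  tbl <- data.frame(erev_mV = c(-80, -40, 0, 30), v_half_mV = rep(12, 4))
  expect_equal(v_half_vs_erev(tbl)$slope, 0, tolerance = 1e-12)
  expect_error(v_half_vs_erev(tbl[1:2, ]), "at least 3")
  same <- data.frame(erev_mV = rep(0, 4), v_half_mV = 1:4)
  expect_error(v_half_vs_erev(same), "identical")
})
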
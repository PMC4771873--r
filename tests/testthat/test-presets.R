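# Preset registry, provenance, and the synthetic generators.

test_that("the registry carries the expected channel presets", {
  names <- list_presets()$name
  required <- c("traak_wt_symK", "trek1_wt_symK", "trek1_rb",
                "trek2_wt_symK", "talk2_wt_symK", "task3_wt_symK",
                "tresk_wt_symK", "twik1_leak", "kv_control", "traak_aa",
                "traak_physK", "traak_invK")
  expect_true(all(required %in% names))
  expect_error(get_preset("nope"), "unknown preset")
})

test_that("every preset simulates the step family without error", {
  for (nm in list_presets()$name) {
    fam <- quick_family(nm, prepulse_mV = c(-100, 100))
    expect_true(all(is.finite(unlist(lapply(fam$traces,
                                            `[[`, "current_pA")))),
                info = nm)
  }
})

test_that("every preset documents provenance for its parameters", {
  for (nm in list_presets()$name) {
    pr <- get_preset(nm)
    expect_gt(length(pr$provenance), 0)
    expect_true(all(nzchar(unlist(pr$provenance))), info = nm)
  }
})

test_that("twik1 is a pure GHK leak and the inverted gradient silences TRAAK", {
  expect_equal(get_preset("twik1_leak")$params$mode_shift, 1)
  # mode shift 0 -> 1 at -80 mV in the inverted gradient boosts the inward
  # current by far more than 50-fold (the check-valve holds it shut)
  pr <- get_preset("traak_invK")
  ss <- steady_state(-80, pr$conditions, pr$params)
  po_gated <- ss["AO"] + ss["AI"] +
    pr$params$po_floor * (ss["ID"] + ss["IO"])
  expect_gt(1 / po_gated, 50)
})

test_that("families are reproducible and exactly noise-free at sigma 0", {
  a <- quick_family("traak_wt_symK", prepulse_mV = c(0, 100),
                    noise = 0.02, seed = 7)
  b <- quick_family("traak_wt_symK", prepulse_mV = c(0, 100),
                    noise = 0.02, seed = 7)
  expect_identical(a$traces[["100mV"]]$current_pA,
                   b$traces[["100mV"]]$current_pA)
  clean <- quick_family("traak_wt_symK", prepulse_mV = c(100))
  pr <- get_preset("traak_wt_symK")
  prot <- voltage_protocol(data.frame(ms = c(20, 120, 60),
                                      mV = c(-80, 100, -80)), dt = 0.1)
  direct <- simulate_current(prot, pr$conditions, pr$params)
  expect_identical(clean$traces[[1]]$current_pA, direct$current_pA)
})

test_that("flux-gated K2P families rectify strongly outward", {
  fam <- generate_family("traak_wt_symK")
  expect_gt(rectification_coefficient(fam), 10)
})

test_that("dose-response generation follows the preset Hill law", {
  expect_error(generate_dose_response("traak_aa", numeric(0)), "empty")
  expect_error(generate_dose_response("traak_wt_symK", 1), "mode-shift law")
  dr <- generate_dose_response("traak_aa", c(0, 0.3, 1.2, 10, 1000))
  expect_equal(dr$fold_activation[1], 1)
  # saturating concentration approaches the maximal fold (1/po_gated)
  fmax <- 1 / attr(dr, "truth")$po_gated
  expect_equal(dr$fold_activation[5], fmax, tolerance = 0.01)
  # round trip: Hill fit on a noise-free series recovers the preset EC50
  cc <- 10^seq(-1, log10(30), length.out = 7)
  fit <- fit_hill(generate_dose_response("traak_aa", cc))
  expect_equal(fit$ec50, 1.2, tolerance = 1e-3)
  expect_equal(fit$n, 1.3, tolerance = 1e-3)
})

test_that("mode-shift fractions interpolate the Hill law", {
  pr <- get_preset("traak_aa")
  expect_equal(mode_shift_fraction(pr, 0), 0)
  expect_equal(mode_shift_fraction(pr, pr$hill$ec50_uM),
               pr$hill$m_max / 2, tolerance = 1e-12)
})
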
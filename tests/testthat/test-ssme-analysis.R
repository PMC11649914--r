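make_trace <- function(t, i, phase = rep("A", length(t))) {
  structure(data.frame(time_s = t, current_nA = i, phase = phase,
                       stringsAsFactors = FALSE),
            class = c("current_trace", "data.frame"))
}

test_that("peak_current returns the signed A-phase extremum", {
  t <- seq(0, 1, by = 1e-3)
  tr <- make_trace(c(t, t + 1.001), c(rep(0, length(t)), 2 * exp(-t / 0.1)),
                   c(rep("NA", length(t)), rep("A", length(t))))
  pk <- peak_current(tr)
  expect_equal(pk$peak_nA, 2)
  ## negative transient keeps its sign
  tr$current_nA <- -tr$current_nA
  expect_equal(peak_current(tr)$peak_nA, -2)
  ## flat zero trace: 0 at A onset
  tr$current_nA <- 0
  pk0 <- peak_current(tr)
  expect_equal(pk0$peak_nA, 0)
  expect_equal(pk0$index, which(tr$phase == "A")[1])
  expect_error(peak_current(make_trace(t, t * 0, rep("NA", length(t)))),
               "no A phase")
})

test_that("mono-exponential decay is recovered exactly on noiseless data", {
  t <- seq(0, 0.2, by = 1e-3)
  tr <- make_trace(t, 1 * exp(-t / 0.02))
  f <- fit_decay(tr, 1)
  expect_equal(f$tau_s, 0.02, tolerance = 1e-6)
  expect_equal(f$amplitudes_nA, 1, tolerance = 1e-6)
  expect_equal(f$k_obs, 50, tolerance = 1e-6)
})

test_that("bi-exponential components are recovered within 5% at SNR 100", {
  t <- seq(0, 0.3, by = 5e-4)
  y <- 0.6 * exp(-t / 0.005) + 0.4 * exp(-t / 0.05)
  set.seed(42)
  tr <- make_trace(t, y + rnorm(length(t), sd = max(y) / 100))
  f <- fit_decay(tr, 2)
  expect_equal(f$tau_s[1], 0.005, tolerance = 0.05)
  expect_equal(f$tau_s[2], 0.05, tolerance = 0.05)
  expect_equal(abs(f$amplitudes_nA[1]), 0.6, tolerance = 0.1)
})

test_that("a WT-like pre-steady-state trace yields k_obs near 79 1/s", {
  ## trace generated from the induced-fit model at 50 mM galactonate with
  ## the wild-type parameters (K_D 15.1 mM, k+ 70.6, k- 23.8)
  k_obs_true <- kobs_model(50, 15.1, 70.6, 23.8)
  t <- seq(0, 0.15, by = 2e-4)
  tr <- make_trace(t, 0.7 * exp(-t * k_obs_true))
  f <- fit_decay(tr, 1)
  expect_equal(f$k_obs, k_obs_true, tolerance = 1e-6)
  ## consistent with the reported 79 +/- 14 1/s
  expect_lt(abs(f$k_obs - 79), 14)
})

test_that("kobs_model has the hyperbolic limits", {
  expect_equal(kobs_model(0, 15.1, 70.6, 23.8), 23.8)
  expect_equal(kobs_model(1e9, 15.1, 70.6, 23.8), 23.8 + 70.6,
               tolerance = 1e-6)
  expect_equal(kobs_model(50, 15.1, 70.6, 23.8), 78.0, tolerance = 0.01)
  expect_error(kobs_model(-1, 15.1, 70.6, 23.8), "non-negative")
})

test_that("pKa fits recover titration parameters", {
  ## half-saturation identity at pH = pK
  expect_equal(1 / (1 + 10^(6 - 6)), 0.5)
  pH <- seq(4.5, 8, by = 0.5)
  d <- gen_pka_dataset(pK = 6, I_max = 1, mode = "acidic", pH = pH,
                       noise_frac = 0.03, seed = 11)
  f <- pka_fit(d$pH, d$current, "acidic")
  expect_equal(f$pK, 6, tolerance = 0.1 / 6)
  expect_equal(f$I_max, 1, tolerance = 0.05)
  ## alkaline mode on its own curve
  d2 <- gen_pka_dataset(pK = 8.6, I_max = 2, mode = "alkaline",
                        pH = seq(7.5, 10, by = 0.5), noise_frac = 0.02,
                        seed = 3)
  f2 <- pka_fit(d2$pH, d2$current, "alkaline")
  expect_equal(f2$pK, 8.6, tolerance = 0.1 / 8.6)
  ## wrong mode on monotone-increasing data is flagged
  expect_error(pka_fit(seq(7.5, 10, by = 0.5),
                       1 / (1 + 10^(6 - seq(7.5, 10, by = 0.5))),
                       "alkaline"), "mode")
  expect_error(pka_fit(c(5, 6), c(0.1, 0.5), "acidic"), "3 points")
})

test_that("pKa recovery: median absolute error < 0.05 over 100 datasets", {
  errs <- vapply(1:100, function(s) {
    d <- gen_pka_dataset(pK = 6, I_max = 1, mode = "acidic",
                         pH = seq(4.5, 8, by = 0.5), noise_frac = 0.03,
                         seed = s)
    abs(pka_fit(d$pH, d$current, "acidic")$pK - 6)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("induced-fit fits recover Table-style truths exactly without noise", {
  concs <- c(2, 5, 10, 20, 40, 80, 160)
  for (truth in list(c(15.1, 70.6, 23.8), c(10.9, 69.9, 6.6))) {
    k <- kobs_model(concs, truth[1], truth[2], truth[3])
    f <- fit_induced_fit(concs, k)
    expect_equal(f$K_D, truth[1], tolerance = 1e-6)
    expect_equal(f$k_plus, truth[2], tolerance = 1e-6)
    expect_equal(f$k_minus, truth[3], tolerance = 1e-6)
  }
  expect_error(fit_induced_fit(c(1, 10), c(25, 60)), "4 distinct")
  ## degenerate design far below K_D
  k <- kobs_model(c(0.1, 0.2, 0.3, 0.4), 15.1, 70.6, 23.8)
  expect_warning(fit_induced_fit(c(0.1, 0.2, 0.3, 0.4), k), "identifies")
})

test_that("chemical-potential ratio matches the closed form and its symmetry", {
  cond <- solution_condition(7.3, 7.6, 0.5, 2.0)
  expect_equal(chemical_potential_ratio(cond),
               log(0.25) / (-0.3 * log(10)), tolerance = 1e-12)
  expect_equal(chemical_potential_ratio(cond), 2.01, tolerance = 0.005)
  ## equal galactonate: 0
  expect_equal(chemical_potential_ratio(solution_condition(7, 7.4, 3, 3)), 0)
  ## swapping both gradients leaves the ratio unchanged
  swapped <- solution_condition(7.6, 7.3, 2.0, 0.5)
  expect_equal(chemical_potential_ratio(swapped),
               chemical_potential_ratio(cond))
  expect_error(chemical_potential_ratio(solution_condition(7, 7, 1, 2)),
               "equals")
})

test_that("charge integration matches closed-form integrals", {
  t <- seq(0, 1, by = 1e-4)
  ## rectangular 1 nA x 1 s pulse = 1 nC
  tr <- make_trace(t, rep(1, length(t)))
  expect_equal(integrate_charge(tr, baseline = 0), 1, tolerance = 1e-6)
  ## zero-mean biphasic transient integrates to ~0
  tr2 <- make_trace(t, sin(2 * pi * t))
  expect_lt(abs(integrate_charge(tr2, baseline = 0)), 1e-6)
  ## analytic A tau (1 - exp(-T/tau))
  A <- 2.5; tau <- 0.1
  tr3 <- make_trace(t, A * exp(-t / tau))
  expect_equal(integrate_charge(tr3, baseline = 0),
               A * tau * (1 - exp(-1 / tau)), tolerance = 1e-6)
})

test_that("control subtraction is exact on matched grids and close after resampling", {
  t <- seq(0, 1, by = 1e-3)
  tr <- make_trace(t, sin(2 * pi * t))
  ctl <- make_trace(t, 0.2 * cos(2 * pi * t))
  out <- subtract_control(tr, ctl)
  expect_equal(out$current_nA, tr$current_nA - ctl$current_nA)
  ## identical traces give a zero trace; zero control is the identity
  expect_true(all(subtract_control(tr, tr)$current_nA == 0))
  expect_equal(subtract_control(tr, make_trace(t, 0 * t))$current_nA,
               tr$current_nA)
  ## resampled control agrees with the exact-grid case
  t2 <- seq(0, 1, by = 1e-3 / 3)
  ctl2 <- make_trace(t2, 0.2 * cos(2 * pi * t2))
  expect_error(subtract_control(tr, ctl2), "resample")
  out2 <- subtract_control(tr, ctl2, resample = TRUE)
  expect_equal(out2$current_nA, out$current_nA, tolerance = 1e-4)
})

test_that("reversal zero-crossing interpolation brackets correctly", {
  s <- stoichiometry_from_reversal(c(1, 3), c(1, -1))
  expect_equal(s$n_over_m, 2)
  expect_equal(s$bracket, c(1, 3))
  expect_error(stoichiometry_from_reversal(c(1, 2, 3), c(1, 2, 3)),
               "no reversal")
})

test_that("LPR decay comparison distinguishes transport from pre-steady state", {
  t <- seq(0, 1, by = 1e-3)
  mk <- function(tau) make_trace(t, exp(-t / tau))
  ## turnover-limited discharge: tau falls as LPR rises
  res <- lpr_decay_comparison(list(mk(0.4), mk(0.2), mk(0.1)),
                              lpr = c(25, 50, 100))
  expect_equal(res$verdict, "monotone_decreasing")
  ## identical decays across LPR: pre-steady-state signature
  res2 <- lpr_decay_comparison(list(mk(0.2), mk(0.2), mk(0.2)),
                               lpr = c(25, 50, 100))
  expect_equal(res2$verdict, "independent")
  ## shuffled: non-monotone
  res3 <- lpr_decay_comparison(list(mk(0.2), mk(0.4), mk(0.1)),
                               lpr = c(25, 50, 100))
  expect_equal(res3$verdict, "non_monotone")
  expect_error(lpr_decay_comparison(list(mk(0.2)), lpr = 25), "two LPR")
})
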
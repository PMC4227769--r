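test_that("generating parameters are recovered exactly from noiseless sums", {
  tt <- seq(0.001, 2, length.out = 300)
  y <- 1 + 0.5 * exp(-100 * tt) - 0.8 * exp(-3.6 * tt)
  fit <- fit_exponential_phases(data.frame(tt, y), 2)
  expect_rel(fit$rates[1], 100, 1e-6)
  expect_rel(fit$rates[2], 3.6, 1e-6)
  expect_rel(fit$amplitudes[1], 0.5, 1e-6)
  expect_rel(fit$amplitudes[2], -0.8, 1e-6)
  expect_rel(fit$y_inf, 1, 1e-6)
  expect_true(fit$converged)
  expect_true(all(diff(fit$rates) <= 0))  # descending order
})

test_that("fits are invariant under time-unit rescaling", {
  tt <- seq(0.001, 2, length.out = 300)
  y <- 1 + 0.5 * exp(-100 * tt) - 0.8 * exp(-3.6 * tt)
  fs <- fit_exponential_phases(data.frame(tt, y), 2)
  fms <- fit_exponential_phases(data.frame(tt * 1000, y), 2)  # ms axis
  expect_rel(fms$rates[1] * 1000, fs$rates[1], 1e-6)
  expect_rel(fms$rates[2] * 1000, fs$rates[2], 1e-6)
})

test_that("degenerate fits are refused or flagged rather than reported", {
  tt <- seq(0.001, 2, length.out = 300)
  # constant trace: amplitude zero, rate unidentifiable
  fc <- fit_exponential_phases(data.frame(tt, rep(2, 300)), 1)
  expect_lt(abs(fc$amplitudes[1]), 1e-8)
  expect_false(fc$identifiable[1])
  # three phases requested on two-phase data: third amplitude ~ 0
  y2 <- 1 + 0.5 * exp(-100 * tt) - 0.8 * exp(-3.6 * tt)
  f3 <- fit_exponential_phases(data.frame(tt, y2), 3)
  spurious <- which.min(abs(f3$amplitudes))
  expect_lt(abs(f3$amplitudes[spurious]), 1e-8)
  expect_false(f3$identifiable[spurious])
  # rates closer than 5% are merged and flagged
  ym <- 1 + 0.5 * exp(-10 * tt) + 0.4 * exp(-10.2 * tt)
  fm <- fit_exponential_phases(data.frame(tt, ym), 2)
  expect_true(fm$merged)
  expect_equal(fm$n_used, 1L)
  expect_error(fit_exponential_phases(data.frame(tt[1:4], y2[1:4]), 1),
               "at least")
})

test_that("flip phase of a saturating WT trace reads the flipping rate", {
  fit <- fit_exponential_phases(wt_tec_association(), 2)
  expect_rel(min(fit$rates), 3.6, 0.02)
})

test_that("bimolecular slope regression is exact on exact points", {
  conc <- c(0.5, 1, 2, 3, 4) * 1e-7
  rate <- 1.1e9 * conc - 20
  out <- fit_bimolecular_slope(conc, rate)
  expect_rel(out$k_on, 1.1e9, 1e-9)
  expect_equal(out$intercept, -20, tolerance = 1e-6)
  flat <- fit_bimolecular_slope(conc, rep(80, 5))
  expect_lt(abs(flat$k_on), 1e-3)  # zero slope to numerical precision
  expect_error(fit_bimolecular_slope(rep(1e-7, 4), 1:4), "singular")
  expect_error(fit_bimolecular_slope(conc[1:2], rate[1:2]), ">= 3")
})

test_that("concentration dependence is classified by slope significance", {
  conc <- c(2, 4, 6, 8, 10) * 1e-7
  flat <- classify_concentration_dependence(conc, rep(116, 5))
  expect_equal(flat$classification, "independent")
  expect_equal(flat$summary_rate, 116)
  lin <- classify_concentration_dependence(conc, 2e8 * conc)
  expect_equal(lin$classification, "dependent")
  lin_w <- classify_concentration_dependence(conc, 2e8 * conc,
                                             sd = rep(0.5, 5))
  expect_equal(lin_w$classification, "dependent")
  noisy <- classify_concentration_dependence(
    conc, 116 + c(-1, 2, 0.5, -2, 1), sd = rep(2, 5))
  expect_equal(noisy$classification, "independent")
  expect_rel(noisy$summary_rate, 116, 0.02)
  expect_error(classify_concentration_dependence(conc, 1:5, sd = rep(0, 5)),
               "zero-variance")
})

test_that("quadratic binding fits recover Kd, stoichiometry and quench", {
  E <- seq(0, 1.2e-6, length.out = 25)
  cur <- synthesize_titration(Kd = 5e-9, n = 1, D_tot = 4e-7,
                              enzyme_series = E, quench_factor = 5)
  fb <- fit_quadratic_binding(cur, 4e-7)
  expect_rel(fb$Kd, 5e-9, 0.2)
  expect_rel(fb$n, 1, 0.02)
  expect_rel(fb$quench_factor, 5, 0.02)
  expect_true(fb$Kd_is_limit)   # tight-binding regime: Kd is an upper limit
  cur0 <- synthesize_titration(Kd = 0, n = 1, D_tot = 4e-7,
                               enzyme_series = E, quench_factor = 5)
  fb0 <- fit_quadratic_binding(cur0, 4e-7)
  expect_rel(fb0$n, 1, 0.02)
  expect_true(fb0$Kd_is_limit)
  expect_error(fit_quadratic_binding(data.frame(E, rep(1, 25)), 4e-7),
               "curvature|unidentifiable")
})

test_that("IC50 fits recover inhibition and flag its absence", {
  s <- synthesize_competition_series(0.02, 20e-6,
                                     c(0, 2e-6, 5e-6, 1e-5, 2e-5, 5e-5, 1e-4))
  out <- fit_ic50(s[, c("competitor_M", "norm_rate")])
  expect_rel(out$IC50, 20e-6, 0.01)
  expect_false(out$no_inhibition)
  flat <- fit_ic50(data.frame(N = c(0, 1e-5, 2e-5, 1e-4), r = rep(1, 4)))
  expect_true(flat$no_inhibition)
  expect_equal(flat$IC50, Inf)
  half <- fit_ic50(data.frame(N = c(0, 5e-6, 20e-6, 8e-5),
                              r = 1 / (1 + c(0, 5e-6, 20e-6, 8e-5) / 20e-6)))
  expect_rel(half$IC50, 20e-6, 0.01)
})

test_that("single-turnover fits read the excision rate constant", {
  st <- synthesize_single_turnover(0.05, seq(0, 90, by = 4), digits = NULL)
  expect_rel(fit_single_turnover(st)$k_obs, 0.05, 1e-6)
  st2 <- synthesize_single_turnover(0.02, seq(0, 200, by = 8), digits = NULL)
  expect_rel(fit_single_turnover(st2)$k_obs, 0.02, 1e-6)
  zero <- fit_single_turnover(data.frame(t = seq(0, 60, by = 5),
                                         f = rep(0, 13)))
  expect_false(zero$identifiable)
  expect_true(check_saturation(0.050, 0.052))
  expect_false(check_saturation(0.05, 0.10))
})

test_that("noiseless synthetic traces round-trip through phase fitting", {
  # generator -> fit -> generating rates, across variants (eigenvalue level)
  tr <- y162a_double_mix()
  expect_rel(fit_exponential_phases(tr, 1)$rates[1], 10, 0.01)
  trw <- wt_tec_association()
  f <- fit_exponential_phases(trw, 3)
  expect_rel(f$rates[3], 3.6, 0.01)
})
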
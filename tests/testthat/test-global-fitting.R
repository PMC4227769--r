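test_that("a noiseless WT ensemble returns the generating constants", {
  ens <- wt_ensemble(noise_sd = 0, n = 100)
  start <- rate_constants(k_on = 5e8, k_find = 200, k_flip = 2,
                          k_unflip = 5e-3, k_chem = 8e-4)
  fit <- global_fit(ens, start, n_starts = 1, seed = 1)
  est <- coef(fit)
  expect_rel(est[["k_flip"]], 3.6, 0.05)
  expect_rel(est[["k_unflip"]], 1.6e-3, 0.05)
  expect_rel(est[["k_on"]], 1.1e9, 0.05)
  expect_rel(est[["k_find"]], 116, 0.05)
  expect_true(all(fit$identifiable))
  expect_true(fit$converged)
})

test_that("flat traces leave kinetic parameters unidentifiable", {
  flT <- fluorescence_model("TEC", "WT")
  tgrid <- stopped_flow_times(5e-4, 2, 80)
  flat <- data.frame(time_s = tgrid, signal = rep(1, 80))
  e1 <- mixing_experiment("association", E_tot = 1e-7, D_tot = 5e-8,
                          times = tgrid, noise_sd = 0)
  e2 <- mixing_experiment("association", E_tot = 2e-7, D_tot = 5e-8,
                          times = tgrid, noise_sd = 0)
  r0 <- rate_constants(k_on = 1e9, k_find = 100, k_flip = 1,
                       k_unflip = 0.01, k_chem = 1e-4)
  fit <- global_fit(trace_ensemble(ensemble_entry(e1, flat, flT),
                                   ensemble_entry(e2, flat, flT)),
                    r0, free = c("k_on", "k_find", "k_flip", "k_unflip"),
                    bounds = 6, n_starts = 1, seed = 1)
  expect_false(any(fit$identifiable))
})

test_that("unflipping needs a chase trace to be identifiable", {
  r <- aag_rates("WT")
  flT <- fluorescence_model("TEC", "WT")
  spec <- mechanism(r, "additive")
  entries <- lapply(list(c(2e-7, 21), c(4e-7, 22)), function(v) {
    e <- mixing_experiment("association", E_tot = v[1], D_tot = 5e-8,
                           times = stopped_flow_times(5e-4, 2, 100),
                           noise_sd = 0.005, seed = v[2])
    ensemble_entry(e, synthesize_association_trace(spec, flT, e), flT)
  })
  fit <- global_fit(trace_ensemble(entries), r,
                    free = c("k_on", "k_find", "k_flip", "k_unflip"),
                    n_starts = 1, seed = 3)
  expect_false(fit$identifiable[["k_unflip"]])
  expect_true(fit$identifiable[["k_flip"]])
})

test_that("fluorescence coefficients can be co-fit with the rates", {
  r <- aag_rates("WT")
  flT <- fluorescence_model("TEC", "WT")
  spec <- mechanism(r, "additive")
  mk <- function(E, seed) {
    e <- mixing_experiment("association", E_tot = E, D_tot = 5e-8,
                           times = stopped_flow_times(5e-4, 2, 100),
                           noise_sd = 0.002, seed = seed)
    ensemble_entry(e, synthesize_association_trace(spec, flT, e), flT)
  }
  start <- rate_constants(k_on = 5e8, k_find = 200, k_flip = 2,
                          k_unflip = 1.6e-3, k_chem = 8e-4)
  fit <- global_fit(trace_ensemble(mk(2e-7, 41), mk(4e-7, 42)), start,
                    free = c("k_on", "k_find", "k_flip"),
                    free_coefficients = c("TEC.IRC", "TEC.SRC"),
                    n_starts = 1, seed = 5)
  est <- coef(fit)
  expect_rel(est[["TEC.IRC"]], 1.6, 0.02)
  expect_rel(est[["TEC.SRC"]], 0.55, 0.02)
  expect_rel(est[["k_flip"]], 3.6, 0.05)
})

test_that("parameter count is bounded by the residual budget", {
  ens <- wt_ensemble(noise_sd = 0, n = 100)
  short <- trace_ensemble(lapply(ens[1:2], function(e) {
    e$trace <- e$trace[1:20, ]; e
  }))
  expect_error(global_fit(short, aag_rates("WT"),
                          free = c("k_on", "k_find", "k_flip", "k_unflip"),
                          free_coefficients = c("TEC.IRC", "TEC.SRC")),
               "too many free parameters")
})

test_that("global and phase-wise routes agree on a shared ensemble", {
  ens <- wt_ensemble(noise_sd = 0, n = 100)
  gf <- global_fit(ens, aag_rates("WT"), n_starts = 1, seed = 2)
  # phase-wise: flip rate from a saturating association trace,
  # unflip from the chase trace
  f_assoc <- fit_exponential_phases(ens[[2]]$trace, 3)
  f_chase <- fit_exponential_phases(ens[[4]]$trace, 1)
  phasewise <- c(k_flip = derive_k_flip(min(f_assoc$rates),
                                        f_chase$rates[1] - 8.0e-4),
                 k_unflip = unname(f_chase$rates[1]) - 8.0e-4)
  rep <- compare_fits(gf, phasewise)
  expect_false(any(rep$discordant))
  expect_true(all(rep$ratio > 0.9 & rep$ratio < 1.1))
  expect_error(compare_fits(c(a = 1), c(b = 2)), "shared")
  same <- compare_fits(c(k_flip = 3.6), c(k_flip = 3.6))
  expect_equal(same$ratio, 1)
})

test_that("a mis-specified dead time is flagged as fast-phase discordance", {
  # a 3.5 ms time-base error (dead time treated as 5 ms instead of 1.5 ms)
  # biases the fast relaxations the model fits but not the slow flip phase
  r <- aag_rates("WT")
  flT <- fluorescence_model("TEC", "WT")
  spec <- mechanism(r, "single")
  entries <- lapply(list(c(4e-7, 31), c(8e-7, 32)), function(v) {
    e <- mixing_experiment("association", E_tot = 1e-7, D_tot = v[1],
                           times = stopped_flow_times(5e-4, 2, 100),
                           noise_sd = 0.002, seed = v[2])
    list(e = e, tr = synthesize_association_trace(spec, flT, e))
  })
  mkens <- function(shift) trace_ensemble(lapply(entries, function(x) {
    tr <- x$tr; tr$time_s <- tr$time_s + shift
    e <- x$e; e$times <- tr$time_s
    ensemble_entry(e, tr, flT)
  }))
  fit3 <- c("k_on", "k_find", "k_flip")
  g_ok <- global_fit(mkens(0), r, free = fit3, n_starts = 1, seed = 1,
                     occupancy_model = "single")
  g_bad <- global_fit(mkens(3.5e-3), r, free = fit3, n_starts = 1, seed = 1,
                      occupancy_model = "single")
  rep <- compare_fits(g_bad, coef(g_ok))
  expect_true(rep$discordant[rep$parameter == "k_on"])     # 2-3x biased
  rep10 <- compare_fits(g_bad, coef(g_ok), flag_range = c(0.9, 1.1))
  expect_true(rep10$discordant[rep10$parameter == "k_find"])
  expect_false(rep10$discordant[rep10$parameter == "k_flip"])
})
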
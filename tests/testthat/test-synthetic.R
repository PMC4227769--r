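test_that("all-zero rates give a flat trace at the free-DNA level", {
  r <- rate_constants(k_on = 0, k_search = 0, k_escape = 0, k_off_ns = 0,
                      k_flip = 0, k_unflip = 0, k_chem = 0)
  exp1 <- mixing_experiment("association", E_tot = 1e-7, D_tot = 5e-8,
                            times = stopped_flow_times(5e-4, 1, 50),
                            noise_sd = 0)
  tr <- synthesize_association_trace(mechanism(r),
                                     fluorescence_model("TEC"), exp1)
  expect_equal(tr$signal, rep(1, nrow(tr)), tolerance = 1e-9)
})

test_that("WT TEC association rises then falls (amplitude sign pattern)", {
  tr <- wt_tec_association()
  expect_gt(max(tr$signal), 1.2)           # transient brighter than free DNA
  expect_lt(tr$signal[nrow(tr)], 0.7)      # quenched end point
  fit <- fit_exponential_phases(tr, 2)
  # y = y_inf + A1 exp(-k1 t) + A2 exp(-k2 t): rise A < 0, fall A > 0
  expect_lt(fit$amplitudes[1], 0)
  expect_gt(fit$amplitudes[2], 0)
})

test_that("Y162A TEC association shows a single decreasing phase", {
  exp1 <- mixing_experiment("association", E_tot = 5e-7, D_tot = 1e-7,
                            times = stopped_flow_times(5e-4, 0.2, 250),
                            noise_sd = 0)
  spec <- mechanism(aag_rates("Y162A", "TEC"), "additive")
  tr <- synthesize_association_trace(spec, fluorescence_model("TEC", "Y162A"),
                                     exp1)
  # binding completes within the dead time: first observed point is maximal
  expect_equal(which.max(tr$signal), 1L)
  fit <- fit_exponential_phases(tr, 1)
  expect_gt(fit$amplitudes[1], 0)          # decay only
  expect_rel(fit$rates[1], observed_flip_rate(170, 10), 0.01)
})

test_that("double-mixing recovery reports unflipping", {
  fit <- fit_exponential_phases(y162a_double_mix(), 1)
  expect_rel(fit$rates[1], 10, 0.01)
  # nothing unflips when k_unflip = 0 (and chemistry is off)
  r0 <- rate_constants(k_on = 2e10, k_find = 2e4, k_flip = 66, k_unflip = 0,
                       k_chem = 0)
  exp1 <- mixing_experiment("double_mix", E_tot = 4e-7, D_tot = 1e-7,
                            times = seq(2e-3, 0.8, length.out = 100),
                            age_time = 1, noise_sd = 0)
  tr0 <- synthesize_double_mixing_trace(mechanism(r0, "additive"),
                                        fluorescence_model("AEA", "Y162A"),
                                        exp1)
  expect_lt(diff(range(tr0$signal)), 1e-6)
  # WT recovery is limited by the slow exit from the flipped complex
  rw <- aag_rates("WT")
  expw <- mixing_experiment("double_mix", E_tot = 4e-7, D_tot = 1e-7,
                            times = seq(1, 3000, length.out = 200),
                            age_time = 1, noise_sd = 0)
  trw <- synthesize_double_mixing_trace(mechanism(rw, "additive"),
                                        fluorescence_model("AEA", "WT"), expw)
  fw <- fit_exponential_phases(trw, 1)
  expect_rel(fw$rates[1], rw$k_unflip + rw$k_chem, 0.01)
})

test_that("dead time removes exactly the early points; seeds reproduce", {
  times <- stopped_flow_times(5e-4, 1, 120)
  exp1 <- mixing_experiment("association", E_tot = 2e-7, D_tot = 5e-8,
                            times = times, dead_time = 3e-3,
                            noise_sd = 0.005, seed = 99)
  spec <- mechanism(aag_rates("WT"), "additive")
  fl <- fluorescence_model("TEC")
  tr <- synthesize_association_trace(spec, fl, exp1)
  expect_identical(tr$time_s, times[times >= 3e-3])
  tr2 <- synthesize_association_trace(spec, fl, exp1)
  expect_identical(tr, tr2)
  exp3 <- exp1; exp3$seed <- 100L
  tr3 <- synthesize_association_trace(spec, fl, exp3)
  expect_false(identical(tr$signal, tr3$signal))
  # empty post-dead-time grid errors
  exp_bad <- mixing_experiment("association", E_tot = 2e-7, D_tot = 5e-8,
                               times = c(1e-4, 5e-4), dead_time = 1e-3,
                               noise_sd = 0)
  expect_error(synthesize_association_trace(spec, fl, exp_bad), "dead time")
})

test_that("titrations follow the quadratic binding solution", {
  E <- seq(0, 1.2e-6, length.out = 30)
  # stoichiometric limit: piecewise linear, break at n * D_tot, plateau 1/q
  cur <- synthesize_titration(Kd = 0, n = 1, D_tot = 4e-7, enzyme_series = E,
                              quench_factor = 5)
  expect_equal(cur$signal[E == 0], 1)
  expect_equal(cur$signal[E >= 4e-7], rep(0.2, sum(E >= 4e-7)))
  before <- E < 4e-7
  expect_equal(cur$signal[before], 1 - 0.8 * E[before] / 4e-7)
  # quadratic root cross-checked against direct numeric root finding
  fb <- flipkin:::bound_fraction_quadratic(4e-7, 4e-7, 4e-7)
  oracle <- uniroot(function(b) (4e-7 - b) * (4e-7 - b) / b - 4e-7,
                    c(1e-12, 4e-7 - 1e-12), tol = 1e-16)$root / 4e-7
  expect_rel(fb, oracle, 1e-6)
  expect_equal(fb, 0.381966, tolerance = 1e-6)
})

test_that("single-turnover courses and competition series behave", {
  st <- synthesize_single_turnover(0.05, c(0, 5, 13.8629, 30, 60),
                                   digits = NULL)
  expect_equal(st$fraction[1], 0)
  expect_rel(st$fraction[st$time == 13.8629], 0.5, 1e-4)  # ln 2 / k
  # gel quantization to 3 decimals
  stq <- synthesize_single_turnover(0.05, c(0, 10, 20))
  expect_equal(stq$fraction, round(stq$fraction, 3))
  cs <- synthesize_competition_series(0.02, 20e-6, c(0, 20e-6))
  expect_equal(cs$norm_rate, c(1, 0.5))
  flat <- synthesize_competition_series(0.05, Inf, c(0, 1e-5, 1e-4))
  expect_equal(flat$norm_rate, rep(1, 3))
})

test_that("trace CSVs round-trip with their JSON sidecar", {
  tr <- wt_tec_association(noise_sd = 0.005, seed = 5, n = 40)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 5)
  expect_equal(side$mode, "association")
  unlink(c(path, paste0(path, ".json")))
})
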
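# shared fixtures: all synthetic, built in code at test time

wt_tec_association <- function(E_tot = 3e-7, D_tot = 5e-8, noise_sd = 0,
                               seed = 1, n = 250) {
  exp1 <- mixing_experiment("association", E_tot = E_tot, D_tot = D_tot,
                            times = stopped_flow_times(5e-4, 2, n),
                            noise_sd = noise_sd, seed = seed)
  spec <- mechanism(aag_rates("WT"), "additive")
  synthesize_association_trace(spec, fluorescence_model("TEC", "WT"), exp1)
}

y162a_double_mix <- function(noise_sd = 0, seed = 1) {
  exp1 <- mixing_experiment("double_mix", E_tot = 4e-7, D_tot = 1e-7,
                            times = seq(2e-3, 0.8, length.out = 400),
                            age_time = 1, noise_sd = noise_sd, seed = seed)
  spec <- mechanism(aag_rates("Y162A", "AEA"), "additive")
  synthesize_double_mixing_trace(spec, fluorescence_model("AEA", "Y162A"),
                                 exp1)
}

# small WT ensemble spanning both regimes plus a chase trace
wt_ensemble <- function(noise_sd = 0, seed = 1, n = 120) {
  r <- aag_rates("WT")
  flT <- fluorescence_model("TEC", "WT")
  flA <- fluorescence_model("AEA", "WT")
  spec <- mechanism(r, "additive")
  exps <- list(
    mixing_experiment("association", E_tot = 2e-7, D_tot = 5e-8,
                      times = stopped_flow_times(5e-4, 2, n),
                      noise_sd = noise_sd, seed = seed + 1),
    mixing_experiment("association", E_tot = 4e-7, D_tot = 5e-8,
                      times = stopped_flow_times(5e-4, 2, n),
                      noise_sd = noise_sd, seed = seed + 2),
    mixing_experiment("association", E_tot = 1e-7, D_tot = 8e-7,
                      times = stopped_flow_times(5e-4, 2, n),
                      noise_sd = noise_sd, seed = seed + 3),
    mixing_experiment("double_mix", E_tot = 4e-7, D_tot = 1e-7,
                      times = seq(1, 3000, length.out = n), age_time = 1,
                      noise_sd = noise_sd, seed = seed + 4))
  traces <- list(
    synthesize_association_trace(spec, flT, exps[[1]]),
    synthesize_association_trace(spec, flT, exps[[2]]),
    synthesize_association_trace(spec, flT, exps[[3]]),
    synthesize_double_mixing_trace(spec, flA, exps[[4]]))
  fls <- list(flT, flT, flT, flA)
  trace_ensemble(lapply(1:4, function(i)
    ensemble_entry(exps[[i]], traces[[i]], fls[[i]])))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
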
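#' Synthesize a single-mixing stopped-flow association trace
#'
#' Simulates the mechanism from free enzyme plus free DNA, converts the
#' species trajectory to a normalized eA-fluorescence signal through the
#' fluorescence model, removes points before the instrument dead time, and
#' adds Gaussian noise (reproducibly, from the experiment seed).
#'
#' @param spec a [mechanism] object (chase must be off)
#' @param fl a [fluorescence_model]
#' @param exp a [mixing_experiment] with `mode = "association"`
#' @return a data.frame of class `kinetic_trace` with columns
#'   `time_s`, `signal`
#' @export
synthesize_association_trace <- function(spec, fl, exp) {
  stopifnot(inherits(exp, "mixing_experiment"))
  if (exp$mode != "association")
    stop("`exp` must have mode = \"association\"")
  if (exp$E_tot <= 0 || exp$D_tot <= 0)
    stop("association experiments need positive E_tot and D_tot")
  if (spec$chase) stop("association traces are simulated without chase")
  init <- species_state(E = exp$E_tot, D = exp$D_tot)
  traj <- simulate_timecourse(spec, init, exp$times)
  finish_trace(traj$time_s, trajectory_signal(traj, fl, exp$D_tot), exp)
}

#' Synthesize a double-mixing chase trace
#'
#' Stage 1 mixes enzyme with lesion DNA and ages the complex for
#' `exp$age_time` seconds without chase; stage 2 adds the chase (free enzyme
#' sequestered, re-flipping suppressed) and records the fluorescence
#' recovery as the flipped-out complex unflips and releases bright free DNA.
#' Stage-2 time is reported from the second mix; the dead time applies to
#' stage 2.
#'
#' @inheritParams synthesize_association_trace
#' @param exp a [mixing_experiment] with `mode = "double_mix"` and a
#'   positive `age_time`
#' @export
synthesize_double_mixing_trace <- function(spec, fl, exp) {
  stopifnot(inherits(exp, "mixing_experiment"))
  if (exp$mode != "double_mix")
    stop("`exp` must have mode = \"double_mix\"")
  spec1 <- spec; spec1$chase <- FALSE
  init <- species_state(E = exp$E_tot, D = exp$D_tot)
  age_grid <- c(0, exp$age_time / 2, exp$age_time)
  aged <- simulate_timecourse(spec1, init, age_grid)
  s1 <- aged[nrow(aged), species_names()]
  state1 <- do.call(species_state, as.list(as.numeric(s1)) |>
                      stats::setNames(species_names()))
  spec2 <- spec; spec2$chase <- TRUE
  # keep the occupancy of the aged mixture rather than of the chased state
  spec2$occupancy <- resolve_occupancy(spec, init)
  traj <- simulate_timecourse(spec2, state1, exp$times)
  finish_trace(traj$time_s, trajectory_signal(traj, fl, exp$D_tot), exp)
}

finish_trace <- function(times, signal, exp) {
  keep <- times >= exp$dead_time
  if (!any(keep)) stop("no observation points remain after the dead time")
  times <- times[keep]; signal <- signal[keep]
  if (exp$noise_sd > 0)
    signal <- signal + with_seed(exp$seed,
                                 stats::rnorm(length(signal), 0, exp$noise_sd))
  structure(data.frame(time_s = times, signal = signal),
            class = c("kinetic_trace", "data.frame"), experiment = exp)
}

#' Synthesize a tight-binding fluorescence titration
#'
#' Fraction of DNA bound comes from the quadratic solution of the
#' two-component binding equilibrium with total site concentration
#' `n * D_tot`; the normalized signal interpolates from 1 (free DNA) to
#' `1/quench_factor` (saturated complex). `Kd = 0` gives the stoichiometric
#' limit: a piecewise-linear titration breaking at `E_tot = n * D_tot`.
#'
#' @param Kd dissociation constant (M), >= 0
#' @param n stoichiometry (equivalents of enzyme per DNA at the break point)
#' @param D_tot DNA concentration (M)
#' @param enzyme_series vector of total enzyme concentrations (M)
#' @param quench_factor fold quench of the saturated complex (>= 1)
#' @param noise_sd Gaussian noise SD (signal units)
#' @param seed integer seed for the noise draw
#' @return data.frame with columns `E_tot`, `signal`
#' @export
synthesize_titration <- function(Kd, n = 1, D_tot, enzyme_series,
                                 quench_factor = 5, noise_sd = 0, seed = 1L) {
  if (!is.finite(Kd) || Kd < 0) stop("`Kd` must be a finite value >= 0")
  if (D_tot <= 0) stop("`D_tot` must be positive")
  if (quench_factor < 1) stop("`quench_factor` must be >= 1")
  fb <- bound_fraction_quadratic(enzyme_series, n * D_tot, Kd)
  signal <- 1 - (1 - 1 / quench_factor) * fb
  if (noise_sd > 0)
    signal <- signal + with_seed(seed,
                                 stats::rnorm(length(signal), 0, noise_sd))
  data.frame(E_tot = enzyme_series, signal = signal)
}

# fraction of sites occupied for total ligand E, total sites S, dissociation
# constant Kd (standard quadratic root, stable form)
bound_fraction_quadratic <- function(E, S, Kd) {
  if (Kd == 0) return(pmin(E / S, 1))
  b <- E + S + Kd
  bound <- (b - sqrt(b^2 - 4 * E * S)) / 2
  bound / S
}

#' Synthesize a single-turnover excision time course
#'
#' Fraction product follows a single-exponential approach to completion,
#' `1 - exp(-k_obs t)`, with optional Gaussian noise, clipped to
#' \[0, 1.05\] and quantized to gel-densitometry precision (3 decimals by
#' default; `digits = NULL` disables quantization).
#'
#' @param k_obs observed excision rate constant, in the reciprocal of the
#'   unit `times` is given in (typically min^-1 with times in minutes)
#' @param times sampling times
#' @param noise_sd Gaussian noise SD (fraction units)
#' @param seed integer seed
#' @param digits decimals for gel quantization (default 3)
#' @return data.frame with columns `time`, `fraction`
#' @export
synthesize_single_turnover <- function(k_obs, times, noise_sd = 0, seed = 1L,
                                       digits = 3) {
  if (k_obs < 0) stop("`k_obs` must be >= 0")
  frac <- 1 - exp(-k_obs * times)
  if (noise_sd > 0)
    frac <- frac + with_seed(seed, stats::rnorm(length(frac), 0, noise_sd))
  frac <- pmin(pmax(frac, 0), 1.05)
  if (!is.null(digits)) frac <- round(frac, digits)
  data.frame(time = times, fraction = frac)
}

#' Synthesize a competition-inhibition series
#'
#' Observed single-turnover rates in the presence of an undamaged-DNA
#' competitor, normalized to the uninhibited rate: `1 / (1 + [N]/IC50)`.
#' `IC50 = Inf` encodes no inhibition (all values 1).
#'
#' @param k_ref uninhibited rate constant (any unit; returned for reference)
#' @param IC50 half-inhibition concentration (M), > 0, or `Inf`
#' @param competitor_series competitor concentrations (M)
#' @param noise_sd Gaussian noise SD (normalized-rate units)
#' @param seed integer seed
#' @return data.frame with columns `competitor_M`, `norm_rate`, `rate`
#' @export
synthesize_competition_series <- function(k_ref, IC50, competitor_series,
                                          noise_sd = 0, seed = 1L) {
  if (!(IC50 > 0)) stop("`IC50` must be positive (or Inf for no inhibition)")
  nr <- if (is.infinite(IC50)) rep(1, length(competitor_series))
        else 1 / (1 + competitor_series / IC50)
  if (noise_sd > 0)
    nr <- nr + with_seed(seed, stats::rnorm(length(nr), 0, noise_sd))
  data.frame(competitor_M = competitor_series, norm_rate = nr,
             rate = k_ref * nr)
}

#' Write a kinetic trace as CSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the full experiment descriptor
#' including the seed, so a trace file is self-describing.
#'
#' @param trace a `kinetic_trace` (or any data.frame of a trace)
#' @param path CSV output path
#' @param sidecar write the JSON descriptor next to the CSV
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  exp <- attr(trace, "experiment")
  if (sidecar && !is.null(exp)) {
    desc <- unclass(exp)
    desc$times <- NULL  # recoverable from the CSV
    jsonlite::write_json(desc, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a kinetic trace CSV
#'
#' @param path CSV with columns `time_s,signal` (or `time,fraction`)
#' @return a data.frame of class `kinetic_trace`
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path)
  structure(df, class = c("kinetic_trace", "data.frame"))
}
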
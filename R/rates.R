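#' Microscopic rate constants for a glycosylase variant
#'
#' Bundles the microscopic rate constants of the minimal lesion-recognition
#' mechanism: bimolecular association with the oligonucleotide duplex
#' (`k_on`), macroscopic dissociation from nonspecific DNA (`k_off_ns`),
#' the searching steps that form the initial recognition complex
#' (`k_search` forward, `k_escape` back; their sum is the observable
#' `k_find`), nucleotide flipping (`k_flip`) and unflipping (`k_unflip`),
#' and N-glycosidic bond cleavage (`k_chem`).
#'
#' `k_search`, `k_escape` and `k_off_ns` are an internal decomposition: the
#' experimentally constrained quantities are `k_on` and
#' `k_find = k_search + k_escape`. When `k_find` is supplied instead of the
#' pair, it is split so that escape from the initial recognition complex is
#' slow relative to finding (`k_escape = escape_fraction * k_find`), and
#' `k_off_ns` defaults to `k_find / 500`, i.e. nonspecific binding is
#' committed on the timescale of searching and the bound fraction stays at
#' unity across the excess-DNA concentration series. See the package
#' vignette for why these defaults are required by the observed
#' concentration regimes.
#'
#' @param k_on bimolecular association rate constant (M^-1 s^-1)
#' @param k_find macroscopic lesion-finding rate constant (s^-1); used to
#'   derive `k_search`/`k_escape` unless both are given explicitly
#' @param k_flip,k_unflip forward and reverse flipping rate constants (s^-1)
#' @param k_chem N-glycosidic bond cleavage rate constant (s^-1)
#' @param k_search,k_escape optional explicit decomposition of `k_find` (s^-1)
#' @param k_off_ns nonspecific dissociation rate constant (s^-1)
#' @param escape_fraction fraction of `k_find` assigned to `k_escape` when the
#'   decomposition is derived (default 0.005)
#' @param variant optional variant label (e.g. "WT")
#' @return an object of class `rate_constants` (a named list)
#' @seealso [aag_rates()] for the tabulated variant presets
#' @export
rate_constants <- function(k_on, k_find = NULL, k_flip, k_unflip, k_chem,
                           k_search = NULL, k_escape = NULL,
                           k_off_ns = NULL, escape_fraction = 0.005,
                           variant = NA_character_) {
  if (is.null(k_find)) {
    if (is.null(k_search) || is.null(k_escape))
      stop("supply either `k_find` or both `k_search` and `k_escape`")
  } else if (is.null(k_search) && is.null(k_escape)) {
    k_escape <- escape_fraction * k_find
    k_search <- k_find - k_escape
  } else if (is.null(k_search) || is.null(k_escape)) {
    stop("supply `k_search` and `k_escape` together")
  }
  if (is.null(k_off_ns)) k_off_ns <- (k_search + k_escape) / 500
  rates <- list(k_on = k_on, k_off_ns = k_off_ns, k_search = k_search,
                k_escape = k_escape, k_flip = k_flip, k_unflip = k_unflip,
                k_chem = k_chem)
  bad <- vapply(rates, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x < 0, logical(1))
  if (any(bad))
    stop("rate constants must be finite, non-negative scalars: ",
         paste(names(rates)[bad], collapse = ", "))
  structure(c(rates, list(variant = variant)), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Microscopic rate constants",
      if (!is.na(x$variant)) paste0(" [", x$variant, "]"), "\n", sep = "")
  cat(sprintf("  k_on      %.3g M^-1 s^-1\n", x$k_on))
  cat(sprintf("  k_find    %.4g s^-1  (k_search %.4g, k_escape %.4g)\n",
              k_find(x), x$k_search, x$k_escape))
  cat(sprintf("  k_off_ns  %.3g s^-1\n", x$k_off_ns))
  cat(sprintf("  k_flip    %.3g s^-1   k_unflip %.3g s^-1\n",
              x$k_flip, x$k_unflip))
  if (x$k_unflip > 0)
    cat(sprintf("  K_flip    %.3g\n", x$k_flip / x$k_unflip))
  cat(sprintf("  k_chem    %.3g s^-1\n", x$k_chem))
  invisible(x)
}

#' Macroscopic lesion-finding rate constant
#'
#' `k_find` is the observed concentration-independent rate constant of the
#' first phase under conditions of excess DNA: the sum of the rate constants
#' for finding and leaving the site of damage.
#'
#' @param rates a [rate_constants] object
#' @return `k_search + k_escape` (s^-1)
#' @export
k_find <- function(rates) rates$k_search + rates$k_escape

#' Tabulated rate constants for AAG variants
#'
#' Presets of the measured microscopic rate constants for wild-type human
#' alkyladenine DNA glycosylase and its intercalating-residue mutants Y162F
#' and Y162A, acting on 25mer duplexes containing a central
#' 1,N6-ethenoadenine (eA) lesion. Flipping for Y162A is context dependent
#' (170 s^-1 in the TEC sequence context, 66 s^-1 in AEA); all other
#' constants are context independent within error. Association and searching
#' are too fast to measure for Y162A: its binding phase is complete within
#' the stopped-flow dead time even at low protein concentrations. The preset
#' carries point values chosen to emulate exactly that behaviour
#' (k_on = 2e10 M^-1 s^-1, k_find = 2e4 s^-1, both well above the
#' dead-time-limited detection ceiling); downstream reporting treats them as
#' one-sided limits (k_on >= 1e9 M^-1 s^-1), never as measurements.
#'
#' @param variant one of "WT", "Y162F", "Y162A"
#' @param context sequence context, "TEC" or "AEA" (affects Y162A `k_flip`)
#' @return a [rate_constants] object
#' @export
aag_rates <- function(variant = c("WT", "Y162F", "Y162A"),
                      context = c("TEC", "AEA")) {
  variant <- match.arg(variant)
  context <- match.arg(context)
  switch(variant,
    WT = rate_constants(k_on = 1.1e9, k_find = 116, k_flip = 3.6,
                        k_unflip = 1.6e-3, k_chem = 8.0e-4, variant = "WT"),
    Y162F = rate_constants(k_on = 2.1e9, k_find = 114, k_flip = 7.9,
                           k_unflip = 4.6e-3, k_chem = 4.3e-4,
                           variant = "Y162F"),
    Y162A = rate_constants(k_on = 2e10, k_find = 2e4,
                           k_flip = if (context == "TEC") 170 else 66,
                           k_unflip = 10, k_chem = 3.8e-4, variant = "Y162A"))
}

#' Equilibrium constant for nucleotide flipping
#'
#' @param k_flip,k_unflip flipping and unflipping rate constants (s^-1)
#' @return the dimensionless ratio `k_flip / k_unflip`
#' @export
equilibrium_flip_constant <- function(k_flip, k_unflip) {
  stopifnot(is.numeric(k_flip), is.numeric(k_unflip),
            all(k_flip >= 0), all(k_unflip >= 0))
  if (any(k_unflip == 0))
    stop("K_flip is undefined when k_unflip = 0")
  k_flip / k_unflip
}

#' Observed relaxation rate of the isolated flipping step
#'
#' For a two-state flipping equilibrium the observed rate constant is the
#' sum of the forward and reverse rate constants.
#'
#' @inheritParams equilibrium_flip_constant
#' @return `k_flip + k_unflip` (s^-1)
#' @export
observed_flip_rate <- function(k_flip, k_unflip) {
  stopifnot(all(k_flip >= 0), all(k_unflip >= 0))
  k_flip + k_unflip
}

#' Commitment to catalysis
#'
#' Fraction of the flipped-out specific recognition complex that partitions
#' forward to excised product rather than unflipping and dissociating during
#' a pulse-chase, assuming dissociation of the unflipped complex is fast:
#' `C = k_chem / (k_chem + k_unflip)`.
#'
#' @param k_chem cleavage rate constant (s^-1)
#' @param k_unflip unflipping rate constant (s^-1)
#' @return commitment fraction in \[0, 1\]
#' @export
commitment_to_catalysis <- function(k_chem, k_unflip) {
  stopifnot(all(k_chem >= 0), all(k_unflip >= 0))
  if (any(k_chem + k_unflip == 0))
    stop("commitment is undefined when k_chem and k_unflip are both zero")
  k_chem / (k_chem + k_unflip)
}

#' Unflipping rate constant implied by a measured commitment
#'
#' Inverts [commitment_to_catalysis()]: `k_unflip = k_chem (1 - C) / C`.
#' A commitment of zero (all complex dissociates) implies only a lower limit
#' on the unflipping rate and raises an error.
#'
#' @param k_chem cleavage rate constant (s^-1), must be positive
#' @param C measured commitment fraction, in (0, 1\]
#' @return `k_unflip` (s^-1)
#' @export
unflip_from_commitment <- function(k_chem, C) {
  stopifnot(all(k_chem > 0))
  if (any(C <= 0))
    stop("C = 0 implies an infinite unflipping rate; only a limit is available")
  if (any(C > 1)) stop("C must lie in (0, 1]")
  k_chem * (1 - C) / C
}

#' Microscopic flipping rate from the observed flip-phase rate
#'
#' The observed rate constant of the flipping phase is the sum of forward and
#' reverse rates, so `k_flip = k_2obs - k_unflip`. Uncertainties, when given,
#' propagate in quadrature.
#'
#' @param k_2obs observed rate constant of the flipping phase (s^-1)
#' @param k_unflip independently measured unflipping rate constant (s^-1)
#' @param se_k_2obs,se_k_unflip optional standard errors
#' @return `k_flip` (s^-1), with attribute `"se"` when uncertainties are given
#' @export
derive_k_flip <- function(k_2obs, k_unflip, se_k_2obs = NULL,
                          se_k_unflip = NULL) {
  stopifnot(all(k_unflip >= 0))
  if (any(k_2obs < k_unflip))
    stop("inconsistent inputs: k_2obs < k_unflip")
  out <- k_2obs - k_unflip
  if (!is.null(se_k_2obs) || !is.null(se_k_unflip)) {
    se1 <- if (is.null(se_k_2obs)) 0 else se_k_2obs
    se2 <- if (is.null(se_k_unflip)) 0 else se_k_unflip
    attr(out, "se") <- sqrt(se1^2 + se2^2)
  }
  out
}

#' Round to significant figures, half away from zero
#'
#' Reported kinetic constants and fold changes are conventionally quoted
#' with halves rounded away from zero; base `signif()` rounds half to even
#' and disagrees on values such as 135 at two significant figures.
#'
#' @param x numeric
#' @param digits significant figures
#' @return rounded numeric
#' @export
signif_half_up <- function(x, digits) {
  ifelse(x == 0, 0, {
    m <- floor(log10(abs(x)))
    f <- 10^(digits - 1 - m)
    sign(x) * floor(abs(x) * f + 0.5) / f
  })
}

#' Fold change between two rate or equilibrium constants
#'
#' @param numerator,denominator positive values to compare
#' @param sig_figs significant figures for the reported ratio, rounded half
#'   away from zero (the convention used when quoting fold differences)
#' @return a list with `fold` (rounded) and `raw` (unrounded ratio)
#' @export
fold_change <- function(numerator, denominator, sig_figs = 2) {
  stopifnot(all(denominator > 0), all(numerator >= 0))
  raw <- numerator / denominator
  list(fold = signif_half_up(raw, sig_figs), raw = raw)
}

#' Fold excess of undamaged over damaged nucleotides
#'
#' Competition experiments are quoted as the ratio of undamaged nucleotides
#' (competitor duplex concentration times the number of undamaged nucleotides
#' it carries) to damaged nucleotides (one lesion per substrate duplex).
#'
#' @param competitor_conc competitor duplex concentration (M)
#' @param substrate_conc lesion-containing duplex concentration (M)
#' @param nt_per_competitor undamaged nucleotides per competitor duplex
#' @return fold excess (dimensionless)
#' @export
nucleotide_excess <- function(competitor_conc, substrate_conc,
                              nt_per_competitor = 50) {
  stopifnot(all(substrate_conc > 0), all(competitor_conc >= 0),
            all(nt_per_competitor > 0))
  competitor_conc * nt_per_competitor / substrate_conc
}
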
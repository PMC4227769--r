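#' Bimolecular rate constant from a concentration series
#'
#' Under excess protein the observed rate constant of the binding phase is
#' linear in enzyme concentration; a (weighted) linear fit yields the
#' bimolecular association rate constant `k_on` as the slope. The intercept
#' is unconstrained — slightly negative intercepts are observed for very
#' fast, tight binding and are permitted.
#'
#' @param conc concentrations (M), at least 3 distinct values
#' @param rate observed rate constants (s^-1)
#' @param sd optional per-point standard deviations for inverse-variance
#'   weighting
#' @return list with `k_on` (M^-1 s^-1), `intercept` (s^-1), their standard
#'   errors, and the underlying `lm` fit
#' @export
fit_bimolecular_slope <- function(conc, rate, sd = NULL) {
  if (length(conc) < 3L || length(rate) != length(conc))
    stop("need >= 3 matched (conc, rate) points")
  if (length(unique(conc)) < 2L) stop("singular design: all concentrations equal")
  w <- series_weights(sd, length(conc))
  fit <- stats::lm(rate ~ conc, weights = w)
  co <- suppressWarnings(summary(fit))$coefficients
  list(k_on = unname(co["conc", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       se_k_on = unname(co["conc", "Std. Error"]),
       se_intercept = unname(co["(Intercept)", "Std. Error"]),
       fit = fit)
}

series_weights <- function(sd, n) {
  if (is.null(sd)) return(NULL)
  if (length(sd) != n) stop("`sd` must match the series length")
  if (any(sd == 0)) stop("zero-variance inputs: provide positive SDs or none")
  1 / sd^2
}

#' Classify a rate series as concentration dependent or independent
#'
#' Tests the slope of observed rate vs concentration at significance
#' `alpha` (weighted by inverse variance when SDs are supplied). If the
#' slope is not significant the phase is concentration independent and the
#' summary rate is the inverse-variance weighted mean — this is `k_find`
#' for the first phase under excess DNA, and the flipping rate for the
#' second phase.
#'
#' @inheritParams fit_bimolecular_slope
#' @param alpha significance level for the slope t-test
#' @return list with `classification` ("dependent"/"independent"),
#'   `summary_rate` (weighted mean, independent case only), `se_summary`,
#'   `p_value`, `slope`
#' @export
classify_concentration_dependence <- function(conc, rate, sd = NULL,
                                              alpha = 0.05) {
  if (length(conc) < 3L) stop("need >= 3 points")
  w <- series_weights(sd, length(conc))
  spread <- diff(range(rate))
  if (spread <= 1e-10 * max(abs(rate))) {
    # exactly flat series: trivially independent
    m <- if (is.null(w)) mean(rate) else sum(w * rate) / sum(w)
    return(list(classification = "independent", summary_rate = m,
                se_summary = 0, p_value = 1, slope = 0))
  }
  fit <- stats::lm(rate ~ conc, weights = w)
  co <- suppressWarnings(summary(fit))$coefficients
  p <- co["conc", "Pr(>|t|)"]
  slope <- co["conc", "Estimate"]
  if (!is.finite(p)) {
    # numerically perfect fit: decide by whether the trend is material
    trend <- abs(slope) * diff(range(conc))
    p <- if (trend > 1e-8 * max(abs(rate))) 0 else 1
  }
  if (p < alpha) {
    list(classification = "dependent", summary_rate = NA_real_,
         se_summary = NA_real_, p_value = unname(p), slope = unname(slope))
  } else {
    if (is.null(w)) {
      m <- mean(rate); se <- stats::sd(rate) / sqrt(length(rate))
    } else {
      m <- sum(w * rate) / sum(w); se <- sqrt(1 / sum(w))
    }
    list(classification = "independent", summary_rate = m, se_summary = se,
         p_value = unname(p), slope = unname(slope))
  }
}

#' Fit a tight-binding titration with the quadratic binding model
#'
#' Signal model `F/F0 = 1 - (1 - 1/q) * fb(E_tot; Kd, n*D_tot)` where `fb`
#' is the bound fraction from the two-component quadratic root. When the
#' fitted Kd is below `D_tot/10` the titration is in the stoichiometric
#' (tight-binding) regime and Kd is reported as an upper limit.
#'
#' @param curve data.frame with columns `E_tot`, `signal`
#' @param D_tot DNA concentration (M)
#' @return list with `Kd` (M), `n`, `quench_factor`, `Kd_is_limit`,
#'   standard errors, and residual RMS
#' @export
fit_quadratic_binding <- function(curve, D_tot) {
  E <- curve[[1L]]; y <- curve[[2L]]
  if (length(E) < 5L) stop("need >= 5 titration points")
  if (diff(range(y)) < 1e-6)
    stop("titration shows no curvature; Kd/n/quench unidentifiable")
  model <- function(p) {
    Kd <- 10^p[1L]; n <- p[2L]; q <- p[3L]
    1 - (1 - 1 / q) * bound_fraction_quadratic(E, n * D_tot, Kd)
  }
  obj <- function(p) y - model(p)
  starts <- expand.grid(lKd = log10(D_tot) + c(-3, -1, 0.5),
                        n = c(0.8, 1.2), q = c(2, 6))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    out <- tryCatch(minpack.lm::nls.lm(
      par = as.numeric(starts[i, ]), fn = obj,
      lower = c(log10(D_tot) - 8, 0.05, 1.0001),
      upper = c(log10(D_tot) + 4, 20, 1000),
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = out$par, rss = rss, hess = out$hessian)
  }
  if (is.null(best)) stop("tight-binding fit failed to converge")
  p <- best$par
  dof <- max(length(y) - 3L, 1L)
  cov <- tryCatch(solve(best$hess) * best$rss / dof, error = function(e) NULL)
  se <- if (is.null(cov)) rep(Inf, 3) else sqrt(pmax(diag(cov), 0))
  Kd <- 10^p[1L]
  list(Kd = Kd, n = p[2L], quench_factor = p[3L],
       Kd_is_limit = Kd < D_tot / 10,
       se = list(log10_Kd = se[1L], n = se[2L], quench_factor = se[3L]),
       rms = sqrt(best$rss / length(y)))
}

#' Fit a competition-inhibition series for its IC50
#'
#' Fits `rate = r0 / (1 + [N]/IC50)`. When the best-fit IC50 exceeds ten
#' times the highest tested competitor concentration the series carries no
#' evidence of inhibition and `Inf` is reported (with `no_inhibition`
#' flagged), which is the behaviour of enzymes insensitive to undamaged
#' DNA.
#'
#' @param series data.frame with columns competitor concentration (M) and
#'   (normalized) rate
#' @return list with `IC50` (M, possibly `Inf`), `r0`, `no_inhibition`,
#'   and `rms`
#' @export
fit_ic50 <- function(series) {
  N <- series[[1L]]; r <- series[[2L]]
  if (length(N) < 4L || !any(N == 0))
    stop("need >= 4 competitor concentrations including 0")
  finite <- is.finite(N)
  Nf <- N[finite]; rf <- r[finite]
  ord <- order(Nf)
  if (any(diff(rf[ord]) > 3 * max(stats::sd(rf) / sqrt(length(rf)), 1e-3)))
    warning("competition series is non-monotonic beyond noise; fitting anyway")
  n_max <- max(Nf)
  model <- function(p) p[2L] / (1 + Nf / 10^p[1L])
  best <- NULL
  for (l0 in log10(n_max) + c(-2, -1, 0, 1, 3)) {
    out <- tryCatch(minpack.lm::nls.lm(
      par = c(l0, max(rf)), fn = function(p) rf - model(p),
      lower = c(log10(n_max) - 8, 0), upper = c(log10(n_max) + 8, 10 * max(rf)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = out$par, rss = rss)
  }
  if (is.null(best)) stop("IC50 fit failed to converge")
  ic50 <- 10^best$par[1L]
  none <- ic50 > 10 * n_max
  list(IC50 = if (none) Inf else ic50, r0 = best$par[2L],
       no_inhibition = none, rms = sqrt(best$rss / length(rf)))
}

#' Fit a single-turnover excision time course
#'
#' Exponential approach `fraction = a (1 - exp(-k t))` with the endpoint
#' constrained to at most 1.05. The rate unit follows the time unit of the
#' input (gel courses are usually in minutes, so `k_obs` is min^-1).
#'
#' @param series data.frame with columns time and fraction product
#' @return list with `k_obs`, `endpoint`, `se_k`, `identifiable`, `rms`
#' @export
fit_single_turnover <- function(series) {
  tm <- series[[1L]]; y <- series[[2L]]
  if (length(tm) < 5L) stop("need >= 5 points")
  if (max(abs(y)) < 1e-9)
    return(list(k_obs = NA_real_, endpoint = 0, se_k = Inf,
                identifiable = FALSE, rms = 0))
  model <- function(p) p[2L] * (1 - exp(-exp(p[1L]) * tm))
  k_seed <- log(log(2) / max(tm[which(y >= max(y) / 2)][1L], min(tm[tm > 0])))
  best <- NULL
  for (dk in c(-2, -1, 0, 1, 2)) {
    out <- tryCatch(minpack.lm::nls.lm(
      par = c(k_seed + dk, min(max(y), 1.0)), fn = function(p) y - model(p),
      lower = c(k_seed - 12, 0.01), upper = c(k_seed + 12, 1.05),
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = out$par, rss = rss, hess = out$hessian)
  }
  if (is.null(best)) stop("single-turnover fit failed to converge")
  k <- exp(best$par[1L])
  cov <- tryCatch(solve(best$hess) * best$rss / max(length(y) - 2L, 1L),
                  error = function(e) NULL)
  se_logk <- if (is.null(cov)) Inf else sqrt(max(cov[1L, 1L], 0))
  list(k_obs = k, endpoint = best$par[2L], se_k = k * se_logk,
       identifiable = is.finite(se_logk) && se_logk < 1,
       rms = sqrt(best$rss / length(y)))
}

#' Check that two single-turnover rates indicate saturation
#'
#' Single-turnover conditions are saturating when doubling the enzyme
#' concentration leaves the observed rate unchanged within tolerance.
#'
#' @param k1,k2 observed rate constants at the two enzyme concentrations
#' @param tol maximum relative difference regarded as "identical"
#' @return logical
#' @export
check_saturation <- function(k1, k2, tol = 0.2) {
  abs(k1 - k2) / max(k1, k2) <= tol
}
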
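#' Fit a sum of exponentials to a kinetic trace
#'
#' Fits \eqn{y(t) = y_\infty + \sum_{i=1}^{n} A_i e^{-k_i t}} by nonlinear
#' least squares. Sums of exponentials are notoriously ill-conditioned, so
#' the fit uses variable projection (amplitudes and offset solved linearly
#' at every step) over log-parameterized rates, with a log-spaced multistart
#' grid (8 starts by default) whose span is derived from the sampling window
#' — which also makes the optimum invariant under time-unit rescaling. The
#' best start by residual sum of squares wins.
#'
#' Phases are labeled by rate order after fitting (`k_1 >= k_2 >= ...`).
#' Two fitted rates closer than `merge_tol` (5%) are considered degenerate:
#' the model is refit with one fewer phase and the result flagged `merged`.
#' A phase whose amplitude is indistinguishable from zero is flagged
#' unidentifiable (its rate is meaningless).
#'
#' @param trace a data.frame whose first two columns are time and signal
#'   (e.g. a `kinetic_trace`), or a matrix-like with columns `time`, `y`
#' @param n_phases number of exponential phases, 1 to 3
#' @param n_starts multistart grid size
#' @param merge_tol relative rate separation below which phases are merged
#' @return an object of class `phase_fit` with elements `rates` (descending,
#'   s^-1 if time is in s), `amplitudes`, `y_inf`, `rms`, `se` (per
#'   parameter), `n_phases` (requested), `converged`, `merged`,
#'   `identifiable` (per phase), and `fitted`
#' @export
fit_exponential_phases <- function(trace, n_phases = 2, n_starts = 8,
                                   merge_tol = 0.05) {
  if (!(n_phases %in% 1:3)) stop("`n_phases` must be 1, 2 or 3")
  tm <- as.numeric(trace[[1L]])
  y <- as.numeric(trace[[2L]])
  ok <- is.finite(tm) & is.finite(y)
  tm <- tm[ok]; y <- y[ok]
  if (length(tm) < 5L * n_phases)
    stop("need at least ", 5L * n_phases, " points for ", n_phases, " phases")
  if (any(diff(tm) <= 0)) stop("trace times must be strictly increasing")

  fit <- exp_fit_multistart(tm, y, n_phases, n_starts)
  merged <- FALSE
  if (n_phases > 1L && !is.null(fit)) {
    k <- sort(fit$rates, decreasing = TRUE)
    rel <- abs(diff(k)) / pmax(k[-length(k)], .Machine$double.eps)
    if (any(rel < merge_tol)) {
      fit <- exp_fit_multistart(tm, y, n_phases - 1L, n_starts)
      merged <- TRUE
    }
  }
  if (is.null(fit))
    stop("multi-exponential fit failed to converge after multistart")

  ord <- order(fit$rates, decreasing = TRUE)
  rates <- fit$rates[ord]; amps <- fit$amplitudes[ord]
  se <- exp_fit_se(tm, y, fit$y_inf, amps, rates)
  scale <- max(diff(range(y)), .Machine$double.eps)
  # a phase with essentially zero amplitude carries no rate information
  identifiable <- abs(amps) > 1e-6 * max(scale, abs(fit$y_inf))
  structure(list(rates = rates, amplitudes = amps, y_inf = fit$y_inf,
                 rms = sqrt(mean(fit$residuals^2)), se = se,
                 n_phases = n_phases, n_used = length(rates),
                 converged = fit$converged, merged = merged,
                 identifiable = identifiable,
                 fitted = fit$fitted, time = tm, y = y),
            class = "phase_fit")
}

# one varpro evaluation: residuals for log-rates, plus linear coefficients
exp_design <- function(tm, logk) {
  k <- exp(logk)
  cbind(1, exp(-outer(tm, k)))
}

exp_varpro <- function(logk, tm, y) {
  X <- exp_design(tm, logk)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) {
    co <- qr.coef(qr(X, LAPACK = TRUE), y)
    co[is.na(co)] <- 0
    res <- y - X %*% co
    return(list(residuals = drop(res), coef = co))
  }
  list(residuals = fit$residuals, coef = fit$coefficients)
}

exp_fit_multistart <- function(tm, y, n, n_starts) {
  if (n == 0L) {
    co <- mean(y)
    return(list(rates = numeric(0), amplitudes = numeric(0), y_inf = co,
                residuals = y - co, fitted = rep(co, length(y)),
                converged = TRUE))
  }
  span <- max(tm) - min(tm)
  dt_min <- min(diff(tm))
  k_lo <- 0.5 / max(span, .Machine$double.eps)
  k_hi <- 2 / max(dt_min, .Machine$double.eps)
  centers <- exp(seq(log(k_lo), log(k_hi), length.out = n_starts))
  spread <- if (n == 1L) 1 else 10^(seq_len(n) - (n + 1) / 2)
  best <- NULL
  for (ct in centers) {
    start <- log(ct * spread)
    out <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(p) exp_varpro(p, tm, y)$residuals,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss)
      best <- list(par = out$par, rss = rss, info = out$info)
  }
  if (is.null(best)) return(NULL)
  vp <- exp_varpro(best$par, tm, y)
  k <- exp(best$par)
  list(rates = k, amplitudes = vp$coef[-1L], y_inf = vp$coef[1L],
       residuals = vp$residuals, fitted = y - vp$residuals,
       converged = best$info %in% 1:4)
}

# covariance of the full (y_inf, A, k) parameter set by numeric Jacobian
exp_fit_se <- function(tm, y, y_inf, amps, rates) {
  n <- length(rates)
  model <- function(p) {
    yi <- p[1L]; a <- p[seq_len(n) + 1L]; k <- p[seq_len(n) + 1L + n]
    yi + drop(exp(-outer(tm, k)) %*% a)
  }
  p0 <- c(y_inf, amps, rates)
  m <- length(y); np <- length(p0)
  J <- matrix(0, m, np)
  for (j in seq_len(np)) {
    h <- max(abs(p0[j]) * 1e-6, 1e-12)
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    J[, j] <- (model(pp) - model(pm)) / (2 * h)
  }
  rss <- sum((y - model(p0))^2)
  dof <- max(m - np, 1L)
  sigma2 <- rss / dof
  cov <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
  if (is.null(cov)) {
    ses <- rep(Inf, np)
  } else {
    d <- diag(cov)
    ses <- ifelse(d >= 0, sqrt(d), Inf)
  }
  list(y_inf = ses[1L], amplitudes = ses[seq_len(n) + 1L],
       rates = ses[seq_len(n) + 1L + n], sigma = sqrt(sigma2))
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("Multi-exponential fit: %d phase(s)%s%s\n", x$n_used,
              if (x$merged) " (degenerate pair merged)" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  for (i in seq_along(x$rates))
    cat(sprintf("  phase %d: k = %.6g +/- %.2g s^-1, A = %+.4g%s\n",
                i, x$rates[i], x$se$rates[i], x$amplitudes[i],
                if (!x$identifiable[i]) "  [unidentifiable]" else ""))
  cat(sprintf("  offset y_inf = %.6g, residual RMS = %.3g\n", x$y_inf, x$rms))
  invisible(x)
}

#' @export
coef.phase_fit <- function(object, ...) {
  n <- length(object$rates)
  stats::setNames(c(object$y_inf, object$amplitudes, object$rates),
                  c("y_inf", paste0("A", seq_len(n)), paste0("k", seq_len(n))))
}

#' @export
predict.phase_fit <- function(object, times = object$time, ...) {
  object$y_inf + drop(exp(-outer(times, object$rates)) %*% object$amplitudes)
}

#' @export
residuals.phase_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.phase_fit <- function(x, ...) {
  graphics::plot(x$time, x$y, log = "x", pch = 16, cex = 0.4,
                 xlab = "time (s)", ylab = "signal", ...)
  graphics::lines(x$time, x$fitted, col = 2, lwd = 2)
  invisible(x)
}
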
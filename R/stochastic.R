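#' Stochastic per-molecule simulation of the mechanism
#'
#' Simulates the fate of individual lesion-containing DNA molecules as a
#' continuous-time Markov chain over the mechanism states (free DNA,
#' nonspecific complex, initial recognition complex, specific complex,
#' product), using the exact (Gillespie) jump algorithm vectorized over
#' molecules. Binding is treated pseudo-first-order at a fixed free-enzyme
#' concentration. Under a chase, association and re-flipping are off (see
#' [mechanism()]), so a molecule that unflips proceeds irreversibly to
#' dissociation; this makes the simulation an independent cross-check of the
#' analytic pulse-chase partition [commitment_to_catalysis()].
#'
#' @param spec a [mechanism] object
#' @param n number of molecules (>= 1)
#' @param seed integer seed; a fixed seed gives reproducible tallies
#' @param horizon simulated time horizon (s)
#' @param start starting state for all molecules, one of
#'   `"SRC"`, `"IRC"`, `"ENS"`, `"D"`
#' @param enzyme_conc free enzyme concentration (M) for pseudo-first-order
#'   binding (ignored under chase)
#' @return a list with integer `tally` over fates
#'   (`product`, `dissociated`, `still_bound`), the corresponding
#'   `fractions`, `n`, and the final `states`
#' @export
simulate_stochastic <- function(spec, n, seed, horizon,
                                start = c("SRC", "IRC", "ENS", "D"),
                                enzyme_conc = 0) {
  if (!inherits(spec, "mechanism")) stop("`spec` must be a mechanism object")
  if (n < 1L) stop("`n` must be >= 1")
  if (!is.finite(horizon) || horizon <= 0) stop("`horizon` must be positive")
  start <- match.arg(start)
  r <- spec$rates
  occ <- if (is.null(spec$occupancy)) 1 else spec$occupancy
  chase <- spec$chase

  # states: 1 D(free), 2 ENS, 3 IRC, 4 SRC, 5 P
  k_bind <- if (chase) 0 else r$k_on * enzyme_conc
  trans <- list(
    list(to = 2L, rate = k_bind),                        # D -> ENS
    list(to = c(1L, 3L),
         rate = c(r$k_off_ns,
                  if (chase) 0 else occ * r$k_search)),  # ENS -> D | IRC
    list(to = c(2L, 4L),
         rate = c(r$k_escape, if (chase) 0 else r$k_flip)), # IRC -> ENS | SRC
    list(to = c(3L, 5L), rate = c(r$k_unflip, r$k_chem)),   # SRC -> IRC | P
    list(to = integer(0), rate = numeric(0)))               # P absorbing
  total_rate <- vapply(trans, function(tr) sum(tr$rate), numeric(1))
  # under chase, reaching free DNA means the enzyme is captured: absorbing
  if (chase) total_rate[1L] <- 0

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  state <- rep.int(match(start, c("D", "ENS", "IRC", "SRC")), n)
  t_now <- numeric(n)
  for (iter in seq_len(10000L)) {
    active <- which(total_rate[state] > 0 & t_now < horizon)
    if (length(active) == 0L) break
    s <- state[active]
    rt <- total_rate[s]
    t_next <- t_now[active] + stats::rexp(length(active), rt)
    u <- stats::runif(length(active))
    new_state <- s
    for (si in unique(s)) {
      idx <- s == si
      tr <- trans[[si]]
      p <- tr$rate / sum(tr$rate)
      if (length(tr$to) == 1L) new_state[idx] <- tr$to
      else new_state[idx] <- ifelse(u[idx] < p[1L], tr$to[1L], tr$to[2L])
    }
    crossed <- t_next > horizon
    t_now[active] <- pmin(t_next, horizon)
    state[active[!crossed]] <- new_state[!crossed]
  }
  fate <- ifelse(state == 5L, "product",
                 ifelse(state == 1L, "dissociated", "still_bound"))
  tally <- c(product = sum(fate == "product"),
             dissociated = sum(fate == "dissociated"),
             still_bound = sum(fate == "still_bound"))
  list(tally = tally, fractions = tally / n, n = n,
       states = c("D", "ENS", "IRC", "SRC", "P")[state])
}
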
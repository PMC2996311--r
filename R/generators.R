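#' Draw bout durations from a power-law distribution
#'
#' Inverse-CDF sampling from the Pareto density `f(x) = c x^(-alpha)` on
#' `[x_min, Inf)`: `x = x_min * (1 - u)^(-1 / (alpha - 1))` for
#' `u ~ Uniform(0, 1)`. With `x_min >= 1` every draw already satisfies the
#' >= 1 epoch truncation rule, so no rejection is needed.
#'
#' @param n number of draws (>= 1).
#' @param alpha scaling exponent, > 1.
#' @param x_min lower threshold in epochs (default 1, as in all experiments).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return a [bout_sample()] of `n` continuous durations >= `x_min`.
#' @export
#' @examples
#' s <- draw_power_law(100, alpha = 3, seed = 1)
#' min(s) >= 1
draw_power_law <- function(n, alpha, x_min = 1, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (!is.finite(alpha) || alpha <= 1)
    stop("invalid parameter: alpha must be > 1 (density not normalizable otherwise)")
  set_task_seed(seed)
  u <- stats::runif(n)
  x <- x_min * (1 - u)^(-1 / (alpha - 1))
  bout_sample(x, provenance = list(family = "powerlaw", alpha = alpha,
                                   x_min = x_min, seed = seed))
}

# Accepted draws from one exponential component: rejection-and-redraw of
# values < 1 epoch until exactly `n` survivors, preserving draw order.
draw_truncated_exponential <- function(n, tau, truncate_at_one = TRUE) {
  if (n == 0L) return(numeric(0))
  if (!truncate_at_one) return(stats::rexp(n, rate = 1 / tau))
  out <- numeric(n)
  filled <- 0L
  # expected acceptance rate exp(-1/tau); over-draw accordingly
  accept <- exp(-1 / tau)
  while (filled < n) {
    need <- n - filled
    m <- max(need + 10L, ceiling(need / max(accept, 1e-6) * 1.2))
    x <- stats::rexp(m, rate = 1 / tau)
    x <- x[x >= 1]
    take <- min(length(x), need)
    if (take > 0L) {
      out[(filled + 1L):(filled + take)] <- x[seq_len(take)]
      filled <- filled + take
    }
  }
  out
}

#' Draw bout durations from an exponential mixture
#'
#' For each component of the [mixture_spec()], exactly `n_draws` accepted
#' values are drawn from an exponential with mean `tau`; draws below 1 epoch
#' are rejected and redrawn (the histogramming convention scores no bout
#' shorter than one epoch). The returned sample concatenates the components,
#' so per-component quotas are met exactly. Components with a zero quota
#' consume no random numbers, which makes the degenerate one-component edges
#' of a sweep bit-identical to a plain mono-exponential run under the same
#' seed.
#'
#' @param spec a [mixture_spec()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param truncate_at_one apply the >= 1 epoch rejection rule (default `TRUE`;
#'   turning it off reproduces the reading in which only power-law samples
#'   were truncated).
#' @return a [bout_sample()] of `sum(n_draws)` durations with a `component`
#'   attribute recording the generating component of each draw.
#' @export
#' @examples
#' s <- draw_exponential_mixture(mixture_spec(c(1, 15), c(30, 10)), seed = 7)
#' length(s)
draw_exponential_mixture <- function(spec, seed = NULL, truncate_at_one = TRUE) {
  stopifnot(inherits(spec, "mixture_spec"))
  set_task_seed(seed)
  parts <- vector("list", length(spec$tau))
  for (i in seq_along(spec$tau)) {
    parts[[i]] <- draw_truncated_exponential(spec$n_draws[i], spec$tau[i],
                                             truncate_at_one = truncate_at_one)
  }
  x <- unlist(parts, use.names = FALSE)
  s <- bout_sample(x,
                   provenance = list(family = "expmix", tau = spec$tau,
                                     n_draws = spec$n_draws, seed = seed,
                                     truncate_at_one = truncate_at_one),
                   truncated = truncate_at_one)
  attr(s, "component") <- rep.int(seq_along(spec$tau), spec$n_draws)
  s
}

#' Simulate a two-state Markov hypnogram and extract bout durations
#'
#' Scores a first-order sleep/wake Markov chain epoch by epoch and returns the
#' run lengths of each state as integer bout durations. Dwell times are
#' geometric: sleep bouts have mean `1 / (1 - p_stay_sleep)` epochs. The chain
#' is extended until `n_bouts` complete bouts of *each* state have been
#' observed; the trailing incomplete run is discarded.
#'
#' @param spec a [markov_spec()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return list with elements `sleep_bouts` and `wake_bouts`, each a
#'   [bout_sample()] of `n_bouts` integer durations (epochs >= 1).
#' @export
#' @examples
#' h <- simulate_markov_hypnogram(markov_spec(0.9, 0.9, n_bouts = 50), seed = 3)
#' mean(h$sleep_bouts)
simulate_markov_hypnogram <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "markov_spec"))
  set_task_seed(seed)
  p_stay <- c(sleep = spec$p_stay_sleep, wake = spec$p_stay_wake)
  # expected epochs needed; simulate in chunks until both quotas are met
  mean_bout <- 1 / (1 - p_stay)
  chunk <- as.integer(ceiling(1.5 * spec$n_bouts * sum(mean_bout)) + 100)
  states <- integer(0)
  cur <- 1L # start asleep; the first bout is counted like any other
  repeat {
    u <- stats::runif(chunk)
    new_states <- integer(chunk)
    for (t in seq_len(chunk)) {
      new_states[t] <- cur
      stay <- if (cur == 1L) p_stay[["sleep"]] else p_stay[["wake"]]
      if (u[t] >= stay) cur <- 3L - cur
    }
    states <- c(states, new_states)
    r <- rle(states)
    # drop the final (possibly incomplete) run before counting
    complete_vals <- r$values[-length(r$values)]
    if (sum(complete_vals == 1L) >= spec$n_bouts &&
        sum(complete_vals == 2L) >= spec$n_bouts) break
  }
  r <- rle(states)
  vals <- r$values[-length(r$values)]
  lens <- r$lengths[-length(r$lengths)]
  sleep <- lens[vals == 1L][seq_len(spec$n_bouts)]
  wake <- lens[vals == 2L][seq_len(spec$n_bouts)]
  prov <- list(family = "markov", p_stay_sleep = spec$p_stay_sleep,
               p_stay_wake = spec$p_stay_wake, seed = seed)
  list(
    sleep_bouts = bout_sample(as.numeric(sleep), provenance = c(prov, state = "sleep")),
    wake_bouts = bout_sample(as.numeric(wake), provenance = c(prov, state = "wake"))
  )
}

#' Draw a reference sample from a fitted model
#'
#' Sampling step of the parametric bootstrap: reference datasets are drawn
#' from the distribution defined by a fitted model, restricted to
#' `[1, Inf)`. For a power-law model the inverse CDF is used directly. For an
#' exponential mixture normalized on `[1, Inf)`, a component is chosen with
#' probability `w_i = a_i tau_i exp(-1/tau_i) / Z` and the draw is
#' `1 + Exponential(tau_i)` (the memoryless shift of a left-truncated
#' exponential).
#'
#' @param model a [power_law_model()] or [exp_mixture_model()].
#' @param n number of draws.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return a [bout_sample()] of `n` durations >= 1 (or >= `x_min`).
#' @export
#' @examples
#' m <- exp_mixture_model(1, 4)
#' mean(sample_from_fitted(m, 1000, seed = 2)) # about 1 + 4
sample_from_fitted <- function(model, n, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  set_task_seed(seed)
  if (inherits(model, "power_law_model")) {
    u <- stats::runif(n)
    x <- model$x_min * (1 - u)^(-1 / (model$alpha - 1))
    return(bout_sample(x, provenance = list(family = "fitted_powerlaw",
                                            alpha = model$alpha,
                                            x_min = model$x_min, seed = seed)))
  }
  if (inherits(model, "exp_mixture_model")) {
    dens <- normalize_to_pdf(model)
    comp <- sample.int(model$k, n, replace = TRUE, prob = dens$weights)
    x <- 1 + stats::rexp(n, rate = 1 / model$taus[comp])
    return(bout_sample(x, provenance = list(family = "fitted_expmix",
                                            taus = model$taus,
                                            weights = dens$weights,
                                            seed = seed)))
  }
  stop("model must be a power_law_model or an exp_mixture_model")
}
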
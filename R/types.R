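#' Bout-duration sample
#'
#' The basic data container: a finite vector of bout durations measured in
#' 30-second epochs, each at least 1 epoch long (shorter events are never
#' scored in clinical practice), together with provenance describing how the
#' sample was generated.
#'
#' @param durations numeric vector of bout durations in epochs, all >= 1
#'   (unless `truncated = FALSE`, used internally for untruncated draws).
#' @param provenance named list describing the generator (family, parameters,
#'   seed); free-form.
#' @param truncated logical; enforce the >= 1 epoch rule (default `TRUE`).
#' @return an object of class `bout_sample`: the numeric duration vector with
#'   attributes `n` and `provenance`.
#' @export
#' @examples
#' bout_sample(c(1.5, 2, 7.25))
bout_sample <- function(durations, provenance = list(), truncated = TRUE) {
  durations <- as.numeric(durations)
  if (length(durations) == 0L) stop("a bout sample must contain at least one duration")
  if (any(!is.finite(durations))) stop("durations must be finite")
  if (truncated && any(durations < 1)) {
    stop("durations below 1 epoch violate the truncation convention ",
         "(all bouts are >= 1 epoch = 30 s); offending minimum: ",
         format(min(durations)))
  }
  structure(durations,
            n = length(durations),
            provenance = provenance,
            class = "bout_sample")
}

#' @export
print.bout_sample <- function(x, ...) {
  prov <- attr(x, "provenance")
  fam <- if (!is.null(prov$family)) prov$family else "unknown"
  cat(sprintf("Bout sample: n = %d durations (epochs), generator = %s\n",
              attr(x, "n"), fam))
  cat(sprintf("  range [%.3g, %.3g], mean %.3g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
as.double.bout_sample <- function(x, ...) {
  attributes(x) <- NULL
  x
}

#' Exponential-mixture generator specification
#'
#' Describes a bout-duration generator that concatenates accepted draws from
#' up to three exponential components. Each component is an exponential decay
#' with constant `tau` (epochs) and a quota `n_draws` of accepted draws
#' (values < 1 epoch are rejected and redrawn). Component proportions are
#' therefore exact draw counts, not probabilities.
#'
#' @param tau numeric vector (length 1-3) of decay constants, all > 0.
#' @param n_draws integer vector, same length, of accepted-draw quotas >= 0;
#'   at least one must be positive.
#' @return object of class `mixture_spec`.
#' @export
#' @examples
#' mixture_spec(tau = c(1, 15), n_draws = c(30, 10))
mixture_spec <- function(tau, n_draws) {
  tau <- as.numeric(tau)
  n_draws <- as.integer(round(n_draws))
  if (length(tau) < 1L || length(tau) > 3L)
    stop("a mixture has 1, 2 or 3 exponential components")
  if (length(n_draws) != length(tau))
    stop("`tau` and `n_draws` must have the same length")
  if (any(tau <= 0)) stop("all decay constants tau must be > 0")
  if (any(n_draws < 0) || sum(n_draws) < 1L)
    stop("draw quotas must be >= 0 with at least one positive")
  structure(list(tau = tau, n_draws = n_draws, n = sum(n_draws)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Exponential mixture spec: %d component(s), n = %d accepted draws\n",
              length(x$tau), x$n))
  for (i in seq_along(x$tau)) {
    cat(sprintf("  tau = %-8.4g n_draws = %d (%.1f%%)\n",
                x$tau[i], x$n_draws[i], 100 * x$n_draws[i] / x$n))
  }
  invisible(x)
}

#' Two-state Markov hypnogram specification
#'
#' A first-order two-state (sleep/wake) Markov chain scored epoch by epoch.
#' Dwell times in each state are geometric with mean `1 / (1 - p_stay)`.
#'
#' @param p_stay_sleep per-epoch probability of remaining asleep, in (0, 1).
#' @param p_stay_wake per-epoch probability of remaining awake, in (0, 1).
#' @param n_bouts number of complete bouts of each state to collect.
#' @return object of class `markov_spec`.
#' @export
#' @examples
#' markov_spec(0.9, 0.9, n_bouts = 400)
markov_spec <- function(p_stay_sleep = 0.9, p_stay_wake = 0.9, n_bouts) {
  if (!(p_stay_sleep > 0 && p_stay_sleep < 1) ||
      !(p_stay_wake > 0 && p_stay_wake < 1))
    stop("stay probabilities must lie strictly in (0, 1)")
  n_bouts <- as.integer(n_bouts)
  if (n_bouts < 1L) stop("n_bouts must be >= 1")
  structure(list(p_stay_sleep = p_stay_sleep, p_stay_wake = p_stay_wake,
                 n_bouts = n_bouts),
            class = "markov_spec")
}

#' Power-law (Pareto) bout-duration model
#'
#' Density `f(x) = c * x^(-alpha)` on `[x_min, Inf)` with
#' `c = (alpha - 1) * x_min^(alpha - 1)`. All experiments here fix
#' `x_min = 1` epoch so that the whole sample enters the fit.
#'
#' @param alpha scaling exponent, > 1 (otherwise the density is not
#'   normalizable).
#' @param x_min lower threshold in epochs, >= 1 by the truncation convention.
#' @return object of class `power_law_model`.
#' @export
#' @examples
#' power_law_model(alpha = 3)
power_law_model <- function(alpha, x_min = 1) {
  if (!is.finite(alpha) || alpha <= 1)
    stop("invalid parameter: alpha must be > 1 for a normalizable power law")
  if (x_min < 1) stop("x_min must be >= 1 epoch")
  structure(list(alpha = alpha, x_min = x_min,
                 c = (alpha - 1) * x_min^(alpha - 1)),
            class = "power_law_model")
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("Power law model: f(x) = c x^-alpha, alpha = %.4f, x_min = %g\n",
              x$alpha, x$x_min))
  invisible(x)
}

#' Exponential-mixture bout-duration model
#'
#' The fitted frequency function `f(x) = sum_i a_i exp(-x / tau_i)` with zero
#' offset. Amplitudes `a_i` are in count units (the y-intercept of each
#' component on the frequency-duration histogram); [normalize_to_pdf()] turns
#' the model into a probability density on `[1, Inf)`. Components are stored
#' in ascending-`tau` order so fits are comparable despite label switching.
#'
#' @param amplitudes numeric vector of component amplitudes, all > 0.
#' @param taus numeric vector of decay constants (epochs), all > 0.
#' @return object of class `exp_mixture_model` with components sorted by tau.
#' @export
#' @examples
#' exp_mixture_model(amplitudes = c(50, 5), taus = c(1, 12))
exp_mixture_model <- function(amplitudes, taus) {
  amplitudes <- as.numeric(amplitudes)
  taus <- as.numeric(taus)
  k <- length(taus)
  if (k < 1L || k > 3L) stop("k must be 1, 2 or 3")
  if (length(amplitudes) != k) stop("amplitudes and taus must match in length")
  if (any(!is.finite(amplitudes)) || any(!is.finite(taus)) ||
      any(amplitudes <= 0) || any(taus <= 0))
    stop("constraint violation: all amplitudes and taus must be positive ",
         "(only decaying components are biologically admissible)")
  o <- order(taus)
  structure(list(k = k, amplitudes = amplitudes[o], taus = taus[o], offset = 0),
            class = "exp_mixture_model")
}

#' @export
print.exp_mixture_model <- function(x, ...) {
  cat(sprintf("Exponential mixture model: k = %d component(s), zero offset\n", x$k))
  for (i in seq_len(x$k)) {
    cat(sprintf("  a = %-10.5g tau = %-.5g epochs\n", x$amplitudes[i], x$taus[i]))
  }
  invisible(x)
}
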
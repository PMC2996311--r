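#' Constrained multi-exponential least-squares fit to a histogram
#'
#' Fits `f(x) = sum_{i=1}^{k} a_i exp(-x / tau_i)` (zero offset) to the
#' (bin representative, count) pairs of a unit-width frequency-duration
#' histogram by unweighted nonlinear least squares, then screens the result
#' against the biological constraints: every amplitude and every decay
#' constant must be strictly positive (only decaying components are
#' admissible). Fits that converge but violate the constraints are discarded,
#' not projected back.
#'
#' Numerically the problem is separable: for fixed decay constants the
#' amplitudes solve a linear least-squares problem, so the optimizer (a
#' Nelder-Mead search refined by BFGS) works on the `k` decay constants only
#' (variable projection). Multi-exponential least squares is sensitive to
#' starting values, so the deterministic geometric-progression start
#' (`tau0` spanning 1 to the histogram range) is followed by up to
#' `max_restarts` seed-jittered restarts before the fit is declared failed.
#' Histograms with fewer bins than free parameters (`2k`) are
#' underdetermined and reported as optimizer failures.
#'
#' @param hist a `duration_histogram` from [bin_histogram()].
#' @param k number of exponential components (1, 2 or 3).
#' @param seed integer seed controlling the jittered restarts.
#' @param max_restarts additional jittered starts tried after the
#'   deterministic one (default 20).
#' @param representative `"midpoint"` (default) or `"left"` bin abscissa.
#' @return on success, an [exp_mixture_model()] (tau-ascending) with
#'   attributes `ss` (residual sum of squares) and `n_starts`; on failure an
#'   object of class `boutlaw_nonconvergence` whose `reason` distinguishes
#'   `"optimizer-failure"` from `"constraint-violation"`. Use
#'   [is_converged()] to branch.
#' @export
#' @examples
#' h <- bin_histogram(draw_exponential_mixture(mixture_spec(4, 5000), seed = 1))
#' fit_exponentials_nls(h, k = 1, seed = 2)
fit_exponentials_nls <- function(hist, k, seed = NULL, max_restarts = 20,
                                 representative = c("midpoint", "left")) {
  stopifnot(inherits(hist, "duration_histogram"))
  k <- as.integer(k)
  if (!(k %in% 1:3)) stop("invalid parameter: k must be 1, 2 or 3")
  offset <- if (match.arg(representative) == "midpoint") 0.5 else 0
  ch <- compress_hist(hist$bin_start, hist$counts, offset = offset)
  if (ch$m < 2L * k) {
    return(nonconvergence("optimizer-failure",
                          detail = sprintf("%d bins cannot identify %d parameters",
                                           ch$m, 2L * k)))
  }
  R <- max(ch$x_nz)
  tau0 <- switch(k,
                 `1` = max(sum(ch$x_nz * ch$y_nz) / sum(ch$y_nz), 0.5),
                 `2` = c(1, R),
                 `3` = c(1, sqrt(R), R))
  jitter_seeds <- if (max_restarts > 0 && !is.null(seed)) {
    derive_seeds(seed, max_restarts)
  } else if (max_restarts > 0) {
    sample.int(2147483646L, max_restarts)
  } else integer(0)

  saw_constraint_violation <- FALSE
  violating_ss <- c()
  n_starts <- 0L
  for (attempt in 0:max_restarts) {
    start <- if (attempt == 0L) {
      tau0
    } else {
      set.seed(jitter_seeds[attempt])
      tau0 * exp(stats::runif(k, -1, 1))
    }
    n_starts <- n_starts + 1L
    res <- varpro_optim(start, ch, k)
    if (is.null(res)) {
      # a pure failure streak (no start even converged) is a property of the
      # data, typically a near-degenerate histogram; stop burning restarts
      if (n_starts >= 6L && !saw_constraint_violation) break
      next
    }
    if (all(res$amplitudes > 0) && all(res$taus > 0)) {
      model <- exp_mixture_model(res$amplitudes, res$taus)
      attr(model, "ss") <- res$ss
      attr(model, "n_starts") <- n_starts
      return(model)
    }
    saw_constraint_violation <- TRUE
    # restarts exist to escape local minima; once two starts agree on the
    # same constraint-violating optimum the violation is a property of the
    # least-squares solution, not of the start, so stop early
    violating_ss <- c(violating_ss, res$ss)
    if (sum(abs(violating_ss - res$ss) <= 1e-4 * (1 + abs(res$ss))) >= 2L) break
  }
  nonconvergence(if (saw_constraint_violation) "constraint-violation" else "optimizer-failure")
}

# Variable-projection objective: residual sum of squares over taus with the
# amplitudes profiled out by linear least squares.
# Compressed representation of a unit-bin histogram for least squares: the
# nonzero bins explicitly, runs of consecutive zero bins by closed form.
# Sums over a zero run (and the Gram matrix over the whole consecutive bin
# range) are geometric series, so the objective costs O(#nonzero * k)
# per evaluation no matter how far the histogram's tail reaches.
compress_hist <- function(bins, ys, offset = 0.5) {
  # `bins` are the occupied bin starts (ascending); zero runs are the gaps
  gap <- diff(bins) - 1
  has_gap <- gap > 0
  list(x_nz = bins + offset, y_nz = as.numeric(ys),
       run_start = bins[which(has_gap)] + 1 + offset,
       run_len = gap[has_gap],
       x0 = bins[1L] + offset,
       m = bins[length(bins)] - bins[1L] + 1)
}

# sum_{t=0..L-1} exp(-c (x0 + t)) for c > 0, via expm1 for small c; all
# arguments may be vectors of equal length
geom_sum <- function(c, x0, L) {
  exp(-c * x0) * (-expm1(-c * L)) / (-expm1(-c))
}

# Gram matrix G_ij = sum over all bins of exp(-x (1/tau_i + 1/tau_j)) and
# rhs b_i = sum over nonzero bins of y exp(-x / tau_i); solved in C++.
varpro_solve <- function(taus, ch) {
  out <- varpro_solve_cpp(taus, ch$x_nz, ch$y_nz,
                          ch$run_start, ch$run_len, ch$x0, ch$m)
  if (length(out) == 1L) return(NULL)
  list(a = out[-1L], ss = out[1L])
}

varpro_ss <- function(taus, ch) {
  if (any(!is.finite(taus)) || any(taus < 1e-8) || any(taus > 1e12))
    return(.Machine$double.xmax)
  out <- varpro_solve_cpp(taus, ch$x_nz, ch$y_nz,
                          ch$run_start, ch$run_len, ch$x0, ch$m)
  if (length(out) == 1L) return(.Machine$double.xmax)
  out[1L]
}

# Search over log(tau): the decay constants live on a ratio scale and the
# log parametrization removes the flat invalid region at tau <= 0, which
# otherwise strands the simplex. Amplitudes stay unconstrained (profiled by
# linear least squares), so the positivity screen still has teeth.
varpro_ss_log <- function(ltaus, ch) varpro_ss(exp(ltaus), ch)

varpro_optim <- function(start, ch, k) {
  k <- as.integer(k)
  if (k == 1L) {
    opt <- tryCatch(
      stats::optim(log(start), varpro_ss_log, ch = ch, method = "Brent",
                   lower = log(1e-3), upper = log(50 * (ch$x0 + ch$m)),
                   control = list(reltol = 1e-14)),
      error = function(e) NULL)
  } else {
    opt <- tryCatch(
      stats::optim(log(start), varpro_ss_log, ch = ch, method = "Nelder-Mead",
                   control = list(maxit = if (k >= 3L) 300 else 400,
                                  reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$convergence == 0 &&
        opt$value < .Machine$double.xmax) {
      # refine only candidates that already satisfy the positivity screen;
      # a violating optimum is discarded anyway and needs no extra precision
      cand <- varpro_solve(exp(opt$par), ch)
      if (!is.null(cand) && all(cand$a > 0)) {
        polish <- tryCatch(
          stats::optim(opt$par, varpro_ss_log, ch = ch, method = "BFGS",
                       control = list(maxit = 50, reltol = 1e-12)),
          error = function(e) NULL)
        if (!is.null(polish) && polish$value <= opt$value) opt <- polish
      }
    }
  }
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value) ||
      opt$value >= .Machine$double.xmax) return(NULL)
  taus <- exp(as.numeric(opt$par))
  sol <- varpro_solve(taus, ch)
  if (is.null(sol)) return(NULL)
  list(taus = taus, amplitudes = sol$a, ss = sol$ss)
}

nonconvergence <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail),
            class = "boutlaw_nonconvergence")
}

#' @export
print.boutlaw_nonconvergence <- function(x, ...) {
  cat("Exponential fit did not converge:", x$reason,
      if (!is.null(x$detail)) paste0("(", x$detail, ")") else "", "\n")
  invisible(x)
}

#' Did a fit converge within the constraints?
#'
#' @param fit result of [fit_exponentials_nls()] (or any model object).
#' @return `TRUE` for a returned model, `FALSE` for a
#'   `boutlaw_nonconvergence` outcome.
#' @export
is_converged <- function(fit) {
  !inherits(fit, "boutlaw_nonconvergence")
}

#' Predicted histogram counts from an exponential-mixture model
#'
#' @param object an [exp_mixture_model()].
#' @param x abscissae (bin representatives).
#' @param ... unused.
#' @return numeric vector `sum_i a_i exp(-x / tau_i)`.
#' @export
predict.exp_mixture_model <- function(object, x, ...) {
  as.numeric(exp(outer(x, -1 / object$taus)) %*% object$amplitudes)
}

#' Normalize a fitted exponential mixture to a density on [1, Inf)
#'
#' The NLS fit returns a frequency function (a probability mass function up
#' to scale); dividing by `Z = sum_i a_i tau_i exp(-1/tau_i)` (its integral
#' over `[1, Inf)`) turns it into a probability density with closed-form CDF
#' \deqn{G(q) = \sum_i a_i \tau_i (e^{-1/\tau_i} - e^{-q/\tau_i}) / Z,}
#' which is what the KS distance, the bootstrap sampler and the Vuong
#' likelihood all consume. The mixture weight of component `i` under the
#' normalized density is `w_i = a_i tau_i exp(-1/tau_i) / Z`.
#'
#' @param model an [exp_mixture_model()].
#' @return object of class `expmix_density`: list with `Z`, `weights`,
#'   `pdf(x)` and `cdf(q)` closures.
#' @export
#' @examples
#' d <- normalize_to_pdf(exp_mixture_model(1, 1))
#' d$Z        # exp(-1)
#' d$cdf(2)   # 1 - exp(-1)
normalize_to_pdf <- function(model) {
  stopifnot(inherits(model, "exp_mixture_model"))
  a <- model$amplitudes
  tau <- model$taus
  mass <- a * tau * exp(-1 / tau)
  Z <- sum(mass)
  if (!is.finite(Z) || Z <= 0)
    stop("invalid parameter: model is not normalizable on [1, Inf)")
  structure(list(
    Z = Z,
    weights = mass / Z,
    pdf = function(x) {
      out <- numeric(length(x))
      ok <- x >= 1
      if (any(ok)) out[ok] <- as.numeric(exp(outer(x[ok], -1 / tau)) %*% a) / Z
      out
    },
    cdf = function(q) {
      # survival form: G(q) = 1 - sum_i w_i exp(-(q - 1) / tau_i)
      out <- numeric(length(q))
      ok <- q >= 1
      if (any(ok)) {
        w <- mass / Z
        out[ok] <- 1 - as.numeric(exp(outer(q[ok] - 1, -1 / tau)) %*% w)
      }
      out
    }
  ), class = "expmix_density")
}

#' Exponential-mixture density and CDF on [1, Inf)
#'
#' Convenience wrappers around [normalize_to_pdf()].
#'
#' @param x,q evaluation points.
#' @param model an [exp_mixture_model()].
#' @return numeric vector.
#' @export
expmix_pdf <- function(x, model) normalize_to_pdf(model)$pdf(x)

#' @rdname expmix_pdf
#' @export
expmix_cdf <- function(q, model) normalize_to_pdf(model)$cdf(q)

# CDF closure for either model family, on [1, Inf) / [x_min, Inf).
model_cdf <- function(model) {
  if (inherits(model, "power_law_model")) {
    function(q) plaw_cdf(q, model)
  } else if (inherits(model, "exp_mixture_model")) {
    normalize_to_pdf(model)$cdf
  } else stop("unsupported model class")
}
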
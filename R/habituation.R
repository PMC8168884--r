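#' Habituation model parameters
#'
#' Bundles the three quantities that determine the whole decay of information
#' gain under repeated exposure, plus the learning rate: the *initial
#' uncertainty* s_pI (variance of the initial prior), the *initial prediction
#' error* delta_I = |eta - xbar| (absolute difference between the prior mean
#' and the peak of the likelihood), and the *external noise* s_l (variance of
#' the encoded data).
#'
#' `delta_I` is stored as given and must be non-negative: a negative value is
#' rejected rather than silently absolute-valued, since a sign here is always
#' a caller error. Use `abs(eta - xbar)` at the call site when starting from
#' means.
#'
#' @param initial_uncertainty s_pI >= 0, variance of the initial prior.
#' @param initial_prediction_error delta_I >= 0.
#' @param noise s_l > 0, external noise variance.
#' @param learning_rate alpha in \[0, 1\]; 0 is the degenerate no-learning
#'   case.
#' @return An object of class `habituation_params`.
#' @examples
#' habituation_params(1, 10, 0.5, 0.1) # the canonical simulation setting
#' @export
habituation_params <- function(initial_uncertainty, initial_prediction_error,
                               noise, learning_rate) {
  vals <- c(initial_uncertainty, initial_prediction_error, noise,
            learning_rate)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  if (initial_uncertainty < 0) stop("initial_uncertainty must be >= 0")
  if (initial_prediction_error < 0)
    stop("initial_prediction_error must be >= 0 (pass abs(eta - xbar))")
  if (noise <= 0) stop("noise must be > 0")
  if (learning_rate < 0 || learning_rate > 1)
    stop("learning_rate must lie in [0, 1]")
  structure(list(initial_uncertainty = initial_uncertainty,
                 initial_prediction_error = initial_prediction_error,
                 noise = noise, learning_rate = learning_rate),
            class = "habituation_params")
}

#' @export
print.habituation_params <- function(x, ...) {
  cat(sprintf(
    "<habituation_params> s_pI = %g, delta_I = %g, s_l = %g, alpha = %g\n",
    x$initial_uncertainty, x$initial_prediction_error, x$noise,
    x$learning_rate))
  invisible(x)
}

check_params <- function(params) {
  if (!inherits(params, "habituation_params"))
    stop("params must be a habituation_params object")
  params
}

check_exposure <- function(n) {
  if (!is.numeric(n) || length(n) < 1L || any(!is.finite(n)) || any(n < 1) ||
      any(n != round(n)))
    stop("exposure index n must contain positive integers")
  n
}

#' Closed-form terms of the n-th information gain
#'
#' Decomposes the n-th information gain into its variance-driven and
#' prediction-error-driven parts:
#' G_n = (A_n + B_n delta_I^2) / 2, with
#' A_n = g_{n-1}/g_n - ln(g_{n-1}/g_n) - 1,
#' B_n = alpha^2 s_pI s_l / (g_{n-1} g_n^2), and
#' g_n = alpha n s_pI + s_l (so g_0 = s_l: the initial prior plays the role
#' of the 0-th posterior).
#'
#' @param params A [habituation_params()].
#' @param n Exposure index (positive integer); may be a vector.
#' @return A list of class `gain_terms` with numeric fields `a_term`,
#'   `b_term`, `g_prev`, `g_curr`, each of `length(n)`.
#' @seealso [information_gain()], which equals
#'   `(a_term + b_term * delta_I^2) / 2` exactly.
#' @export
gain_terms <- function(params, n) {
  check_params(params); check_exposure(n)
  a <- params$learning_rate * params$initial_uncertainty
  sl <- params$noise
  g_curr <- a * n + sl
  g_prev <- a * (n - 1) + sl
  r <- g_prev / g_curr
  structure(list(
    a_term = r - log(r) - 1,
    b_term = params$learning_rate^2 * params$initial_uncertainty * sl /
      (g_prev * g_curr^2),
    g_prev = g_prev, g_curr = g_curr
  ), class = "gain_terms")
}

#' Information gain at the n-th exposure
#'
#' The Kullback-Leibler divergence from the (n-1)-th posterior (which serves
#' as the n-th prior) to the n-th posterior of the conjugate Gaussian update
#' - the model's index of surprise, and of arousal evoked by the n-th
#' presentation of the same stimulus. Habituation is the decay of this
#' quantity with n.
#'
#' Degenerate cases return 0: no learning (alpha = 0) or a point-mass prior
#' (s_pI = 0) yields no belief change and hence no gain.
#'
#' @inheritParams gain_terms
#' @return Numeric vector of gains (nats), same length as `n`; always >= 0.
#' @examples
#' p <- habituation_params(1, 10, 0.5, 0.1)
#' information_gain(p, 1) # ~ 1.3967
#' information_gain(p, 1:5) # strictly decreasing
#' @export
information_gain <- function(params, n) {
  check_params(params); check_exposure(n)
  if (params$learning_rate == 0 || params$initial_uncertainty == 0)
    return(rep(0, length(n)))
  tm <- gain_terms(params, n)
  0.5 * (tm$a_term + tm$b_term * params$initial_prediction_error^2)
}

#' Decay curve of information gain
#'
#' Evaluates the per-exposure information gain G_1..G_{n_max}. For alpha > 0
#' and s_pI > 0 the sequence decays strictly towards zero.
#'
#' @param params A [habituation_params()].
#' @param n_max Number of exposures; a single positive integer.
#' @return An object of class `gain_curve`: list with `params` and numeric
#'   `gains` of length `n_max` (element n is G_n).
#' @export
gain_curve <- function(params, n_max) {
  check_params(params)
  if (!is.numeric(n_max) || length(n_max) != 1L || !is.finite(n_max) ||
      n_max < 1 || n_max != round(n_max))
    stop("n_max must be a single positive integer")
  structure(list(params = params,
                 gains = information_gain(params, seq_len(n_max))),
            class = "gain_curve")
}

#' @export
print.gain_curve <- function(x, ...) {
  cat(sprintf("<gain_curve> %d exposures; G_1 = %.4g, G_%d = %.4g\n",
              length(x$gains), x$gains[1], length(x$gains),
              x$gains[length(x$gains)]))
  invisible(x)
}

#' @export
as.data.frame.gain_curve <- function(x, ...) {
  data.frame(n = seq_along(x$gains), gain = x$gains)
}

#' Reversal threshold for the uncertainty ordering of first-exposure gain
#'
#' At delta_I = 0, first-exposure gain G_1 is always increasing in the
#' initial uncertainty. When the prediction error dominates, the ordering of
#' G_1 between two uncertainties s_p1 and s_p2 reverses exactly when
#' s_p1 * s_p2 > (s_l / alpha)^2. This function returns that threshold on
#' the product of the two uncertainties.
#'
#' The product predicate characterises the ordering of the B (prediction
#' error) term exactly for every pair; at a finite prediction error the
#' observed G_1 flip additionally requires the B-term difference to outweigh
#' the always-increasing A term, so pairs close to the threshold need a
#' larger delta_I to show the reversal.
#'
#' @param noise External noise variance s_l > 0.
#' @param learning_rate Learning rate alpha > 0.
#' @return `(noise / learning_rate)^2`, the threshold on s_p1 * s_p2.
#' @examples
#' reversal_threshold(0.5, 0.1) # 25
#' @export
reversal_threshold <- function(noise, learning_rate) {
  stopifnot(is.numeric(noise), length(noise) == 1L, is.finite(noise),
            is.numeric(learning_rate), length(learning_rate) == 1L,
            is.finite(learning_rate))
  if (noise <= 0 || learning_rate <= 0)
    stop("noise and learning_rate must be > 0")
  (noise / learning_rate)^2
}

## Antiderivative of the continuous-exposure gain, evaluated at n.
## G(t) uses g(t) = a t + s_l and g(t-1); defined where g(t-1) > 0.
gain_antiderivative <- function(params, n) {
  a <- params$learning_rate * params$initial_uncertainty
  sl <- params$noise
  sp <- params$initial_uncertainty
  al <- params$learning_rate
  d2 <- params$initial_prediction_error^2
  g <- a * n + sl
  h <- g - a
  lr <- log(h / g)
  a_part <- sl / (sp * g) + sl / (al * sp^2) * lr
  b_part <- (1 - sl / (al * sp)) * lr - n * lr
  0.5 * (a_part * d2 + b_part)
}

## smallest continuous exposure index at which the previous-posterior
## precision term g(t-1) is positive
continuous_domain_start <- function(params) {
  a <- params$learning_rate * params$initial_uncertainty
  if (a <= 0) return(-Inf)
  1 - params$noise / a
}

#' Integrated information gain over continuous exposure count
#'
#' Treats the exposure index as continuous and integrates the gain G(t) from
#' `from` to `n` in closed form. With the default `from = 0` the integration
#' constant is fixed so the value at n = 0 is 0.
#'
#' The continuous extension uses g(t - 1), which is positive for all t >= 1
#' but reaches 0 at t = 1 - s_l / (alpha s_pI) when alpha * s_pI > s_l; the
#' integral is only defined for `from` (and `n`) beyond that point, so the
#' from-0 convention requires alpha * s_pI < s_l. Use `from = 1` (gain
#' accumulated from the first exposure onward) for arbitrary parameters.
#'
#' @param params A [habituation_params()].
#' @param n Upper limit(s), real >= `from`; may be a vector. `Inf` is
#'   allowed and gives the asymptotic total.
#' @param from Lower limit of integration (default 0).
#' @return Numeric vector: the integral of G over \[from, n\].
#' @seealso [total_gain_limit()] for the n -> Inf limit,
#'   [total_gain_sum()] for the discrete-sum analogue.
#' @export
integrated_gain <- function(params, n, from = 0) {
  check_params(params)
  stopifnot(is.numeric(n), length(n) >= 1L, is.numeric(from),
            length(from) == 1L, is.finite(from))
  if (any(is.na(n)) || any(n < from))
    stop("n must satisfy n >= from")
  if (params$learning_rate == 0 || params$initial_uncertainty == 0)
    return(rep(0, length(n)))
  t0 <- continuous_domain_start(params)
  if (from <= t0)
    stop(sprintf(paste0(
      "the continuous-exposure gain is undefined at the lower limit: ",
      "alpha * s_pI >= s_l makes g(t - 1) <= 0 for t <= %.4g; ",
      "use from = 1 or reduce alpha * s_pI below s_l"), t0))
  ## limit of the antiderivative at +Inf is exactly 1/2 (all log terms
  ## vanish and -n log(g(n-1)/g(n)) -> 1)
  upper <- ifelse(is.infinite(n), 0.5, gain_antiderivative(params, n))
  upper - gain_antiderivative(params, from)
}

#' Asymptotic total information gain
#'
#' The limit of [integrated_gain()] as the exposure count goes to infinity:
#' the total gain available from indefinitely repeated exposure, counted
#' from `from`. The limit is finite for all valid parameters and 0 in the
#' degenerate no-learning / no-uncertainty cases.
#'
#' The default `from = 1` counts the gain accumulated from the first
#' exposure onward, which is defined for every parameter set; set
#' `from = 0` for the antiderivative's at-zero convention (requires
#' alpha * s_pI < s_l). At large prediction error the total is decreasing
#' in the initial uncertainty (faster habituation loses more of the
#' available gain than the extra uncertainty adds); at delta_I = 0 it is
#' increasing (it vanishes with s_pI).
#'
#' @inheritParams integrated_gain
#' @return A single number, >= 0.
#' @export
total_gain_limit <- function(params, from = 1) {
  check_params(params)
  if (params$learning_rate == 0 || params$initial_uncertainty == 0) return(0)
  integrated_gain(params, Inf, from = from)
}

#' Discrete total information gain
#'
#' The sum of the per-exposure gains G_n over n = 1, 2, ...: the discrete
#' analogue of [total_gain_limit()]. The series converges but only like
#' 1/n, so the first `n_exact` terms are summed directly and the remainder
#' is taken from the closed-form antiderivative via the midpoint
#' (Euler-Maclaurin) rule, whose error is O(1/n_exact^3).
#'
#' @param params A [habituation_params()].
#' @param n_exact Number of leading terms summed exactly.
#' @return A single number, >= 0.
#' @export
total_gain_sum <- function(params, n_exact = 4000L) {
  check_params(params)
  if (params$learning_rate == 0 || params$initial_uncertainty == 0) return(0)
  head <- sum(information_gain(params, seq_len(n_exact)))
  tail <- 0.5 - gain_antiderivative(params, n_exact + 0.5)
  head + tail
}

#' Habituation half-life
#'
#' The smallest exposure index n at which the information gain has fallen to
#' at most half of the first-exposure gain G_1 -- a convenience summary of
#' habituation speed.
#'
#' @param params A [habituation_params()]; G_1 must be positive.
#' @param n_limit Search cap (the half-life of any valid parameter set is
#'   finite; the cap only guards against runaway loops).
#' @return A single positive integer.
#' @export
half_life <- function(params, n_limit = 1e6) {
  check_params(params)
  g1 <- information_gain(params, 1)
  if (g1 <= 0)
    stop("half_life is undefined when G_1 = 0 (no gain to halve)")
  n <- 1L
  width <- 1L
  ## exponential search then bisect on the monotone tail
  while (information_gain(params, n) > g1 / 2) {
    n <- n + width
    width <- width * 2L
    if (n > n_limit) stop("half_life search exceeded n_limit")
  }
  lo <- max(1L, n - width %/% 2L)
  hi <- n
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (information_gain(params, mid) <= g1 / 2) hi <- mid else lo <- mid + 1L
  }
  as.integer(hi)
}
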
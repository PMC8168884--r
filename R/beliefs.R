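#' Gaussian belief over a latent stimulus feature
#'
#' A belief about the latent mean of a stimulus feature, represented as a
#' Gaussian with mean `eta` and variance `tau2`. The variance of the initial
#' prior is the model's *initial uncertainty*.
#'
#' @param mean Prior (or posterior) mean, in units of the stimulus feature.
#' @param variance Prior (or posterior) variance; must be finite and >= 0.
#'   Zero is the degenerate point-mass belief of an observer with no
#'   uncertainty.
#' @return An object of class `gaussian_belief` with fields `mean` and
#'   `variance`.
#' @seealso [posterior_after_n()], [habituation_params()]
#' @examples
#' gaussian_belief(0, 1)
#' @export
gaussian_belief <- function(mean, variance) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(variance), length(variance) == 1L, is.finite(variance))
  if (variance < 0) stop("belief variance must be >= 0")
  structure(list(mean = mean, variance = variance), class = "gaussian_belief")
}

#' Encoded sensory event
#'
#' The sensed datum an exposure delivers: the brain is assumed to encode the
#' repeated stimulus as a Gaussian likelihood centred on `mean` (the data
#' mean) with variance `noise_variance` (the external noise of the sensory
#' channel).
#'
#' @param mean Likelihood mean (the encoded data mean), same units as the
#'   belief mean.
#' @param noise_variance External noise variance; must be finite and > 0.
#' @return An object of class `stimulus_encoding`.
#' @export
stimulus_encoding <- function(mean, noise_variance) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(noise_variance), length(noise_variance) == 1L,
            is.finite(noise_variance))
  if (noise_variance <= 0) stop("noise_variance must be > 0")
  structure(list(mean = mean, noise_variance = noise_variance),
            class = "stimulus_encoding")
}

#' Learning-rate configuration
#'
#' The learning rate alpha tempers the likelihood in each Bayesian update
#' (the likelihood enters raised to the power alpha), controlling how much a
#' single exposure moves the belief. It is restricted to (0, 1]; alpha = 0 is
#' accepted as the degenerate no-learning edge case.
#'
#' @param learning_rate Learning rate alpha in \[0, 1\].
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(learning_rate) {
  stopifnot(is.numeric(learning_rate), length(learning_rate) == 1L,
            is.finite(learning_rate))
  if (learning_rate < 0 || learning_rate > 1)
    stop("learning_rate must lie in [0, 1]")
  structure(list(learning_rate = learning_rate), class = "learning_config")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> mean = %g, variance = %g\n",
              x$mean, x$variance))
  invisible(x)
}

#' @export
print.stimulus_encoding <- function(x, ...) {
  cat(sprintf("<stimulus_encoding> mean = %g, noise_variance = %g\n",
              x$mean, x$noise_variance))
  invisible(x)
}

#' Posterior belief after n identical exposures
#'
#' Conjugate Gaussian update with a learning rate. After `n` exposures to the
#' identical encoded datum, a Gaussian prior N(eta, s_pI) combined with the
#' tempered likelihood yields the posterior
#' N((alpha n s_pI xbar + s_l eta) / (alpha n s_pI + s_l),
#'   s_pI s_l / (alpha n s_pI + s_l)),
#' where xbar is the data mean and s_l the noise variance. With `n = 0` the
#' prior is returned unchanged. Posterior variance is strictly decreasing in
#' `n` whenever alpha > 0 and the prior variance is positive.
#'
#' @param prior A [gaussian_belief()].
#' @param stim A [stimulus_encoding()].
#' @param cfg A [learning_config()].
#' @param n Number of identical exposures; a single non-negative integer.
#' @return A [gaussian_belief()]: the posterior after `n` exposures.
#' @examples
#' prior <- gaussian_belief(0, 1)
#' stim <- stimulus_encoding(2, 1)
#' posterior_after_n(prior, stim, learning_config(1), 1) # mean 1, var 0.5
#' @export
posterior_after_n <- function(prior, stim, cfg, n) {
  stopifnot(inherits(prior, "gaussian_belief"),
            inherits(stim, "stimulus_encoding"),
            inherits(cfg, "learning_config"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 ||
      n != round(n))
    stop("n must be a single non-negative integer")
  if (n == 0) return(prior)
  a_n <- cfg$learning_rate * n * prior$variance
  g_n <- a_n + stim$noise_variance
  gaussian_belief(
    mean = (a_n * stim$mean + stim$noise_variance * prior$mean) / g_n,
    variance = prior$variance * stim$noise_variance / g_n
  )
}
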
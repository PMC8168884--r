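# Independent quadrature oracle for the information gain: numerically
# integrated KL divergence between the Gaussian posteriors after n and n-1
# exposures, built from posterior_after_n densities only (never from the
# closed-form gain).
kl_quadrature <- function(params, n, rel.tol = 1e-10) {
  prior <- gaussian_belief(0, params$initial_uncertainty)
  stim <- stimulus_encoding(params$initial_prediction_error, params$noise)
  cfg <- learning_config(params$learning_rate)
  post_n <- posterior_after_n(prior, stim, cfg, n)
  post_p <- posterior_after_n(prior, stim, cfg, n - 1L)
  if (post_n$variance == 0 || post_p$variance == 0) return(0)
  sd_n <- sqrt(post_n$variance)
  integrand <- function(mu) {
    p <- stats::dnorm(mu, post_n$mean, sd_n)
    q <- stats::dnorm(mu, post_p$mean, sqrt(post_p$variance))
    out <- p * (log(p) - log(q))
    out[p == 0] <- 0
    out
  }
  stats::integrate(integrand, post_n$mean - 12 * sd_n,
                   post_n$mean + 12 * sd_n,
                   rel.tol = rel.tol, subdivisions = 500L)$value
}

# random but reproducible parameter draws spanning the relevant ranges
draw_params <- function(k, seed = 101) {
  set.seed(seed)
  lapply(seq_len(k), function(i)
    habituation_params(
      initial_uncertainty = stats::runif(1, 0.05, 20),
      initial_prediction_error = stats::runif(1, 0, 15),
      noise = stats::runif(1, 0.1, 3),
      learning_rate = stats::runif(1, 0.02, 1)
    ))
}

# continuous-exposure gain used as an independent quadrature target
continuous_gain <- function(t, params) {
  a <- params$learning_rate * params$initial_uncertainty
  sl <- params$noise
  g <- a * t + sl
  h <- a * (t - 1) + sl
  0.5 * (h / g - log(h / g) - 1 +
           params$learning_rate^2 * params$initial_uncertainty * sl /
           (h * g^2) * params$initial_prediction_error^2)
}

expect_close <- function(x, y, abs_tol = 1e-8, rel_tol = 1e-6) {
  ok <- abs(x - y) <= abs_tol | abs(x - y) <= rel_tol * pmax(abs(x), abs(y))
  expect_true(all(ok),
              info = sprintf("max abs err %.3g, max rel err %.3g",
                             max(abs(x - y)),
                             max(abs(x - y) / pmax(abs(x), abs(y), 1e-300))))
}
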
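#' Observed decay curve
#'
#' A decay observation pairs exposure indices (or block midpoints) with
#' observed responses (rating means or P300 block amplitudes) assumed to be
#' an unknown affine transform of the model's information gain.
#'
#' @param exposure Strictly increasing positive exposure indices.
#' @param response Observed responses, same length, all finite.
#' @return An object of class `decay_observation` (a data frame).
#' @export
decay_observation <- function(exposure, response) {
  stopifnot(is.numeric(exposure), is.numeric(response),
            length(exposure) == length(response))
  if (length(exposure) < 3L) stop("need at least 3 observation points")
  if (any(!is.finite(exposure)) || any(!is.finite(response)))
    stop("exposure and response must be finite")
  if (any(exposure < 1) || any(exposure != round(exposure)))
    stop("exposure indices must be positive integers")
  if (is.unsorted(exposure, strictly = TRUE))
    stop("exposure indices must be strictly increasing")
  structure(data.frame(exposure = as.integer(exposure), response = response),
            class = c("decay_observation", "data.frame"))
}

fit_free_names <- c("initial_uncertainty", "initial_prediction_error",
                    "learning_rate")

default_fit_bounds <- function(free) {
  lower <- c(initial_uncertainty = 1e-3, initial_prediction_error = 0,
             learning_rate = 1e-3)
  upper <- c(initial_uncertainty = 1e3, initial_prediction_error = 1e3,
             learning_rate = 1)
  list(lower = lower[free], upper = upper[free])
}

## residual sum of squares after projecting out the affine map
## (variable projection: offset and slope solved linearly)
decay_rss <- function(theta, free, fixed, obs) {
  p <- fixed
  p[free] <- as.list(theta)
  p <- habituation_params(p$initial_uncertainty, p$initial_prediction_error,
                          p$noise, p$learning_rate)
  g <- information_gain(p, obs$exposure)
  X <- cbind(1, g)
  fit <- stats::lm.fit(X, obs$response)
  sum(fit$residuals^2)
}

#' Fit the habituation model to an observed decay curve
#'
#' Least-squares fit of `offset + slope * G_n(params)` to the observations,
#' with a chosen subset of model parameters free and the affine readout
#' (offset, slope) solved linearly at every candidate (variable
#' projection). The nonlinear search is multi-start bounded L-BFGS-B,
#' deterministic given `seed`.
#'
#' A single decay curve weakly identifies the full parameter set: the
#' affine readout absorbs overall scale, so s_pI, delta_I and alpha trade
#' off against each other. The recommended use fixes noise and all but one
#' or two parameters (as the shared-stimulus design of the experiment
#' does) and frees the rest.
#'
#' @param obs A [decay_observation()] (or data frame with `exposure`,
#'   `response`).
#' @param free Character vector naming the free parameters, a subset of
#'   `"initial_uncertainty"`, `"initial_prediction_error"`,
#'   `"learning_rate"`.
#' @param fixed A [habituation_params()] giving the fixed values (its
#'   entries for free parameters seed nothing; starts are drawn from the
#'   bounds).
#' @param bounds Optional list with named numeric `lower`, `upper` over the
#'   free parameters; defaults to \[1e-3, 1e3\] for variances, \[0, 1e3\]
#'   for the prediction error and \[1e-3, 1\] for the learning rate.
#' @param n_starts Number of random multi-starts (default 16).
#' @param seed Integer seed for the start draws.
#' @return An object of class `fit_result`: `estimate` (a complete
#'   [habituation_params()]), `offset`, `slope`, `loss` (RSS),
#'   `converged`, `non_identifiable` (flat-curve flag), `free`,
#'   `diagnostics` (start values and per-start losses).
#' @examples
#' p <- habituation_params(0.5, 10, 0.5, 0.1)
#' y <- 2 + 25 * information_gain(p, 1:60)
#' fit <- fit_decay(decay_observation(1:60, y), free = "learning_rate",
#'                  fixed = p)
#' abs(fit$estimate$learning_rate - 0.1) < 1e-3
#' @export
fit_decay <- function(obs, free = "learning_rate", fixed,
                      bounds = NULL, n_starts = 16L, seed = 1L) {
  if (!inherits(obs, "decay_observation"))
    obs <- decay_observation(obs$exposure, obs$response)
  if (!all(free %in% fit_free_names) || length(free) < 1L)
    stop("free must be a non-empty subset of: ",
         paste(fit_free_names, collapse = ", "))
  check_params(fixed)
  if (nrow(obs) < length(free) + 2L)
    stop("need at least length(free) + 2 observation points")
  if (is.null(bounds)) bounds <- default_fit_bounds(free)
  lower <- bounds$lower[free]; upper <- bounds$upper[free]
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))

  ## degenerate flat observations: slope 0, nothing identifiable
  if (stats::sd(obs$response) < .Machine$double.eps^0.5 * max(1, abs(mean(obs$response)))) {
    est <- fixed
    return(structure(list(estimate = est, offset = mean(obs$response),
                          slope = 0, loss = sum((obs$response - mean(obs$response))^2),
                          converged = TRUE, non_identifiable = TRUE,
                          free = free, diagnostics = list()),
                     class = "fit_result"))
  }

  set.seed(as.integer(seed))
  ## geometric-ish start spread across the box, plus the fixed values when
  ## they fall inside
  starts <- lapply(seq_len(n_starts), function(i) {
    u <- stats::runif(length(free))
    pos_lo <- pmax(lower, 1e-6)
    exp(log(pos_lo) + u * (log(upper) - log(pos_lo)))
  })
  fx <- unlist(fixed[free])
  if (all(fx >= lower & fx <= upper)) starts <- c(list(fx), starts)

  best <- NULL; losses <- numeric(0)
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, decay_rss, method = "L-BFGS-B", lower = lower,
                   upper = upper, free = free, fixed = fixed, obs = obs,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    losses <- c(losses, o$value)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed")
  ## polish a single free parameter with a bracketed golden-section pass
  if (length(free) == 1L) {
    pol <- stats::optimize(function(v) decay_rss(v, free, fixed, obs),
                           lower = lower, upper = upper, tol = 1e-10)
    if (pol$objective <= best$value) {
      best$par <- pol$minimum; best$value <- pol$objective
      best$convergence <- 0L
    }
  }
  p <- fixed
  p[free] <- as.list(best$par)
  est <- habituation_params(p$initial_uncertainty,
                            p$initial_prediction_error, p$noise,
                            p$learning_rate)
  g <- information_gain(est, obs$exposure)
  aff <- stats::lm.fit(cbind(1, g), obs$response)
  ## L-BFGS-B reports 52 when the line search cannot improve further, which
  ## at a (near-)exact minimum is successful termination, not failure
  converged <- best$convergence %in% c(0L, 52L)
  structure(list(
    estimate = est, offset = unname(aff$coefficients[1]),
    slope = unname(aff$coefficients[2]),
    loss = best$value, converged = converged,
    non_identifiable = FALSE, free = free,
    diagnostics = list(n_starts = length(starts), start_losses = losses,
                       optim_code = best$convergence,
                       optim_message = best$message)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> free: %s; loss = %.4g; offset = %.3g, slope = %.3g%s\n",
    paste(x$free, collapse = ", "), x$loss, x$offset, x$slope,
    if (x$non_identifiable) " [non-identifiable]" else ""))
  print(x$estimate)
  invisible(x)
}

#' Compare fitted habituation across the four condition cells
#'
#' Tabulates the fitted parameters and the implied habituation half-life of
#' each cell's decay fit, and evaluates the uncertainty-ordering claims:
#' higher fitted initial uncertainty should imply a shorter half-life.
#'
#' @param fits Named list of at least two `fit_result`s (typically the four
#'   cells AX, AY, BX, BY).
#' @return Data frame with one row per cell (`cell`, the fitted parameters,
#'   `offset`, `slope`, `loss`, `converged`, `half_life`); the attribute
#'   `"half_life_ordered"` records whether half-life is non-increasing in
#'   fitted uncertainty across converged cells.
#' @export
compare_cells <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("fits must be a named list of at least two fit_result objects")
  if (!all(vapply(fits, inherits, logical(1), "fit_result")))
    stop("all elements of fits must be fit_result objects")
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be named by cell")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    hl <- if (!f$non_identifiable &&
              information_gain(f$estimate, 1) > 0) half_life(f$estimate)
          else NA_integer_
    data.frame(cell = nm,
               initial_uncertainty = f$estimate$initial_uncertainty,
               initial_prediction_error = f$estimate$initial_prediction_error,
               noise = f$estimate$noise,
               learning_rate = f$estimate$learning_rate,
               offset = f$offset, slope = f$slope, loss = f$loss,
               converged = f$converged, half_life = hl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$converged & !is.na(out$half_life)
  ord <- order(out$initial_uncertainty[ok])
  attr(out, "half_life_ordered") <-
    !is.unsorted(-out$half_life[ok][ord], strictly = FALSE)
  out
}
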
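#' Fit a double stretched-exponential desorption model
#'
#' Fits the survival curve to
#' S(t) = A exp(-(k1 t)^mu1) + (1 - A) exp(-(k2 t)^mu2),
#' the standard model for non-Markovian desorption from protein surfaces:
#' the two terms capture the short- and long-time decays, and exponents
#' mu < 1 measure the deviation from simple exponential kinetics. The
#' amplitudes are parameterized as A and 1 - A so S(0) = 1 exactly.
#'
#' Optimization is bounded Levenberg-Marquardt (via minpack.lm) from a
#' deterministic multi-start grid anchored on the curve's 1/e crossing
#' time; the best converged start by residual sum of squares wins. The two
#' terms are ordered so k1 >= k2 (fast component first).
#'
#' @param curve a [survival_curve()] with at least 10 lag points and
#'   S(0) = 1.
#' @param weights `"uniform"` or `"tail"` (weights proportional to
#'   1/sqrt(S), emphasizing the tail the slow rate is sensitive to).
#' @param t_max optional fit range: lags above `t_max` are dropped.
#' @return object of class `desorption_fit` with components `parameters`
#'   (named vector: amplitude, k1, mu1, k2, mu2), `std_errors`, `fit` (the
#'   underlying `nls` object), `curve`, `rss`.
#' @examples
#' sc <- make_survival_curve(0.6, 2, 0.9, 0.3, 0.5, seq(0, 10, 0.1))
#' fit <- fit_desorption(sc)
#' coef(fit)
#' @export
fit_desorption <- function(curve, weights = c("uniform", "tail"), t_max = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  weights <- match.arg(weights)
  t <- curve$lag_times
  S <- curve$S
  if (!is.null(t_max)) { keep <- t <= t_max; t <- t[keep]; S <- S[keep] }
  if (length(t) < 10L) stop("need at least 10 lag points to fit")
  if (min(S) > 0.99)
    stop("survival curve shows no decay (min S = ", format(min(S), digits = 3),
         "); nothing to fit")
  w <- if (weights == "tail") 1 / sqrt(pmax(S, 1e-3)) else rep(1, length(S))

  # characteristic time: interpolated 1/e crossing (fallback: a third of span)
  t63 <- if (any(S <= exp(-1))) stats::approx(S, t, xout = exp(-1), ties = "ordered")$y
         else NA_real_
  if (!is.finite(t63) || t63 <= 0) t63 <- max(t) / 3

  dat <- data.frame(t = t, S = S)
  lower <- c(A = 0, k1 = 1e-8, mu1 = 1e-3, k2 = 1e-8, mu2 = 1e-3)
  upper <- c(A = 1, k1 = Inf, mu1 = 1.5, k2 = Inf, mu2 = 1.5)
  starts <- expand.grid(A = c(0.3, 0.6, 0.9),
                        k1 = c(1, 5, 20) / t63,
                        mu1 = c(0.6, 1.0),
                        k2 = c(0.1, 0.5) / t63,
                        mu2 = c(0.35, 0.8))
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        S ~ A * exp(-(k1 * t)^mu1) + (1 - A) * exp(-(k2 * t)^mu2),
        data = dat, start = as.list(starts[i, ]),
        lower = lower, upper = upper, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("desorption fit failed to converge from any start (best residual Inf)")

  p <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 5))
  names(se) <- names(p)
  if (p[["k1"]] < p[["k2"]]) {  # order: fast term first
    p <- c(A = 1 - p[["A"]], k1 = p[["k2"]], mu1 = p[["mu2"]],
           k2 = p[["k1"]], mu2 = p[["mu1"]])
    se <- c(A = se[["A"]], k1 = se[["k2"]], mu1 = se[["mu2"]],
            k2 = se[["k1"]], mu2 = se[["mu1"]])
  }
  pars <- c(amplitude = unname(p[["A"]]), k1 = unname(p[["k1"]]),
            mu1 = unname(p[["mu1"]]), k2 = unname(p[["k2"]]),
            mu2 = unname(p[["mu2"]]))
  ses <- c(amplitude = unname(se[["A"]]), k1 = unname(se[["k1"]]),
           mu1 = unname(se[["mu1"]]), k2 = unname(se[["k2"]]),
           mu2 = unname(se[["mu2"]]))
  structure(list(parameters = pars, std_errors = ses, fit = best,
                 curve = curve, rss = best_rss, weights = weights),
            class = "desorption_fit")
}

#' @export
print.desorption_fit <- function(x, digits = 4, ...) {
  cat("Double stretched-exponential desorption fit\n")
  cat("  S(t) = A exp(-(k1 t)^mu1) + (1-A) exp(-(k2 t)^mu2)\n\n")
  tab <- rbind(estimate = x$parameters, std.error = x$std_errors)
  print(round(tab, digits))
  cat("\n  RSS:", format(x$rss, digits = digits),
      " (", length(x$curve$S), "lag points )\n")
  invisible(x)
}

#' @export
summary.desorption_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.desorption_fit <- function(object, ...) object$parameters

#' Evaluate a fitted desorption model at new lag times
#' @param object a `desorption_fit`.
#' @param newdata optional data frame with column `t`, or a numeric vector
#'   of lag times; defaults to the fitted curve's lags.
#' @param ... unused.
#' @export
predict.desorption_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$curve$lag_times
       else if (is.numeric(newdata)) newdata
       else newdata$t
  p <- object$parameters
  p[["amplitude"]] * exp(-(p[["k1"]] * t)^p[["mu1"]]) +
    (1 - p[["amplitude"]]) * exp(-(p[["k2"]] * t)^p[["mu2"]])
}

#' @export
residuals.desorption_fit <- function(object, ...) {
  object$curve$S - predict(object)
}

#' @export
fitted.desorption_fit <- function(object, ...) predict(object)

#' @export
plot.desorption_fit <- function(x, ...) {
  graphics::plot(x$curve$lag_times, x$curve$S, pch = 16, cex = 0.5,
                 xlab = "lag time (ps)", ylab = "S(t)", ...)
  tt <- seq(0, max(x$curve$lag_times), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  invisible(x)
}

#' Simulate survival curves from a fitted desorption model
#'
#' Draws `nsim` noisy replicates of the fitted curve with Gaussian noise at
#' the fit's residual standard deviation.
#' @param object a `desorption_fit`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of [survival_curve()] objects.
#' @export
simulate.desorption_fit <- function(object, nsim = 1, seed = 1L, ...) {
  sd_res <- sqrt(object$rss / max(1, length(object$curve$S) - 5))
  p <- object$parameters
  with_seed(seed, lapply(seq_len(nsim), function(i)
    make_survival_curve(p[["amplitude"]], p[["k1"]], p[["mu1"]],
                        p[["k2"]], p[["mu2"]], object$curve$lag_times,
                        noise_sd = sd_res, seed = stats::runif(1, 1, 2^30))))
}
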
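# Non-linear fit of the cone-growth power law y = a + b * t^c to a flow
# curve. The exponent c has the ideal-cone limit 1/3; in practice fitted
# values run roughly 0.34-0.50 on real recordings. The fit is bounded
# nonlinear least squares (Levenberg-Marquardt via minpack.lm) with an
# analytic Jacobian and a small multi-start ladder on the exponent.

.pl_model <- function(p, t) {
  tc <- ifelse(t > 0, t^p[3], 0)   # 0^c = 0 for c > 0; value at t = 0 is a
  unname(p[1] + p[2] * tc)
}

.pl_resid <- function(p, t, y) y - .pl_model(p, t)

.pl_jac <- function(p, t, y) {
  tc <- ifelse(t > 0, t^p[3], 0)
  dc <- ifelse(t > 0, p[2] * tc * log(pmax(t, .Machine$double.xmin)), 0)
  -cbind(1, tc, dc)
}

#' Fit the power-law flow model y = a + b * t^c
#'
#' Least-squares fit of the three-parameter growth law to a flow curve.
#' `a` is the intercept (pixels), `b` the growth coefficient
#' (pixels / s^c) and `c` the dimensionless scaling exponent, bounded to
#' (0.05, 1.5). The model value at `t = 0` is `a` (taking `0^c = 0`).
#'
#' The default start uses `a0` = first area, `c0 = 1/3` (the ideal-cone
#' exponent) and `b0` from the curve endpoints; if the optimizer does not
#' converge, restarts at `c0 = 0.25` and `c0 = 0.5` are tried and the
#' best iterate is returned with `converged = FALSE` if all fail.
#'
#' @param curve a [flow_curve()] with at least 10 points.
#' @param init optional numeric start `c(a, b, c)`.
#' @param t_max optional fit window: only points with `times <= t_max`
#'   (e.g. the measured flow time) enter the fit. Default uses the whole
#'   curve.
#' @param lower,upper parameter bounds, defaults `c(-Inf, -Inf, 0.05)`
#'   and `c(Inf, Inf, 1.5)`.
#' @return Object of class `"powerlaw_fit"` with components
#'   `coefficients` (named `a`, `b`, `c`), `a_plus_b` (the model value at
#'   t = 1 s, a Table-style summary quantity), `rss`, `r_squared`,
#'   `sigma`, `converged`, `fitted`, `residuals`, `vcov`, `curve`.
#' @seealso [area_under_flow_curve()], [detrend()], [detect_avalanches()]
#' @examples
#' fc <- flow_curve(-40 + 28 * ((0:199) / 25)^(1/3))
#' fit <- fit_power_law(fc)
#' coef(fit)
#' @export
fit_power_law <- function(curve, init = NULL, t_max = NULL,
                          lower = c(-Inf, -Inf, 0.05),
                          upper = c(Inf, Inf, 1.5)) {
  stopifnot(inherits(curve, "flow_curve"))
  t <- curve$times
  y <- curve$areas
  if (!is.null(t_max)) {
    keep <- t <= t_max
    t <- t[keep]
    y <- y[keep]
  }
  if (length(y) < 10) stop("need at least 10 points to fit", call. = FALSE)
  if (diff(range(y)) == 0) {
    stop("degenerate flat curve: areas are all equal", call. = FALSE)
  }
  t_pos <- t[t > 0]
  b0_end <- (y[length(y)] - y[1]) / max(t)^(1 / 3)
  if (!is.finite(b0_end) || b0_end == 0) b0_end <- 1
  starts <- if (!is.null(init)) {
    list(as.numeric(init))
  } else {
    lapply(c(1 / 3, 0.25, 0.5),
           function(c0) c(y[1], b0_end, c0))
  }
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = .pl_resid, jac = .pl_jac,
                         t = t, y = y, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && fit$deviance < best$fit$deviance)) {
      best <- list(fit = fit, ok = ok)
    }
    if (ok) break
  }
  if (is.null(best)) stop("power-law fit failed from all starts",
                          call. = FALSE)
  fit <- best$fit
  p <- fit$par
  names(p) <- c("a", "b", "c")
  fitted <- .pl_model(p, t)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  dfres <- n - 3
  sigma <- sqrt(rss / dfres)
  vc <- tryCatch({
    jtj <- crossprod(.pl_jac(p, t, y))
    sigma^2 * solve(jtj)
  }, error = function(e) matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(names(p), names(p))
  structure(list(coefficients = p,
                 a_plus_b = unname(p["a"] + p["b"]),
                 rss = rss,
                 r_squared = 1 - rss / tss,
                 sigma = sigma,
                 df.residual = dfres,
                 converged = best$ok,
                 fitted = fitted,
                 residuals = res,
                 vcov = vc,
                 times = t,
                 curve = curve,
                 niter = fit$niter),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, digits = 4, ...) {
  cat("Power-law flow model  y = a + b * t^c\n")
  print(round(x$coefficients, digits))
  cat(sprintf("a + b = %.*f   R-squared = %.4f   n = %d%s\n", digits,
              x$a_plus_b, x$r_squared, length(x$fitted),
              if (x$converged) "" else "   (NOT converged)"))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) object$coefficients

#' @export
vcov.powerlaw_fit <- function(object, ...) object$vcov

#' @export
residuals.powerlaw_fit <- function(object, ...) object$residuals

#' @export
fitted.powerlaw_fit <- function(object, ...) object$fitted

#' @export
predict.powerlaw_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  .pl_model(object$coefficients, times)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(abs(tval), object$df.residual, lower.tail = FALSE)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  out <- list(coefficients = tab, a_plus_b = object$a_plus_b,
              r_squared = object$r_squared, sigma = object$sigma,
              converged = object$converged, n = length(object$fitted))
  class(out) <- "summary.powerlaw_fit"
  out
}

#' @export
print.summary.powerlaw_fit <- function(x, ...) {
  cat("Power-law flow model  y = a + b * t^c\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\na + b = %.4f   sigma = %.3f px   R-squared = %.4f   n = %d\n",
              x$a_plus_b, x$sigma, x$r_squared, x$n))
  if (!x$converged) cat("warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
plot.powerlaw_fit <- function(x, ...) {
  plot(x$curve, ...)
  graphics::lines(x$times, x$fitted, col = 2, lwd = 2)
  graphics::legend("bottomright", legend = c("measured", "fit"),
                   col = c(1, 2), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate flow curves from a fitted power law
#'
#' Draws `nsim` synthetic curves from the fitted model plus Gaussian
#' noise at the residual standard deviation (parametric bootstrap of
#' the trend model).
#'
#' @param object a `"powerlaw_fit"`.
#' @param nsim number of curves.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of [flow_curve()] objects.
#' @export
simulate.powerlaw_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fps <- object$curve$fps
  lapply(seq_len(nsim), function(i) {
    flow_curve(object$fitted + stats::rnorm(length(object$fitted),
                                            sd = object$sigma),
               times = object$times, fps = fps)
  })
}

#' Area under the flow curve (AUFC)
#'
#' Trapezoidal integral of the bright area against the frame index.
#' The frame-index abscissa (rather than seconds) matches the magnitude
#' convention of the avalanche wavelength, which is likewise reported in
#' frame units (1 frame = 0.04 s at 25 fps).
#'
#' @param curve a [flow_curve()] with at least 2 points.
#' @return AUFC in pixel-frames; non-negative for non-negative curves.
#' @export
area_under_flow_curve <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  y <- curve$areas
  n <- length(y)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  sum((y[-1] + y[-n]) / 2)
}

#' Detrended flow curve
#'
#' Residuals of the flow curve around its fitted power-law trend,
#' `r_k = y_k - (a + b * t_k^c)`; the avalanche oscillation lives in this
#' series.
#'
#' @param curve a [flow_curve()].
#' @param fit a [fit_power_law()] result computed on the same curve
#'   (and the same fit window).
#' @return Numeric residual series in pixels.
#' @export
detrend <- function(curve, fit) {
  stopifnot(inherits(curve, "flow_curve"), inherits(fit, "powerlaw_fit"))
  pred <- predict(fit, times = curve$times)
  curve$areas - pred
}
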
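#' Collect bias measurements into a time series
#'
#' @param t day indices (strictly increasing).
#' @param y distance biases in mm (negative = appears farther).
#' @param label series label, e.g. \code{"Bunch1-left"}.
#' @return A \code{bias_series}: data frame with columns \code{t} and
#'   \code{y} and a \code{label} attribute.
#' @export
bias_series <- function(t, y, label = "") {
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) >= 2L && any(diff(t) <= 0))
    stop("day indices t must be strictly increasing")
  if (!all(is.finite(t)) || !all(is.finite(y)))
    stop("t and y must be finite")
  structure(data.frame(t = as.numeric(t), y = as.numeric(y)),
            label = label, class = c("bias_series", "data.frame"))
}

#' Fit a maturity curve to a bias time series
#'
#' Ordinary least-squares fit of distance bias (mm) against time (days).
#' The LiDAR measurements of single berries follow straight lines
#' \eqn{y = a t + b} with negative slopes (bias magnitude grows roughly
#' 0.2–0.7 mm/day); the ToF series is better described by a quadratic
#' \eqn{y = a t^2 + b t + c}.  Both are plain OLS with an intercept — no
#' weighting or robust loss.
#'
#' @param series a \code{\link{bias_series}} or a data frame with columns
#'   \code{t} (days) and \code{y} (mm).
#' @param kind \code{"linear"} (default; needs >= 2 distinct days) or
#'   \code{"quadratic"} (needs >= 3).
#' @return A \code{maturity_fit} object with components \code{kind},
#'   \code{coefficients} (named \code{a}, \code{b}[, \code{c}], highest
#'   power first), \code{r_squared}, \code{residuals}, \code{fitted},
#'   \code{sigma} (residual SD), \code{data}, and the underlying
#'   \code{lm} fit.  Supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{plot} and
#'   \code{simulate}.
#' @examples
#' s <- bias_series(1:12, -0.62 * (1:12) - 8.9)
#' fit <- fit_maturity(s)
#' coef(fit)          # a = -0.62, b = -8.9
#' predict(fit, t = 7)
#' @seealso \code{\link{invert_age}}, \code{\link{predict_bias}}
#' @export
fit_maturity <- function(series, kind = c("linear", "quadratic")) {
  kind <- match.arg(kind)
  if (!is.data.frame(series) || !all(c("t", "y") %in% names(series)))
    stop("series must be a data frame with columns 't' and 'y'")
  t <- as.numeric(series$t); y <- as.numeric(series$y)
  need <- if (kind == "linear") 2L else 3L
  if (length(t) < need)
    stop(sprintf("a %s fit needs at least %d points, got %d",
                 kind, need, length(t)))
  if (length(unique(t)) < need)
    stop("degenerate design: too few distinct day values")
  df <- data.frame(t = t, y = y)
  mod <- if (kind == "linear") lm(y ~ t, data = df)
         else lm(y ~ I(t^2) + t, data = df)
  cf <- coef(mod)
  coefficients <- if (kind == "linear")
    c(a = unname(cf["t"]), b = unname(cf["(Intercept)"]))
  else
    c(a = unname(cf["I(t^2)"]), b = unname(cf["t"]),
      c = unname(cf["(Intercept)"]))
  res <- unname(stats::residuals(mod))
  fitted_y <- unname(stats::fitted(mod))
  sst <- sum((y - mean(y))^2)
  ssr <- sum(res^2)
  r2 <- if (sst == 0) {
    if (ssr <= .Machine$double.eps) 1.0
    else stop("R^2 undefined: constant observed y with non-zero residuals")
  } else 1 - ssr / sst
  structure(list(kind = kind, coefficients = coefficients,
                 r_squared = r2, residuals = res, fitted = fitted_y,
                 sigma = if (length(t) > length(coefficients))
                   sqrt(ssr / (length(t) - length(coefficients))) else NA_real_,
                 data = df, label = attr(series, "label"),
                 lm = mod, call = match.call()),
            class = "maturity_fit")
}

.poly_eval <- function(fit, t) {
  cf <- fit$coefficients
  if (fit$kind == "linear") cf["a"] * t + cf["b"]
  else cf["a"] * t^2 + cf["b"] * t + cf["c"]
}

#' @export
print.maturity_fit <- function(x, digits = 4, ...) {
  cf <- signif(x$coefficients, digits)
  eqn <- if (x$kind == "linear")
    sprintf("y = %g*t + %g", cf["a"], cf["b"])
  else
    sprintf("y = %g*t^2 + %g*t + %g", cf["a"], cf["b"], cf["c"])
  lbl <- x$label
  cat(sprintf("Maturity fit (%s)%s\n", x$kind,
              if (!is.null(lbl) && nzchar(lbl)) paste0(" for ", lbl) else ""))
  cat(" ", eqn, "  (t in days, y in mm)\n")
  cat(sprintf("  R^2 = %.4f on %d days\n", x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
summary.maturity_fit <- function(object, ...) {
  s <- summary(object$lm)
  structure(list(fit = object, coef_table = s$coefficients,
                 sigma = object$sigma, r_squared = object$r_squared),
            class = "summary.maturity_fit")
}

#' @export
print.summary.maturity_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coef_table)
  if (is.finite(x$sigma))
    cat(sprintf("\nResidual SD: %.4f mm\n", x$sigma))
  invisible(x)
}

#' @export
coef.maturity_fit <- function(object, ...) object$coefficients

#' @export
residuals.maturity_fit <- function(object, ...) object$residuals

#' @export
fitted.maturity_fit <- function(object, ...) object$fitted

#' @export
predict.maturity_fit <- function(object, t = NULL, newdata = NULL, ...) {
  if (is.null(t)) {
    if (is.null(newdata)) return(object$fitted)
    t <- newdata$t
  }
  unname(.poly_eval(object, as.numeric(t)))
}

#' @export
plot.maturity_fit <- function(x, ...) {
  d <- x$data
  plot(d$t, d$y, xlab = "time (days)", ylab = "distance bias y (mm)",
       main = sprintf("Maturity fit (%s), R^2 = %.3f", x$kind, x$r_squared),
       pch = 19, ...)
  tt <- seq(min(d$t), max(d$t), length.out = 200L)
  lines(tt, .poly_eval(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.maturity_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  sig <- if (is.finite(object$sigma)) object$sigma else 0
  out <- as.data.frame(replicate(nsim, object$fitted + rnorm(n, 0, sig)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(t = object$data$t, out)
}

#' Evaluate a maturity fit at given days
#'
#' Polynomial evaluation of the fitted bias curve.
#'
#' @param fit a \code{\link{fit_maturity}} object.
#' @param t day values (vectorized).
#' @return Predicted biases in mm.
#' @export
predict_bias <- function(fit, t) {
  stopifnot(inherits(fit, "maturity_fit"))
  unname(.poly_eval(fit, as.numeric(t)))
}

#' Coefficient of determination for a maturity fit
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with \eqn{SS_{tot}} about the mean
#' of the observed biases.  With no new data this returns the stored
#' training-set value; given a series it is recomputed from the fit's
#' predictions on that series.
#'
#' @param fit a \code{\link{fit_maturity}} object.
#' @param series optional \code{\link{bias_series}} / data frame with
#'   columns \code{t}, \code{y}.
#' @return R-squared (dimensionless, <= 1).
#' @export
r_squared <- function(fit, series = NULL) {
  stopifnot(inherits(fit, "maturity_fit"))
  if (is.null(series)) return(fit$r_squared)
  y <- as.numeric(series$y)
  pred <- predict_bias(fit, series$t)
  sst <- sum((y - mean(y))^2)
  ssr <- sum((y - pred)^2)
  if (sst == 0) {
    if (ssr <= .Machine$double.eps) return(1.0)
    stop("R^2 undefined: constant observed y with non-zero residuals")
  }
  1 - ssr / sst
}

#' Invert a maturity fit: age from bias
#'
#' Given a measured distance bias, solve the fitted curve for the day.
#' Linear fits invert directly, \eqn{t = (y - b)/a}.  Quadratic fits are
#' non-monotone, so the root is taken on the ageing branch
#' \eqn{t \ge -b/(2a)} (at or beyond the vertex), which is the monotone
#' segment needed for a single-valued maturity estimate; a bias not
#' attainable on that branch is a domain error reporting the attainable
#' range.
#'
#' @param fit a \code{\link{fit_maturity}} object.
#' @param y bias in mm (vectorized).
#' @return Estimated day(s).
#' @examples
#' fit <- fit_maturity(bias_series(1:12, -0.62 * (1:12) - 8.9))
#' invert_age(fit, predict_bias(fit, 7))   # 7
#' @export
invert_age <- function(fit, y) {
  stopifnot(inherits(fit, "maturity_fit"))
  y <- as.numeric(y)
  cf <- fit$coefficients
  if (fit$kind == "linear") {
    if (abs(cf["a"]) < 1e-12 * max(1, abs(cf["b"])))
      stop("cannot invert a flat (zero-slope) linear fit")
    return(unname((y - cf["b"]) / cf["a"]))
  }
  a <- cf["a"]; b <- cf["b"]; cc <- cf["c"]
  if (a == 0) stop("degenerate quadratic (a = 0); refit as linear")
  vertex_t <- -b / (2 * a)
  vertex_y <- .poly_eval(fit, vertex_t)
  disc <- b^2 - 4 * a * (cc - y)
  if (any(disc < 0)) {
    bad <- y[disc < 0][1L]
    stop(sprintf(
      "bias %.4g mm is not attainable: the fitted quadratic %s %.4g mm at its vertex (t = %.3g)",
      bad, if (a > 0) "bottoms out at" else "peaks at", vertex_y, vertex_t))
  }
  # branch t >= vertex: the root on the ageing side
  unname(vertex_t + sqrt(disc) / (2 * abs(a)))
}

#' Percentage weight change from Day 1
#'
#' \eqn{W_p = 100 (W - W_o) / W_o}: the percentage change of a berry's
#' weight relative to its Day-1 weight.  Negative values are loss; the
#' magnitude tracks post-harvest water-content loss.
#'
#' @param W weight in grams on the day of interest (vectorized).
#' @param Wo weight in grams on Day 1 (> 0).
#' @return Percent change (negative = loss).
#' @export
weight_loss_percent <- function(W, Wo) {
  if (!is.numeric(Wo) || length(Wo) != 1L || !is.finite(Wo) || Wo <= 0)
    stop("Wo must be a single positive weight in grams")
  100 * (W - Wo) / Wo
}

#' Daily weight-loss rate
#'
#' OLS slope of the percentage weight change (relative to the first
#' entry) against day, returned as a magnitude in percent per day; the
#' signed slope (negative = loss) is attached as attribute
#' \code{"slope"}.
#'
#' @param series a \code{\link{make_weight_series}} result, or any data
#'   frame with columns \code{t} (days) and \code{W} (grams).
#' @return Weight-loss rate magnitude in \%/day.
#' @export
weight_loss_rate <- function(series) {
  if (!is.data.frame(series) || !all(c("t", "W") %in% names(series)))
    stop("series must be a data frame with columns 't' and 'W'")
  if (nrow(series) < 2L) stop("need at least 2 weight measurements")
  t <- as.numeric(series$t)
  if (length(unique(t)) < 2L) stop("degenerate design: all days equal")
  W <- as.numeric(series$W)
  if (any(W <= 0)) stop("weights must be positive")
  Wp <- weight_loss_percent(W, W[1L])
  slope <- unname(coef(lm(Wp ~ t))["t"])
  structure(abs(slope), slope = slope)
}
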
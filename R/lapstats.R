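# Lap-wise trend statistics: linear regression, exponential decay with
# offset, and slope comparison between groups.

new_trend_fit <- function(model, parameters, r_squared, p_slope, n, data,
                          extra = list()) {
  structure(c(list(model = model, parameters = parameters,
                   r_squared = r_squared, p_slope = p_slope, n = n,
                   data = data), extra),
            class = "trend_fit")
}

#' Linear lap trend (ordinary least squares)
#'
#' @param x,y numeric vectors (pairs with missing values are dropped).
#' @return object of class `trend_fit` with `parameters` (`intercept`,
#'   `slope`), `r_squared`, the two-sided p-value for slope = 0 (`p_slope`)
#'   and `n`.
#' @export
linear_trend <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite (x, y) pairs")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  new_trend_fit(
    "linear",
    c(intercept = unname(stats::coef(fit)[1L]),
      slope = unname(stats::coef(fit)[2L])),
    sm$r.squared,
    sm$coefficients["x", "Pr(>|t|)"],
    n, list(x = x, y = y),
    extra = list(rss = sum(stats::residuals(fit)^2))
  )
}

#' Exponential decay with offset
#'
#' Fits `Y(X) = (A - C) * exp(-k * X) + C` by nonlinear least squares
#' (Levenberg-Marquardt), initialized at `A` = first y, `C` = last y and `k`
#' from a log-linear fit of `y - C`, with `k` bounded in `bounds`. Also
#' reports the extra-sum-of-squares F statistic comparing the linear fit
#' (2 parameters) against the exponential (3 parameters): large F with small
#' `p_vs_linear` means the exponential is the better description.
#'
#' @param x,y numeric vectors (>= 4 finite pairs).
#' @param bounds bounds on the decay rate `k` (default `c(0, 10)`).
#' @return `trend_fit` with `parameters` (`A`, `C`, `k`), `r_squared`,
#'   `p_slope` (slope test from the companion linear fit), `f_vs_linear`,
#'   `p_vs_linear`, and `converged` (`FALSE` when the optimizer failed or the
#'   decay is unidentifiable, in which case the parameters fall back to the
#'   best constant/linear description).
#' @export
exp_decay_fit <- function(x, y, bounds = c(0, 10)) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 finite (x, y) pairs")
  lin <- linear_trend(x, y)
  rss_lin <- lin$rss
  rss_const <- sum((y - mean(y))^2)
  A0 <- y[which.min(x)]
  C0 <- y[which.max(x)]
  resid0 <- y - C0
  k0 <- 0.1
  pos <- resid0 > 0
  if (sum(pos) >= 2L && stats::sd(x[pos]) > 0) {
    sl <- stats::coef(stats::lm(log(resid0[pos]) ~ x[pos]))[2L]
    if (is.finite(sl) && sl < 0) k0 <- min(max(-sl, bounds[1L] + 1e-3), bounds[2L])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (A - C) * exp(-k * x) + C,
      start = list(A = A0, C = C0, k = k0),
      lower = c(A = -Inf, C = -Inf, k = bounds[1L]),
      upper = c(A = Inf, C = Inf, k = bounds[2L]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  converged <- !is.null(fit)
  if (converged) {
    pars <- stats::coef(fit)
    rss_exp <- sum(stats::residuals(fit)^2)
    if (rss_exp > rss_const + 1e-12) {
      # worse than a constant: decay unidentifiable, collapse to the constant
      pars <- c(A = mean(y), C = mean(y), k = 0)
      rss_exp <- rss_const
      converged <- FALSE
    }
  } else {
    pars <- c(A = unname(lin$parameters["intercept"]),
              C = unname(lin$parameters["intercept"]), k = 0)
    rss_exp <- rss_lin
  }
  if (abs(pars[["A"]] - pars[["C"]]) < 1e-8 * max(1, abs(pars[["A"]]))) {
    converged <- FALSE  # k unidentifiable when there is nothing to decay
  }
  df_exp <- n - 3L
  f <- if (df_exp > 0L && rss_exp > 0) {
    ((rss_lin - rss_exp) / 1) / (rss_exp / df_exp)
  } else NA_real_
  p_f <- if (is.finite(f) && f > 0) {
    stats::pf(f, 1, df_exp, lower.tail = FALSE)
  } else 1
  r2 <- if (rss_const > 0) 1 - rss_exp / rss_const else NA_real_
  new_trend_fit(
    "exp_decay", c(A = unname(pars[["A"]]), C = unname(pars[["C"]]),
                   k = unname(pars[["k"]])),
    r2, lin$p_slope, n, list(x = x, y = y),
    extra = list(rss = rss_exp, f_vs_linear = f, p_vs_linear = p_f,
                 converged = converged)
  )
}

#' Compare linear regression parameters of two groups
#'
#' Extra-sum-of-squares (ANCOVA-style) test of a common slope between two
#' linear fits; when the slopes are compatible, a second test asks whether a
#' common intercept also suffices.
#'
#' @param fitA,fitB `trend_fit` objects of model `"linear"` carrying their
#'   raw data.
#' @return list with `slope = c(F, p)` and `intercept = c(F, p)`.
#' @export
compare_slopes <- function(fitA, fitB) {
  if (fitA$model != "linear" || fitB$model != "linear") {
    stop("both fits must be linear")
  }
  x <- c(fitA$data$x, fitB$data$x)
  y <- c(fitA$data$y, fitB$data$y)
  g <- factor(rep(c("A", "B"), c(fitA$n, fitB$n)))
  if (stats::sd(fitA$data$x) == 0 || stats::sd(fitB$data$x) == 0) {
    stop("degenerate design: a group has zero x-variance")
  }
  m_add <- stats::lm(y ~ x + g)
  m_int <- stats::lm(y ~ x * g)
  a_slope <- stats::anova(m_add, m_int)
  m_common <- stats::lm(y ~ x)
  a_int <- stats::anova(m_common, m_add)
  list(slope = c(F = a_slope$F[2L], p = a_slope$`Pr(>F)`[2L]),
       intercept = c(F = a_int$F[2L], p = a_int$`Pr(>F)`[2L]))
}

#' @export
print.trend_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf("<trend_fit linear> y = %.4g + %.4g x; R2 = %.3f, p(slope) = %.3g, n = %d\n",
                x$parameters[["intercept"]], x$parameters[["slope"]],
                x$r_squared, x$p_slope, x$n))
  } else {
    cat(sprintf("<trend_fit exp-decay> y = (%.4g - %.4g) exp(-%.4g x) + %.4g; R2 = %.3f, n = %d\n",
                x$parameters[["A"]], x$parameters[["C"]], x$parameters[["k"]],
                x$parameters[["C"]], x$r_squared, x$n))
    cat(sprintf("  vs linear: F = %.3g, p = %.3g%s\n", x$f_vs_linear,
                x$p_vs_linear,
                if (isFALSE(x$converged)) " [not converged]" else ""))
  }
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) object$parameters

#' @export
predict.trend_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  p <- object$parameters
  if (object$model == "linear") {
    p[["intercept"]] + p[["slope"]] * x
  } else {
    (p[["A"]] - p[["C"]]) * exp(-p[["k"]] * x) + p[["C"]]
  }
}
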
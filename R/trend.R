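#' Design matrix of the harmonic trend model with linearly varying amplitude
#'
#' Columns, in order: intercept, t, sin(2*pi*t/12), cos(2*pi*t/12),
#' t*sin(2*pi*t/12), t*cos(2*pi*t/12). The t * harmonic interactions are
#' the standard linearization of a seasonal amplitude that changes
#' linearly in time; the seasonal period is fixed at 12 months. The time
#' index is used uncentred, so the intercept refers to the first month of
#' the series.
#'
#' @param t numeric month index (0-based by convention), no duplicates.
#' @return numeric matrix with columns `intercept`, `trend`, `sin`, `cos`,
#'   `t_sin`, `t_cos`.
#' @export
build_design <- function(t) {
  if (anyDuplicated(t)) stop("duplicate values in 't'")
  if (length(t) < 7)
    stop("need at least 7 observations to fit six coefficients")
  if (length(t) < 24)
    warning("T < 24: harmonic coefficients weakly identified")
  w <- 2 * pi * t / 12
  X <- cbind(intercept = 1, trend = t, sin = sin(w), cos = cos(w),
             t_sin = t * sin(w), t_cos = t * cos(w))
  X
}

#' Fit the harmonic trend model to a monthly series
#'
#' Ordinary least squares (QR decomposition) of the series on the design
#' of [build_design()]. When the series carries a denominator, the
#' response is first standardized to a percentage, 100 * y / denominator.
#' The secular trend is tested by a two-sided t-test on the linear
#' coefficient with n - 6 degrees of freedom; a joint Wald F-test on the
#' two amplitude-interaction coefficients is reported alongside, since a
#' changing amplitude is a two-parameter statement.
#'
#' @param series a `monthly_series`, or any data.frame with columns `t`,
#'   `y` and optionally `denominator`.
#' @return object of class `harmonic_fit`: list with `beta` (named
#'   six-vector), `se`, `trend_t_stat`, `trend_p`, `amp_change_F`,
#'   `amp_change_p`, `r_squared`, `residuals`, `fitted`, `n_obs`,
#'   `sigma2_hat`, `cov_beta`, `t`, `label`. For a zero-variance response
#'   `r_squared` is defined as 0.
#' @export
fit_harmonic_trend <- function(series) {
  if (!all(c("t", "y") %in% names(series)))
    stop("'series' needs columns 't' and 'y'")
  t <- series$t
  y <- series$y
  if (!is.null(series$denominator)) y <- 100 * y / series$denominator
  X <- build_design(t)
  n <- length(y)
  p <- ncol(X)

  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrx))
  cov_beta <- sigma2 * XtXinv
  se <- sqrt(diag(cov_beta))
  names(se) <- names(beta)

  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= .Machine$double.eps * n * max(1, mean(y)^2)) 0 else
    1 - rss / tss
  r2 <- min(max(r2, 0), 1)

  t_stat <- beta[["trend"]] / se[["trend"]]
  trend_p <- 2 * stats::pt(-abs(t_stat), df = n - p)

  # joint Wald F on (t_sin, t_cos): does the amplitude change over time?
  idx <- c(5L, 6L)
  b2 <- beta[idx]
  W <- drop(crossprod(b2, solve(cov_beta[idx, idx], b2))) / 2
  amp_p <- stats::pf(W, 2, n - p, lower.tail = FALSE)

  structure(list(beta = beta, se = se, trend_t_stat = t_stat,
                 trend_p = trend_p, amp_change_F = W, amp_change_p = amp_p,
                 r_squared = r2, residuals = res, fitted = fitted,
                 n_obs = n, sigma2_hat = sigma2, cov_beta = cov_beta,
                 t = t, label = attr(series, "label") %||% "series"),
            class = "harmonic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("Harmonic trend fit:", x$label, "(n =", x$n_obs, ")\n")
  tab <- data.frame(estimate = x$beta, se = x$se)
  print(round(tab, 5))
  cat(sprintf("trend t = %.3f, p = %.3g; amplitude-change F = %.3f, p = %.3g\n",
              x$trend_t_stat, x$trend_p, x$amp_change_F, x$amp_change_p))
  cat(sprintf("R-squared = %.3f\n", x$r_squared))
  invisible(x)
}

#' Instantaneous seasonal amplitude of a harmonic fit
#'
#' sqrt((beta_sin + beta_t_sin * t)^2 + (beta_cos + beta_t_cos * t)^2),
#' the modulus of the seasonal component at month t.
#'
#' @param fit a `harmonic_fit`.
#' @param t month index (vectorized).
#' @return non-negative amplitude value(s).
#' @export
amplitude_at <- function(fit, t) {
  b <- fit$beta
  sqrt((b[["sin"]] + b[["t_sin"]] * t)^2 + (b[["cos"]] + b[["t_cos"]] * t)^2)
}

#' Classify the secular trend of a fitted series
#'
#' "decreasing" or "increasing" according to the sign of the linear trend
#' coefficient when its two-sided p-value is below `alpha`, otherwise
#' "none".
#'
#' @param fit a `harmonic_fit`.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return one of "decreasing", "increasing", "none".
#' @export
classify_trend <- function(fit, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (fit$trend_p >= alpha) return("none")
  if (fit$beta[["trend"]] < 0) "decreasing" else "increasing"
}

#' Concordance regression between two per-area count sources
#'
#' Simple linear regression with intercept of per-area complaint counts
#' (`y`) on per-area landlord/owner report counts (`x`), as a check of
#' agreement between resident-initiated and owner-mandated reporting. A
#' slope near 1 indicates proportional agreement.
#'
#' @param x,y paired per-area counts, length at least 3.
#' @param conf_level confidence level for the slope interval (default
#'   0.95).
#' @return list with `slope`, `slope_ci` (length-2), `intercept`,
#'   `r_squared`, `p` (two-sided, slope), `n`.
#' @export
concordance_regression <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3) stop("need at least 3 paired areas")
  if (stats::var(x) == 0) stop("zero-variance regressor 'x'")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = conf_level)
  list(slope = unname(stats::coef(fit)["x"]),
       slope_ci = unname(ci[1, ]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p = sm$coefficients["x", "Pr(>|t|)"],
       n = length(x))
}

#' Fit the harmonic trend model to many series and tabulate
#'
#' @param series_list named list of `monthly_series`.
#' @param alpha significance level for trend classification.
#' @return data.frame, one row per series: the six coefficients, their
#'   standard errors, trend test, R-squared, amplitude at the first and
#'   last month, and the trend classification.
#' @export
trend_report <- function(series_list, alpha = 0.05) {
  rows <- lapply(names(series_list), function(nm) {
    f <- fit_harmonic_trend(series_list[[nm]])
    t0 <- min(f$t); t1 <- max(f$t)
    data.frame(series = nm,
               as.list(stats::setNames(f$beta, paste0("beta_", names(f$beta)))),
               as.list(stats::setNames(f$se, paste0("se_", names(f$se)))),
               trend_p = f$trend_p, amp_change_p = f$amp_change_p,
               r_squared = f$r_squared,
               amplitude_first = amplitude_at(f, t0),
               amplitude_last = amplitude_at(f, t1),
               trend = classify_trend(f, alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
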
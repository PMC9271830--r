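#' Least-squares power-law fit in log-log coordinates
#'
#' Fits \code{log(y) = intercept + exponent * log(x)} by ordinary least
#' squares, optionally restricted to a scale window. Every scaling exponent
#' in the package (fractal dimension slope, local roughness exponent, global
#' roughness exponent, visibility-degree exponent, multifractal h(q)/tau(q)
#' slopes) is reported as one of these fits.
#'
#' @param x positive scales (abscissa).
#' @param y positive ordinates; non-positive pairs are dropped.
#' @param fit_range optional \code{c(min, max)} window on \code{x}
#'   (inclusive); \code{NULL} uses all finite positive pairs.
#' @return an object of class \code{"powerlaw_fit"}: a list with
#'   \code{exponent}, \code{intercept} (natural-log units), \code{fit_range},
#'   \code{r_squared}, \code{stderr} (standard error of the exponent) and
#'   \code{n} (points used).
#' @export
fit_powerlaw <- function(x, y, fit_range = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2, fit_range[1] < fit_range[2])
    keep <- keep & x >= fit_range[1] & x <= fit_range[2]
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L)
    stop("fit_powerlaw: fewer than 2 usable points in the fit range")
  lx <- log(x); ly <- log(y)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  beta <- fit$coefficients
  res <- fit$residuals
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  se <- if (length(x) > 2L) {
    s2 <- sum(res^2) / (length(x) - 2L)
    sqrt(s2 / sum((lx - mean(lx))^2))
  } else NA_real_
  structure(list(
    exponent = unname(beta[2L]), intercept = unname(beta[1L]),
    fit_range = range(x), r_squared = r2, stderr = se, n = length(x)
  ), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: exponent = %.4f (se %.4f), r^2 = %.4f, %d scales in [%.3g, %.3g]\n",
              x$exponent, x$stderr, x$r_squared, x$n,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Best contiguous log-log scaling window
#'
#' Scans all contiguous windows of at least \code{min_points} scales and
#' returns the one with maximal r-squared; used to locate the linear region
#' of a box-count or fluctuation curve automatically.
#'
#' @param x,y as in [fit_powerlaw()].
#' @param min_points minimum scales per window (default 5).
#' @return a \code{"powerlaw_fit"} for the winning window.
#' @export
best_scaling_window <- function(x, y, min_points = 5L) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  min_points <- min(min_points, n)
  if (n < 2L) stop("best_scaling_window: need at least 2 points")
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      f <- fit_powerlaw(x[i:j], y[i:j])
      if (is.null(best) || f$r_squared > best$r_squared) best <- f
    }
  }
  best
}

#' Detect a scaling crossover by a two-segment piecewise-linear fit
#'
#' Fits every possible breakpoint of a two-segment linear model in log-log
#' coordinates and returns the breakpoint minimizing the total residual sum
#' of squares. Used to split the small-scale power-law regime of an
#' interface-width curve from its large-scale saturation plateau.
#'
#' @param x scales, @param y values (positive).
#' @param min_seg minimum points per segment (default 3).
#' @return list with \code{crossover} (the scale at the breakpoint; last
#'   point of the first segment), \code{i_break} (its index among usable
#'   points), \code{slope1}, \code{slope2}, and \code{x}, \code{y} (the
#'   usable, sorted points).
#' @export
detect_crossover <- function(x, y, min_seg = 3L) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  if (n < 2L * min_seg)
    return(list(crossover = x[n], i_break = n, slope1 = NA_real_,
                slope2 = NA_real_, x = x, y = y))
  lx <- log(x); ly <- log(y)
  rss_lin <- function(ii) {
    f <- stats::lm.fit(cbind(1, lx[ii]), ly[ii])
    sum(f$residuals^2)
  }
  best_i <- NA_integer_; best_rss <- Inf
  for (i in seq(min_seg, n - min_seg)) {
    rss <- rss_lin(1:i) + rss_lin((i + 1L):n)
    if (rss < best_rss) { best_rss <- rss; best_i <- i }
  }
  s1 <- fit_powerlaw(x[1:best_i], y[1:best_i])$exponent
  s2 <- fit_powerlaw(x[(best_i + 1L):n], y[(best_i + 1L):n])$exponent
  list(crossover = x[best_i], i_break = best_i,
       slope1 = s1, slope2 = s2, x = x, y = y)
}
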
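#' Natural visibility graph of an ordered series
#'
#' Nodes are the series samples (abscissa = angle, ordinate = value); two
#' samples are linked iff the straight segment between them passes strictly
#' above every intermediate sample. The series is treated as non-periodic
#' (no wrap-around visibility); consecutive samples are always mutually
#' visible. Implemented as the O(n^2) forward sweep that keeps the maximal
#' blocking slope.
#'
#' @param series an [ordered_series()] (or plain numeric vector).
#' @return a \code{visibility_graph}: list with \code{n}, \code{edges}
#'   (2-column index matrix, i < j), \code{degrees}.
#' @export
visibility_graph <- function(series) {
  if (is.numeric(series)) series <- ordered_series(series)
  t <- series$angles; y <- series$values
  n <- length(y)
  if (n < 3L) stop("visibility_graph: need at least 3 points")
  if (anyDuplicated(t)) stop("visibility_graph: duplicate angles")
  deg <- integer(n)
  ei <- integer(0); ej <- integer(0)
  for (a in seq_len(n - 1L)) {
    smax <- -Inf
    for (b in (a + 1L):n) {
      s <- (y[b] - y[a]) / (t[b] - t[a])
      if (b == a + 1L || s > smax) {
        ei <- c(ei, a); ej <- c(ej, b)
        deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      }
      if (s > smax) smax <- s
    }
  }
  structure(list(n = n, edges = cbind(ei, ej, deparse.level = 0),
                 degrees = deg), class = "visibility_graph")
}

#' @export
print.visibility_graph <- function(x, ...) {
  cat(sprintf("Visibility graph: %d nodes, %d edges, degree range %d-%d\n",
              x$n, nrow(x$edges), min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Degree-distribution exponent of a visibility graph
#'
#' Fits \code{P(k) ~ k^gamma} by least squares on the log-log normalized
#' degree histogram, restricted to \code{k < k_max}: beyond that the
#' distribution decays abruptly because the finite series length caps the
#' attainable connectivity.
#'
#' @param graph a [visibility_graph()] (or a plain degree vector).
#' @param k_max upper connectivity cutoff (default 20).
#' @param k_min lower cutoff (default 4): P(k) rises up to the distribution
#'   mode (~3-4 for natural visibility graphs) before the power-law decay
#'   sets in, and the rising head would flatten the fitted slope.
#' @return a \code{"powerlaw_fit"}; \code{exponent} is gamma (negative),
#'   with the P(k) table attached as attribute \code{"table"}.
#' @export
degree_exponent <- function(graph, k_max = 20L, k_min = 4L) {
  deg <- if (inherits(graph, "visibility_graph")) graph$degrees else graph
  tab <- table(deg)
  k <- as.numeric(names(tab))
  P <- as.numeric(tab) / sum(tab)
  sel <- k >= k_min & k < k_max
  if (sum(sel) < 4L)
    stop("degree_exponent: fewer than 4 occupied degree bins below k_max")
  fit <- fit_powerlaw(k[sel], P[sel])
  attr(fit, "table") <- data.frame(k = k, P = P)
  fit
}

#' Windowed standard deviation of the connectivity series
#'
#' For each angular span phi, slides a contiguous window of that span along
#' the series and averages the within-window standard deviation of the
#' vertex degrees; the span 2*pi window returns the global degree standard
#' deviation (the graph's overall heterogeneity). The small-span power law
#' of this curve defines the local variance exponent.
#'
#' @param graph a [visibility_graph()].
#' @param series the [ordered_series()] the graph was built from.
#' @param windows angular spans in (0, 2*pi]; default 12 log-spaced spans
#'   from 4 samples' worth of angle up to the full circle.
#' @return data.frame with columns \code{phi} (span), \code{Wk}; windows
#'   holding < 2 nodes are skipped.
#' @export
local_degree_std <- function(graph, series, windows = NULL) {
  stopifnot(inherits(graph, "visibility_graph"))
  deg <- graph$degrees
  t <- series$angles
  n <- length(deg)
  span_total <- max(t) - min(t)
  step <- span_total / (n - 1)
  if (is.null(windows))
    windows <- exp(seq(log(4 * step), log(2 * pi), length.out = 12))
  out <- vapply(windows, function(ph) {
    if (ph >= 2 * pi - 1e-9)
      return(stats::sd(deg) * sqrt((n - 1) / n))  # population SD of all degrees
    w <- max(2L, round(ph / step))
    if (w > n) return(NA_real_)
    m <- n - w + 1L
    cs <- cumsum(c(0, deg)); cs2 <- cumsum(c(0, deg^2))
    s1 <- cs[(w + 1):(w + m)] - cs[1:m]
    s2 <- cs2[(w + 1):(w + m)] - cs2[1:m]
    v <- pmax(s2 / w - (s1 / w)^2, 0)
    mean(sqrt(v))
  }, numeric(1))
  data.frame(phi = windows, Wk = out)[!is.na(out), ]
}

#' Local variance exponent of the connectivity fluctuations
#'
#' The power-law exponent of W_k(phi) at small spans, using the same
#' two-segment crossover detector as the interface-width analysis. A
#' regular (constant-degree) graph has W_k identically 0 and returns NaN,
#' flagged.
#'
#' @param Wk_table a data.frame from [local_degree_std()].
#' @param fit_window optional \code{c(min, max)} span window.
#' @return a \code{"powerlaw_fit"}, or a structure with \code{exponent =
#'   NaN} and \code{degenerate = TRUE} if all W_k vanish.
#' @export
variance_exponent <- function(Wk_table, fit_window = NULL) {
  ok <- is.finite(Wk_table$Wk) & Wk_table$Wk > 0
  if (sum(ok) == 0L)
    return(structure(list(exponent = NaN, intercept = NA_real_,
                          fit_range = c(NA_real_, NA_real_),
                          r_squared = NA_real_, stderr = NA_real_, n = 0L,
                          degenerate = TRUE), class = "powerlaw_fit"))
  if (sum(ok) < 4L) stop("variance_exponent: fewer than 4 positive W_k values")
  tb <- Wk_table[ok, ]
  if (!is.null(fit_window)) return(fit_powerlaw(tb$phi, tb$Wk, fit_window))
  cr <- detect_crossover(tb$phi, tb$Wk)
  i <- max(cr$i_break, 4L)
  fit_powerlaw(cr$x[1:i], cr$y[1:i])
}
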
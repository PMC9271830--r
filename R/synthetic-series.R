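#' Fractional Brownian motion series (Davies-Harte synthesis)
#'
#' Generates a fractional Brownian motion sample path of length \code{n} with
#' Hurst exponent \code{hurst} by circulant embedding of the fractional
#' Gaussian noise autocovariance (Davies-Harte method), which is exact up to
#' floating point. The returned object is an angularly ordered series on a
#' uniform abscissa, the substrate the visibility-graph and 1D multifractal
#' estimators consume.
#'
#' @param n series length (>= 64).
#' @param hurst Hurst exponent in (0, 1). The increments (fractional Gaussian
#'   noise) have unit variance.
#' @param seed integer seed; all randomness is local to the call.
#' @return an \code{ordered_series}: list with \code{angles} (uniform in
#'   \code{[0, 2*pi)}), \code{values} (the fBm path) and \code{slice_index = NA}.
#' @export
gen_fbm_series <- function(n, hurst, seed) {
  if (!is.numeric(n) || n < 64) stop("gen_fbm_series: n must be >= 64")
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1)
    stop("gen_fbm_series: hurst must lie in (0, 1)")
  fgn <- gen_fgn(n, hurst, seed)
  ordered_series(values = cumsum(fgn))
}

# Fractional Gaussian noise by Davies-Harte circulant embedding (exact
# covariance; the embedding of the fGn autocovariance is nonnegative
# definite for all H in (0,1)).
gen_fgn <- function(n, hurst, seed) {
  h2 <- 2 * hurst
  acov <- function(k) 0.5 * ((abs(k) + 1)^h2 - 2 * abs(k)^h2 + abs(abs(k) - 1)^h2)
  m <- 2L * n
  row <- c(acov(0:n), acov((n - 1L):1))
  lam <- Re(stats::fft(row))
  lam[lam < 0 & lam > -1e-8] <- 0  # roundoff clip
  if (any(lam < 0)) stop("gen_fgn: circulant embedding not nonnegative definite")
  rng <- local_rng(seed)
  z <- rng$rnorm(2L * m)
  # Hermitian-symmetric Gaussian spectral weights
  v <- complex(length.out = m)
  v[1L] <- z[1L] * sqrt(2)
  v[n + 1L] <- z[2L] * sqrt(2)
  idx <- 2:n
  v[idx] <- complex(real = z[2 * idx - 1L], imaginary = z[2 * idx])
  v[m + 2L - idx] <- Conj(v[idx])
  x <- stats::fft(sqrt(lam) * v) / sqrt(2 * m)
  Re(x[1:n])
}

# Deterministic local RNG: never touches the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = with_state(stats::rnorm),
       runif = with_state(stats::runif),
       sample = with_state(base::sample))
}

#' Construct an angularly ordered series
#'
#' @param values numeric radii (or degrees) at the ordered angles.
#' @param angles strictly increasing angles in \code{[0, 2*pi)}; defaults to a
#'   uniform grid.
#' @param slice_index the axial slice the series came from, if any.
#' @return an object of class \code{ordered_series}.
#' @export
ordered_series <- function(values, angles = NULL, slice_index = NA_integer_) {
  n <- length(values)
  if (is.null(angles)) angles <- 2 * pi * (seq_len(n) - 1L) / n
  stopifnot(length(angles) == n, !is.unsorted(angles, strictly = TRUE))
  structure(list(angles = angles, values = as.numeric(values),
                 slice_index = slice_index),
            class = "ordered_series")
}

#' @export
print.ordered_series <- function(x, ...) {
  cat(sprintf("Ordered series: %d points, angle span [%.3f, %.3f], value range [%.3g, %.3g]\n",
              length(x$values), min(x$angles), max(x$angles),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Deterministic binomial multiplicative cascade
#'
#' Builds the binomial measure on \code{2^levels} dyadic cells: starting from
#' unit mass, each cell is split in two with mass fractions \code{p} and
#' \code{1 - p}. Its multifractal spectrum is known in closed form,
#' \code{tau(q) = -log2(p^q + (1-p)^q)}, which makes it the oracle fixture
#' for the partition-function estimator.
#'
#' @param levels number of dyadic refinement levels (2..20).
#' @param p left-cell mass fraction in (0, 1).
#' @param seed seed used only when \code{shuffle = TRUE}.
#' @param shuffle if \code{TRUE}, the (p, 1-p) order is randomized per split.
#' @return an \code{ordered_series} whose \code{values} are the cell masses
#'   (summing to 1).
#' @export
gen_binomial_cascade <- function(levels, p, seed = 1L, shuffle = FALSE) {
  if (!is.numeric(levels) || levels < 2 || levels > 20)
    stop("gen_binomial_cascade: levels must be in 2..20")
  if (!is.numeric(p) || p <= 0 || p >= 1)
    stop("gen_binomial_cascade: p must lie in (0, 1)")
  m <- 1
  rng <- if (shuffle) local_rng(seed) else NULL
  for (l in seq_len(levels)) {
    if (shuffle) {
      flip <- rng$runif(length(m)) < 0.5
      left <- ifelse(flip, 1 - p, p)
    } else left <- rep(p, length(m))
    m <- as.vector(rbind(m * left, m * (1 - left)))
  }
  ordered_series(values = m)
}

#' Closed-form multifractal exponents of the binomial cascade
#'
#' @param q moment orders.
#' @param p cascade mass fraction.
#' @return list with \code{tau}, \code{D} (generalized dimensions; the q = 1
#'   information dimension by the entropy limit) and \code{h}.
#' @export
cascade_theory <- function(q, p) {
  tau <- -log2(p^q + (1 - p)^q)
  D <- ifelse(abs(q - 1) < 1e-12,
              -(p * log2(p) + (1 - p) * log2(1 - p)),
              tau / (q - 1))
  h <- ifelse(abs(q) < 1e-12, NA_real_, (tau + 1) / q)
  list(tau = tau, D = D, h = h)
}

#' Koch curve point set
#'
#' Generates the classical triadic Koch curve at a given recursion depth as a
#' densely resampled 2D polyline; its box-counting dimension is
#' \code{log(4)/log(3)} and serves as the closed-form oracle for the
#' box-count estimator.
#'
#' @param depth recursion depth (1..8).
#' @param resample_per_segment points interpolated per elementary segment so
#'   that the finest box scale is covered (default 4).
#' @return a two-column matrix of (x, y) points; base segment length 1.
#' @export
gen_koch_curve <- function(depth, resample_per_segment = 4L) {
  if (!is.numeric(depth) || depth < 1 || depth > 8)
    stop("gen_koch_curve: depth must be in 1..8")
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  rot60 <- matrix(c(cos(pi / 3), sin(pi / 3), -sin(pi / 3), cos(pi / 3)), 2, 2)
  for (d in seq_len(depth)) {
    a <- pts[-nrow(pts), , drop = FALSE]
    b <- pts[-1, , drop = FALSE]
    v <- (b - a) / 3
    p1 <- a + v
    p3 <- a + 2 * v
    p2 <- p1 + v %*% t(rot60)
    out <- matrix(NA_real_, nrow(a) * 4 + 1, 2)
    for (k in seq_len(nrow(a))) {
      out[(4 * k - 3):(4 * k), ] <- rbind(a[k, ], p1[k, ], p2[k, ], p3[k, ])
    }
    out[nrow(out), ] <- pts[nrow(pts), ]
    pts <- out
  }
  if (resample_per_segment > 1L) {
    a <- pts[-nrow(pts), , drop = FALSE]
    b <- pts[-1, , drop = FALSE]
    t <- seq(0, 1, length.out = resample_per_segment + 1L)[-(resample_per_segment + 1L)]
    xs <- outer(a[, 1], rep(1, length(t))) + outer(b[, 1] - a[, 1], t)
    ys <- outer(a[, 2], rep(1, length(t))) + outer(b[, 2] - a[, 2], t)
    pts <- rbind(cbind(as.vector(t(xs)), as.vector(t(ys))), pts[nrow(pts), ])
  }
  pts
}
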
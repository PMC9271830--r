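#' Cumulative profile of an ordered series
#'
#' The running sum of the mean-centered values; by construction the last
#' element is 0. The profile is the substrate of the partition-function
#' analysis.
#'
#' @param series an [ordered_series()] or numeric vector.
#' @param center subtract the series mean first (default TRUE). Positive
#'   measure-like series (e.g. cascade masses) are analyzed uncentered so
#'   box increments equal box masses.
#' @return numeric profile R_i.
#' @export
mf_profile <- function(series, center = TRUE) {
  v <- if (inherits(series, "ordered_series")) series$values else as.numeric(series)
  if (length(v) < 2L) stop("mf_profile: need at least 2 values")
  cumsum(if (center) v - mean(v) else v)
}

#' Box probabilities at one segment length
#'
#' Partitions the profile into \code{floor(N/s)} disjoint segments of
#' length s and returns the profile increments over the segments (the box
#' "probabilities"); the leftover tail is discarded, or covered by an
#' optional reversed pass.
#'
#' @param R profile from [mf_profile()].
#' @param s segment length (>= 1); scales leaving fewer than 4 segments are
#'   rejected.
#' @param both_ends also take segments from the series end and concatenate
#'   (default FALSE).
#' @return numeric vector of increments p_s(v).
#' @export
box_probabilities <- function(R, s, both_ends = FALSE) {
  N <- length(R)
  Ns <- N %/% s
  if (s < 1 || Ns < 4) stop("box_probabilities: floor(N/s) must be >= 4")
  ends <- seq_len(Ns) * s
  p <- R[ends] - c(0, R[ends[-Ns]])
  if (both_ends && N %% s != 0) {
    Rr <- rev(R[1] + R[N] - R)  # reversed profile with same increments
    endsr <- seq_len(Ns) * s
    p <- c(p, Rr[endsr] - c(0, Rr[endsr[-Ns]]))
  }
  p
}

#' Partition-function multifractal analysis of a series
#'
#' Computes \code{Z_q(s) = sum_v |p_s(v)|^q} over a ladder of segment
#' lengths and extracts \code{tau(q)} as the per-q slope of \code{log Z_q}
#' versus \code{log s}. Generalized dimensions \code{D(q) = tau(q)/(q-1)}
#' (the q = 1 information dimension by the central-difference limit of
#' \code{dtau/dq}) and generalized Hurst exponents
#' \code{h(q) = (tau(q)+1)/q} follow.
#'
#' @param series an [ordered_series()] or numeric vector.
#' @param q_grid moment orders; default \code{seq(-5, 5, 0.25)}. q = 1 is
#'   never used in a division (limit handling), q = 0 gives the support
#'   box-counting.
#' @param scales segment lengths; default dyadic \code{2^(2:floor(log2(N/4)))}.
#' @param center see [mf_profile()].
#' @param fit_range optional scale window for the tau fits.
#' @return a \code{multifractal_result}: list with \code{q}, \code{tau},
#'   \code{D}, \code{h}, \code{scale_fits} (per-q \code{powerlaw_fit}),
#'   \code{Z} (scales x q matrix), \code{scales}, \code{dimensionality = 1}.
#' @export
mf_partition <- function(series, q_grid = seq(-5, 5, by = 0.25),
                         scales = NULL, center = TRUE, fit_range = NULL) {
  v <- if (inherits(series, "ordered_series")) series$values else as.numeric(series)
  N <- length(v)
  R <- mf_profile(v, center = center)
  if (is.null(scales)) {
    scales <- 2^(2:max(3, floor(log2(N / 4))))
    if (length(scales) < 5L)  # short series: denser log-spaced ladder
      scales <- unique(round(exp(seq(log(4), log(max(N / 4, 8)),
                                     length.out = 8))))
  }
  scales <- scales[scales >= 1 & (N %/% scales) >= 4]
  if (length(scales) < 5L) stop("mf_partition: need >= 5 usable scales")
  q_grid <- sort(unique(q_grid))
  Z <- matrix(NA_real_, length(scales), length(q_grid))
  for (i in seq_along(scales)) {
    p <- abs(box_probabilities(R, scales[i]))
    p <- p[p > 0]          # zero boxes excluded from the moment sums
    if (length(p) < 2L) next
    lp <- log(p)
    Z[i, ] <- vapply(q_grid, function(q) sum(exp(q * lp)), numeric(1))
  }
  fits <- lapply(seq_along(q_grid), function(j) {
    ok <- is.finite(Z[, j]) & Z[, j] > 0
    fit_powerlaw(scales[ok], Z[ok, j], fit_range)
  })
  tau <- vapply(fits, function(f) f$exponent, numeric(1))
  D <- D_from_tau(tau, q_grid)
  h <- ifelse(abs(q_grid) < 1e-9, NA_real_, (tau + 1) / q_grid)
  structure(list(q = q_grid, tau = tau, D = D, h = h, scale_fits = fits,
                 Z = Z, scales = scales, dimensionality = 1L),
            class = "multifractal_result")
}

# D(q) = tau/(q-1) with the q -> 1 information-dimension limit taken by a
# central difference of tau on the q grid.
D_from_tau <- function(tau, q) {
  D <- rep(NA_real_, length(q))
  at1 <- abs(q - 1) < 1e-9
  reg <- !at1
  D[reg] <- tau[reg] / (q[reg] - 1)
  if (any(at1)) {
    i <- which(at1)
    lo <- which(q < 1 - 1e-9); hi <- which(q > 1 + 1e-9)
    if (length(lo) && length(hi)) {
      lo <- lo[which.max(q[lo])]; hi <- hi[which.min(q[hi])]
      D[i] <- (tau[hi] - tau[lo]) / (q[hi] - q[lo])
    }
  }
  D
}

#' @export
print.multifractal_result <- function(x, ...) {
  i2 <- which.min(abs(x$q - 2)); i1 <- which.min(abs(x$q - 1))
  cat(sprintf("Multifractal result (%dD): D(1) = %.3f, D(2) = %.3f over q in [%g, %g]\n",
              x$dimensionality, x$D[i1], x$D[i2], min(x$q), max(x$q)))
  invisible(x)
}

#' Two-dimensional multifractal detrended fluctuation analysis
#'
#' Standard 2D MF-DFA of a surface r(i, j): double cumulative sum of the
#' mean-centered grid, partition into disjoint s x s segments from the
#' origin corner (optionally averaged over all four corners), least-squares
#' plane (or higher-order polynomial) detrending per segment, q-th order
#' average of the per-segment fluctuation, and per-q slopes
#' \code{F_q(s) ~ s^h2(q)}. Exponents follow as
#' \code{tau2(q) = q h2(q) - 2} and \code{D2(q) = tau2(q)/(q-1)} with the
#' q = 1 limit from the tau derivative.
#'
#' @param grid an [parameterize_interface()] result or numeric matrix.
#' @param scales segment sizes; default ~8 log-spaced from 6 to
#'   \code{min(dim)/4}.
#' @param q_grid moment orders (default \code{seq(-4, 4, 0.25)}).
#' @param detrend_order 1 (plane, default) or 2 (quadratic surface).
#' @param four_corners average segment tilings anchored at all four grid
#'   corners so trailing margins are used (default TRUE).
#' @param cumulate apply the double cumulative sum (default TRUE; set FALSE
#'   to analyze a pre-integrated surface).
#' @param fit_range optional scale window for the h2 fits.
#' @return a \code{multifractal_result} with \code{dimensionality = 2} and
#'   \code{Fq} (scales x q fluctuation matrix).
#' @export
dfa2d <- function(grid, scales = NULL, q_grid = seq(-4, 4, by = 0.25),
                  detrend_order = 1L, four_corners = TRUE, cumulate = TRUE,
                  fit_range = NULL) {
  r <- if (inherits(grid, "interface_grid")) grid$r else as.matrix(grid)
  M <- nrow(r); N <- ncol(r)
  if (min(M, N) < 24L) stop("dfa2d: grid must be at least 24 x 24")
  if (is.null(scales)) {
    smax <- min(M, N) %/% 4L
    scales <- sort(unique(round(exp(seq(log(6), log(max(smax, 8)), length.out = 8)))))
  }
  scales <- scales[scales >= detrend_order + 2L & scales <= min(M, N)]
  if (length(scales) < 4L) stop("dfa2d: fewer than 4 usable scales")
  Y <- if (cumulate) {
    x <- r - mean(r)
    t(apply(apply(x, 2, cumsum), 1, cumsum))
  } else r
  q_grid <- sort(unique(q_grid))
  corners <- if (four_corners) 1:4 else 1L
  Fq <- matrix(NA_real_, length(scales), length(q_grid))
  for (si in seq_along(scales)) {
    s <- scales[si]
    X <- dfa_design(s, detrend_order)
    XtX_inv_Xt <- solve(crossprod(X), t(X))
    f2 <- numeric(0)
    for (cn in corners) {
      Yc <- switch(cn, Y, Y[M:1, , drop = FALSE], Y[, N:1, drop = FALSE],
                   Y[M:1, N:1, drop = FALSE])
      Ms <- M %/% s; Ns <- N %/% s
      if (Ms < 1 || Ns < 1) next
      # gather all segments as columns of an (s^2 x Ms*Ns) matrix
      sub <- Yc[seq_len(Ms * s), seq_len(Ns * s), drop = FALSE]
      segm <- matrix(NA_real_, s * s, Ms * Ns)
      k <- 0L
      for (w in seq_len(Ns)) for (v in seq_len(Ms)) {
        k <- k + 1L
        segm[, k] <- sub[((v - 1) * s + 1):(v * s), ((w - 1) * s + 1):(w * s)]
      }
      beta <- XtX_inv_Xt %*% segm
      resid <- segm - X %*% beta
      f2 <- c(f2, colMeans(resid^2))
    }
    lf <- log(pmax(f2, 1e-300)) / 2      # log F(v,w,s)
    Fq[si, ] <- vapply(q_grid, function(q) {
      if (abs(q) < 1e-9) exp(mean(lf))                # geometric mean, q = 0
      else mean(exp(q * lf))^(1 / q)                  # [mean F^q]^(1/q)
    }, numeric(1))
  }
  fits <- lapply(seq_along(q_grid), function(j) {
    ok <- is.finite(Fq[, j]) & Fq[, j] > 0
    fit_powerlaw(scales[ok], Fq[ok, j], fit_range)
  })
  h2 <- vapply(fits, function(f) f$exponent, numeric(1))
  tau <- q_grid * h2 - 2
  D <- D_from_tau(tau, q_grid)
  structure(list(q = q_grid, tau = tau, D = D, h = h2, scale_fits = fits,
                 Fq = Fq, scales = scales, dimensionality = 2L),
            class = "multifractal_result")
}

# Polynomial design matrix over an s x s segment (order 1: plane).
dfa_design <- function(s, order = 1L) {
  ij <- expand.grid(i = seq_len(s), j = seq_len(s))
  X <- cbind(1, ij$i, ij$j)
  if (order >= 2L) X <- cbind(X, ij$i^2, ij$j^2, ij$i * ij$j)
  X
}
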
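#' Box-counting fractal dimension of a point set
#'
#' Counts occupied boxes N(eps) on a geometric ladder of box sizes, averaged
#' over shifted grid origins, and reports the fractal dimension as minus the
#' slope of log N versus log eps on the best contiguous scaling window
#' (maximal r-squared with at least \code{min_fit_points} scales), or on a
#' caller-supplied window.
#'
#' @param points n x 2 or n x 3 numeric matrix.
#' @param scales box sizes; default: a factor-sqrt(2) geometric ladder from
#'   2 length units (the voxel-cloud regime) up to 1/4 of the largest
#'   bounding-box extent, or bbox/256..bbox/4 for sub-unit point sets.
#' @param offsets number of grid-origin shifts averaged per scale (default 4).
#' @param fit_range optional \code{c(min, max)} window of scales for the fit.
#' @param min_fit_points minimum scales in the automatic window (default 5).
#' @return a \code{"powerlaw_fit"} whose \code{exponent} is d_F (positive),
#'   with the N(eps) table attached as attribute \code{"table"}.
#' @export
box_count <- function(points, scales = NULL, offsets = 4L, fit_range = NULL,
                      min_fit_points = 5L) {
  points <- as.matrix(points)
  if (nrow(points) < 100L) stop("box_count: need at least 100 points")
  ext <- apply(points, 2, function(v) diff(range(v)))
  if (max(ext) <= 0) stop("box_count: degenerate point set")
  if (is.null(scales)) {
    top <- max(ext) / 4
    # keep the ladder out of the sampling-limited regime: the smallest scale
    # is the first (descending) candidate where boxes still hold >= ~3
    # points on average, found on a coarse trial ladder
    trial <- exp(seq(log(top), log(max(ext) / 512), length.out = 24))
    n <- nrow(points)
    bottom <- trial[length(trial)]
    for (eps in trial) {
      ids <- floor(points / eps)
      K <- max(ids) - min(ids) + 2
      key <- ids[, 1] - min(ids)
      for (j in 2:ncol(ids)) key <- key * K + (ids[, j] - min(ids))
      if (length(unique(key)) > n / 3) { bottom <- eps; break }
    }
    if (bottom >= top) bottom <- top / 8
    nsc <- max(6L, ceiling(2 * log2(top / bottom)) + 1L)
    scales <- exp(seq(log(bottom), log(top), length.out = nsc))
  }
  scales <- sort(unique(scales))
  N <- vapply(scales, function(eps) {
    counts <- vapply(seq_len(offsets) - 1L, function(o) {
      sh <- eps * o / offsets
      ids <- floor((points + sh) / eps)
      K <- max(ids) - min(ids) + 2
      key <- ids[, 1] - min(ids)
      for (j in 2:ncol(ids)) key <- key * K + (ids[, j] - min(ids))
      length(unique(key))
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  fit <- if (!is.null(fit_range)) fit_powerlaw(scales, N, fit_range)
  else best_scaling_window(scales, N, min_points = min_fit_points)
  fit$exponent <- -fit$exponent
  attr(fit, "table") <- data.frame(scale = scales, N = N)
  fit
}

#' Gliding-box lacunarity
#'
#' Lacunarity at box size eps is the variance-to-squared-mean ratio of the
#' box occupancy (point count) over all box positions. A perfectly uniform
#' occupancy gives 0; sparse, gappy sets give large values. Points are
#' rasterized to a binary grid of cell size \code{cell}; a binary array can
#' be passed directly.
#'
#' @param points n x d point matrix (d = 2 or 3), or a logical/0-1 array.
#' @param epsilons box sizes in grid cells (integers >= 1).
#' @param cell rasterization cell size for point input (default 1).
#' @param mode \code{"gliding"} (all positions, default) or \code{"fixed"}
#'   (disjoint tiling from the origin).
#' @param as_grid treat \code{points} as an occupancy grid rather than a
#'   point list; defaults to TRUE for 3D arrays and matrices wider than 3
#'   columns (a 2D occupancy matrix must be flagged explicitly).
#' @return data.frame with columns \code{epsilon} and \code{lambda}; the
#'   scalar summary used in cohort tables is \code{mean(lambda)} over the
#'   box-count scale range.
#' @export
lacunarity <- function(points, epsilons, cell = 1, mode = c("gliding", "fixed"),
                       as_grid = NULL) {
  mode <- match.arg(mode)
  if (is.null(as_grid))
    as_grid <- length(dim(points)) == 3L ||
      (is.matrix(points) && ncol(points) > 3L)
  grid <- if (as_grid) {
    (points != 0) + 0
  } else {
    points <- as.matrix(points)
    ids <- floor(sweep(points, 2, apply(points, 2, min)) / cell) + 1L
    d <- apply(ids, 2, max)
    g <- array(0, dim = d)
    g[ids] <- 1
    g
  }
  d <- dim(grid)
  epsilons <- as.integer(epsilons)
  if (any(epsilons < 1) || any(epsilons >= min(d)))
    stop("lacunarity: epsilon must be >= 1 and smaller than the grid")
  if (sum(grid) == 0) stop("lacunarity: empty occupancy grid")
  lam <- vapply(epsilons, function(eps) {
    counts <- box_sums(grid, eps, stride = if (mode == "gliding") 1L else eps)
    m <- mean(counts)
    if (m == 0) return(NA_real_)
    stats::var(counts) * (length(counts) - 1) / length(counts) / m^2
  }, numeric(1))
  data.frame(epsilon = epsilons, lambda = lam)
}

# Sums of the array over all eps^d windows at the given stride (integral image).
box_sums <- function(grid, eps, stride = 1L) {
  d <- dim(grid)
  nd <- length(d)
  cs <- grid
  for (ax in seq_len(nd)) cs <- apply_cumsum(cs, ax)
  pad <- function(i, ax) pmax(i, 0L)
  starts <- lapply(d, function(n) seq(1L, n - eps + 1L, by = stride))
  # windowed sums by inclusion-exclusion on the padded cumulative array
  csp <- array(0, dim = d + 1L)
  idx <- lapply(d, function(n) 2L:(n + 1L))
  if (nd == 2L) {
    csp[idx[[1]], idx[[2]]] <- cs
    i <- starts[[1]]; j <- starts[[2]]
    S <- csp[i + eps, j + eps, drop = FALSE] - csp[i, j + eps, drop = FALSE] -
      csp[i + eps, j, drop = FALSE] + csp[i, j, drop = FALSE]
    as.vector(S)
  } else {
    csp[idx[[1]], idx[[2]], idx[[3]]] <- cs
    i <- starts[[1]]; j <- starts[[2]]; k <- starts[[3]]
    S <- csp[i + eps, j + eps, k + eps, drop = FALSE] -
      csp[i, j + eps, k + eps, drop = FALSE] -
      csp[i + eps, j, k + eps, drop = FALSE] -
      csp[i + eps, j + eps, k, drop = FALSE] +
      csp[i, j, k + eps, drop = FALSE] +
      csp[i, j + eps, k, drop = FALSE] +
      csp[i + eps, j, k, drop = FALSE] -
      csp[i, j, k, drop = FALSE]
    as.vector(S)
  }
}

apply_cumsum <- function(a, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(seq_along(d), ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  m <- apply(m, 2, cumsum)
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Interface width versus patch scale
#'
#' For each patch scale s, slides an s x s window over the (phi, z) radius
#' grid (periodic in phi, valid-only in z), computes the per-window variance
#' of the radius about the window mean, and reports
#' \code{W(s) = sqrt(mean window variance)} — the patch-averaged interface
#' width whose small-s power law defines the local roughness exponent.
#'
#' @param grid an [parameterize_interface()] result, or a plain radius matrix
#'   (phi along rows, periodic).
#' @param scales integer patch sizes; default: ~12 log-spaced values from 2
#'   to half the smaller grid dimension.
#' @param valid_only when the grid carries a \code{fill_mask}, restrict the
#'   window average to windows made entirely of observed bins (default TRUE;
#'   interpolated polar-cap bins are artificially smooth and would bias the
#'   small-scale width down). Scales where no fully-observed window exists
#'   fall back to all windows.
#' @return data.frame with columns \code{scale}, \code{W} and
#'   \code{n_windows} (windows averaged at that scale).
#' @export
interface_width <- function(grid, scales = NULL, valid_only = TRUE) {
  r <- if (inherits(grid, "interface_grid")) grid$r else as.matrix(grid)
  mask <- if (valid_only && inherits(grid, "interface_grid"))
    grid$fill_mask + 0 else NULL
  np <- nrow(r); nz <- ncol(r)
  if (is.null(scales)) {
    smax <- max(2L, min(np, nz) %/% 2L)
    scales <- sort(unique(round(exp(seq(log(2), log(smax), length.out = 12)))))
  }
  scales <- scales[scales >= 2 & scales <= min(np, nz)]
  win_stats <- function(mat, s) {
    rp <- rbind(mat, mat[seq_len(s - 1L), , drop = FALSE])  # periodic phi pad
    matrix(box_sums(rp, s), ncol = nz - s + 1L)[seq_len(np), , drop = FALSE]
  }
  out <- vapply(scales, function(s) {
    S1 <- win_stats(r, s); S2 <- win_stats(r^2, s)
    m <- s * s
    v <- pmax(S2 / m - (S1 / m)^2, 0)
    if (!is.null(mask)) {
      full <- win_stats(mask, s) > m - 0.5
      if (any(full)) v <- v[full]
    }
    c(sqrt(mean(v)), length(v))
  }, numeric(2))
  data.frame(scale = scales, W = out[1, ], n_windows = out[2, ])
}

#' Local roughness exponent from the interface-width table
#'
#' The power-law exponent of W(s) at small s. With \code{fit_window = NULL}
#' the small-s regime is found automatically by the two-segment crossover
#' detector (the fit stops where W(s) bends toward saturation).
#'
#' @param Ws a data.frame from [interface_width()] (columns scale, W).
#' @param fit_window optional \code{c(min, max)} scale window.
#' @param min_scale smallest scale admitted to the automatic fit (default 4:
#'   below ~4 grid cells the window variance is dominated by bin-level
#'   discretization and overestimates the slope).
#' @return a \code{"powerlaw_fit"}; exponent is alpha_loc.
#' @export
local_roughness <- function(Ws, fit_window = NULL, min_scale = 4) {
  ok <- is.finite(Ws$W) & Ws$W > 0
  if (sum(ok) < 4L) stop("local_roughness: fewer than 4 positive W values")
  Ws <- Ws[ok, ]
  if (!is.null(fit_window)) return(fit_powerlaw(Ws$scale, Ws$W, fit_window))
  cr <- detect_crossover(Ws$scale, Ws$W)
  keep <- which(cr$x >= min_scale & cr$x <= cr$crossover)
  if (length(keep) < 4L) {
    # too few scales below the crossover: extend upward from min_scale
    # rather than down into the discretization-dominated region
    keep <- utils::head(which(cr$x >= min_scale), 4L)
    if (length(keep) < 4L) keep <- seq_len(min(4L, length(cr$x)))
  }
  fit_powerlaw(cr$x[keep], cr$y[keep])
}

#' Saturation value of the interface width
#'
#' The plateau of W(s) at large s: the mean of W over scales above the
#' detected crossover. If no plateau is detected (the breakpoint sits at the
#' end of the table) the top quartile of scales is used and the result is
#' flagged.
#'
#' @param Ws a data.frame from [interface_width()].
#' @return list with \code{W_sat}, \code{crossover}, \code{flagged}.
#' @export
saturation_width <- function(Ws) {
  ok <- is.finite(Ws$W) & Ws$W >= 0
  Ws <- Ws[ok, ]
  n <- nrow(Ws)
  if (n == 0L) stop("saturation_width: empty table")
  if (all(Ws$W == 0)) return(list(W_sat = 0, crossover = NA_real_, flagged = TRUE))
  cr <- detect_crossover(Ws$scale, Ws$W)
  flagged <- FALSE
  idx <- which(Ws$scale > cr$crossover)
  if (length(idx) < 2L) {
    idx <- which(Ws$scale >= stats::quantile(Ws$scale, 0.75))
    flagged <- TRUE
  }
  list(W_sat = mean(Ws$W[idx]), crossover = cr$crossover, flagged = flagged)
}

#' Global roughness exponent across a cohort
#'
#' Fits \code{W_sat ~ <R>^alpha} over tumors: the slope of log W_sat versus
#' log mean radius. Requires at least 5 tumors with positive entries.
#'
#' @param W_sat,R_mean equal-length positive vectors (one entry per tumor).
#' @return a \code{"powerlaw_fit"}; exponent is the global alpha.
#' @export
global_roughness <- function(W_sat, R_mean) {
  ok <- is.finite(W_sat) & is.finite(R_mean) & W_sat > 0 & R_mean > 0
  if (sum(ok) < 5L) stop("global_roughness: need >= 5 tumors with positive W_sat and R_mean")
  fit_powerlaw(R_mean[ok], W_sat[ok])
}

#' Family-Vicsek consistency sum
#'
#' For a kinetically roughened closed surface obeying the Family-Vicsek
#' ansatz the local roughness exponent and the interface fractal dimension
#' sum to the embedding dimension (3). The deviation from 3 diagnoses how
#' well a tumor conforms to the ballistic (proliferative-invasive) growth
#' model.
#'
#' @param d_F interface fractal dimension.
#' @param alpha_loc local roughness exponent.
#' @param d_E embedding dimension (default 3).
#' @return list with \code{fv_sum = d_F + alpha_loc} and
#'   \code{deviation = |fv_sum - d_E|}.
#' @export
family_vicsek_sum <- function(d_F, alpha_loc, d_E = 3) {
  stopifnot(is.finite(d_F), is.finite(alpha_loc))
  s <- d_F + alpha_loc
  list(fv_sum = s, deviation = abs(s - d_E))
}
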
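#' Parzen density estimator of image digital levels
#'
#' Gaussian kernel density of the grey-level histogram on a uniform
#' intensity grid covering \code{[min - 3 sigma, max + 3 sigma]}. This
#' density plays the role of the ground-state wavefunction in the quantum
#' clustering scheme: the Schrodinger potential is derived from it.
#'
#' @param levels integer digital levels (raw voxel values), or a named table
#'   of counts.
#' @param sigma kernel width in digital levels; default (range)/20.
#' @param grid_step spacing of the evaluation grid (default 0.5 digital
#'   level).
#' @return a \code{parzen_density}: list with \code{grid}, \code{phi}
#'   (unnormalized density), \code{sigma}.
#' @export
parzen_estimator <- function(levels, sigma = NULL, grid_step = 0.5) {
  if (is.table(levels)) {
    vals <- as.numeric(names(levels)); wts <- as.numeric(levels)
  } else {
    tab <- table(levels)
    vals <- as.numeric(names(tab)); wts <- as.numeric(tab)
  }
  if (length(vals) == 0L) stop("parzen_estimator: empty histogram")
  rng <- range(vals)
  if (is.null(sigma)) sigma <- max(diff(rng) / 20, 1e-3)
  stopifnot(sigma > 0)
  grid <- seq(rng[1] - 3 * sigma, rng[2] + 3 * sigma, by = grid_step)
  # column-wise kernel accumulation; weights keep voxel multiplicity
  phi <- rep(0, length(grid))
  for (i in seq_along(vals))
    phi <- phi + wts[i] * exp(-(grid - vals[i])^2 / (2 * sigma^2))
  structure(list(grid = grid, phi = phi, sigma = sigma),
            class = "parzen_density")
}

#' Schrodinger potential associated with a Parzen density
#'
#' Treating the Parzen density phi as the ground state (energy 0) of a
#' Schrodinger operator with squared width \code{sigma2} yields the
#' potential \code{V = (sigma2 / 2) * lap(phi) / phi}. V is shifted so its
#' minimum is 0; its local minima are the cluster attractors. phi is floored
#' at \code{1e-12 * max(phi)} before division and grid points at the floor
#' are flagged as masked.
#'
#' @param density a [parzen_estimator()] result.
#' @param sigma2 the "mass" parameter (squared digital levels); default the
#'   kernel width squared. Raising sigma2 merges potential minima and
#'   coarsens the downstream segmentation.
#' @return a \code{schrodinger_potential}: list with \code{grid}, \code{V},
#'   \code{sigma2}, \code{minima} (intensity locations), \code{masked}.
#' @export
schrodinger_potential <- function(density, sigma2 = NULL) {
  stopifnot(inherits(density, "parzen_density"))
  if (is.null(sigma2)) sigma2 <- density$sigma^2
  stopifnot(sigma2 > 0)
  g <- density$grid; phi <- density$phi
  h <- g[2] - g[1]
  n <- length(g)
  floorv <- 1e-12 * max(phi)
  masked <- phi < floorv
  phis <- pmax(phi, floorv)
  # central second difference, reflective boundary
  lap <- c(phis[2] - phis[1], diff(phis, differences = 2),
           phis[n - 1] - phis[n]) / h^2
  lap[1] <- 2 * lap[1]; lap[n] <- 2 * lap[n]
  V <- sigma2 / 2 * lap / phis
  V <- V - min(V[!masked])
  minima <- local_minima(g, V, exclude = masked)
  structure(list(grid = g, V = V, sigma2 = sigma2, minima = minima,
                 masked = masked), class = "schrodinger_potential")
}

# Locations of strict local minima by discrete gradient sign change.
local_minima <- function(x, y, exclude = rep(FALSE, length(y))) {
  n <- length(y)
  dy <- diff(y)
  s <- sign(dy)
  # a minimum where slope goes from <0 to >0 (plateaus resolved leftward)
  idx <- which(s[-1] > 0 & s[-(n - 1)] < 0) + 1L
  idx <- idx[!exclude[idx]]
  x[idx]
}

#' Parameters of the dissipative quantum-clustering dynamics
#'
#' @param sigma2 particle "mass" (squared digital levels).
#' @param gamma_dissipation damping coefficient; stability requires
#'   \code{gamma_dissipation * dt < 2}.
#' @param dt time step; default set so \code{gamma_dissipation * dt = 0.1}.
#' @param n_steps maximum integration steps.
#' @param convergence_tol stop when the largest per-step displacement falls
#'   below this (digital levels).
#' @return a \code{dqc_params} list.
#' @export
dqc_params <- function(sigma2, gamma_dissipation = 1, dt = 0.1 / gamma_dissipation,
                       n_steps = 4000L, convergence_tol = 1e-4) {
  stopifnot(sigma2 > 0, gamma_dissipation > 0, dt > 0, n_steps > 0,
            convergence_tol > 0)
  if (gamma_dissipation * dt >= 2)
    stop("dqc_params: gamma_dissipation * dt must be < 2 for stability")
  structure(list(sigma2 = sigma2, gamma_dissipation = gamma_dissipation,
                 dt = dt, n_steps = as.integer(n_steps),
                 convergence_tol = convergence_tol), class = "dqc_params")
}

#' Evolve digital levels down the Schrodinger potential
#'
#' Integrates \code{sigma2 * x'' = -V'(x) - gamma * x'} from rest for every
#' initial level with a semi-implicit (symplectic) Euler scheme: the damped
#' second-order Langevin dynamics that carries each grey level to a
#' potential minimum. Positions are clamped to the potential grid.
#'
#' @param initial numeric vector of starting digital levels.
#' @param potential a [schrodinger_potential()].
#' @param params a [dqc_params()].
#' @param keep_every record every k-th step in the returned trajectories
#'   (default 10; use 1 for dense output).
#' @return list with \code{final} (terminal positions), \code{trajectories}
#'   (matrix steps x levels, subsampled), \code{converged}, \code{steps}.
#' @export
evolve_levels <- function(initial, potential, params, keep_every = 10L) {
  stopifnot(inherits(potential, "schrodinger_potential"),
            inherits(params, "dqc_params"))
  g <- potential$grid
  h <- g[2] - g[1]
  n <- length(g)
  # precomputed gradient of V, linear interpolation between nodes
  dV <- c(diff(potential$V) / h, 0)
  gradV <- function(x) {
    xi <- pmin(pmax((x - g[1]) / h, 0), n - 1 - 1e-9)
    i0 <- floor(xi)
    dV[i0 + 1L]
  }
  x <- as.numeric(initial); v <- numeric(length(x))
  lo <- g[1]; hi <- g[n]
  span <- 3 * sqrt(params$sigma2)
  traj <- list(x)
  converged <- FALSE; step <- 0L
  while (step < params$n_steps) {
    step <- step + 1L
    a <- (-gradV(x) - params$gamma_dissipation * v) / params$sigma2
    v <- v + params$dt * a
    xn <- x + params$dt * v
    if (any(xn < lo - span | xn > hi + span))
      stop("evolve_levels: trajectory left the potential grid; ",
           "reduce dt or increase gamma_dissipation")
    xn <- pmin(pmax(xn, lo), hi)
    disp <- max(abs(xn - x))
    x <- xn
    if (step %% keep_every == 0L) traj[[length(traj) + 1L]] <- x
    if (disp < params$convergence_tol) { converged <- TRUE; break }
  }
  list(final = x, trajectories = do.call(rbind, traj),
       converged = converged, steps = step)
}

#' Dynamic quantum clustering segmentation of an intensity volume
#'
#' Two-pass scheme. Dynamic A: the distinct digital levels of the image
#' evolve under the potential derived from the image histogram; the terminal
#' positions form a clustered histogram. A Parzen estimator of that
#' clustered histogram gives the "trap" potential, whose well-separated
#' minima fix the number of classes. Dynamic B: the original levels evolve
#' again under the trap potential, and every voxel is labeled by the basin
#' its level terminates in (nearest trap minimum; ties go to the
#' lower-intensity minimum).
#'
#' @param volume numeric/integer array of digital levels (any
#'   dimensionality); values are rounded to integers.
#' @param params a [dqc_params()]; \code{NULL} uses
#'   \code{sigma = range/20}, \code{sigma2 = sigma^2}, \code{gamma = 1}.
#' @param sigma Parzen kernel width; default (range)/20.
#' @param roi optional logical mask restricting the histogram (and the
#'   labeling) to a region of interest.
#' @return list with \code{labels} (integer array, 1-based class per voxel,
#'   0 outside roi), \code{result}: a \code{clustering_result} carrying
#'   \code{assignments} (level -> class map), \code{centroids} (mean level
#'   per class), \code{trap_potential}, \code{potential}, \code{dynA},
#'   \code{dynB}, \code{params}.
#' @export
dqc_segment <- function(volume, params = NULL, sigma = NULL, roi = NULL) {
  vals <- if (is.null(roi)) as.vector(volume) else as.vector(volume[roi])
  vals <- round(vals)
  lv <- sort(unique(vals))
  if (length(lv) < 2L) stop("dqc_segment: constant image (need >= 2 distinct levels)")
  rngw <- diff(range(lv))
  if (is.null(sigma)) sigma <- rngw / 20
  if (is.null(params)) params <- dqc_params(sigma2 = sigma^2)
  dens <- parzen_estimator(vals, sigma = sigma)
  pot <- schrodinger_potential(dens, sigma2 = params$sigma2)
  dynA <- evolve_levels(lv, pot, params)
  # Parzen re-estimate on the clustered histogram (terminal positions
  # weighted by the original level multiplicities)
  wts <- as.numeric(table(vals))
  clustered <- round(dynA$final * 2) / 2  # half-level binning
  tabB <- tapply(wts, clustered, sum)
  tb <- structure(as.numeric(tabB), names = names(tabB), class = "table")
  densB <- parzen_estimator(tb, sigma = sigma)
  trap <- schrodinger_potential(densB, sigma2 = params$sigma2)
  dynB <- evolve_levels(lv, trap, params)
  minima <- trap$minima
  if (length(minima) == 0L) minima <- densB$grid[which.max(densB$phi)]
  cls <- basin_assign(dynB$final, minima)
  centroids <- vapply(sort(unique(cls)), function(k) {
    sel <- cls == k
    sum(lv[sel] * wts[sel]) / sum(wts[sel])
  }, numeric(1))
  # relabel so centroids are strictly increasing
  ord <- order(centroids)
  relab <- integer(max(cls)); relab[sort(unique(cls))[ord]] <- seq_along(ord)
  cls <- relab[cls]
  centroids <- centroids[ord]
  assignments <- stats::setNames(cls, lv)
  labels <- array(0L, dim = if (is.null(dim(volume))) length(volume) else dim(volume))
  vol_round <- round(volume)
  map <- integer(diff(range(lv)) + 1L)
  map[lv - min(lv) + 1L] <- cls
  inside <- if (is.null(roi)) TRUE else roi
  vclamp <- pmin(pmax(vol_round, min(lv)), max(lv))
  labels[inside] <- map[vclamp[inside] - min(lv) + 1L]
  result <- structure(list(assignments = assignments, centroids = centroids,
                           trap_potential = trap, potential = pot,
                           dynA = dynA, dynB = dynB, params = params,
                           sigma = sigma, n_classes = length(centroids)),
                      class = "clustering_result")
  list(labels = labels, result = result)
}

# Nearest-minimum basin assignment; equidistant points go to the
# lower-intensity minimum.
basin_assign <- function(x, minima) {
  minima <- sort(minima)
  d <- abs(outer(x, minima, "-"))
  max.col(-d, ties.method = "first")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("DQC clustering: %d classes, centroids: %s\n",
              x$n_classes, paste(sprintf("%.1f", x$centroids), collapse = ", ")))
  invisible(x)
}
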
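#' Specification of a synthetic rough tumor
#'
#' Bundles the parameters of the star-convex rough-sphere generator and
#' checks its geometric invariants (the surface must fit inside the grid
#' with margin).
#'
#' @param mean_radius mean radius in voxels.
#' @param hurst Hurst exponent of the radial roughness field, in (0, 1).
#' @param roughness_amplitude standard deviation of the relative radial
#'   fluctuation (fraction of \code{mean_radius}).
#' @param axis_ratios three positive scalars scaling the principal axes
#'   (ellipsoidal deformation).
#' @param core_fraction radius fraction of a concentric contrast-free core
#'   in [0, 1); 0 means solid.
#' @param grid_shape three positive integers, the label-volume dimensions.
#' @param seed integer seed for the roughness field.
#' @return a \code{tumor_spec} list.
#' @export
tumor_spec <- function(mean_radius, hurst = 0.5, roughness_amplitude = 0.2,
                       axis_ratios = c(1, 1, 1), core_fraction = 0,
                       grid_shape = c(96L, 96L, 96L), seed = 1L) {
  stopifnot(mean_radius > 0, length(axis_ratios) == 3, all(axis_ratios > 0),
            length(grid_shape) == 3, all(grid_shape >= 8),
            core_fraction >= 0, core_fraction < 1,
            roughness_amplitude >= 0)
  if (hurst <= 0 || hurst >= 1) stop("tumor_spec: hurst must lie in (0, 1)")
  # worst-case radius per axis: ~3 sd of the roughness field plus stretch
  rmax <- mean_radius * (1 + 3 * roughness_amplitude) * axis_ratios
  if (any(rmax + 2 > grid_shape / 2))
    stop("tumor_spec: surface does not fit inside grid_shape with margin")
  structure(list(mean_radius = mean_radius, hurst = hurst,
                 roughness_amplitude = roughness_amplitude,
                 axis_ratios = axis_ratios, core_fraction = core_fraction,
                 grid_shape = as.integer(grid_shape), seed = as.integer(seed)),
            class = "tumor_spec")
}

#' Self-affine random field on a periodic 2D grid
#'
#' Spectral synthesis: Fourier amplitudes follow the power law
#' \code{|k|^-(hurst + 1)} (power spectrum \code{k^-(2 hurst + 2)}, the
#' spectral exponent of a 2D surface with Hurst exponent \code{hurst}),
#' phases are random, and the field is normalized to zero mean and unit
#' standard deviation. Periodic in both directions, which guarantees seam
#' continuity when used as the angular roughness of a closed surface.
#'
#' @param nx,ny grid dimensions.
#' @param hurst Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @return an \code{nx} by \code{ny} numeric matrix.
#' @export
gen_self_affine_field <- function(nx, ny, hurst, seed) {
  if (hurst <= 0 || hurst >= 1) stop("gen_self_affine_field: hurst in (0,1)")
  gen_spectral_field(nx, ny, beta = 2 * hurst + 2, seed = seed)
}

#' Stationary Gaussian random field with power-law spectrum
#'
#' Spectral synthesis of a periodic Gaussian field whose power spectrum
#' follows \code{|k|^-beta}; \code{beta = 2 hurst + 2} gives the self-affine
#' surface of [gen_self_affine_field()], while \code{beta < 2} gives
#' stationary long-range-correlated "noise-like" fields (2D fluctuation
#' exponent \code{h2 = beta / 2}), the clean monofractal reference for
#' detrended fluctuation analysis.
#'
#' @param nx,ny grid dimensions.
#' @param beta spectral exponent (> 0).
#' @param seed integer seed.
#' @return an \code{nx} by \code{ny} matrix, zero mean, unit variance.
#' @export
gen_spectral_field <- function(nx, ny, beta, seed) {
  stopifnot(beta > 0)
  rng <- local_rng(seed)
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  k2 <- outer(kx^2, ky^2, "+")
  amp <- k2^(-beta / 4)
  amp[1, 1] <- 0
  z <- matrix(complex(real = rng$rnorm(nx * ny), imaginary = rng$rnorm(nx * ny)), nx, ny)
  f <- Re(stats::fft(amp * z, inverse = TRUE))
  f <- f - mean(f)
  f / stats::sd(f)
}

# Bilinear interpolation of a (phi, w) field: phi periodic in [0, 2pi),
# w = (1 + cos(theta))/2 in [0, 1] clamped; grid nodes at cell centers. The
# second coordinate matches the cylindrical z parameterization used by the
# interface analysis, so generated and measured index spaces agree up to a
# linear stretch.
interp_sphere_field <- function(field, phi, theta) {
  np <- nrow(field); nt <- ncol(field)
  u <- phi / (2 * pi) * np - 0.5         # fractional row index (0-based)
  v <- (1 + cos(theta)) / 2 * nt - 0.5
  i0 <- floor(u); fu <- u - i0
  j0 <- floor(v); fv <- v - j0
  i0p <- (i0 %% np) + 1L; i1p <- ((i0 + 1) %% np) + 1L
  j0p <- pmin(pmax(j0, 0), nt - 1L) + 1L
  j1p <- pmin(pmax(j0 + 1, 0), nt - 1L) + 1L
  f00 <- field[cbind(i0p, j0p)]; f10 <- field[cbind(i1p, j0p)]
  f01 <- field[cbind(i0p, j1p)]; f11 <- field[cbind(i1p, j1p)]
  (1 - fu) * ((1 - fv) * f00 + fv * f01) + fu * ((1 - fv) * f10 + fv * f11)
}

#' Voxelized star-convex rough tumor with known ground truth
#'
#' Builds a solid whose boundary radius field is
#' \code{mean_radius * (1 + roughness_amplitude * f(phi, theta))} with
#' \code{f} a zero-mean, unit-variance self-affine field of exponent
#' \code{hurst} synthesized on an angular grid, then stretched by
#' \code{axis_ratios}. A voxel belongs to the tumor when its center lies
#' inside the analytic radius field. If \code{core_fraction > 0} a
#' concentric contrast-free cavity is carved out of the contrast label,
#' emulating a necrotic core.
#'
#' Labels: 0 = background, 1 = contrast-enhancing tumor, 2 = contrast-free
#' core (so the full tumor mask is labels \{1, 2\} and the contrast region
#' is label 1).
#'
#' @param spec a [tumor_spec()].
#' @param field_dims angular resolution \code{c(n_phi, n_z)} of the
#'   roughness field (default \code{c(1024, 512)}: several times finer than
#'   the analysis grid, so the surface carries power below the measurement
#'   bin scale as a real self-affine surface would).
#' @return list with \code{labels} (integer 3D array) and \code{truth}
#'   (list: \code{true_hurst}, \code{center} — 0-based voxel coordinates,
#'   \code{radius_fun(phi, theta)} — the analytic radius field before axis
#'   stretching, \code{field}, \code{spec}).
#' @export
gen_rough_sphere <- function(spec, field_dims = c(1024L, 512L)) {
  stopifnot(inherits(spec, "tumor_spec"))
  gs <- spec$grid_shape
  ctr <- (gs - 1) / 2
  f <- if (spec$roughness_amplitude > 0)
    gen_self_affine_field(field_dims[1], field_dims[2], spec$hurst, spec$seed)
  else matrix(0, field_dims[1], field_dims[2])
  radius_fun <- function(phi, theta) {
    fac <- 1 + spec$roughness_amplitude * interp_sphere_field(f, phi, theta)
    spec$mean_radius * pmax(fac, 0.05)
  }
  rmax_box <- spec$mean_radius * (1 + 3.5 * spec$roughness_amplitude) * max(spec$axis_ratios)
  lo <- pmax(1L, floor(ctr + 1 - rmax_box))
  hi <- pmin(gs, ceiling(ctr + 1 + rmax_box))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  dx <- rep((xs - 1) - ctr[1], times = ny * nz) / spec$axis_ratios[1]
  dy <- rep(rep((ys - 1) - ctr[2], each = nx), times = nz) / spec$axis_ratios[2]
  dz <- rep((zs - 1) - ctr[3], each = nx * ny) / spec$axis_ratios[3]
  rho <- sqrt(dx^2 + dy^2 + dz^2)
  phi <- atan2(dy, dx); phi[phi < 0] <- phi[phi < 0] + 2 * pi
  theta <- acos(pmin(pmax(ifelse(rho > 0, dz / rho, 1), -1), 1))
  R <- radius_fun(phi, theta)
  lab_box <- integer(nx * ny * nz)
  inside <- rho <= R
  lab_box[inside] <- 1L
  if (spec$core_fraction > 0)
    lab_box[inside & rho <= spec$core_fraction * R] <- 2L
  labels <- array(0L, dim = gs)
  labels[xs, ys, zs] <- array(lab_box, dim = c(nx, ny, nz))
  truth <- list(true_hurst = spec$hurst, center = ctr,
                radius_fun = radius_fun, field = f, spec = spec)
  list(labels = labels, truth = truth)
}

#' Multi-class Gaussian intensity mixture volume
#'
#' Each voxel's class is drawn from \code{weights} and its intensity from the
#' corresponding Gaussian, then rounded to integer digital levels; ground
#' truth records the class map and the component means. The fixture for
#' segmentation tests.
#'
#' @param means,sds,weights equal-length component parameter vectors;
#'   \code{weights} must sum to 1.
#' @param shape grid dimensions (length 3, or any positive integer vector).
#' @param seed integer seed.
#' @return list with \code{volume} (integer digital-level array),
#'   \code{truth} (list: \code{true_labels} array of component indices,
#'   \code{true_centroids = means}).
#' @export
gen_mixture_volume <- function(means, sds, weights, shape, seed) {
  k <- length(means)
  if (length(sds) != k || length(weights) != k)
    stop("gen_mixture_volume: means, sds, weights must have equal length")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("gen_mixture_volume: weights must sum to 1")
  n <- prod(shape)
  rng <- local_rng(seed)
  cls <- rng$sample(k, n, replace = TRUE, prob = weights)
  vals <- rng$rnorm(n, mean = means[cls], sd = sds[cls])
  vol <- array(as.integer(round(vals)), dim = shape)
  list(volume = vol,
       truth = list(true_labels = array(cls, dim = shape),
                    true_centroids = means))
}
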
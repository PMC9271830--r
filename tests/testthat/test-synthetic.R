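test_that("fBm generator is deterministic and rejects bad parameters", {
  a <- gen_fbm_series(64, 0.5, seed = 7)
  b <- gen_fbm_series(64, 0.5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$values, gen_fbm_series(64, 0.5, seed = 8)$values))
  expect_error(gen_fbm_series(32, 0.5, 1), "n must be")
  expect_error(gen_fbm_series(128, 1.2, 1), "hurst")
  # generation never touches the global RNG stream
  set.seed(42); r1 <- rnorm(1)
  set.seed(42); invisible(gen_fbm_series(128, 0.5, 1)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("fBm increments carry the requested Hurst exponent", {
  # independent DFA-2 oracle on the increment series, averaged over seeds
  for (H in c(0.3, 0.5, 0.8)) {
    est <- vapply(1:50, function(s) {
      x <- gen_fbm_series(1024, H, s)
      dfa2_exponent(diff(x$values))
    }, numeric(1))
    expect_lt(abs(mean(est) - H), 0.05)
  }
})

test_that("persistent fBm increments are positively autocorrelated", {
  pos <- vapply(1:100, function(s) {
    dx <- diff(gen_fbm_series(1024, 0.9, s)$values)
    stats::cor(dx[-1], dx[-length(dx)]) > 0
  }, logical(1))
  expect_gt(mean(pos), 0.95)
})

test_that("binomial cascade reproduces its closed-form structure", {
  m <- gen_binomial_cascade(2, 0.3)$values
  expect_equal(sort(m), sort(c(0.09, 0.21, 0.21, 0.49)), tolerance = 1e-12)
  u <- gen_binomial_cascade(14, 0.5)$values
  expect_true(all(abs(u - 2^-14) < 1e-18))
  expect_equal(sum(gen_binomial_cascade(14, 0.3)$values), 1, tolerance = 1e-12)
  expect_error(gen_binomial_cascade(14, 1.2), "p must lie")
  expect_error(gen_binomial_cascade(1, 0.5), "levels")
})

test_that("Koch curve has the generator's vertex count and length", {
  k1 <- gen_koch_curve(1, resample_per_segment = 1)
  expect_equal(nrow(k1), 5)
  seglen <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  for (d in c(2, 4)) {
    kd <- gen_koch_curve(d, resample_per_segment = 1)
    expect_equal(nrow(kd), 4^d + 1)
    expect_equal(seglen(kd), (4 / 3)^d, tolerance = 1e-9)
  }
})

test_that("mixture volume matches its ground truth", {
  mx <- gen_mixture_volume(c(40, 100, 180), c(8, 8, 8), rep(1 / 3, 3),
                           c(24, 24, 24), seed = 2)
  expect_equal(dim(mx$volume), dim(mx$truth$true_labels))
  expect_equal(length(unique(as.vector(mx$truth$true_labels))), 3)
  expect_identical(mx$truth$true_centroids, c(40, 100, 180))
  # per-class voxel means sit near the component means
  for (k in 1:3) {
    mu <- mean(mx$volume[mx$truth$true_labels == k])
    expect_lt(abs(mu - c(40, 100, 180)[k]), 1)
  }
  one <- gen_mixture_volume(100, 5, 1, c(8, 8, 8), seed = 1)
  expect_true(all(one$truth$true_labels == 1))
  expect_error(gen_mixture_volume(c(1, 2), c(1, 1), 1, c(4, 4, 4), 1),
               "equal length")
})

test_that("histogram of a bimodal mixture has modes at the component means", {
  hits <- vapply(1:10, function(s) {
    mx <- gen_mixture_volume(c(50, 150), c(5, 5), c(0.5, 0.5),
                             c(20, 20, 20), seed = s)
    tab <- tabulate(as.vector(mx$volume), nbins = 200)
    m1 <- which.max(tab[1:100]); m2 <- 100 + which.max(tab[101:200])
    abs(m1 - 50) <= 2 && abs(m2 - 150) <= 2
  }, logical(1))
  expect_true(all(hits))
})

test_that("rough-sphere generator honors its degenerate and shaped cases", {
  s20 <- fix_sphere20()
  expect_true(all(abs(s20$interface$radii - 20) < 1))
  # PCA axes on an analytically sampled ellipsoid (affine image of uniform
  # sphere directions) recover the 2:1:1 ratio; the voxelized boundary
  # samples by surface area, which concentrates mass near the equator and
  # compresses the apparent elongation, so it is only checked loosely
  set.seed(8)
  u <- matrix(rnorm(3 * 4000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ell <- sweep(u, 2, c(2, 1, 1) * 14, "*")
  ifc_a <- structure(list(points = ell, center = c(0, 0, 0),
                          radii = sqrt(rowSums(ell^2)), n_points = nrow(ell)),
                     class = "tumor_interface")
  axa <- pca_ellipsoid(ifc_a)$axes
  expect_equal(axa[1] / axa[3], 2, tolerance = 0.05)
  expect_equal(axa[2] / axa[3], 1, tolerance = 0.05)
  spe <- tumor_spec(14, roughness_amplitude = 0, axis_ratios = c(2, 1, 1),
                    grid_shape = c(72, 64, 64))
  ge <- gen_rough_sphere(spe)
  ax <- pca_ellipsoid(extract_interface(ge$labels))$axes
  expect_gt(ax[1] / ax[3], 1.5)
  expect_equal(ax[2] / ax[3], 1, tolerance = 0.1)
  # concentric core removes (core_fraction)^3 of the volume from contrast
  spc <- tumor_spec(16, roughness_amplitude = 0, core_fraction = 0.5,
                    grid_shape = c(48, 48, 48))
  gc_ <- gen_rough_sphere(spc)
  frac <- sum(gc_$labels == 1L) / sum(gc_$labels > 0L)
  expect_equal(frac, 1 - 0.5^3, tolerance = 0.02)
  # determinism
  expect_identical(gen_rough_sphere(spc)$labels, gc_$labels)
  expect_error(tumor_spec(40, grid_shape = c(64, 64, 64)), "margin")
})

test_that("self-affine field is normalized and seed-stable", {
  f <- gen_self_affine_field(64, 64, 0.5, 3)
  expect_equal(mean(f), 0, tolerance = 1e-12)
  expect_equal(stats::sd(f), 1, tolerance = 1e-12)
  expect_identical(f, gen_self_affine_field(64, 64, 0.5, 3))
})
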
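test_that("sphere interface has the expected size, radii and center", {
  s <- fix_sphere20()
  ifc <- s$interface
  expect_true(all(abs(ifc$radii - 20) < 1))
  # surface voxel count ~ area / voxel face
  expect_gt(ifc$n_points, 0.6 * 4 * pi * 400)
  expect_equal(ifc$center, rep(31.5, 3), tolerance = 0.05)
  expect_error(extract_interface(s$labels, tumor_label = 99L), "absent")
})

test_that("interface is invariant under volume translation", {
  sp <- tumor_spec(10, roughness_amplitude = 0, grid_shape = c(40, 40, 40))
  g <- gen_rough_sphere(sp)
  lab2 <- array(0L, c(48, 48, 48))
  lab2[5 + 1:40, 3 + 1:40, 7 + 1:40] <- g$labels
  i1 <- extract_interface(g$labels, min_points = 10)
  i2 <- extract_interface(lab2, min_points = 10)
  expect_equal(sort(i1$radii), sort(i2$radii), tolerance = 1e-6)
  expect_equal(i2$center - i1$center, c(5, 3, 7), tolerance = 1e-6)
})

test_that("tiny interfaces are flagged, not silently dropped", {
  lab <- array(0L, c(12, 12, 12)); lab[6, 6, 6] <- 1L
  ifc <- extract_interface(lab, min_points = 10)
  expect_true(ifc$rejected)
  expect_equal(ifc$n_points, 1)
})

test_that("parameterized sphere grid is constant and phi-equivariant", {
  s <- fix_sphere30()
  gr <- s$grid
  expect_lt(max(abs(gr$r - 30)) / 30, 0.03)
  expect_true(mean(gr$fill_mask) > 0.5)
  # rotating a rough tumor about z shifts the grid circularly by the same
  # number of phi bins (the sphere is degenerate for this: its frame is
  # arbitrary, so use a structured surface)
  g <- fix_rough_cored()
  ifc <- extract_interface(g$labels, min_points = 500)
  gr1 <- parameterize_interface(ifc)
  kshift <- 10L
  th <- 2 * pi * kshift / gr1$phi_bins
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ifc2 <- ifc
  ifc2$points <- sweep(sweep(ifc$points, 2, ifc$center) %*% Rz, 2,
                       ifc$center, "+")
  gr2 <- parameterize_interface(ifc2, gr1$phi_bins, gr1$z_bins)
  ccor <- vapply(0:(gr1$phi_bins - 1L), function(k) {
    idx <- ((seq_len(gr1$phi_bins) - 1L + k) %% gr1$phi_bins) + 1L
    stats::cor(as.vector(gr1$r[idx, ]), as.vector(gr2$r))
  }, numeric(1))
  best <- which.max(ccor) - 1L
  expect_true(min((best - kshift) %% gr1$phi_bins,
                  (kshift - best) %% gr1$phi_bins) <= 1L)
  expect_gt(max(ccor), 0.9)
})

test_that("ordered series reproduces analytic slice contours", {
  s <- fix_sphere30()
  mid <- 41L  # central slice of the 80^3 sphere
  os <- ordered_series_from_slice(s$interface, slice_index = mid)
  expect_lt(stats::sd(os$values), 0.35)
  expect_equal(mean(os$values), 30, tolerance = 0.5)
  # square contour: polar radius L / (2 max(|cos|, |sin|)) with 4 maxima
  lab <- array(0L, c(64, 64, 9))
  lab[13:52, 13:52, 2:8] <- 1L
  ifc <- extract_interface(lab, min_points = 10, subvoxel = FALSE)
  osq <- ordered_series_from_slice(ifc, slice_index = 5L, angle_bins = 90L)
  ang <- osq$angles
  theo <- 19.5 / (2 * pmax(abs(cos(ang)), abs(sin(ang)))) * 2
  expect_gt(cor(osq$values, theo), 0.97)
  pk <- sort(ang[order(osq$values, decreasing = TRUE)[1:8]])
  # corner angles at odd multiples of pi/4
  expect_lt(min(abs(outer(pk, pi / 4 * c(1, 3, 5, 7), "-"))), 0.15)
})

test_that("max-points slice selector is deterministic with ties to lower index", {
  lab <- array(0L, c(30, 30, 9))
  lab[6:25, 6:25, 3] <- 1L
  lab[6:25, 6:25, 7] <- 1L
  ifc <- extract_interface(lab, min_points = 10, subvoxel = FALSE)
  os <- ordered_series_from_slice(ifc)
  expect_equal(os$slice_index, 3L)
})

test_that("surface measures match closed forms for spheres and shells", {
  s <- fix_sphere20()
  sm <- surface_measures(s$labels)
  expect_equal(sm$TV, 4 / 3 * pi * 20^3, tolerance = 0.02)
  expect_equal(sm$TS, 4 * pi * 400, tolerance = 0.03)
  expect_equal(sm$R_mean, 20, tolerance = 0.02)
  expect_equal(sm$TV_C, sm$TV)
  expect_equal(sm$TS_C, sm$TS)
  # concentric shell: inner + outer areas, TS_C ~ TS (1 + 0.25)
  spc <- tumor_spec(20, roughness_amplitude = 0, core_fraction = 0.5,
                    grid_shape = c(64, 64, 64))
  gc_ <- gen_rough_sphere(spc)
  smc <- surface_measures(gc_$labels, contrast_label = 1L)
  expect_equal(smc$TS_C / smc$TS, 1.25, tolerance = 0.05)
  expect_equal(smc$TV_C / smc$TV, 1 - 0.5^3, tolerance = 0.02)
})

test_that("PCA ellipsoid is rotation invariant and sphere-calibrated", {
  s <- fix_sphere20()
  pe <- pca_ellipsoid(s$interface)
  expect_lt(diff(range(pe$axes)) / mean(pe$axes), 0.02)
  expect_equal(mean(pe$axes), 20, tolerance = 0.05)
  ifc2 <- s$interface
  th <- 0.7
  R3 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ifc2$points <- ifc2$points %*% R3
  expect_equal(pca_ellipsoid(ifc2)$axes, pe$axes, tolerance = 1e-6)
  ifc3 <- s$interface
  ifc3$points <- ifc3$points[, c(1, 2, 3)] * 0 + cbind(
    ifc3$points[, 1], ifc3$points[, 2], 0)  # coplanar
  expect_error(pca_ellipsoid(ifc3), "rank-deficient")
})
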
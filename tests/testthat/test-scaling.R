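test_that("box counting recovers the dimension of smooth reference sets", {
  t <- seq(0, 1, length.out = 4000)
  line3 <- cbind(t, 2 * t, 0.5 * t) * 100
  expect_equal(box_count(line3)$exponent, 1, tolerance = 0.05)
  s <- fix_sphere30()
  dF <- box_count(s$interface$points)$exponent
  expect_gte(dF, 1.9); expect_lte(dF, 2.1)
  expect_error(box_count(matrix(1, 200, 3)), "degenerate")
  expect_error(box_count(line3[1:50, ]), "at least 100")
})

test_that("Koch curve box dimension matches log4/log3", {
  k <- gen_koch_curve(6)
  f <- box_count(k, scales = (1 / 3)^(2:7))
  expect_lt(abs(f$exponent - log(4) / log(3)), 0.05)
})

test_that("lacunarity matches binomial moments and degenerate limits", {
  # uniformly filled grid: zero variance
  g <- matrix(1, 32, 32)
  expect_equal(lacunarity(g, 4, as_grid = TRUE)$lambda, 0)
  # Bernoulli(p) occupancy: lambda ~ (1-p)/(n p)
  p <- 0.3; eps <- 4L; ncell <- 16
  lam <- vapply(1:50, function(s) {
    set.seed(s)
    gb <- matrix(runif(64^2) < p, 64, 64)
    lacunarity(gb, eps, as_grid = TRUE, mode = "fixed")$lambda
  }, numeric(1))
  expect_equal(mean(lam), (1 - p) / (ncell * p), tolerance = 0.05)
  # fixed-mode translation by a box multiple leaves lambda unchanged
  set.seed(1)
  pts <- cbind(runif(500, 0, 32), runif(500, 0, 32))
  l1 <- lacunarity(pts, 4, mode = "fixed")$lambda
  l2 <- lacunarity(sweep(pts, 2, c(8, 8), "+"), 4, mode = "fixed")$lambda
  expect_equal(l1, l2, tolerance = 0.1)
  expect_error(lacunarity(matrix(0, 16, 16), 4, as_grid = TRUE), "empty")
})

test_that("interface width behaves on constant, noise and power-law inputs", {
  expect_true(all(interface_width(matrix(5, 48, 32))$W == 0))
  # iid noise: W(s) ~ sigma, flat in s => alpha_loc ~ 0 (Monte Carlo mean)
  al <- vapply(1:10, function(s) {
    set.seed(s)
    gno <- matrix(rnorm(64 * 48, sd = 2), 64, 48)
    Ws <- interface_width(gno)
    if (s == 1) expect_lt(abs(Ws$W[nrow(Ws)] - 2) / 2, 0.1)
    local_roughness(Ws)$exponent
  }, numeric(1))
  expect_lt(abs(mean(al)), 0.1)
})

test_that("exact power-law tables return exponents to 1e-6", {
  Ws <- data.frame(scale = 2:24, W = 3 * (2:24)^0.7)
  expect_equal(local_roughness(Ws)$exponent, 0.7, tolerance = 1e-6)
  expect_lt(abs(local_roughness(data.frame(scale = 2:24, W = rep(2, 23)))$exponent),
            1e-9)
  al <- global_roughness(0.1 * (10:29)^0.9, 10:29)
  expect_equal(al$exponent, 0.9, tolerance = 1e-6)
  expect_lt(abs(global_roughness(rep(2, 10), 10:19)$exponent), 1e-9)
  expect_error(global_roughness(1:3, 1:3), ">= 5 tumors")
})

test_that("saturation width finds the plateau", {
  expect_equal(saturation_width(data.frame(scale = 2:20, W = 4))$W_sat, 4)
  ws <- data.frame(scale = 2:40, W = pmin((2:40)^0.7, 5))
  expect_equal(saturation_width(ws)$W_sat, 5, tolerance = 0.02)
  # pure power law: no plateau, flagged fallback
  wp <- saturation_width(data.frame(scale = 2:10, W = (2:10)^0.6))
  expect_true(is.finite(wp$W_sat))
})

test_that("W_sat scales linearly with the generator roughness amplitude", {
  wsat <- vapply(c(0.1, 0.2, 0.3), function(a) {
    sp <- tumor_spec(20, hurst = 0.5, roughness_amplitude = a,
                     grid_shape = c(80, 80, 80), seed = 11)
    ifc <- extract_interface(gen_rough_sphere(sp)$labels)
    saturation_width(interface_width(parameterize_interface(ifc)))$W_sat
  }, numeric(1))
  f <- fit_powerlaw(c(0.1, 0.2, 0.3), wsat)
  expect_equal(f$exponent, 1, tolerance = 0.25)
  expect_true(all(diff(wsat) > 0))
})

test_that("Family-Vicsek sum is plain arithmetic with its deviation", {
  fv <- family_vicsek_sum(2.2, 0.8)
  expect_equal(fv$fv_sum, 3); expect_equal(fv$deviation, 0)
  fv2 <- family_vicsek_sum(1.97, 0.68)
  expect_equal(fv2$fv_sum, 2.65)
  expect_equal(fv2$deviation, 0.35, tolerance = 1e-12)
})

test_that("W(s) is non-decreasing in s for self-affine grids", {
  for (s in 1:3) {
    f <- gen_self_affine_field(96, 48, 0.5, s)
    Ws <- interface_width(f)
    expect_true(all(diff(Ws$W) > -0.02 * max(Ws$W)))
  }
})
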
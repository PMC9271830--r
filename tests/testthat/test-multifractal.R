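test_that("profile and box probabilities follow their definitions", {
  expect_equal(mf_profile(c(1, 3, 2)), c(-1, 0, 0))
  expect_true(all(mf_profile(rep(4, 10)) == 0))
  for (i in 1:5) {
    set.seed(i)
    expect_equal(mf_profile(rnorm(50))[50], 0, tolerance = 1e-12)
  }
  R <- mf_profile(c(2, 5, 1, 7, 3, 3, 6, 1))
  expect_equal(box_probabilities(R, 1), c(2, 5, 1, 7, 3, 3, 6, 1) - 3.5)
  expect_equal(sum(box_probabilities(R, 2)), 0, tolerance = 1e-12)
  expect_error(box_probabilities(R, 3), ">= 4")
})

test_that("cascade box increments reproduce the cascade masses", {
  cs <- gen_binomial_cascade(8, 0.3)
  R <- mf_profile(cs, center = FALSE)
  p <- box_probabilities(R, 4)   # level-6 dyadic boxes
  m6 <- gen_binomial_cascade(6, 0.3)$values
  expect_equal(p, m6, tolerance = 1e-12)
})

test_that("partition function recovers cascade exponents in closed form", {
  cs <- gen_binomial_cascade(14, 0.3)
  mf <- mf_partition(cs, center = FALSE)
  th <- cascade_theory(mf$q, 0.3)
  i1 <- which(mf$q == 1); i2 <- which(mf$q == 2); i0 <- which(mf$q == 0)
  expect_equal(mf$D[i2], th$D[i2], tolerance = 1e-6)          # 0.786
  expect_lt(abs(mf$D[i1] - th$D[i1]), 0.01)                   # 0.881 entropy
  expect_equal(mf$tau[i0], -1, tolerance = 1e-9)              # support
  off1 <- abs(mf$q - 1) > 0.11
  expect_lt(max(abs(mf$D[off1] - th$D[off1])), 0.05)
  # uniform measure: D(q) = 1 for all q, tau(q) = q - 1
  mfu <- mf_partition(gen_binomial_cascade(14, 0.5), center = FALSE)
  expect_lt(max(abs(mfu$D - 1), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(mfu$tau - (mfu$q - 1))), 1e-9)
})

test_that("tau is concave and D non-increasing on every fixture", {
  # exact on measure-like fixtures
  for (p in c(0.25, 0.35, 0.5)) {
    mf <- mf_partition(gen_binomial_cascade(12, p), center = FALSE)
    expect_true(all(diff(mf$tau, differences = 2) < 1e-6))
    D <- mf$D[is.finite(mf$D)]
    expect_true(all(diff(D) < 0.02))
  }
  # noisy estimates on signed series satisfy the Legendre structure up to
  # fit noise (extreme negative moments of near-zero increments dominate
  # the residual violations)
  for (s in 3:4) for (H in c(0.5, 0.8)) {
    mf <- mf_partition(gen_fbm_series(1024, H, s), q_grid = seq(-3, 3, 0.25))
    expect_true(all(diff(mf$tau, differences = 2) < 0.05))
    D <- mf$D[is.finite(mf$D)]
    expect_true(all(diff(D) < 0.1))
  }
})

test_that("monofractal 1D series give a flat h(q) at the target exponent", {
  for (H in c(0.3, 0.5, 0.8)) {
    hh <- vapply(1:10, function(s) {
      m <- mf_partition(diff(gen_fbm_series(2048, H, s)$values),
                        q_grid = c(1.75, 2, 2.25))
      m$h[2]
    }, numeric(1))
    expect_lt(abs(mean(hh) - H), 0.1)
  }
})

test_that("2D DFA satisfies its analytic reference cases", {
  # iid grid: h2(2) ~ 1/2
  h2 <- vapply(1:5, function(s) {
    set.seed(s)
    dfa2d(matrix(rnorm(128^2), 128, 128), q_grid = 2)$h
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.1)
  # exact plane: residuals annihilated
  pl <- outer(1:64, 1:64, function(i, j) 2 + 0.3 * i - 0.1 * j)
  d <- dfa2d(pl, cumulate = FALSE, q_grid = 2, scales = c(6, 8, 12, 16))
  expect_lt(max(d$Fq), 1e-10)
  # adding a global plane to a pre-integrated surface changes nothing
  set.seed(9)
  base <- apply(apply(matrix(rnorm(64^2), 64, 64), 2, cumsum), 1, cumsum)
  d1 <- dfa2d(base, cumulate = FALSE, q_grid = 2, scales = c(6, 8, 12, 16))
  d2 <- dfa2d(base + pl, cumulate = FALSE, q_grid = 2, scales = c(6, 8, 12, 16))
  expect_equal(d1$Fq, d2$Fq, tolerance = 1e-8)
})

test_that("monofractal surfaces give a flat h2(q) across moments", {
  # stationary long-range-correlated Gaussian field: the clean monofractal
  # reference (strongly correlated surfaces show the well-known spurious
  # negative-q multifractality at finite size); seed-averaged h2(q)
  # segments below ~10 cells underresolve the plane fit and inflate the
  # negative moments, so the fit ladder starts at 10
  sc <- sort(unique(round(exp(seq(log(10), log(64), length.out = 8)))))
  hq <- rowMeans(vapply(1:4, function(s) {
    dfa2d(gen_spectral_field(256, 256, 1.0, s), q_grid = seq(-4, 4, 1),
          scales = sc)$h
  }, numeric(9)))
  expect_lt(max(abs(hq - hq[7])), 0.1)  # q = 2 is entry 7
})

test_that("q = 0 and q = 1 never produce non-finite output on valid input", {
  m <- mf_partition(gen_fbm_series(512, 0.5, 2), q_grid = c(-1, 0, 0.5, 1, 2))
  expect_true(all(is.finite(m$tau)))
  expect_true(is.finite(m$D[m$q == 1]))
  d <- dfa2d(gen_self_affine_field(96, 96, 0.5, 2), q_grid = c(-1, 0, 1, 2))
  expect_true(all(is.finite(d$tau)))
  expect_true(is.finite(d$D[d$q == 1]))
})
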
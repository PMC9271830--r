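test_that("Parzen estimator reduces to its analytic forms", {
  # single level: one Gaussian centered at the value
  d <- parzen_estimator(rep(80L, 10), sigma = 5)
  expect_equal(d$grid[which.max(d$phi)], 80, tolerance = 0.5)
  expect_equal(max(d$phi), 10, tolerance = 1e-6)   # unnormalized count scale
  # two equal-weight levels: symmetric, modes near 50 and 150
  d2 <- parzen_estimator(c(rep(50L, 100), rep(150L, 100)), sigma = 10)
  expect_equal(d2$phi, rev(d2$phi), tolerance = 1e-9)
  peaks <- d2$grid[order(d2$phi, decreasing = TRUE)[1:2]]
  expect_true(any(abs(peaks - 50) < 1) && any(abs(peaks - 150) < 1))
  expect_error(parzen_estimator(integer(0)), "empty")
})

test_that("potential is scale invariant in the histogram counts", {
  lv <- c(rep(50L, 40), rep(150L, 60))
  p1 <- schrodinger_potential(parzen_estimator(lv, sigma = 10))
  p2 <- schrodinger_potential(parzen_estimator(rep(lv, 2), sigma = 10))
  expect_equal(p1$V, p2$V, tolerance = 1e-9)
  expect_equal(p1$minima, p2$minima)
})

test_that("Schrodinger potential has the harmonic-oscillator structure", {
  # phi Gaussian at mu: V is an upward-opening well with minimum at mu
  d <- parzen_estimator(rep(100L, 50), sigma = 8)
  pot <- schrodinger_potential(d)
  expect_length(pot$minima, 1)
  expect_equal(pot$minima, 100, tolerance = 0.5)
  inner <- abs(pot$grid - 100) < 16
  vin <- pot$V[inner]; gin <- pot$grid[inner]
  # quadratic in the well core: V ~ (x-mu)^2/(2 sigma^2) * sigma2/sigma^2...
  fitq <- stats::lm(vin ~ I((gin - 100)^2))
  expect_gt(summary(fitq)$r.squared, 0.999)
})

test_that("well-separated bimodal density yields exactly two minima", {
  lv <- c(rep(50L, 100), rep(150L, 100))
  pot <- schrodinger_potential(parzen_estimator(lv, sigma = 10))
  expect_length(pot$minima, 2)
  expect_equal(sort(pot$minima), c(50, 150), tolerance = 1)
})

test_that("raising sigma2 never increases the number of minima", {
  lv <- c(rep(40L, 80), rep(90L, 60), rep(170L, 90))
  d <- parzen_estimator(lv, sigma = 9)
  n_min <- vapply(c(1, 3, 9, 27) * 81, function(s2)
    length(schrodinger_potential(d, sigma2 = s2)$minima), numeric(1))
  expect_true(all(diff(n_min) <= 0))
})

test_that("level evolution obeys damped-oscillator mechanics", {
  # rest at a minimum stays fixed
  lv <- c(rep(50L, 100), rep(150L, 100))
  pot <- schrodinger_potential(parzen_estimator(lv, sigma = 10))
  pr <- dqc_params(sigma2 = 100)
  ev <- evolve_levels(pot$minima[1], pot, pr)
  expect_equal(ev$final, pot$minima[1], tolerance = 1e-3)
  # quadratic well: overdamped relaxation toward mu matches the closed form
  g <- seq(0, 200, by = 0.5)
  k <- 0.1; mu <- 100
  quad <- structure(list(grid = g, V = 0.5 * k * (g - mu)^2, sigma2 = 1,
                         minima = mu, masked = rep(FALSE, length(g))),
                    class = "schrodinger_potential")
  pq <- dqc_params(sigma2 = 1, gamma_dissipation = 5, dt = 0.02,
                   n_steps = 60000L, convergence_tol = 1e-8)
  evq <- evolve_levels(140, quad, pq, keep_every = 1L)
  expect_lt(abs(evq$final - mu), 0.01)
  # overdamped limit: x(t) - mu ~ exp(-k t / gamma); check the decay rate
  tt <- 1000; xt <- evq$trajectories[tt + 1, 1]
  expect_equal(log(abs(xt - mu) / 40) / (tt * pq$dt), -k / 5, tolerance = 0.1)
  # two wells: levels fall into their own basins
  ev2 <- evolve_levels(c(45, 155), pot, pr)
  expect_equal(ev2$final, c(50, 150), tolerance = 1.5)
  # energy is non-increasing along trajectories
  evd <- evolve_levels(c(70, 120), pot, pr, keep_every = 1L)
  Vat <- function(x) approx(pot$grid, pot$V, xout = x, rule = 2)$y
  tr <- evd$trajectories
  vel <- rbind(0, diff(tr)) / pr$dt
  E <- 0.5 * pr$sigma2 * vel^2 + apply(tr, 2, Vat)
  expect_true(all(diff(E[, 1]) < 1e-6) && all(diff(E[, 2]) < 1e-6))
})

test_that("two-pass segmentation recovers a bimodal mixture", {
  mx <- gen_mixture_volume(c(50, 150), c(5, 5), c(0.5, 0.5),
                           c(32, 32, 32), seed = 3)
  seg <- dqc_segment(mx$volume)
  expect_equal(seg$result$n_classes, 2)
  expect_gte(mean(seg$labels == mx$truth$true_labels), 0.98)
  expect_equal(seg$result$centroids, c(50, 150), tolerance = 1.5)
  expect_error(dqc_segment(array(7, c(4, 4, 4))), "constant image")
})

test_that("assignments are stable under voxel permutation and reclustering", {
  mx <- gen_mixture_volume(c(60, 140), c(6, 6), c(0.4, 0.6),
                           c(20, 20, 20), seed = 9)
  seg <- dqc_segment(mx$volume)
  # permutation invariance: assignments depend only on the level histogram
  perm <- sample(length(mx$volume))
  vol2 <- array(as.vector(mx$volume)[perm], dim = dim(mx$volume))
  seg2 <- dqc_segment(vol2)
  expect_identical(seg$result$assignments, seg2$result$assignments)
  # idempotence: evolving again under the same trap potential moves nothing
  lv <- as.numeric(names(seg$result$assignments))
  again <- evolve_levels(seg$result$dynB$final, seg$result$trap_potential,
                         seg$result$params)
  cls_again <- tumorfract:::basin_assign(again$final, seg$result$trap_potential$minima)
  expect_identical(unname(cls_again), unname(tumorfract:::basin_assign(
    seg$result$dynB$final, seg$result$trap_potential$minima)))
})

test_that("DQC centroids agree with a K-means oracle on seeded mixtures", {
  hits <- vapply(1:20, function(s) {
    mx <- gen_mixture_volume(c(55, 145), c(7, 7), c(0.5, 0.5),
                             c(16, 16, 16), seed = s)
    seg <- dqc_segment(mx$volume)
    if (seg$result$n_classes != 2) return(FALSE)
    km <- suppressWarnings(stats::kmeans(as.vector(mx$volume), centers = 2,
                                         nstart = 5))
    all(abs(sort(km$centers) - seg$result$centroids) <= 1)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
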
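# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# Voxelized smooth sphere, r = 30 voxels, 80^3 grid.
fix_sphere30 <- function() fixture("sphere30", function() {
  sp <- tumor_spec(30, roughness_amplitude = 0, grid_shape = c(80, 80, 80))
  g <- gen_rough_sphere(sp)
  ifc <- extract_interface(g$labels)
  list(labels = g$labels, interface = ifc,
       grid = parameterize_interface(ifc))
})

# Smaller smooth sphere for cheap geometry tests.
fix_sphere20 <- function() fixture("sphere20", function() {
  sp <- tumor_spec(20, roughness_amplitude = 0, grid_shape = c(64, 64, 64))
  g <- gen_rough_sphere(sp)
  list(labels = g$labels, interface = extract_interface(g$labels))
})

# Rough cored tumor for pipeline tests.
fix_rough_cored <- function() fixture("rough_cored", function() {
  sp <- tumor_spec(18, hurst = 0.6, roughness_amplitude = 0.2,
                   core_fraction = 0.5, grid_shape = c(72, 72, 72), seed = 5)
  gen_rough_sphere(sp)
})

# Brute-force (all-pairs, all-intermediates) natural visibility oracle.
visibility_oracle <- function(series) {
  t <- series$angles; y <- series$values
  n <- length(y)
  edges <- NULL
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    vis <- TRUE
    if (b > a + 1L) {
      cc <- (a + 1L):(b - 1L)
      lim <- y[b] + (y[a] - y[b]) * (t[b] - t[cc]) / (t[b] - t[a])
      vis <- all(y[cc] < lim)
    }
    if (vis) edges <- rbind(edges, c(a, b))
  }
  edges
}

# Independent DFA-2 Hurst estimator (order-2 polynomial detrending), used
# as the oracle for fBm/fGn exponents; deliberately separate from the
# package's partition-function path.
dfa2_exponent <- function(x, scales = NULL) {
  N <- length(x)
  y <- cumsum(x - mean(x))
  if (is.null(scales))
    scales <- unique(round(exp(seq(log(8), log(N / 4), length.out = 10))))
  Fs <- vapply(scales, function(s) {
    ns <- N %/% s
    t <- seq_len(s)
    X <- cbind(1, t, t^2)
    H <- X %*% solve(crossprod(X), t(X))
    f2 <- vapply(seq_len(ns), function(v) {
      seg <- y[((v - 1) * s + 1):(v * s)]
      mean((seg - H %*% seg)^2)
    }, numeric(1))
    sqrt(mean(f2))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(Fs) ~ log(scales)))[2])
}
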
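test_that("stationary chain solution: normalization, center value, K/k scaling", {
  model <- hopping_model(K = 0.05, k = 0.1, a = 8, layout = "chain",
                         n_rings = 101)
  laser <- laser_profile(sigma = 40)
  st <- stationary_1d(model, laser)
  expect_equal(st$p_norm[51], 1)
  expect_true(all(st$p > 0))
  # p_norm depends only on K/k: scale both rates by 7
  st2 <- stationary_1d(hopping_model(K = 0.35, k = 0.7, a = 8,
                                     layout = "chain", n_rings = 101), laser)
  expect_lt(max(abs(st$p_norm - st2$p_norm)), 1e-10)
  expect_error(stationary_1d(hopping_model(K = 0, k = 0.1, a = 8,
                                           layout = "chain", n_rings = 11),
                             laser), "diverges")
})

test_that("closed-form stationary solution matches the rate-equation oracle", {
  model <- hopping_model(K = 0.05, k = 0.1, a = 8, layout = "chain",
                         n_rings = 101)
  laser <- laser_profile(sigma = 40)
  st <- stationary_1d(model, laser)
  relaxed <- ode_oracle(model, laser = laser, times = c(0, 2000))[2, ]
  expect_lt(max(abs(st$p - relaxed)) / max(st$p), 1e-8)
})

test_that("long chains evaluate without overflow", {
  model <- hopping_model(K = 1e-3, k = 0.1, a = 8, layout = "chain",
                         n_rings = 4001)
  st <- stationary_1d(model, laser_profile(sigma = 169.86))
  expect_true(all(is.finite(st$p)) && all(st$p > 0))
  expect_equal(st$p_norm[2001], 1)
})

test_that("1D Bessel propagator matches the oracle and conserves with K = 0", {
  model <- hopping_model(K = 0.02, k = 0.1, a = 8, layout = "chain",
                         n_rings = 201)
  laser <- laser_profile(sigma = 30)
  p0 <- initial_excitation(model, laser)
  expect_identical(dynamics_1d(p0, model, 0), p0)
  for (tt in c(1, 10, 100)) {
    pb <- dynamics_1d(p0, model, tt)
    po <- ode_oracle(model, p0 = p0, times = c(0, tt))[2, ]
    expect_lt(max(abs(pb - po)), 1e-7)
  }
  m0 <- hopping_model(K = 0, k = 0.1, a = 8, layout = "chain", n_rings = 301)
  p00 <- initial_excitation(m0, laser_profile(sigma = 20))
  for (tt in c(5, 50)) {
    expect_lt(abs(sum(dynamics_1d(p00, m0, tt)) - 1), 1e-8)
  }
})

test_that("2D stationary solve is consistent and hexagonally symmetric", {
  model <- hopping_model(K = 1, k = 0.05, a = 8, layout = "hexagonal",
                         extent = 12)
  laser <- laser_profile(sigma = 12, center = c(2, 0))
  s <- stationary_2d(model, laser)
  expect_lt(s$residual, 1e-10)
  # rotating the laser by 60 degrees rotates the solution: (i,j) -> (-j, i+j)
  s2 <- stationary_2d(model, laser_profile(sigma = 12, center = c(0, 2)))
  ext <- model$extent
  err <- 0
  for (i in -6:6) for (j in -6:6) {
    err <- max(err, abs(s$p[i + ext + 1, j + ext + 1] -
                          s2$p[-j + ext + 1, i + j + ext + 1]))
  }
  # residual finite-domain asymmetry only through the far Gaussian tail
  expect_lt(err / max(s$p), 1e-8)
  # decoupled limit K >> k: p ~ A / (K + 6k) at interior rings
  m2 <- hopping_model(K = 50, k = 0.01, a = 8, layout = "hexagonal",
                      extent = 10)
  l2 <- laser_profile(sigma = 30)
  s3 <- stationary_2d(m2, l2)
  A <- excitonsim:::laser_amplitudes_2d(m2, l2)
  expect_lt(max(abs(s3$p - A / (m2$K + 6 * m2$k))) / max(s3$p), 0.01)
  expect_error(stationary_2d(hopping_model(K = 0, layout = "hexagonal",
                                           extent = 3),
                             l2), "singular")
})

test_that("2D Bessel propagator matches the oracle and conserves with K = 0", {
  model <- hopping_model(K = 0.001, k = 0.1, a = 8, layout = "hexagonal",
                         extent = 25)
  p0 <- initial_excitation(model, laser_profile(sigma = 12))
  expect_identical(dynamics_2d(p0, model, 0), p0)
  for (tt in c(1, 5)) {
    pb <- dynamics_2d(p0, model, tt)
    po <- matrix(ode_oracle(model, p0 = p0, times = c(0, tt))[2, ], 51, 51)
    expect_lt(max(abs(pb - po)), 1e-7)
  }
  m0 <- hopping_model(K = 0, k = 0.1, a = 8, layout = "hexagonal",
                      extent = 15)
  p00 <- initial_excitation(m0, laser_profile(sigma = 10))
  expect_lt(abs(sum(dynamics_2d(p00, m0, 8)) - 1), 1e-8)
})

test_that("rate-equation oracle: pure decay and step-halving convergence", {
  model <- hopping_model(K = 0.3, k = 0, a = 8, layout = "chain", n_rings = 1)
  out <- ode_oracle(model, p0 = 1, times = c(0, 2, 5))
  expect_equal(out[, 1], exp(-0.3 * c(0, 2, 5)), tolerance = 1e-8)
  # stationary limit of the driven system reproduces stationary_1d is covered
  # above; here check integrator self-consistency under tighter tolerances
  m <- hopping_model(K = 0.05, k = 0.1, a = 8, layout = "chain", n_rings = 51)
  l <- laser_profile(sigma = 30)
  o1 <- ode_oracle(m, laser = l, times = c(0, 100), rtol = 1e-8, atol = 1e-10)
  o2 <- ode_oracle(m, laser = l, times = c(0, 100), rtol = 1e-11, atol = 1e-13)
  expect_lt(max(abs(o1[2, ] - o2[2, ])), 1e-6)
})

test_that("laser profile and FWHM follow the Gaussian closed forms", {
  expect_equal(laser_fwhm(laser_profile(sigma = 169.86)), 400,
               tolerance = 1e-4)
  model <- hopping_model(K = 0.01, k = 0.1, a = 8, layout = "chain",
                         n_rings = 11)
  laser <- laser_profile(sigma = 16, center = 6)
  A <- excitonsim:::laser_amplitudes_1d(model, laser)
  expect_equal(A[6], 1)
  expect_equal(A[7], exp(-(8)^2 / (2 * 16^2)))
  expect_error(laser_profile(sigma = -1), "positive")
})

test_that("diffusion length: no-transport limit and K/k monotonicity", {
  laser <- laser_profile(sigma = 80)
  # K >> k: stationary profile approaches the laser profile, Ld -> 0
  big <- stationary_1d(hopping_model(K = 100, k = 0.1, a = 8,
                                     layout = "chain", n_rings = 501), laser)
  expect_lt(abs(diffusion_length(big, laser)$Ld), 0.5)
  ratios <- 10^seq(-2.5, 0, length.out = 7)
  lds <- sapply(ratios, function(r) {
    st <- stationary_1d(hopping_model(K = r * 0.1, k = 0.1, a = 8,
                                      layout = "chain", n_rings = 2001),
                        laser)
    diffusion_length(st, laser)$Ld
  })
  expect_true(all(diff(lds) < 0))
})

test_that("2D spreading is faster but peaks lower than 1D at matched distance", {
  # matched comparison: same laser SD, same rates; ring m on the chain vs
  # ring (m, 0) on the hexagonal lattice, initial probabilities scaled equal
  K <- 0.001; k <- 0.1
  m1 <- hopping_model(K = K, k = k, a = 8, layout = "chain", n_rings = 501)
  m2 <- hopping_model(K = K, k = k, a = 8, layout = "hexagonal", extent = 25)
  laser <- laser_profile(sigma = 33.97)
  p1 <- initial_excitation(m1, laser)
  p2 <- initial_excitation(m2, laser)
  m <- 5
  i1 <- 251 + m
  times <- c(2, 5, 10, 20, 40, 80)
  tr1 <- sapply(times, function(t) dynamics_1d(p1, m1, t)[i1])
  tr2 <- sapply(times, function(t) dynamics_2d(p2, m2, t)[26 + m, 26])
  scale <- p1[i1] / p2[26 + m, 26]
  tr2 <- tr2 * scale
  expect_lt(max(tr2), max(tr1))
  expect_lte(times[which.max(tr2)], times[which.max(tr1)])
})
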
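# one short Case II trajectory with a real bath, reused by several blocks
traj_cache <- new.env()
case2_short <- function() {
  if (is.null(traj_cache$tr)) {
    sys <- chain3_system()
    st <- initial_state(sys$H, sys$bath, "bright")
    traj_cache$sys <- sys
    traj_cache$tr <- propagate(st, sys$H, sys$bath, t_end = 500, dt = 0.05,
                               stride_fs = 1)
  }
  list(sys = traj_cache$sys, tr = traj_cache$tr)
}

test_that("density matrix at t = 0 is the pure exciton projector", {
  sys <- chain3_system()
  st <- initial_state(sys$H, sys$bath, "bright")
  rho <- reduced_density_matrix(st, sys$H)
  expect_equal(Re(sum(diag(rho))), 1, tolerance = 1e-12)
  expect_equal(unclass(rho), outer(Conj(st$alpha), st$alpha),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Debye-Waller structure: unit diagonal, Hermitian, bounded coherence", {
  cs <- case2_short()
  for (i in c(101, 301, 501)) {
    st <- trajectory_state(cs$tr, i)
    S <- debye_waller_matrix(st$lambda, cs$sys$H)
    expect_equal(diag(S), rep(1 + 0i, 48))
    expect_lt(max(Mod(S) - 1), 1e-12)
    rho <- reduced_density_matrix(st, cs$sys$H)
    expect_lt(max(Mod(rho - Conj(t(rho)))), 1e-10)
    expect_true(all(Re(diag(rho)) >= -1e-12))
    # |rho_mn| <= |alpha_m||alpha_n| (overlap modulus at most one)
    bound <- outer(Mod(st$alpha), Mod(st$alpha))
    expect_true(all(Mod(rho) <= bound + 1e-12))
    expect_equal(Re(sum(diag(rho))), cs$tr$norm[i], tolerance = 1e-8)
  }
})

test_that("ring populations and MSD follow the distance weighting", {
  cs <- case2_short()
  pops <- ring_populations(cs$tr)
  expect_true(all(abs(colSums(pops) - 1) < 1e-6))
  m <- msd_trace(cs$tr)
  d <- ring_center_distances(cs$sys$geom, 2)
  expect_equal(m$msd, as.numeric(d^2 %*% pops), tolerance = 1e-12)
  expect_equal(m$msd[1], 0, tolerance = 1e-20)
})

test_that("an immobile exciton (J = 0) has zero MSD", {
  geom <- build_nanoarray("chain", n_rings = 3)
  bath <- make_bath("linear_dispersion")
  H <- structure(list(J = diag(12500, 48), n_rings = 3L,
                      n_sites_per_ring = 16L, geometry = geom),
                 class = "exciton_hamiltonian")
  st <- initial_state(H, bath, "single_site", ring = 2, site = 1)
  traj <- propagate(st, H, bath, t_end = 60, dt = 0.05, stride_fs = 10)
  expect_lt(max(msd_trace(traj)$msd), 1e-10)
})

test_that("diffusion exponent recovers exact power laws and crossovers", {
  tt <- seq(1, 1000, by = 1)
  fit <- diffusion_exponent(tt, 0.37 * tt^1.5, window = c(1, 1000))
  expect_equal(fit$gamma, 1.5, tolerance = 1e-10)
  # broken power law t^2 -> t^0.8 crossing at 300
  y <- ifelse(tt <= 300, tt^2, 300^2 * (tt / 300)^0.8)
  fit2 <- diffusion_exponent(tt, y, window = c(1, 1000), crossover = TRUE)
  expect_equal(fit2$gamma, 2, tolerance = 0.02)
  expect_equal(fit2$gamma2, 0.8, tolerance = 0.02)
  expect_equal(fit2$t_cross, 300, tolerance = 0.1 * 300)
  expect_error(diffusion_exponent(tt[1:3], tt[1:3]), "3 points")
})

test_that("coherence size has its closed-form values and bounds", {
  N <- 24
  uni <- matrix(1 / N, N, N)
  expect_equal(coherence_size(uni), N)
  single <- matrix(0, N, N); single[3, 3] <- 1
  expect_equal(coherence_size(single), 1 / N)
  expect_error(coherence_size(matrix(0, 4, 4)), "zero")
  set.seed(11)
  for (rep in 1:20) {
    v <- complex(real = rnorm(N), imaginary = rnorm(N))
    rho <- outer(Conj(v), v) / sum(Mod(v)^2)
    lr <- coherence_size(rho)
    expect_gte(lr, 1 / N - 1e-12)
    expect_lte(lr, N + 1e-12)
  }
})

test_that("superradiance of a single pigment is exactly 1", {
  sys <- chain3_system()
  M <- dipole_metric(sys$geom)
  st <- initial_state(sys$H, sys$bath, "single_site", site = 3)
  expect_equal(superradiance(reduced_density_matrix(st, sys$H), M), 1)
  expect_error(superradiance(matrix(0i, 2, 2), M), "mismatch")
})

test_that("L_s and L_rho oscillate out of phase for the bright start", {
  cs <- case2_short()
  dl <- delocalization_trace(cs$tr)
  # after the initial transient (a few phonon periods) the oscillations of
  # L_s and L_rho are out of phase; increments isolate the oscillation from
  # the slow drift
  sel <- dl$time >= 100 & dl$time <= 500
  r <- stats::cor(diff(dl$L_s[sel]), diff(dl$L_rho[sel]))
  expect_lt(r, 0)
})

test_that("free-exciton absorption peaks at the bright eigenstate", {
  geom <- build_nanoarray("chain", n_rings = 1)
  H <- coupling_matrix(geom)
  bath0 <- make_bath("linear_dispersion", S = 0)
  sp <- absorption_spectrum(H, bath0, damping = 50, t_max = 300)
  ee <- exciton_eigenstates(H)
  expect_lt(abs(sp$freq[which.max(sp$intensity)] - ee$values[2]), 20)
  expect_error(absorption_spectrum(H, bath0, damping = -1), "tau")
})

test_that("frequency-integrated free-exciton intensity obeys the sum rule", {
  geom <- build_nanoarray("chain", n_rings = 1)
  H <- coupling_matrix(geom)
  bath0 <- make_bath("linear_dispersion", S = 0)
  tau <- 40
  sp <- absorption_spectrum(H, bath0, damping = tau, t_max = 800,
                            freq_range = c(10000, 14500), n_freq = 3000)
  # oracle: sum of Lorentzians of width 1/tau at the eigenenergies weighted
  # by oscillator strength, normalized to unit peak like the spectrum
  ee <- exciton_eigenstates(H)
  gam <- 1 / (cm1_to_radfs(1) * tau)   # half-width in cm^-1
  stick <- function(f) {
    colSums(ee$osc_strength * sapply(f, function(fi)
      gam / ((fi - ee$values)^2 + gam^2)) / pi)
  }
  ref <- stick(sp$freq)
  ref <- ref / max(ref)
  int_sp <- sum(sp$intensity) * diff(sp$freq[1:2])
  int_ref <- sum(ref) * diff(sp$freq[1:2])
  expect_equal(int_sp, int_ref, tolerance = 0.02)
})
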
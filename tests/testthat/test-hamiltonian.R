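test_that("point-dipole orientation factors are correct", {
  # parallel dipoles perpendicular to the separation: kappa = +1
  g1 <- make_pair_geometry(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 1, 0))
  H1 <- coupling_matrix(g1, dipole_strength = 100, site_energy = 0)
  expect_equal(H1$J[1, 2], 100 / 8, tolerance = 1e-12)
  # collinear head-to-tail dipoles: kappa = -2
  g2 <- make_pair_geometry(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0), c(1, 0, 0))
  H2 <- coupling_matrix(g2, dipole_strength = 100, site_energy = 0)
  expect_equal(H2$J[1, 2], -2 * 100 / 8, tolerance = 1e-12)
})

test_that("couplings scale as the inverse cube of all distances", {
  geom <- build_nanoarray("chain", n_rings = 2, spacing = 7,
                          ring_template = build_b850_ring(n_sites = 6,
                                                          radius = 1.5))
  J1 <- coupling_matrix(geom, site_energy = 0)$J
  big <- geom
  big$spacing <- 14
  big$rings <- lapply(seq_along(geom$rings), function(r) {
    rg <- geom$rings[[r]]
    rg$positions <- rg$positions * 2
    rg$ring_center <- rg$ring_center * 2
    rg$radius <- rg$radius * 2
    rg
  })
  big$centers <- geom$centers * 2
  J2 <- coupling_matrix(big, site_energy = 0)$J
  off <- row(J1) != col(J1)
  expect_equal(J2[off], J1[off] / 8, tolerance = 1e-10)
})

test_that("Hamiltonian is symmetric and dominated by intra-ring couplings", {
  H <- chain3_system()$H
  expect_lt(max(abs(H$J - t(H$J))), 1e-10)
  ns <- 16
  intra <- abs(H$J[1:ns, 1:ns][row(diag(ns)) != col(diag(ns))])
  inter <- abs(H$J[1:ns, (ns + 1):(2 * ns)])
  expect_gt(max(intra), max(inter))
})

test_that("coincident pigments are rejected", {
  g <- make_pair_geometry(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 0))
  expect_error(coupling_matrix(g), "oincident")
})

test_that("uniform nearest-neighbour ring reproduces the circulant spectrum", {
  ns <- 16
  J1 <- -200
  ring <- build_b850_ring()
  geom <- build_nanoarray("chain", n_rings = 1, ring_template = ring)
  Jc <- diag(12000, ns)
  for (n in seq_len(ns)) {
    m <- n %% ns + 1
    Jc[n, m] <- Jc[m, n] <- J1
  }
  H <- structure(list(J = Jc, n_rings = 1L, n_sites_per_ring = ns,
                      geometry = geom), class = "exciton_hamiltonian")
  ee <- exciton_eigenstates(H)
  analytic <- sort(12000 + 2 * J1 * cos(2 * pi * (0:(ns - 1)) / ns))
  expect_equal(ee$values, analytic, tolerance = 1e-10)
})

test_that("eigen-decomposition reconstructs J and rotations leave it invariant", {
  H <- chain3_system()$H
  ee <- exciton_eigenstates(H)
  expect_lt(max(abs(ee$vectors %*% diag(ee$values) %*% t(ee$vectors) - H$J)),
            1e-8)
  rot <- rotate_geometry(H$geometry, 1.1)
  Hrot <- coupling_matrix(rot)
  expect_equal(eigen(Hrot$J, symmetric = TRUE, only.values = TRUE)$values,
               eigen(H$J, symmetric = TRUE, only.values = TRUE)$values,
               tolerance = 1e-8)
})

test_that("default B850 ring has a dark lowest state below a bright degenerate pair", {
  geom <- build_nanoarray("chain", n_rings = 1)
  ee <- exciton_eigenstates(coupling_matrix(geom))
  expect_lt(ee$osc_strength[1], 1e-6)
  expect_equal(ee$values[2], ee$values[3], tolerance = 1e-8)
  # the degenerate pair carries (essentially all of) the maximal strength
  expect_true(which.max(ee$osc_strength) %in% 2:3)
  expect_equal(ee$osc_strength[2], ee$osc_strength[3], tolerance = 1e-6)
  # oscillator strengths sum to the pigment count (sum rule)
  expect_equal(sum(ee$osc_strength), 16, tolerance = 1e-10)
})

test_that("linear-dispersion bath matches the printed dispersion and sum rule", {
  bath <- make_bath("linear_dispersion", omega0 = 1670, W = 0.1, S = 0.5,
                    n_sites = 16)
  expect_length(bath$omega, 16)
  expect_equal(range(bath$omega), 1670 * c(0.9, 1.1))
  expect_equal(sort(unique(round(bath$q / (2 * pi / 16)))), -7:8)
  expect_equal(sum(bath$g^2 * bath$omega) / 16, 0.5 * 1670,
               tolerance = 1e-12)
  expect_true(all(bath$omega > 0))
})

test_that("zero bandwidth collapses to an Einstein bath", {
  bath <- make_bath("linear_dispersion", W = 0)
  expect_true(all(bath$omega == 1670))
})

test_that("Drude discretization preserves the reorganization energy", {
  bath <- make_bath("drude", lambda_D = 220, gamma_D = 80, n_modes = 200)
  analytic <- stats::integrate(function(w)
    (1 / pi) * 2 * 220 * 80 / (w^2 + 80^2), 0, 100 * 80)$value
  expect_equal(reorganization_energy(bath), analytic, tolerance = 0.01)
  expect_true(all(bath$omega > 0))
})

test_that("mode tables are parsed and bad rows are reported", {
  path <- withr::local_tempfile(lines = c(
    "# omega_cm1  huang_rhys", "750 0.2", "1200 0.15"))
  bath <- make_bath("mode_table", path = path, n_sites = 16)
  expect_equal(bath$omega, c(750, 1200))
  expect_equal(reorganization_energy(bath), 750 * 0.2 + 1200 * 0.15)
  bad <- withr::local_tempfile(lines = c("750 0.2", "-5 0.1"))
  expect_error(make_bath("mode_table", path = bad, n_sites = 16), "row 2")
})

test_that("calibration puts the bright transition at the target wavelength", {
  C <- calibrate_dipole_strength(target_nm = 850)
  geom <- build_nanoarray("chain", n_rings = 1)
  ee <- exciton_eigenstates(coupling_matrix(geom, dipole_strength = C))
  expect_equal(ee$values[2], nm_to_cm1(850), tolerance = 1e-6)
  expect_equal(C, 135.88, tolerance = 1e-3)
})
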
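# shared small systems; everything is built in code, nothing is stored

# a one-ring system with a 2-site "ring": two pigments with hand-set
# positions/dipoles, for checking the point-dipole orientation factors
make_pair_geometry <- function(pos1, pos2, dip1, dip2) {
  ring <- structure(list(
    n_sites = 2L,
    positions = rbind(pos1, pos2),
    dipoles = rbind(dip1 / sqrt(sum(dip1^2)), dip2 / sqrt(sum(dip2^2))),
    ring_center = (pos1 + pos2) / 2,
    radius = sqrt(sum((pos1 - pos2)^2)) / 2,
    site_energy = 0), class = "ring_geometry")
  structure(list(rings = list(ring), layout = "chain", spacing = NA_real_,
                 lattice_index = matrix(1L), central_ring = 1L,
                 centers = matrix((pos1 + pos2) / 2, 1),
                 n_sites_per_ring = 2L), class = "nanoarray")
}

# small two-ring system with few sites: cheap full-pipeline checks
small_system <- function(n_rings = 2, n_sites = 4, S = 0.5) {
  ring <- build_b850_ring(n_sites = n_sites, radius = 1, site_energy = 12000)
  geom <- build_nanoarray("chain", n_rings = n_rings, spacing = 6,
                          ring_template = ring)
  H <- coupling_matrix(geom, site_energy = 12000)
  bath <- make_bath("linear_dispersion", S = S, n_sites = n_sites)
  list(geom = geom, H = H, bath = bath)
}

# default 3-ring chain used by several dynamical tests
chain3_system <- function(S = 0.5) {
  geom <- build_nanoarray("chain", n_rings = 3)
  list(geom = geom, H = coupling_matrix(geom),
       bath = make_bath("linear_dispersion", S = S))
}

# random normalized D1 state for a given system
random_d1_state <- function(N, nq, seed = 1, lam_sd = 0.3) {
  set.seed(seed)
  al <- complex(real = stats::rnorm(N), imaginary = stats::rnorm(N))
  al <- al / sqrt(sum(Mod(al)^2))
  lam <- matrix(complex(real = stats::rnorm(N * nq, sd = lam_sd),
                        imaginary = stats::rnorm(N * nq, sd = lam_sd)), N, nq)
  structure(list(alpha = al, lambda = lam, time = 0), class = "d1_state")
}
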
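#' Frenkel-exciton coupling matrix from point-dipole interactions
#'
#' Builds the N x N exciton Hamiltonian J for a nanoarray. Off-diagonal
#' elements follow the point-dipole approximation
#' \deqn{J_{mn} = C [ d_m \cdot d_n - 3 (d_m \cdot \hat r)(d_n \cdot \hat r) ] / r^3}
#' with r the inter-pigment distance (nm) and C the dipole strength in
#' cm^-1 nm^3. Diagonal elements are the (uniform) site energy. Optionally the
#' intra-ring nearest- and next-nearest-neighbour couplings can be overridden
#' with fixed values, mirroring how literature B850 couplings are often
#' specified.
#'
#' @param geom a `nanoarray`
#' @param dipole_strength C, cm^-1 nm^3; the default is calibrated by
#'   [calibrate_dipole_strength()] so the bright intra-ring transition of the
#'   default ring falls at 850 nm
#' @param site_energy diagonal site energy, cm^-1
#' @param nn_override,nnn_override optional fixed values (cm^-1) replacing
#'   every intra-ring nearest/next-nearest-neighbour coupling
#' @return an object of class `exciton_hamiltonian`: fields `J` (N x N,
#'   cm^-1), `n_rings`, `n_sites_per_ring`, `geometry`
#' @export
coupling_matrix <- function(geom, dipole_strength = 135.88,
                            site_energy = 12500,
                            nn_override = NULL, nnn_override = NULL) {
  if (dipole_strength <= 0) stop("dipole_strength must be positive")
  pos <- pigment_positions(geom)
  dip <- pigment_dipoles(geom)
  N <- nrow(pos)
  ns <- geom$n_sites_per_ring
  nr <- length(geom$rings)

  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  diag(r2) <- 1  # placeholder, diagonal overwritten below
  if (any(r2[upper.tri(r2)] == 0)) stop("coincident pigments (r = 0)")
  r <- sqrt(r2)

  dd <- dip %*% t(dip)
  # projection of each dipole on each unit separation vector
  pm <- (dip[, 1] * dx + dip[, 2] * dy + dip[, 3] * dz) / r    # d_m . rhat
  pn <- -t(pm)                                                  # d_n . rhat
  # rhat defined from n to m; kappa is sign-consistent either way
  J <- dipole_strength * (dd - 3 * pm * pn) / r^3
  J <- (J + t(J)) / 2
  diag(J) <- site_energy

  if (!is.null(nn_override) || !is.null(nnn_override)) {
    for (rr in seq_len(nr)) {
      off <- (rr - 1) * ns
      for (n in seq_len(ns)) {
        if (!is.null(nn_override)) {
          m <- n %% ns + 1
          J[off + n, off + m] <- J[off + m, off + n] <- nn_override
        }
        if (!is.null(nnn_override)) {
          m <- (n + 1) %% ns + 1
          J[off + n, off + m] <- J[off + m, off + n] <- nnn_override
        }
      }
    }
  }

  structure(list(J = J, n_rings = nr, n_sites_per_ring = ns,
                 geometry = geom),
            class = "exciton_hamiltonian")
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat(sprintf("exciton Hamiltonian: %d rings x %d sites (N = %d)\n",
              x$n_rings, x$n_sites_per_ring, nrow(x$J)))
  ns <- x$n_sites_per_ring
  if (ns >= 3)
    cat(sprintf("intra-ring J(1,2) = %.1f cm^-1, J(1,3) = %.1f cm^-1\n",
                x$J[1, 2], x$J[1, 3]))
  invisible(x)
}

#' Exciton eigenstates, transition dipoles and oscillator strengths
#'
#' Diagonalizes J (or one intra-ring block) and attaches per-state transition
#' dipole vectors \eqn{\mu_k = \sum_n c_k(n) d_n} and oscillator strengths
#' \eqn{|\mu_k|^2} in units of the monomer dipole strength.
#'
#' @param H an `exciton_hamiltonian`
#' @param ring if non-NULL, diagonalize only the intra-ring block of that ring
#' @return list with `values` (ascending, cm^-1), `vectors` (columns,
#'   orthonormal), `mu` (n_states x 3), `osc_strength`
#' @export
exciton_eigenstates <- function(H, ring = NULL) {
  ns <- H$n_sites_per_ring
  if (is.null(ring)) {
    J <- H$J
    dip <- pigment_dipoles(H$geometry)
  } else {
    sel <- (ring - 1) * ns + seq_len(ns)
    J <- H$J[sel, sel]
    dip <- H$geometry$rings[[ring]]$dipoles
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  mu <- t(vecs) %*% dip
  list(values = vals, vectors = vecs, mu = mu,
       osc_strength = rowSums(mu^2))
}

#' Calibrate the point-dipole strength to a target bright-band wavelength
#'
#' Solves for the dipole strength C such that the degenerate bright
#' (second-lowest) exciton transition of a single default ring falls at
#' `target_nm`. The bright energy is linear in C at fixed geometry, so the
#' solution is direct.
#'
#' @param ring a `ring_geometry`
#' @param site_energy diagonal site energy, cm^-1
#' @param target_nm target bright-state absorption wavelength, nm
#' @return dipole strength, cm^-1 nm^3
#' @export
calibrate_dipole_strength <- function(ring = build_b850_ring(),
                                      site_energy = 12500,
                                      target_nm = 850) {
  geom <- build_nanoarray("chain", n_rings = 1, ring_template = ring)
  bright_at <- function(C) {
    H <- coupling_matrix(geom, dipole_strength = C, site_energy = site_energy)
    ee <- exciton_eigenstates(H)
    ee$values[2]
  }
  # bright energy = site_energy + C * slope
  slope <- (bright_at(100) - site_energy) / 100
  (nm_to_cm1(target_nm) - site_energy) / slope
}

#' Discrete phonon bath for one B850 ring
#'
#' Three construction schemes:
#' \describe{
#'   \item{linear_dispersion}{Ns modes on the momentum grid
#'     q = 2*pi*nq/Ns, nq = -Ns/2+1, ..., Ns/2, with
#'     omega_q = omega0 * (1 + W (2|q|/pi - 1)) and a uniform coupling g
#'     fixed by the Huang-Rhys sum rule (1/Ns) sum_q g_q^2 omega_q = S omega0.}
#'   \item{drude}{n_modes from density-weighted discretization of the Drude
#'     spectral density J(w) = 2 lambda_D w gamma_D / (w^2 + gamma_D^2),
#'     preserving the reorganization energy lambda_D.}
#'   \item{mode_table}{frequencies (cm^-1) and Huang-Rhys factors read from a
#'     two-column text file; '#' comments allowed.}
#' }
#' Every ring carries an independent, identical copy of this bath.
#'
#' @param scheme one of `"linear_dispersion"`, `"drude"`, `"mode_table"`
#' @param omega0 characteristic phonon frequency, cm^-1
#' @param W fractional bandwidth of the linear dispersion
#' @param S Huang-Rhys factor
#' @param n_sites Ns, sites per ring (also mode count for linear dispersion)
#' @param lambda_D,gamma_D,n_modes,omega_max Drude reorganization energy
#'   (cm^-1), cutoff (cm^-1), mode count and upper integration limit
#' @param path mode-table file for `scheme = "mode_table"`
#' @return object of class `phonon_bath`: `q` (momenta, rad), `omega`
#'   (cm^-1), `g` (dimensionless couplings), `scheme`, `n_sites`
#' @export
make_bath <- function(scheme = c("linear_dispersion", "drude", "mode_table"),
                      omega0 = 1670, W = 0.1, S = 0.5, n_sites = 16,
                      lambda_D = 200, gamma_D = 100, n_modes = 100,
                      omega_max = NULL, path = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "linear_dispersion") {
    if (omega0 <= 0 || S < 0 || W < 0 || W >= 1)
      stop("linear_dispersion needs omega0 > 0, S >= 0, 0 <= W < 1")
    nq <- seq.int(-n_sites / 2 + 1, n_sites / 2)
    q <- 2 * pi * nq / n_sites
    omega <- omega0 * (1 + W * (2 * abs(q) / pi - 1))
    g2 <- S * omega0 * n_sites / sum(omega)   # uniform g, sum rule exact
    g <- rep(sqrt(g2), length(omega))
  } else if (scheme == "drude") {
    if (lambda_D <= 0 || gamma_D <= 0 || n_modes < 1)
      stop("drude needs lambda_D > 0, gamma_D > 0, n_modes >= 1")
    if (is.null(omega_max)) omega_max <- 100 * gamma_D
    # equal-reorganization discretization: split [0, omega_max] into n_modes
    # slices of equal reorganization-energy weight J(w)/w = 2 lam gam/(w^2+gam^2)
    # whose cumulative integral is (2 lam / pi normalization below)
    lam_of <- function(w) atan(w / gamma_D)           # ~ cumulative weight
    total <- lam_of(omega_max)
    targets <- (seq_len(n_modes) - 0.5) / n_modes * total
    omega <- gamma_D * tan(targets)
    # per-mode reorganization lambda_j = lambda_D/n_modes * (total/(pi/2))
    lam_j <- lambda_D * (total / (pi / 2)) / n_modes
    # Holstein convention below: per-site reorg of mode q is g_q^2 omega_q / Ns
    g <- sqrt(lam_j * n_sites / omega)
    q <- rep(0, n_modes)
  } else {
    if (is.null(path)) stop("mode_table scheme needs a file path")
    tab <- tryCatch(
      utils::read.table(path, header = FALSE, comment.char = "#"),
      error = function(e) stop("could not parse mode table: ", conditionMessage(e)))
    if (ncol(tab) < 2) stop("mode table needs two columns: omega, S")
    bad <- which(!is.finite(tab[[1]]) | !is.finite(tab[[2]]) |
                   tab[[1]] <= 0 | tab[[2]] < 0)
    if (length(bad))
      stop("mode table row ", bad[1], " is invalid (need omega > 0, S >= 0)")
    omega <- as.numeric(tab[[1]])
    # per-mode Huang-Rhys S_j: g chosen so (1/Ns) g_j^2 omega_j = S_j omega_j
    g <- sqrt(as.numeric(tab[[2]]) * n_sites)
    q <- rep(0, length(omega))
  }
  structure(list(q = q, omega = omega, g = g, scheme = scheme,
                 n_sites = as.integer(n_sites)),
            class = "phonon_bath")
}

#' @export
print.phonon_bath <- function(x, ...) {
  cat(sprintf("phonon bath (%s): %d modes, omega in [%.1f, %.1f] cm^-1\n",
              x$scheme, length(x$omega), min(x$omega), max(x$omega)))
  cat(sprintf("effective Huang-Rhys sum (1/Ns) sum g^2 omega = %.2f cm^-1\n",
              sum(x$g^2 * x$omega) / x$n_sites))
  invisible(x)
}

#' Reorganization energy of a bath
#'
#' Per-site reorganization energy sum_q g_q^2 omega_q / Ns, cm^-1; for the
#' linear-dispersion scheme this equals S * omega0 by construction.
#' @param bath a `phonon_bath`
#' @return reorganization energy, cm^-1
#' @export
reorganization_energy <- function(bath) {
  sum(bath$g^2 * bath$omega) / bath$n_sites
}
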
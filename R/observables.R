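#' Debye-Waller overlap matrix of a D1 state
#'
#' S_mn = <lambda_m | lambda_n>: the overlap of the phonon coherent states
#' attached to two sites. The cross term sum_q conj(lambda_mq) lambda_nq is
#' present only for sites on the same ring (each ring has its own bath); the
#' Gaussian damping exp(-|lambda_m|^2/2 - |lambda_n|^2/2) always applies.
#' Diagonal entries are exactly 1.
#'
#' @param lambda complex N x Nq displacement matrix
#' @param H the `exciton_hamiltonian` providing the ring structure
#' @return complex N x N matrix with unit diagonal and |S_mn| <= 1
#' @export
debye_waller_matrix <- function(lambda, H) {
  debye_waller_raw(lambda, H$n_rings, H$n_sites_per_ring)
}

#' Reduced single-exciton density matrix
#'
#' rho_mn = conj(alpha_m) alpha_n S_mn, the trace of the D1 projector over
#' the phonon bath. Diagonal entries are the site populations |alpha_n|^2.
#'
#' @param state a `d1_state`
#' @param H an `exciton_hamiltonian` (ring structure for the overlap factor)
#' @return complex Hermitian N x N matrix of class `density_matrix`
#' @export
reduced_density_matrix <- function(state, H) {
  S <- debye_waller_matrix(state$lambda, H)
  rho <- outer(Conj(state$alpha), state$alpha) * S
  structure(rho, class = c("density_matrix", class(rho)))
}

#' Dipole dot-product metric of a nanoarray
#'
#' M_mn = d_m . d_n for unit transition dipoles; symmetric with unit
#' diagonal. This matrix carries all geometric information entering the
#' superradiance enhancement factor.
#' @param geom a `nanoarray`
#' @return N x N real matrix
#' @export
dipole_metric <- function(geom) {
  d <- pigment_dipoles(geom)
  tcrossprod(d)
}

#' Per-ring exciton populations along a trajectory
#'
#' rho_r(t) = sum over the ring's sites of the density-matrix diagonal,
#' i.e. of |alpha_n|^2.
#' @param traj a `d1_trajectory`
#' @return n_rings x n_snap matrix of populations
#' @export
ring_populations <- function(traj) {
  ns <- traj$H$n_sites_per_ring
  nr <- traj$H$n_rings
  pops <- Mod(traj$alpha)^2
  grp <- rep(seq_len(nr), each = ns)
  out <- rowsum(pops, grp)
  rownames(out) <- paste0("ring", seq_len(nr))
  out
}

#' Mean-square displacement of the exciton
#'
#' MSD(t) = sum_r d_r^2 rho_r(t) with d_r the ring-center distance from the
#' initially excited ring.
#' @param traj a `d1_trajectory`
#' @param origin_ring ring of initial excitation (default: central ring)
#' @return data.frame with columns `time` (fs) and `msd` (nm^2)
#' @export
msd_trace <- function(traj, origin_ring = traj$H$geometry$central_ring) {
  d <- ring_center_distances(traj$H$geometry, origin_ring)
  pops <- ring_populations(traj)
  if (length(d) != nrow(pops)) stop("ring count mismatch")
  data.frame(time = traj$times, msd = as.numeric(d^2 %*% pops))
}

#' Power-law diffusion exponent from an MSD time series
#'
#' Fits log(MSD) against log(t) by least squares on a window. With
#' `crossover = TRUE` a continuous two-segment piecewise-linear fit in
#' log-log space is performed instead, scanning every interior breakpoint
#' and minimizing the total squared residual; the early-time slope, the
#' late-time slope and the crossover time are returned.
#'
#' An exponent gamma = 1 is Fickian diffusion, gamma > 1 superdiffusion,
#' 0 < gamma < 1 subdiffusion.
#'
#' @param time time grid, fs
#' @param msd MSD values, nm^2 (must be positive on the window)
#' @param window `c(t_min, t_max)` fit window, fs; the default starts at
#'   20 fs to exclude the ballistic transient (one phonon period)
#' @param crossover detect a two-segment crossover?
#' @return list: `gamma` (single fit or early segment), `intercept`;
#'   with crossover also `gamma2` and `t_cross` (fs); and the `window` used
#' @export
diffusion_exponent <- function(time, msd, window = c(20, max(time)),
                               crossover = FALSE) {
  sel <- which(time >= window[1] & time <= window[2] & msd > 0 & time > 0)
  if (length(sel) <= 3) stop("fit window must contain more than 3 points")
  lx <- log(time[sel]); ly <- log(msd[sel])
  if (!crossover) {
    fit <- stats::lm.fit(cbind(1, lx), ly)
    return(list(gamma = unname(fit$coefficients[2]),
                intercept = unname(fit$coefficients[1]),
                window = window))
  }
  n <- length(lx)
  lo <- 4L; hi <- n - 3L
  if (hi <= lo) stop("too few points for a two-segment fit")
  best <- NULL; best_rss <- Inf
  for (bp in lo:hi) {
    xb <- lx[bp]
    # continuous hinge parameterization: y = a + b x + c (x - xb)_+
    hinge <- pmax(lx - xb, 0)
    fit <- stats::lm.fit(cbind(1, lx, hinge), ly)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      co <- fit$coefficients
      best <- list(gamma = unname(co[2]),
                   gamma2 = unname(co[2] + co[3]),
                   intercept = unname(co[1]),
                   t_cross = exp(xb), window = window)
    }
  }
  best
}

#' Coherence size of a density matrix
#'
#' L_rho = (sum_mn |rho_mn|)^2 / (N sum_mn |rho_mn|^2): the number of
#' pigments over which the density matrix is coherently spread, between 1/N
#' (a single occupied site) and N (a uniform fully coherent matrix).
#' @param rho density matrix (complex N x N)
#' @return L_rho, in pigment units
#' @export
coherence_size <- function(rho) {
  a <- Mod(rho)
  s2 <- sum(a^2)
  if (s2 == 0) stop("all-zero density matrix")
  sum(a)^2 / (nrow(rho) * s2)
}

#' Superradiance enhancement factor
#'
#' L_s = sum_mn M_mn rho_mn: the aggregate radiative rate in units of the
#' monomer rate. Real by Hermitian symmetry; the imaginary residual is
#' checked and discarded.
#' @param rho density matrix
#' @param M dipole metric from [dipole_metric()]
#' @return L_s (dimensionless)
#' @export
superradiance <- function(rho, M) {
  if (!all(dim(rho) == dim(M))) stop("shape mismatch between rho and M")
  v <- sum(M * rho)
  if (abs(Im(v)) > 1e-8 * max(1, abs(Re(v))))
    warning("unexpected imaginary part in L_s: ", format(Im(v)))
  Re(v)
}

#' Coherence-size and superradiance time series of a trajectory
#'
#' @param traj a `d1_trajectory`
#' @return data.frame: `time` (fs), `L_rho`, `L_s`
#' @export
delocalization_trace <- function(traj) {
  M <- dipole_metric(traj$H$geometry)
  n <- length(traj$times)
  lr <- numeric(n); ls <- numeric(n)
  for (i in seq_len(n)) {
    rho <- reduced_density_matrix(trajectory_state(traj, i), traj$H)
    lr[i] <- coherence_size(rho)
    ls[i] <- Re(sum(M * rho))
  }
  data.frame(time = traj$times, L_rho = lr, L_s = ls)
}

#' Absorption spectrum from wavepacket autocorrelation
#'
#' Prepares the dipole-allowed initial state for each field polarization
#' (alpha proportional to the dipole projections, phonon vacuum), propagates
#' it with the D1 dynamics, and Fourier-transforms the damped autocorrelation
#' \deqn{A(\omega) \propto Re \int_0^T e^{i\omega t - t/\tau} <\Psi(0)|\Psi(t)> dt}
#' summed over x, y, z polarizations. The spectrum is normalized to unit
#' peak.
#'
#' @param H an `exciton_hamiltonian` (single ring or small array)
#' @param bath a `phonon_bath`
#' @param damping phenomenological dephasing time tau, fs
#' @param t_max autocorrelation length, fs
#' @param dt integration step, fs
#' @param freq_range c(min, max) output frequency range, cm^-1
#' @param n_freq number of output frequencies
#' @return data.frame: `freq` (cm^-1), `intensity` (unit peak)
#' @export
absorption_spectrum <- function(H, bath, damping = 50, t_max = 500,
                                dt = 0.05,
                                freq_range = NULL, n_freq = 600) {
  if (damping <= 0) stop("damping time tau must be positive")
  dip <- pigment_dipoles(H$geometry)
  N <- nrow(dip)
  nq <- length(bath$omega)
  if (is.null(freq_range)) {
    ev <- range(eigen(H$J, symmetric = TRUE, only.values = TRUE)$values)
    freq_range <- c(ev[1] - 800, ev[2] + 800)
  }
  freq <- seq(freq_range[1], freq_range[2], length.out = n_freq)
  total <- numeric(n_freq)
  weight <- 0
  for (pol in 1:3) {
    a0 <- dip[, pol]
    w2 <- sum(a0^2)
    if (w2 < 1e-12) next
    a0n <- a0 / sqrt(w2)
    st <- structure(list(alpha = a0n + 0i,
                         lambda = matrix(0i, N, nq), time = 0),
                    class = "d1_state")
    traj <- propagate(st, H, bath, t_end = t_max, dt = dt,
                      stride_fs = dt * 10)
    # autocorrelation <Psi(0)|Psi(t)>; <0|lambda> = exp(-|lambda|^2/2)
    corr <- vapply(seq_along(traj$times), function(i) {
      sum(Conj(a0n) * traj$alpha[, i] *
            exp(-0.5 * rowSums(Mod(traj$lambda[, , i, drop = FALSE])^2)))
    }, complex(1))
    # restore the gauge phase removed by the propagation frame shift
    corr <- corr * exp(-1i * cm1_to_radfs(traj$energy_shift) * traj$times)
    damp <- exp(-traj$times / damping)
    dtau <- diff(traj$times[1:2])
    wt <- rep(dtau, length(traj$times))
    wt[c(1, length(wt))] <- dtau / 2       # trapezoidal quadrature
    ph <- exp(1i * outer(cm1_to_radfs(freq), traj$times))
    total <- total + w2 * Re(ph %*% (corr * damp * wt))
    weight <- weight + w2
  }
  data.frame(freq = freq, intensity = as.numeric(total / max(total)))
}
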
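#' Incoherent inter-ring hopping model
#'
#' Classical description of a B850 nanoarray: each ring is one aggregate,
#' excitation hops between nearest-neighbour rings at rate `k` and decays
#' locally at rate `K`. On the hexagonal lattice every interior ring has six
#' neighbours.
#'
#' @param K dissipation rate, 1/ps
#' @param k inter-ring transfer rate, 1/ps
#' @param a ring spacing, nm
#' @param layout `"chain"` or `"hexagonal"`
#' @param n_rings chain length (1D)
#' @param extent half-width of the axial-coordinate rhombus (2D): indices
#'   i, j each run -extent..extent
#' @return object of class `hopping_model`
#' @export
hopping_model <- function(K = 1e-3, k = 0.1, a = 8,
                          layout = c("chain", "hexagonal"),
                          n_rings = 101, extent = 25) {
  layout <- match.arg(layout)
  if (K < 0) stop("K must be >= 0")
  if (k < 0) stop("k must be >= 0")
  if (a <= 0) stop("a must be > 0")
  structure(list(K = K, k = k, a = a, layout = layout,
                 n_rings = as.integer(n_rings), extent = as.integer(extent)),
            class = "hopping_model")
}

#' @export
print.hopping_model <- function(x, ...) {
  size <- if (x$layout == "chain") sprintf("%d rings", x$n_rings)
          else sprintf("(2*%d+1)^2 rings", x$extent)
  cat(sprintf("hopping model (%s, %s): K = %g /ps, k = %g /ps, a = %g nm\n",
              x$layout, size, x$K, x$k, x$a))
  invisible(x)
}

#' Gaussian excitation laser profile
#'
#' A_i = A0 exp(-((i - i0) a)^2 / (2 sigma^2)) on a chain;
#' on the 2D lattice the exponent uses the physical ring-center distance.
#'
#' @param sigma standard deviation of the profile, nm
#' @param A0 amplitude (dimensionless)
#' @param center ring index i0 (1D; default: middle ring) or c(i, j) axial
#'   coordinates (2D; default: origin)
#' @param r_a absorption rate; drops out of normalized distributions
#' @return object of class `laser_profile`
#' @export
laser_profile <- function(sigma, A0 = 1, center = NULL, r_a = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(sigma = sigma, A0 = A0, center = center, r_a = r_a),
            class = "laser_profile")
}

#' Full width at half maximum of a Gaussian profile
#' @param laser a `laser_profile` (or a numeric sigma)
#' @return FWHM = 2 sqrt(2 log 2) sigma, nm
#' @export
laser_fwhm <- function(laser) {
  sigma <- if (inherits(laser, "laser_profile")) laser$sigma else laser
  2 * sqrt(2 * log(2)) * sigma
}

# ring positions (nm) along the chain, centered on the laser center index
chain_positions <- function(model, center = NULL) {
  i0 <- if (is.null(center)) ceiling(model$n_rings / 2) else center
  (seq_len(model$n_rings) - i0) * model$a
}

laser_amplitudes_1d <- function(model, laser) {
  x <- chain_positions(model, laser$center)
  laser$A0 * exp(-x^2 / (2 * laser$sigma^2))
}

# axial lattice of the 2D model: data.frame(i, j, x, y)
hex_lattice <- function(model) {
  g <- expand.grid(i = -model$extent:model$extent,
                   j = -model$extent:model$extent)
  g$x <- model$a * (g$i + g$j / 2)
  g$y <- model$a * g$j * sqrt(3) / 2
  g
}

laser_amplitudes_2d <- function(model, laser) {
  g <- hex_lattice(model)
  c0 <- if (is.null(laser$center)) c(0, 0) else laser$center
  x0 <- model$a * (c0[1] + c0[2] / 2)
  y0 <- model$a * c0[2] * sqrt(3) / 2
  d2 <- (g$x - x0)^2 + (g$y - y0)^2
  matrix(laser$A0 * exp(-d2 / (2 * laser$sigma^2)),
         nrow = 2 * model$extent + 1)
}

# scaled sinh: sinh(x lam) * exp(-x lam) = (1 - exp(-2 x lam)) / 2
sh_scaled <- function(x, lam) 0.5 * (1 - exp(-2 * x * lam))

#' Stationary excitation distribution on a 1D chain (closed form)
#'
#' Evaluates the analytic stationary solution of the driven chain master
#' equation: the lattice Green's function of (K + 2k) p_i - k(p_{i-1} +
#' p_{i+1}) = r_a A_i with absorbing ends, built from hyperbolic functions of
#' lambda = arccosh((K + 2k) / (2k)). The evaluation uses exponentially
#' scaled running sums so arbitrarily long chains cannot overflow.
#'
#' @param model a `hopping_model` with `layout = "chain"` and K > 0
#' @param laser a `laser_profile`
#' @return list: `p` (unnormalized), `p_norm` (scaled to 1 at the laser
#'   center), `positions` (nm), `lambda` (decay constant per ring)
#' @export
stationary_1d <- function(model, laser) {
  if (model$layout != "chain") stop("stationary_1d needs a chain model")
  if (model$k <= 0) stop("stationary_1d needs a transfer rate k > 0")
  if (model$K <= 0)
    stop("the stationary solution diverges for K = 0 (no dissipation)")
  A <- laser$r_a * laser_amplitudes_1d(model, laser)
  n <- model$n_rings
  lam <- acosh((model$K + 2 * model$k) / (2 * model$k))
  elam <- exp(-lam)

  # forward sum  S1_i = sum_{j<=i} sh(j) A_j e^{(j-i)lam}
  s1 <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc * elam + sh_scaled(i, lam) * A[i]
    s1[i] <- acc
  }
  # backward sum S2_i = sum_{j>i} sh(n+1-j) A_j e^{(i-j)lam}
  s2 <- numeric(n)
  acc <- 0
  for (i in seq.int(n - 1, 1)) {
    acc <- (acc + sh_scaled(n - i, lam) * A[i + 1]) * elam
    s2[i] <- acc
  }
  i <- seq_len(n)
  p <- exp(-lam) * (sh_scaled(n + 1 - i, lam) * s1 + sh_scaled(i, lam) * s2) /
    (model$k * sh_scaled(1, lam) * sh_scaled(n + 1, lam))
  i0 <- if (is.null(laser$center)) ceiling(n / 2) else laser$center
  list(p = p, p_norm = p / p[i0],
       positions = chain_positions(model, laser$center), lambda = lam)
}

#' Stationary excitation distribution on the 2D hexagonal lattice
#'
#' Solves the sparse linear system (K + 6k) p - k sum_neighbours p = r_a A
#' on the finite axial rhombus; boundary rings simply lack the missing
#' neighbour terms.
#'
#' @param model a `hopping_model` with `layout = "hexagonal"` and K > 0
#' @param laser a `laser_profile`
#' @return list: `p` (matrix over axial indices), `p_norm`, `lattice`
#'   (data.frame i, j, x, y), `residual` (max |residual| of the solve)
#' @export
stationary_2d <- function(model, laser) {
  if (model$layout != "hexagonal") stop("stationary_2d needs a hexagonal model")
  if (model$K <= 0) stop("K = 0 makes the stationary system singular")
  A <- laser$r_a * laser_amplitudes_2d(model, laser)
  n1 <- 2 * model$extent + 1
  idx <- function(i, j) (j - 1) * n1 + i   # column-major over (i, j) grid
  ii <- rep(seq_len(n1), n1)
  jj <- rep(seq_len(n1), each = n1)
  nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(-1, 1), c(1, -1))
  tri_i <- list(); tri_j <- list()
  for (d in nb) {
    i2 <- ii + d[1]; j2 <- jj + d[2]
    ok <- i2 >= 1 & i2 <= n1 & j2 >= 1 & j2 <= n1
    tri_i[[length(tri_i) + 1]] <- idx(ii[ok], jj[ok])
    tri_j[[length(tri_j) + 1]] <- idx(i2[ok], j2[ok])
  }
  M <- Matrix::sparseMatrix(i = c(idx(ii, jj), unlist(tri_i)),
                            j = c(idx(ii, jj), unlist(tri_j)),
                            x = c(rep(model$K + 6 * model$k, n1 * n1),
                                  rep(-model$k, length(unlist(tri_i)))),
                            dims = c(n1 * n1, n1 * n1))
  b <- as.numeric(A)
  p <- as.numeric(Matrix::solve(M, b))
  res <- max(abs(as.numeric(M %*% p) - b))
  g <- hex_lattice(model)
  pm <- matrix(p, nrow = n1)
  c0 <- if (is.null(laser$center)) c(0, 0) else laser$center
  icent <- idx(c0[1] + model$extent + 1, c0[2] + model$extent + 1)
  list(p = pm, p_norm = pm / p[icent], lattice = g, residual = res)
}

# exponentially scaled modified Bessel kernel e^{-x} I_nu(x), nu = 0..n_max,
# with n_max chosen so the neglected tail is below tol (hard capped)
bessel_kernel <- function(x, tol = 1e-14) {
  n_cap <- ceiling(10 * (x + 20))
  n_max <- min(ceiling(x + 12 * sqrt(x + 1) + 12), n_cap)
  v <- besselI(x, 0:n_max, expon.scaled = TRUE)
  keep <- which(v > tol * max(v, 1e-300))
  v[seq_len(max(keep))]
}

#' Time-dependent excitation probabilities on a chain (Bessel propagator)
#'
#' Evaluates the free-relaxation solution
#' p_i(t) = e^{-(K + 2k) t} sum_m p_m(0) I_{i-m}(2kt) with modified Bessel
#' functions, truncating the sum where the exponentially scaled Bessel
#' weights fall below `tol`.
#'
#' @param p0 initial probabilities (finite support on the stored chain)
#' @param model a chain `hopping_model`
#' @param t time, ps (scalar)
#' @param tol relative truncation tolerance for the Bessel sum
#' @return vector p(t) on the same ring grid
#' @export
dynamics_1d <- function(p0, model, t, tol = 1e-14) {
  if (t < 0) stop("t must be >= 0")
  if (t == 0) return(p0)
  x <- 2 * model$k * t
  kern <- bessel_kernel(x, tol)
  n <- length(p0)
  out <- kern[1] * p0
  for (d in seq_len(length(kern) - 1)) {
    w <- kern[d + 1]
    out[seq_len(n - d)] <- out[seq_len(n - d)] + w * p0[seq_len(n - d) + d]
    out[seq_len(n - d) + d] <- out[seq_len(n - d) + d] + w * p0[seq_len(n - d)]
  }
  exp(-model$K * t) * out
}

#' Time-dependent excitation probabilities on the hexagonal lattice
#'
#' Triple Bessel-sum propagator for the six-neighbour master equation with
#' no driving: the hexagonal walk factorizes into three independent 1D walks
#' along the lattice directions, giving
#' p_ij(t) = e^{-(K + 6k) t} sum_{lmn} p_lm(0) I_{i-n-l} I_{j+n-m} I_n (2kt).
#'
#' @param p0 initial probability matrix over the axial rhombus
#' @param model a hexagonal `hopping_model`
#' @param t time, ps (scalar)
#' @param tol relative truncation tolerance
#' @return matrix p(t) over the same lattice
#' @export
dynamics_2d <- function(p0, model, t, tol = 1e-14) {
  if (t < 0) stop("t must be >= 0")
  if (t == 0) return(p0)
  x <- 2 * model$k * t
  kern <- bessel_kernel(x, tol)
  nk <- length(kern) - 1
  off <- -nk:nk
  kv <- kern[c(rev(seq_len(nk) + 1), 1, seq_len(nk) + 1)]  # I_{|n|}, n = off
  # kernel over displacement (di, dj): sum_n I_{di-n} I_{dj+n} I_n
  get <- function(d) ifelse(abs(d) > nk, 0, kv[abs(d) + nk + 1])
  Tk <- matrix(0, 2 * nk + 1, 2 * nk + 1)
  for (n in off) {
    if (kv[n + nk + 1] == 0) next
    Tk <- Tk + kv[n + nk + 1] * outer(get(off - n), get(off + n))
  }
  n1 <- nrow(p0)
  out <- matrix(0, n1, ncol(p0))
  for (di in off) for (dj in off) {
    w <- Tk[di + nk + 1, dj + nk + 1]
    if (w < tol * max(Tk)) next
    si <- max(1, 1 - di):min(n1, n1 - di)
    sj <- max(1, 1 - dj):min(ncol(p0), ncol(p0) - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + w * p0[si, sj, drop = FALSE]
  }
  exp(-model$K * t) * out
}

#' Direct numerical integration of the hopping master equations
#'
#' Integrates the exact rate equations (driven or free) with a stiff-safe
#' solver. This is the validation oracle for the closed-form stationary and
#' Bessel-propagator solutions.
#'
#' @param model a `hopping_model`
#' @param p0 initial probabilities (vector for chains, matrix for hexagonal)
#' @param laser optional `laser_profile` driving term (NULL: free relaxation)
#' @param times output times, ps
#' @param rtol,atol solver tolerances
#' @return matrix of deSolve output: one row per time, columns = rings
#' @export
ode_oracle <- function(model, p0 = NULL, laser = NULL, times,
                       rtol = 1e-10, atol = 1e-12) {
  if (model$layout == "chain") {
    n <- model$n_rings
    drive <- if (is.null(laser)) numeric(n)
             else laser$r_a * laser_amplitudes_1d(model, laser)
    if (is.null(p0)) p0 <- numeric(n)
    rhs <- function(t, p, parms) {
      flux <- c(p[-1], 0) + c(0, p[-n])
      list(drive - (model$K + 2 * model$k) * p + model$k * flux)
    }
    out <- deSolve::ode(y = p0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    unname(out[, -1, drop = FALSE])
  } else {
    n1 <- 2 * model$extent + 1
    drive <- if (is.null(laser)) matrix(0, n1, n1)
             else laser$r_a * laser_amplitudes_2d(model, laser)
    if (is.null(p0)) p0 <- matrix(0, n1, n1)
    shift <- function(m, di, dj) {
      out <- matrix(0, n1, n1)
      si <- max(1, 1 - di):min(n1, n1 - di)
      sj <- max(1, 1 - dj):min(n1, n1 - dj)
      out[si + di, sj + dj] <- m[si, sj]
      out
    }
    nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(-1, 1), c(1, -1))
    rhs <- function(t, p, parms) {
      pm <- matrix(p, n1, n1)
      flux <- Reduce(`+`, lapply(nb, function(d) shift(pm, d[1], d[2])))
      list(as.numeric(drive - (model$K + 6 * model$k) * pm + model$k * flux))
    }
    out <- deSolve::ode(y = as.numeric(p0), times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    unname(out[, -1, drop = FALSE])
  }
}

#' Laser-prepared initial condition for free relaxation
#'
#' The paper-style preparation "switch the laser on, then off immediately":
#' p(0) proportional to the Gaussian profile, normalized to unit total
#' probability.
#' @param model a `hopping_model`
#' @param laser a `laser_profile`
#' @return vector (chain) or matrix (hexagonal)
#' @export
initial_excitation <- function(model, laser) {
  if (model$layout == "chain") {
    A <- laser_amplitudes_1d(model, laser)
    A / sum(A)
  } else {
    A <- laser_amplitudes_2d(model, laser)
    A / sum(A)
  }
}

#' Exciton diffusion length from a stationary distribution
#'
#' Ld = sigma_s - sigma: the standard deviation of ring position under the
#' normalized stationary excitation distribution, minus the SD of the
#' exciting laser profile.
#'
#' @param stationary result of [stationary_1d()] (or a list with `p` and
#'   `positions`)
#' @param laser the `laser_profile` used
#' @return list: `Ld` (nm), `sigma_s` (nm), `sigma` (nm)
#' @export
diffusion_length <- function(stationary, laser) {
  p <- as.numeric(stationary$p)
  tot <- sum(p)
  if (tot <= 0) stop("stationary field has zero total probability")
  x <- as.numeric(stationary$positions)
  mu <- sum(x * p) / tot
  sigma_s <- sqrt(sum((x - mu)^2 * p) / tot)
  list(Ld = sigma_s - laser$sigma, sigma_s = sigma_s, sigma = laser$sigma)
}
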
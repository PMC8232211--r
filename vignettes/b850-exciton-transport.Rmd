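---
title: "Quantum and classical exciton transport in B850 nanoarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum and classical exciton transport in B850 nanoarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonsim)
```

# The physical problem

The light-harvesting 2 (LH2) complex of purple bacteria carries a ring of 16
tightly packed bacteriochlorophyll *a* pigments — the B850 ring — whose
strong excitonic couplings delocalize an absorbed photon over several
molecules. Engineered arrays of such rings transport excitation energy over
tens of nanometres. This package simulates that transport in two
complementary ways:

* a **fully quantum route**: Davydov D1 variational dynamics for the
  Holstein exciton–phonon Hamiltonian of the whole nanoarray, with every
  phonon mode treated explicitly at zero temperature; and
* a **classical route**: nearest-neighbour incoherent hopping between rings,
  with closed-form stationary and time-dependent solutions.

On top of both sits a measurement layer (reduced density matrices, ring
populations, mean-square displacement and anomalous diffusion exponents,
coherence size, superradiance, absorption spectra) and an adaptive fractal
analysis (AFA) module for the Hurst exponents of population time series.

# The quantum model

## Hamiltonian

With $\hbar = 1$, energies in cm$^{-1}$, time in fs and distances in nm, the
Holstein Hamiltonian is

$$\hat H = \sum_{r_1 r_2}\sum_{mn} J_{mn}^{r_1 r_2}
  \hat a^\dagger_{m r_1} \hat a_{n r_2}
  + \sum_r \sum_q \omega_q \hat b^\dagger_{qr} \hat b_{qr}
  - \frac{1}{\sqrt{N_s}} \sum_{r n q} g_q \omega_q\,
    \hat a^\dagger_{nr}\hat a_{nr}
    \big(e^{iqn} \hat b_{qr} + e^{-iqn}\hat b^\dagger_{qr}\big).$$

Each ring carries its own independent copy of the bath. The exciton coupling
matrix $J$ is built from the point-dipole interaction
$J_{mn} = C\,[\,d_m\!\cdot\!d_n - 3 (d_m\!\cdot\!\hat r)(d_n\!\cdot\!\hat r)\,]/r^3$
over all pigment pairs, with unit transition dipoles $d$ from the idealized
ring geometry and a single strength constant $C$.

## Trial state and equations of motion

The Davydov D1 Ansatz attaches an independent coherent-state displacement
field to every site amplitude:

$$|\Psi(t)\rangle = \sum_{rn} \alpha_{n}^{r}(t)\, \hat a^\dagger_{nr}\,
  e^{\sum_q \lambda^r_{nq}(t) \hat b^\dagger_{qr} - \mathrm{c.c.}} |0\rangle.$$

Displacements of a site in *other* rings' baths are identically zero, which
makes inter-ring coherent-state overlaps factor through the phonon vacuum —
exactly the $\delta_{r_1 r_2}$ structure of the Debye–Waller factor used in
the density matrix. Projecting the Schrödinger residual on the tangent space
of this manifold (the Dirac–Frenkel condition) gives, after eliminating the
implicit couplings between the $\dot\lambda$ equations,

$$i\dot\alpha_j = \sum_k J_{jk} S_{jk} \alpha_k
  - \alpha_j\,\mathrm{Re}(\lambda_j^\dagger \kappa_j)
  - \alpha_j\,\frac{\mathrm{Re}(\lambda_j^\dagger R_j)
      - |\lambda_j|^2\,\mathrm{Re}\,G_j}{|\alpha_j|^2},$$

$$i\dot\lambda_{jq} = \omega_q \lambda_{jq} - \kappa_{jq}
  + \frac{R_{jq} - \lambda_{jq} G_j}{|\alpha_j|^2},$$

with $S_{jk}$ the coherent-state overlap, $G_j = \bar\alpha_j\,[(J\circ
S)\alpha]_j$, $R_{jq} = \bar\alpha_j \sum_{k \in \mathrm{ring}(j)} (J\circ
S)_{jk}\alpha_k \lambda_{kq}$ and $\kappa_{jq} = g_q\omega_q
e^{-iqn_j}/\sqrt{N_s}$. Two limits are exact on this manifold and anchor the
test suite: $g = 0$ recovers free-exciton unitary dynamics, and $J$ diagonal
recovers the independent-boson closed form
$\lambda_q(t) = (g_q/\sqrt{N_s})e^{-iqn}(1 - e^{-i\omega_q t})$.

## Numerical choices

* **Integrator.** Fixed-step classical Runge–Kutta (RK4), default
  `dt = 0.05` fs, which resolves the fastest phonon period (about 18 fs at
  $1.1\,\omega_0$) more than 350-fold. Fixed stepping keeps trajectories
  bit-reproducible; adaptive control would trade that away for little gain
  at these smooth time scales. A guard refuses `dt` above $T_{\min}/40$.
* **Gauge frame.** The equations are integrated in a frame shifted by the
  mean site energy. This is a pure global phase for every observable
  ($\rho_{mn}=\bar\alpha_m\alpha_n S_{mn}$ is invariant) but removes the
  dominant 12500 cm$^{-1}$ oscillation from the ODEs and improves norm and
  energy conservation by several orders of magnitude. The shift is stored
  and restored where absolute phases matter (absorption autocorrelation).
* **Regularization.** The $\dot\lambda$ equations are singular on unoccupied
  sites; denominators use $|\alpha_j|^2 + \varepsilon$ with
  $\varepsilon = 10^{-12}$ (config-exposed). Both $G_j$ and $R_{jq}$ carry a
  factor $\bar\alpha_j$, so the regularized term vanishes smoothly where a
  site empties.
* **Conservation monitoring.** Norm and total energy are recorded at every
  snapshot; amplitudes are never renormalized. The run aborts if the norm
  drifts beyond `norm_tol` ($10^{-3}$ by default). Halving `dt` reduces the
  drift about 16-fold, as the tests assert.
* **Degeneracy tie-break.** The optically bright state of a ring is the
  combination of the degenerate second-lowest pair maximizing
  $|\sum_n c_n d_n|^2$ (leading eigenvector of the $2\times 2$ dipole Gram
  matrix); the global phase is fixed by making the largest amplitude real
  positive.

## Geometry, couplings and bath: defaults and what they emulate

The idealized ring has 16 pigments on a 2.3 nm circle, with tangential
dipoles whose in-plane offsets alternate between $10^\circ$ ($\alpha$
pigments) and $170^\circ$ ($\beta$ pigments), so adjacent dipoles point in
nearly opposite directions, as in the LH2 crystal structure. This
reproduces the essential exciton-band structure: an optically dark lowest
state and a degenerate bright pair just above it carrying an oscillator
strength of $\sim N_s/2$ monomer units. Arrays use an 8.0 nm center-to-center
spacing (1D chains and 2D hexagonal layouts); all rings are coplanar and
identical, with no structural or energetic disorder.

The dipole strength $C$ is the one genuinely free constant: published
coupling tables for B850 derive from crystal-structure quantum chemistry
that an idealized geometry cannot reproduce. We fix
$C = 135.88$ cm$^{-1}$nm$^3$ by requiring the bright transition of a single
ring to sit at 850 nm given a 12500 cm$^{-1}$ site energy
(`calibrate_dipole_strength()` recomputes this in one step). The resulting
intra-ring nearest-neighbour couplings are 352–376 cm$^{-1}$; inter-ring
couplings at 8 nm spacing are a few cm$^{-1}$. A config hook can override
intra-ring nearest/next-nearest couplings with fixed literature values.

The default bath is the 16-mode linear dispersion
$\omega_q = \omega_0[1 + W(2|q|/\pi - 1)]$ on the momentum grid
$q = 2\pi n_q/16$, $n_q = -7,\dots,8$, with $\omega_0 = 1670$ cm$^{-1}$,
$W = 0.1$, and a uniform coupling $g$ fixed by the Huang–Rhys sum rule
$(1/N_s)\sum_q g_q^2\omega_q = S\omega_0$ with $S = 0.5$ — the sum rule
pins only the total, and a uniform split is the least-informative choice.
A Drude discretizer (equal reorganization-energy slices, preserving
$\lambda_D$) and a plain-text mode-table reader cover the other two bath
families.

# Observables

The reduced density matrix is
$\rho_{mn} = \bar\alpha_m \alpha_n S_{mn}$ with the Debye–Waller factor
$S_{mn} = \exp[\sum_q \bar\lambda_{mq}\lambda_{nq}\delta_{r_1r_2}
- \tfrac12|\lambda_m|^2 - \tfrac12|\lambda_n|^2]$, so diagonal entries are
exactly the site populations. From it:

* ring populations $\rho_r = \sum_{m \in r} \rho_{mm}$ and the MSD
  $\langle x^2\rangle = \sum_r d_r^2 \rho_r$ over ring-center distances;
* the diffusion exponent $\gamma$ from a least-squares fit of
  $\log \mathrm{MSD}$ vs $\log t$. The fit window starts at 20 fs by default
  — one phonon period — to exclude the ballistic transient, and the window
  is always reported with the fit. Crossovers use a continuous two-segment
  (hinge) fit scanning every interior breakpoint;
* the coherence size $L_\rho = (\sum|\rho_{mn}|)^2/(N\sum|\rho_{mn}|^2)$,
  bounded between $1/N$ and $N$ (the printed source formula is ambiguous;
  this standard ratio is the only reading consistent with values of a few
  pigments);
* the superradiance enhancement factor $L_s = \sum_{mn} M_{mn}\rho_{mn}$
  with $M_{mn} = d_m\cdot d_n$;
* absorption spectra from the damped autocorrelation of a dipole-prepared
  wavepacket, $A(\omega) \propto \mathrm{Re}\int_0^T e^{i\omega t - t/\tau}
  \langle\Psi(0)|\Psi(t)\rangle\,dt$, summed over three polarizations with
  trapezoidal quadrature; $\tau$ defaults to 50 fs. The source reports no
  lineshape formula, so this scheme (and $\tau$) are documented knobs and
  only qualitative band positions are claimed.

# The classical hopping model

Treating each ring as one aggregate, excitation hops to nearest neighbours
at rate $k$ and decays locally at rate $K$, driven by a Gaussian laser
profile $A_i = A_0 e^{-((i-i_0)a)^2/2\sigma^2}$. The package provides:

* the closed-form stationary solution of the driven chain — the lattice
  Green's function of hyperbolic functions of
  $\lambda = \operatorname{arccosh}[(K+2k)/2k]$ — evaluated with
  exponentially scaled running sums so 4000-ring chains cannot overflow;
* a sparse linear solve for the stationary hexagonal lattice
  ($(K+6k)p - k\sum_{\rm nb} p = r_a A$, missing neighbours simply absent
  at the boundary);
* Bessel-function propagators for free relaxation,
  $p_i(t) = e^{-(K+2k)t}\sum_m p_m(0) I_{i-m}(2kt)$ in 1D and the triple
  Bessel sum on the hexagonal lattice (the six-direction walk factorizes
  into three independent 1D walks). Exponentially scaled Bessel functions
  avoid overflow, and the sums truncate where the scaled weights fall below
  $10^{-14}$ (hard cap $10(2kt+20)$);
* a stiff-safe direct integrator of the exact rate equations
  (`ode_oracle()`), which validates every closed form above — on every test
  run, not just once;
* the diffusion length $L_d = \sigma_s - \sigma$ from the SD of the
  normalized stationary distribution. Because the stationary solution is a
  convolution of the laser Gaussian with a two-sided exponential kernel of
  decay $\lambda$ per ring, variances add:
  $\sigma_s = \sqrt{\sigma^2 + 2a^2/\lambda^2}$, which the implementation
  reproduces to oracle accuracy. With $K = 10^{-3}$ ps$^{-1}$,
  $k = 0.1$ ps$^{-1}$, $a = 8$ nm and $\sigma = 169.86$ nm this gives
  $L_d = 34.2$ nm; a substantially larger value would require
  $K/k \approx 0.003$. The acceptance suite records this computed value.

Normalized stationary distributions depend only on $K/k$ (asserted to
$10^{-10}$), and with $K = 0$ both propagators conserve total probability.

# Adaptive fractal analysis

AFA partitions a series into windows of odd length $w = 2n+1$ overlapping by
$n+1$ points, fits a polynomial of order $M$ (default 1) in each, and
stitches neighbouring fits with weights ramping linearly from 1 to 0 across
the overlap, producing a globally continuous trend $\nu$. The fluctuation
function $F(w) = [\tfrac1{N}\sum_i (u_i - \nu_i)^2]^{1/2} \sim w^H$ yields
the Hurst exponent as the slope of $\log_2 F$ vs $\log_2 w$; $H > 1$ lies
beyond the fBm/fGn family and signals superdiffusive dynamics. Segmented
fits (fixed boundary at $w = 2^8$, matching a 1 fs sampling grid, or
automatic change-point detection) and a local-slope persistence measure
(`hurst_persistence()`) are provided. $N$ in $F(w)$ is the full trend
length; trajectories are sampled on a uniform 1 fs grid so window sizes map
to femtoseconds.

The companion generator `fbm_generator()` synthesizes exact fractional
Brownian motion by Davies–Harte circulant embedding; the test suite
verifies mean Hurst recovery within $\pm 0.05$ for
$H \in \{0.3, 0.5, 0.8\}$ and $t^{2H}$ variance scaling.

# Problem sizes and what the tests do (and do not) show

The shipped experiments use desk-scale systems: 3-, 5- and 11-ring chains
and the 7-ring hexagonal array, 1–2 ps of dynamics at `dt` = 0.05 fs, and
a 4001-ring classical chain. These reproduce the structure of the study —
superdiffusive MSD growth with $\gamma \approx 1.7$–$1.8$ crossing over to
slower growth within a picosecond, bright-state superradiance
$L_s(0) \approx 8$ decaying as phonons destroy coherence, dark-state
coherence size oscillating about 5 pigments, and Hurst exponents above 1
for windows under 256 fs.

Two caveats delimit what passing tests mean for real LH2 arrays. First, the
idealized geometry with a calibrated single dipole constant yields
inter-ring couplings of only a few cm$^{-1}$, so inter-ring transfer is
slower here than in studies built on crystal-structure coupling tables: the
central-ring population stays near 0.9 after 1 ps, the superdiffusive
crossover sits near 800 fs rather than 600 fs, and the long-time $L_s$
plateau (3.6 at 2 ps on a 3-ring chain) has not yet decayed to the
experimental value of about 2, which emerges in much longer chains and
times. Second, disorder — static energetic and positional — is deliberately
absent in both routes, and the quantum route is strictly zero-temperature
single-excitation dynamics; neither multi-exciton effects nor finite-
temperature displacement sampling (multiple-Davydov extensions) are in
scope. The $L_s$–$L_\rho$ anti-correlation in bright-state runs is asserted
after the first 100 fs; during the initial transient the two measures drop
together.

# Known limitations

* The D1 manifold is variational: it is exact in the two anchor limits but
  approximate in between; no multiple-D1/D2 hierarchy is provided to
  quantify that error.
* Point-dipole couplings degrade at sub-nm separations typical of adjacent
  B850 pigments; the intra-ring override hook exists for exactly that
  reason.
* The hexagonal master-equation domain is an axial rhombus; observables
  near the boundary feel its shape (the tests quantify this).
* The absorption lineshape scheme is a documented substitute for an
  unspecified original; only qualitative comparisons are appropriate.
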
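# excitonsim

Quantum and classical simulation of excitation energy transport in
mesoscale arrays of B850 pigment rings — the 16-bacteriochlorophyll
aggregates of the LH2 antenna complex of purple bacteria. The package is
aimed at researchers in photosynthetic energy transfer and molecular
aggregates who want a self-contained, fully deterministic playground for
exciton–phonon dynamics on 1D chains and 2D hexagonal nanoarrays of rings.

Two transport descriptions are implemented end to end:

**Fully quantum (Davydov D1).** The nanoarray is a Holstein model
(ħ = 1):

    H = Σ J_mn a†_m a_n  +  Σ_rq ω_q b†_qr b_qr
        − (1/√Ns) Σ_rnq g_q ω_q a†_nr a_nr (e^{iqn} b_qr + h.c.)

propagated with the Dirac–Frenkel time-dependent variational principle on
the D1 trial manifold |Ψ⟩ = Σ α_n a†_n exp(Σ λ_nq b†_q − h.c.)|0⟩, which
treats every phonon mode explicitly at zero temperature. The measurement
layer computes the bath-traced density matrix ρ_mn = ᾱ_m α_n S_mn
(S = Debye–Waller overlap), ring populations, MSD(t) = Σ d_r² ρ_r and its
power-law exponent γ (γ > 1: superdiffusion), the coherence size
L_ρ = (Σ|ρ|)²/(N Σ|ρ|²), the superradiance enhancement factor
L_s = Σ (d_m·d_n) ρ_mn, and absorption spectra.

**Classical hopping.** Rings as single aggregates with nearest-neighbour
transfer rate k and dissipation K: closed-form stationary distributions
(hyperbolic lattice Green's function), modified-Bessel time propagators
I_n(2kt) in 1D and their triple-sum hexagonal analogue, a direct
rate-equation oracle, and the exciton diffusion length L_d = σ_s − σ.

An adaptive fractal analysis (AFA) module extracts Hurst exponents from
population time series (overlapping-window linear detrending, F(w) ~ w^H),
with an exact circulant-embedding fractional-Brownian-motion generator for
validation.

## Worked example

```r
library(excitonsim)

geom <- build_nanoarray("chain", n_rings = 3, spacing = 8.0)
H    <- coupling_matrix(geom)                      # point-dipole couplings
H
#> exciton Hamiltonian: 3 rings x 16 sites (N = 48)
#> intra-ring J(1,2) = 375.9 cm^-1, J(1,3) = -43.9 cm^-1

bath <- make_bath("linear_dispersion", omega0 = 1670, W = 0.1, S = 0.5)
exciton_eigenstates(H, ring = 2)$osc_strength[1:4]
#> [1] 0.000 7.784 7.784 0.000        # dark lowest state, bright pair above

st   <- initial_state(H, bath, "bright")           # "Case II" preparation
traj <- propagate(st, H, bath, t_end = 500, dt = 0.05, stride_fs = 1)
traj
#> D1 trajectory: 48 sites, 501 snapshots over 500.0 fs (dt = 0.05 fs)
#> norm drift 6.50e-10, relative energy drift 1.16e-09

m   <- msd_trace(traj)
diffusion_exponent(m$time, m$msd, window = c(20, 500))$gamma
#> [1] 1.764                          # superdiffusive exciton spreading

dl <- delocalization_trace(traj)
c(dl$L_s[1], tail(dl$L_s, 1))
#> [1] 7.78 5.95                      # superradiance decays from ~8

model <- hopping_model(K = 1e-3, k = 0.1, a = 8, layout = "chain",
                       n_rings = 4001)
laser <- laser_profile(sigma = 169.86)             # FWHM 400 nm
diffusion_length(stationary_1d(model, laser), laser)$Ld
#> [1] 34.22924                       # nm, incoherent-hopping regime
```

The initial oscillator strength of the bright pair (7.78 ≈ Ns/2) sets
L_s(0); phonon-induced decoherence then bleeds it away while the MSD grows
superdiffusively (γ ≈ 1.8) for several hundred fs. `run_simulation()` wires
the whole pipeline (geometry → Hamiltonian → bath → propagation →
observables) from a single nested-list or YAML configuration, and
`inst/cli/excitonsim` exposes the same drivers as shell subcommands.

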
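# promodyn

Exact spectral and steady-state analysis of stochastic gene expression
driven by a combinatorial promoter.

Promoters are not two-state switches: transcription factors, DNA
conformations and chromatin marks bind and unbind in a combinatorial,
sometimes energy-consuming interplay. `promodyn` models a single gene's
promoter as a continuous-time Markov chain over the `2^N` combinations of
`N` bound factors, with generator `M` (the chemical master equation
`dφ/dt = Mφ`), and couples it to standard RNA/protein birth–death stages.
It is aimed at quantitative/systems biologists who want exact — not
simulated or moment-closed — answers about promoter-driven expression
noise: which timescales and oscillations the regulatory structure
produces, how they filter through to RNA and protein, what the full RNA
copy-number distribution looks like, and what the dynamics costs in free
energy.

## What it computes

* **Spectral decomposition of the promoter.** Eigenvalues/eigenvectors of
  `M`; autocorrelation and power spectrum of any promoter observable as a
  sum of `2^N − 1` elementary modes: real eigenvalues give Lorentzians
  (relaxations), conjugate pairs give peaks at `ω = |Im λ|` (stochastic
  oscillations) with coherence `Z = |Im λ| / (2π |Re λ|)`. Eigenvalue
  trajectories under concentration sweeps; relaxation of synchronized
  populations (ChIP-style time courses). Closed form for homogeneous
  reaction cycles: `λ_j = k^f(e^{2πij/n} − 1) + k^b(e^{−2πij/n} − 1)`.
* **Noise propagation.** `S_R(ω) = (2γ⟨R⟩ + S_X(ω))/(γ² + ω²)` and the
  analogous protein stage: shot noise plus low-pass filtering; normalized
  variances (CV²) by exact partial-fraction integration.
* **Exact distributions.** Sparse steady-state solve of the joint
  promoter–RNA master equation; RNA marginals, multimodality detection.
* **Energetics.** Dual parameterization by state free energies `G⁰` and
  activation barriers `E⁰` (`k⁰ = ν e^{−(E⁰−G⁰)/k_BT}`); closed systems
  (shared barriers) obey detailed balance, relax to Boltzmann occupancies
  and cannot oscillate; open systems sustain directed cycles whose cost is
  the entropy production `Ė = Σ π_s M_{s's} log(M_{s's}/M_{ss'})` (kBT/s),
  convertible to ATP equivalents per oscillation cycle.
* **Exact Gillespie simulation** (compiled, seed-reproducible) with Welch
  periodograms, used throughout as an independent oracle.
* Ready-made systems: two-state promoter, n-step recruitment cycles, a
  minimal two-TF system whose noise *rises* with TF concentration, a
  16-state energetically closed looped promoter, random ensembles, and a
  stochastic coherence optimizer.

## Worked example

A TF at 5 nM binding with `k_on⁰ = 0.2 /nM/s` and unbinding with
`k_off = 3 /s`; the bound promoter transcribes at 8 /s; RNA lifetime 10 s,
protein lifetime 20 s with one translation per RNA per second:

```r
library(promodyn)
sys <- two_state_system(kon0 = 0.2, conc = 5, koff = 3, rho_off = 0, rho_on = 8)
M   <- build_generator(sys)
stationary_distribution(M)
#>    0    A
#> 0.75 0.25
decompose_generator(M)$values
#> [1]  0+0i -4+0i
```

The promoter is free 75% of the time and relaxes at 4 /s (the single
nonzero eigenvalue: `k_on⁰[A] + k_off = 1 + 3`). Propagating to RNA and
protein:

```r
cas <- cascade_params(gamma = 0.1, beta = 1, gamma_p = 0.05)
nv  <- normalized_variances(sys, cas)
unlist(attr(nv, "means"))
#> mean_X mean_R mean_P
#>      2     20    400
unlist(nv)
#>      cv2_X      cv2_R      cv2_P
#> 3.00000000 0.12317073 0.04415914
```

Mean transcription is `π·ρ = 2 /s`, hence 20 RNA and 400 protein copies.
The RNA noise `CV²_R = 0.123` decomposes into the Poisson floor
`1/⟨R⟩ = 0.05` plus a promoter term: fast switching is strongly averaged
by the 10-s RNA lifetime. The exact distribution shows the same thing —
broader than Poisson but unimodal:

```r
m <- rna_marginal(joint_steady_state(sys, gamma = 0.1))
m[21]            # P(R = 20)
#> [1] 0.05592
```

Energetics of a driven recruitment cycle (3 states, forward 2 /s,
backward 1 /s — a promoter cycling against detailed balance):

```r
energy_consumption_rate(build_generator(homogeneous_cycle_system(3, 2, 1)))$edot_kBT_s
#> [1] 0.6931472       # = ln 2 kBT/s
atp_equivalent_per_cycle(0.05, 40 * 60, 20)
#> [1] 6               # 0.05 kBT/s over a 40-min cycle = 6 ATP
```

The last line is the headline bookkeeping for a cyclically recruiting
eukaryotic-like promoter: a 40-minute occupancy cycle dissipating
0.05 kBT/s costs the equivalent of ~6 ATP hydrolyses per cycle.

See the vignette (`vignettes/promoter-dynamics.Rmd`) for the model,
assumptions, parameter conventions and the two reference regulatory
systems; `inst/cli/promodyn` provides a command-line wrapper
(`example`, `spectrum`, `eigen`, `noise`, `distribution`, `energy`,
`simulate`, `sweep`, `optimize`).

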
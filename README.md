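# flimreach

Lifetime-based FRET analysis for TCSPC fluorescence-lifetime imaging
(FLIM), together with the polymer calculations that frame such
experiments. The package is aimed at cell biologists and microscopists
who measure protein–protein proximity through donor-lifetime quenching
— for example, asking whether a large coiled-coil complex folds back on
itself in vivo — and who need every stage of that measurement to be
testable against simulated data with known ground truth.

## What it computes

**Decay model and fitting.** TCSPC histograms are modeled as a periodic
two-component exponential decay convolved with the instrument response
function (IRF) plus background,

```
I(t) = C [ α e^(−t/τ₁) + (1−α) e^(−t/τ₂) ] ⊛ IRF(t) + D ,
```

with the incomplete-decay wrap across the excitation period handled in
closed form and each bin integrated exactly. `fit_decay()` recovers
`(C, α, τ₁, τ₂, D)` by bound-constrained Poisson maximum likelihood
(weighted least squares optional); `correct_irf_drift()` removes the
few-ps timing drift between IRF measurement and experiment by a sub-bin
grid search that rejects shifts producing unphysically fast components.

**FRET efficiency.** FRET adds an independent de-excitation channel
with time constant τ′, so the donor lifetime drops from τ₀ to
τ = τ₀τ′/(τ₀+τ′), and the efficiency is `E = (τ₀ − τ)/τ₀`
(`fret_efficiency()`, `estimate_group_fret()`).

**Polymer reach.** For a disordered linker of `n` residues at
`r = 0.37` nm/residue, the ideal-chain RMS end-to-end distance is
`r √(n−1)` and the worm-like chain gives
`√(2pL[1 − (p/L)(1 − e^(−L/p))])` with contour length `L = (n−1) r` and
persistence length `p` (`random_walk_rmsd()`, `wlc_rmsd()`, plus a
Monte-Carlo cross-check `mc_random_walk_rmsd()`).

**Synthetic experiments and pipeline.** `simulate_experiment()` writes
complete in-silico FLIM datasets (per-nucleus histograms, IRF, truth
table); `run_pipeline()` takes a dataset directory to per-cell
lifetimes, group means ± 95% CI, Welch t-tests / ANOVA with
Dunnett-style comparisons to a control, and group FRET efficiencies,
emitting TSV tables and a JSON manifest.

## Worked example

```r
library(flimreach)

# How far can a 107-residue disordered span reach?
random_walk_rmsd(linker_spec(107))
#> <chain_estimate> model = random_walk, RMSD = 3.809 nm (contour 39.22 nm)
wlc_rmsd(linker_spec(107, persistence_nm = 0.3))
#> <chain_estimate> model = wlc, RMSD = 4.832 nm (contour 39.22 nm)
wlc_rmsd(linker_spec(107, persistence_nm = 0.7))
#> <chain_estimate> model = wlc, RMSD = 7.344 nm (contour 39.22 nm)

# A 0.10 ns donor quenching is a 3.6% FRET efficiency
fret_efficiency(2.79, 2.69)
#> <fret_quantities> tau0 = 2.79 ns, tau = 2.69 ns -> E = 3.6% (tau' = 75.05 ns)

# Simulate a small two-group experiment and analyze it end to end
dir <- file.path(tempdir(), "demo")
irf <- make_gaussian_irf(300, 2, time_binning(256))
groups <- emulation_groups(n_donor = 10, n_da = 10, photons_mean = 5e5, seed = 1)
simulate_experiment(groups, irf, dir)
run_pipeline(list(dataset_dir = dir, control_group = "donor_only",
                  fit = list(max_shift_ps = 0), seed = 1))
#> <flim_report> 20 cells analyzed, 0 excluded
#>   donor_acceptor   n =  10  tau = 2.686 +/- 0.051 ns (95% CI)
#>   donor_only       n =  10  tau = 2.797 +/- 0.034 ns (95% CI)
#>   FRET donor_acceptor_vs_donor_only E = 4.0%
#>   welch:donor_acceptor_vs_donor_only t = -4.065, df = 15.6, p = 0.000947
```

The ideal-chain estimate says the span reaches under 4 nm on average;
the stiffer worm-like chain widens that to a 4.8–7.3 nm window — both
well short of the >12 nm separation an extended conformation would
demand, which is the geometric argument the FRET measurement then tests.
In the simulated experiment the donor+acceptor group was generated with
a 3.6% ensemble efficiency; the pipeline recovers 4.0% from 10 cells per
group, within the CI scatter shown.

A command-line wrapper over the same functions (subcommands `polymer`,
`simulate`, `fit`, `fret`, `run`) is installed at
`system.file("cli", "flimreach.R", package = "flimreach")`.

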
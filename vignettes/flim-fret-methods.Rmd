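---
title: "Methods: lifetime-based FRET quantification and disordered-linker reach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime-based FRET quantification and disordered-linker reach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimreach)
```

# Scope

`flimreach` implements the quantitative chain behind a lifetime-based
FRET measurement of protein conformation, end to end: polymer estimates
of how far a disordered peptide linker can reach, the TCSPC
photon-arrival forward model and its reconvolution fit, the algebra that
turns donor lifetimes into FRET efficiencies, group statistics, and a
synthetic-data generator that stands in for microscopy data so that
every stage can be validated against known ground truth.

# The reconvolution decay model

A TCSPC histogram records photon arrival times relative to a pulsed
laser (repetition period $T$, default 50 ns, i.e. 20 MHz) in $N$ equal
bins. The expected signal is a two-component exponential decay convolved
with the instrument response function (IRF) plus a flat background:

$$ I(t) \;=\; C\left[\alpha\, e^{-t/\tau_1} + (1-\alpha)\,
   e^{-t/\tau_2}\right] \circledast \mathrm{IRF}(t) \; + \; D . $$

Two components are used because fluorescent-protein decays are
intrinsically multi-exponential and because a partially quenched
ensemble (see below) is genuinely biexponential; more components
over-fit at realistic photon budgets.

Numerical choices, all visible in `forward_model()`:

* **Periodicity.** Under pulsed excitation the decay does not finish
  within one period, so the model lives on a circle. The wrapped decay
  is summed in closed form,
  $\sum_{k\ge 0} e^{-(t+kT)/\tau} = e^{-t/\tau}/(1-e^{-T/\tau})$,
  instead of truncating at an arbitrary horizon, and the convolution
  with the IRF is circular (FFT, $O(N\log N)$; a direct $O(N^2)$ sum is
  kept in the test suite as the independent oracle).
* **Bin integration.** Each bin holds the *integral* of the decay over
  the bin, a difference of exponentials, not a midpoint sample. This
  keeps the model exact on the coarse 64–256-bin grids the tests use.
* **Cancellation guard.** All $1-e^{-x}$ factors are evaluated with
  `expm1`.
* **Label symmetry.** The model is invariant under
  $(\alpha,\tau_1,\tau_2)\to(1-\alpha,\tau_2,\tau_1)$; parameters are
  stored in the canonical order $\tau_1\le\tau_2$ so that compared
  outputs are well defined.

Counting noise is Poisson per bin, which the simulator reproduces
exactly and the test suite checks by chi-square calibration against the
model's own expectation.

# Fitting

`fit_decay()` maximizes the Poisson likelihood of the observed counts
(equivalently minimizes $\sum_i \mu_i - k_i\log\mu_i$) over
$(C,\alpha,\tau_1,\tau_2,D)$ with box constraints, using L-BFGS-B.
TCSPC bins *are* Poisson counts, which makes this the natural
objective; weighted least squares (variance $\max(k_i,1)$) is provided
for comparison and agrees with the MLE to better than 2% on lifetime at
$\ge 10^6$ photons. Initialization is data driven — background from the
lowest-decile bins, amplitude from the remaining counts, lifetimes
bracketing fluorescent-protein values (1 and 3 ns) — with a small
seeded multistart (default 3) to escape local optima. Fits that park
the signal amplitude below 1% of the total counts are flagged
degenerate rather than reported as lifetimes.

The per-cell summary is the **amplitude-weighted** mean lifetime
$\bar\tau = \alpha\tau_1 + (1-\alpha)\tau_2$. The total detected
intensity of a single exponential is $S = C\tau$, and the
amplitude-weighted mean is the two-component analogue of that identity,
which is what the FRET-efficiency derivation below rests on; the
intensity-weighted mean is available as an option but is not used in
efficiency calculations.

## IRF drift correction

TCSPC timing electronics drift by a few picoseconds between the IRF
measurement and the experiment. Left uncorrected, the mismatch is
absorbed by a spurious ultra-fast decay component. `correct_irf_drift()`
grid-searches sub-bin IRF translations over $\pm 2$ ps in 0.1 ps steps
(linear interpolation between bins, circular), refits at each shift, and
keeps the best-objective shift among those whose refit contains no
component faster than 0.3 ns — a threshold well below any
fluorescent-protein lifetime but above optimizer-degenerate spikes.
Ties within the convergence tolerance resolve to the smallest |shift|,
so clean data select zero.

Because a shift of a pure exponential is absorbed almost entirely by
the amplitude, the information about the drift lives in the few bins of
the IRF rising edge. The implied standard error of the recovered shift
is therefore substantial at per-nucleus photon budgets (about 0.5 ps at
$10^6$ photons with a 300 ps FWHM IRF). Drift is a property of the
acquisition, not of a cell, so the package's validation estimates it
from pooled counts at the $10^7$-photon scale of a whole field of view,
where recovery is reliable to a fraction of the grid step times a few.

# From lifetimes to FRET efficiency

FRET adds an independent de-excitation channel with time constant
$\tau'$, so the donor's excited-state survival is
$e^{-(1/\tau_0 + 1/\tau')t}$ and its measured lifetime becomes

$$ \tau = \frac{\tau_0\,\tau'}{\tau_0+\tau'} < \tau_0 , $$

while total intensity drops from $S_0 = C\tau_0$ to $S = C\tau$. The
efficiency — the fraction of de-excitations routed through FRET — is

$$ E = \frac{S_0 - S}{S_0} = \frac{\tau_0-\tau}{\tau_0}. $$

`fret_efficiency(2.79, 2.69)` gives $E = 3.6\%$;
`fret_efficiency(2.78, 2.16)` (a tandem donor–acceptor tag) gives
$22\%$. Group-level efficiency (`estimate_group_fret()`) uses the
*group mean* lifetimes, not the mean of per-cell efficiencies, matching
how ensemble efficiencies are reported from lifetime scatter; a
donor+acceptor group that happens to measure longer than the reference
yields efficiency 0 with a `negative_estimate` annotation instead of a
negative number or an error, because no-FRET controls produce exactly
this case by chance.

# Polymer reach of a disordered linker

Whether a FRET geometry is plausible depends on how far a disordered
peptide can reach. Two classical estimates, with per-residue step
$r = 0.37$ nm and $n$ residues ($L = (n-1)r$ the contour length):

* ideal chain (3-D random walk, no excluded volume):
  $\sqrt{\langle D^2\rangle} = r\sqrt{n-1}$;
* worm-like chain with persistence length $p$ (0.3–0.7 nm for
  disordered peptides):
  $\sqrt{\langle D^2\rangle} = \sqrt{2pL\left[1 - \tfrac{p}{L}
  (1-e^{-L/p})\right]}$,
  which tends to the rigid rod $L$ as $L/p\to 0$ and to $\sqrt{2pL}$ as
  $L/p\to\infty$.

For the motivating case — the disordered stretch of CDC20 between its
BOX1 and MIM motifs — the package defaults to the outermost
residue boundaries, 27–133 inclusive (107 residues, 106 steps). Either
motif boundary is a defensible endpoint, so the span is an explicit
argument of `linker_spec()` rather than a constant; any span from 34–129 to 27–133
preserves both qualitative conclusions (ideal chain under 4 nm; WLC
window roughly 4.5–7.4 nm). `mc_random_walk_rmsd()` cross-checks the
ideal-chain formula by direct simulation of isotropic unit-step walks
(uniform direction on the sphere, matching the zero-correlation step
assumption; no steric exclusion), converging to the closed form within
1% at $10^6$ chains.

# The synthetic-data generator

`simulate_experiment()` produces a complete in-silico FLIM experiment:
per-nucleus TCSPC histograms, a shared IRF, and a ground-truth table.
Its defaults emulate the imaging design the package is built around:

| quantity | default | why |
|---|---|---|
| excitation period | 50 ns (20 MHz) | pulsed-laser repetition rate |
| IRF | Gaussian, 300 ps FWHM | detector-jitter-dominated response |
| donor lifetime $\tau_0$ | 2.79 ns | unquenched mNeonGreen-scale value |
| cell-to-cell SD of $\tau_0$ | 0.05 ns | reproduces ±0.03–0.05 ns 95% CIs at N ≈ 40 once fit noise is added |
| photons per nucleus | $5\times 10^5$ | per-cell counts are not directly observable from summary statistics, so the budget is calibrated to reproduce the CI widths only |
| group sizes | 40–52 nuclei | reported Ns |

Small ensemble efficiencies are generated by **partial pairing**: a
fraction $f$ of donor molecules has an acceptor within FRET range
(heterozygous tagging leaves unlabeled endogenous protein competing for
slots), each paired donor transferring strongly. With $\tau' = \tau_0$
(pair efficiency 50%), the amplitude-weighted ensemble efficiency is
$E = f/2$, so $f = 7.2\%$ reproduces the 3.6% headline case
(`emulation_groups()`); `solve_tau_fret()` inverts the general relation
$E = f\,\tau_0/(\tau_0+\tau')$ numerically when $f$ is fixed instead.
Per-cell draws ($\tau_0$ truncated-normal above 0.5 ns, photon budget
Poisson) use counter-derived per-cell seeds, so growing a group never
reshuffles earlier cells.

What the generator deliberately does **not** emulate: detector pile-up
and afterpulsing, the asymmetric tail of real quenched-dye IRFs,
inter-complex FRET, pixel-level segmentation of the nuclear envelope
(the pipeline consumes already-aggregated per-ROI histograms), and any
cell-cycle or expression-level structure in the lifetime spread.
Passing tests therefore demonstrate correctness of the estimation chain
under the stated noise model, not robustness to every instrumental
artifact of a real microscope.

# Group statistics

Per-group summaries are means with $t$-based 95% CIs. Two groups are
compared by Welch's unpaired two-sided $t$-test; three or more by
ordinary one-way ANOVA plus comparisons of each treatment with the
control. The per-comparison adjusted $p$ is computed against a
simulated null of the maximum |t| statistic (shared pooled variance,
$10^5$ seeded replicates) — the Dunnett construction, computed by
Monte Carlo rather than by quadrature; the test suite checks it against
`multcomp`'s quadrature implementation and verifies 5% family-wise
type-I error by simulation. Bonferroni is available as a conservative
fallback.

# Problem sizes used in validation

The package's own validation (test suite and the worked examples) uses
256-bin grids for per-nucleus fits, 1024 bins for drift recovery,
40-cell groups at $5\times 10^5$ photons for end-to-end emulation,
$10^5$–$10^6$ chains for Monte-Carlo polymer checks, and $10^3$
simulated experiments against a shared $10^5$-replicate null for the
type-I-error calibration. These sizes were chosen to give each check a
comfortable statistical margin on a single workstation core; all are
arguments, not constants.

# Known limitations

* The fit covariance is not reported; uncertainties enter only at the
  group level (cell-to-cell scatter), which is how the measurements are
  summarized in practice.
* The drift search is a grid, not a continuous optimization; its
  resolution is `step_ps`.
* Efficiencies are ensemble quantities; no attempt is made to infer the
  paired fraction and the pair-level efficiency separately from a
  single group, which are confounded in $E = f\,\tau_0/(\tau_0+\tau')$.
* Vendor TCSPC file formats are out of scope; the plain-text histogram
  format documented in `?histogram_io` is the interchange format.
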
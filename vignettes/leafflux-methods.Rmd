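---
title: "Models and methods behind leafflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafflux)
```

`leafflux` analyses short-term ¹⁵N leaf-disc labeling experiments: it turns
raw isotopologue mass fractions and amino-acid concentrations into
biosynthesis flux estimates per leaf rank, plus the fingerprint statistics
used to characterize the amino-acid pools themselves. This vignette explains
the models, the defaults and the numerical choices, and what the synthetic
generator does and does not emulate.

## 1. Isotopologue correction

A metabolite with `n` nitrogen atoms is observed as mass shifts
M+0 … M+n. What the instrument measures mixes three things: tracer-derived
¹⁵N, naturally occurring heavy isotopes, and tracer impurity (2% of the
tracer substrate's N is ¹⁴N). The correction matrix `A` for a metabolite
predicts, in column `j`, the measured mass-shift distribution of a molecule
carrying exactly `j` tracer atoms:

* a binomial over the `j` labeled positions with success probability =
  purity (default 0.98);
* a binomial over the `n − j` unlabeled N positions at natural ¹⁵N
  abundance (0.00364);
* in **full** mode, additionally the natural mass-shift envelopes of C, H,
  O and S, obtained by per-element multinomial convolution. Rows beyond M+n
  are truncated, so full-mode columns sum to slightly less than 1.

**Default mode is `tracer_only`**: at an Orbitrap resolving power of 70,000
(at 400 m/z) the ¹³C, ²H, ¹⁷O/¹⁸O and ³³S/³⁴S species of small amino acids
are mass-resolved from the ¹⁵N isotopologues, so only the tracer element
needs deconvolution. Full mode is one argument away and is tested with a
brute-force enumeration oracle. The natural-abundance table (IUPAC 2021
values) is an editable argument, since published analyses rarely print the
table they used.

Correction solves `min ‖A·x − raw‖₂` subject to `x ≥ 0` (Lawson–Hanson
non-negative least squares, implemented in the package because no installed
NNLS routine was available), then renormalizes to sum 1. Nonnegativity
matters: with measurement noise, plain inversion produces small negative
fractions that are unphysical and would bias the mean enrichment
`Σ i·xᵢ / n` used downstream. Raw vectors are clipped at 0 before the solve;
an all-zero vector is an error ("empty measurement"), not a silent zero.

## 2. Label-input functions

Each flux subsystem is driven by the measured enrichment of its precursor
(Glu for Pro and Val, Asp for Thr), represented analytically. The default
family is monotone and bounded:

* constant: `f(t) = x₀` (1 parameter)
* single-saturating: `f(t) = x₀ + a₁(1 − e^(−k₁t))` (3 parameters)
* double-saturating: adds `a₂(1 − e^(−k₂t))` (5 parameters)

fitted by weighted least squares with the isotopic measurement SD
(σ = 0.02) as weight, under the constraint that values stay in [0, 1].

**Family selection.** With the experiment's four time points, textbook AICc
has denominator `n − p − 1 = 0` for the single-saturating family, which
would degenerately force the constant model even on clearly saturating
data. The package therefore (i) restricts candidates to families with
`p ≤ n − 1` and (ii) floors the AICc denominator at 1. With 4 points this
selects the single-saturating curve whenever it actually reduces the
residual; with ≥ 6 points the double-saturating family competes. Requesting
a family with more parameters than points falls back to the
single-exponential family with a warning; a fit missing any point by more
than 10σ is flagged but not fatal.

`x₀` defaults to 0 for products: corrected distributions have the
natural-abundance baseline removed, so a pre-labeling sample should sit at
zero enrichment. It is a visible, configurable parameter because deposited
t = 0 samples occasionally carry residual baseline.

## 3. Subsystem flux model and estimation

Every subsystem has exactly two reactions — biosynthesis into the product
pool and a sink out of it — operating at the same rate `v`, reflecting the
observed metabolic pseudo steady-state (pool sizes did not change during
the 2 h labeling window). The product enrichment then obeys the linear ODE

`dx_p/dt = (v / M′)(x_in(t) − x_p),  x_p(0) = x₀`

where `M′` is the pool size in the same amount unit as the flux (fluxes are
nmol g⁻¹ DW min⁻¹, pools µmol g⁻¹ DW; the 1000× conversion lives in one
internal function). For the exponential input family the solution is closed
form, including the repeated-eigenvalue limit `k → kᵢ` (handled explicitly
with the `t·e^(−kt)` term); arbitrary input functions fall back to a
fixed-step RK4 integrator whose step is chosen against both the turnover
time `M′/v` and the output grid. Both paths are tested against an
independent fine-step explicit integrator.

Estimation minimizes

`SSR(v, M) = Σ_t ((x_sim − x_obs)/σ_x)² + Σ_t ((M − c_obs)/σ_c)²`

per biological replicate (not pooled — the goodness of fit is verified per
replicate). The optimizer is bounded L-BFGS-B with 20 log-spaced starts for
`v` (10⁻² to 10³) and `M` started at the mean observed concentration,
followed by a Nelder–Mead polish; any bounded least-squares minimizer
reaching the same global minimum would satisfy the same contract. `v` may
legitimately hit 0 (no labeling ⇒ no flux); an estimate pinned at the upper
bound raises a boundary warning. Fewer than three informative time points
is reported as non-identifiable rather than fitted.

**Concentration weights.** No concentration error model is printed for this
kind of experiment, so σ_c defaults to
`max(replicate SD at that time point, 5% of the group-mean concentration)`.
The floor prevents zero or near-zero weights, which three replicates
produce regularly. A consequence worth knowing: when the replicate SD
happens to underestimate the true spread, the chi-square statistic inflates,
so at the synthetic generator's 10% concentration CV the per-replicate gate
rejects more than its nominal 5% in full-pipeline runs (the gate itself is
calibrated — see below). A `fix_M` mode (pool fixed at the mean observed
concentration, only `v` fitted) is available.

**Chi-square gate.** A fit passes iff `SSR ≤ χ²₁₋α(dof)` with
`dof = n_x + n_c − 2` and α = 0.05 — upper-tail only, the standard
goodness-of-fit reading: overdispersion rejects, while a
suspiciously small SSR only warns. Calibration is tested by Monte Carlo
under the stated noise model (Gaussian σ = 0.02 on enrichments): the
empirical rejection rate over 1000 replicates must sit within 0.05 ± 0.02.
This calibration deliberately applies noise at the enrichment level, where
the σ = 0.02 precision is defined; the generator's mass-fraction noise path
involves clipping at zero and renormalization, which is intentionally
non-Gaussian near the simplex boundary.

Replicate fluxes are summarized per leaf rank as mean ± sample SD of the
gate-passing fits (excluded fits are counted, groups with no passing fit
are dropped with a warning), and rank differences in estimated fluxes are
tested by one-way ANOVA + Tukey HSD. Label-input curves are fitted per
replicate by default; a shared-input option pools a rank's replicates, which
is the other defensible reading of the original workflow.

## 4. Fingerprint statistics

* `filter_major()`: strictly `> 1 µmol g⁻¹ DW` in at least half the
  samples. The boundary is exclusive on the threshold and inclusive on the
  fraction, matching the stated rule; a metabolite at exactly 1.0 is
  excluded.
* `normality_screen()`: Shapiro–Wilk at α = 0.05 per metabolite. The
  original analysis names no test; Shapiro–Wilk is the conventional choice
  at these sample sizes, and the method and level are attached to the
  result so exclusion lists are auditable.
* `run_pca()`: PCA on standardized (unit-variance) columns. Scaling is not
  stated in the source analyses, but amino-acid pools span two orders of
  magnitude, making the correlation form the defensible default. Loadings
  are reported as Pearson correlations between each metabolite and the
  component scores — the quantity shown on fingerprint loading plots — and
  are tested against the definitional oracle.
* `anova_tukey()`: one-way ANOVA, Tukey HSD from the studentized-range
  distribution, and a compact letter display built by insert-and-absorb
  over the significant-pair matrix (ties broken by group order; written in
  the package since no CLD implementation is installed). Pairwise
  two-sample Student tests are available for follow-up contrasts when the
  ANOVA is borderline. Zero-variance data take a degenerate path: one
  shared letter, F undefined.
* 95% confidence ellipses for score plots use the 2-D normal quantile form;
  rendering is optional (`autoplot`).

## 5. The synthetic world

`default_scenario()` states the simulated experiment once:

| quantity | default | why |
|---|---|---|
| leaf ranks | L15, L11, L7, L3 | young sink → old source gradient |
| replicates × times | 3 × {0, 30, 60, 120} min | the labeling design |
| glycine input | plateau 0.80, rate 0.2 min⁻¹ | isotopic steady state before 30 min at ≈ 80%; the 20% shortfall models the unlabeled N pool feeding Gly |
| tracer purity | 0.98 | labeled substrate specification |
| σ_x | 0.02 | stated isotopic measurement precision |
| concentration CV | 0.10 (lognormal) | no stated model; 10% is typical UPLC-DAD quantification spread, lognormal keeps positivity |
| true fluxes (nmol g⁻¹ DW min⁻¹) | Pro (30, 22, 14, 10); Thr = Val (90, 66, 42, 30) | 3:1 Thr:Pro and Val:Pro ratio in the youngest rank, monotone decline with source status; absolute magnitudes are the package's own choice since no absolute values are printed, picked so that the turnover `v/M′` gives 50–85% approach to the input plateau within 2 h (identifiable but not saturated) |
| pools (µmol g⁻¹ DW) | 1–12 by metabolite × rank | encode the fingerprint contrasts: Asn/Gln/Pro/SMCSO highest in L15, Thr rising with age, Val peaking at L7, SMCSO the largest pool, Trp kept at 0.4 to exercise the abundance filter |

Precursor (Glu, Asp) enrichment curves are parameterized directly
(saturating curves whose plateaus decline with source status) rather than
derived mechanistically from glycine, because the upstream transamination
network is explicitly not modeled. Noise enters on mass fractions (then
clip at 0, renormalize) — where the 0.02 precision applies — and
multiplicatively on concentrations. Everything is deterministic given the
scenario seed.

**What a green test establishes, and what it does not.** The generator
emulates the design's dimensions, noise magnitudes and qualitative
contrasts; it does not emulate chromatographic artifacts, missing
isotopologues, run-order drift, or the two-nitrogen assimilation kinetics
of Gln (whose M+2 behaviour was the interesting one in real data). Passing
recovery tests therefore validates the estimator on data that obey the
model; they cannot certify behaviour under model violations.

## 6. Numerical choices and limitations

* Correction matrices are small ((n+1)², n ≤ 2 here); NNLS tolerance is
  scaled to the matrix magnitude; round-trips are exact to ≤ 1e−8.
* Mass shifts are integer nominal; fine isotopic structure within one
  nominal shift is aggregated (the data model is per-isotopologue).
* The closed-form ODE solution is exact; the RK4 fallback is accurate to
  well below the 1e−8 relative target at its default step.
* Optimizer determinism: all fits are deterministic given the data; the
  pipeline contains no random draws, so identical inputs give byte-identical
  output files.
* Multi-nitrogen flux modeling (Gln M+2), multi-intermediate subsystems
  (e.g. Glu → P5C → Pro), and positional isotopomer correction are out of
  scope.
* With only 4 time points, `v` and `M` are jointly identifiable only
  because concentrations constrain `M`; with enrichment data alone the
  model would be identifiable in `v/M` only. The `fix_M` mode makes that
  explicit.
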
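---
title: "Dynamical phenotyping of anaesthesia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical phenotyping of anaesthesia: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Anaesthesia abolishes consciousness in animals whose brains differ by six
orders of magnitude in neuron count. If that abolition has a shared dynamical
signature, it should appear as a *direction* in the space of time-series
statistics: some properties of regional neural activity should move the same
way under anaesthesia in every species, every drug, every recording modality.
`dynphen` implements a pipeline to look for such a signature, together with a
synthetic multi-species study generator that plants a known signature so every
stage can be validated end to end.

The pipeline has five scientific stages, mirrored by the numbered scripts in
`analysis/`:

1. **Massive feature extraction** — each region's time series is summarised
   by a catalogue of univariate statistics (autocorrelations, Gaussian and
   histogram automutual information, local forecast errors, and 22 canonical
   distribution/scaling/periodicity features).
2. **Effect-size contrasts** — each awake-vs-anaesthesia contrast yields a
   region-by-feature matrix of Hedge's *g* (anaesthesia minus awake).
3. **Sign-consistency discovery** — features whose contrast-level mean effect
   has the same strict sign in *every* contrast form the candidate signature;
   its size is tested against a random-sign surrogate null.
4. **Complementary dynamical measures** — intrinsic timescales, functional
   connectivity (FC), dynamical profile similarity (DPS), and their coupling.
5. **Mechanism** — PLS correlation of the regional change maps against gene
   expression under spatial-autocorrelation-preserving nulls, and a dynamic
   mean-field (DMF) whole-brain model asking whether lowering global coupling
   reproduces the anaesthesia direction.

## The synthetic study generator

The generator is first-class, tested code, not a fixture. Its defaults are
the frozen study conditions; tests and analysis scripts may scale down region
counts and recording length for runtime, but never retune the condition
parameters.

Each region follows a first-order autoregressive process driven by shared
latent factors:

$$x_t = \phi\, x_{t-1} + \sqrt{1-\phi^2}\,\bigl(\kappa \textstyle\sum_p L_{np}
z_{p,t} + \epsilon_t\bigr)$$

* $\phi$ sets the intrinsic timescale axis (awake 0.8, anaesthesia 0.4);
* $\kappa$ sets the synchrony axis through 3 shared latent factors
  (awake 0.6, anaesthesia 0.1);
* the $\sqrt{1-\phi^2}$ innovation scaling keeps the stationary variance
  independent of $\phi$. This matters: without it, lowering $\phi$ shrinks
  the signal and *reduces* absolute forecast errors, confounding a timescale
  change with an amplitude change. With variance matching, anaesthesia makes
  activity faster and *less* predictable — the planted direction for the
  forecast-error features — while autocorrelation-family features drop.
* a smooth spatial gradient map modulates $\phi$ regionally (amplitude 0.15),
  so regions with longer awake timescales show larger anaesthetic drops, and
  the *same* map seeds the planted gene-expression association — giving the
  timescale, spatial-null and PLS stages a common ground truth.

The study layout mirrors a five-species design: 100/82/70/72/120 regions
with 2/6/3/2/1 awake-vs-anaesthesia contrasts (14 in total), 10 subjects per
condition, paired designs except the mouse-like block, 500 timepoints at
TR = 1 s, and 81 genes per species normalised to $[0,1]$ by a robust sigmoid.

The synthetic connectome draws edges without replacement with probability
decaying exponentially in Euclidean distance until a 27% density is reached,
weights decay with distance under multiplicative log-normal scatter
(emulating streamline counts), and the matrix is scaled so the maximum weight
is 0.2 — the whole-brain mean-field convention that places the usual
global-coupling range $G \in [0.5, 2.5]$ in the DMF model's stable operating
regime. (At twice this scale, a substantial fraction of connectome draws
makes the 3 Hz balanced state at $G = 1.8$ merely metastable, with
noise-driven escape to a saturated attractor within minutes of model time,
and feedback inhibition control becomes infeasible.) A disconnected draw is
a hard error, never silently patched.

## Statistical machinery

**Hedge's g.** $g = J\,(\bar{x}_\text{anaes} - \bar{x}_\text{awake})/s_p$
with the small-sample correction $J = 1 - 3/(4(n_1+n_2)-9)$. Non-finite
feature values are zero-filled with a QC count: a zero carries no directional
evidence and cannot fake consistency.

**Sign consistency.** A feature survives iff its contrast-level mean effect
is strictly positive in all 14 contrasts or strictly negative in all 14.
Under the null the probability is $2 \times 0.5^{14} \approx 1.2\times
10^{-4}$ per feature; the set-size null is estimated from genuine i.i.d.
±1 surrogate matrices (no binomial shortcut), with add-one-corrected
p-values. Category enrichment of the surviving set uses a resampling null
whose mean and variance match the hypergeometric law.

**Intrinsic timescale.** $\tau = TR \sum_{k=1}^{K-1} \text{ACF}(k)$ summed
over the initial positive run of the autocorrelation function (K is the
first lag at or below zero). Lag 0 is excluded by default — including it
adds a constant TR to every region and cannot change any comparison; a flag
exposes the alternative. For an AR(1), $\tau \to \phi/(1-\phi) \cdot TR$,
which the tests verify within 15%.

**FC, DPS, coupling.** FC is zero-lag Pearson correlation of the raw
series; DPS correlates regions' z-scored feature vectors — similarity of
computational phenotype without time-locking; coupling is the correlation of
the two matrices' upper triangles. The planted anaesthesia condition lowers
all three.

**Spatial nulls.** Moran spectral randomisation on the inverse-distance
weight matrix. We use the *singleton* sign-flip variant: the map is expanded
on the Moran eigenvector basis and each coefficient's sign is randomised,
$s = \bar{x} + \sum_k \epsilon_k a_k v_k$. This preserves the map's mean and
variance exactly and — because Moran's I is a quadratic form in the
coefficients — preserves Moran's I *exactly*, while scrambling the map. A
map lying on a single eigenvector yields only its two sign-flipped copies,
which is the correct degenerate behaviour.

**PLS correlation.** Per species, the expression block and the
dynamics-change block are column-z-scored and stacked; the SVD of
$Y^\top X$ yields paired saliences, with covariance shares
$d_k^2 / \sum d^2$. Significance randomises only the dynamics side, per
species, through the Moran surrogates above (re-z-scored before stacking),
keeping the gene maps and their spatial structure fixed.

## The dynamic mean-field model

Each region holds one excitatory (NMDA) and one inhibitory (GABA)
population with the canonical reduced parameter set (I₀ = 0.382 nA,
w₊ = 1.4, J_NMDA = 0.15 nA, gains 310/615 nC⁻¹, thresholds
0.403/0.288 nA, shape constants 0.16/0.087 s, time constants 100/10 ms,
γ = 0.641, σ = 0.01 nA), coupled through the connectome scaled by G. The
transfer function $F(I) = g(I - I_\text{thr}) / (1 - e^{-d\,g(I -
I_\text{thr})})$ has a removable singularity at threshold whose value is
$1/d$ (6.25 Hz for the excitatory population) — implemented with an explicit
guard rather than left to floating-point luck. Integration is
Euler–Maruyama at dt = 1 ms in compiled code, using R's own RNG so every
simulation is seed-reproducible.

**Feedback inhibition control.** Per-region inhibitory weights are
initialised at the *analytic* solution of the noise-free current-balance
equations for a uniform 3 Hz target state, then refined over stochastic
epochs (12 s read after a 4 s burn, each warm-started from the last state)
with damped multiplicative corrections on the log-rate error. Three
safeguards matter, all because the coupled network is bistable at realistic
G: epochs are long enough that rate reads are not biased low by the
post-correction transient; the per-step correction factor is tightly
bounded, and more tightly downward — lowering inhibition is the direction
that can tip the network onto its saturated branch; and when an epoch's
worst deviation clearly worsens the calibrator backtracks to the best
weights seen so far and halves the step bound. Production simulations are
warm-started from the calibration state for the same reason.

**Haemodynamics and filtering.** The excitatory gating variable drives a
balloon–windkessel model (rate constants 0.65 and 0.41 s⁻¹, transit 0.98 s,
stiffness 0.32, resting extraction 0.34, V₀ = 0.02); BOLD is sampled at
TR = 0.72 s, the first 20 s are discarded (haemodynamic onset transient),
each region is linearly detrended, and a zero-phase second-order Butterworth
band-pass at 0.008–0.09 Hz is applied. Detrending before filtering is not
cosmetic: without it, edge transients from the DC level leak a shared
artefact into every region and FC saturates near 1. One honest caveat: a
second-order Butterworth skirt decays slowly, so roughly 9% of output power
sits outside the nominal band; the filter contract we test (and meet) is
<1% of power beyond one octave outside the band edges. Features that are
dominated by the filter's own autocorrelation (e.g. lag-1 autocorrelation of
band-passed data) should be computed on unfiltered BOLD, which the sweep
functions expose via a `band` argument.

**Fitting G.** The functional-connectivity-dynamics (FCD) matrix correlates
sliding-window FC patterns (30-TR windows, 3-TR steps); candidate G values
are compared with an empirical FCD value sample by the Kolmogorov–Smirnov
statistic, recalibrating FIC at each G; ties go to the smaller G. In the
model, as in the planted data, reducing G lowers FC, the anaesthesia-signed
feature deltas, and synchrony–dynamics coupling.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; pipeline stages derive child
seeds by hashing a master seed with a stage label (`child_seed`), so adding a
stage never perturbs another stage's stream. `with_seed` restores the
caller's RNG state, so library code never tramples a user's session.

Tests and the `analysis/` scripts run the study at reduced region counts and
recording lengths (a runtime choice we make explicitly; condition parameters
are never scaled), and `scripts/acceptance.R` recomputes the two quantitative
targets — the Monte-Carlo sign-consistency rate over 10,000 surrogate
6,958 × 14 matrices and the calibrated DMF grand-mean excitatory rate on an
84-region synthetic connectome — from a single command-line seed.

## Limitations

* The generator's AR(1)-plus-factors family is a deliberately minimal model
  of regional dynamics: it plants monotone, unconfounded axes for timescale
  and synchrony but cannot exhibit oscillatory, bursting, or
  cross-frequency structure, so features sensitive to those properties are
  exercised only for robustness, not recovery.
* The 22-feature canonical set is authored from the published definitions
  and validated by closed-form and behavioural oracles; numerical equality
  with the reference C implementation is not asserted (binning and edge
  conventions differ in places).
* The expression maps are smooth Gaussian fields pushed through a robust
  sigmoid — adequate for testing spatial-null logic, far from transcriptomic
  realism.
* DMF simulations at desk scale (tens of regions, minutes of model time)
  reproduce directions, not the fine quantitative G-contrasts that full-size
  empirical studies resolve; the acceptance suite therefore tests sweep-range
  directions (e.g. G = 1.4 vs 2.1) rather than adjacent grid points.
* The model's G-sensitivity scales with the connectome's row sums, i.e. with
  region count at fixed density and weight scale. G-sweep checks (coupling
  monotonicity, FCD-based recovery of G) therefore run on the full 84-region
  connectome: a 30–40-region surrogate sits so far below the critical
  coupling that the 0.5–2.1 grid resolves nothing, and recovering a deeply
  subcritical G from finite FCD data is ill-posed.
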
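---
title: "Methods: compound-specific lipid 2H/1H data reduction and growth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound-specific lipid 2H/1H data reduction and growth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipid2h)
```

## What the package computes

`lipid2h` reduces compound-specific hydrogen-isotope (²H/¹H) measurements
of microbial fatty acids, made by gas chromatography coupled to
isotope-ratio mass spectrometry (GC-irMS), to biologically interpretable
fractionations, and couples them to growth kinetics. The motivating system
is the sulfate-reducing bacterium *Desulfovibrio alaskensis* G20 (wild
type and two transhydrogenase-disrupted mutants) grown on five
donor/acceptor combinations, but every stage is generic to FAME-based
lipid ²H work.

The quantities of interest are:

* per-lipid apparent fractionation against growth-medium water,
  ²ε~lipid-water~ = α − 1 with α = (δ²H~lipid~ + 1)/(δ²H~water~ + 1)
  (fractional units; reported in ‰);
* the pool-weighted total, δ²H~total~ and ²ε~total~, where each lipid is
  weighted by its relative abundance times its count of non-exchangeable
  hydrogen atoms (a hydrogen mass balance);
* biomass-weighted average growth rates μ~avg~ from optical-density time
  series, including diauxic (two-phase) growth;
* descriptive statistics linking profiles, rates and fractionations, and
  a two-pool mass-balance inference for the isoleucine-derived primer of
  anteiso-branched fatty acids.

All delta arithmetic is done internally in fractional units
(`delta/1000`); permil appears only at the interfaces. Mass balances are
linear in delta, so forward and inverse operations round-trip exactly
(to machine precision), which the tests exploit.

## The reduction chain

Raw per-injection FAME deltas are measured against a coinjected standard
(methyl tetracosanoate, C24:0) of known composition. The chain is:

1. **Bracketing QC.** Each standard-mix injection gets an RMS against the
   mix's known values; a sample injection is kept only if the nearest
   preceding *and* following mix injections both have RMS ≤ 7 ‰ (samples
   at the sequence edges, without both brackets, are discarded). The
   pooled RMS of passing standards is the session's instrument
   uncertainty floor. The discard rule applies to biological samples;
   derivatization standards for the methyl calibration are aggregated
   across the whole session, since a single unlucky bracket would
   otherwise void the global calibration.
2. **Referencing.** δ vs the coinjected standard is chained onto the
   V-SMOW scale: δ~s/VSMOW~ = (1 + δ~s/ref~)(1 + δ~ref/VSMOW~) − 1.
3. **Pseudoreplicate aggregation.** Repeat injections of one extract are
   averaged; the standard error is max(sd/√n, RMS~session~/√n), so a
   single (or suspiciously consistent) injection still carries the
   instrument uncertainty.
4. **Methyl correction.** Derivatization adds three methanol hydrogens
   per acid group. The methyl delta is calibrated from derivatized
   standards of known free-acid composition (a mono-acid such as myristic
   acid and a diacid such as phthalic acid, which contributes six methyl
   hydrogens): δ~Me~ = (h~FAME~ δ~meas~ − h~nonexch~ δ~known~)/h~Me~,
   combined across standards as an unweighted mean (disagreement > 20 ‰
   warns but does not fail). Sample FAMEs are then corrected:
   δ~FA~ = (h~FAME~ δ~FAME~ − h~Me~ δ~Me~)/h~nonexch~.
5. **Fractionation and pooling.** Per-lipid ε against the medium water,
   then the pool total with hydrogen-weighted abundances (an
   abundance-only mode is provided because a "weighted average of each
   fatty acid pool" admits both readings).

Error propagation is first-order throughout. One subtlety matters: the
methyl-calibration error is *shared* by every lipid in a study, so in the
pool it propagates linearly through the weights, while the per-lipid
measurement errors add in quadrature. Treating the calibration part as
independent underestimates the pool uncertainty by roughly the square
root of the number of lipids, which is observable as under-coverage in
simulation.

Hydrogen accounting follows the molecular formulas: a mono-carboxylic
acid C~n~H~2n−2d~O~2~ has 2n − 2d hydrogens, of which only the carboxyl
O-H is exchangeable (lost on methylation); branching moves carbons but
never changes counts. Primer hydrogens are 3 (acetyl) for straight
chains, 7 (valine-derived isobutyryl) for even-carbon iso acids, and 9
(leucine-derived isovaleryl / isoleucine-derived 2-methylbutyryl) for
odd-carbon iso and anteiso acids; for hypothetical acids too small to
retain the intact primer the count is reported as `NA`.

```{r inventory}
hydrogen_inventory("a-C17:0")
```

For anteiso-C17:0 the primer share is 9/36 ≈ 25% of methyl-ester
hydrogen and 9/33 ≈ 27% of free-acid non-exchangeable hydrogen. The
two-pool primer inference defaults to the free-acid basis (the FAME basis
exists only in the derivatized molecule), but both fractions are always
reported because the conventional "roughly 25%" statement matches the
methyl-ester denominator exactly.

## Growth model

Optical density is fit with the reparameterized (Zwietering-style)
logistic

OD(t) = OD₀ + A / (1 + exp(4 μ (λ − t) / A + 2)),

with asymptotic rise `A`, maximum slope `μ` at the inflection, and lag
`λ` (the inflection tangent's baseline intercept). Fitting is
Levenberg–Marquardt least squares with multiple jittered starts (factors
0.5–2 around data-derived initial values); flat series are rejected
rather than fit. Note that with this OD-scale parameterization μ is an
OD slope: uniform OD rescaling rescales μ by the same factor (curve shape,
and hence lag and relative timing, are unchanged).

**Diauxic detection** works on the derivative of the smoothed OD series
(3-point running median, then 3-point mean). A second phase is declared
when the derivative falls below 10% of its running maximum — sustained
for two points, and only after a substantive first phase — and later
rebounds above 25% of that maximum, again sustained; the series is split
at the intervening derivative minimum. Two design points deserve
explanation:

* The *OD* derivative is used rather than the log-OD derivative. A second
  phase rides on a high OD baseline, so its log-derivative is an order of
  magnitude smaller than the first phase's early-growth log-derivative
  and a rebound criterion on log-OD essentially never fires even for
  textbook diauxie.
* A detected "phase" whose fitted rise across its window is below 10% of
  the total OD rise is treated as a detector artifact and merged back;
  reading noise cannot produce a resolvable growth phase below that.

Phases blending into one another without a plateau are reported as a
single window — a stated limitation of plateau-based detection.

Per-phase biomass is the rise of the *fitted* curve across the window
(noise-robust, and immune to a degenerate fit parking its asymptote
outside the window), and the biomass-weighted average rate is
μ~avg~ = Σ μ~k~ ΔOD~k~ / Σ ΔOD~k~. Replicates are summarized as mean ±
SEM; a single replicate reports `NA` rather than zero uncertainty.

## Rate–fractionation models

Three least-squares candidates relate ²ε~total~ to μ~avg~: linear
(ε = a + bμ), exponential decay (ε = ε~∞~ + c·e^−kμ^), and hyperbolic
(ε = ε~∞~ + c/(K + μ)). They are ranked by AICc (small samples; k counts
the residual variance); a gap below 2 AICc units between the top two is
reported as indistinguishable rather than declaring a winner. The Pearson
correlation screen across abundances, μ~avg~ and ²ε~total~ is
descriptive; Benjamini–Hochberg adjusted p-values are available on
request.

## The synthetic study

`generate_study()` emulates the full measurement campaign so the pipeline
is testable without instrument data: 3 strains × 5 conditions, 2
biological × 3–6 pseudoreplicate injections, bracketing mix injections at
least every 6 samples, an alkane ladder, and derivatized calibration
standards. Per-cell truth is drawn uniformly inside observation-anchored
envelopes (²ε~total~ ∈ [−175, −55] ‰; μ ∈ [0.007, 0.172] /h), with fixed
per-lipid offsets encoding the observed isotopic orderings (unsaturated
below saturated homologs, anteiso below straight chains, iso-C18:0 least
depleted) plus a small jitter that cannot reorder them. Measured deltas
are the *forward* methyl mass balance of the truth, re-referenced to the
coinjected standard, plus Gaussian noise (σ = 5.5 ‰, the emulated
session RMS); areas carry 2% relative lognormal noise; OD readings carry
1% relative Gaussian noise (duplicate-culture growth curves are reported
with error bars smaller than plotting symbols, so a small reading error
is the realistic regime). Mutants on malate or fumarate get two-phase OD
truth (second-phase rate 0.5× on 40% of the biomass). One RNG stream per
output file is derived from the master seed, and the caller's RNG state
is restored.

What the generator does *not* emulate: chromatographic peak shape and
integration, retention drift, H₃⁺-factor variation (carried as metadata
only, never applied), matrix-dependent derivatization yield, and any
coupling between growth rate and fractionation — the synthetic ε and μ
are independent by design. Passing recovery tests therefore demonstrates
the correctness of the arithmetic, the QC logic and the error
propagation, not that real instruments behave this way; and the
rate–fractionation model comparison on synthetic data exercises only the
fitting machinery, not any biological relationship.

Truth is written as three tables: `truth_lipids.csv` (cell × lipid: true
δ²H vs V-SMOW, ε, abundance, water δ), `truth_growth.csv` (cell × phase:
μ, A, λ, μ~avg~, diauxic flag), `truth_global.csv` (methanol methyl δ,
coinjected-standard δ, noise settings, seed).

## Numerical choices and degenerate inputs

* δ > −1000 ‰ is enforced everywhere (a ratio must be positive); sem ≥ 0,
  n ≥ 1.
* permil↔fraction conversions and both mass balances invert to better
  than 1e−12; recovery of a noise-free synthetic study is exact to ~1e−9
  through the whole chain.
* Logistic fitting uses up to 6 jittered starts; non-convergence of every
  start is an error carrying the data's identity. Windows shorter than 5
  points are never fit.
* Kovats indices interpolate linearly between bracketing alkane rungs
  (appropriate for the temperature-programmed separation emulated);
  retention times outside the ladder span are a range error, not an
  extrapolation.
* Pool weighting treats abundances as exact; lipids with missing deltas
  are excluded and reported.
* Ties/edges in QC: a sample with no standard-mix injection on either
  side fails (strict reading of "bracketed").

## Problem sizes used by the test suite

The shipped tests run the default synthetic design (15 cells, ~160
injections) through the full reduction across 100 master seeds for the
coverage property (ε~total~ within 3 propagated SEM of truth in ≥ 99% of
cells), ten further seeds for pipeline-level checks, and dozens of
constructed curves for growth-kinetics properties. These sizes were
chosen so the complete suite exercises every stage at statistically
meaningful depth while remaining a desk-scale run.

## Known limitations

* The bracketing rule is the only drift control; no within-block drift
  regression is attempted.
* The methyl calibration assumes every acid group esterifies with the
  same methanol pool; per-batch methanol differences are not modeled.
* The diauxic detector needs a plateau; overlapping phases collapse to a
  single effective rate.
* The elongation-hydrogen proxy in the primer inference (the measured
  straight-chain homolog) inherits that lipid's biosynthetic signal; the
  inferred primer delta is a mass-balance attribution, not a measurement.
* With the OD-scale logistic, μ is an OD slope; converting to a specific
  growth rate requires an external OD-to-biomass calibration.
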
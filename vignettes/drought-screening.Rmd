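---
title: "Drought-stress response indices for early-season genotype screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drought-stress response indices for early-season genotype screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparscreen)
```

## The screening problem and the model

`sparscreen` analyses the standard early-season drought screening design: a
small set of genotypes grown under an imposed drought treatment (D) and an
irrigated control (C) in a controlled environment, replicated in blocks, and
phenotyped once at the end of the juvenile stage over a panel of
developmental, root-architecture and physiological traits.

The core statistic is deliberately simple. For genotype $g$ and trait $P$,
the individual drought stress response index is the ratio of the
treatment-level cell means,

$$\mathrm{IDSRI}_g(P) = \frac{\bar P_{D,g}}{\bar P_{C,g}},$$

and the cumulative index is the unweighted sum over a fixed member panel of
$m$ traits,

$$\mathrm{CDSRI}_g = \sum_{P \in \mathcal{M}} \mathrm{IDSRI}_g(P).$$

The index rests on three assumptions worth making explicit:

1. **Ratios are meaningful**, i.e. every member trait is positive-valued
   under control conditions. A zero control mean is a hard error, never a
   silently dropped term.
2. **Equal weights**: each trait contributes its raw ratio. Traits are not
   normalised or direction-adjusted — including traits that typically
   *increase* under drought (root-to-shoot ratio RSR, longest root length
   LRL, root diameter RD). This is intentional: the index rewards any form
   of phenotype retention or compensatory growth equally, and a higher
   CDSRI always reads "more drought tolerant".
3. **Fixed panel size**: CDSRI magnitudes are only comparable at a fixed
   trait count $m$. A missing member trait therefore errors; scoring an
   explicit subset is supported (`cdsri(..., traits = )`, reported with its
   own `n_traits`), but scores from different subsets must not be compared.

The default panel (`trait_panel()`) has 22 traits, of which 21 are CDSRI
members; electron transport rate (ETR) is measured and summarised but is not
a member. Stem dry weight without leaves (STDW) is accepted as a custom
trait but is not part of the default panel, since no default-panel analysis
uses it. Input aliases `RL` (for TRL), `ARD` (for RD), `RS` (for RSR) and
`"Fv/Fm"` (for FvFm) are resolved on every entry point, as are treatment
aliases `T1` (drought, D) and `T2` (control, C).

## Classification

Genotypes are grouped by splitting the observed score range
$[\min, \max]$ into three equal-width bins labelled, in increasing CDSRI,
*sensitive*, *moderate* and *tolerant*. Numerical conventions:

* the lower two bins are half-open $[lo, hi)$ and the top bin is closed, so
  a score exactly on an interior edge joins the *upper* class;
* all scores equal (degenerate range) is an error rather than an arbitrary
  assignment;
* classification needs at least three scores; fixed, externally supplied
  bin edges are supported via `breaks` (and are what `predict.dsri()` uses
  to classify new scores under a fitted binning).

The equal-width-of-observed-range rule is a design choice. The interval
widths reported alongside the bundled trial are equal (1.16), and applying
the rule to the trial's reported scores reproduces its published group
memberships exactly; the intervals as printed there are internally
inconsistent (the stated lower edge excludes the lowest reported score, and
the stated edges do not span the observed maximum), so the rule implemented
here is a reconstruction that favours the memberships over the printed
edges.

## The bundled reference trial and its known discrepancy

`spar_trial_means()` ships the complete trait-mean table of a six-hybrid
maize SPAR trial (6 hybrids × 2 treatments × 22 traits, measured 28 days
after sowing), verbatim to its published precision and guarded by a frozen
value-sum integrity check. All percent stress responses narrated for that
trial are recomputable from this table at two-decimal printing precision;
`stress_summary()` is the table behind them. Percent responses are defined
as $100\,(\bar P_C - \bar P_D)/\bar P_C$ (decline; increase is its exact
negative) and are always computed on unrounded means, rounding only for
display.

The cumulative scores *reported* for that trial (25.21–28.32,
`reported_cdsri_scores()`) are **not** reproducible from its published
trait means: the printed-formula recomputation gives 15.1–18.0, and the two
orderings disagree. The package takes the trait-mean table as ground truth
for all recomputation, treats the reported scores purely as classification
inputs, and surfaces the mismatch explicitly —
`reference_analysis()$discrepancy` flags every hybrid whose reported and
recomputed scores differ beyond printed rounding (all six, here). No
attempt is made to tune the recomputation toward the reported magnitudes.

## Inference layer

With replicate-level observations the package fits, per trait, a balanced
two-factor randomized-complete-block ANOVA with the replicate as the block
and treatment × genotype as crossed factors, using the explicit
textbook sum-of-squares partition (squared totals over their cell sizes
minus the correction factor). For the reference layout (4 blocks, 2
treatments, 6 hybrids, N = 48) the degrees of freedom are 3/1/5/5/33/47.
Only balanced designs are supported; unbalanced data errors rather than
silently switching to a different estimator. Numerical details:

* the error SS is obtained by subtraction and clamped at zero against tiny
  negative round-off; the partition is property-tested to conserve the
  total SS at 1e-8 relative tolerance;
* noise-free inputs with distinct cell means legitimately give a zero error
  mean square; F is then reported as `Inf` (p = 0) rather than erroring;
* ANOVA stars use strict thresholds, most significant first: `***`
  p < 0.001, `**` p < 0.01, `*` p < 0.05, `NS` otherwise (p = 0.05 exactly
  is NS).

Fisher's protected LSD (`fisher_lsd()`) uses
$t_{1-\alpha/2,\ df_{err}} \sqrt{2\,MS_{err}/n}$ at the conventional
$\alpha = 0.05$ and is *protected*: a non-significant omnibus F for the
factor skips mean separation entirely. Letters are assigned from maximal
windows of the descending-sorted means whose range is within the LSD, which
guarantees the display invariant that two levels share a letter if and only
if their difference is at most the LSD.

Trait–trait Pearson correlations (`pearson_matrix()`) are computed within a
treatment on replicate-level values aligned by (hybrid, replicate) — n = 24
in the reference design. Computing on replicates rather than on the six
cell means is a deliberate choice: it is the only reading under which the
conventional significance tiers of such tables have their stated degrees of
freedom. Two-sided p-values use $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$
df. The star legend for correlation tables follows the trait-correlation
convention — `*` p < 0.01, `**` p < 0.001 — which deliberately differs from
the ANOVA legend; each emitting function honours its own table's legend. A
zero-variance trait yields `NA` (undefined), never 0.
`combined_matrix_report()` produces the compact display with drought
correlations above the diagonal and control below.

## The synthetic trial generator

`simulate_trial()` generates replicate-level observations around known cell
means — by default the bundled trial's table — so that every inference
stage has a testable ground truth. What it emulates and what it does not:

* **Emulates**: the design dimensions (genotype × treatment × block), known
  cell means, within-cell variation proportional to the mean
  (`Normal(mean, cv·|mean|)`, default CV 0.10 — a typical replicate-level
  CV for controlled-environment phenotyping; the reference trial published
  no within-cell variance, so this is a modelling choice, not a measured
  value), and non-negativity of the trait scales. Truncation at zero is by
  rejection (re-drawing), keeping the distribution continuous with no point
  mass at zero.
* **Does not emulate**: trait–trait correlation within a plant (cells are
  independent), block effects (blocks differ only by sampling noise),
  spatial or temporal chamber structure, or any soil-moisture dynamics.
  Passing tests on synthetic data therefore validate the arithmetic and the
  sampling behaviour of the estimators, not the biological covariance
  structure of real trials — in particular, synthetic correlation matrices
  are near-diagonal by construction.

A single RNG stream is seeded once per call and the row order is fixed
(genotype × treatment × replicate, traits in panel order), so output is
byte-reproducible from the seed. `randomize_layout()` produces a
randomized chamber-position assignment with each genotype occupying exactly
`n_replicates` positions per treatment.

## Replicate-level versus mean-only input

`dsri()` accepts either input. Replicate-level observations are collapsed
to cell means first (`collapse_to_means()`: arithmetic mean, SE as sample
standard deviation over $\sqrt n$ with the $n-1$ denominator, single-
replicate cells get an undefined SE) and the indices are computed from the
cell means — not averaged over per-replicate ratios, matching how the
indices are defined at the treatment level. `run_pipeline()` makes the
capability difference explicit: in mean-only mode the ANOVA and correlation
stages are skipped with the reason recorded in the manifest, because they
require replicates.

## Problem sizes and test design

The packaged checks run at desk scale by choice: everything computed from
the bundled means is instantaneous and exact; the generator-based
properties use 200 simulated trials (CV 0.10) for the drought-detection
rate of the Phot ANOVA, 50 trials (CV 0.05) for mean recovery, and small
toy designs for the ANOVA/correlation oracle equivalences (direct-summation
sums of squares, naive covariance ratios, paired-t equivalence of the
two-level treatment F). The drought effects in the bundled trial are large
(e.g. photosynthesis roughly halves), so the detection-rate property is
expected to sit at the ceiling.

## Known limitations

* Balanced designs only; no mixed models, no recovery of inter-block
  information, no unbalanced/missing-cell ANOVA.
* No multiple-testing correction across traits or correlation cells, by
  design fidelity to the screening convention the package implements.
* Exactly two treatments (one stressed, one control); multi-level stress
  gradients are out of scope.
* The CDSRI weights all member traits equally; no sensitivity analysis of
  trait subsets is automated beyond explicit `traits =` scoring.
* Single-harvest trials only: no time courses or growth curves.
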
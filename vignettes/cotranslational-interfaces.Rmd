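---
title: "Interface build-up during translation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface build-up during translation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotasm)
library(dplyr)
```

This vignette is the package's own account of the methods it implements:
the geometric model behind buried-interface areas, the translational
metrics derived from them, the assembly-order and onset-mapping
procedures, the inference layer, and — importantly — where the design was
genuinely open and what was decided.

## The geometric model

All interface quantities rest on solvent-accessible surface area (SASA):
the area traced by the centre of a 1.4 Å probe rolling over the van der
Waals spheres of the heavy atoms. We use the Shrake–Rupley sphere-point
method with a *deterministic golden-section lattice* rather than random
points, so results are exactly reproducible for a fixed point count. The
default of 960 points per atom keeps single-sphere areas within a few
hundredths of a per cent of the closed form $4\pi(r+p)^2$, and two-sphere
configurations within ~0.3% of the spherical-cap solution; the test suite
checks convergence against a 3840-point lattice. Hydrogens are ignored and
element radii come from a fixed table (C 1.70, N 1.55, O 1.52, S 1.80 Å),
the common heavy-atom convention of SASA tools.

The **buried surface area** of a chain pair is computed in the *pure
pairwise context*: side *a*'s in-complex ASA for the pair (*a*, *b*) is
evaluated in the presence of *b* only. This matches the additivity
assumption of interface-size based assembly prediction, where each
pairwise interface contributes its area independently of the rest of the
complex. The full-complex alternative is deliberately exposed as a
*different function* (`chain_buried_area()`) rather than a flag, because
per-pair attribution is undefined in the full-complex context and a flag
silently changing the semantics of "pair BSA" invites misuse.

Interfaces whose larger side buries ≤ 400 Å² are dropped by default; this
cutoff excludes crystal-packing contacts and restricts analyses to
biologically significant interfaces. A stricter 800 Å² per-partner rule is
used only in the multi-interface *inclusion* filter (a subunit must bury
> 800 Å² with at least two different partners to qualify as
multi-interface). Both are configuration keys (`min_area`,
`filter_config()$large_iface`), not hard-wired constants.

## Translational metrics

Residue positions are 1-based in the *full-length* protein sequence, so
gaps in the observed structure retain native numbering — required because
the relative location formula $(i-1)/(L-1)$ indexes the translated
sequence. $L$ is taken from a supplied full-length sequence table when
available, and from the maximum observed position otherwise; the source is
recorded per chain, because structures are often incomplete and the two
conventions differ.

The **midpoint** of an interface side is the smallest position whose
N-to-C cumulative per-residue BSA reaches half the side total. "Reaches"
is implemented as ≥ so that a single-residue interface is its own
midpoint; the midpoint is invariant to uniform scaling of the areas.
A midpoint with relative location ≤ 0.5 classifies the interface as
N-terminal-half — the boundary is assigned to the earlier-synthesised
half.

The **first** and **last translated interfaces** of a multi-interface
subunit are the ones exposing the most N-terminal and most C-terminal
interface residues (the symmetric treatment of the two termini). Two edge
cases are not dictated by the definitions and were decided here:

* *ties* on the extreme residue go to the larger-area interface (the one
  more likely to matter for assembly);
* *fully nested* interface sets — where one interface both starts first
  and ends last — have no meaningful first/last pair; such subunits are
  flagged `nested` and excluded from first/last comparisons.

## Assembly order

Assembly pathways are predicted by greedy agglomeration under interface
additivity: starting from single subunits, each step merges the two
components whose union gains the largest summed pairwise buried area.
An interface "forms" at the step where its chains first co-occur in one
component, so a late merge can gain several interfaces at once, all
sharing that step's normalised order $(s-1)/(S-1)$. A heterodimer's single
step is defined to have order 0. Steps at or below 0.5 are "early". Ties
in gained area are broken by the lexicographically smallest pair of
component representatives, making the pathway fully deterministic. Greedy
choice versus global optimisation was genuinely open (the underlying idea
is stated only as additivity); we committed to greedy and verify on every
complex of up to five subunits that it coincides with exhaustive
enumeration of merge sequences maximising stepwise gain — for tie-free
areas the two are provably the same, and the tests exercise this.
Sub-cutoff interfaces still contribute gained area but are not emitted as
ordered interfaces.

## Onset mapping

Assembly-onset positions name the codon being decoded when cotranslational
binding is detected; the residue actually outside the ribosome is ~30
residues behind, so onsets are shifted by a 30-residue tunnel offset
(configurable) and clamped at position 1 — the clamping rule covers onsets
≤ 30, for which no convention is stated anywhere. Each adjusted onset maps
to the *nearest interface midpoint*: compressing an interface to one
residue removes the bias whereby large interfaces, having many residues,
would attract onsets by area alone. If the nearest midpoint belongs to a
homomeric interface the onset is discarded (homomeric interfaces are
assumed to assemble in *cis* and sit higher in the interface hierarchy).
Equidistant midpoints resolve to the more N-terminal midpoint, consistent
with translation-time logic. Onsets beyond the annotated length
(isoform/annotation mismatches) are logged as `out_of_range` and skipped.

## Inference layer

Interface areas are right-skewed and left-bounded by the minimum-area
cutoff, hence rank tests throughout. Conventions worth stating:

* signed-rank tests default to one tailed (the directional "first larger"
  hypothesis); zero differences are dropped before ranking (standard
  Wilcoxon practice) and the method string records exact vs approximate;
* effect sizes are $r = |Z|/\sqrt{n}$ with $Z$ recovered from the p value;
  $|Z|$ because effect sizes are reported unsigned. The $n$ convention is
  exposed as a parameter (`effect_n`) since published values vary in what
  they count;
* Dunn's test is computed from pooled ranks with the standard tie
  correction and Holm step-down adjustment; no installed package provides
  it, so it is implemented here and validated against independently
  computed reference values;
* the odds ratio is the *sample* odds ratio $ad/bc$ (which matches printed
  "x times more likely" figures), not the conditional-MLE estimate of
  `fisher.test()`; the p value is Fisher's exact (two-sided by default,
  with `alternative` exposed);
* the stratified bootstrap resamples within strata at their own sizes and
  applies the finite-sampling correction
  $p = (1 + \#\{\hat\theta \le 0\})/(B+1)$, so $p$ is never 0 and is
  bounded below by $1/(B+1)$; $B = 10^4$ by default. A seed is a required
  argument of every stochastic operation — there is no hidden global
  state;
* Jeffreys binomial intervals are equal-tailed quantiles of
  $\mathrm{Beta}(x+\tfrac12,\, n-x+\tfrac12)$ at 68% coverage (one-sigma
  error bars), with the lower/upper limit pinned to 0/1 at the boundaries.

## The synthetic generator: what it emulates, and what it does not

`generate_complex()` builds coarse-grained complexes with one 3 Å bead per
residue. Planned contact windows of a chain pair interdigitate at a
dedicated site ≥ 1000 Å from everything else, so interfaces are strictly
pairwise, additive, and their areas scale with window length — which makes
closed-form and brute-force oracles tractable. The bead model reproduces
none of real protein geometry (packing, secondary structure, atom-level
chemistry); what it shares with real structures is exactly what the
pipeline consumes: spheres with radii, chain/residue bookkeeping, and
sequence-localised contacts. Passing tests therefore validate the
*machinery* (SASA, BSA accounting, midpoints, ordering, mapping), not any
claim about real proteomes.

`generate_cohort()` draws tabular cohorts of multi-interface subunits.
Calibration of the defaults, chosen once:

* first/last areas are log-normal (interface sizes are right-skewed) with
  `meanlog = log(1300)`, giving a ~205 Å² mean first-last difference at
  the default ratio — the magnitude reported for bacterial subunits;
* the first/last mean ratio is `delta = 1.15` (a 15% excess);
* the log-sd `sigma_log = 0.35` was calibrated jointly against the two
  magnitudes the cohort is meant to exhibit: the first interface larger in
  ~60% of subunits ($\Phi(\log 1.15 / (\sigma\sqrt2)) = 0.61$) *and* a
  reliably detectable paired excess at cohorts of ~150 subunits
  (one-tailed signed-rank power ≈ 0.95). The exact inversion of the 60%
  figure alone ($\sigma = 0.39$) would put detection power exactly at the
  design threshold, which is not a usable operating point for a generator
  whose purpose is recovery testing;
* the cotranslational flag follows a logistic link on centred log area
  (slope 1, base rate 0.3) — larger-interface subunits are more often
  cotranslational; a zero slope decouples them, the null used in tests;
* onsets are placed at a designated interface's midpoint + 30 (tunnel) +
  Gaussian noise (σ = 5 residues by default), and 15% of subunits carry a
  C-terminal homomeric decoy interface to exercise the discard rule;
* age-class and operon labels are assigned at fractions 0.5 and 0.45, and
  per-stratum `delta` overrides allow stratum-specific effects for
  bootstrap recovery tests.

What the cohort generator does **not** emulate: correlation between
interface size and protein length, multi-complex membership, measurement
error in onset detection beyond Gaussian jitter, and the confidence-class
structure of experimental annotation pipelines.

Titration curves are Henderson–Hasselbalch net charge on a 0–14 pH grid
(step 0.1) with the EMBOSS pKa set including free termini; the curve is
monotone non-increasing, so the isoelectric point interpolation is
well-defined. These synthetic curves stand in for continuum-electrostatics
outputs, which model structure-dependent pKa shifts the
Henderson–Hasselbalch form ignores; the *interpolation step* is identical
either way.

## Numerical choices and degenerate inputs

* Coincident atom centres are tolerated: each sphere's points lie on the
  other's surface and are occluded under the strict inequality, which is
  the conservative outcome.
* Per-residue BSA is exactly non-negative (occluders only added), so no
  clipping is needed; the per-residue detail sums to the side totals to
  within 10⁻⁶ relative, a tested conservation law.
* Identical samples short-circuit the rank-sum test to $p = 1$, $r = 0$;
  all-zero difference vectors are an error (the signed-rank test is
  undefined); $p = 0$ raises an underflow error in the effect size rather
  than returning $\infty$.
* Degenerate 2×2 tables (a zero cell) report an infinite or zero odds
  ratio with a `degenerate` flag instead of failing.
* Dunn's variance can collapse to zero when all values tie; $z$ is then
  defined as 0 ($p = 1$).

## Problem sizes in tests

The suite exercises the oracles at sizes where exhaustive computation is
exact and fast: bead complexes of 2–3 chains × 45 residues for the
brute-force BSA checks (20 random complexes), all merge orders for 2–5
subunit complexes (≤ 180 sequences each), 100 random configurations for
occlusion monotonicity, 100 seeds for detection power, 2000 simulations
for null calibration, and 500 replications at $B = 500$ for bootstrap
null uniformity. These sizes were chosen to make the Monte-Carlo error of
each check small relative to its tolerance.

## Known limitations

* The SASA engine is sphere-point, not analytic (Lee–Richards); accuracy
  is bounded by the lattice density, though 960 points is ample for
  residue-level areas.
* Pure pairwise BSA ignores three-body occlusion; in tightly packed
  complexes a pair's buried area in situ differs from the isolated-pair
  value. The choice is deliberate (additivity), but users comparing to
  full-complex numbers should use `chain_buried_area()`.
* Whole residues are classified apolar/charged/polar; boundary residues'
  buried area is not split by atom class.
* The contact-based affinity model ships *no* trained coefficients —
  predictions require a user-supplied coefficient vector, and the model is
  a plain linear form.
* Greedy assembly prediction is known to degrade for very large
  complexes; complexes with ≥ 10 subunits are excluded by the standard
  filter for exactly that reason.
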
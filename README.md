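# cotasm

Structural analysis of cotranslational protein complex assembly.

Most proteins work as multimeric complexes, and many complexes begin to
assemble while their subunits are still being translated. Because synthesis
is vectorial (N to C), an interface encoded early in the sequence has more
time to capture a partner before translation finishes. `cotasm` implements
the structural side of testing whether complexes have *evolved* for this:
from multi-chain atomic structures it computes pairwise buried interfaces
and how they build up during translation, maps experimentally determined
assembly-onset positions onto interfaces, predicts complex assembly order
from interface sizes, and provides the nonparametric inference layer used
to compare first- and last-translated interfaces across cohorts of
subunits. It is aimed at structural bioinformaticians working with protein
complex structures (PDB biological assemblies or computed models) together
with ribosome-profiling-derived assembly-onset annotations.

## The quantities at the core

For a chain pair (*a*, *b*), the per-residue **buried surface area** (BSA)
is the difference in solvent-accessible surface area (Shrake–Rupley, 1.4 Å
probe) of each residue with its chain in isolation versus in the presence
of the partner: the "interface size" of each side. From the per-residue
build-up the package derives, per subunit of length *L*:

- **interface midpoint** *i* — the residue at which half of an interface's
  eventual buried area is exposed, and its **relative location**
  (*i* − 1)/(*L* − 1);
- **first / last translated interfaces** — the interfaces exposing the most
  N- and most C-terminal interface residues;
- **relative translational distance** (*f*<sub>last</sub> −
  *f*<sub>first</sub>)/*L*, where *f* is an interface's first residue;
- **relative size difference** (BSA<sub>first</sub> − BSA<sub>last</sub>) /
  (BSA<sub>first</sub> + BSA<sub>last</sub>);
- **assembly order** — greedy agglomeration of subunits assuming additivity
  of pairwise interfaces, giving each interface a normalised 0-to-1 order
  (early ⇔ ≤ 0.5);
- onset mapping — assembly-onset positions, shifted 30 residues for the
  ribosome exit tunnel, mapped to the nearest interface midpoint
  (homomeric nearest ⇒ discarded).

The statistics layer provides Wilcoxon rank-sum/signed-rank tests with
*r* = |*Z*|/√*n* effect sizes, Dunn's test with Holm–Bonferroni correction,
Fisher's exact odds ratios, stratified bootstrap with finite-sampling
correction, Jeffreys 68% binomial intervals, and Spearman correlation.
A synthetic generator (bead-model complexes with planned contact windows,
and tabular cohorts with controlled effect sizes) makes every stage
testable against closed-form and brute-force oracles.

## Worked example

A toy three-chain complex in which chain A contacts B through an early,
24-residue window and C through a late, 12-residue window:

```r
library(cotasm)
library(dplyr)

spec <- complex_spec(
  chains = c(A = 60, B = 40, C = 40),
  interfaces = tibble::tibble(
    chain_a = c("A", "A"), chain_b = c("B", "C"),
    start_a = c(5, 35), end_a = c(28, 46),
    start_b = c(5, 10), end_b = c(28, 21)
  )
)
cx     <- generate_complex(spec, complex_id = "toy")
ifaces <- pairwise_interfaces(cx, probe = 1.4, min_area = 400)
select(ifaces, chain_a, chain_b, bsa_a, bsa_b, midpoint_a, first_res_a, last_res_a)
#> # A tibble: 2 × 7
#>   chain_a chain_b bsa_a bsa_b midpoint_a first_res_a last_res_a
#> 1 A       B        981. 1005.         17           5         28
#> 2 A       C        504.  515.         41          35         46
```

Chain A buries ~981 Å² with B (midpoint at residue 17) and ~504 Å² with C
(midpoint at 41) — the planned 2:1 window ratio. Its first/last interface
summary and the predicted assembly order:

```r
profiles <- subunit_profiles(ifaces, chains = chain_summary(cx))
first_last_interfaces(profiles, min_area = 400)
#>   chain first_partner last_partner bsa_first bsa_last rel_distance rel_size_diff
#> 1 A     B             C                 981.     504.          0.5         0.322

tidy(predict_assembly_pathway(ifaces))
#>   chain_a chain_b   bsa  step normalized_order label
#> 1 A       B       1986.     1                0 early
#> 2 A       C       1019.     2                1 late
```

The first-translated interface (with B) is the larger one (relative size
difference +0.32) and is predicted to form at the first assembly step. An
assembly-onset at raw position 45 (tunnel-adjusted to 15) maps to that
interface's midpoint:

```r
map_onsets(profiles, tibble::tibble(protein_id = "A", onset = 45))
#>   protein_id raw_onset adjusted_onset interface midpoint status
#> 1 A                 45             15 B               17 mapped
```

Cohort-level inference on a synthetic cohort of 150 multi-interface
subunits whose first interfaces are 15% larger on average:

```r
co <- generate_cohort(n = 150, delta = 1.15, seed = 20220728)
wilcoxon_signed_rank(co$bsa_first - co$bsa_last, alternative = "greater")
#>   statistic p_value effect_size     n tails method
#> 1      7299 0.00107       0.251   150 one   wilcoxon_signed_rank_normal_approx
```

The one-tailed signed-rank test detects the first-interface excess
(p ≈ 0.001, effect size r ≈ 0.25).

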
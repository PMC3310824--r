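---
title: "Inferring parents and correcting linkage phase in biparental inbred populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring parents and correcting linkage phase in biparental inbred populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossphase)
```

## The data-generating model

`crossphase` targets populations derived from a single cross between two
(nominally) inbred parents, followed by repeated selfing: F₂, F₃, ...
and recombinant inbred lines (RILs). We index generations by `x` with
F₁ = the hybrid itself, so a population selfed `x − 1` times is F_x.
For RILs whose exact generation is unknown, `generation = "RIL"` is an
alias for x = 10, where residual heterozygosity (1/2)⁹ is below 0.2% and
all statistics are effectively at their fixation limits.

Per marker, three cross types are possible at the initial cross, and each
implies a closed-form genotype distribution at F_x
(`expected_proportions()`):

| cross | p(hom1) | p(het) | p(hom2) |
|---|---|---|---|
| AA × aa | 1/2 − (1/2)^x | (1/2)^(x−1) | 1/2 − (1/2)^x |
| Aa × Aa | 1/2 − (1/2)^(x+1) | (1/2)^x | 1/2 − (1/2)^(x+1) |
| AA × Aa | 3/4 − (1/2)^(x+1) | (1/2)^x | 1/4 − (1/2)^(x+1) |

Each selfing round halves the heterozygote class and adds a quarter of the
previous heterozygote fraction to each homozygote, which is the recurrence
the property tests quantify. Two consequences drive the whole method: a
homozygote × homozygote marker segregates 1:1 between its homozygote
classes at every generation, while a homozygote × heterozygote marker
approaches a 3:1 split of major homozygote versus everything else.

## Cross-type inference and filtering

`infer_cross_type()` compares two 1-df χ² statistics: the 1:1 test on the
homozygote counts, (n₁ − n₂)²/(n₁ + n₂), and the Pearson test of
(major homozygote) : (other homozygote + heterozygotes) against
(3/4 − (1/2)^(x+1)) : (1/4 + (1/2)^(x+1)). The cross type with the smaller
statistic is assigned. Design choices here:

* **Heterozygotes are excluded from the 1:1 test** — it is defined on the
  two homozygote classes only. Using major-vs-rest for the second test
  absorbs the shrinking heterozygote class and avoids the small-sample bias
  that a three-class test would suffer in advanced generations.
* **Ties go to hom × hom**, the default assumption for inbred parents.
* **A het × het cross is never called.** After selfing it is
  indistinguishable from hom × hom (both give a 1:1 homozygote ratio), and
  its prior probability for inbred, self-pollinated parents is negligible;
  only the hom-hom/hom-het distinction changes the parental output.
* **No multiple-testing correction**: each marker is tested at a fixed
  α (default 0.05), configurable. With dense, linked markers both false
  positives and true distortions arrive in runs of adjacent markers; a
  study-wide correction would trade distortion sensitivity for retention in
  a way the downstream phase walk does not need.

`segregation_filter()` removes non-biallelic, monomorphic, uninformative
(no homozygous call), overly missing (default > 50%), and distorted markers
— those whose *better-fitting* cross-type test is still rejected at α. Note
the deliberate consequence that a hom × hom marker with a badly skewed 1:1
ratio may instead be retained as hom × het when that model fits; the
parental output then reports a heterozygous parent, which is exactly the
reinterpretation the off-parent model calls for.

## Phase between adjacent markers

For two markers at map distance `d` the recombination fraction is
`map_distance_to_r(d)`: Haldane r = (1 − e^(−2d))/2 (no interference) or
Kosambi r = tanh(2d)/2. **Haldane is the default** because the per-interval
independence assumed by both the phase walk and the simulator *is* the
Haldane model; Kosambi is offered for maps expressed in Kosambi units.
Distances are centimorgan and converted to Morgan internally.

Only individuals double-homozygous at both markers are informative
(`pair_counts()`). Under coupling, the same-class diagonal (AABB + aabb)
expects proportion P_p = (1 − r)²/(1 − 2r(1 − r)) of the diagonal and the
opposite-class pairs expect P_r = r²/(1 − 2r(1 − r)):

```{r}
pp <- expected_phase_proportions(map_distance_to_r(30))
round(unlist(pp), 4)
```

Because P_p ≥ P_r with equality only at r = 0.5, `infer_pair_phase()`
decides by the raw count comparison — coupling if n_parental >
n_recombinant, repulsion if smaller, ambiguous on ties — and attaches the
1:1 χ² of the two counts for audit only. Even a weak 35:15 outcome at a
30 cM interval is decisive:

```{r}
infer_pair_phase(35, 15, d = 30)[, c("phase", "statistic", "p_value")]
```

One caveat recorded as a known limitation: for this worked configuration our
statistic is (35 − 15)²/50 = 8 with a 1-df p of 0.0047; an exact one-sided
binomial gives ≈ 0.003. Values materially smaller than that are not
reproducible from the count test itself. The decision (coupling, clearly
significant) is what matters and is unaffected.

## The walk along a linkage group

Crossover events in disjoint intervals are treated as independent, so phase
information propagates marker-to-marker as a left-to-right Markov walk
(`phase_linkage_group()`):

* Anchor markers (orientation known, e.g. from observed parents) seed each
  group. Every other marker is phased against the nearest already-oriented
  marker on its left, with the diagonal counts taken against the anchor's
  *corrected* orientation, so the reported phase is relative to the
  reference chain and `flipped` is simply `phase == "repulsion"`.
* Ambiguous markers stay unoriented and never anchor later markers.
* Markers left of a segment's first anchor are phased right-to-left from
  it. The one-directional walk alone would leave a masked leftmost marker
  arbitrarily oriented even with anchors just to its right; the backward
  pass costs nothing and removes that edge case.
* Gaps wider than `max_gap` (default 50 cM) sever propagation: beyond that
  distance P_p approaches P_r and the count comparison carries little
  information. The downstream segment restarts as its own arbitrarily
  oriented block, flagged `arbitrary`.
* A group with no anchor at all is seeded by its leftmost informative
  marker, declared coupling by convention, and flagged: without parental
  information the group's *global* orientation is unidentifiable — only
  relative orientations within the group are meaningful. Validation
  therefore scores orientation recovery modulo this per-group sign.

`recode_abh()` swaps A↔B at every `flipped` marker (progeny and parental
rows alike); H and missing calls are untouched, and applying the same phase
table twice is the identity.

## Parental reconstruction and recoding

`infer_parent_genotypes()` anchors the walk at markers whose observed
parents are complete, homozygous for the two progeny alleles, and
consistent with a hom × hom cross. For each marker the orientation assigns
one allele to each parent: a hom × hom marker gets the two homozygotes; for
hom × het the heterozygous parent is the one whose haplotype carries the
minor homozygote's allele. That minor-allele assignment is only attempted
when at least `min_informative = 5` individuals are double homozygous at
the marker and its anchor with the minor class involved — below that the
phase of a rare class is noise and the marker is left unresolved.

Observed parental calls that contradict the inference are reported as
`conflict` — the off-parent case. In the inferred-genotype columns the
inference wins (the premise is that the genotyped stock differs from the
real parent), but both values are always reported side by side.
`acgt_to_abh()` recodes progeny relative to the reconstructed parents
(parent-1 allele → A, parent-2 → B, heterozygote → H); markers that are
unresolved, in conflict, or monomorphic in the parents are excluded and
listed rather than guessed at. For a heterozygous parent the allele unique
to that parent defines its side. The heterozygous parent itself is written
as the two-allele token (e.g. `AC`); ABH output writes `H`.

## The simulator

`simulate_population()` generates data from exactly the model above: true
parents built with a chosen fraction of residual heterozygosity in parent 1;
each line descending from its own F₁; `x − 1` rounds of selfing with
per-interval Bernoulli recombination at the Haldane rate of the interval
(under Kosambi the per-interval rates are still applied independently,
which makes Kosambi an approximation there — documented trade-off);
then three noise layers with ground truth recorded: off-parent fixation of
heterozygous parent-1 loci at a chosen rate, uniform missingness, and
A↔B flip injection into the emitted ABH matrix. One seeded stream drives
everything, so a configuration plus seed is bit-reproducible.

What it does *not* emulate: crossover interference, genotyping error in the
progeny, segregation distortion from selection, non-uniform missingness,
and multi-allelic markers. Passing the recovery tests therefore shows the
algorithms are correct under the model's assumptions, not that real data
meet those assumptions — distorted markers must be filtered first, which is
why the filter is part of every pipeline entry point.

## Numerical and validation choices

* χ² p-values use the exact 1-df survival function (`pchisq`,
  upper tail); tests cross-check it against the erfc(√(s/2)) identity and
  the two-cell statistics against `chisq.test` as independent oracles.
* Validation problem sizes are chosen so the whole suite runs in seconds:
  the Monte-Carlo check of the simulator against the analytic two-locus
  table uses one F₂ of 20,000 individuals and a 3-standard-error band;
  recovery experiments use a RIL of 150 lines × 100 markers at 2 cM with
  20% flips and 5% missing calls (orientation restored ≥ 99% modulo the
  group sign) and 10% masked parent-1 calls (≥ 95% recovered).
* Degenerate inputs: tied diagonal counts and empty diagonals are
  `ambiguous`, zero-homozygote markers are `uninformative` errors at the
  single-marker level and filtered reasons at the dataset level; all-missing
  columns fall under the missingness filter.
* Tokens: missing defaults to {`-`, `.`, `N`, ``} case-insensitively,
  configurable, since file conventions vary. ACGT heterozygotes are
  accepted both as two-letter tokens (order-insensitive) and IUPAC
  ambiguity letters, and written back in canonical alphabetical two-letter
  form; ABH also accepts AA/AB/BB doubled tokens.

## Limitations

Outcrossing designs (CP, backcross), multi-allelic markers, estimating r
from the data (r always comes from the supplied map), marker re-ordering,
and multipoint-likelihood phasing are out of scope. Exporters cover the
generic tab-delimited table and MapQTL `.loc`; the `popt` token for `.loc`
defaults to `RI<x>` and is exposed as an argument because conventions
differ between MapQTL versions.
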
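# crossphase

Parental genotype inference and linkage phase correction for biparental
inbred mapping populations.

## The problem

Genetic maps for recombinant inbred line (RIL) and other selfing-derived
populations need the *parental phase* of every marker: which allele came
from which parent. In practice the genotyped parental stocks are often not
the plants that actually made the cross — a parent may have been
heterozygous at some loci when the population was initiated and fixed at
random during later maintenance, or the genotyped individual may carry
residual variation of the line. Markers then segregate although the
genotyped "parents" look fixed (or vice versa), parental calls are missing,
and ABH-coded matrices contain phase flips that wreck map construction.
With modern SNP densities these "off parent" cases number in the hundreds
per population and fixing them by hand is slow and subjective.

`crossphase` automates the repair. It works on plain tab-delimited genotype
matrices (individuals × markers, ACGT or ABH coding) plus a genetic map
(marker, linkage group, position in cM), and it is aimed at people building
linkage maps for selfing crops.

## The model

For a marker in generation F_x (x − 1 rounds of selfing after the
cross; F₁ is the hybrid) the expected genotype proportions are closed
forms in x. For a homozygote × homozygote cross (AA × aa) the two homozygote
classes stay 1:1 forever with heterozygote fraction (1/2)^(x−1); for a
homozygote × heterozygote cross (AA × Aa) the major homozygote expects
3/4 − (1/2)^(x+1) of the population. Two 1-df χ² tests decide each marker's
cross type:

* test (a): χ² = (n₁ − n₂)² / (n₁ + n₂) on the two homozygote counts
  against 1:1;
* test (b): Pearson χ² of the split (major homozygote) : (rest) against
  (3/4 − (1/2)^(x+1)) : (1/4 + (1/2)^(x+1)).

The smaller statistic wins (ties go to hom × hom). Markers that fail the
better-fitting test at α are removed as distorted, along with monomorphic,
gap-ridden, and non-biallelic markers.

For two markers at map distance d, the recombination fraction r comes from
Haldane's map function r = (1 − e^(−2d)) / 2 (or Kosambi's r = tanh(2d)/2),
and among the four double-homozygote classes the same-class (parental,
coupling) and opposite-class (recombinant) proportions are

    P_p = (1 − r)² / (1 − 2r(1 − r)),   P_r = r² / (1 − 2r(1 − r)).

At 30 cM (Haldane) these are 0.9218 and 0.0782 — so even at large
intervals the direct comparison of the two diagonal counts decides the
phase safely without any test; the χ² of the counts is attached for audit.
Phase propagates along each linkage group from anchor markers (those with
trustworthy observed parents) and repulsion-phase markers are flipped when
recoding ABH data. Combining cross type and phase reconstructs the actual
parental genotypes, flags off-parent conflicts, and converts ACGT matrices
to ABH.

## Worked example

Simulate a RIL population (F₈, 150 lines, 40 SNPs at 2 cM) whose parent 1
was heterozygous at 10% of loci and was genotyped after fixation at half of
those — the off-parent scenario — then repair it:

```r
library(crossphase)

sim <- simulate_population(sim_config(
  n_ind = 150, generation = 8, markers_per_group = 40, spacing_cM = 2,
  coding = "ACGT", het_parent1 = 0.1, offparent_rate = 0.5,
  missing_rate = 0.03, seed = 42))

flt     <- segregation_filter(sim$data)   # removes 8 distorted markers
parents <- infer_parent_genotypes(flt$data, sim$map)
glance(parents)
#> # A tibble: 1 × 5
#>   n_markers n_observed n_inferred n_conflict n_unresolved
#>       <int>      <int>      <int>      <int>        <int>
#> 1        32         31          0          1            0

dplyr::filter(parents, source == "conflict") |>
  dplyr::select(marker, p1_observed, p1_inferred, cross_type)
#> # A tibble: 1 × 4
#>   marker p1_observed p1_inferred cross_type
#> 1 M1_017 C           AC          hom_het
```

The one conflict is exactly the injected off parent: the genotyped parent 1
reads a fixed `C` at M1_017, but the progeny segregation (major:rest fit of
test (b)) plus the phase of the minor homozygote along the map show the real
parent 1 was heterozygous `AC`. `acgt_to_abh(flt$data, parents)` then
yields a clean ABH matrix for mapping; for data already in ABH,
`phase_linkage_group()` + `recode_abh()` fix phase flips:

```r
r <- map_distance_to_r(30)            # 0.2255942  (Haldane)
expected_phase_proportions(r)         # P_p = 0.9218, P_r = 0.0782
infer_pair_phase(35, 15, d = 30)      # coupling; chi-square 8.0, p = 0.0047
```

The same workflow is available from the shell via
`Rscript inst/cli/crossphase.R <subcommand> ...` with subcommands
`simulate`, `filter`, `check-parents`, `convert`, `phase-correct`
(see `run_cli()`).

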
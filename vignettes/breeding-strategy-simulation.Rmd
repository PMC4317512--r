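---
title: "Simulating marker-assisted breeding strategies with breedsimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating marker-assisted breeding strategies with breedsimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsimr)
```

## The question the package answers

A breeder who knows, from QTL analysis, which alleles they want at a few
dozen diagnostic loci still has to choose *how* to assemble them into one
homozygous line: produce doubled haploids straight from the F2, bulk-self
to F6 as recombinant inbred lines, or advance a few seeds per plant by
single-seed descent. The strategies differ in cost, in cycle length and —
because selection acts at different points — in how many finished lines
carry the full target genotype. `breedsimr` simulates these choices for a
biparental cross between fully homozygous parents and scores them by the
number of target genotypes recovered and by genetic gain per cycle and
per year.

## Genetic model

Every locus is biallelic, with alleles coded by parental origin: `A` for
the Avalon-derived allele and `C` for the Cadenza-derived allele. A line
is two phased haplotypes per chromosome, aligned to a linkage map.

* **Recombination.** Adjacent-locus recombination fractions come from the
  Haldane map function, $r = \tfrac12(1 - e^{-2d/100})$ for a distance
  $d$ in cM, i.e. crossovers are a Poisson process with no interference.
  Loci on different chromosomes segregate freely ($r = 0.5$). A gamete is
  sampled per chromosome as a two-state Markov chain along the loci: fair
  choice of starting haplotype, switch between adjacent loci with
  probability $r$.
* **Genotype to phenotype.** Traits are purely additive. A locus with
  additive effect $a$ (in trait units) contributes $+a$ when homozygous
  for the effect-increasing parent's allele, $-a$ for the opposite
  homozygote, and $0$ when heterozygous — no dominance, no epistasis.
  Effects are tabulated per trait and environment; genotypic values are
  sums over effect loci plus a baseline. The default baseline is 0, so
  predictions are genotypic values relative to the midparent; absolute
  parental means, if known, can be supplied as `baseline`.
* **Pleiotropy.** A locus may carry effect entries for several traits
  (one entry per trait × environment). Tightly linked pairs can instead
  be represented as separate co-located loci; at distance 0 the map
  machinery makes them a single inheritance unit.

## Line-development strategies

All three strategies start from the F1 of two homozygous parents and an
F2 of configurable size, apply **F2 enrichment** — discard every F2
plant homozygous for the non-target allele at any segregating target
locus — and end with marker-assisted selection of lines homozygous for
the target allele at *all* target loci:

* **F2–DH**: the requested number of DH lines is produced from the
  retained F2 plants (one sampled gamete per line, doubled). Lines are
  allocated round-robin so retained plants contribute near-equally; the
  alternative (uniform random donors) changes only the variance, not the
  expectation.
* **RIL**: bulk selfing from F3 to F6 at a fixed census; each plant is a
  self-seed of a random plant of the previous generation (round-robin
  from the retained F2 into the F3). Final selection at F6.
* **Modified SSD**: a large F2 with pedigree-tracked enrichment; each
  retained plant leaves three self-seeds in the F3, and from F4 to F6 the
  three-seeds-per-plant bulk is sampled back to the F3 census, so the
  census stays at three times the retained count. Final selection at F6.

Enrichment never discards a plant that could still reach the target:
a removed plant is homozygous for a wrong allele somewhere and has
target probability exactly zero. For $k$ independently segregating loci
the closed forms used as oracles are: retention $N(3/4)^k$; F2–DH target
count $N_\mathrm{DH}(2/3)^k$ (after enrichment a locus is fixed-target
with probability 1/3 and heterozygous with 2/3); and F6 target count
$N(31/48)^k$, since four selfing generations leave a heterozygous locus
fixed-target with probability $15/32$, giving
$1/3 + (2/3)(15/32) = 31/48$ per locus (`analytic_expectations()`).

## Adjusted fitness and genetic gain

Yield fitness is reported on a 0–100 scale anchored at the two extreme
target genotypes: with $TG_l$ and $TG_h$ the genotypic values of the
all-decreasing and all-increasing homozygotes,
$$F_{ad} = \frac{F - TG_l}{TG_h - TG_l}\times 100,$$
where $F$ is the population mean yield genotypic value. Gain per cycle is
$F_{ad}$ of the selected target lines minus $F_{ad}$ of the F2 before any
selection; replicates that recover no target line leave the population
unchanged and contribute zero. Gain per year divides by the cycle length:
2 years for F2–DH (doubled haploids within a year, two glasshouse
generations per year), 3 years for RIL and modified SSD. $F_{ad}$ is
invariant under affine rescaling of all effects and baseline, which makes
gains comparable across effect parameterisations.

## The packaged Avalon × Cadenza panel

`avalon_cadenza_fixture()` ships the 23-locus selection panel of the
Avalon × Cadenza wheat reference population: yield (GY), height (PH),
ear-emergence (EM), grain-dimension, root, solid-stem, vernalisation
(*Vrn-A1b*), mosaic-resistance (*Sbm1*) and yellow-rust (*Yr6*, *Yr7*)
loci, the five DH parents DH27, DH61, DH182, DH109 and DH160, and the
homozygous target genotype. The three canonical crosses segregate at 13
(DH61×DH182), 15 (DH27×DH61) and 16 (DH109×DH160) target loci.

Two aspects of the fixture are package choices, clearly flagged:

* **Effects.** Printed additive effects (e.g. 0.37 t/ha for the 2D yield
  locus, 4.92 cm for its pleiotropic height effect, 2.4 cm at the 3B
  solid-stem locus) carry `provenance = "paper"`. Magnitudes that were
  never published — including all per-year (2005–2008) effects, which are
  the multi-environment value plus a zero-sum synthetic year deviation —
  carry `provenance = "synthetic"`. The deviations are constructed so the
  all-favourable yield genotype has its worst predicted year in 2006.
* **Map positions.** Chromosome assignments follow the locus names, but
  within-chromosome cM positions for these loci were never published.
  The packaged positions are therefore defaults, not measurements. They
  were fixed once, using an exact per-chromosome enumeration of
  enrichment survival and target probabilities, so that the panel's
  documented selection outcomes (retained population sizes around
  47/40/50/238 and mean target counts around 9.6/6.2/2.3 for the three
  strategies on DH61×DH182) are reproduced in expectation. Loci sharing
  a chromosome are loosely linked (gaps of roughly 78–150 cM). A tight
  cluster of the five 5A selection loci would be inconsistent with those
  outcomes: the DH61×DH182 target haplotype needs a double crossover
  within that group, so tight linkage would make target genotypes
  vanishingly rare. Supply your own locus table to
  `avalon_cadenza_fixture()` to explore other geometries;
  `unlink_map()` gives the independence benchmark.

## Scenario populations

`scenario_spec()` defines the 14-locus GY/PH/EM panel used to generate
large simulated DH (SDH) populations from the Avalon × Cadenza F1.
Scenario 1 treats all 14 loci as independent (200,000 lines by default:
with $2^{14}$ equally likely DH classes at $0.0061\%$ each, that size
leaves every class represented). Scenario 2 merges the 2D yield/height
pair and the 3A height/ear-emergence pair into single pleiotropic units
(complete linkage; 50,000 lines over $2^{12}$ classes at $0.0244\%$).
Complete linkage is the deliberate default reading of pleiotropy —
partial linkage is available by editing the scenario map, but then the
"merged" classes are no longer structurally empty. Consequences probed
by `classify_by_yield()` and `attainable_ideal_genotypes()`: under
scenario 2 no recombinant class inside a merged pair ever occurs, short
plants are absent from the highest yield category, and three of the nine
packaged ideal genotypes (which combine the 3A height and ear-emergence
alleles from different parents) become unattainable. The nine ideal
patterns are themselves synthetic reconstructions consistent with the
published constraints, shipped as `ideal_sdh_synthetic.tsv`.

## Randomness, reproducibility and problem sizes

A single master seed governs every run. Replicate $i$ uses
`derive_seed(master, i)` — a deterministic map into $[0, 2^{31})$ — so
any replicate is reproducible in isolation and `run_pipeline()` output
is byte-identical for a fixed configuration and seed. Headline
quantities are means over 1,000 replicates with standard errors
$s/\sqrt{n}$ (reported as absent, not zero, when $n = 1$).

The test suite validates the engine against independent oracles: exact
closed forms for one- and two-locus Mendelian and linkage expectations;
an exact enumeration oracle (HMM gamete distributions and exact selfing
transitions over haplotype-pair states) for multi-locus enrichment
strategies; and chi-square goodness-of-fit at $p > 0.001$ for ratio
checks. Monte-Carlo assertions use three standard errors. To keep the
default suite fast, tests use $10^4$–$10^5$ gametes for meiosis checks,
150–300 replicates for full strategy runs (1,000 for enrichment-only
runs), and a 6-locus down-scaled panel for the class-frequency
chi-square; `scripts/acceptance.R` runs the full 1,000-replicate
configurations.

## What the simulator does and does not show

Passing tests demonstrate internal consistency with the stated genetic
model, not field reality. The model has no dominance, no epistasis, no
genotype-by-environment re-estimation (per-year effects are fixed
inputs), perfectly diagnostic markers (selection acts on the QTL
themselves, with no flanking-marker recombination loss), no missing
genotype calls, no selection between F3 and F6 in the bulked strategies,
and no cost model — cycle counts stand in for time but not money. The
synthetic-cross generator (`generate_synthetic_cross()`) emulates the
structure of the panel — homozygous parents, mixed-origin targets,
field-realistic effect magnitudes, optional linked clusters — but draws
effects uniformly and places clusters regularly; it does not reproduce
the empirical joint distribution of real QTL effects and positions.
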
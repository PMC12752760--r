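---
title: "Scoring the neoantigenic potential of TP53 missense variants"
author: "neoPNS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the neoantigenic potential of TP53 missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoPNS)
```

## The problem

Carriers of pathogenic germline *TP53* missense variants (Li-Fraumeni
syndrome, LFS) differ widely in age at first cancer and in tumour spectrum,
even among variants with near-identical functional profiles. One candidate
explanation is immunological: a missense variant changes the protein
sequence, and some of the resulting mutant nonamers are predicted to bind
HLA class I molecules and be presented to CD8+ T cells. A variant whose
peptides are widely presentable may be under immune surveillance in its
carriers, delaying or attenuating tumour development; a variant sitting in
a "gap" of the HLA-I repertoire escapes it.

neoPNS quantifies this per variant, combines the prediction with
population HLA-I allele frequencies, and provides the statistical battery
for relating the resulting score to carrier phenotypes.

## From a variant to its Predicted Neoantigenic Score

For a missense variant at protein position $p$ of a protein of length $L$,
every 9-residue window containing $p$ is a candidate MHC-I ligand. Window
starts run from $\max(1, p-8)$ to $\min(L-8, p)$: nine windows for
interior positions, fewer within eight residues of a terminus. Terminal
variants are scored on their reduced window set rather than excluded, so
the whole missense space of the protein can be scored uniformly.

Each mutant window (paired with its wild-type counterpart) is assigned a
predicted binding affinity in nM against a panel of HLA-I alleles — in
practice 145 alleles across loci A, B and C. Affinities at or above 500 nM
are treated as non-relevant, the conventional binder threshold for
IC50-like predictions. Four per-variant metrics follow:

* **MAS** (Minimal Affinity Score): the lowest affinity over all
  (window, allele) cells; undefined when nothing falls below 500 nM.
* **HCS** (HLA Count Score): the number of alleles with at least one
  sub-threshold window.
* **WCS** (World Coverage Score): the estimated fraction of the world
  population carrying at least one responsive allele. With $s_\ell$ the
  summed frequency of responsive alleles at locus $\ell$ (clamped to 1),

  $$\mathrm{WCS} = 1 - \prod_{\ell \in \{A,B,C\}} (1 - s_\ell)^2,$$

  i.e. Hardy-Weinberg equilibrium within each locus and independence
  across loci. The frequency source names the data, not the formula; this
  is the standard population-coverage model used for epitope panels, and
  `wcsMonteCarlo()` cross-checks it by sampling diploid six-allele
  genotypes from the same table.
* **AMS** (Amplitude Score): the mutant/wild-type affinity ratio at the
  MAS-defining cell. It is reported for completeness but excluded from the
  combined score — across variants it tracks onset phenotypes poorly,
  consistent with incomplete central tolerance to the wild-type peptide.

MAS (inverted), HCS and WCS are min–max normalised to $[0,1]$ over the
scored variant set and summed into the **Predicted Neoantigenic Score**
(PNS, range 0–3), categorised Low (PNS < 1), Intermediate
($1 \le$ PNS $\le 2$) and High (PNS > 2).

Normalisation choices that matter:

* An undefined MAS enters the min–max as the worst value, the 500 nM
  cutoff itself. This anchors the floor: in any set containing a no-binder
  variant, a variant with the best affinity gets MAS component 1 and the
  no-binder gets 0 exactly.
* HCS and WCS floors are anchored at 0 (not the empirical minimum), so a
  no-binder variant scores exactly 0 on all three components and lands in
  Low with PNS 0.
* The min–max anchors of every run are recorded in the output's
  `anchors` attribute (and the JSON manifest), so scores can be reproduced
  or new variants scored against frozen anchors.
* MAS inversion is plain negation by default; a $-\log_{10}$ option exists
  for heavy-tailed affinity sets but is off by default, since the ordering
  (and hence the ranks entering most downstream analyses) is unchanged.
* If a component has zero range across the set it is set to 0 for all
  variants and a message is emitted, rather than dividing by zero.

Category boundaries put both 1 and 2 in Intermediate; `categorizePNS()`
rejects values outside $[0,3]$ (up to $10^{-8}$ float fuzz).

## The missense space and the packaged TP53 sequences

`enumerateMissenseSpace()` enumerates, for a frame-complete CDS, every
protein-level substitution reachable by a single nucleotide change,
excluding synonymous changes and stop gains, and deduplicating at the
(position, ref, alt) level. Substitutions in the initiator codon are
excluded by default — they abolish translation rather than produce a
missense protein — and this convention is what makes the packaged TP53
CDS yield exactly 2314 distinct variants, the size of the classical
functionally-assayed TP53 missense set. `includeStartCodon = TRUE`
restores codon 1 (2320 variants for TP53). The packaged CDS is a
reconstruction equivalent to the canonical TP53 transcript (its FASTA
header says so); its translation is the canonical 393-residue p53, and
the tests assert both the landmark codons and the 2314 count against a
whole-sequence-translation oracle.

## Affinity input and the surrogate predictor

Real runs consume external predictor output: `parsePredictionTable()`
reads both NetMHCpan-4.1-style whitespace tables (columns `Peptide`,
`MHC`, `Aff(nM)`) and generic TSV. Duplicate (peptide, allele) rows
resolve to the minimum affinity — conservative toward calling a binder —
with a warning; non-positive affinities are dropped with a count.
Rank-percentile (eluted-ligand) output is out of scope: all semantics here
are IC50-like nM, lower = stronger.

For offline work, `surrogateAffinity()` is a deterministic hash-based
stand-in: a pure function of (peptide, allele, salt) emitting affinities
log-uniformly, with a configurable fraction (default 2%) below 500 nM. It
has no sequence biology in it — no anchor-residue motifs, no
allele-specific binding preferences — and is meant for plumbing tests and
simulations, not for prediction.

## Patient-level stratification

A carrier presents peptides only on their own six HLA-I alleles.
`personalMAS()` restricts the variant's affinity grid to the genotype
(homozygous loci count once) and `stratifyMAS()` maps the result to four
strata: High ($\le 10$ nM), Intermediate ($(10, 250]$ nM), Low
($(250, 500)$ nM), NoAffinity (nothing below 500 nM). The 250 nM edge is
assigned to Intermediate; the boundary set $\{10, 250, 500\}$ partitions
the domain with no gaps, which the tests probe at $\pm 10^{-9}$. A
personal MAS can never beat the panel-wide MAS, and values $\ge 500$
reaching `stratifyMAS()` indicate an upstream bug and raise an error.

## The association battery

`kmOnsetCurve()` fits the product-limit estimator of age at first cancer
(carriers without cancer are censored at last-known age — the cohort
schema makes the censoring explicit) and reports per-group median onset
with a 95% CI from the complementary log-log transform of $S(t)$ (a
linear-scale option exists; the CI method is otherwise a free choice).
Onset curves are conventionally read inverted, $1 - S(t)$.
`logrankGlobal()` and `logrankPairwise()` wrap the K-group and pairwise
log-rank tests, the latter Bonferroni-corrected by the number of pairs and
clipped at 1.

`topologyRR()` compares tumour-topology proportions among first cancers
between two groups. The risk ratio is computed directly from the 2×2
table — a logistic fit would natively deliver odds ratios, so the direct
estimator is used and documented — with a Wald interval on $\log RR$, the
chi-square p-value of the table, and Benjamini-Hochberg adjustment across
topologies. Zero cells switch to the Haldane-Anscombe 0.5 correction,
flagged per row. `topologyAgeCompare()` runs two-sided Wilcoxon rank-sum
tests on diagnosis ages within each topology, BH-adjusted across the whole
(topology × pair) family; strata with fewer than 2 observations per side
are skipped, and fully tied strata report p = 1.

`pnsOnsetCorrelation()` relates per-variant PNS to median onset over
frequent variants (default floor: 20 carriers). The method is gated by
Shapiro-Wilk at $\alpha = 0.05$ on both variables: Pearson when both pass,
Spearman otherwise, with the method reported. All tests in the battery are
two-sided at $\alpha = 0.05$.

Out of scope by design: frailty or familial-clustering models,
competing-risks estimators, multivariable adjustment, multiple primaries
(first cancers only), HLA typing from sequencing data, HLA class II, and
proteasomal-cleavage filtering of the candidate peptides.

## What the synthetic generator emulates — and what it does not

The generators under `sim*()` reproduce the statistical structure the
analyses assume, so the whole pipeline is exercisable without restricted
registry data:

* **Allele frequencies**: 145 alleles (45/60/40 across A/B/C), per-locus
  Dirichlet frequencies scaled to a 0.95 listed mass; the residual is the
  unlisted-allele remainder a real database extract has.
* **Affinities**: per-variant latent immunogenicity $z \sim N(0,
  \sigma_{\text{eff}})$, log10 affinities $= 5.85 - z + N(0, 1)$, clamped
  to $[1, 5\times10^4]$ nM. The shared driver makes $-$MAS, HCS and WCS
  strongly rank-correlated, as observed on the real variant set, and the
  location is set so that roughly half the variants have no sub-500 nM
  binder at all — the sparsity the real scoring run shows. There is no
  peptide-sequence realism here: affinities are statistical stand-ins.
* **Cohorts**: onset ages Weibull with shape 2 and the category's median
  (scale $=$ median$/\ln(2)^{1/\text{shape}}$; medians default to 25/29/34
  years for Low/Intermediate/High). Censoring is non-informative: an
  independent last-contact age, uniform with its upper bound set so the
  expected censored fraction equals the configured 20%, competes with
  onset and the earlier age is observed. Topologies follow a seven-class
  multinomial whose defaults approximate an LFS first-cancer spectrum,
  shifted multiplicatively in the High category (bones ×0.3, soft tissues
  ×0.4, non-LFS ×1.6 — the directions and rough magnitudes reported for
  High-vs-Low risk ratios), at square-root strength in Intermediate, and
  renormalised. Default cohort sizes (481/765/190) put the expected event
  counts near 385/612/152, the scale of the public-database analysis.
* **Genotypes**: two alleles per locus drawn with the table frequencies
  (Hardy-Weinberg); the genotype sampler doubles as the Monte-Carlo
  cross-check of the WCS closed form, so the oracle and the generator
  cannot drift apart.

Every generator is seeded and pure: identical (config, seed) gives
byte-identical output. Problem sizes in the test-suite recovery runs —
100 replicate cohorts at the sizes above, 20 random tables × 100,000
genotypes for the coverage check, 1000 null replicates for the log-rank
type-I error — were chosen as the smallest sizes at which the Monte-Carlo
tolerances (3 binomial SEs) are meaningfully tight.

Passing tests on these data show that the arithmetic, the estimators and
the multiplicity handling are correct under the assumed structure; they do
not validate predictor accuracy, real HLA linkage disequilibrium (loci are
simulated independent), registry ascertainment, or cohort representativeness
across ancestries.

## A worked run

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1L)
bundle <- simBundle(cfg)

head(bundle$scores[, c("variant", "MAS", "HCS", "WCS", "PNS", "category")])
kmOnsetCurve(bundle$cohort)$summary
logrankPairwise(bundle$cohort)$pairs
topologyRR(bundle$cohort, "High", "Low")
```

The acceptance script (`scripts/acceptance.R`) runs exactly this chain
from scratch — the missense-space enumeration, a seeded default bundle,
the survival and topology battery, and a twelve-variant frequent-variant
correlation — and writes the headline numbers as JSON.

## Known limitations

* The surrogate predictor carries no binding-motif biology; conclusions
  about specific peptides or alleles require real predictor output.
* WCS uses global allele frequencies; it is a population-level quantity
  and can misrepresent coverage in any specific ancestry group.
* The min–max normalisation makes PNS values set-relative: scores from
  different variant sets are comparable only through the recorded anchors.
* The AMS aggregation cell (the MAS-defining cell) is one of several
  defensible choices; it is flagged in the documentation and trivially
  changed, but alternatives are not implemented.
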
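---
title: "Methods: super-BSA trait mapping with SLAF markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-BSA trait mapping with SLAF markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superbsa)
```

## The problem

Bulked-segregant analysis (BSA) locates trait loci in a segregating
population by pooling plants with extreme phenotypes and comparing pooled
allele frequencies, read directly from sequencing depth. The super-BSA
variant implemented here genotypes the pools with SLAF-seq (specific length
amplified fragment sequencing), a reduced-representation protocol: genomic
DNA is double-digested (XhoI + MseI), fragments in a narrow size window are
sequenced to high depth, and each retained fragment becomes a *SLAF locus*
whose distinct sequences are *tags*. In a diploid cross of two homozygous
parents, a locus carries at most four tags; loci with more are repetitive
and discarded.

The package covers the full analysis of such a study on a melon F2
population segregating for fruit sweetness (total soluble solids, TSS, in
degrees Brix) and sourness (juice pH): parental variant triage, SLAF locus
construction and typing, the per-marker bulk depth-ratio statistic,
candidate-region calling, chromosome anchoring, and candidate-gene
intersection. Because no sequencing data are deposited for the emulated
study, a first-class synthetic-data module generates every input from a
seeded simulation of the cross.

## The cross model

`make_genome()` simulates a draft assembly (random scaffolds, non-overlapping
gene models with in-frame CDS, a repeat mask). `make_parents()` plants SNPs
(transition probability 0.71, giving the Ts/Tv near 2.4 typical of plant
resequencing), small indels and structural variants on it; each variant
records its carrier (female/sweet parent "M", male/sour parent "P", or
shared). Parents are homozygous by construction. `simulate_cross()` selfs
the F1: each gamete is a recombinant mosaic with a Poisson number of
crossovers per scaffold and uniform breakpoints — a no-interference model,
so two-point recombination follows the Haldane map function. The default of
0.05 expected crossovers per scaffold per gamete corresponds to a
sub-megabase scaffold in a genome with a few centimorgans per megabase, the
regime of the melon genetic map.

### Phenotypes and dominance

Each trait is controlled by a `QtlSpec`: trait value =
baseline + per-QTL contributions + Gaussian residual. A QTL with additive
effect $a$ (per copy of the sweet-parent allele) and dominance degree
$d \in [-1, 1]$ contributes $0$, $a(1+d)$ or $2a$ for 0, 1 or 2 sweet
alleles. Defaults emulate the greenhouse trait table of the cross
(sweet parent 12.7 °Brix / pH 6.1; sour parent 6.8 / 4.4):

* TSS: four QTLs of equal effect 0.7375 °Brix (so baseline
  $6.8 + 2\times4\times0.7375 = 12.7$), dominance $+0.8$, residual sd 0.9.
* pH: four QTLs (one major of 0.70, three minor of 0.05, summing to 0.85),
  dominance $-0.5$, residual sd 0.2.

A purely additive model is untenable for this cross: it forces the F2 mean
to the midparent value (TSS 9.75), whereas the emulated F2 means are
10.9 °Brix and pH 5.2, and the F1 (12.6 °Brix, pH 4.8) sits near the sweet
parent for TSS and near the sour parent for pH. The chosen dominance values
reproduce all of these simultaneously; setting `dominance = 0` recovers the
additive model. The single-major pH architecture follows the literature on
melon fruit acidity, which consistently reports one major pH locus.

### Bulks

`select_bulks()` implements the published pool rules
(sweet: TSS > 12 and pH > 6; sour: TSS < 8 and pH < 5;
non-sweet-non-sour: TSS < 8 and pH > 5.3; 50 plants each) as
`method = "threshold"`, erroring when a pool cannot be filled. That error
is the *generic* outcome for a 500-plant F2 whose trait means match the
published table: with F2 TSS distributed around 10.9 with any plausible
spread, the probability of TSS < 8 is far below the 20% needed to fill two
50-plant low-TSS pools, and the joint classes (e.g. TSS > 12 *and* pH > 6)
are products of roughly quarter-frequency genotype classes. The published
F2 summary statistics and the published pool counts are mutually
inconsistent; no Mendelian simulation can satisfy both. The pipeline
therefore uses `method = "extreme-rank"`: pools are the 50 most extreme
plants by phenotype rank (sweet = highest TSS-rank + pH-rank, sour =
lowest, non-sweet-non-sour = highest pH among the lowest-TSS remainder),
which preserves the selective structure of the published rules and always
yields three disjoint full pools.

### Pooled depths

`simulate_slaf_depths()` draws, per polymorphic locus and pool, a total
depth from a negative binomial around the pooled mean (default 160×;
overdispersion $\phi$ with variance $\mu + \phi\mu^2$, $\phi = 0$ giving
Poisson — amplified reduced-representation libraries are overdispersed),
assigns reads to the M or P allele binomially at the pool's true allele
frequency, and flips alleles at the sequencing error rate (default 1%).
Parental pools are fixed for their own allele. Parental *resequencing*
calls (used by the variant-triage module) are simulated at the 13× scale
typical of the emulated study.

## The ratio statistic

For every polymorphic marker the package computes, exactly as the method
defines them,

$$Ratio_{sweet} = M_{sweet} / P_{nsns}, \qquad
  Ratio_{sour} = P_{sour} / M_{nsns},$$

where $M_{pool}$/$P_{pool}$ are the pooled depths of the female- and
male-parent alleles. A zero denominator maps to the sentinel 1000 (applied
first, so a 0/0 marker is also 1000, though such markers are effectively
depthless and unreliable); a marker is differential at ratio ≥ 3; plots cap
the displayed value at 20, without ever affecting the differential
decision. All three constants are parameters.

`call_regions()` turns runs of at least `min_run` consecutive differential
markers (no intervening non-differential marker on the scaffold) into
candidate regions, with bounds rounded outward to 1 kb — the convention of
the published region tables, whose coordinates are all multiples of 1000.
`min_run` defaults to 2 because those tables contain several two-marker
regions even though the accompanying text states a three-marker rule; pass
`min_run = 3` for the text rule.

### What the statistic can and cannot detect

With equal pool depths, $Ratio_{sweet} \ge 3$ requires
$f_{M,sweet} \ge 3\,(1 - f_{M,nsns})$, which is only reachable when the
control (non-sweet-non-sour) pool itself leans toward the *same* parent as
the sweet pool ($f_{M,nsns} \gtrsim 2/3$). The non-sweet-non-sour pool is
selected for low TSS and high pH, so it is M-rich only at pH loci and
P-rich at TSS loci. Consequently the sweet statistic fires at pH-driving
loci and the sour statistic at TSS-driving loci — the two trait labels
cross. This is a property of the printed formulas, not of this
implementation: even a perfectly M-fixed sweet pool cannot reach ratio 3
against a control pool that is neutral (ratio 2) or opposite-leaning at the
locus. The simulation reproduces this cleanly: called sweet regions sit on
the major pH-QTL scaffold in every seed, called sour regions sit only on
TSS-QTL scaffolds, and no region is ever called on a QTL-free scaffold.
Users mapping a single trait with a truly neutral control pool should
expect the threshold of 3 to be conservative; the per-marker `ratio_*`
columns are returned so other thresholds can be explored.

Sensitivity is also architecture-limited: splitting a 5.9 °Brix parental
difference across four equal-effect QTLs caps per-locus pool enrichment
well below fixation (a 50-of-500 extreme pool cannot be homozygous at four
independent loci at once), so expected ratios at TSS loci hover near the
threshold and individual scaffolds are recovered stochastically. The major
pH locus, carrying most of its trait's variance, is recovered
deterministically. This asymmetry is intrinsic to threshold-3 BSA on
polygenic traits at these pool sizes and depths.

## Variant triage and annotation

SNP calls are filtered by the published criteria — depth ≥ 2 (homozygous)
or ≥ 3 (heterozygous), depth ≤ 3× the sample mean, and no repeat overlap —
with the mean supplied by the caller, because the emulated study quotes an
11× mean in the rule while its own coverage table reports ~13×. SV calls
are valid at depth 2–100× and quality strictly > 20. Substitutions are
transitions iff C↔T or G↔A. Coding effects mutate the affected codon of
the spliced CDS (reverse-complemented for minus-strand genes) and compare
translations under the standard genetic code. Differential sites are those
where the two homozygous parents' effective alleles differ, counting
call-absent parents as reference; polymorphic genes contain a differential
non-synonymous SNP or a validated exonic SV/indel.

## SLAF construction and anchoring

`digest()` cuts at every occurrence of either enzyme motif and
size-selects fragments (default window 314–414 bp); concatenating all
fragments reconstructs the input, a tested invariant. `cluster_tags()`
groups fixed-length tags at ungapped identity strictly over 90% by single
linkage (equal to the transitive closure, so input order is irrelevant);
gapped alignment is deliberately not used — length differences are the
INDEL marker class, handled by `type_marker()`. The EPSNP category, never
defined in the source material, is implemented as a substitution inside an
enzyme recognition-site occurrence (a cut-site-destroying polymorphism),
and this interpretation is flagged here. Locus filters: more than four
distinct tags = repetitive; total depth must exceed 10× (selection rule),
with an optional non-strict 164-read cutoff exposed separately because the
two published depth rules cannot be reconciled.

`anchor_markers()` places markers by near-exact matching (mismatch budget
from `min_identity`) on both strands, merges overlapping matches into
distinct loci, discards markers with more than `max_hits = 2` loci
(a literal reading of "more than two different locations"), and reports
the best hit, breaking exact ties by smallest (chromosome, start) with a
logged message. It is a documented stand-in for a seed-and-extend aligner;
alignment scoring is not reproduced.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; BED export is
  0-based half-open on disk, GFF3 1-based (via rtracklayer).
* All randomness flows through one integer seed per entry point
  (`withr::with_seed`), never the global RNG state; `run_super_bsa()`
  derives per-stage sub-seeds below $2^{31}$ from its master seed.
* 0/0 depth markers take the sentinel (denominator rule first).
* Phenotype classes do not tile the (TSS, pH) plane; an explicit
  `unclassified` class closes the gap and sweet-and-sour is checked first,
  since the F1 satisfies only that rule.
* Empty inputs (no fragments, no anchors, no regions) return typed empty
  tables, not errors.

## Problem sizes

The default emulation uses 10 scaffolds × 400 kb (4 Mb genome; eight
scaffolds carry one QTL each), SNP rate 5×10⁻³/bp between parents
(the genome-wide density of a diverged melon cross), 500 F2 plants, three
50-plant bulks, ~1,300 polymorphic SLAF markers and 160× pooled depth.
One full run takes a few seconds; the test suite's ten-seed recovery study
runs in under a minute.

## What the simulation does not emulate

Read-level FASTQ data (depth tables are the interface, alignment and
variant calling being external tools' territory), PCR/GC bias in SLAF
libraries, heterozygous parental residues, interference in meiosis,
season or environment effects beyond the residual term, translocation
breakpoint sequences (CTX/ITX are recorded with partner coordinates only),
and any real melon sequence. Passing tests therefore demonstrate
correctness of the statistics and bookkeeping under an idealised cross,
not performance on real, biased sequencing data.
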
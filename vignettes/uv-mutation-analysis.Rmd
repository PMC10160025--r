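---
title: "Analysing UV-induced mutation spectra and strand asymmetries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing UV-induced mutation spectra and strand asymmetries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvspectra)
```

## The analysis problem

Mutation-accumulation experiments in UV-irradiated yeast produce, for each
sequenced isolate, a list of called base substitutions against the reference
genome. Four questions recur when interpreting such data:

1. **What is the substitution spectrum?** Counts of single-base substitutions
   in trinucleotide context (96 strand-collapsed channels) and of tandem
   (doublet) substitutions (78 canonical channels), summarised per isolate
   and compared across genotypes or UV doses.
2. **Are mutations transcriptionally asymmetric?** Transcription-coupled
   nucleotide excision repair removes photoproducts preferentially from the
   transcribed strand (TS) of genes, so lesion-derived mutations accumulate
   on the non-transcribed strand (NTS). The direction of the bias reveals
   which strand carried the lesion.
3. **Are mutations replicatively asymmetric?** If translesion synthesis is
   more mutagenic on the leading or the lagging strand, complementary
   substitution types (say C>T vs G>A, read on the reference top strand)
   diverge as a function of a site's position between flanking replication
   origins, giving the characteristic "cross" profile.
4. **What do reporter assays say?** Reversion reporters count a specific
   substitution by selective plating; the arithmetic of frequencies, upper
   estimates for zero-revertant experiments, and fold changes needs
   consistent conventions.

uvspectra implements these four analyses plus a seeded synthetic-data
generator that emulates the statistical structure each analysis measures, so
the whole pipeline can be validated without any sequencing data.

## Conventions and core definitions

**Coordinates.** Mutation tables are 1-based (VCF convention); genes and
origins are 0-based half-open / 0-based midpoints (BED convention). All
conversions happen at ingest.

**Validation.** Every record is checked against the reference genome; ref
mismatches are rejected into a report rather than dropped silently, because
they usually mean a genome-build mismatch. Mitochondrial records are removed
by a configurable chromosome-name filter (default `chrM`, `chrMito`,
`mitochondrion`); the organellar genome has its own replication and repair
context and is excluded from all nuclear analyses.

**Tandem merging.** Runs of substitutions at strictly consecutive positions
in the same isolate are merged: runs of exactly two become one tandem
record; runs of three or more become a `multi` record that both spectra
exclude (only single and tandem classes are analysed). Isolate identity
separates runs: adjacent calls in different isolates stay single.

**Strand collapse.** A single substitution is represented with its mutated
reference base as a pyrimidine: purine-reference records have both the
substitution and the trinucleotide context reverse-complemented. Tandems are
collapsed onto the standard 78-class doublet space whose canonical reference
dinucleotides are {AC, AT, CC, CG, CT, GC, TA, TC, TG, TT}; for palindromic
reference dinucleotides the lexicographically smaller alternate is
canonical. This reproduces the field's printed labels (GT>AA is reported as
AC>TT, AG>TA as CT>TA).

## Spectrum statistics

Per-class summaries are the mean and sample (n−1) standard deviation across
isolates. Group comparisons use:

* **Median density fold change** — the ratio of median per-isolate
  substitution counts between two genotypes. Medians resist the occasional
  jackpot isolate.
* **Chi-squared spectrum comparison** — a two-sided test on the 2 × K table
  of pooled per-class counts, with no continuity correction. Classes whose
  smaller expected count falls below 5 are pooled into an "other" class
  first; the asymptotic test is unreliable below that floor. Whether singles
  and tandems are tested jointly or separately is the caller's choice
  (`compare_spectra_chi2` takes any concatenation of class totals); separate
  testing is the natural default since the two spectra have different
  denominators.
* **Pearson concordance** — correlation of raw per-class counts (matching
  figure axes that plot counts, not frequencies).
* **Mann–Whitney density comparison** — two-sided rank-sum test of
  per-isolate totals. Both groups at most 8 observations: exact enumeration
  of all rank assignments (ties handled by midranks; fully tied groups give
  p = 1, with no continuity correction). Larger groups: normal approximation
  with the usual tie correction plus a half-step lattice correction, which
  keeps the approximation within about 0.01 of exact enumeration at the
  cutover. Complete separation at n = 6 vs 6 gives exactly 2/924 ≈ 0.0022,
  the familiar floor for that design.

## Transcriptional asymmetry

NTS is the gene's coding (mRNA-like) strand, TS the template strand. A
strand-collapsed mutation inside exactly one gene is NTS if its pyrimidine
representation lies on the coding strand. Regions covered by two or more
genes are masked — from both the mutation assignment and the denominator —
because strand identity is undefined there.

Raw NTS/TS counts are confounded by composition: a context can simply be
more frequent on one strand. The expected split of a class is therefore
derived from the frequency of its context on each strand over (unmasked)
gene bodies, counted with `Biostrings` k-mer machinery; the TS frequency of
a context equals the NTS frequency of its reverse complement. Each class
with at least `min_count` mutations (default 30; fewer gives a 1-df test
with little power and unstable expectations) is tested by a two-sided 1-df
goodness-of-fit chi-squared against that expectation, and p-values are
Bonferroni-corrected with family size equal to the number of tested classes
in the dataset. The reported effect size is the composition-normalised ratio
(obs/exp on NTS)/(obs/exp on TS), which equals 1 exactly when the observed
split matches the composition expectation, however imbalanced the raw
counts. Per-context NTS fractions n_NTS/(n_NTS + n_TS) are also reported,
with zero-count classes flagged not-determined.

Tandems are assigned by their 5′ position and analysed as their own
canonical classes against dinucleotide strand frequencies, when counts
permit.

## Replicative asymmetry

Strand collapse destroys replicative strand information, so here mutations
are kept as read on the reference top strand. Each mutation between two
origins on its chromosome gets a fractional position
(pos − left)/(right − left); mutations outside the outermost origins, on
chromosomes with fewer than two origins, or exactly at the midpoint (where
fork polarity is undefined) are excluded and counted. The fractional axis,
rather than raw distance in bp, normalises the highly variable inter-origin
spacing; 10 equal bins is the default (enough resolution for a line fit,
rarely an empty bin at realistic counts).

For a complementary pair, the per-bin fractional abundance of member 1 is
fitted by unweighted least squares against bin midpoints; member 2's line is
its mirror, and the slope difference (twice the member-1 slope) summarises
the cross. Uncertainty comes from a seeded bootstrap that resamples
mutations — implemented as a multinomial redraw over the (bin, member)
cells, which is distributionally identical for this binned statistic and
orders of magnitude faster — with percentile 95% intervals over 1,000
replicates by default.

## Reversion and canavanine arithmetic

Reversion frequency is revertants divided by surviving cells plated, the
survivor count being the mean of colonies/dilution over countable plates
(default window 30–300 colonies, the usual plate-counting range). A
zero-revertant experiment reports the maximum estimated frequency 1/N — the
frequency at which one revertant would have been expected among the N cells
plated — flagged as an upper estimate; fold changes whose numerator or
denominator median rests on such estimates are flagged as bounds
accordingly. Group summaries use the median (mean available). The
canavanine-resistance frequency is (CanR colonies × SC dilution)/(SC
colonies × canavanine dilution); a zero CanR count is reported as 0 with a
flag, since no upper-estimate convention is established for that assay.

## The synthetic-data generator

`generate_reference()` draws i.i.d. bases at a configurable GC content
(default 0.38, the yeast nuclear value), places non-overlapping fixed-length
genes with uniformly random gaps and strands, and spaces origins evenly with
20% jitter. `generate_mutations()` draws classes from configurable single
(96-channel) and tandem simplexes — defaults are UV-like: C>T-dominated,
concentrated at 5′-pyrimidine (CPD-forming) contexts, with a CC>TT-led
tandem component at 5% of events — and places each class at a genomic site
whose context matches, sampled with weights that realise two biases at once:

* **transcriptional**: sites whose pyrimidine orientation is NTS inside a
  gene carry weight odds/(1+odds), TS sites 1/(1+odds), intergenic or
  ambiguous sites 1/2; and
* **replicative**: top-strand pyrimidine orientation carries weight
  0.5 + rep_slope·(fraction − 0.5) between origins.

Defaults are odds 1 and slope 0 (no bias). Tandems are emitted as two
adjacent single-base rows so that ingest and `merge_tandems()` are exercised
rather than bypassed, and events are greedily spaced at least 2 bp apart so
unrelated draws never merge into spurious runs. All draws run off the config
seed; the same seed reproduces every output byte-for-byte.

**What the generator does and does not emulate.** It reproduces the
statistical structure the analyses measure: multinomial class spectra,
within-gene strand odds, and a linear positional bias between origins. It
does not model lesion formation, repair kinetics, polymerase choice,
replication timing, clonal structure among isolates, or realistic gene
length and origin-spacing distributions. Passing recovery tests therefore
demonstrates that the estimators are correct and calibrated on data obeying
their assumptions — not that real genomes obey them.

**Numerical caveats.** Sites are sampled without replacement within a class
and isolate (duplicate positions in one genome are not meaningful), so when
the number of draws approaches the number of candidate sites the realised
odds attenuate slightly toward 1 — at the default problem sizes (thousands
of draws against tens of thousands of sites) the attenuation is well inside
the sampling noise, and recovery tests size their tolerance as 3 standard
errors plus a 0.01 allowance for it. Rare classes whose context is absent
from a small toy genome are skipped with a warning.

## Problem sizes used in validation

The shipped tests validate classification against brute-force
reverse-complement enumeration over all 96 + 78 classes and 10,000 random
records; family-wise error of the Bonferroni family over 1,000 unbiased
replicates (binomial 99% envelope); NTS-fraction recovery at odds 2 with
over 5,000 genic mutations; cross-slope recovery at slope 0.5 with 6,000
mutations and CI coverage over 500 zero-bias replicates; and the exact
rank-sum landmarks. These sizes give each check enough resolution that a
real defect would not hide inside its tolerance, while the whole suite runs
in a few minutes.

## Known limitations

* Expected NTS fractions come from gene-body composition only; flanking
  regions and expression-weighted repair are out of scope.
* The chi-squared spectrum comparison treats isolates as exchangeable and
  pools them; isolate-level overdispersion is not modelled.
* Shared (putatively clonal) mutations across isolates are kept by default;
  `dedup_shared = TRUE` keeps one representative per site, but which
  treatment is right depends on the experimental lineage structure, which
  the package cannot know.
* The replication analysis assumes fork polarity is fixed by the nearest
  flanking origins and ignores origin firing efficiency and replication
  timing.
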
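---
title: "Models and methods behind guidescreen"
author: "guidescreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind guidescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`guidescreen` analyses pooled CRISPR/SpCas9 knockout screens and designs
sequence-optimized guide libraries. A pooled dropout screen infects a large
cell population with a lentiviral guide library, passages the cells for two
to three weeks, and sequences the integrated guides at an early control
timepoint (T0, or the plasmid pool) and at one or more endpoints. Guides
that knock out fitness genes deplete; the analysis problem is to turn the
guide-level readcounts into calibrated gene-level essentiality calls, and
the design problem is to pick guides that maximize that signal.

The package covers five connected pieces:

1. **Fold-changes** from readcount tables (`compute_foldchange()`).
2. **Gene essentiality Bayes Factors** with a kernel-density classifier
   trained on reference essential/nonessential genes (`bayes_factors()`),
   with precision-recall and posterior-probability machinery.
3. **Core-essential calling** across panels of screens
   (`call_core_essentials()`).
4. An **empirical positional sequence score** for 20-mer guides
   (`derive_score_table()`, `score_guides()`) and a **library designer**
   built on it (`design_library()`).
5. **Screen quality metrics** and a **synthetic-data module** with known
   ground truth and exhaustive off-target oracles.

# Fold-change normalization

For each sample, a pseudocount (default 0.5 reads) is added to every raw
count and the sample is scaled so the pseudocounted counts total the target
depth (default $10^7$ reads). The guide-level fold-change against the
designated control sample is then

$$\mathrm{fc}_{g,s} = \log_2 \frac{n_{g,s}}{n_{g,\mathrm{ctrl}}}$$

on the normalized scale. Guides with fewer than 30 raw reads in the control
sample are considered unassayed: they are excluded from the fold-change
matrix for *all* replicates of the screen (the filter expresses doubt about
the library representation, which is a property of the infection, not of a
replicate) and reported in a mask with reasons.

Two ordering decisions are deliberate. The pseudocount is added *before*
depth scaling, which guarantees finite fold-changes and makes the
normalization totals exact; and each sample is scaled by its own
pseudocounted total rather than by a shared size factor, which is what
"normalize each sample to 10 million reads" means operationally. Because
the depth is fixed, dropout of essential guides slightly inflates everyone
else's share: in a screen where 10% of genes drop out 8-fold, neutral
guides sit near $\log_2(1/0.9125) \approx +0.13$ rather than at 0. The
synthetic-data tests account for this compositional shift explicitly.

# The Bayes Factor classifier

The classifier follows the BAGEL family. Guide fold-changes of reference
essential genes and reference nonessential genes train two one-dimensional
Gaussian kernel densities ($f_E$, $f_N$); a gene's Bayes Factor is

$$\mathrm{BF}(g) = \sum_{i \in \text{guides}(g)} \log_2
  \frac{f_E(\mathrm{fc}_i)}{f_N(\mathrm{fc}_i)}$$

summed over all retained guide × replicate values. Internals are pinned for
reproducibility:

* bandwidths by Scott's rule (`stats::bw.nrd`);
* evaluation points clamped to the training fold-change range, densities
  floored at $10^{-12}$, so log ratios stay finite in the tails;
* each bootstrap iteration (default 1000) resamples the reference *genes*
  with replacement — resampling genes rather than guides respects the
  gene-level correlation of guide effects — and the mean BF over
  iterations is reported;
* all randomness is seeded (default seed 1934, recorded in run metadata).

At least 20 reference genes of each class must have retained guides;
below that the density estimates are not trustworthy and the function
refuses to run.

Precision, recall, and FDR are computed over the reference genes only,
ranking genes by descending BF (`precision_recall()`; FDR $= 1 -$
precision). The FDR attached to a BF threshold is read off the curve at
the smallest cutoff at or above the threshold.

A BF converts to a posterior through the prior odds: with the default
prior of 10% essential genes per cell line, posterior log2 odds are
$\mathrm{BF} + \log_2(0.1/0.9) \approx \mathrm{BF} - 3.17$, so a BF of 3
corresponds to roughly even posterior odds (probability ≈ 47%) and a BF of
6 to posterior probability ≈ 88%.

# Core-essential calling across a panel

A gene is *assayed* in a screen if at least 3 of its guides survived the
control-read filter, and *eligible* if assayed in at least 7 screens. It is
*called essential* in a screen when its BF is at least 6 and that screen's
FDR at the BF-6 cutoff is at most 3%. Eligible genes called essential in at
least $\lceil 0.85 \times \text{screens assayed} \rceil$ of their assayed
screens form the core set — the ceiling makes the rule "all but one" for
genes assayed in 7 through 12 screens (6 of 7, 11 of 12). Screen-level FDR
is evaluated per screen, from that screen's own precision-recall curve.

# The positional sequence score

High- and low-performing guides differ in sequence composition. The score
table is derived empirically from screens of genes with exactly six
retained guides each, using core-essential genes so that every guide
*should* deplete and residual differences reflect guide efficiency:

1. per endpoint sample, rank each qualifying gene's six guides by
   fold-change (ties broken by sequence, so the split is deterministic) and
   pool the three best (most negative) and the three worst;
2. compute nucleotide frequencies at each of the 20 positions in both
   pools and subtract worst from best, giving a Δ-frequency table whose
   columns sum to zero by construction;
3. sum the tables over samples and scale so the most extreme absolute cell
   equals 1 (the anchor cell — C at position 18 in the data the procedure
   was developed on — keeps its sign);
4. cells never observed in either pool across all samples (for example
   when the source library categorically excludes T at the four
   PAM-proximal positions 17–20) carry no information and are assigned the
   score −1, generalizing the original manual assignment.

Positions are numbered 1 (PAM-distal) to 20 (PAM-proximal). A guide's
score is the sum of its 20 positional weights; quartile validation
(`quartile_validation()`) compares fold-changes of top- versus
bottom-quartile-scored guides targeting reference essentials with a
two-sided Welch t-test.

Because every column of a Δ-frequency table sums to zero, the derivation
estimates positional preferences *relative to the column mean*. The
synthetic recovery tests therefore plant signatures of the same family
(column-centered); a non-centered planted matrix is only identifiable up to
its column offsets, which is a property of the statistic, not of the
implementation.

# Library design

`design_library()` runs five stages, each usable on its own:

* **Enumeration** — every 20-mer adjacent to an NGG PAM, on either strand,
  whose blunt cut site falls inside a coding exon of the target gene. The
  cut is taken between protospacer positions 17 and 18 (3 bp 5′ of the
  PAM), the canonical SpCas9 cut; both bases flanking the cut bond must lie
  in the exon. One canonical transcript per gene (longest total CDS, ties
  by transcript id) defines the coding exons, numbered from the
  transcription start site.
* **Filters** — GC content in [40%, 75%], no single-nucleotide run of 4 or
  more, none of the cloning restriction sites AgeI/KpnI/BveI/BsmI/BsmBI in
  the protospacer+PAM on either strand, and no supplied variant position
  overlapping protospacer or PAM. Rejections are annotations with reasons,
  not errors.
* **Off-target classes** — all genomic sites with an exact GG in the PAM
  (the N is free) and at most 2 protospacer mismatches. Any hit inside a
  *different* gene's body (exons or introns) excludes the candidate. Hits
  in the target gene never count against the off-target budget. Class 1:
  ≥2 target hits, no off-targets; class 2: unique clean hit; class 3: 1–2
  intergenic off-targets; class 4: exactly 3; more: excluded. The search
  uses `Biostrings` pattern matching with a post-filter enforcing the
  exact-GG PAM; an independent exhaustive scanner (`oracle_offtargets()`)
  verifies it position by position in the test suite.
* **Ranks** — rank 1: class 1 with positive score; rank 2: classes 1–3,
  score > 0.85; rank 3: classes 1–4, score > 0.85; rank 4: classes 1–3,
  score in [0, 0.85]; rank 5: classes 1–4, score in [−1, 0.85]. A guide
  gets the first rank it satisfies.
* **Selection** — ranks are consumed in order; within a rank, rounds give
  each gene below its quota (default 4) at most one guide per round: the
  highest-scoring candidate in an exon with no selected guide yet, falling
  back to covered exons only when no fresh-exon candidate remains in the
  current rank. This "fresh exon first, then score" reading reconciles the
  two goals of exon coverage and guide quality: a gene whose high-rank
  candidates cluster in one exon still gets them, but exon diversity wins
  within a rank when available. Ties break by lower exon number then
  lexicographic protospacer, making reruns byte-identical. Duplicate
  protospacers across genes keep the first gene in processing order and
  log a conflict.

Coordinates are 1-based inclusive throughout, matching R/Bioconductor
convention and the emitted TSVs.

# Screen quality metrics

* **Fraction of active guides** — the share of essential-targeting guides
  whose replicate-averaged fold-change falls below the 5th percentile of
  nonessential-targeting guides. Percentiles use linear interpolation
  between order statistics (`quantile` type 7). Under the null (no true
  signal) the statistic sits near 0.05 by construction.
* **Guides-per-gene subsampling** — k guides per gene are drawn without
  replacement (k = 2…7, 10 iterations by default), the fold-change and BF
  analysis reruns on the subset, and hits are counted at BF > 3, FDR < 5%,
  along with the fraction of a core-essential set recovered (mean ± SD per
  k). Genes with fewer than k guides are skipped and logged.
* **Replicate subsampling** — for a three-replicate screen, the seven
  analyses (3 singles, 3 pairs, 1 triple) quantify the marginal value of
  replication.
* **Control comparison** — nontargeting guides versus guides targeting
  reference nonessentials, two-sided Welch t-test on replicate-averaged
  fold-changes. Degenerate inputs (zero variance in both groups) are
  flagged rather than raised.

# The synthetic-data module

`make_genome()` lays out multi-exon genes on random-sequence chromosomes,
plants one known guide site per gene inside exon 1, and optionally plants
mismatched copies of those guides at intergenic or intronic locations,
emitting FASTA/GTF/VCF plus truth tables. `make_screen()` draws T0 counts
from a negative binomial around uniform representation (variance
$\mu + \mu^2/r$, dispersion $r = 10$ by default, a standard count
overdispersion level) and multiplies the endpoint abundance of
essential-gene guides by $2^{-\text{effect} \times \text{efficiency}}$,
where efficiency is either 1 or a logistic function of the guide's score
under a planted table ($\mathrm{plogis}(1.5 \cdot \text{score})$, spanning
≈0.01–0.99 over scores −4…4). The default essential fraction is 10%,
matching the prior used in the posterior conversion; the default effect
size of 3 log2 units reflects the strong depletion of fully efficient
guides against essential genes. Identical specs and seeds produce
byte-identical outputs.

What the generator does **not** emulate: PCR amplification bias,
infection multiplicity effects, copy-number-driven multi-cut toxicity,
chromatin accessibility, or realistic human sequence composition. Passing
tests on synthetic data therefore demonstrate the correctness and
calibration of the algorithms under the stated noise model, not their
performance on any particular real screen.

# Problem sizes and numerical choices

The test suite and acceptance checks run at desk scale, chosen so each
property is exercised far from its trivial regime while the whole suite
stays fast: screens of 120–300 genes (up to 3000 for score-table
derivation, whose per-sample pools then match the hundreds of genes used
in practice), 4–8 guides per gene, 1–3 replicates, panels of 12 screens,
bootstrap iterations reduced to 8–20 (the default remains 1000), and
off-target verification on dozens of ≤10-kb genomes against the exhaustive
oracle. Two numerical guards matter in practice: the density floor of
$10^{-12}$ bounds any single guide's BF contribution, and clamping
evaluation to the training range prevents the extrapolated Gaussian tails
from dominating.

# Known limitations

* The classifier scores reference genes with densities trained on them
  (standard for this family); held-out evaluation requires the user to
  split reference sets.
* Gene symbols are exact case-sensitive strings; no alias resolution.
* Replicate subsampling is specified for exactly three replicates.
* The designer assumes one canonical transcript per gene and NGG PAMs
  only; alternative nucleases and chromatin features are out of scope.
* Genome-scale design on a full mammalian genome is supported in principle
  but the off-target search is engineered (and verified) for desk-scale
  genomes; a production genome-wide run would substitute an indexed
  aligner for the in-memory scan.
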
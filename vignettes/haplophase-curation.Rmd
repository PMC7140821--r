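---
title: "Curating heterozygous diploid assemblies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating heterozygous diploid assemblies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-read assemblies of highly heterozygous diploid genomes — outcrossing
crops are the canonical case — do not resolve the two parental haplotypes
uniformly. Where heterozygosity is high, the assembler separates the
haplophases and emits two contigs for the same genomic region; where
heterozygosity is low, both haplotypes collapse into one consensus
("merged") sequence. A single multi-megabase contig typically alternates
between phase-separated and merged stretches, so the assembly is neither a
haploid nor a diploid representation, and every downstream count — genes,
orthologs, assembly size — is biased unless the two region types are told
apart.

hapcurate implements the downstream curation such a draft needs:

1. **Contig screening** — purge short contigs, classify against
   white/black lists, screen low-coverage contigs, detect organelles.
2. **Pseudo-genetic-map scaffolding** — order and orient contigs along a
   related species' pseudochromosomes.
3. **Haplophase classification** — classify gene models as
   phase-separated or merged from mapped read depth, and corroborate with
   heterozygous-variant density.
4. **Gene-model post-processing** — database score-ratio filtering,
   representative transcripts, annotation transfer, reciprocal-best-hit
   (RBH) allele pairing, and a haploid gene-number estimate.

A synthetic diploid genome generator with a full truth table makes every
stage testable end to end without external data or aligners.

## Read-depth model for haplophase classification

With short reads mapped to the assembly at haploid coverage $c$ per
haplotype, a phase-separated region attracts the reads of one haplotype
(depth $\approx c$) while a merged region attracts both
($\approx 2c$). Per-gene mean depth $d$ is therefore bimodal, and genes
are classified with three thresholds $t_\mathrm{low} < t_\mathrm{mid} <
t_\mathrm{high}$ (defaults 50, 150, 250 for $c \approx 100$):

* $d < t_\mathrm{low}$: **low** (poorly covered, dubious);
* $t_\mathrm{low} \le d < t_\mathrm{mid}$: **separated** (haploid depth);
* $t_\mathrm{mid} \le d < t_\mathrm{high}$: **merged** (diploid depth);
* $d \ge t_\mathrm{high}$: **high** (collapsed repeats, organelles).

Bins are half-open with *inclusive lower bounds* — prose like "between
50-fold and 150-fold" does not fix the boundary convention, so we declare
one and keep it configurable (`depth_bins()`). Mean depth is taken over
the full gene span, positions missing from the depth track counting as
zero. `estimate_bins()` automates the threshold choice: the haploid peak
$\hat c$ is the mode of a kernel-density smooth of the depths restricted
to the lower half of the observed range (degenerate, constant input
returns that constant exactly), and the bins are $(0.5\hat c, 1.5\hat c,
2.5\hat c)$, which makes the classification scale-equivariant in $c$. If
fewer than 30 genes fall into the lower half the defaults are returned
and flagged.

The same logic explains heterozygous-variant density: reads from two
alleles pile onto one merged consensus, so merged genes are het-dense,
while separated genes carry only mapping noise. `het_per_gene()` counts
records whose genotype has two distinct alleles (`0/1`, `0|2`, ...;
multi-allelic records count once) and reports medians and upper quartiles
per class. The comparison is deliberately descriptive; a rank-sum test
adds nothing to a difference that is structural.

## Pseudo-genetic-map scaffolding

Without a genetic map, a related species' pseudochromosomes can order the
contigs. Chromosomes at least 100 kbp long are cut into 1000-bp chunks
(`chunk_reference()`; the trailing remainder is dropped), and the chunk
order along each chromosome is treated as a genetic map with the chunk
ordinal as map position. Chunks are aligned to the assembly; hits are
kept when identity $\ge$ 70% and chunk coverage $\ge$ 70% (both
inclusive), and a chunk is discarded entirely when its second-best hit
exceeds 90% of the top bitscore — close paralogs and repeats must not
anchor anything. The surviving top hit becomes an anchor at the
subject-interval midpoint.

Contig arrangement is a deliberate built-in replacement for an external
multi-map scaffolder: with a single map and unit weights, ordering
contigs by the mean map position of their anchors and orienting them by
the sign of the Spearman rank correlation between contig positions and
map positions optimizes the same objective, and it is small enough to be
fully testable. Guard rails: a contig needs at least 3 anchors (one-hit
placements are noise), a strict majority of its anchors on one linkage
group (ties stay unplaced), and $|\rho| \ge 0.3$ with $\ge 2$ anchors for
a called orientation — otherwise `"?"`, emitted as `+`. Scaffolds are
materialized with 100-N gaps and described in AGP v2.1
(`write_scaffolds()`); placed plus unplaced sequence always equals the
retained assembly exactly.

Because the two haplotype contigs of a phase-separated region both match
the same reference chunk at similar scores, such chunks are usually
removed by the 90% ambiguity rule: with a reference at ~10% divergence
and alleles at ~2%, the score ratio between the two haplotype hits is
~0.95. Merged regions anchor cleanly. This is inherent to the method, not
an artifact — placements concentrate on merged and strongly diverged
regions, and accuracy is measured over placed contigs.

## Contig screening

Stages run in the narrative order length → lists → low-coverage →
organelle, each relabelling only still-retained contigs, so labels
partition the input and the filter is idempotent:

* length: keep contigs $\ge$ 100 kbp (a contig of exactly 100 kbp
  survives);
* lists: a perfect cross-match (operationalized as 100% identity over
  $\ge$ 500 bp, configurable — "perfect" needs a working definition)
  against a genome sequenced in parallel marks `cross_contaminant`;
  otherwise a black-list hit at $e \le 10^{-10}$ with no white-list hit
  marks `blacklist`; the white list dominates conflicts (anything
  matching the related species is kept), with a warning;
* low coverage: mean depth strictly below 3-fold *and* a bacterial/fungal
  hit at the cutoff; low coverage alone never discards;
* organelle: best organelle-reference hit covering $\ge$ 50% of the
  contig *and* mean depth $\ge 5\times$ the median retained-contig depth
  ("very high coverage" also needs a number; 5x is configurable and
  robust because the median ignores the organelle outlier itself).

## The synthetic genome

`sim_config()` defaults define the study conditions: 2 chromosomes of
2 Mbp, blocks of exponential length (mean 250 kbp, floor 120 kbp so
block-derived contigs survive the length purge), each block
high-heterozygosity with probability 0.5; SNP rates 2% (high) and 0.05%
(low) between haplotypes — values chosen to produce the clean bimodality
the classification assumes, not a claim about any species; ~500
non-overlapping 3-kbp genes; haploid depth 100-fold with Poisson noise
(negative binomial available for over-dispersion checks); four
contaminant contigs at 1-fold depth and one 150-kbp organelle at 50x
haploid depth. Spurious het calls on separated contigs at $2 \times
10^{-5}$ per bp and homozygous-alt records at $10^{-5}$ keep the variant
table from being artificially clean.

Emission rules: a run of consecutive high-het blocks yields two contigs
(one per haplotype), a low-het run yields one merged contig carrying
haplotype A's sequence (a consensus model would not change any
depth/variant logic, so the simpler convention is recorded in the truth
table instead). Orientations are random and recorded; output order is
shuffled. The relative's pseudochromosomes are haplotype A mutated at a
configurable divergence, optionally with whole-run inversions (restricted
to run boundaries so per-contig expected orientations stay well defined).
Hit tables are generated from the known placements with identities and
scores computed by positionwise comparison of the actual sequences
(score $= 2\,\mathrm{matches} - 3\,\mathrm{mismatches}$, the classic
ungapped match/mismatch currency); a decoy mode plants second-best hits
above the ambiguity (or pairing-margin) threshold to exercise those
filters. A small built-in seed-and-extend aligner (`naive_chunk_align()`)
provides alignment-derived hits independently of the truth tables for
cross-checks.

One global seed drives a derived RNG stream per emitter, so outputs are
byte-identical under a fixed seed and adding one emitter never perturbs
another.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: indels and structural variants between
haplotypes (classification logic is substitution-agnostic, but real
alignments are not), repeats and segmental duplications (decoy hits only
caricature them), GC-dependent coverage bias, chimeric contigs, and real
aligner scoring quirks (e-values are not modelled; all rules rank by
bitscore).

## Allele pairing and the haploid gene count

Phase-separated gene models come in allelic pairs. Candidates are mutual
best hits in an all-vs-all CDS comparison restricted to separated models
(self-hits excluded; an exact score tie for best makes a gene ambiguous
and unpaired — the conservative reading, in the same spirit as the chunk
ambiguity rule). A candidate is valid only if, in *both* directions, the
second-best match — excluding self and the reciprocal partner, otherwise
the rule would be vacuous — scores at most 99% of the best; absence of a
second hit passes. This margin is what rejects recent paralogs, which is
also why pairing recall on real data cannot reach 1.

The haploid gene number follows as `n_total - floor(n_separated / 2)`;
an externally determined copy count can be substituted when one is
available (published analyses sometimes report a curated copy count that
differs from the naive halving, so the function accepts either and
reports the estimate raw and rounded to the nearest thousand).

Gene-model filtering keeps a gene when its best database bitscore reaches
at least 0.25 of its self-alignment score *and* the best alignment covers
at least 0.25 of the query (inclusive; the best score is taken across all
databases, with a per-database mode exposed). Representative transcripts
maximize peptide length with ties broken by CDS length, then transcript
id. Annotation transfer prefers RBH partners, then best hits at
$e \le 10^{-4}$.

## Numerical conventions

* N50/N90: first contig (descending order) whose cumulative sum reaches
  $\ge$ 50% / 90% of the total — the common assembler convention; `>=`
  rather than `>` is declared since reports rarely say which they used.
* Coverage folds round half away from zero ("about 207x" arithmetic).
* GC excludes N and is computed after uppercasing.
* All in-memory intervals are 1-based inclusive (GFF3 convention);
  minus-strand alignments are encoded on subject coordinates
  (`s_start > s_end`), query coordinates must ascend.
* Degenerate inputs error early and name the offender: empty contig
  sets, illegal sequence characters, non-numeric hit fields (with line
  number), genes on unknown contigs, non-positive self-scores.

## Problem sizes

The test suite exercises unit logic on purpose-built tiny tables, the
simulator-driven checks on a 600-kbp single-chromosome genome with 60
genes, and the end-to-end recovery suite plus the acceptance script on
the default 2 x 2 Mbp / 500-gene configuration — large enough for
depth means to concentrate (Poisson s.e. of a 3-kbp gene mean is
~0.2-fold) and small enough to run the whole pipeline in well under a
minute per configuration.

## Known limitations

* The scaffolder handles a single pseudo-map; true multi-map weighting
  and gap-size estimation are out of scope.
* Whole contigs are deliberately never phase-classified: real contigs
  alternate between separated and merged stretches, so only gene-level
  (or window-level) classification is meaningful.
* Chunks straddling an inversion boundary in the simulator produce no
  truth hits; real aligners would produce split hits.
* The built-in aligner is ungapped and meant for testing, not for
  aligning real assemblies at scale.
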
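---
title: "ClonoTrack: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ClonoTrack: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClonoTrack)
```

## Scope

ClonoTrack analyses longitudinal IGH repertoires from sorted B-cell
subsets, and their overlap with serum Ig peptides. This vignette
documents the statistical models, the tunable parameters and their
defaults, the synthetic-data generator that backs the test suite, and
the places where a design decision had to be made because common
practice admits more than one reading.

## Clone definition and clustering

Two rearrangements belong to the same clone when they come from the
same patient and share (1) junction (CDR3) nucleotide length, (2) V
gene and J gene (alleles stripped: `IGHV3-2*02` counts as `IGHV3-2`),
and (3) at least 88% CDR3 nucleotide identity. Within a
(patient, V gene, J gene, junction length) group, identity between two
junctions of common length $L$ is $1 - d_H/L$ with $d_H$ the Hamming
distance — no indels are possible at fixed length, so edit distance
would add nothing. Clustering is **single linkage**: sequences are in
one clone when a chain of pairwise links connects them. This matches
the effective behaviour of hierarchical clustering cut at a fixed
distance, the default of widely used clone-assignment tools. The
boundary is **inclusive**: identity exactly 0.88 links. Internally the
cut uses integer mismatch counts ($d_H \le \lfloor 0.12 L \rfloor$), so
floating-point rounding cannot move the boundary. Clustering is pooled
per patient across all time points and subsets — the span analysis
(below) is only well defined when one clone identifier covers all
samples of a patient. Records lacking a V or J call are set aside and
counted; comma-separated ambiguous calls use the first listed gene.
Clone labels are assigned in sorted group-key order, so the partition
is independent of record order.

On groups of up to 12 sequences the package's clustering is tested for
exact equality against brute-force connected components of the
thresholded identity graph, and clone counts are verified to be
monotone in the identity threshold.

## Read processing

* **Quality filter**: a read (pair) is kept when its mean Phred score
  is at least the threshold (default 20). "Mean per read" is the
  common semantic of amplicon pipelines; a per-base filter would
  change retention on synthetic data where the flanks are clean.
* **Pair assembly**: mates are matched by read identifier (orphans
  dropped and counted); the merged amplicon takes the longest 3'
  overlap with mismatch rate below 0.1, resolving overlap conflicts
  toward the higher-quality base. A full overlap-error-correcting
  assembler is out of scope; the simulator guarantees a genuine
  overlap.
* **Demultiplexing**: the amplicon 3' end carries an 8-nt isotype tag
  followed by an 8-nt subset barcode (the sort-then-barcode design in
  which the constant-region primer encodes the cell population).
  Tags are matched with ≤ 1 mismatch by default; the built-in tables
  have pairwise Hamming distance 8, so single-error correction is
  unambiguous. Ambiguous or distant tags go to an `undetermined` bin.
* **UMI consensus**: position-wise majority over the reads of a UMI
  group, ties resolved by summed quality then alphabetically (hence
  deterministic and order-independent). A group is rejected when fewer
  than 2 reads support it, or when the **mean per-read normalized
  Hamming distance to the consensus** exceeds 0.1. That error-rate
  definition is an interpretation: "maximum mismatch error rate per
  read group" could also be read per position; the group-mean reading
  matches the behaviour of the standard consensus builders. Reads of
  discordant length within a group are restricted to the modal length.
  UMI collisions (one UMI, two molecules) are not split; at 12-nt UMIs
  and the simulated library sizes they are vanishingly rare, and the
  package assigns UMIs collision-free by construction.
* **Duplicate collapse**: identical nucleotide sequences within a
  (patient, time point, subset, isotype) stratum become one record
  with `duplicate_count` equal to the number of distinct UMIs — the
  copy number used as the abundance proxy downstream.

Every step logs input/pass/fail counts, and the tests assert the
conservation identity records_in = retained + dropped per step.

## Germline assignment

The annotator is a deliberately simple, gap-free semi-global scorer:
each V segment is scored by Hamming identity against the read prefix
(at codon-aligned offsets up to a configurable shift, default 0) and
each J segment against the suffix; the best segment wins, ties break
lexicographically and are flagged. The junction runs from the
conserved cysteine codon that ends the V segment to the conserved
tryptophan codon that starts the J segment. Records below a 70%
identity floor, or with an impossible junction, are excluded as
unannotatable. This replaces a full aligner-based annotator by design:
real data should be annotated externally and ingested through
`readAirr()`; the analysis layer is the package's contribution.
Productivity requires an in-frame junction (length divisible by 3) and
a stop-free translation; unproductive records are excluded **before**
clone inference (whether the original pipelines filter before or
inside the clone-assignment step is not documented; filtering first is
the conservative reading and is flagged here as an interpretation).

## Diversity

Hill numbers $^qD = (\sum_i p_i^q)^{1/(1-q)}$ interpolate richness
($q=0$) and the exponential Shannon entropy ($q=1$, computed by its
limit expression when $|q-1| < 10^{-8}$). Clone abundance $p_i$ is the
clone's summed `duplicate_count` — copies approximate cells; a
unique-sequence weighting is available by dropping the column. The
bootstrap draws `nResample = 951` records with replacement per
repetition, weighted by copy number, recomputes clone abundances from
the draw and re-evaluates the Hill number; 200 repetitions by default;
samples holding fewer copies than the resample size are resampled
anyway and flagged rather than silently dropped. The resampling unit
(copy-weighted records) is one of two defensible readings of
"bootstrap sample of n sequences"; it mirrors the abundance bootstrap
of the standard repertoire toolkits and is configurable in effect via
the duplicate counts. Expanded clones are those with strictly more
than 100 member sequences (`> 100`, a boundary the tests pin down).

## Clone spans and overlap proportions

A clone's span is the exact set of time points at which it has at
least one member sequence; the seven non-empty subsets of
{B, 6M, 12M} are mutually exclusive and exhaustive classes. Per-subset
spans are computed analogously from the clone's members within each
subset, so one clone may occupy different classes in different subsets
and contributes once to every subset it appears in. Overlap
percentages are reported, by default, over the clones spanning at
least two time points — the four multi-time-point classes then sum to
100% (2 + 12 + 26 + 60 in the worked example) — because
single-time-point clones answer a different question; `denominator =
"all"` includes them.

## Ig proteogenomics

Translated productive rearrangements form the per-patient BCR
database; CDR1/CDR2 intervals come from the germline V annotation and
CDR3 from the junction. Tryptic digestion cleaves after K or R except
before P (the classical rule; a Trypsin/P-style variant is a flag on
the matcher side by disabling boundary checks), emitting fragments
with up to 2 missed cleavages and at least 6 residues. A peptide
match is an exact substring occurrence whose boundaries are
tryptic-consistent; requiring tryptic consistency for transcriptome
matches is an interpretation (spectral search engines enforce it on
the spectrum side) and can be disabled. A peptide is **specific** when
it matches exactly one distinct BCR sequence — distinct at the
amino-acid level, since two nucleotide variants with one translation
are the same proteomic entity; clone-level uniqueness is available —
and covers at least 3 residues of a single CDR interval (inclusive).
Spectra, FDR and quantification are outside the package: the interface
is a peptide list, as produced by a search engine's evidence table or
by the simulator. Light-chain-derived peptides simply fail to match an
IGH database.

## Statistics

* Friedman chi-square on within-patient ranks, with Dunn's pairwise
  z-tests on mean ranks gated on the omnibus (default $\alpha=0.05$)
  and Holm adjustment by default (the adjustment used by point-and-
  click packages is not documented; Holm is the conservative default,
  Bonferroni and none are available). Fully tied blocks degenerate the
  tie-corrected statistic to 0/0; the package reports statistic 0 and
  p = 1 there.
* Kruskal–Wallis omnibus gating pairwise Wilcoxon tests. The gated
  test is the **signed-rank (paired)** test — a "paired rank-sum test"
  is internally contradictory, and the paired design is what repeated
  measures require; the rank-sum variant is a flag. For $n \le 14$
  pairs the two-sided p-value is computed exactly by enumerating all
  $2^n$ sign patterns on midranks, which stays exact under tied
  absolute differences where the classical exact distribution is
  unavailable; above that, the standard exact/normal switch applies.
* Null calibration is tested: simulated-null p-values of all three
  tests pass a Kolmogorov–Smirnov uniformity check.

## The synthetic cohort generator

`simulateCohort()` draws, per patient, a set of true clones with:

* **Power-law clone sizes**: expected molecule counts from a density
  $\propto s^{-1.5}$ truncated to [1, 1000]. Published repertoire
  studies report expanded clones but no size law; a Zipf-type law is
  the standard assumption. The truncation keeps desk-scale runs
  bounded; tests verify the draw against the truncated CDF by KS test.
* **Persistence classes** over {B, 6M, 12M} with configurable
  probabilities; by default half the clones are single-time-point
  (split evenly) and the multi-time-point half follows the
  2/12/26/60% split across B+6M / B+12M / 6M+12M / B+6M+12M. A clone
  realises at least one molecule at every time point of its class, so
  generated spans are exact ground truth.
* **Subset propensities** from a Dirichlet around a naive-heavy cohort
  composition (45/30/15/10%), floored away from zero so no clone is
  confined to one subset; isotype usage follows the dominant subset
  (naive IgM/IgD-heavy, memory/plasmablast IgG/IgA-heavy).
* **Memory depletion**: with fold factor $d$ (default 3), each clone's
  memory compartment is silenced at 6M and 12M with a probability
  averaging $1 - 1/d$, biased toward small clones
  ($\propto \lambda^{-0.5}$). Expected memory clone counts at 6M are
  therefore reduced $d$-fold, while the surviving memory clones are
  preferentially the expanded ones — reproducing both the clone-count
  reduction and the expanded-fraction increase. $d = 1$ is the null
  scenario.
* **Somatic hypermutation**: uniform per-base substitutions per
  molecule relative to the clone founder, default 2% — enough
  intra-clone variation to exercise the clustering while staying well
  under the 12% distance threshold; variants acquiring an in-frame
  stop are redrawn, since stop-bearing transcripts are not part of the
  expressed, selected repertoire. Hotspot-aware SHM models are a
  non-goal.
* **Reads**: one UMI per molecule (collision-free by construction),
  $1 + \mathrm{Pois}(\mu - 1)$ read pairs per molecule, amplicon =
  VDJ + isotype tag + subset barcode, mates covering 60% of the
  amplicon from each end, uniform per-base substitution errors applied
  independently per mate.
* **Serum peptides**: tryptic fragments drawn from clones weighted by
  abundance and plasmablast propensity (antibody-secreting cells
  dominate serum Ig), plus a configurable fraction of decoy peptides
  verified to match nothing in the repertoire.

The generator emulates the *structure* the analysis assumes — clone
sharing across samples, copy counts, barcoded subsets, a
treatment-like memory effect — not the biology of real repertoires:
germline segments are random in-frame sequences (5 families × 2
alleles, 6 J by default, families < 90% identical), there is no
class-switch lineage structure, no SHM hotspots, no sequencing-quality
profile beyond uniform errors. Passing tests therefore demonstrate
that the implementation recovers known structure under its own model
assumptions, not that those assumptions hold in any particular
dataset.

## Numerical choices and degenerate inputs

* Consensus base ties: summed quality, then alphabetical — never
  random.
* Zero-length junction groups: each sequence its own clone, with a
  warning.
* Empty abundance vectors, zero-clone samples and empty cohorts are
  explicit errors, not NaN propagation.
* Printed-table means are rounded half away from zero to integers,
  matching how cohort tables are typically printed.
* Seeds: every stochastic entry point takes a `seed` and restores the
  caller's RNG state; fixed seed means byte-identical FASTA/FASTQ/TSV
  output.

## Problem sizes in the test suite

The suite favours scaled-down cohorts chosen to keep the full run in
the tens of minutes on one core while leaving the statistical checks
well powered: module tests use 1–2 patients × 100–350 clones; the
end-to-end depletion/null recovery uses 20 + 20 reruns of 8 patients ×
250 clones (no SHM — the diversity contrast does not need it); span
recovery uses one patient × 2000 clones with 2% SHM; null-calibration
checks use 1000 simulations per test with 60×5 blocks (Friedman),
3×25 groups (Kruskal–Wallis) and 40 pairs (Wilcoxon). The acceptance
script simulates 8 patients × 400 clones with SHM.

## Known limitations

* The built-in annotator assumes reads start at the V 5' end (up to a
  small codon-aligned shift) and cannot handle indels; real data needs
  an external annotator and `readAirr()`.
* UMI collisions are not subclustered.
* `duplicate_count` as a cell-count proxy inherits the usual caveats
  (per-cell mRNA differences, especially for plasmablasts).
* The span analysis treats detection as presence: a clone sampled
  below detection at one time point is classified as absent there,
  exactly as in the underlying study design.
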
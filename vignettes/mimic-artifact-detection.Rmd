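---
title: "Detecting artifact RNA species from transfected miRNA mimics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artifact RNA species from transfected miRNA mimics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicqc)
```

## The problem

Synthetic miRNA mimics are double-stranded RNA duplexes transfected into
cells to mimic a mature miRNA. Small-RNA sequencing of mimic-transfected
cells reveals that a substantial part of the delivered material is not the
intended guide strand: libraries contain mutated guides carrying single-base
deletions, "antisense" species perfectly complementary to the guide
(the mimic's unnatural passenger strand), and a family of high molecular
weight (HMW) species longer than the mature form — concatemers of two or
more guide units, guides with non-templated 5'/3' tails, polyadenylated
guides, and hybrids of a guide with an endogenous miRNA. These artifacts
matter because they accumulate at supraphysiological levels and can drive
non-specific transcriptional responses.

`mimicqc` implements the detection and quantification of these species as a
reusable, fully testable pipeline: a seeded simulator with per-read truth
labels, preprocessing (adapter trimming, length, contaminant and abundance
filters), an edit-distance classifier over the artifact taxonomy, and the
accompanying bench quantification conventions (ΔΔCT, internal-control
normalization, spike-in calibration, division-normalized decay).

## The artifact taxonomy and the classifier

Every unique insert receives exactly one label from:

`MATURE`, `TRIMMED`, `MUTANT_DELETION`, `ANTISENSE`, `HMW_CONCATEMER`,
`HMW_5TAIL`, `HMW_3TAIL`, `HMW_POLYA`, `HMW_HYBRID`, `ENDOGENOUS`,
`UNASSIGNED`.

Matching uses unit-cost Levenshtein distance (substitutions, insertions and
deletions all cost 1) with a default radius of `max_edits = 5`, permitting
indels — the matching regime of `vcountPattern(..., max.mismatch = 5,
with.indels = TRUE)` that this analysis is built around. The matcher
(`edit_match()`) performs a semi-global alignment of the whole guide against
any substring of the insert, on both strands, and reduces overlapping
placements to non-overlapping, locally optimal hits (lowest distance, then
leftmost start, then longest span). `N` bases mismatch everything.

Classification precedence is *exact before approximate, single-unit before
multi-unit*:

1. exact guide → `MATURE`; exact reverse complement → `ANTISENSE`;
   exact endogenous sequence → `ENDOGENOUS`;
2. an insert obtainable from a guide by deletions only:
   removal of **exactly one base** (anywhere) → `MUTANT_DELETION`;
   removal of 2–3 bases from the ends → `TRIMMED` (sub-labelled 5'/3'/both);
   any other deletion-only pattern → `MUTANT_DELETION`;
3. inserts of 25–74 nt containing at least one guide unit are decomposed
   (`decompose_hmw()`): ≥ 2 mimic units → `HMW_CONCATEMER`; one mimic unit
   plus an exact endogenous unit → `HMW_HYBRID`; one unit with an unmatched
   flank ≥ `min_tail` (3 nt) → `HMW_5TAIL`/`HMW_3TAIL`, except that an
   entirely-A 3' flank ≥ `polya_min` (5 nt) is `HMW_POLYA`;
4. anything else → `UNASSIGNED`.

Design choices where the taxonomy is genuinely ambiguous:

* **One-base end removal.** A guide missing its terminal base is
  string-identical whether one calls it a 1-nt trim or a terminal deletion.
  We always call single-base removal `MUTANT_DELETION`, so that the complete
  enumeration of single-deletion variants of a guide is labelled uniformly;
  `TRIMMED` therefore requires 2–3 bases off the ends. The simulator still
  generates 1-nt trims and flags them `ambiguous` in the truth table with
  the alternative label.
* **Deletion positions in homopolymers** are reported leftmost; the recorded
  deleted bases reconstruct the guide regardless of which physical base was
  lost. Note that distinct guides can share a deletion variant (deleting
  C11 of miR-19b and T11 of miR-19a give the same 22-mer); the classifier
  reports one parent deterministically (lowest distance, then reference
  order).
* **Poly(A) vs generic 3' tailing.** Operationally, `HMW_POLYA` requires the
  whole 3' flank to be adenines; a mixed tail that merely ends in A-runs
  stays `HMW_3TAIL`. Poly(A) takes precedence over generic 3' tailing.
* **Hybrids** require the endogenous unit to match exactly (distance 0):
  allowing approximate endogenous units would make hybrids indistinguishable
  from mutant concatemers.
* **HMW window.** Decomposition applies only to 25–74 nt inserts, so a
  24-nt tailed guide falls outside HMW territory by construction; windows
  are inclusive.

## Preprocessing conventions

* Reads are insert + 3' adapter (`TGGAATTCTCGGGTGCCAAGG`); trimming is
  3'-anchored, matching the longest read suffix against an adapter prefix
  with mismatch rate ≤ 10% and overlap ≥ 3 (the common small-RNA trimming
  regime; the analysis this reproduces names the tool but not parameters).
  Reads without an adapter-like suffix pass through untrimmed and flagged.
* The length filter keeps 15–80 nt inclusive: the discard rule is strictly
  "shorter than 15" / "longer than 80".
* Contaminant (rRNA-like) removal is an exact-substring filter against a
  user-supplied FASTA (either strand). This deliberately replaces genome
  alignment: it is deterministic, dependency-free, and adequate at the scale
  this package targets. The bundled contaminant file is synthetic.
* The enrichment filter keeps unique inserts whose fraction of
  post-length-filter reads is **strictly** greater than 0.1%. We apply it to
  collapsed unique sequences (the underlying description is ambiguous
  between unique sequences and read multisets); both pre- and
  post-filter totals are reported so either convention can be compared.
* Read conservation is tracked at every stage:
  `reads_in = retained + short + long + contaminant (+ empty)`.
* Qualities are parsed but not used; no quality trimming is applied.

## The simulator

`sim_config()`/`simulate_library()` generate FASTQ libraries with a truth
table (one row per read). Class counts are multinomial in the configured
mixture; each class is constructed literally from its definition (exact
guide, reverse complement, single internal deletion, 2–3-unit concatemers,
uniform-random tails of 3–25 nt, ≥ 5-A poly(A) tails, guide + endogenous
hybrids, verbatim endogenous/contaminant sequences). Reads are insert +
adapter truncated to 75 nt, unpadded, constant Phred 30, with optional
per-base substitution errors. Identical configs (including `rng_seed`)
produce byte-identical output.

The default mixture (40% mature, 12% antisense, 5% mutant, 3% trimmed,
30% HMW across the five subclasses, 10% endogenous) represents a
mimic-transfected library in which the exact guide dominates and artifacts
are individually minor; sample sizes in the tests (2–50 k reads) keep the
suite fast while leaving per-class counts in the hundreds to thousands.

Two generator rules keep truth labels well-defined rather than tuning any
result: random tails may not be entirely A at poly(A)-qualifying lengths
(such a tail *is* a poly(A) tail), and may not themselves contain a guide
unit within the edit radius (such an insert *is* a concatemer under the
matching rule — about 1 in 4 000 random 25-mers lies within 5 edits of a
guide, and mislabelling those would be a simulator bug, not a classifier
error). Constructions that remain genuinely ambiguous — 1-nt end-trims, and
tailed species whose total length falls outside the 25–74 nt window (a
21-nt guide with a 3-nt tail) — are flagged in the truth table together
with the alternative label the classifier may legitimately assign;
agreement metrics accept the flagged alternative.

What the simulator does **not** emulate: ligation bias, PCR duplication,
quality degradation along the read, indel sequencing errors, isomiR
heterogeneity of the endogenous background, and abundance skew within a
class (species within a class are sampled uniformly). Passing round-trip
tests therefore demonstrates correctness of the algorithms under the
taxonomy's own generative model, not performance on any particular
biological library.

## Quantification conventions

* **ΔΔCT**: fold = 2^−ΔΔCT with PCR efficiency fixed at 2; the reference
  gene and calibrator sample are explicit arguments, and the calibrator's
  fold is exactly 1.
* **Internal-control normalization**: per lane, target/control rescaled to a
  designated reference lane (the non-transfected lane is 1 by convention).
* **Spike-in ladder**: copies are interpolated piecewise-linearly in
  log(copies) vs log(intensity) — band intensity is multiplicative — with
  clamped extrapolation at the ladder ends, then divided by cells per lane.
* **Division-normalized decay**: observed signal is corrected by
  2^(t/Td) (Td = doubling time, 23 h for HeLa); the observed half-life
  comes from an OLS fit of log2 signal vs time (simple, deterministic, and
  adequate for monotone series — nonlinear fitting would add nothing here);
  the corrected decay rate is k = ln2·(1/t_obs − 1/Td), and k ≤ 0 is
  reported as *no active decay*. A 28 h observed half-life against a 23 h
  doubling time gives k < 0: the decline is dilution, not decay.
* **HMW fold change** between sample and control uses library-normalized
  fractions within a 30–60 nt window (chosen to exclude a co-migrating
  endogenous snoRNA); the control is 1 by construction, a zero control
  count yields an `Inf` sentinel rather than a pseudo-count, and the
  concatemer/5'/3' composition triple is emitted normalized to 1. Raw-count
  mode (`normalized = FALSE`) is available for comparisons with
  near-identical library sizes.

## Worked example

```{r, eval = FALSE}
library(mimicqc)

cfg <- sim_config(n_reads = 10000, rng_seed = 7)
sim <- simulate_library(cfg)
tab <- preprocess_fastq(sim)                 # trim, filter, collapse, enrich
cls <- classify_inserts(tab, mir17_92_guides(), example_endogenous())
dplyr::count(cls, class, wt = count, sort = TRUE)

hist <- length_histogram(cls)
plot_length_distribution(hist)

fit <- division_normalized_decay(seq(0, 72, 12),
                                 100 * 2^(-seq(0, 72, 12) / 28),
                                 doubling_time = 23)
glance(fit)        # k_decay < 0: no active decay
autoplot(fit)
```

## Numerical choices and limitations

* Tolerances: closed-form identities (decay correction, ΔΔCT, interval
  arithmetic) are tested to 1e-9; simulation-based recoveries use 99%
  binomial confidence bands at n = 50 000.
* Ties in the matcher are broken deterministically (distance, then leftmost,
  then longest), so all outputs are reproducible bit-for-bit from the seed.
* The edit radius of 5 is generous for ~22-nt guides; random ≥ 25-nt
  sequences occasionally fall within it (see the simulator rules above).
  Lowering `max_edits` tightens specificity at the cost of missing heavily
  mutated units.
* The contaminant filter only removes exact substrings; diverged rRNA
  fragments would survive it. Genome alignment remains out of scope.
* Fold-change attribution assigns multi-guide concatemers to the first
  (leftmost) unit's guide.
* `UNASSIGNED` random sequences in the simulator are not screened against
  the guide set, so mixtures that include `UNASSIGNED` can rarely contain a
  guide-like insert; the default mixture does not include it.
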
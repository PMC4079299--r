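---
title: "Quantifying endogenous retrovirus expression from short tags: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endogenous retrovirus expression from short tags: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human endogenous retroviruses (HERVs) make up roughly 8% of the human
genome. They are organized in families (HERV-K, -H, -W, -R, -E, -FRD, ...)
of related proviral loci, each provirus carrying long terminal repeats
(LTRs) around internal *gag*, *pol* and *env* genes. Because family members
are numerous and mutually similar, short sequencing reads ("tags") from
HERV transcripts are hard to attribute: a tag may fit several family
references almost equally well, and a naive best-hit assignment silently
converts that ambiguity into systematic misattribution.

`retroscope` implements a transcriptome-profiling pipeline for exactly this
regime: fixed-length single-end tags (default 36 nt), a labeled reference
universe, hierarchical source-class triage, *unambiguous* family assignment
with an explicit margin, length-normalized region abundance, and a
host-gene association screen against HERV-K *env* abundance. A seeded
synthetic-data generator reproduces the statistical structure of the
problem so every stage is testable with exact ground truth.

## Classification model

### Alignment

Tags are matched to references by Hamming distance (substitutions only, no
gaps), on both strands, with at most `max_mismatches` mismatches (default
2). The search is seed-and-extend: references are indexed by exact k-mers
and only candidate diagonals found through a seed are verified.

The seed length matters for completeness. With seeds of length $s$ placed
at non-overlapping offsets along a tag of length $L$, the pigeonhole
principle guarantees that any placement with at most $m$ mismatches retains
a mismatch-free seed only when $(m+1)\,s \le L$. The configured default
($s = 18$, $m = 2$, $L = 36$) does not satisfy this: two mismatches can be
spread so that every 18-mer window of the tag contains one. We therefore
shorten the *effective* seed to $\lfloor L/(m+1)\rfloor$ (12 nt at the
defaults) whenever the configured seed cannot give the guarantee. With that
choice the seeded search is provably identical to an exhaustive
all-positions Hamming scan — the test suite asserts this identity against
an independently written brute-force scanner — while remaining fast,
because a 12-mer in a reference universe of a few hundred kilobases has few
spurious matches.

### Hierarchical triage

Each tag is assigned to the first tier, in a fixed order, where it has at
least one hit:

1. rRNA
2. host transcriptome (a hit to a nuclear-genome-only reference, with no
   transcript hit, is reported under its own `NUCLEAR` label)
3. mitochondrial DNA
4. microbial
5. HERV

A tag with no hit anywhere is `UNASSIGNED`. The order encodes the usual
contamination logic of bulk brain RNA-seq: abundant rRNA first, then the
host transcript background, and HERV only for what remains. The tier rule
is absolute — a tag matching both an rRNA and a HERV reference is counted
as rRNA regardless of mismatch counts — which makes the class counts
exclusive and additive.

### Unambiguous family assignment

Within the HERV tier, let $d_f$ be the best mismatch count against family
$f$ and $d_1 \le d_2$ the two smallest values over families. The tag is
assigned to the argmin family only when the argmin is unique and
$d_2 - d_1 \ge$ `ambiguity_margin`; otherwise it is `HERV_AMBIGUOUS` and is
excluded from every family's count. The default margin of 1 is the
strictest reading of "unambiguous": any tie is ambiguous. Raising the
margin demands that the best family win by a clear gap, trading sensitivity
for specificity.

The region label (`ENV`, `GAG_POL`, `LTR`) is taken from the annotation
containing the **midpoint** of the aligned interval, so a tag straddling a
boundary is counted exactly once, deterministically, and independently of
input order. *gag* and *pol* are modeled as a single `GAG_POL` label
because the two are quantified jointly in this tag regime.

## Abundance quantities

* **Family tag frequency**: a family's percent share of the sample's
  unambiguously HERV-assigned tags. Ambiguous tags are excluded from the
  denominator by default (`include_ambiguous = TRUE` reports them as their
  own category instead); frequencies over *unambiguous* tags are what the
  assignment rule is designed to make meaningful.
* **Region rate and frequency**: per family, tags per annotated nucleotide
  (`count / total annotated length of that label summed over the family's
  references`), rescaled to percentages within the family. Length
  normalization is essential because `GAG_POL` is typically several times
  longer than `ENV` or the LTR; under uniform coverage the normalized
  frequencies are flat regardless of the length ratios, which the
  acceptance suite verifies. Where a region label could be normalized
  per-reference instead, we use the per-label sum across the family's
  references, treating the family as the unit of reporting.
* **Global normalization**: each sample's column of the gene count matrix
  is rescaled so all column totals equal the mean of the original totals,
  under the assumption that the expression distribution is similar across
  samples. Targeting the *mean* total (rather than a fixed constant)
  preserves the overall scale and makes the operation exactly idempotent.

## Group comparison

Group contrasts (e.g. HERV-K tag frequency in HIV+ vs HIV− brain) use the
two-sided Mann-Whitney test. With at most 8 values per group the p-value is
computed exactly by enumerating all $\binom{n_1+n_2}{n_1}$ assignments of
the pooled values, counting arrangements whose U statistic deviates from
its null mean at least as much as observed; ties receive the conventional
half credit in U, and the enumeration handles them exactly. Larger groups
use the tie-corrected normal approximation with continuity correction. The
exact path is cross-checked in the tests against `wilcox.test`'s exact
distribution on tie-free cases; medians are the reported per-group summary.

## Host-gene association screen

The clinical-mode pipeline is

1. global normalization,
2. detection filter: keep genes with ≥ `min_tags` (default 2) counts —
   by default in at least one sample; `per_sample = TRUE` implements the
   stricter every-sample reading,
3. Pearson correlation of each gene with per-sample HERV-K *env*
   abundance; keep genes with $r^2 \ge 0.5$ (both signs; zero-variance
   genes are flagged undefined and fail),
4. fold-change filter: keep genes with
   $|\text{mean(case)}/\text{mean(control)} - 1| \ge 0.3$. The symmetric
   definition is deliberate — a screen feeding a functional-enrichment step
   should keep suppressed genes as well as induced ones — and the
   one-sided `ratio` mode is available by flag. A zero control mean with a
   positive case mean counts as an infinite change and passes,
5. term overrepresentation of the selected set against the
   detection-passing universe: hypergeometric upper tail
   $p = P[X \ge k]$ for a term with $K$ universe genes, $k$ of them among
   the $n$ selected out of $N$, with Benjamini-Hochberg adjustment across
   terms. BH (rather than Bonferroni) is the standard choice for
   enrichment lists of correlated terms.

The enrichment test runs on a user-supplied gene-to-term table, so the same
machinery serves GO-style and pathway-style annotations; nothing depends on
an external annotation service. The universe is the set of genes that
passed detection — the genes that were actually testable — not the full
matrix.

In healthy mode (no group labels) step 4 is skipped. Every run can write
its intermediates plus a JSON manifest recording parameters and MD5 digests
of the inputs.

## What the synthetic generator emulates

`sim_config()` defaults are the package's study conditions:

* **Tag regime**: 36-nt single-end tags, substitution-only errors at 1%
  per base (indels are negligible for this read length and are not
  modeled), constant qualities.
* **Source-class mixture**: `RRNA .3145, HOST_TX .1179, NUCLEAR .3260,
  MTDNA .0767, MICROBIAL .0010, HERV .0200, JUNK .1439`. These follow the
  triage proportions observed in deep-sequenced brain tissue
  (roughly 33/12/34/8/0.1% with ~15% unmappable), rescaled to sum to one —
  the observed buckets overlap slightly because paired reads can hit
  several databases — after carving out a small HERV fraction; `JUNK`
  (i.i.d. random sequence) models the unmappable fraction.
* **Family structure**: six families drawn from one random ancestor by
  i.i.d. substitution at 10% per site, so cross-family identity (~81% at
  the defaults) makes family assignment non-trivial but mostly resolvable
  at 2 mismatches over 36 nt. The family mixture defaults to an
  HERV-H-dominated profile (57% H, 31% K) as observed in healthy brain.
* **Planted ambiguity**: one 80-nt motif copied verbatim into every
  family's LTR at the same offset. Tags lying wholly inside it are
  *exactly* equidistant from all families and must end up
  `HERV_AMBIGUOUS`; this is the hard test of the no-leakage property.
* **Proviral geometry**: LTR 500 nt, gag-pol 2000 nt, env 500 nt — a
  compact provirus with the gag-pol segment dominating by length, which is
  what makes length normalization consequential.
* **Cohort**: 8 samples (4 HIV+, 4 HIV−). True HERV-K env abundance is
  log-normal within group with a 10-fold higher median in HIV+ (an
  order-of-magnitude induction, chosen once as a clearly "strong" effect
  for an 8-sample design; with only 4 + 4 samples an r²≥0.5 screen needs a
  large separation to have high per-gene power). The per-sample HERV-K
  share of simulated tags scales with env abundance, so the group contrast
  is visible to the classifier as well.
* **Host module**: 200 genes with log-normal baseline means
  (median ≈ 100 counts), negative-binomial counts at dispersion 0.1;
  a 20-gene module whose means scale linearly with env abundance
  (`module_effect = 1` means exactly proportional; 0 removes the effect,
  and dispersion 0 degenerates to deterministic means for exact tests).
  One planted annotation term covers the module plus 5 decoy genes; ten
  decoy terms of 15 random genes each complete the term table.

Everything is a pure function of the seed (per-sample streams are derived
deterministically from it), so repeated runs are byte-identical — the demo
and the tests rely on this.

**What the generator does not emulate**: quality-score structure,
paired-end reads, indels, PCR duplicates, splicing, locus-level (rather
than family-level) reference redundancy, GC or positional coverage bias,
and annotation terms with realistic overlap structure. Passing tests
therefore demonstrate the correctness and calibration of the algorithms
under the stated generative model, not performance on any particular real
library.

## Numerical and design choices

* Coordinates are 0-based half-open (BED convention) everywhere.
* Sequences are uppercased on load; IUPAC ambiguity codes are rejected
  rather than interpreted, because Hamming scoring needs a fixed
  four-letter alphabet and the generator never emits them.
* Hit ties at equal mismatch count are ordered by (reference id, position,
  strand); reference ids are sorted with locale-independent (radix)
  ordering, so results do not depend on the session locale.
* Strand is unknown for these libraries, so every comparison considers the
  tag and its reverse complement.
* The exact Mann-Whitney enumeration is cut off at 8 values per group
  (12,870 arrangements at 8 + 8), balancing exactness against runtime.
* A fold-change denominator of zero is reported as infinite, not an error;
  a gene absent in both groups scores zero change.
* `family_frequencies()` raises an error (rather than returning NaN) for a
  sample with no HERV-assigned tags.
* Problem sizes in the test and acceptance suites (50,000-tag samples for
  mixture recovery, 30,000 HERV tags for region flatness, 40 replicates
  for null calibration of the enrichment step, 20 seeds for the
  correlation-separation property) were chosen so that the binomial or
  Monte-Carlo error of each checked quantity is several times smaller than
  the tolerance it is checked against.

## Known limitations

* Family-level, not locus-level, assignment: the reference universe
  carries one or a few exemplars per family, and "unambiguous" is defined
  between families.
* No gapped alignment; a tag spanning an indel relative to the reference
  is lost to `UNASSIGNED` rather than recovered.
* The triage order is fixed; a different contamination hierarchy requires
  relabeling the reference classes.
* The association screen is a marginal per-gene filter pipeline, not a
  joint model; it inherits the multiple-screening behavior of the original
  design rather than correcting for it, and the enrichment step knows
  nothing of term-term dependence beyond BH.
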
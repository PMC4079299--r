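# retroscope

Quantification of human endogenous retrovirus (HERV) expression from short
single-end sequencing tags, with a host-gene association screen — for
transcriptomics researchers profiling repeat-family expression in tissue
(e.g. brain) where tags must be triaged against rRNA, host and microbial
backgrounds before any HERV family can be credited.

## What it computes

HERVs are families of mutually similar proviral loci (HERV-K, -H, -W, -R,
-E, -FRD, ...), each provirus carrying LTRs around *gag-pol* and *env*.
Short tags from HERV transcripts often fit several family references almost
equally well, so the pipeline's core is an *unambiguous* assignment rule:

1. **Triage.** Each tag is Hamming-aligned (substitutions only, both
   strands, ≤ 2 mismatches by default) against a labeled reference
   universe and assigned to the first tier with a hit, in the fixed order
   rRNA → host transcriptome (nuclear-genome-only tracked separately) →
   mtDNA → microbial → HERV; no hit ⇒ unassigned. The aligner is
   seed-and-extend with an effective seed of ⌊L/(m+1)⌋ nt, which makes it
   provably identical to an exhaustive all-positions Hamming scan.
2. **Family assignment.** Within the HERV tier, with d₁ ≤ d₂ the two best
   per-family mismatch counts, a tag is assigned to the best family only
   if the argmin is unique and d₂ − d₁ ≥ margin (default 1: any tie is
   ambiguous). Ambiguous tags never enter any family's count.
3. **Abundance.** Family tag frequency = percent share of unambiguously
   HERV-assigned tags. Region frequency = tags per annotated nucleotide of
   ENV / GAG_POL / LTR, rescaled to percent within the family ("normalized
   to gene lengths"). Group contrasts use the Mann-Whitney test, exact by
   enumeration for groups of ≤ 8.
4. **Association screen.** On a globally normalized count matrix (column
   totals equalized to their mean): detection filter (≥ 2 tags), Pearson
   r² ≥ 0.5 against per-sample HERV-K *env* abundance, fold-change filter
   |case/control − 1| ≥ 0.3 in clinical mode, then hypergeometric term
   overrepresentation (p = P[X ≥ k]) with Benjamini-Hochberg control.

A seeded synthetic-data generator (`sim_config()`, `build_reference()`,
`simulate_tags()`, `simulate_cohort()`) produces reference sets with
controlled family divergence and a planted shared LTR motif, tag FASTQs
with substitution errors, and a two-group cohort with a planted
env-tracking gene module — so every stage is testable against exact ground
truth without any external data.

## Worked example

```r
library(retroscope)

## simulate one brain-like sample and triage its 20,000 tags
cfg   <- sim_config(seed = 1, n_tags = 20000)
built <- build_reference(cfg)
fq    <- tempfile(fileext = ".fastq")
simulate_tags(built$ref, cfg, "brain_1", fastq_path = fq)
cl <- classify_sample(fq, built$ref, sample_id = "brain_1")
cl$breakdown
#>  sample_id       category count fraction
#>    brain_1           RRNA  6307   31.535
#>    brain_1        HOST_TX  2304   11.520
#>    brain_1        NUCLEAR  6518   32.590
#>    brain_1          MTDNA  1514    7.570
#>    brain_1      MICROBIAL    13    0.065
#>    brain_1           HERV   381    1.905
#>    brain_1 HERV_AMBIGUOUS    15    0.075
#>    brain_1     UNASSIGNED  2948   14.740
```

The triage percentages recover the simulated mixture (31.45% rRNA, 11.79%
transcriptome, 32.60% nuclear, 7.67% mtDNA, 0.10% microbial, 2% HERV,
14.39% junk) to binomial accuracy; tags inside the planted shared LTR motif
surface as `HERV_AMBIGUOUS` rather than inflating any family.

Family and region frequencies on a HERV-only sample:

```r
ff <- family_frequencies(ah)        # ah: assignments of a HERV-only sample
ff
#>    family count    freq
#>    HERV-H 10849 56.1979
#>    HERV-K  6060 31.3908
#>    HERV-W  1030  5.3354
#>    HERV-R   760  3.9368
#>    HERV-E   423  2.1911
#>  HERV-FRD   183  0.9479

region_frequencies(ah, bh$ref, "HERV-K")
#>    label count length_nt  rate  freq
#>      ENV   995       500 1.990 34.27
#>  GAG_POL  4209      2000 2.104 36.24
#>      LTR   856       500 1.712 29.48
```

The family shares recover the simulated mixture (57/31/5/4/2/1%); note the
`rate` column — raw counts are dominated by the 2000-nt gag-pol region, but
per-nucleotide rates are flat under this sample's uniform coverage, which
is exactly what length normalization is for.

A group contrast, exact because both groups have ≤ 8 samples:

```r
compare_groups(list(HIVpos = c(81.2, 79.3, 83.5, 77.9),
                    HIVneg = c(30.1, 28.9, 33.2, 29.5)),
               metric = "HERV-K tag frequency (%)")
#> Mann-Whitney (HERV-K tag frequency (%)) - exact enumeration
#>   medians: HIVpos=80.25 HIVneg=29.8
#>   U = 16  two-sided p = 0.02857
```

p = 2/70, the smallest two-sided value a 4-vs-4 design can produce. The
full pipeline — cohort simulation, classification, quantification, group
contrast, association screen, truth-recovery report — runs as one command:

```r
run_demo(seed = 1, out_dir = "demo_out")
```

or from a shell via the bundled CLI
(`inst/cli/retroscope.R simulate|classify|quantify|associate|demo`).

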
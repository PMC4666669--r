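---
title: "clipsv: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clipsv: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the signal

Structural variants (SVs) — deletions, tandem duplications, inversions and
inter-chromosomal copy insertions — interrupt the collinearity between a
sequenced genome and its reference. In paired-end short-read data every
junction leaves mapping fingerprints: reads crossing a breakpoint are
soft- or hard-clipped exactly at it, their clipped portions realign at the
partner locus (recorded by the aligner in the `SA` supplementary and `XA`
alternative-alignment tags), and read pairs straddling the event show
stretched inserts (deletion), everted orientation (tandem duplication),
same-strand mates (inversion) or trans-chromosomal mates (insertion).
`clipsv` detects breakpoints from the clip signal jointly across samples,
locates the partner breakpoint from the tag evidence, genotypes each
sample with a mapping-quality likelihood model, types the event with a
random forest, and optionally contrasts two cohorts with a binomial
likelihood-ratio test.

## Breakpoint detection

All BAMs are scanned once and every soft/hard clip boundary is hashed by
exact `(chromosome, position, side)`. Unmapped and duplicate-flagged
records are excluded (PCR duplicates re-report one molecule and otherwise
convert noise into support); secondary/supplementary records are indexed
but flagged non-primary. A key becomes a candidate when at least
`min_support` (default 3) *primary* reads share it. No positional fuzzing
happens here: distinct alleles with distinct breakpoints at overlapping
loci remain distinct candidates.

The clipped overhangs of a candidate are collapsed into a consensus by an
anchored, gap-free column vote: clips share a fixed anchor (the
breakpoint), so left-side clips are right-aligned, right-side clips
left-aligned, and each column takes its majority base (ties to the
lexicographically smallest base, for determinism). We deliberately do not
run a gapped multiple sequence alignment — with a shared anchor it adds
nearly nothing, while the column vote is deterministic and linear in
total bases. The mismatch fraction is the share of non-pad characters
disagreeing with their column consensus; the reported sequence is trimmed
to columns supported by at least two reads. Candidates whose consensus is
shorter than 10 bp, or has strictly more than 50% mismatch, are
discarded as likely mapping noise; a key failing the mismatch filter is
dropped entirely rather than split into sub-alleles.

## Partner-breakpoint resolution

Each `SA`/`XA` entry of a supporting read implies a partner position: the
clip-adjacent boundary of the tag alignment — its start when the tag
alignment continues the read on the same strand past a right-side clip,
its end in the strand- or side-mirrored cases (inversions match on the
opposite strand). Implied positions are rounded to the nearest multiple
of 10 bp (halves up; "tenth base pair" on an integer coordinate grid can
only mean a 10 bp bin) and clustered; the cluster with most reads wins,
ties to the leftmost. Reads with no tags contribute their discordant
mate's far edge as a low-precision fallback, used only when no
tag-derived cluster exists and never refined.

The winning cluster is then refined by local (Smith-Waterman) alignment
of the clip consensus — and its reverse complement — against the
reference within ±200 bp of the rounded position, scored +2/−2 with gap
open 3 and extend 1. The refinement is accepted only when at least 90%
of the consensus aligns at 80% identity or better, with identity
measured over the full gapped alignment length so that gap-stitched
random matches fail while substitution-only true matches pass; a random
30-mer is accepted in well under 1% of windows, while a true consensus
with a couple of sequencing errors is kept. On acceptance the breakpoint
moves to the breakpoint-proximal end of the alignment.

Safety filters for the pathological corner: inter-chromosomal calls and
spans above 1 Mb require two reads at the exact (refined, un-rounded)
partner position, and a candidate whose `SA` split reads scatter over
more than three chromosomes is discarded as repeat-driven mapping noise.

## Genotyping

Reads at a call are classified once each, strongest basis first: clipped
exactly at a breakpoint; carrying a ≥10 bp internal insertion/deletion
CIGAR operation spanning it (the 10 bp floor matches the consensus length
floor); discordantly mapped (|TLEN| beyond μ+3σ of the robustly
estimated insert distribution, or mate on another chromosome);
same-strand mate pair; otherwise reference-spanning. Insert statistics
are median/MAD per sample over the first 100,000 proper pairs.

The diploid bi-allelic likelihood uses the read's mapping quality where a
SNV caller would use base quality: with error probability
`e = min(10^(-MAPQ/10), 0.5)` the read contributes
`(g/2)·P(obs|alt) + (1−g/2)·P(obs|ref)` to genotype `g`; the site
likelihood is the product over reads, the genotype the flat-prior
maximum, GQ the phred-scaled probability of being wrong. Capping `e` at
0.5 makes MAPQ 0 reads exactly uninformative. Ploidy is fixed at two
even for pooled material; for pooled analyses the honest statistic is
the reported allele balance (`DP` and alternative counts), not `GT`.
A joint-calling site filter requires at least one sample with three or
more alternative-supporting reads, so weak clipping shared by chance
across many individuals does not call a site.

Two properties of the evidence geometry are worth knowing. Homozygous
tandem duplications genotype toward 0/1: the second copy contributes
reference-spanning reads over the junction coordinate, so the allele
balance sits near 50% even when both haplotypes carry the event (the
original tool shows the same bias). And insertion records emitted at the
donor locus genotype the *donor* site, which genuinely is reference
there.

## SV-type classification

Fourteen depth-normalised attributes summarise the pileup at the call
position — clip fractions on both sides, `SA`/`XA` carriage, long/short
discordant inserts, same-strand and everted pair fractions, unmapped and
trans-chromosomal mates, large internal indels, supplementary records,
low MAPQ (<20) and duplicate flags. The identities and order are fixed
in `attribute_names()` and flow verbatim into the `AT` INFO field, so a
model trained on one run applies to another; they are this package's own
reconstruction of "every mapping signal an SV leaves", and `AT` vectors
are not interchangeable with other tools'. The pileup at a breakpoint
includes the reads whose clip boundary sits exactly on it — they are the
evidence that defined the candidate.

A 200-tree random forest is trained on labelled attribute vectors
(tab-separated, 14 columns plus a free-form label, so users can add
their own classes, including an explicit false-positive class).
Stratified k-fold cross-validation (k = 5 by default) is reported before
the final refit on all rows; everything is deterministic under the
seed. Classification is post hoc: `WC`/`WP` are added and nothing else
changes.

## Association testing

With target and background cohorts, each called genotype contributes two
alleles to its cohort and the site is scored with
`D = −2 ln[ B(n_c,k_c,af_c) / (B(n_t,k_t,af_t)·B(n_b,k_b,af_b)) ]`,
where `B` is the binomial *kernel* `p^n (1−p)^{k−n}` at each group's own
frequency and `0·ln 0 ≡ 0`. Keeping only the kernels (the full densities
with coefficients would allow `D < 0`, because the numerator pools
counts) makes the statistic the standard two-sample binomial
likelihood-ratio: non-negative, zero exactly at equal frequencies,
symmetric in the cohorts, and asymptotically χ²(1) under the null, which
is the conversion `chi2_pvalue()` applies. Sites where a cohort has no
called alleles emit no `LRT` rather than a NaN. Null calibration is
excellent in the tail already at ~100 diploid samples per cohort
(E[D] ≈ 1, 5% rejection at 3.84); an *exact* uniformity test of the
p-value distribution (Kolmogorov-Smirnov) additionally needs the allele
counts to be large enough that their discrete lattice is invisible,
which is why the test suite runs that check at 500 samples per cohort.

## The simulator: what it emulates and what it does not

The generator builds a uniform-random reference (default ten 2 Mb
contigs), implants non-overlapping SVs at least 1 kb apart with
log-uniform sizes on [50 bp, 1 Mb], assigns het/hom zygosity per sample,
and emits the *alignment-level* evidence a paired-end run plus aligner
would produce: proper pairs tiling both haplotypes (Normal(400, 50)
inserts, 100 bp reads), junction-crossing reads soft-clipped at the
junction with `SA` tags for overhangs of 20 bp or more, strand flips
across inversion junctions, everted pairs over duplication junctions,
donor-mapped reads inside insertions, substitution errors at 0.1%, and a
small rate of artefactual random clips. Emitting BAM records directly
keeps the whole system testable without an external aligner; sequence is
stored only on clip-carrying records because nothing downstream consumes
it elsewhere.

The default study sizing (100 SVs per class on 20 Mb) cannot be
satisfied by literal log-uniform draws — 300 span-consuming SVs of
~100 kb expected size need ~30 Mb — so placement is by rejection:
a draw that cannot be placed has its size redrawn, making the realised
distribution the log-uniform law conditioned on fitting. The largest
size bins are correspondingly thinner than the nominal law.

What is *not* modelled, by design: reference repeats and low-complexity
sequence (a uniform-random genome has essentially unique 20-mers, so
every placement is unique, `XA` tags do not arise and no read is
mapping-ambiguous), mobile elements, reference errors, base-quality
structure, and aligner idiosyncrasies. The consequence is important for
reading the benchmark numbers: on this evidence the pipeline's
sensitivity and FDR are essentially ideal (≈1.0 and ≈0.0 at 50x), i.e.
noticeably *better* than published figures for clip-based callers on
read-level simulations through a real aligner, where repeat-induced
mapping error is the dominant loss. Passing the simulated benchmarks
demonstrates the machinery is correct and well calibrated on clean
evidence; it does not predict real-data performance.

## Numerical and design choices

- Internal coordinates are 0-based half-open everywhere; the shift to
  1-based happens once, in the VCF writer, and `VCF POS` values written
  (`AT`, `WP`, `GL`, `LRT`) use a shortest-round-trip number format so
  `read_sv_vcf(write_sv_vcf(x))` is exact.
- Rounding to the 10 bp endpoint grid is half-up (`round_to()`);
  base R's half-to-even would split clusters unpredictably.
- Consensus ties, cluster ties and probability ties all break to the
  lexicographically/positionally smallest option: determinism over
  micro-optimality.
- The candidate loop is order-independent, so `threads` changes wall
  time, never output; candidate lists are stably sorted by
  (chromosome, position, side).
- Test problem sizes: unit tests run on hand-built read tibbles and a
  shared two-chromosome 300 kb / 50x dataset; the study-scale acceptance
  checks run one 20 Mb / 50x dataset (~10 M read records) shared across
  the sensitivity, FDR, breakpoint-accuracy and classifier checks.
- The each-breakpoint-is-a-record representation (with the partner in
  `BE`) follows the joint-calling design; a merged one-record-per-SV
  representation would be a plausible alternative and is deliberately
  not attempted.

## Known limitations

No gapped MSA of clip sequences; no local assembly; no multi-allelic or
population-prior genotyping; no CRAM or long-read support; complex
multi-breakpoint events are reported as their constituent simple
records; duplication genotypes are biased as described above; and
benchmark numbers from the hermetic simulator overstate real-data
performance for the reasons given. Population-genetic corrections
(stratification, kinship) are out of scope — export the genotypes to
dedicated association tooling if those matter.
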
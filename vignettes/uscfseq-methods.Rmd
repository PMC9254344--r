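---
title: "Models and methods behind uscfseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uscfseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uscfseq` simulates the two-population plasma cfDNA fragmentome — ultrashort
single-stranded cfDNA (uscfDNA) and mononucleosomal double-stranded cfDNA
(mncfDNA) — together with the laboratory operations used to tell the
populations apart, and implements the fragmentomics statistics used to
characterize them. This vignette records the models, the parameter choices
and their rationale, and the numerical decisions, so that a user knows
exactly what a passing test suite does and does not demonstrate.

## The generative model

A fragment is a molecule with a genomic interval (0-based, half-open), a
strand, a strandedness state (`ss`, `ds_intact`, `ds_nicked`), an 8-mer UMI,
and a population label. The simulator draws, per fragment:

1. **Population.** `uscf` with probability `frac_uscf` (default 0.5), else
   `mncf`. The true in-plasma abundance ratio of the two populations is not
   established — library counts confound abundance with extraction and
   ligation efficiency — so the mixture fraction is a first-class parameter
   and every downstream statistic is tested at several values of it.
2. **Length.** uscf lengths are drawn on 25–100 nt with mode exactly 50 nt;
   mncf lengths on 101–250 bp with mode exactly 160 bp. Both laws are
   discretized two-sided exponential (Laplace-type) peaks; the uscf law is
   asymmetric (left scale 6, right scale 13 nt) so mass rises gently toward
   100 nt, the mncf law symmetric with scale 6 bp.
3. **Nicked molecules.** With probability `nick_fraction` (default 0.25) an
   mncf molecule is a nicked duplex. Its *observed* length — what a
   single-stranded library reports after heat denaturation — is drawn from
   the 10 bp ladder {150, 140, 130, 120, 110} with mild geometric decay
   (ratio 0.85) and ±1 bp jitter; its full duplex length is drawn from the
   intact law truncated above the piece and stored alongside
   (`duplex_length`), because the double-stranded identity of the molecule
   matters to nick repair and to ds-library chemistry.
4. **Placement.** A functional class is chosen with probability
   proportional to (genomic baseline bp share) × (per-class enrichment
   multiplier), for uscf further modulated by piecewise-linear
   length-conditioned curves (knots 25/45/55/100 nt; promoter multiplier
   peaking at 45–55 nt, intergenic rising toward 100 nt). A position is then
   drawn uniformly within that class and the fragment placed so its midpoint
   lands on it. With all multipliers equal to 1, placement is uniform per
   bp over the genome — the null used by several tests.

### Why exponential peaks rather than Gaussians

The headline observables are *discrete sample modes* (50, 160, and 150 bp
after S1). A wide Gaussian peak (e.g. sd 15 bp) has an almost flat discrete
top: adjacent lengths differ by under half a percent in probability, so at
realistic fragment counts the sample argmax wanders several bp around the
nominal mode, and any ladder weight at 150 bp overtakes the 160 bp bin
outright. The two-sided exponential concentrates enough probability at the
modal length (each step away loses a factor `exp(-1/scale)` ≈ 15% at scale
6) that the sample mode is stable at the simulation sizes used here, while
the tails still look cfDNA-like. This is a deliberate sharpening of the
peak shape, traded for mode stability; the scale parameters are exposed.

### Mitochondrial fraction

The default genome is two 10 Mb autosome-like contigs plus a 16,569 bp
mitochondrial contig with no gene models. Under uniform placement the
expected chrM fragment share is its bp share, 16,569/20,016,569 ≈ 8.28e-4,
i.e. below 0.1%; `mito_weight` can scale this. Tests check the observed
fraction against a binomial interval around that expectation.

## Treatment operators

Susceptibility is by state: dsDNase removes duplexes, S1/P1/Exo I remove
single strands, DNase I removes everything, RNase removes nothing (all
simulated molecules are DNA). Each susceptible molecule is acted on
independently with probability `efficiency` (default 0.95; digestion is
efficient but not perfect in practice, and nothing downstream is sensitive
to the exact value).

Two operators need molecule-level mechanics that no published description
pins down; the package's choices are:

* **S1 jagged-end trim.** Surviving duplexes lose a total of
  `s1_trim_total` (default 10) bp, split binomially between the two ends.
  The total is drawn as `10 + {-1, 0, +1}` with probabilities 0.1/0.8/0.1:
  a deliberately concentrated law. A spread-out law (e.g. Poisson with mean
  10, whose mode ties at 9 and 10) convolves the 160 bp peak into a plateau
  where the post-digestion mode is a coin flip between 149–151; the
  concentrated law reproduces a stable 160→150 bp downshift. Acted-on
  nicked duplexes are additionally cleaved at their nick offsets and the
  pieces re-enter the set as intact duplexes, which destroys the ladder.
* **Nick repair.** Repaired molecules are restored to their stored full
  duplex length, with nicks cleared. This makes the operator's observable
  consequence — the ladder modes vanish from the subsequent histogram, so
  the periodicity contrast drops — testable at the fragment-table level.

Library preparation: the ds kit admits duplexes only (nicked ones at full
duplex length; physically nicked duplexes are ligatable, so this is the
default, but `include_nicked_in_ds = FALSE` models a strict-intact
chemistry). The ss kit with heat denaturation admits everything, each
original molecule counted once (a simplification of strand stoichiometry
that keeps molecule counts conserved); without heat, duplexes leak in with
probability 0.05. Every accepted molecule gets
`library_size = insert + 150` bp of adapters.

Electropherogram synthesis places a Gaussian kernel (sd 5 bp, matching
typical band widths at this scale) at each molecule's library size on a
1 bp axis from 35 to 1000 bp. Quantification integrates the 180–250 bp
band against the 251–350 bp band (trapezoidal rule); the alternative
250–350 bp region definition is selectable.

## Analysis statistics

* **Size classes.** uscf = length in [25, 100], mncf = [101, 250],
  everything else excluded. Boundaries are tested exhaustively.
* **Deduplication.** Exact-match on `(contig, start, end, strand, UMI)`,
  first occurrence kept. With 4^8 ≈ 65,536 UMIs, two molecules sharing
  exact coordinates collide with probability 1/65,536 per pair — negligible
  at desk scale and intentionally simple (no error-tolerant clustering).
* **Modal length.** Histogram argmax, ties broken toward the smaller
  length (a fixed, documented convention; ties are otherwise unstable).
* **Periodicity.** On the 100–160 bp window the counts are detrended by a
  centered running *median* (half-width 10 bp) and the dominant period is
  the argmax over candidate lags 2–20 of the autocorrelation of the
  residual, using the biased fixed-n normalization (as `stats::acf` does).
  Both choices are load-bearing. A running mean leaves a curvature residual
  on the convex exponential flank of the 160 bp peak, which scores as
  spurious short-lag autocorrelation — strongly enough that a spike-free
  (nick-repaired) histogram can out-score the untreated one; the running
  median tracks a smooth monotone flank exactly while ignoring the spikes.
  And normalizing each lag by its own overlap count ranks lag 20 above lag
  10 on sparse spike trains (fewer but identical aligned products over a
  shorter overlap), so a 10 bp comb would be reported as period 20; the
  fixed-n normalization restores the correct ranking, with ties broken
  toward the smaller period.
* **Fragment-to-locus assignment.** Everywhere (element classes, coverage
  bins) a fragment is assigned by the single bp at `floor((start+end)/2)`.
  Fragments are annotated directly rather than via peak calling: simulated
  desk-scale fragment sets are far too sparse for peak calling to be
  meaningful, and direct midpoint annotation makes the statistics exact
  functions of the fragment table.
* **Element profiles.** Class proportions and their ratios to the exact bp
  baseline; per 10 bp size bin over [25, 100] with half-open bins except
  the last (closed at 100). Empty bins are undefined (`NA`), not zero.
* **Binned coverage and correlation.** 100 bp bins tile each contig
  independently (final partial bin kept); Pearson correlation on raw bin
  counts (no transformation — a documented simple choice); zero-variance
  vectors are an error naming the offending sample.

## Annotation fixture

Gene models (default 400 genes, 3–8 exons of 150–400 bp, introns of
500–3000 bp) are placed without overlap on the non-mitochondrial contigs,
with enough clearance that the flank windows of neighbouring genes never
touch. Promoter = `[TSS − 1000, TSS + 100)` on the gene strand and TTS =
`[TES − 100, TES + 1000)` by symmetry — the conventional peak-annotation
defaults, exposed as parameters. Precedence resolution (promoter > TTS >
exon > intron > intergenic) assigns every bp exactly one class; the
resulting default baseline is intergenic-dominated (roughly three quarters
of bp), as intended for a genome profile where intergenic dominates.
Intergenic is always the computed complement, never stored. An exhaustive
per-bp brute-force oracle verifies the resolution on ≤ 100 kb genomes.

## What the simulator does not model

Sequence content beyond uniform-random bases, sequencing errors, PCR
amplification bias, adapter-dimer artifacts (beyond excluding the regime
in insert-size conversion), GC effects, enzyme kinetics, real genome
builds and real annotations. Passing tests therefore demonstrate the
internal consistency of the pipeline and the detectability of the designed
signals at desk scale — not performance on real sequencing data.

## Problem sizes and reproducibility

Default analyses simulate 50,000 fragments (100,000 for the
uniform-placement chromosome profile), sizes at which the designed modes
and the ladder period are detected with comfortable margins while the full
test suite runs in about a minute. Every stochastic operation takes an
explicit integer seed and is byte-reproducible; pipeline stages write
manifests with output checksums so a replay with the same configuration
and seed is verifiable end to end.
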
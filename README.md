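# uscfseq

Simulation and fragmentomic analysis of ultrashort single-stranded
cell-free DNA (cfDNA).

## The problem

Liquid-biopsy sequencing conventionally measures mononucleosomal cfDNA
(mncfDNA): double-stranded, ~160 bp fragments protected by nucleosomes.
Extraction chemistry that retains low-molecular-weight DNA, combined with
single-stranded library preparation, reveals a second population —
ultrashort cfDNA (uscfDNA): 25–100 nt, predominantly single-stranded, with
a modal length of 50 nt, distributed genome-wide but enriched over
promoters, exons and introns. Strandedness of the two populations is
inferred operationally, by differential nuclease digestion (single-strand
specific S1/P1/Exo I vs double-strand specific dsDNase vs strand-agnostic
DNase I), by ss- vs ds-library chemistry, and by skipping the heat
denaturation step of the ss protocol.

`uscfseq` re-creates that entire experimental matrix in silico, for method
development and for testing fragmentomics statistics against a ground truth:

* **fixtures** — a deterministic synthetic genome (two 10 Mb autosome-like
  contigs + a 16,569 bp mitochondrial contig) and a functional-element
  annotation resolved by precedence `promoter > TTS > exon > intron >
  intergenic`, with the exact bp baseline; the published lambda spike-in /
  control oligo catalog.
* **simulate** — the bimodal fragmentome. Fragment lengths follow
  discretized two-sided exponential peaks: uscf mode 50 nt on [25, 100]
  (asymmetric scales 6/13), mncf mode 160 bp on [101, 250] (scale 6). A
  fraction (default 0.25) of mncf molecules are nicked duplexes observed at
  10 bp-ladder lengths {150, 140, 130, 120, 110} ± 1, producing the 10 bp
  periodicity of the left shoulder. Placement targets fragment midpoints
  with per-class enrichment multipliers of the baseline (size-conditioned
  for uscf). Length-dependent extraction retention is a logistic curve per
  method (QiaC / QiaM / SPRI), measurable with lambda ladder spike-ins.
* **treatments** — digestion operators (dsDNase, S1 with jagged-end
  trimming and nick cleavage, P1, Exo I, DNase I, nick repair, RNase no-op),
  ss/ds library preparation with optional heat denaturation, and
  electropherogram trace synthesis (library size = insert + 150 bp of
  adapters).
* **analysis** — size classification (uscf 25–100, mncf 101–250, the rest
  excluded), exact-match UMI deduplication, 1 bp length histograms and
  modal lengths, a 10 bp-periodicity estimator (running-median detrend +
  autocorrelation over candidate periods 2–20 on the 100–160 bp shoulder),
  chromosome distributions, 100 bp binned coverage with Pearson correlation
  matrices, functional-element profiles normalized to the genomic baseline
  (overall and per 10 bp size bin), and %uscfDNA quantification of
  electropherogram traces (area 180–250 bp over areas 180–250 + 251–350 bp).

## Worked example

```r
library(uscfseq)

gm  <- genome_model()                       # chrA + chrB (10 Mb) + chrM
ann <- annotate_elements(gm, seed = 1)
fr  <- simulate_population(gm, ann, population_config(), seed = 42)

parts <- size_filter_classify(deduplicate(fr))
modal_length(length_histogram(parts$uscf))
#> [1] 50
modal_length(length_histogram(parts$mncf))
#> [1] 160
periodicity(length_histogram(parts$mncf))
#> Dominant period: 10 bp (contrast 0.761)

# S1 removes the single strands, trims duplex ends ~10 bp and destroys
# the nicked ladder:
s1 <- digest(fr, treatment_spec("S1"), seed = 7, genome = gm)
modal_length(length_histogram(size_filter_classify(s1)$mncf))
#> [1] 150

chrom_distribution(fr, gm)
#>   contig count fraction     per_mb
#> 1   chrA 24958  0.49916 0.04991600
#> 2   chrB 25005  0.50010 0.05001000
#> 3   chrM    37  0.00074 0.04466172
```

The modal lengths are the two populations' signature sizes; the dominant
period of 10 bp on the 100–160 bp shoulder is the nicked-molecule ladder;
the mitochondrial fraction stays below 0.1% because chrM is sampled in
proportion to its share of genome bp. An end-to-end replay
(`run_make_fixtures`, `run_simulate`, `run_treat`, `run_analyze`) and a
thin CLI (`exec/uscfseq`, one subcommand per stage) drive the same
functions from configuration files.

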
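# TFdirect

Infers a transcription factor's **direct target (DT) genes** by
intersecting ChIP-Seq binding with tissue-contrast coexpression, and
dissects the cis-regulatory grammar of the resulting binding sites.
Built for regulatory genomicists working on seed-development TF networks
(WRI1/LEC1-style factors), but the machinery is organism-agnostic: it
takes a genome FASTA, a GFF3 annotation, replicate narrowPeak files and a
count matrix.

## The model

A gene *g* is **bound** when a reproducible peak summit *s* satisfies, in
strand-aware coordinates,

```
TSS(g) − 1000  ≤  s  ≤  TTS(g)
```

(reproducible = replicate-A peak overlapping replicate B by ≥ 1 bp).
A gene is **coexpressed** with the factor when, in at least 2 of the 4
embryo-vs-seed-coat contrasts,

```
log2FC ≥ 1   and   FDR < 0.01
```

with fold changes and p-values from TMM-normalized counts and a
conditional negative-binomial exact test (common method-of-moments
dispersion; the conditional law of one group's sum given the total is
free of the mean when dispersions are shared). Then

```
DT = bound ∩ coexpressed
```

with the overlap's significance from the log-space hypergeometric upper
tail P(X ≥ k), X ~ Hypergeom(N, K, n), over an explicit gene universe.

Binding-site grammar: 100 bp summit-centered windows (50 bp for the
two-factor comparison) are scanned double-stranded for degenerate IUPAC
elements — AW Box `CNTNGNNNNNNNCG`, CNC Box `CNCCNCC`, G Box, RY, CCAAT
Box — and tested against (i) random regions matched in width and signed
TSS offset (one-sided Fisher, Bonferroni over the panel, α = 0.01) and
(ii) 1,000 random gene sets of matched size (empirical p =
(1 + #{bg ≥ obs}) / 1001 on 500 bp TSS windows). Peak and motif positional
profiles, genomic-feature composition (5′ UTR > exon > intron > 3′ UTR >
2 kb upstream > 1 kb downstream > intergenic, by summit), ChIP library QC
(NRF, strand cross-correlation) and nearest-summit distances between two
factors complete the pipeline.

A synthetic-study generator (`simulateDataset()`) plants all of this with
known ground truth — downstream-biased peaks, motif instances in a
controlled fraction of sites, NB counts with planted tissue effects, a
second factor at median-142 bp offsets — so every stage is testable
without any external data.

## Worked example

```r
library(TFdirect)

cfg <- simulationConfig(seed = 1, n_genes = 300, n_peaks = 200,
                        n_chroms = 2, chrom_length = 1000000L,
                        replicate_noise = 0, planted_fold_change = 8)
d <- simulateDataset(cfg, dir = "demo")

pc <- pipelineConfig(
  genome = "demo/genome.fa", annotation = "demo/annotation.gff3",
  peaks_rep_a = "demo/tf_a_rep1.narrowPeak",
  peaks_rep_b = "demo/tf_a_rep2.narrowPeak",
  counts = "demo/counts.tsv", groups = "demo/groups.tsv",
  tf_b = "demo/tf_b.narrowPeak", seed = 1)
report <- runFullPipeline(pc, quiet = TRUE)
report
#> RunReport
#>   peaks_rep_a            200
#>   peaks_rep_b            200
#>   reproducible_peaks     200
#>   bound_genes            200
#>   coexpressed_genes      60
#>   dt_genes               36

setequal(report@sets$dt, dtGenes(readTruthJSON("demo/truth.json")))
#> [1] TRUE

report@tables$motif_enrichment[, c(1, 6, 7, 9, 10)]
#>       motif observed_fraction background_fraction adjusted_pvalue significant
#> 1    AW-Box            0.5833              0.1111        0.000117        TRUE
#> 2   CNC-Box            0.0000              0.0278        1.000000       FALSE
#> 3     G-Box            0.0278              0.0000        1.000000       FALSE
#> 4        RY            0.0833              0.0278        1.000000       FALSE
#> 5 CCAAT-Box            0.1667              0.1667        1.000000       FALSE
```

Reading: 200 raw peaks are all replicate-reproducible (no noise was
simulated), they bind 200 genes, 60 genes pass the coexpression rule, and
the 36 genes in the intersection are exactly the planted direct targets.
Their binding sites carry the AW Box in 58% of cases versus 11% in
width- and offset-matched random regions — Bonferroni-significant — while
the unplanted panel motifs are flat. `writeRunReport(report, "demo/out")`
emits `report.json`, per-stage TSVs and the gene sets.

A thin CLI mirrors this (`inst/scripts/tfdirect.R` with `simulate` and
`run --config run.yaml` subcommands); the functions above are the primary
interface.

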
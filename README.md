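# broadH3K4

Broad H3K4me3 domain classification and integrative ChIP/RNA analysis.

## What this is for

H3K4me3 usually forms a narrow peak at active promoters, but on
cell-identity genes it can spread into *broad domains* of tens of
kilobases, and the breadth of that domain tracks how strongly the gene
is transcribed. In cardiomyocytes, conditions that activate the
α-ketoglutarate–dependent KDM5 demethylases erode exactly these broad
domains and repress the maturation genes underneath them. `broadH3K4`
is for epigenomics analysts who want to run that style of analysis —
peak breadth per gene, quartile classification, metagene coverage
profiles, differential ChIP/RNA testing, and the integration of the
two — as one reproducible, fully tested R pipeline.

The core quantities:

- **Breadth** of gene *g*: total merged span (bp) of the H3K4me3 peaks
  assigned to *g* (assignment window `[TSS − 2 kb, TES]`, largest
  overlap wins).
- **Groups**: rank genes by breadth; *broad* = top `floor(0.25 N)`,
  *narrow* = bottom `floor(0.25 N)`, *medium* = the rest.
- **Metagene profile**: mean RPM in 50 bp flank bins (±2 kb) and 100
  length-scaled body bins from TSS to TES, strand-oriented, averaged
  per group.
- **Differential test**: median-of-ratios size factors
  `s_j = median_g (K_gj / (∏_j K_gj)^(1/m))`, then a two-sided Welch
  test on `log2(K̃ + 1)` per feature with
  `log2FC = log2((μ̃_mut + 0.5)/(μ̃_ctl + 0.5))`, called at P < 0.05.
- **Integration**: Venn overlap of "reduced H3K4me3" and "reduced
  expression" gene sets, reported as a percentage of the reduced-ChIP
  set plus the broad/medium/narrow composition of the overlap.

A seeded synthetic-data generator (toy genome, log-normal domain
breadths with a >40 kb tail on identity genes, Poisson coverage,
negative-binomial counts coupled to breadth, planted mutant effects)
makes the whole chain testable with known ground truth — no external
data needed.

## Worked example

```r
library(broadH3K4)

cfg   <- SynthConfig(seed = 7, nGenes = 120L)
genes <- simulateGenome(cfg)
sim   <- simulatePeaks(genes, cfg)                   # control + mutant + truth
asn   <- assignPeaksToGenes(sim$control, genes)
bt    <- classifyBreadth(geneBreadth(asn))
bt
#> BreadthTable | 120 genes | broad 30 medium 60 narrow 30
#>   gene_id breadth rank group
#> 1   g0026   63253    1 broad
#> 2   g0065   59267    2 broad
#> 3   g0074   50583    3 broad
#> 4   g0096   49547    4 broad
#> 5   g0012   36572    5 broad

mp <- groupMetaprofile(genes, bt, rpmScale(simulateCoverage(sim$control, cfg)))
mp
#> Metaprofile | 3 group(s) x 180 bins ( 40 up / 100 body / 40 down )
#>    broad : n = 30 , mean RPM = 28.69
#>    medium : n = 60 , mean RPM = 3.839
#>    narrow : n = 30 , mean RPM = 2.128

de  <- deTest(simulateCounts(sim$truth, cfg))        # gene expression
pc  <- simulatePeakCounts(sim$truth, cfg)            # per-domain ChIP signal
dir <- peakSignalChange(pc, setNames(as.list(paste0(sim$truth$gene_id,
                        "_domain")), sim$truth$gene_id))
overlapSummary(dir$gene_id[dir$direction == "reduced"],
               de$feature_id[de$call == "down"], bt)
#> IntegrationSummary | reduced H3K4me3: 12 | reduced expression: 10 | overlap: 8 (66.7% of reduced H3K4me3)
#>    broad       6  (75.00%)
#>    medium      2  (25.00%)
#>    narrow      0  (0.00%)
```

The breadth table ranks every peak-bearing gene and splits 120 genes
30/60/30; the metaprofile shows the broad group carrying an order of
magnitude more body signal than the narrow group; and the integration
summary intersects the genes that lost ChIP signal with those that lost
expression — here 8 genes, dominated by the broad group, as planted by
the simulator.

One call runs everything and writes per-stage TSVs plus a checksummed
manifest:

```r
runPipeline(list(seed = 7, synthetic = list(nGenes = 120L)), outdir = "run1")
```

(or `Rscript inst/scripts/run-pipeline.R --config cfg.yaml --outdir run1`).

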
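# homeoscan

Homeolog expression partitioning and responsive-gene hotspot detection
in allopolyploid transcriptomes.

## What it is for

Allohexaploid bread wheat carries three subgenomes (A, B, D); most genes
exist as a **triplet** of near-identical homeologs, one per subgenome.
Under stress (the motivating design is a salt-stress time-course at
6/12/24/48 h in a tolerant and a sensitive cultivar, one RNA-seq library
per condition), the three copies often respond unequally. `homeoscan` is
for researchers who want to quantify that partitioning from short-read
RNA-seq:

* **Triplet identification** — cross-subgenome global alignment with
  identity ≥ 0.90 and coverage ≥ 0.75 gates; only clusters with exactly
  one gene per subgenome are kept; diagnostic SNP sites extracted per
  triplet.
* **SNP-based read quantification** — reads are seeded by exact 31-mers,
  placed end-to-end, and classed by mismatch counts into the seven
  homeolog compatibility classes (`A`, `B`, `D`, `AB`, `AD`, `BD`,
  `ABD`) under a two-mismatch mapping gate; shared classes are divided
  **proportionally to the subgenome-specific counts**
  (`n_AB` splits A : B as `n_A : n_B`), conserving totals exactly.
* **Response statistics** — unreplicated differential expression by the
  two-sided Fisher exact test with Benjamini–Hochberg FDR per contrast
  (call: fold ≥ 2 and q < 0.01); homeolog bias by a chi-square
  goodness-of-fit test against 1A:1B:1D
  (`X² = Σ (O − E)² / E`, `E = total/3`, df = 2) gated by
  Exp<sub>max</sub>/Exp<sub>min</sub> ≥ 1.5; partitioned-response
  summaries; one-sided Fisher-exact term enrichment (p ≤ 0.01).
* **Hotspot scan** — sliding window of 10 genes with 5-gene step along
  ordered gene maps; hotspots are maximal runs of ≥ 3 consecutive
  responsive genes, annotated as tandem arrays when ≥ 2 members share a
  gene family.
* **Ground-truth simulator** — substitution-only homeologous triplets at
  a calibrated divergence, Dirichlet homeolog proportions, per-homeolog
  stress fold-changes, uniform-error 125-bp reads, and chromosome
  layouts with planted hotspots, so every stage is testable without
  external data.

## Worked example

```r
library(homeoscan)

cfg <- pipeline_config(
  n_triplets = 10, gene_length = 600, divergence = 0.02,
  design = sim_design(depth = 1200, read_length = 125),
  hotspot_spec = data.frame(chrom = 1, start = 25, length = 5,
                            family = "HSP20-like"),
  background_responsive_rate = 0.02, seed = 42)
res <- run_pipeline(cfg, "demo_run")

head(subset(res$counts, library == "tolerant_control_06h",
     select = c(triplet_id, n_A, n_B, n_D, n_ABD, c_A, c_B, c_D)), 4)
#>   triplet_id n_A n_B n_D n_ABD    c_A   c_B   c_D
#> 1   TRP00001  89  67  26     0 92.096 69.16 27.74
#> 2   TRP00002  14  57  15     0 15.645 57.80 16.55
#> 3   TRP00003   1   2   0     0  1.000  2.00  0.00
#> 4   TRP00004   4  24  14     0  4.429 26.57 14.00
```

`n_A/n_B/n_D` are subgenome-specific read counts for each triplet in
that library; `n_ABD` (and `n_AB`, `n_AD`, `n_BD`, not shown) are reads
compatible with several homeologs; `c_*` are the allocated counts after
proportional division — each row sums to the number of classified reads.

```r
res$partition$totals
#>    genotype n_triplets n_responsive n_unequal pct_responsive pct_unequal
#> 1  tolerant         10            5         5             50          50
#> 2 sensitive         10            5         5             50          50

head(summarize_bias(res$bias), 2)
#>                library n_tested n_biased pct_biased
#> 1 tolerant_control_06h       10        8         80
#> 2 tolerant_control_12h       10        8         80

res$hotspots[, c("chrom", "start", "end", "n_genes", "tandem",
                 "dominant_family")]
#>   chrom start end n_genes tandem dominant_family
#> 1  chr1    25  30       5   TRUE      HSP20-like
```

Half the simulated triplets had at least one differentially expressed
homeolog in some stress condition (`n_responsive`), and in every such
triplet the three homeologs' calls disagreed somewhere (`n_unequal`) —
the partitioned-response signature. Eight of ten triplets exceed both
bias gates (chi-square p < 0.01 and ratio ≥ 1.5) in the control
libraries, reflecting the simulated Dirichlet proportion spread. The
planted run of five HSP20-like genes is recovered as a single tandem
hotspot with exact boundaries.

A thin command-line wrapper over the same function is installed at
`inst/scripts/homeoscan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "homeoscan.R", package = "homeoscan"))')" \
  all --out demo_run --seed 42
```

## Learn more

The methods vignette (`vignettes/homeolog-partitioning.Rmd`) documents
the model and every numerical choice: the alignment gates, the read
classing rule, the proportional-allocation fallbacks, the statistics and
their thresholds, what the simulator does and does not emulate, and
known limitations.
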
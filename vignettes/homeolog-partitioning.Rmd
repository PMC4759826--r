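---
title: "Homeolog expression partitioning and hotspot detection with homeoscan"
author: "homeoscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeolog expression partitioning and hotspot detection with homeoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Allohexaploid bread wheat carries three ancestral subgenomes (A, B and
D), so most genes exist as a *triplet* of homeologs — three near-identical
copies (typically 95–99% coding-sequence identity), one per subgenome.
Under stress, the three copies of a triplet often respond differently:
one homeolog may be induced while its partners stay flat or are
repressed. This *expression partitioning* is thought to underpin part of
the adaptability of polyploids, and measuring it requires (i) knowing
which three genes form a triplet, (ii) assigning short RNA-seq reads to
the correct subgenome using the few diagnostic SNPs that distinguish the
copies, and (iii) statistics that work on an unreplicated time-course
design.

`homeoscan` implements that analysis chain as reusable, tested
components, together with a ground-truth simulator so that every stage
can be validated end to end without external data. The emulated design
is two cultivars (salt-tolerant and salt-sensitive) sampled under
control and salt-stress conditions at 6, 12, 24 and 48 h — sixteen
libraries, one per condition, with no sequenced replicates.

## Triplet identification

`build_triplets()` scores cross-subgenome gene pairs by global alignment
(match +1, mismatch −1, gap open −5, gap extend −2, via
`Biostrings::pairwiseAlignment`) and applies two gates:

* **identity** = matches / aligned (non-gap) columns ≥ 0.90,
* **coverage** = aligned columns / length of the shorter sequence ≥ 0.75.

The coverage denominator is the shorter sequence length: the gate is
meant to reject partial-domain matches, and the shorter-length
denominator is the strictest choice that still scores a full-length
match of unequal-length genes as 1. Pairs are pre-screened by shared
16-mers; since a true homeolog pair at ≤10% divergence retains on the
order of `0.9^16 ≈ 19%` of its 16-mers (hundreds per kilobase), the
prescreen only removes pairs that could never pass the identity gate.

Genes are then single-linkage clustered over passing hits, and a cluster
is kept as a triplet only when it contains **exactly one gene per
subgenome** and all three pairwise hits pass. Clusters with paralogs (two
candidates from one subgenome) are dropped whole rather than arbitrated:
an incorrectly resolved paralog would contaminate every downstream
homeolog ratio, whereas a dropped cluster only costs coverage. Under
connected-component clustering a gene belongs to exactly one cluster, so
no cross-cluster conflict resolution is needed. When gene positions are
supplied, pairs whose chromosome names parse to different homeologous
group numbers (e.g. `2A` vs `5B`) are discarded before clustering;
without positions the check is skipped with a warning.

`call_diagnostic_sites()` reports every alignment column at which the
three homeolog alleles are not all identical, with its discrimination
class (`A|BD`, `B|AD`, `D|AB`, `all-distinct`). In substitution-only
synthetic data the three sequences share coordinates and the column
comparison is exact; for real (indel-containing) genes, B and D are
projected onto A's coordinates by global alignment and columns gapped in
any member are skipped.

## Read assignment and proportional allocation

Reads are matched to a candidate triplet by exact 31-mer seeding against
all homeolog sequences (up to four seeds per read, with a
reverse-complement fallback), then placed end-to-end and scored by
mismatch count against each homeolog at the best common placement.
Classing uses two rules:

1. **Mapping gate.** A homeolog is a candidate only if the read has at
   most `max_mismatches = 2` mismatches against it — the conventional
   short-read mapping tolerance, which absorbs sequencing errors.
2. **Diagnostic discrimination.** Among candidates, the read's
   *compatibility class* is the set of homeologs achieving the minimum
   mismatch count. A read overlapping one `A|BD` site with the A allele
   has mismatch vector (0, 1, 1) and is class `A`: the diagnostic
   alleles it carries, not the raw gate, decide the class. A read from a
   region with no diagnostic site is class `ABD`.

This yields the seven compatibility classes `A`, `B`, `D`, `AB`, `AD`,
`BD`, `ABD`, plus `UNASSIGNED` for reads failing the gate everywhere. A
read seeding equally well to two different triplets is counted for
neither (the count is reported as an attribute). An import path for
external aligners is provided by `quantify_sam()`, which reads all
reported alignments of each read, takes the `NM` tag as the mismatch
count, and applies the same rules.

`allocate_counts()` keeps subgenome-specific counts as they are and
divides each shared class among its member homeologs **in proportion to
those members' specific counts** — e.g. `n_AB` splits between A and B as
`n_A : n_B`. When the relevant specific counts are all zero the split is
equal: the proportional rule is undefined at 0/0, and the equal split is
the unique choice that is symmetric in the subgenome labels and
conserves totals. Allocation is a single pass (no EM iteration): one
proportional division is the defined procedure, and iterating would
change the estimand. Conservation is exact: allocated counts sum to the
classified read count per triplet and library.

## Response statistics

**Normalisation and fold change.** Counts are normalised as CPM (counts
per million mapped). Fold changes are computed on CPM with a pseudocount
of 0.5 CPM on both sides, which stabilises zeros without materially
moving well-measured genes. Fisher's exact test itself consumes raw
counts against library totals and is scale-free.

**Differential expression without replicates.** The design has one
library per (genotype, condition, timepoint), so dispersion cannot be
estimated; each stress library is contrasted against its matched control
with the two-sided Fisher exact test on the 2×2 table (feature count vs
remaining reads, per library). Benjamini–Hochberg adjustment is applied
within each contrast over the expressed features (raw count ≥ 1 in at
least one library). A feature is called `up` when fold ≥ 2 **and**
q < 0.01, `down` when fold ≤ 0.5 and q < 0.01 — both gates inclusive at
the fold boundary. Unreplicated count tests are sensitive to any real
proportion shift at high depth, which is why the two-fold gate is part
of the call, not a cosmetic filter.

**Homeolog bias.** For each triplet and library, allocated counts are
tested against the balanced 1A:1B:1D expectation by a chi-square
goodness-of-fit test with 2 degrees of freedom (`E = total/3`; the df=2
survival function is exactly `exp(−x/2)`, which the tests exploit as a
closed-form oracle). Allocated counts are fractional, so they are
rounded to the nearest integer first; because allocation conserves
totals, rounding changes each observed count by less than 1 and the
statistic by a negligible amount at the depths where the test has any
power. A triplet is *biased* when p < 0.01 **and** the
expression ratio gate Expmax/Expmin ≥ 1.5 holds; a zero minimum with a
positive maximum counts as an infinite ratio. The ratio gate can only
remove flags, never add them — on null data the gated rate is bounded by
the ungated rate.

**Partitioned response.** Per-homeolog DE calls are collapsed per
triplet: *responsive* = at least one homeolog up or down in at least one
stress condition; *unequal contribution* = responsive, and in at least
one condition the three homeolog calls are not all identical. Summary
tables report counts with percentages through a single reporting path
(`fraction_pct`, one decimal place).

**Enrichment.** Term enrichment of a study set against a population is
the one-sided hypergeometric tail; raw p-values are reported with the
p ≤ 0.01 flag and no multiple-testing correction, and term sets are flat
(no ontology propagation).

## Hotspot scan

Chromosome gene maps (map order, not base pairs) are scanned with a
window of 10 genes advanced 5 genes per step; each window reports the
percentage of responsive genes. A trailing window shorter than 10 genes
is dropped rather than padded, keeping percentages comparable across
windows. *Hotspots* are the maximal runs of at least 3 consecutive
responsive genes; "consecutive" means adjacent in the scanned map, and
unexpressed genes are removed from the map before scanning by default
(`drop_unexpressed = FALSE` restores strict adjacency), since a silent
gene inside a responsive array is not evidence against clustering — both
behaviours are exposed because the underlying biological convention is
genuinely ambiguous. A hotspot is a *tandem array* when at least two
members share a gene family; without family labels, families fall back
to single-linkage sequence clusters at ≥ 60% identity, a deliberately
permissive heuristic standing in for curated family annotation.

## The simulator and what it does (not) emulate

`simulate_triplets()` derives the three homeologs of each triplet from a
common ancestral sequence by independent per-base substitution, with the
per-homeolog rate calibrated so that the **expected pairwise difference
equals the requested divergence** (solving
`2m(1−m) + (2/3)m² = divergence` for `m`). Substitution-only evolution
keeps the three sequences on shared coordinates, so the planted SNP
columns are exactly the diagnostic sites and every downstream oracle is
exact. `simulate_expression()` draws per-triplet homeolog proportions
from a Dirichlet distribution, baseline abundances from a lognormal, and
per-homeolog stress fold-changes; `simulate_reads()` draws reads
proportional to abundance with uniform starts and uniform substitution
errors, writing one library per design cell with the sub-seed
`seed + library index` so adding libraries never perturbs existing ones.
`simulate_layout()` builds ordered chromosomes with planted responsive
runs; background responsive genes are re-rolled wherever they would
create or extend a run of ≥ 3, so the planted intervals are provably the
unique hotspot truth.

Defaults were fixed once as the study conditions: 125-bp single-end
reads, 20,000 reads per library in fixed-count mode (making conservation
tests exact; a Poisson mode exists), substitution error rate 0.001,
Dirichlet α = (2, 2, 2) homeolog proportions (a broad bias spectrum, of
which roughly two-thirds of triplets exceed the bias gates at moderate
depth), responsive fraction 0.25 per homeolog with folds log-uniform in
2–8 and 40% down-regulated, and lognormal baseline abundance
(meanlog = log 100, sdlog = 1). The simulator does **not** model
fragment-size or GC bias, positional bias, quality-dependent errors,
indels, intergenic sequence, or isoforms — so passing tests demonstrate
correctness of the assignment/allocation/statistics chain under the
stated error model, not robustness to every artefact of real libraries.

## Numerical and validation choices

* **Recovery is measured against realized read origins.** The
  quantification-recovery experiment (200 triplets, 2% divergence,
  0.1% error, 20,000 reads per library across the 16-library design)
  compares pooled allocated proportions with the per-read origin
  fractions the simulator actually drew, not with the latent Dirichlet
  proportions: at ~1,600 pooled reads per triplet, multinomial sampling
  noise alone puts the latent proportions out of reach of any estimator,
  while origin fractions isolate the error the quantifier is responsible
  for. For the same reason the experiment holds baseline abundance equal
  across triplets — `depth` is the coverage parameter of that
  experiment; with the default lognormal abundance spread the
  low-coverage tail sits below the ±0.02 resolution floor set by reads
  that overlap no diagnostic site (about 8% of reads per homeolog pair
  at 2% divergence and 125 bp).
* **Problem sizes.** Validation experiments use 200–6,000 simulated
  features and 2,000–12,000 enumerated tables; these sizes give the
  calibration checks standard errors several-fold below the bands they
  must hit while keeping the full suite fast.
* **Ties and degenerate inputs.** Zero-total triplets are "not
  testable" (NA, excluded from bias denominators); all-zero expression
  gives an NA bias flag; equal-split fallback at 0/0 allocation;
  reads tied between triplets are dropped and counted; empty layouts,
  empty libraries and empty hotspot lists propagate as empty results,
  not errors.
* **Determinism.** Every stochastic function takes an explicit seed;
  identical seeds give byte-identical outputs, which the pipeline
  manifest (md5 per output file) makes checkable.

## Known limitations

* The triplet finder is specialised to near-identical homeologs: it is
  not a general homology search, and at divergences far beyond 10% the
  16-mer prescreen and the identity gate both fail by design.
* Fisher-exact DE without replicates cannot separate biological
  variability from treatment effect; calls should be read as "large,
  well-supported proportion shifts", not population-level inference.
* The read classifier assumes substitution-only differences between
  homeologs within a read's span; genes with indel polymorphism between
  homeologs need the SAM import path with an external gapped aligner.
* Allocated proportions inherit an irreducible noise floor from reads
  that overlap no diagnostic site; at low per-triplet coverage this
  floor, not the allocator, limits accuracy.
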
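# p53targets

Identify **direct transcriptional targets of chronically activated p53** by
integrating two independent lines of genomic evidence: p53 ChIP-seq
enrichment near transcription start sites, and differential expression
under p53 knockdown (sh-p53 versus vector control). The package is aimed
at analysts working with replicated ChIP-seq peak calls, TSS-bin read
counts and Illumina-array-style log2 expression matrices across the
classic p53 phenotypes — growing cells, acute DNA damage (acDDR),
RAS-induced senescence (RIS) and E1A/RAS pro-apoptotic (pApo) conditions.

## What it computes

**Consensus peaks.** Per condition, replicate peak calls are clustered by
overlap; clusters supported by ≥ 2 distinct replicates enter the
high-confidence (HC) set, and singleton clusters are rescued when they
overlap peaks in ≥ 2 other conditions, or peaks from ≥ 2 replicates of one
other condition. Surviving spans are merged, with per-peak provenance and
an audit table. Peaks are then classified by genomic feature (core
promoter −3000..+2000 bp around the TSS, downstream extremity, exon,
intron, distal to −50 kb, intergenic beyond) and partitioned by
CpG-island overlap.

**The joint target posterior.** For each gene *g*,

- Pr(DE | data): an empirical-Bayes moderated-*t* analysis of the
  sh-p53 − vector contrast. Variances shrink as
  s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d) with (d₀, s₀²) estimated by log-scale
  moment matching; a two-component model on the moderated *t* converts the
  statistic into a posterior probability of differential expression.
- Pr(C | data): counts in one strand-aware window per gene
  (TSS − 50 bp to TSS + 1500 bp) are compared between ChIP and input with
  two negative-binomial models — shared rate versus chip rate > input
  rate — marginalized over an empirical rate grid, with the model prior π
  estimated from the data (or fixed, e.g. π = 0.5).
- The joint posterior p = Pr(DE|data)·Pr(C|data) is logit-transformed to a
  **B value**, B = ln(p/(1−p)); genes with **B > −1.5** are called
  putative direct targets, ranked by B. Negative log2 fold change (down
  under knockdown) marks p53-induced genes, positive marks repressed.

**Motifs.** A PWM scanner for the p53 response element — two decameric
half-sites (RRRCWWGYYY) with a 0–13 bp spacer — with MATCH-style matrix
and core similarity scores (0.8 cutoffs), positional histograms in 50 bp
bins around the TSS, and a foreground/background promoter enrichment
z-test.

**Synthetic studies.** `sim_config()` / `simulate_dataset()` generate a
toy genome with CGI and non-CGI promoters, condition-structured peak
calls (Grow 2 replicates; acDDR/RIS/pApo 3 each), NB ChIP/input bin
counts with reads that recount exactly, 3 vs 3 expression arms, and a
planted truth table (bound, responsive, and their intersection — the
direct targets, drawn 3:1 from CGI promoters), so the whole pipeline is
benchmarkable end to end.

## Worked example

```r
library(p53targets)

ds  <- simulate_dataset(sim_config(seed = 20150319))  # default study design
set.seed(20150319)
res <- run_pipeline(ds, condition = "RIS")
head(res$targets)
#>    gene log2fc pDE pC p_joint     B pass direction
#> 1 G1201   1.63   1  1       1 10.19 TRUE repressed
#> 2 G0283  -1.41   1  1       1  8.82 TRUE   induced
#> 3 G1074   1.47   1  1       1  8.81 TRUE repressed
#> 4 G0066  -1.41   1  1       1  8.56 TRUE   induced
#> 5 G0008   1.39   1  1       1  8.14 TRUE repressed
#> 6 G1196   1.42   1  1       1  8.11 TRUE repressed
```

Each row is one gene: its knockdown log2 fold change, the two posterior
arms (`pDE`, `pC`), their product `p_joint`, the B value, whether it
clears the −1.5 threshold, and the direction of p53 regulation implied by
the sign of the fold change. On this simulated study the pass set holds
136 genes; compared with the planted truth that is precision 1.0 and
recall 0.907 of the 150 true targets. The HC peak set of the RIS
condition is entirely promoter-proximal by construction of the simulation
and 63.8% CGI-associated — above the genome-wide 50% CGI promoter rate,
reflecting the planted CGI preference of chronic p53 binding:

```r
res$annotation$summary$cgi_fraction
#> [1] 0.638
```

See the vignette (`vignettes/p53-target-calling.Rmd`) for the model
details, parameter meanings and design rationale.

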
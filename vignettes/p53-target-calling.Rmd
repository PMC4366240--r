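---
title: "Calling direct p53 targets from ChIP-seq and knockdown expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling direct p53 targets from ChIP-seq and knockdown expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53targets)
```

# The problem

Chronically active p53 — as in oncogene-induced senescence (RIS) or
E1A/RAS-driven pro-apoptotic cells (pApo) — binds chromatin persistently and
preferentially at CpG-island (CGI) promoters, a profile quite different
from the acute DNA-damage response (acDDR). A gene is a *direct* target when
two independent lines of evidence coincide: p53 occupies its promoter
(ChIP-seq enrichment near the TSS) and its expression responds to p53
depletion (sh-p53 versus vector microarrays). Either line alone is
unreliable — binding without response is common, and most expression changes
under knockdown are indirect. `p53targets` implements the full analysis
path from replicated peak calls and raw TSS-bin counts to a ranked list of
putative direct targets, together with a synthetic-data generator that
plants known targets so every stage can be benchmarked end to end.

# High-confidence consensus peaks

Per condition, replicate peak calls are clustered by overlap: a cluster is
the maximal run of bases covered by any replicate's peaks, and its support
is the number of *distinct* replicates contributing to it (two peaks from
one replicate do not replicate each other). Clusters supported by two or
more replicates enter the high-confidence (HC) set directly. Singleton
clusters get a second chance through cross-condition rescue: a singleton is
kept if it overlaps peaks in at least two *other conditions* (rule i), or
if a single other condition has peaks from at least two distinct replicates
overlapping it (rule ii). Surviving spans are merged into the final
disjoint HC set, with per-peak provenance and a full audit table.

Two points were genuinely open and are fixed as follows:

* *Which partner peaks can rescue.* By default any peak of another
  condition counts (permissive reading); `strict_rescue = TRUE` restricts
  partners to peaks that are themselves part of a replicated cluster in
  their own condition. The audit table records which rule fired.
* *Abutting intervals.* Cluster spans and `merge_intervals()` operate on
  covered base runs, so intervals sharing only a boundary coalesce. This
  makes the implementation exactly equivalent to a per-base set
  formulation of the consensus rules, which is also how the test suite
  verifies it (a brute-force bitmap implementation on a 10 kb toy
  chromosome must agree exactly on 1000 random instances). `overlaps()`
  itself still requires at least one shared base.

# Genomic feature classes and the CGI partition

Peaks are anchored at their midpoint and classified against the nearest
gene by TSS distance (ties broken by gene id), testing categories in a
fixed priority order: core promoter (TSS offset in [-3000, +2000] bp,
signed in the direction of transcription), downstream extremity (TES
offset in [-2000, +3000]), exon, intron, distal (within 50 kb of a TSS),
and intergenic (beyond 50 kb of every gene). The priority order is needed
because the window definitions overlap — a peak can sit in one gene's
intron while 40 kb upstream of another — and published category bar charts
are mutually exclusive. Exon/intron containment is tested against any
gene, not just the TSS-nearest one, so intronic peaks are not mislabelled
distal to a neighbour. The CGI partition is simpler: any peak sharing at
least one base with a CpG island is a CGI peak, the rest are non-CGI.

# The expression arm: moderated t and Pr(DE | data)

Expression matrices (log2 intensities) are quantile normalized across all
arrays, and the contrast is **sh-p53 minus vector**: genes *activated* by
p53 drop under knockdown and get negative log2 fold changes. Per-probe
variances are moderated by empirical Bayes:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

with the prior $(d_0, s_0^2)$ estimated by moment matching on the log
scale (sample variances follow $s_0^2 F(d, d_0)$ under the hierarchical
model, so the variance of $\log s_g^2$ determines $d_0$ through the
inverse trigamma and the mean then gives $s_0^2$). The moderated
$t_g = \mathrm{lfc}_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ has
$d_0 + d$ degrees of freedom; with $d_0 = 0$ it is exactly the classical
pooled t, which is how the tests pin it down.

The posterior probability of differential expression is a two-component
mixture on the t scale: under the null $t_g \sim t_{d_0+d}$, under the
alternative the variance is inflated by `v_prior`, and with prior DE
probability `p0` the posterior log-odds are the prior log-odds plus the
log density ratio. Defaults are `p0 = 0.05` and `v_prior = 16` (effect SD
four times the statistic's null SD, the conventional empirical-Bayes upper
bound). These were set by a power analysis of the generator's declared
conditions — a 1.0 log2 effect with 0.3 SD in a 3 vs 3 design gives
|t| near 4, and the defaults put the posterior for such probes above 0.9
while keeping null probes below 0.1; a flatter alternative (for example a
4-fold variance ratio) cannot separate that design to the same degree.
Both are exposed as arguments. Study gene lists use the conventional
cutoffs q < 0.01 (Benjamini-Hochberg) and |log2 fc| > 0.58; multiple
probes per gene collapse by maximum posterior, with the fold change taken
from the winning probe.

# The binding arm: NB enrichment over input and Pr(C | data)

Rather than thresholding peaks, the binding evidence is read-based: one
strand-aware window per gene from 50 bp upstream to 1500 bp downstream of
the TSS, counted per sample. Between-sample normalization uses
quantile-based effective library sizes by default — each sample's size
factor is the sum of its counts at or below its 75th count percentile.
This is deliberately *not* a full quantile normalization of the count
matrix: forcing identical count distributions across chip and input
columns would transfer the enriched upper tail of the ChIP samples onto
the input, manufacturing enrichment at unbound genes; the quantile library
size keeps the robustness (insensitivity to the enriched tail) without
distorting the counts, and plain total-count scaling is available with
`norm = "libsize"`.

Per gene, two negative-binomial models are compared (dispersion $\varphi$,
$\mathrm{Var} = \mu + \varphi\mu^2$, method-of-moments estimate across
genes unless supplied): M0, chip and input share one underlying rate;
M1, the chip rate strictly exceeds the input rate. Marginal likelihoods
integrate over a discrete empirical rate prior: per-gene pooled rates are
bootstrap-resampled (50 genes x 100 draws), coarsened to about 24 quantile
mass points, and extended with log-spaced tail points so the grid always
spans the most extreme per-gene arm rates. M1 uses the product of two such
priors restricted to the ordered cone *without* renormalization: the
ordered alternative then pays its natural prior-mass (Occam) penalty, so
a gene with identical chip and input counts favours M0 ($pC \le 0.5$ at
any symmetric prior), while a few-fold enrichment across replicates
overwhelms the penalty.

The model prior $\pi$ is estimated from the data by default, by iterating
the mean-posterior fixed point $\pi \leftarrow \mathrm{mean}(pC)$ (capped
to [0.001, 0.5]) — the same empirical-Bayes idea baySeq uses for its model
priors. A fixed value (for example the uninformative $\pi = 0.5$) can be
passed instead, and that is the setting under which the calibration tests
run: under a simulated null (fold change 1) fewer than 7% of genes reach
$pC > 0.95$, while fivefold enrichment with three replicates puts over
90% of bound genes above $pC > 0.9$. Estimating $\pi$ matters for the
joint ranking: with a fixed 0.5 prior, unbound genes retain posterior mass
around 0.3-0.5, which leaks strongly expressed but unbound genes into the
pass set; the estimated prior concentrates the null near zero.
All-zero count rows cannot be scored and return the prior, flagged.

# The joint posterior and B values

The two arms are combined as independent evidence:
$p_{\mathrm{joint}} = \Pr(\mathrm{DE}\mid\mathrm{data}) \cdot
\Pr(C\mid\mathrm{data})$, transformed to a B value
$B = \log\!\big(p_{\mathrm{joint}}/(1-p_{\mathrm{joint}})\big)$, ranked
descending, and thresholded at $B > -1.5$ (strict inequality; the
boundary fails). The proportionality constant of the joint posterior is
taken as 1 — only the ranking and the fixed threshold are consumed, for
which a constant is irrelevant, but this makes the threshold's meaning
explicit: $B = -1.5$ corresponds to $p_{\mathrm{joint}} \approx 0.182$.
Boundary posteriors 0 and 1 map to capped sentinels ($\mp 10^{308}$) so
results serialize. Direction follows the contrast sign: negative log2 fc
(down under knockdown) means induced by p53; positive means repressed —
the pattern of the lipogenic enzyme SCD, which rises when p53 is depleted.
The acute condition is excluded from integration by default, since
acute-phase binding largely fails the TSS-local localization criterion;
`run_pipeline(..., condition = "acDDR")` forces it.

# Motif scanning

The p53 response element is modelled as two decameric half-sites
(consensus RRRCWWGYYY) separated by a 0-13 bp spacer; lone half-sites are
biologically meaningful and are reported by the plain scanner. The shipped
half-site matrix (`p53_halfsite_pwm()`, also in
`inst/extdata/p53_halfsite_synthetic.pwm`) is a synthetic count matrix
uniform within each degeneracy class — a declared stand-in, since curated
commercial matrices cannot be redistributed. Scores are log-odds with a
0.25 pseudocount against a uniform background, min-max normalized to the
matrix similarity score $\mathrm{mss} \in [0,1]$ with the conventional
0.8 cutoff, plus a MATCH-style core score over the five consecutive
highest-information columns. Full sites pair same-strand half hits whose
gap lies within the spacer range, scored by the sum, with overlapping
candidates resolved greedily by score. Positional histograms bin hit
starts by signed strand-aware TSS offset over [-1000, +1000) in 50 bp
bins; foreground-versus-background promoter enrichment uses a z-test on
mean best-hit mss between equal-length promoter sets.

# The synthetic study

`sim_config()` declares the emulated design. Values the study fixes are
used as such: conditions Grow (2 ChIP replicates), acDDR, RIS and pApo
(3 each); 3 vs 3 expression arrays; TSS windows -50/+1500; the B
threshold -1.5. The remaining knobs are the package's own calibration
choices, set once:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | large enough for stable fractions, small enough for test budgets |
| `chrom_length` | 242 Mb | 121 kb gene spacing, so promoter/distal/intergenic all occur |
| `cgi_promoter_fraction` | 0.5 | balanced CGI/non-CGI promoter classes |
| `n_bound_genes` / `n_responsive_genes` / `n_target_genes` | 250 / 200 / 150 | leaves 100 bound-only and 50 responsive-only genes to stress the joint posterior |
| `cgi_target_odds` | 3 | targets drawn 3:1 from CGI promoters, mirroring the chronic p53-CGI association |
| `chip_mean_background` / `chip_fold_enrichment` / `nb_dispersion` | 20 / 5 / 0.1 | typical TSS-bin depth, clearly-but-not-trivially detectable binding, standard overdispersion |
| `expr_effect` / `expr_sd` | 1.0 / 0.3 log2 | a twofold effect against array-like noise |
| `peak_width` / `peak_jitter_sd` / `peak_dropout_prob` | 250 bp / 50 bp / 0.2 | MACS-like peak geometry; 20% per-replicate miss rate exercises both consensus rules |
| `decoy_frac` | 0.1 | singleton decoys per condition exercise the rescue logic |
| `frac_repressed` | 0.2 | a minority of repressed targets, so both directions occur |

Reads are generated *from* the counts (uniformly within each gene's TSS
window), so recounting them reproduces the emitted table exactly — a
round-trip identity the tests assert. Every generator runs on a private
RNG stream derived from the seed and restores the caller's RNG state.

What the generator does **not** emulate: genome sequence composition (no
base-level simulation outside the motif-planting helpers), overlapping
genes and alternative transcripts, batch or spatial array artifacts,
fragment-length effects and GC bias in ChIP coverage, and condition
profiles in which binding differs across chronic conditions. Passing the
end-to-end benchmarks therefore demonstrates correctness of the
statistical machinery under the declared model, not performance on any
particular real dataset.

# Numerical choices and degenerate inputs

* Logit sentinels at $p \in \{0, 1\}$; two-sided p-values floored at the
  smallest representable double when a moderated variance is exactly zero.
* Ranking ties break by gene id; nearest-gene ties break by the smaller
  gene id; both deterministic.
* The variance-prior estimator refuses all-zero variance vectors with an
  actionable message; non-positive log-variance spread yields
  $d_0 = \infty$ (complete shrinkage).
* The dispersion estimator is floored at $10^{-4}$; zero effective
  library sizes are an error rather than silent NaNs.
* The EM for $\pi$ runs at most 25 iterations from 0.5 and stops on a
  $10^{-6}$ fixed-point change.

# Problem sizes used by the checks

The test suite verifies consensus construction against the brute-force
per-base oracle on 1000 random instances (up to 20 peaks, 4 conditions,
up to 3 replicates, 10 kb chromosome), BH adjustment against the
exhaustive step-up oracle on 1000 random vectors, hyperparameter recovery
on 5000 simulated variances, enrichment calibration and power on
2000-gene simulations, and the end-to-end benchmark on the default
2000-gene study (150 planted targets, seed 20150319), where it requires
AUROC at least 0.90, precision at least 0.8 and recall at least 0.7 for
the $B > -1.5$ pass set. `scripts/acceptance.R` re-runs the same
computation from scratch at a caller-supplied seed.

```{r quick-example, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 20150319))
res <- run_pipeline(ds, condition = "RIS")
head(res$targets)
```

# Known limitations

* One transcript per gene; exon/intron classes ignore isoform structure.
* Single-window TSS counting (no sub-bin tiling, no fragment-shift
  model); read positions are taken as given.
* The enrichment grid is empirical; with very few genes (fewer than ~20)
  the bootstrap prior is coarse and posteriors are correspondingly
  conservative.
* The probe-to-gene collapse (max posterior) is one of several defensible
  rules; a per-probe mode is available by leaving `collapse = FALSE`.
* The shipped half-site matrix is synthetic; for real scans supply a
  curated matrix via `read_pwm()`.
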
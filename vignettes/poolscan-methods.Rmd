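---
title: "Methods: replicated pool-seq scans for parallel ecotype divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicated pool-seq scans for parallel ecotype divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poolscan)
```

`poolscan` asks whether repeated ecotype divergence in distinct
geographic locations is built from the same loci. Its input is a
popoolation2-style sync file of per-position A:T:C:G:N:del read counts
for a replicated pooled design — in the canonical layout, three
countries × two ecotypes (crab-predation vs wave-exposure shore snails)
× two replicate pools of ~40 diploid females each — plus a design table
mapping sync columns to those factors. This vignette documents the
statistical model, every tunable that matters, what the synthetic data
generator does and does not emulate, and the numerical conventions and
known limitations of the pipeline.

## The analysis model

### Preprocessing

Pool-seq transcriptome data have two properties the pipeline must
neutralise before FST is comparable across loci: coverage varies wildly
across contigs and samples, and rare sequencing errors masquerade as
low-frequency SNPs.

1. **Deletion removal** (`drop_deletion_sites()`): any position with at
   least one deletion-supporting read in any pool is discarded.
2. **Subsampling to even coverage** (`subsample_sync()`): each retained
   position in each pool is resampled *with replacement* to
   `target_coverage` reads (default 20), multinomially with cell
   probabilities proportional to the observed A/T/C/G counts. Drawing
   with replacement permits upsampling of positions observed below
   target; a floor `min_coverage` (default 10) still excludes positions
   whose resampling noise would be unbounded. A position failing the
   floor in *any* pool is dropped in *all* pools, so every downstream
   pair sees one common site set.
3. **SNP calling** (`call_snps()`): allele counts are summed over all
   pools; the two top totals define the major/minor allele (ties broken
   A < T < C < G); a site is a SNP only if the minor total reaches
   `min_minor_count` (default 24, i.e. 10% of the 12 × 20 = 240
   subsampled reads). Reads supporting a third allele are discarded and
   the two retained alleles are rescaled to target coverage by a second
   binomial draw, keeping the downstream biallelic frequency model
   exact. The threshold is applied *after* subsampling so the 10%
   arithmetic is exact.

### Per-contig FST

Transcriptome reference contigs are short (~660 bp, typically one or a
few exons), so the contig — not the SNP — is the unit of analysis; this
both limits pseudoreplication and integrates differentiation across
linked SNPs. For a pool pair with major-allele frequencies $p_1, p_2$
at a SNP,

$$H_w = \frac{2p_1(1-p_1) + 2p_2(1-p_2)}{2}, \qquad
  H_t = 2\bar p(1-\bar p), \quad \bar p = \frac{p_1+p_2}{2},$$

and the contig's fixation index is the ratio of the *averaged*
components over its SNPs,

$$F_{ST} = \frac{\bar H_t - \bar H_w}{\bar H_t}.$$

The ratio-of-averages form (rather than averaging per-SNP ratios) is
numerically stable and follows from averaging heterozygosities first.
The identity $\bar H_t - \bar H_w = \overline{(p_1-p_2)^2}/2 \ge 0$
guarantees $F_{ST} \in [0, 1]$; contigs with $\bar H_t = 0$ for a pair
are excluded for that pair and counted. No pool-size correction is
applied to the heterozygosities — a documented limitation (see below).

`design_pairs()` enumerates three pair classes: replicate-matched
crab–wave pairs within each country (the selection signal, two
estimates per country), within-ecotype pairs (crab1–crab2, wave1–wave2
— pure experimental noise), and the four ecotype/replicate-matched
cross-country pairs per country pair, averaged per contig so the
between-country estimate keeps ecotype composition balanced.

### Outlier detection and sharing

Classical model-based genome-scan nulls are easily violated by
demography and by pervasive purifying selection in transcriptomes, so
outliers are defined non-parametrically: within each country, the
threshold for each replicate is the empirical `q`-quantile (R's default
linear interpolation between order statistics, quantile type 7) of that
replicate's per-contig FST, and a contig is an outlier only when it is
*strictly above both* replicate thresholds. Because the "true" outlier
fraction is unknown, the scan is repeated over `quantiles` (default
0.94–0.98).

Sharing between two countries is the intersection of their
replicate-consistent outlier sets, judged against the hypergeometric
null for two random subsets of the common universe $N$ (contigs with
both replicate estimates in every country): expectation $n_a n_b / N$,
with discrete 95% limits defined as the largest $k$ with
$P(K \le k-1) \le 0.025$ and the smallest $k$ with
$P(K \le k) \ge 0.975$. Sharing proportions are reported per focal
country (shared / country's outliers) plus the symmetric Jaccard index.
Two controls accompany the main comparison: `replicate_sharing()` (the
marginal top-`q` sets of the two replicates within a country — real
selection makes them agree far beyond chance) and `control_sharing()`
(crab–crab vs wave–wave pseudo-replicates, where no true ecotype signal
can exist).

### SNP-level parallelism

Shared outlier contigs need not be driven by the same nucleotides. For
each SNP the package computes, per country, the crab-minus-wave
frequency difference of a globally fixed reference allele (the
grand-total major allele; any consistent polarization preserves the
correlations up to a joint sign, and this one is deterministic),
averaged over replicates. For each contig with more than two SNPs and
non-degenerate variance, the Pearson correlation of two countries'
difference vectors is positive when the same alleles track the crab
ecotype in both, negative when associations are reversed. Because a
contig with 3 SNPs yields |r| near 1 by chance alone, only the
distribution over contigs is interpretable, never a single contig.

Two tests compare shared outliers with all contigs: a bootstrap of the
mean correlation ($B$ = 10,000 samples of the focal size drawn with
replacement from all contigs' correlations; two-tailed Monte-Carlo
p-value with continuity correction,
$p = (1 + \#\{|\bar r_b - \bar r_{all}| \ge |\bar r_{obs} - \bar
r_{all}|\})/(B+1)$), and a chi-square test on binned correlations
(default edges $-1, -0.5, 0, 0.5, 1$; bins with expected focal count
below 5 are merged with their nearest neighbour, and the test is
reported missing if fewer than two bins survive).

## The synthetic data generator

`simulate_pool_seq()` emulates the generative structure the analysis
assumes, per SNP:

ancestral frequency $\pi \sim \mathrm{Beta}(a, b)$ →
country frequency $f_c = \mathrm{logit}^{-1}(\mathrm{logit}(\pi) +
\varepsilon_c)$ with $\varepsilon_c \sim N(0, \sigma_d^2)$ (optionally
correlated for one designated country pair, emulating a shared
colonization history) → ecotype frequencies $f_c \pm s_c\,\delta/2$
according to the contig's label → replicate pool frequency =
binomial draw of $2 \times 40$ allele copies → coverage $\sim$
negative binomial → read counts binomial in the pool frequency, with a
fraction `error_rate` of reads miscalled uniformly to the other three
nucleotides. All frequencies are clamped to $[0.02, 0.98]$.

Contig labels and their per-country selection signs $s_c$:
`neutral` (0 everywhere), `shared_selected` (+1 everywhere),
`country_specific:<ctry>` (+1 in one country), and
`sign_flipped:<A>:<B>` (+1 in A, −1 in B — the pattern where the same
allele tracks opposite ecotypes in two locations). Selected contigs
apply $\delta$ to *all* their SNPs (complete linkage within a short
contig) and are guaranteed at least `selected_min_snps` SNPs (default
3), since multi-SNP differentiation is what makes a contig-level signal
detectable. The truth table records each contig's label and realized
mean crab-minus-wave difference per country, keyed for recovery tests.

Default parameters and their reasoning:

| parameter | default | rationale |
|---|---|---|
| `n_contigs` | 2000 | thousands of short contigs, desk-scale |
| `snp_mean` / `snp_max` | 3 / 20 | truncated geometric; short exonic contigs carry few SNPs |
| `pool_individuals` | 40 | pools of ~40 females |
| `ancestral_beta` | (1, 1) | uninformative spectrum for *retained* SNPs; the 10% minor-count filter truncates it downstream |
| `drift_sd` | 0.5 | logit-scale country drift giving between-country FST above between-ecotype FST |
| `effect_delta` | 0.3 | places selected contigs in the observed FST tail (~0.1–0.3); an assumption, not an estimate |
| `coverage_mean`, `coverage_dispersion` | 50, 5 | RNA-seq-like overdispersed depth (variance ≈ 550) |
| `error_rate` | 0.002 | post-quality-filter miscall rate |
| `contig_length` | 660 | average draft-assembly contig |
| `frac_shared_selected`, `frac_country_specific`, `frac_sign_flipped` | 0.02, 0.06, 0.02 | a minority of selected contigs, mostly country-specific |

What the generator deliberately does **not** model: individuals as
genotypes with expression weights (RNA-seq expression noise is subsumed
into the overdispersed coverage distribution — the subsampling +
replication design is precisely what absorbs it); within-contig linkage
for *neutral* contigs (their SNPs draw independent pool noise, slightly
understating the per-contig noise correlation); allele-specific
expression; coalescent structure or explicit migration. Passing tests
therefore demonstrate the statistical machinery is calibrated and
powerful under this model, not that any particular biological dataset
will behave identically.

## Numerical conventions and edge cases

* Empirical quantiles use interpolation type 7; "above threshold" is
  strict inequality (ties at interpolated thresholds do not occur for
  continuous FST).
* The hypergeometric CI convention is stated above and is verified
  against full enumeration of the mass function in the test suite;
  discrete CIs are convention-sensitive, so the enumeration oracle is
  the source of truth.
* Multinomial subsampling uses exact sequential conditional binomials;
  alleles with zero input count never appear in the output.
* One top-level seed deterministically derives per-stage seeds
  (simulation, subsampling, SNP-call rescaling, bootstrap), so a fixed
  seed reproduces a byte-identical sync file and scan.
* Degenerate inputs: empty sync files yield empty tibbles; contigs with
  zero total heterozygosity are excluded per pair and counted; focal
  correlation sets that are empty, constant, or too small propagate as
  `NA` results with excluded-contig accounting, never as errors.

## Calibration properties and known limitations

The test suite runs the full pipeline on repeated neutral simulations
(400 runs of 2000 contigs; sizes chosen to keep the suite fast on one
CPU) and on selection scenarios (200 runs each). Three findings are
worth knowing before interpreting real scans:

* **The discrete hypergeometric CI is conservative.** With realistic
  outlier counts the expected overlap is below one contig and the 95%
  band covers ~98–99% of null outcomes per country pair. Observed
  sharing must clear a genuinely high bar before `exceeds_chance` is
  true.
* **The within-country control shares slightly more than chance.** The
  crab–crab and wave–wave scans of one country are built from the same
  underlying site and frequency structure, so their top-quantile sets
  overlap somewhat more than the hypergeometric null allows even
  without any selection — the same mild excess visible in real
  replicated scans. Control sharing near, but slightly above, the
  chance band is therefore expected and not evidence of ecotype
  selection.
* **Outlier-conditioned correlation tests inherit a composition bias.**
  FST outliers skew toward contigs with few SNPs, whose per-contig
  correlations pile up near ±1 by chance; resampling tests are exactly
  calibrated for randomly drawn focal sets, and slightly
  anti-conservative for outlier-selected ones. Overall patterns across
  thresholds — not single p-values — should carry the interpretation.
* **Power at moderate effects is modest.** At coverage 20 the per-pool
  frequency noise SD is ~0.14, so an ecotype shift of δ = 0.3 at 3
  SNPs is detected by one replicate pair only ~40% of the time at the
  94% threshold, and the cross-country shared set recovers a minority
  of truly shared loci. Sharing *proportions* from such scans
  understate true gene reuse; the exceeds-chance verdict remains
  reliable. Larger effects (δ ≥ 0.5), more SNPs per contig, or deeper
  target coverage raise recovery steeply.
* No pool-size correction is applied to heterozygosities, so absolute
  FST carries a small upward bias at coverage 20 that cancels out of
  quantile-based outlier ranking; between-study comparisons of absolute
  FST should account for it.
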
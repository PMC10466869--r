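---
title: "Methods: the ED bulked-segregant scan and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ED bulked-segregant scan and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Bulked segregant analysis localizes quantitative-trait loci by sequencing
two pools of individuals drawn from the opposite tails of a phenotype
distribution. At a locus unlinked to the trait the two pools are random
samples of the same population and their allele frequencies differ only by
sampling noise; at a locus driving the phenotype the tails are enriched
for opposite alleles and the pool frequencies diverge. `edbsa` measures
that divergence per site with the Euclidean distance over the four base
frequencies,

$$ED = \sqrt{(A_m - A_w)^2 + (C_m - C_w)^2 + (G_m - G_w)^2 + (T_m - T_w)^2},$$

where the $m$ subscript is the high-phenotype ("mutant") pool and $w$ the
low-phenotype ("wild-type") pool. For a biallelic site $ED \le \sqrt 2$,
with equality exactly when the pools are fixed for different alleles.

A single site's ED is noisy at ordinary depth, so the scan works on
$ED^4$ — the 4th power shrinks background values (ED below 1) much more
than genuine divergences near $\sqrt 2$ — smoothed along the chromosome,
with an empirical genome-wide threshold of median + 3 SD on the fitted
values. This makes the procedure self-calibrating: the threshold adapts to
the depth and noise level of the data set at hand.

# Stages and their parameters

## Pre-filtering (`prefilter_sites`)

Three stages, each with its count recorded so the cascade can be audited:

| stage | rule | default |
|---|---|---|
| biallelic | exactly two bases observed across both pools | — |
| frequency | drop if one base holds ≥ `fix_threshold` of the wild-type pool's reads (computed over the two retained bases) | 0.95, inclusive |
| depth | drop if either pool's total depth < `min_depth` | 10X |

The fixation screen is applied to the wild-type pool only — a site fixed
in the low pool but segregating in the high pool is exactly the signature
the high pool should show, whereas a site fixed in the reference-like pool
carries no usable contrast. `apply_to_mut = TRUE` extends the screen to
the mutant pool for symmetric designs.

## Smoothing (`fit_scan`)

The fitted curve is a degree-1 local polynomial regression of $ED^4$ on
position, per chromosome: at each site the nearest
$q = \lceil \mathrm{span} \cdot n \rceil$ sites (default span 0.1) receive
tricube weights scaled by the distance to the $q$-th neighbour, and a
weighted straight line is evaluated at the site. One pass, no robustness
re-weighting; fitted values are clipped at 0 since $ED^4 \ge 0$. The
smoother is written in the package (a dozen lines of weighted least
squares) so its neighbourhood and weight definitions are pinned exactly;
the test suite checks it against an independent per-site `lm()` evaluation
to $10^{-9}$ and degree-1 invariants (constants and straight lines are
reproduced exactly). Chromosomes with fewer than 10 sites are too short to
smooth and keep their raw $ED^4$, with a warning.

Local-linear fits extrapolate at chromosome ends, where the neighbourhood
is one-sided; fitted values there have visibly higher variance. This is a
known property of the estimator, kept because degree 1 also removes the
boundary *bias* that a running mean would suffer; its consequence for the
null scan is quantified below.

## Threshold, regions, candidates

The association threshold is `median(fitted) + 3 * sd(fitted)` over **all**
sites genome-wide (sample SD, $n-1$ denominator). Maximal runs of
consecutive sites with `fitted >= threshold` on one chromosome become
regions — a single sub-threshold site splits a run, and regions never
span chromosomes. Within regions, a site is a candidate SNP when its
mutant-pool mutation frequency (the non-reference allele fraction in the
mutant pool) is **strictly** greater than 0.75 and its **raw** ED strictly
greater than 0.5. The candidate rule deliberately uses raw ED, not
$ED^4$, and the mutant pool, not the wild-type pool: the region call
already encodes the smoothed evidence, and in a high/low design the
"mutation" is the allele enriched in the high pool. Both choices are
exposed in `scan_config()`.

## Genotype calling (`call_genotype`)

Per sample and site: depth < 5X → missing; alternate-allele frequency
≥ 0.8 → homozygous alternate, ≤ 0.2 → homozygous reference (both
boundaries inclusive); strictly between, with at least 4 reads on *each*
allele → heterozygous; otherwise missing. The rules partition the whole
$\mathbb{N}^2$ count grid — the suite asserts totality and every boundary
case exhaustively up to depth 100.

## Enrichment (`enrich`, `hypergeom_p`)

Candidate genes are tested per term against the hypergeometric upper tail
$P(X \ge m)$ with $X \sim \mathrm{Hypergeom}(N, M, n)$, evaluated exactly
in log space (`lchoose`), summing the upper tail directly to avoid
cancellation at small $p$. The universe $N$ is the *annotated* background
(genes carrying at least one term): an unannotated gene can never
contribute to $m$ or $M$, so counting it in $N$ would deflate every
p-value. Q-values are Benjamini–Hochberg (`stats::p.adjust`), the standard
reading of "Q value" in enrichment reports, with significance at
$Q \le 0.05$; the rich factor is $m/M$. GO and KEGG maps use the same
engine — the package treats term maps as flat (no DAG propagation).

## Association (`fit_association`)

The phenotype model is $Y_{ij} = \mu + G_i + P_j + e_{ij}$ with genotype
$G$ and age class $P$ as categorical fixed effects, fitted by OLS under
sum-to-zero constraints. The genotype p-value is the partial F-test of the
genotype factor added after age (type-II sums of squares) — the test the
stated model naturally yields. With a single age level this reduces
exactly to one-way ANOVA, which the suite verifies against the closed-form
F. Genotype classes with fewer than 2 observations are dropped; reported
genotype means are raw class means (model-adjusted effects are available
in `$G`). Age can be switched to a numeric covariate with
`age_numeric = TRUE`.

## Annotation (`classify_site`)

Single transcript per gene, category precedence
exonic > splicing > UTR5/UTR3 > intronic > upstream/downstream (≤ 1 kb)
> intergenic across overlapping genes. "Splicing" means within 2 bp of an
*internal* exon boundary on the intron side — the boundary between a CDS
and its own UTR is not a splice site. Codon consequences translate the
affected codon in transcript orientation (reverse-complemented on the
minus strand); a mirror-image property test checks strand consistency.

# The simulator and what it does (not) emulate

`simulate_bulks()` generates the study conditions the pipeline is
validated under: two bulks of `pool_size = 3` animals at
`depth_mean = 28`X (Poisson per pool and site), segregating sites with a
shared neutral frequency drawn from `baseline_maf_range = (0.05, 0.5)`,
and planted QTL where the pool frequencies split to $p \pm \delta w/2$
with $w$ decaying linearly over `linkage_window = 10` Mb — broad linkage
blocks are what 3-animal extreme pools produce, since each pool carries
only a handful of recombination events. Reads are binomial in the pool
frequency; the finite-pool resampling step (3 diploid genomes per pool)
is *not* modelled, so real pools are slightly overdispersed relative to
the simulation. No sequencing error, mapping bias, indels or structural
variants. Passing the planted-QTL tests therefore demonstrates the
statistical machinery recovers frequency divergence at realistic depth —
it does not certify behaviour under alignment artefacts or error-rich
data.

Phenotypes (`simulate_phenotypes()`) follow the association model
directly: $\mu$ + genotype shift + age shift + Gaussian noise, clamped at
0 ng/mL because concentrations cannot be negative.

# Numerical choices and test problem sizes

* Coordinates are 1-based inclusive internally; BED output converts at
  the boundary.
* Sample SD ($n-1$) in the threshold; inclusive `>=` at the threshold,
  strict `>` in the candidate rules, inclusive boundaries in the genotype
  and fixation rules — each pinned by a boundary test.
* Ties in the smoother (several sites at one position are rejected;
  positions must be strictly increasing per chromosome).
* The validation suite runs 5,000-site, 2-chromosome scans (one planted
  QTL, $\delta = 0.8$, 30X) over 40 seeds for recovery and 20 seeds for
  the null, 500 resampling rounds for enrichment calibration, and 200
  permutations for the association null — sizes chosen so the whole suite
  completes in about a minute while keeping Monte-Carlo error well below
  the margins being asserted.
* Enrichment null calibration uses a 500-gene universe with 20 terms of
  50 genes and 50 candidates: at this size the hypergeometric support is
  dense enough that the fraction of null tests below $p = 0.05$ has
  theoretical value 4.8 %; much smaller designs are too discrete to
  calibrate meaningfully.

# Known limitations

* **Null exceedance of the Median + 3 SD rule.** On a fully neutral
  genome the suite measures ≈ 1.2 % of sites inside called regions
  (seeds 1–20 at the sizes above) — slightly above the nominal 1 % one
  might hope for, and intrinsic rather than an implementation artefact:
  swapping in `stats::loess` with identical settings reproduces it.
  The smoothed $ED^4$ field is right-skewed and its variance is inflated
  near chromosome ends, where about half of the null excursions sit.
  Interpret isolated regions at chromosome termini with care.
* Genome-scale thresholds depend on the smoothing span and the data's
  noise level; thresholds from different data sets or spans are not
  comparable.
* Flat term maps only; no GO DAG topology.
* Single-transcript annotation; no isoform arbitration or rsID lookup.
* The two pools must share one reference naming scheme — chromosome
  names are compared as exact strings, deliberately, to avoid silent
  `chr1`/`1` mismatches.
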
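---
title: "Region-based association testing with DMAF: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based association testing with DMAF: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmafscan)
```

## The problem

Single-variant association tests have essentially no power against rare
variants at realistic sample sizes. Region-based (burden/collapsing) tests
recover power by aggregating evidence across the variants of a gene or
region, but most of them assume every causal variant pushes risk in the
same direction, and a region-wide test says nothing about *where* in the
region the signal lives. `dmafscan` implements a region test that is
agnostic to effect direction, and a sliding-window scan that localizes the
signal to a sub-region while controlling the family-wise error across
windows.

## The DMAF statistic

For variant $j$ let $X_j$ and $Y_j$ be the minor allele frequencies among
cases and controls, computed over subjects with a non-missing genotype in
each group, with the minor allele defined by the pooled (cases + controls)
frequency $q_j \le 0.5$. The test statistic over a variant set $A$ is

$$V = \sum_{j \in A} w_j D_j, \qquad
  D_j = |X_j - Y_j| \;\text{("abs")} \quad\text{or}\quad
  D_j = (X_j - Y_j)^2 \;\text{("sq")},$$

with MAF-based weights

$$w_j = \frac{1}{\sqrt{n_j\, q_j (1 - q_j)}},$$

where $n_j$ is the number of genotyped subjects at variant $j$. Because
$D_j$ is a positive function of the frequency difference, risk and
protective variants contribute alike — no assumption on effect direction
is made — and the weights emphasize rare variants, where a fixed absolute
frequency difference is a large relative effect. The variant set $A$ may
be all polymorphic variants or the rare subset ($q_j \le 0.05$ by
default, boundary inclusive).

With equal numbers of cases and controls, complete genotypes and shared
weights, the "sq" flavor is exactly proportional to the covariate-free
score form of the SKAT statistic $Q = \sum_j w_j (g_j^\top(y-\bar y))^2$
(the constant is $n_{\text{case}}^2$); `skat_q()` exists solely so the
test suite can verify that identity. Unlike a variance-component test,
however, DMAF weights cases and controls equally regardless of their
relative sample sizes.

Significance is assessed by permutation: case/control labels are shuffled
uniformly, $X_j$, $Y_j$ and $D_j$ are recomputed per relabeling, and

$$p = \frac{\#\{V_{\text{perm}} \ge V_{\text{obs}}\}}{n_{\text{perm}}}.$$

Ties count as extreme and $p = 0$ is attainable; this convention is
mildly anti-conservative (a fraction of a percent at $\alpha = 0.05$),
which matches the slightly elevated type I error this family of
permutation tests is known to display. The `(r+1)/(n+1)` convention is
available behind the `plus_one` flag for users who want a strictly valid
p-value. The pooled quantities $q_j$, $n_j$, $w_j$ and the minor-allele
orientation are phenotype-free and are therefore held fixed across
permutations.

### Missing genotypes

Group frequencies are estimated over non-missing genotypes within each
group, and $n_j$ in the weight is the genotyped-subject count. This is
the only defensible estimator without imputation; a permutation that
leaves a group with no genotyped subject at some variant contributes
$D_j = 0$ (no frequency information) rather than a `NaN`.

## Sliding windows and step-down correction

Windows are defined in variant-index space: a window of size $k$ covers
$k$ consecutive polymorphic variants (after the `all`/`rare` filter).
Windows advance by $\max(5, \text{round}(0.10\,k))$ variants (round half
up); when the step pattern undershoots the end of the region one final
window anchored at the last $k$ variants is appended so that every
variant is covered. Base-pair or LD-defined windows are out of scope.

Multiple testing across the $m$ windows of one size is controlled by a
Westfall–Young step-down permutation procedure built from two independent
sets of shared relabelings:

1. $B_1$ permutations (default 1000), each applied to *every* window,
   give each window its null distribution of $V$ and the observed
   empirical p-value.
2. A second, independent set of $B_2$ relabelings (default 1000) is
   evaluated against each window's first-set null distribution, filling
   an $m \times B_2$ p-value matrix $M$.
3. Observed p-values are sorted ascending; the smallest is compared to
   the column minima of $M$ (strict `<`), giving its corrected value as
   the fraction of minima below it. The top row is removed, minima are
   recomputed, and each subsequent corrected value is the maximum of its
   own fraction and its predecessor, enforcing monotonicity.

Both permutation sets *must* be shared across windows — one relabeling
per column — or the column minima no longer estimate the distribution of
the most extreme window under the global null; the test suite asserts
this by checking that duplicated windows produce identical matrix rows.
Referencing the second set to the first-set null keeps observed and
permuted p-values on the same (discrete) reference distribution, the
standard construction when the raw statistic's scale differs across
windows. Step-down is never more conservative than the single-step maxT
bound, which is also asserted on random matrices. No correction is
applied across different window *sizes*; robustness of the result across
sizes is treated as a descriptive finding, not a tested family.

A scan "detects" at level $\alpha$ when any corrected p-value is below
$\alpha$ (strict). "Localization" asks whether the window with the
smallest corrected p-value — or, under ties, the union span of the tied
set — overlaps the causal sub-region by at least half the span's length,
measured in markers (boundary inclusive: an overlap of exactly half
counts).

## The simulation framework

The generator reproduces the reference study design used throughout the
tests:

* **Haplotype pools.** Neutral coalescent regions of 50 kb with mutation
  rate $\mu = 10^{-8}$/bp/generation, effective population size
  $N_e = 10^4$ diploids, background recombination 1 cM/Mb, and 100,000
  diploid individuals (200,000 chromosomes). Under these parameters
  $\theta = 4 N_e \mu L = 20$ and the Watterson expectation is
  $\theta \sum_{i<2\times10^5} 1/i \approx 256$ segregating sites per
  region. Two of the three reference regions carry a 2-kb hotspot at
  15 cM/Mb that interrupts LD; the hotspot sits at the region midpoint
  by default (the precise position is a free parameter; the midpoint
  maximizes the LD interruption between the two halves). Simulation is
  delegated to the msprime coalescent engine via a bundled helper, with
  ms-format text as the interchange, so any ms-compatible simulator's
  output can be substituted.
* **Disease models.** Causal variants are chosen among the rare set
  (pooled MAF $\le 0.05$ except where a model varies the threshold):
  models A–C take a uniformly random half of the rare variants as risk
  variants (thresholds 0.05/0.04/0.06); model D makes all rare variants
  causal, half risk and half protective; models E and F repeat A and D
  and add one low-frequency risk variant, the variant with pooled MAF
  closest to 0.10 above the threshold. Models G and H split the rare
  variants into positional thirds and make only the middle third causal
  (all risk for G; half risk, half protective for H). When counts do not
  divide evenly, the middle tier receives the remainder first and risk
  receives the extra over protective — the only allocation consistent
  with the reference counts across all three regions. Effect sizes
  decrease with frequency: whole-region models use per-allele OR
  1.5 / 1.7 / 2.0 for MAF $> 0.01$, $[0.001, 0.01]$, $< 0.001$;
  sub-region models use 1.7 / 2.0 / 2.2 on the same bins; protective
  ORs are exact reciprocals.
* **Phenotypes.** Genetic effects are multiplicative per allele on the
  *odds* of disease: individual $i$ has odds $c \prod_j OR_j^{g_{ij}}$
  over the causal variants, hence case probability
  $cR_i/(1+cR_i)$, with $c$ calibrated by bisection so the pool-mean
  case probability equals the 10% target prevalence to within
  $10^{-6}$ (with no causal variants $c$ is exactly the prevalence
  odds). The odds scale is the natural home of an odds-ratio
  parameter, and it matters here: coalescent rare alleles are
  concentrated on shared clade haplotypes, so a few individuals carry
  many causal alleles. Compounding odds keeps their case probability
  below 1 smoothly, whereas compounding probabilities (with a cap at
  1) turns such clades into certain cases, roughly doubling the trait
  variance explained by the same ORs and smearing association signal
  over every variant the clade carries, region-wide. Studies sample
  200 cases and 200 controls
  uniformly from the realized groups; variants that happen to be
  monomorphic in a sample are retained in the matrix and dropped by
  the tests.
* **Trait variance.** The information content of a scenario is
  summarized by the Nagelkerke pseudo-$R^2$ of the causal set,
  $(1-(L_0/L_1)^{2/N})/(1-L_0^{2/N})$, computed on a phenotype draw for
  the whole pool. The likelihood is maximized by a damped-Newton
  logistic fit on a sparse design: at $10^5$ subjects by $\sim$200
  mostly-zero columns with quasi-separating singleton variants, dense
  IRLS is both slow and oscillation-prone, so the implementation uses
  sparse cross-products with Levenberg damping and is verified against
  `stats::glm` on dense problems.

### What the generator does and does not emulate

The pools are neutral-coalescent: no natural selection, no demographic
history (bottlenecks, growth), no sequencing error or genotype
uncertainty, and no pooled-DNA read model. Passing tests therefore show
that the statistic and its corrections behave as designed under
exchangeable labels and realistic allele-frequency spectra and LD — they
do not certify behavior under population stratification or differential
genotyping error, which the permutation argument does not cover.

## Evaluation conventions

* **Type I error** is the fraction of null-replicate p-values strictly
  below $\alpha$, with an exact binomial CI.
* **Power at empirical $\alpha$** thresholds alternative p-values at the
  lower $\alpha$-quantile (the $\lfloor \alpha n \rfloor$-th order
  statistic) of the null p-values, so methods with different
  finite-sample calibration are compared at the same realized error
  rate. Null replicates are pooled across regions when a pooled
  threshold is requested.
* **Localization rate** is the fraction of replicates whose best window
  (tie sets included) half-overlaps the causal sub-region; replicates
  without a causal sub-region count as failures.
* Window sizes analyzed in fewer than 700 replicates (because long
  windows exceed some replicates' variant counts) are excluded from
  per-size summaries.

## Numerical and design choices

* Empirical p-values use `#\{>=\}/n`; the step-down comparison against
  column minima uses strict `<`, as the procedure is defined. Both
  choices interact: together they reproduce the slightly liberal null
  behavior expected of this construction.
* Minor-allele orientation is fixed by the pooled sample before
  permutation; flipping any variant's 0/2 coding leaves every statistic
  and p-value bit-identical (asserted).
* Monomorphic variants have undefined weights and are dropped before
  analysis; all-missing variants count as monomorphic.
* All randomness flows through user-supplied integer seeds; a fixed
  seed reproduces pools, annotations, samples, permutation matrices and
  hence every p-value bit-exactly. Engine seeds are kept below
  $2^{31}$.
* Problem sizes in the packaged studies: the null calibration and
  family-wise error studies run 300 replicates of 200 + 200 subjects at
  $B_1 = B_2 = 1000$; the variant-yield study averages 20 engine
  draws. These sizes put two binomial standard errors at roughly
  $\pm 0.025$ on a rate of 0.05, which is the precision the packaged
  checks assert.
* The localization study runs 200+ replicates at window size 10 spread
  over several (four to six) independent region realizations. A single
  realization's localization rate is dominated by its clade structure:
  when one mid-frequency haplotype clade happens to carry many rare
  causal alleles, its carriers are near-certain cases and every
  variant private to the clade — wherever it sits in the region —
  shows a large frequency difference, which ties the best-window set
  across a wide span. Single-realization rates consequently vary
  several-fold under identical parameters. Averaging over
  realizations estimates the study design's localization rate rather
  than one draw's.

## Known limitations

* Binary phenotypes only; no covariates, no kinship or stratification
  adjustment, no quantitative-trait extension.
* Functional-annotation weights are accepted conceptually by the
  framework (any positive weight vector) but no annotation-derived
  weighting scheme is provided.
* The permutation argument assumes exchangeable subjects under the
  null; confounded designs need a different inferential tool.
* Window sizes are counts of SNVs; base-pair- or LD-based windows are
  not implemented.

## A worked example

```{r example, eval = FALSE}
pool <- simulate_region(region_params(n_diploids = 5000), seed = 1)
ann <- assign_causal(pool, sim_model("G"), seed = 2)
c0 <- calibrate_baseline(pool, ann, prevalence = 0.10)
study <- sample_case_control(pool, ann, c0, 200, 200, seed = 3)

scan <- dmaf_scan(study$genotypes, study$status,
                  window_sizes = c(10, 30), flavor = "abs",
                  B1 = 1000, B2 = 1000, seed = 4)
summary(scan)
localize(scan$results[["10"]],
         causal_index_range(scan$variant_ids,
                            colnames(pool$genotypes)[ann$causal]))
```
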
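# dmafscan

Region-based case-control association testing for sequence variants with
the **D**ifference in **M**inor **A**llele **F**requency (DMAF) statistic,
plus a sliding-window scan that localizes the association signal within a
region while controlling the family-wise error across windows.

## Who this is for

Statistical geneticists analyzing candidate genes, pathways or resequenced
regions where causal variants are rare, may act in both directions
(risk *and* protective), and may cluster in an unknown sub-region — the
setting where single-variant tests are powerless and same-direction burden
tests cancel themselves out.

## The method

For variant $j$, let $X_j$ and $Y_j$ be the minor allele frequencies in
cases and controls (minor allele oriented by the pooled frequency
$q_j \le 0.5$). The region statistic over the variant set $A$ is

$$V = \sum_{j\in A} w_j D_j,\qquad D_j = |X_j - Y_j| \text{ or } (X_j-Y_j)^2,
\qquad w_j = \frac{1}{\sqrt{n_j q_j(1-q_j)}},$$

with $n_j$ the number of genotyped subjects. Because $D_j$ is positive,
risk and protective variants both add signal; the weights up-weight rare
variants. Significance comes from permuting case/control labels
($p = \#\{V_{\text{perm}} \ge V_{\text{obs}}\}/n_{\text{perm}}$).

The sliding-window scan tests windows of $k$ consecutive variants
(step $\max(5, 0.1k)$) and corrects across the windows of each size with a
Westfall–Young step-down procedure: a first set of shared permutations
gives each window its null distribution and raw p-value; a second set
fills an $m \times B_2$ p-value matrix whose column minima calibrate the
ordered observed p-values. A companion simulation framework (coalescent
haplotype pools, multiplicative disease models A–H with MAF-dependent odds
ratios, 10% prevalence calibration) supports power, type I error and
localization studies.

## A worked example

Simulate a 50-kb region pool, plant causal variants in the middle third of
the rare variants (model G), draw a 200 + 200 case/control study, and scan:

```r
library(dmafscan)

pool  <- simulate_region(region_params(n_diploids = 5000), seed = 1)
ann   <- assign_causal(pool, sim_model("G"), seed = 2)
c0    <- calibrate_baseline(pool, ann, prevalence = 0.10)
study <- sample_case_control(pool, ann, c0, 200, 200, seed = 3)

scan <- dmaf_scan(study$genotypes, study$status, window_sizes = c(10, 30),
                  flavor = "abs", B1 = 1000, B2 = 1000, seed = 4)
scan
#> Sliding-window DMAF_abs scan: 131 analysis variants (all)
#>   permutations: B1 = 1000, B2 = 1000; alpha = 0.05
#>   size  10:  26 windows, min corrected p = 0 at variants 56-65  *
#>   size  30:  22 windows, min corrected p = 0 at variants 46-75  *

localize(scan$results[["10"]],
         causal_index_range(scan$variant_ids,
                            colnames(pool$genotypes)[ann$causal]))
#> [1] TRUE
```

The pool realized 169 polymorphic variants (122 rare), model G made 41 of
them risk variants spanning pool indices 57–112, and the scan flags both
window sizes (`*` marks corrected p < 0.05). The best 10-SNV window
(variants 56–65 of the 131 analyzed) half-overlaps the causal sub-region,
so this replicate counts as localized.

For real data, `read_vcf()` + `read_phenotype()` feed the same functions,
and a command-line wrapper is installed at
`system.file("cli", "dmaf.R", package = "dmafscan")` with subcommands
`test`, `scan`, `simulate-region`, `simulate-study` and `evaluate`.

## Vignette

`vignettes/dmaf-methods.Rmd` documents the statistic, the step-down
construction, the disease models and their parameterization, the
numerical choices (tie handling, rounding, calibration tolerances), and
what the simulation framework does and does not emulate.
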
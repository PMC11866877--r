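# nipaired

Non-inferiority inference for the risk difference from binary matched-pairs
data in which single observations may be missing.

In a matched-pairs design every patient receives two interventions and
contributes a pair of binary outcomes `(y1, y2)`. The parameter of interest
is the risk difference `theta = P(y1 = 1) - P(y2 = 1)`, and non-inferiority
of intervention 1 is the one-sided hypothesis test

    H0: theta <= -delta   vs.   H1: theta > -delta

for a clinically chosen margin `delta > 0`. Throughout, the test at
one-sided level `alpha` is carried out through the uniform decision rule
*reject H0 when the lower bound of the two-sided `100*(1-2*alpha)%`
confidence interval exceeds `-delta`*, so all interval methods are compared
on the same decision surface.

In practice one outcome of a pair is sometimes missing (never both — such
records carry no information and are rejected on input). `nipaired`
implements four interval methods that differ in how they use the
incomplete pairs:

| method | function | uses incomplete pairs? |
|---|---|---|
| Score test (Nam) / score CI (Tango) with restricted-MLE variance | `nam_test()`, `tango_ci()` | no (complete cases only) |
| Multiple-imputation Wald CI with Rubin's rules | `mi_ci()` | yes (imputed) |
| Hybrid Wald CI from back-solved Wilson bounds (Tang et al.) | `hybrid_ci()` | yes (margin estimates) |
| GEE marginal logistic model, sandwich covariance, delta-method CI | `gee_ci()` | yes (singleton clusters) |

plus a correlated-pair simulator (`joint_from_marginals()`,
`generate_pairs()`, `impose_missing()`), a Monte-Carlo study harness
(`scenario()`, `run_scenario()`, `scenario_grid()`, `run_grid()`), and both
asymptotic (`nam_power()`, `nam_samplesize()`) and simulation-based
(`sample_size_search()`) sample-size routines.

## Worked example

Aggregated data enter as the eight observable cells of the 3x3 table: the
four complete-pair cells `n00, n01, n10, n11` (first index = outcome under
intervention 1), `n0x, n1x` for pairs whose second outcome is missing, and
`nx0, nx1` for pairs whose first outcome is missing.

```r
library(nipaired)

tab <- paired_table(n00 = 34, n01 = 8, n10 = 14, n11 = 38,
                    n0x = 2, n1x = 6, nx0 = 1, nx1 = 5)
tab
#> Binary matched-pairs table (108 patients, 94 complete pairs)
#>    y2
#> y1   0  1 x
#>   0 34  8 2
#>   1 14 38 6
#>   x  1  5 0

nam_test(tab, delta = 0.10)
#> Score test of non-inferiority, H0: theta <= -0.1
#>   theta_cc = 0.063830, statistic = 3.0674, one-sided p = 0.00108
#>   non-inferiority concluded at one-sided alpha = 0.05 (complete pairs: 94)

tango_ci(tab)
#> Tango score (RMLE) 90% CI for the risk difference
#>   estimate: 0.063830   interval: [-0.019060, 0.148456]   n used: 94

set.seed(1); mi_ci(tab)
#> Multiple-imputation Wald 90% CI for the risk difference
#>   estimate: 0.056481   interval: [-0.026203, 0.139166]   n used: 108

hybrid_ci(tab)
#> Hybrid Wilson-based Wald 90% CI for the risk difference
#>   estimate: 0.058627   interval: [-0.019424, 0.135288]   n used: 108

ci <- gee_ci(tab)
ci
#> GEE delta-method 90% CI for the risk difference
#>   estimate: 0.061123   interval: [-0.018772, 0.141017]   n used: 108
noninferior(ci, delta = 0.10)
#> [1] TRUE
```

Pair-level data work the same way: every function that takes a
`paired_table` also accepts a data frame with columns `y1`, `y2` (0, 1 or
`NA`), and `tabulate_pairs()` / `read_pairs()` convert explicitly.

### Design: power and sample size

```r
# asymptotic score-test calculation for a paired design with marginals 0.8,
# concordant-pair probability 0.8 (rho = 0.375), margin 0.05:
nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05)
#> [1] 507

# the complete-case method discards every patient with a missing outcome,
# so 20% single-observation missingness inflates it to ceiling(507/0.8):
nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05, p_missing = c(0.1, 0.1))
#> [1] 634

# the MI and GEE methods keep those patients; their requirement is found by
# simulation (conservative rule: smallest n whose estimated power exceeds
# the target at that n and every larger grid value):
sample_size_search("gee", n_grid = seq(560, 640, 2), rho = 0.37,
                   delta = 0.05, p_miss1 = 0.1, p_miss2 = 0.1,
                   n_sim = 10000, seed = 1)
```

### Monte-Carlo studies

```r
sc <- scenario(n = 507, rho = 0.37, delta = 0.05, theta = 0, n_sim = 10000)
run_scenario(sc)        # power / coverage / width per method, with MCSEs
grid <- scenario_grid() # the full 468-scenario default grid
# run_grid(grid, seed = 1)
```

## Command-line interface

A thin executable wrapper is installed at `inst/cli/nipaired`:

```sh
Rscript inst/cli/nipaired tango --table counts.csv --delta 0.05
Rscript inst/cli/nipaired simulate --n 200 --p1 0.8 --p2 0.8 --rho 0.37 \
    --miss1 0.1 --miss2 0.1 --seed 7 --out pairs.csv
Rscript inst/cli/nipaired samplesize nam --rho 0.375 --delta 0.05
Rscript inst/cli/nipaired power --default-grid --nsim 10000 --out results.csv
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "nipaired",
                   load_package = "installed")
```

The suite checks the implementations against independent oracles (dense-grid
score inversion, `glm()` fits, brute-force per-cluster GEE accumulation,
Wilson quadratic roots, exact small-table enumeration) plus
scaled-down Monte-Carlo reproductions of the study results. See
`vignettes/methods.Rmd` for the statistical background and for the known
small-sample caveats of the Wald-type intervals.
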
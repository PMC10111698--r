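# mfpdx

Multivariable fractional polynomial (MFP) model building for continuous
outcomes, with case-deletion influence diagnostics for *function
selection*.

## The problem

When building a descriptive regression model from observational data, two
decisions interact: which covariates to keep, and what functional form to
give the continuous ones.  Fractional polynomials handle the second
decision with a small, fixed class of candidate shapes: FP1 functions
$\beta x^{p}$ and FP2 functions $\beta_1 x^{p_1} + \beta_2 x^{p_2}$ with
exponents from $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (0 meaning $\log x$;
repeated powers $(p,p)$ use $x^p$ and $x^p \log x$) — 8 FP1 and 36 FP2
candidates, 44 in all.  The **function selection procedure (FSP)** is a
closed test: best FP2 vs. null (4 df), vs. linear (3 df), vs. best FP1
(2 df), each on the $\chi^2$ scale of the Gaussian deviance difference
$n\log(\mathrm{RSS}_r/\mathrm{RSS}_f)$, stopping at the first
non-significant step.  **MFP** cycles this test over all covariates,
interleaved with backward elimination, until the model stops changing.

Selected functions can hinge on one or two observations: a single
high-leverage point can make FP2 "significantly" better than FP1.  The
package's diagnostics delete every observation (and optionally every pair
— $\binom{250}{2} = 31{,}125$ deletions at $n=250$), re-search the FP
grids from scratch on each reduced dataset via the exact OLS case-deletion
identity, and flag observations whose removal changes the significance
status of any FSP test against the tabulated thresholds (9.488 / 7.815 /
5.991 at $\alpha = 0.05$; 13.277 / 11.345 / 9.210 at $\alpha = 0.01$).
Univariable (screen, remove, then select) and multivariable (select, then
screen within the model) pipelines are provided, plus a calibrated
synthetic-data generator with a fully known true model for studying
replicability and sample-size effects.

## Worked example

```r
library(mfpdx)

d <- simulate_art(250, seed = 29)   # known true model, sigma^2 = 0.49

m <- mfp(d, "y",
         continuous = c("x1", "x3", "x5", "x6", "x7", "x10"),
         binary     = c("x2", "x4a", "x4b", "x8", "x9a", "x9b"))

scan <- fp_influence(d, "y", "x6", d = 1)
scan
#> Case-deletion scan for `x6`: 250 deletion(s) of size 1 (n = 250)
#> full-data deviance differences: fp2_null=13.023, fp2_linear=9.157, fp2_fp1=1.881
#> flagged at 0.05: 42

fsp(d, "y", "x6")
#> Function selection for `x6` (n = 250)
#>   FP2 vs null:   p = 0.011
#>   FP2 vs linear: p = 0.027
#>   FP2 vs FP1:    p = 0.390
#>   decision: FP1(0)

fsp_drop(d, "y", "x6", ids = 42)
#> Function selection for `x6` (n = 249)
#>   FP2 vs null:   p = 0.011
#>   FP2 vs linear: p = 0.118
#>   FP2 vs FP1:    p = -
#>   decision: linear
```

Reading this: on the full data the closed test selects a log function for
`x6` (FP2 vs. linear significant at 0.027, FP1 adequate thereafter).  The
leave-one-out scan shows that deleting observation 42 drops the
FP2-vs-linear deviance difference from 9.157 to 5.87, below the 7.815
threshold — the evidence for non-linearity rests on that single
observation, and without it a plain linear term is chosen.  `autoplot(scan)`
draws the three deviance-difference panels with both threshold lines;
`ip_univariable()` / `ip_multivariable()` automate screening and refitting;
`tidy()` and `glance()` give tabular access to every result.

A thin command-line wrapper with subcommands `simulate`, `fsp`, `mfp`,
`ip-loo`, `ip-pairs` and `report` lives at `inst/cli/mfpdx.R`; the
vignette (`vignettes/mfp-influence.Rmd`) documents the methods and every
numerical convention.

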
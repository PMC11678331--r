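# floralreg

Regression modeling of floral induction by FT-like florigen genes.

## The problem

In temperate legumes such as the narrow-leafed lupin *Lupinus
angustifolius*, flowering is triggered when FT-like genes (*FTc1*, *FTa1*,
*FTc2*, *FTa2*) — each an integrator hub for photoperiod, vernalization and
circadian signals — activate the meristem identity gene *AGL8* (the
*AP1*/*FUL* ortholog). Loss-of-function mutants for these genes are not
available, so the contribution of each regulator must be inferred from
expression data alone. `floralreg` is for researchers who have
condition-stratified qRT-PCR time courses (mean ± s.d. per sampling term,
split by vernalization and time of day) and want to ask: *which FT-like
genes are essential for AGL8 activation, and under which conditions?*

## The method

*AGL8* expression is modeled as a condition-stratified linear combination of
FT-like inputs,

    AGL8 = c0(block) + c1(stratum) * h(FT inputs, t)

with a separate intercept `c0` per vernalization × daytime block, regulatory
coefficients stratified by vernalization, and a family of regulator terms
`h`: the cumulative sum (M1), major-regulator and gene-specific splits
(M2, M3), squared/exponential/logarithmic responses (M4–M6) and a
time-modulated sum (M7). In-silico knockouts H0–H5 drop genes from M1's sum
to emulate mutants at constant parameter count.

Fits minimize the block-weighted cost

    F = sum over blocks [ RSS(block) / sum(sigma^2 of block) ]

by Nelder–Mead, started at (and verified against) the closed-form weighted
least-squares solution, over an ensemble of datasets resampled from the
interpolated mean ± s.d. curves. Structures are compared by small-sample
AIC, `AICc = 2k + F_min + (2k^2+2k)/(m-k-1)`; knockouts are screened by
paired Wilcoxon tests of the per-replicate `F` distributions plus mean-F
ratios and block-level defect diagnostics. A synthetic-data generator with
known ground truth makes every stage testable end to end.

## A worked example

Screen regulator knockouts on a generated dataset whose ground truth has
*FTc1* as the sole driver of *AGL8*:

```r
library(floralreg)
r <- run_knockout_analysis("Ku_like_SD", n_samples = 100, seed = 1)
r$comparison
#>   model mean_F ratio_vs_baseline   p_value signif
#> 1    H0  5.952            1.0000 1.000e+00
#> 2    H1  5.952            1.0000 6.661e-01
#> 3    H2  5.953            1.0002 3.815e-01
#> 4    H3  5.950            0.9997 3.179e-01
#> 5    H4 27.846            4.6784 3.956e-18     **
#> 6    H5  5.951            0.9999 7.478e-01
```

Excluding the true driver (H4, *FTc1* knocked out) inflates the mean cost
4.7-fold with overwhelming significance, while excluding any dispensable
gene (H1–H3) or keeping only the driver (H5) leaves the fit at the full
model's level — exactly the signature used to call a regulator essential.
The block diagnostics localize the damage:

```r
r$diagnostics$H4
#>       block      rss   sum_var contribution flagged
#> 1 V.morning 64.93935  8.493826     7.645477    TRUE
#> 2 V.evening 64.95926 11.245011     5.776719    TRUE
#> 3 N.morning 18.63686  2.634996     7.072823    TRUE
#> 4 N.evening 18.64185  3.783156     4.927591    TRUE
```

Every block's contribution exceeds twice the full model's, flagging a
global pattern defect rather than a condition-specific one. See the
vignette (`vignettes/modeling-floral-induction.Rmd`) for the model family,
estimation details and the generator's scenarios.

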
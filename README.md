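# dabquant

Semiquantitative analysis of brightfield DAB immunohistochemistry for
Paneth-cell DEFA6 expression in intestinal mucosa, with a synthetic slide
generator for ground-truth validation.

Necrotizing enterocolitis (NEC) is a severe intestinal disease of premature
neonates; diminished Paneth-cell DEFA6 is a candidate piece of its
pathophysiology. Comparing DAB-stained sections across patients is
confounded by strongly varying mucosal height and by batch-dependent
staining intensity. `dabquant` addresses both with two per-sample
statistics computed inside a mucosal region of interest (ROI):

* **Expression per micrometre of mucosa.** With ROI area `A` (μm²) and mean
  mucosal height `h̄` (μm, over ten representative sites), the mucosal
  "length" is `L = A / h̄` and

  ```
  expr/μm = total inverted DAB intensity in ROI / L
  ```

* **Percent DAB-positive area**, `100 · |ROI ∩ DAB⁺| / |ROI|`, robust to
  absolute staining intensity.

DAB detection is explicit optical-density color deconvolution
(Beer–Lambert: `OD_c = −log10(I_c / I0_c)`, per-pixel inversion of the
stain matrix) rather than an opaque brown-pixel classifier; the
conventional H-DAB stain vectors are the default and everything is
configurable through `run_config()`. Groups are compared by two-sample
t-tests (pooled by default, Welch alongside) and per-group age
correlations. Since the original patient slides are not publishable, the
package ships a seeded synthetic slide generator whose ground truth
(per-pixel DAB concentration, true mucosal length, true positive area) is
exact, plus the 12-infant cohort metadata table (`nec_cohort()`).

## Worked example

Simulate a 12-subject cohort with a 60% DAB reduction in the NEC-like
group, quantify every slide under one shared configuration, and compare the
groups:

```r
library(dabquant)

cohort <- generate_cohort(n_nec = 8, n_control = 4, effect_size = 0.6,
                          base_spec = synthetic_slide_spec(), seed = 20260923)
tab <- cohort_results_table(cohort, run_config())
report <- compare_groups(tab)
report$tests[report$tests$variant == "pooled", c("statistic", "mean_nec", "mean_control", "t", "df", "p")]
```

The same analysis, file-based, is the `analysis/` workflow
(`01_simulate.R` writes TIFF/ROI/heights bundles, `02_quantify.R` runs
`run_analysis()` over them, `03_validate.R` runs the validation battery).
Running it prints:

```
true DAB OD per um: NEC-like mean 0.254, control-like mean 0.607
expr_per_um: NEC mean 35.48 vs control mean 153.4, t = -20.375, df = 10, p = 1.789e-09
pct_area: NEC mean 0.3439 vs control mean 1.148, t = -6.750, df = 10, p = 5.045e-05
```

i.e. the simulated NEC-like group shows markedly lower DEFA6 signal under
both evaluation methods — expression per μm of mucosa and percent
DAB-covered area — mirroring the direction of the clinical finding the
method was built to assess. Individual p-values vary with the seed; the
calibration of the tests themselves is part of the validation battery.

Gestational-age bookkeeping follows the weeks+days convention:

```r
format(ga_add_days(gestational_age(23, 2), 50))
#> "30+3"   # birth at 23+2, surgery on postnatal day 50
```

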
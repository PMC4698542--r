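# blotmc

Quantification and inference for multi-group Western-blot panels of synaptic
proteins: band **densitometry** from gel images, two-stage **blot
normalization** with a GAPDH loading-control check, **contrast indices** of
receptor-subunit and excitation/inhibition balance, and a
**parametric-bootstrap Monte-Carlo** group comparison with percentile
confidence intervals — the statistical workflow of small-n (n = 6–8) animal
cohort studies that probe a dozen proteins across several experimental
groups. A synthetic-data module generates band tables and 16-bit gel images
with known truth, so the whole chain is testable without tissue data.

## The method in brief

- **Densitometry.** For a rectangular band ROI of width *w*,
  `D = (1/w) Σ max(I(x,y) − b̂, 0)`, where `b̂` is the median of the
  surrounding pixel frame (margin 3 px, other bands excluded).
- **Normalization.** Per protein: divide by the mean of the blot set (blots
  run together), then by the pooled control-sample band on the band's own
  blot (cancelling the blot-batch factor exactly), then scale so the normal
  group's mean is 1.
- **Contrast index.** For a functional pair (A, B): `(A − B)/(A + B)`,
  computed within animal — e.g. presynaptic E/I = (VGLUT1 − VGAT)/(VGLUT1 +
  VGAT).
- **Comparison.** From the reference group's mean and SD, simulate a normal
  population of 10⁶ points; draw comparator-sized samples 10,000 times; the
  central 95% percentile interval of the resulting means is the
  significance band for the comparator's observed mean, with a two-sided
  empirical p-value floored at 1/reps. The full ordered reference ×
  comparator matrix is reported (one CI column per reference group).

## Worked example

```r
library(blotmc)

cfg <- study_config(design = default_design(seed = 20260925L),
                    mc = mc_config(pool_size = 1e6, reps = 1e4),
                    seed = 20260925L)
res <- run_study(cfg)
print(res)
#> blotmc study result
#>   groups:      fluoxetine, fluoxetine_MD, MD, normal
#>   measures:    18 (13 proteins, 5 indices)
#>   QC:          pass
#>   significant: 130 of 216 non-self comparisons at alpha = 0.05

print(subset(res$comparisons, measure == "VGLUT1" & reference == "normal" & !self,
       c(comparator, observed, ci_low, ci_high, p_empirical, significant)),
      row.names = FALSE)
#>     comparator  observed    ci_low  ci_high p_empirical significant
#>     fluoxetine 0.7166534 0.9266661 1.072947      0.0001        TRUE
#>  fluoxetine_MD 0.8857643 0.9248221 1.074796      0.0024        TRUE
#>             MD 1.2318740 0.9152792 1.085059      0.0001        TRUE
```

The simulated study (28 animals, 4 blots, batch SD 0.2) recovers its
designed effects: fluoxetine's VGLUT1 loss (true effect 0.71, observed
0.72) and MD's gain (true 1.25, observed 1.23) fall far outside the
normal-seeded 95% band and are flagged — the two largest at the smallest
reportable empirical p (1/reps = 1e-4). `res$comparison_table` reshapes the matrix
into the familiar layout — one row per measure × comparator, one CI column
per reference group — and `write_results(res, dir)` writes the full bundle
as tab-delimited text plus a provenance record.

The `analysis/` scripts run the same chain as a narrated workflow
(`01_simulate` → `02_densitometry` → `03_normalize` → `04_indices` →
`05_compare` → `06_calibration`), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # ... through analysis/06_calibration.R
```

See `vignettes/blot-panel-analysis.Rmd` for the model, the defaults and
their rationale, and a calibration analysis of the Monte-Carlo procedure
(exactly calibrated with known reference parameters; anti-conservative when
seeded from an n = 6 estimated reference — a faithfully reproduced property
of the emulated analysis).

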
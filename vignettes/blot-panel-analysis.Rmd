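---
title: "Quantifying multi-group Western-blot panels: densitometry, normalization and Monte-Carlo comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-group Western-blot panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small-cohort animal studies routinely quantify a panel of proteins by
Western blot across several experimental groups — here, a four-group design
(normally reared adult rats n = 6, chronic fluoxetine n = 8, one week of
monocular deprivation n = 6, fluoxetine + MD n = 8) probed for 12
glutamatergic/GABAergic synaptic proteins plus GAPDH. Getting from scanned
membranes to defensible group comparisons involves four coupled steps, each
of which `blotmc` implements and tests:

1. **densitometry** — band intensity from an image region;
2. **normalization** — making bands comparable across blots and runs;
3. **contrast indices** — bounded balance statistics between functional
   protein pairs;
4. **group comparison** — a parametric-bootstrap Monte-Carlo test with
   percentile confidence intervals.

Because raw tissue data are not available, a synthetic-data module generates
band tables (and gel images) with known truth; every downstream stage is
validated against that truth or an independent oracle.

## Forward model of the measurement

For animal $a$ in group $g$, protein $p$, on blot $b$, lane $\ell$:

$$
\mathrm{raw}(a,p) \;=\; s_p \,\mu_{gp}\, e_{ap}\, B_b\, L_{b\ell},
$$

where $\mu_{gp}$ is the true mean as fold-of-normal, $e_{ap}$ is a
between-animal effect, normal with mean 1 and SD $\sigma_{gp}/\mu_{gp}$
truncated to be positive by resampling, $B_b \sim \exp(N(0,
\sigma_B))$ is a blot-batch factor shared by every lane of a blot,
$L_{b\ell} \sim \exp(N(0, \sigma_L))$ is a lane loading factor shared by
every protein in a lane, and $s_p$ is the antibody gain (default 1). Each
blot carries one pooled control-sample lane whose expected level is the
panel average for each protein, mirroring the practice of loading a pooled
aliquot of all samples on every membrane.

Defaults are the study conditions: effects are the printed percent changes
(e.g. VGLUT1: fluoxetine 0.71, MD 1.25, fluoxetine+MD 0.87), and
between-animal SDs are reconstructed from printed SEMs as
$\sigma = \mathrm{SEM}\sqrt{n}$ (VGLUT1 fluoxetine:
$0.030\sqrt{8} \approx 0.085$). Cells without a printed change sit at the
null, effect 1.0 with SD 0.10 — a conservative filler consistent with "no
significant difference". GAPDH has effect 1.0 everywhere by construction.
Nuisance defaults, chosen once as realistic for chemiluminescent/infrared
blots: $\sigma_B = 0.2$ (batch), $\sigma_L = 0.05$ (pipetting), 28 animals
dealt round-robin over 4 blots in 2 blot sets, one blot replicate per animal
× protein (replication is configurable; the truncated-normal noise model is
the same normality assumption the comparison procedure itself makes).

The linear-scale truncated-normal choice has one visible consequence: for
the largest coefficient of variation in the default panel
(GABA$_A\alpha$1, fluoxetine+MD: SD 0.57 at mean 1.24) truncation lifts the
realized mean by ≈1.7% above the nominal effect. Tests that check recovery
of design truth therefore aggregate bias across the panel rather than
asserting per-cell equality.

## Densitometry

A band is a rectangular ROI (0-based, half-open pixel coordinates). The
background is the **median of the surrounding frame** (default margin 3 px),
excluding pixels that belong to other registered ROIs — the vendor
software's exact background rule is unpublished, so this robust, local,
deterministic stand-in is used and documented as such. The density is

$$
D \;=\; \frac{1}{w}\sum_{(x,y)\in \mathrm{ROI}} \max\{I(x,y) - \hat{b},\, 0\},
$$

the background-subtracted pixel integral divided by the ROI width $w$ (the
lane-width direction), to control for lane-width variation. Per-pixel
clipping at zero keeps densities non-negative and bounds speckle influence;
it also makes $D$ non-increasing in $\hat b$. Note the arithmetic
consequence of width normalization: two bands with equal per-unit-width
signal agree, while spreading a fixed total over a wider lane lowers $D$
proportionally.

The synthetic renderer draws each band as a 2-D Gaussian bump truncated to
its ROI and scaled so the ROI integral is exactly $D\,w$, on a constant
background; the round trip render → quantify is exact to floating point,
and within 0.1% after 16-bit TIFF quantization at realistic gains. Tests
compare the implementation against a deliberately naive double-loop pixel
oracle, exactly on integer images and to 1e-9 relative on float images.

## Normalization

Two ratio stages, per protein, then fold-of-reference scaling:

1. **blot-set average**: divide each band by the mean of all same-protein
   bands in its blot set ("blots run at the same time"). The average is per
   protein, not pooled across proteins, because antibody gains differ by
   orders of magnitude.
2. **control sample**: divide by the (equally normalized) pooled
   control-sample band of the same protein on the band's own blot.
3. **fold of reference**: scale so the reference (normal) group's mean is
   exactly 1 for each protein.

The order of the first two stages is not observable: both are ratios, and
algebraically the set mean cancels once the control ratio is taken, so the
final values equal `raw / control` rescaled — which is also why the blot
batch factor $B_b$ cancels *exactly* (the control lane shares it). The
chosen order is fixed and recorded in the table's provenance attribute.
Multiplying any one blot by an arbitrary constant leaves the output
bit-identical; across 50 simulations with batch SD up to 0.3 the mean
absolute systematic bias of recovered group means is below 1%. The price of
the control-lane ratio is that the control lane's own loading noise enters
all bands of its blot as a shared factor.

GAPDH is used for **QC only** (not as a per-lane divisor, which the
two-stage scheme already makes unnecessary): each group is compared with the
reference on the control protein using the same Monte-Carlo procedure, and
QC passes iff nothing is significant at $\alpha$. A QC failure is reported
and recorded but does not abort the run. Summaries use the $n-1$ sample SD
and SEM $= s/\sqrt{n}$.

## Contrast indices

For a functional pair $(A, B)$ the contrast index is $(A-B)/(A+B)$: 0 at
balance, bounded by $\pm 1$, antisymmetric, scale-invariant, strictly
increasing in $A$. The five default definitions are AMPAR–NMDAR
(GluA2, GluN1), NMDAR subunits (GluN2A, GluN2B), GABA$_A$ subunits
($\alpha$1, $\alpha$3), presynaptic E/I (VGLUT1, VGAT) and postsynaptic E/I
(PSD-95, gephyrin). Indices are computed **within animal** (the source
protocol does not say whether per-animal or on group means; per-animal is
the default because group comparisons of an index need per-animal
dispersion), then summarized and compared exactly like proteins.

## The Monte-Carlo comparison

For reference group $r$ (mean $m_r$, SD $s_r$) and comparator $c$
(size $n_c$, observed mean $\bar x_c$):

1. simulate a pool of `pool_size` points from $N(m_r, s_r)$
   (default $10^6$; the procedure is insensitive to pool size from $10^5$
   up, which settles the ambiguous printed figure "1,00,000" operationally);
2. draw $n_c$ points from the pool with replacement and average; repeat
   `reps` = 10,000 times;
3. the central 95% **percentile interval** of those means is the
   significance band (percentile construction chosen because the decision
   rule compares an observed mean against the simulated distribution);
   boundary values count as inside;
4. $c$ differs from $r$ when $\bar x_c$ falls outside; the two-sided
   empirical p-value is $2\min(\Pr(\le), \Pr(\ge))$, floored at
   $1/\mathrm{reps}$ (zero exceedances cannot justify $p = 0$) and capped
   at 1.

The full ordered matrix is computed — every (reference, comparator) pair in
both directions, self-comparisons flagged — giving the familiar table shape
with one CI column per reference group. No multiple-testing correction is
applied (none is applied in the emulated analysis); the comparison count is
recorded alongside.

### Calibration, and an honest caveat

With *known* reference parameters the procedure is exactly calibrated: for
$N(1, 0.15)$ and $n_c = 8$ the measured null rejection rate over 2,000
replications is ~5%, and the empirical CI half-width matches
$1.96\,s/\sqrt{n_c}$ within Monte-Carlo tolerance.

Applied to *estimated* summaries — the study situation — the procedure
treats the reference sample mean and SD as truth. The observed difference
$\bar x_c - \bar m_r$ has variance $\sigma^2(1/n_c + 1/n_r)$, but the
interval only spans $\sigma^2/n_c$; the effective two-sided threshold is
$1.96\sqrt{(1/n_c)/(1/n_c+1/n_r)} \approx 1.28$ for $n_r = 6$, $n_c = 8$,
inflated further by the $n_r - 1 = 5$ d.f. noise in $s_r$. The measured
per-comparison type-I rate at study scale is ~20–24% (and the GAPDH QC,
three comparators deep, false-alarms on roughly 40% of null runs). This is
a property of the emulated procedure itself, reproduced faithfully; the
package reports it rather than repairing it, and the calibration suite pins
both numbers. Power for the large designed effects is unaffected in
practice (VGLUT1 fluoxetine-vs-normal: ~100%). Users wanting nominal error
rates should use Welch-type intervals; that is deliberately out of scope
here.

## Numerical and implementation choices

- Percentile interval via `stats::quantile` type 7 (the default
  interpolation); with 10,000 reps the interpolation choice moves bounds by
  well under the Monte-Carlo noise.
- One master seed per run drives table simulation and every comparison in
  sequence, so whole result bundles are byte-identical across runs; the
  matrix is seeded once, not per cell.
- `sd = 0` degenerates cleanly: point pool, point interval, observed equal
  to the mean counts as inside, $p$ capped at 1.
- Rendered images are kept as doubles in memory; 16-bit quantization happens
  only on TIFF write, and intensities must fit `[0, 65535]` (errors
  otherwise). Image quantization adds at most 0.5 per pixel, negligible at
  realistic gains.
- Degenerate inputs error with names (unmapped lanes, missing control
  bands, unknown group labels, groups of size < 2, undefined index at
  $A+B=0$).

## Problem sizes used by the tests and scripts

The validation suite runs 100-ROI oracle checks, full-panel round trips,
50-simulation bias studies, 2,000-replication calibration, and 150–200-run
power studies with per-comparison pools of $5\times 10^4$–$10^6$; these
sizes put Monte-Carlo noise an order of magnitude below every asserted
tolerance while keeping the whole suite inside a coffee break.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the analysis assumes:
multiplicative batch and loading nuisance, normal between-animal variation,
a condition-invariant loading control, a pooled control sample. It does not
model antibody binding kinetics, chemiluminescence saturation or other
detector nonlinearity, membrane-stripping losses, spatially structured
backgrounds, band-shape irregularities, or molecular-weight ladders.
Passing tests therefore demonstrate that the pipeline's algebra and
inference behave as specified under the assumed noise model — not that the
assumed model captures every failure mode of real membranes.
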
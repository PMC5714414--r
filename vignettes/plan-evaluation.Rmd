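---
title: "Evaluating arc-therapy plans from dose-volume histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating arc-therapy plans from dose-volume histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

planrad evaluates and compares external-beam radiotherapy plans using only
their dose-volume histograms (DVHs). This vignette is the package's
methodological account: the models implemented, the parameters that matter,
the conventions chosen where several were defensible, what the synthetic
cohort generator does and does not emulate, and the numerical decisions a
careful user should know about.

## The DVH model

A cumulative DVH samples `V(D)`, the fraction of a structure receiving at
least dose `D`, on a strictly increasing dose grid starting at 0 Gy with
`V(0) = 1`. The differential form gives the volume fraction `v_i` per dose
bin centred at `D_i`, with `sum(v_i) = 1`. Volumes are held internally as
relative fractions; absolute cm^3 appear only at the file boundary, where a
`total_volume_cm3` header converts. Doses are Gy everywhere (cGy files are
converted on read), and all doses are *total physical course doses*: no
linear-quadratic or EQD2 correction is applied anywhere in the package, a
deliberate modelling simplification that users fitting fractionation-
sensitive endpoints should keep in mind.

Conversion between the two forms is exact differencing, not smoothing:
`v_i = V(d_i) - V(d_(i+1))` at the bin-centre dose, with any residual
volume at the last sample absorbed into the top bin so the fractions always
sum to one. The inverse reconstructs edges midway between centres. On a
uniform grid the two maps are mutual inverses to 1e-9, which the test suite
checks property-style over randomized DVHs; on non-uniform grids the
reconstructed edges are not the original ones and only volume conservation
is guaranteed. Planning-system exports carry float noise, so cumulative
monotonicity violations up to a relative 1e-6 are clamped; anything larger
is rejected with the offending row named.

## Point metrics and their tie-breaks

All metric extraction is linear interpolation in (dose, volume); no splines,
so monotone inputs give monotone, hand-checkable outputs.

* `Dx%` is the dose where the cumulative curve crosses `x/100` coming down.
  Two conventions needed fixing because real curves have flat segments: an
  *interior* run sitting exactly at the target returns the run's lower dose
  (conservative and reproducible), while a *leading* plateau at the target -
  the `x = 100` case - returns the plateau's end, which is the structure's
  minimum dose and the clinically meaningful D100.
* `VxGy` is `100 * V(d)`, 100 at zero dose and 0 beyond the last sample.
* `max_dose()` is DVH-derived: the dose where `V` crosses `epsilon_volume`
  (default 0). Planning systems usually report a 3D point maximum instead;
  the two can differ by the export bin width, and the package makes no
  attempt to emulate a point dose. The `epsilon_volume` argument gives the
  common "near-max" variants (e.g. the D at 1% volume).
* `mean_dose()` is `sum(v_i * D_i)` of the differential form; supplying a
  cumulative DVH converts first, so the two representations agree within
  half a bin width.

The default evaluation sheet for a 78 Gy prostate plan is PTV D99% >= 74.1
Gy (95% of prescription), rectum and bladder D30% <= 70 Gy and D50% <= 53
Gy, and femoral-head D5% <= 53 Gy.

## Tumour control probability

Control follows a two-parameter logistic in dose,
`TCP(D) = exp(p + qD) / (1 + exp(p + qD))`, parameterised clinically by
`D50` and the normalised slope `gamma50`. The mapping is the standard logit
algebra: the logistic slope at its midpoint is `q/4`, so
`q = 4 * gamma50 / D50` and `p = -4 * gamma50`, making `TCP(D50) = 0.5`
exact and the normalised slope at `D50` equal to `gamma50` (both verified by
finite differences in the tests). A heterogeneous dose distribution is
scored by the tumorlet product over differential-DVH bins,
`TCP = prod_i TCP(D_i)^(v_i)`, i.e. sub-volumes are assumed to be
controlled independently and the whole volume is controlled only if every
tumorlet is. Two consequences are used as tests: a uniform DVH recovers the
uniform-dose logistic exactly, and splitting a bin into sub-bins at the
same dose changes nothing. Accumulation happens in log space so a cold
tumorlet cannot underflow the product.

The shipped defaults, `D50 = 67.5` Gy and `gamma50 = 2.0`, are a
conventional prostate adenocarcinoma set from pooled clinical dose-control
summaries. They are configuration with documented defaults - not physical
constants - and any reported TCP should be read as conditional on them.

## Rectal NTCP: Lyman model with Kutcher-Burman reduction

Complication probability uses the Lyman probit with the power-law volume
dependence: `NTCP = Phi(t)`, `t = (D - TD50(v)) / (m * TD50(v))`,
`TD50(v) = TD50(1) * v^(-n)`. Defaults are the conventional late-rectal
set `TD50(1) = 80` Gy, `m = 0.15`, `n = 0.12`. A heterogeneous DVH is first
reduced to the Kutcher-Burman effective volume at the maximum dose bin,
`veff = sum_i v_i * (D_i / D_ref)^(1/n)`, which is invariant under common
dose scaling and collapses to the irradiated fraction for uniform partial
irradiation - the closed-form `lyman_ntcp_uniform()` is kept as a separate
code path precisely so the two routes can be cross-checked to 1e-12.
`ntcp()` returns `veff`, `D_ref`, `TD50(v)` and `t` alongside the
probability so every reported NTCP is auditable. A DVH with no irradiated
volume returns NTCP 0 with a `degenerate` flag rather than NaN. Only the
rectum is scored by default: bladder and femoral-head complication
probabilities are orders of magnitude smaller at these dose levels and add
noise, not signal, to a technique comparison.

## Cohort comparison conventions

Plan records are tidy rows (patient, technique, structure, metric, value).
Cohort summaries use the arithmetic mean and the sample SD (n - 1), the
small-cohort convention. Percent change is always
`100 * (double - single) / single` *between cohort means* (ratio of means),
which is how planning studies quote "on average X% lower"; mean-of-ratios
per patient is a different statistic and is not the default. Pairing is
enforced: every patient must appear under both techniques or the comparison
aborts naming the offenders. Text rendering rounds to one decimal (monitor
units to integers); CSV/JSON keep full precision and the JSON document
round-trips to an identical report.

## What the synthetic generator emulates

The generator produces seeded cohorts with the statistical structure the
analysis assumes, so the whole pipeline is testable without patient data.
Its fidelity target is *summary statistics*, not curve shapes: the
reference five-patient summary (bundled as `prostate_vmat_summary()`)
supplies the target means and SDs, and curve families were chosen for
exact steerability:

* **Targets (PTV).** A probit fall-off `V(D) = Phi((Dc - D)/sigma)` with
  `(Dc, sigma)` solved in closed form from the requested D99% and maximum
  dose (`V(dmax) = 1e-3`, where the grid is truncated). Both metrics are
  recovered to well under half a bin.
* **Overlap OARs (rectum, bladder).** A fraction `f` of the organ sits in
  the target-overlap region and receives near-prescription dose (probit at
  `overlap_dose`, width 1 Gy); the remainder sees a stretched-exponential
  bath `(1-f) * exp(-(D/tau)^k)`. Given requested V17Gy/V35Gy, `f` is
  root-solved and `tau` follows in closed form. A plain exponential tail
  (`k = 1`) cannot satisfy the bundled V17/V35 pairs with a positive
  overlap fraction, which is why the shape parameter exists; `k = 1.6` is
  the default, raised per draw to the smallest feasible value when an
  extreme draw needs it (`adapt_tail`). The double-arc rectal overlap is
  centred 0.6 Gy hotter than the single-arc one, encoding the mechanism by
  which the second arc trades anterior-posterior dose for lateral dose and
  concentrates the rectal high-dose region.
* **Lateral OARs (femoral heads).** No overlap; `(k, tau)` of the
  stretched exponential are solved from the requested D5% and maximum dose.

Between-patient variation uses one latent standard-normal effect per
(patient, structure), *shared between the two techniques* of a patient -
plans re-optimised on the same anatomy are strongly paired, and independent
draws would wash out small technique contrasts that the paired design
resolves. The effects are jittered stratified quantiles (a Latin-hypercube
design in one dimension): they tile the quantile range, so even a
five-patient cohort realises each configured mean closely while keeping
realistic spread. Monitor units are fixture constants of the reference
cohort, not simulated; MU and delivery time are delivery properties outside
a DVH model.

What passing tests therefore show: the pipeline recovers configured
coverage/volume metrics to 0.1 Gy / 1 percentage point, and reproduces the
direction of every reference technique contrast, including a higher rectal
NTCP for the technique with the hotter overlap region. What they do not
show: anything about spatial dose distributions, point maxima, conformity
indices, plan optimiser behaviour, or metrics the curve families do not
calibrate (e.g. the PTV mean dose and the overlap-OAR maximum dose track
their targets only approximately, and extreme latent draws can push an
overlap fraction above 30%, putting a D30% into the high-dose plateau).

## Numerical choices and degenerate inputs

* Default DVH bin width 0.1 Gy, a typical planning-system export
  resolution; all grids start at 0 Gy.
* Interpolation is linear everywhere; ties on exactly flat segments follow
  the rules above.
* The logistic is evaluated through `plogis` and the probit through
  `pnorm`, both numerically stable; probit arguments beyond |t| = 8
  saturate to within 1e-15 of 0/1.
* Root solves (`uniroot`) for generator calibration run at tolerance
  1e-12 on provably bracketing intervals; infeasible requests
  (`dmax <= d99`, `v35 >= v17`, a shape too shallow without adaptation)
  raise classed infeasibility errors rather than producing distorted
  curves.
* Differential fractions are renormalised to sum exactly to 1 after
  validation at 1e-9; zero-dose bins carry no weight in `veff` and the
  tumorlet product skips zero-volume bins.

Problem sizes in the shipped tests were chosen for sharp statistics at
interactive runtimes: property loops run 10-25 randomized DVHs per
invariant, generator closure uses 200 seeded draws per metric family, and
end-to-end checks use the default five-patient cohort.

## Known limitations

Physical course doses without fractionation correction; DVH-resolution
maxima rather than point doses; TCP/NTCP values conditional on literature
parameter sets rather than institution-fitted ones; no DICOM-RT ingestion
(the CSV dialect plus manifest is the interface); no statistical testing
between techniques (five patients support direction checks, not inference);
and the generator's curve families are phenomenological - they reproduce
summary statistics, not the anatomy-driven shapes of real DVHs.
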
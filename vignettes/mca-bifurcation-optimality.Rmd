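---
title: "Minimum-work optimality and aneurysm risk at the MCA bifurcation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-work optimality and aneurysm risk at the MCA bifurcation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcabif)
```

## The scientific question

The principle of minimum work predicts that an arterial bifurcation
minimising the energetic cost of circulation satisfies the cube law
`r0^3 = r1^3 + r2^3` between the parent-trunk radius and the two branch
radii, and that the branches leave the trunk axis at angles fixed by the
radii alone. A bifurcation's departure from this optimum — a junction
exponent below 3, branch angles wider than predicted — has been proposed as
a geometric risk factor for saccular aneurysm formation. This package
implements that analysis for the middle cerebral artery (MCA) bifurcation
as a case-control pipeline: aneurysmal bifurcations against non-aneurysmal
controls, with morphometric and Doppler-hemodynamic indices as candidate
predictors.

## Per-bifurcation indices

Given canonical radii (`r1 >= r2`; `canonicalize()` enforces this, keeping
the measured trunk-branch angles paired with their branches and preserving
input order on exact ties):

* **Junction exponent.** The unique positive root of
  `f(n) = (r1/r0)^n + (r2/r0)^n - 1` when `r0 > r1`; `f` is strictly
  decreasing from 1, so plain bisection on `[1e-3, n_cap]` is a safeguarded
  solver. Defaults: tolerance `1e-10` on `|f|`, cap `n_cap = 20`. The cap
  matters because `n` diverges as `r0` approaches `r1` from above; published
  group SDs of the exponent (up to ±1.5) imply such near-singular
  bifurcations occur, and a capped status is more honest than a huge
  finite number. `r0 <= r1` has no positive root and is flagged
  `no_solution`; both non-`ok` statuses are excluded from group summaries
  and counted in the report's exclusion block.
* **Shape ratios.** Asymmetry `r2^2/r1^2` in (0, 1] under canonical
  labeling; area ratio `(r1^2 + r2^2)/r0^2`. Both scale-invariant.
* **Observed angles.** The measured trunk-branch angles `beta`, `gamma`
  open between trunk and branch; the analysis works with their
  complements from the trunk-axis prolongation, `Phi1 = 180 - beta`,
  `Phi2 = 180 - gamma`, plus the inter-branch angle `alpha`. All angles are
  carried in degrees end to end; radians appear only inside `acos` calls.
* **Optimal angles.** Both rule families are triangle solutions: sides
  `(r0, r1, r2)` for the minimum-surface / minimum-endothelial-drag rules,
  sides `(r0^2, r1^2, r2^2)` for the minimum-volume / minimum-pumping-power
  rules. A cosine argument outside `[-1, 1]` means the radii admit no
  interior optimum under that rule; the package returns NA with a validity
  flag rather than clamping, because clamping would fabricate a 0° or 180°
  "optimum" the theory does not support. Arguments within `1e-12` of ±1
  are accepted as boundary geometry. The two flags are independent: a
  triple can satisfy the radius triangle inequality yet fail it on squares.
  Degeneracy behaves one power apart: the surface-rule total collapses to
  0° as `r0 -> r1 + r2`, the volume-rule total collapses to 0° as
  `r0^2 -> r1^2 + r2^2` and passes through 90° exactly where
  `r0^4 = r1^4 + r2^4`.
* **Doppler indices.** `PI = (Vps - Ved)/Vm`;
  `VFR = Vm * p0/100` with the trunk cross-section tabulated in mm² and
  flow in cm³/s — the division by 100 is the single mm→cm conversion in the
  package, fixed here because it reproduces the published flow magnitudes
  (≈4 cm³/s).

### The weighted-Fermat oracle

The closed-form optima are cross-checked by an independent numerical
construction: three fixed endpoints in the plane and the junction position
`J` minimising `sum_i w_i |J - X_i|` with `w_i = r_i^k` (`k = 1` for the
surface rules, `k = 2` for the volume rules), found by Weiszfeld iteration
from the endpoint centroid (derivative-free; stops when `J` moves < 1e-10).
The optimum is interior only when the branch endpoints subtend a
sufficiently narrow angle at the parent endpoint — for squared weights the
optimal total angle can be small, and a wide placement parks the optimum on
an endpoint. The oracle therefore tries a shrinking schedule of subtended
angles (150° down to 2°, with seeded jitter) and accepts the first
solution whose weighted force-balance residual `|sum_i w_i e_i|/sum_i w_i`
is below `1e-7` with all endpoint distances positive — an interiority
certificate that does not reference the closed forms under test. Tests
require agreement within 0.1° across random radii and seeds.

## The synthetic cohort

Patient-level data are unavailable, so `default_table1_specs()` encodes the
published per-group summary statistics — sample sizes 102 / 82 / 88 / 87
and mean ± SD for radii, cross-sections, tortuosity, the three observed
angles, mean velocity, VFR and PI — and `generate_cohort()` draws from
them.

* **Distributional form.** Truncated normal per parameter. Only means and
  SDs are published (and the original data were non-normal enough to
  motivate nonparametric tests), so normal marginals are the minimal
  assumption; the resulting discrimination metrics land close to the
  published AUCs, which is the calibration the pipeline relies on.
* **Truncation.** Physiologic bounds: radii > 0.3 mm, areas > 0.3 mm²,
  inter-branch angle in (5°, 179°), branch-axis angles in (1°, 175°),
  velocities > 5 cm/s, PI > 0.05, VFR > 0.1 cm³/s. Tortuosity is an
  undefined pass-through index (its published definition is not given) and
  is left unbounded rather than truncated at zero, which at mean 0.06 and
  SD 0.04-0.07 would bias its moments noticeably. Note the (5°, 179°)
  bound sits only ~2 SD above the aneurysmal-group mean `alpha`
  (128.6 ± 24.2), giving an analytic mean shift of about −1.1°; this is
  visible in large-sample summaries but moves the case-control AUC by
  < 0.005. The generator-recovery test therefore disables truncation (a
  per-parameter spec field) to measure sampler fidelity to the
  specified moments; pipeline runs keep the physiologic defaults.
* **Two modes.** `marginal` (default): every parameter drawn
  independently; the drawn `vfr` and `pi` columns travel with the table
  and are used directly by the discrimination stage. This mode exists
  because the published mean VFR (4.42 cm³/s in the aneurysm group)
  exceeds the product of the mean velocity and mean cross-section
  (≈4.31), implying a positive vm-p0 correlation whose magnitude is not
  recoverable from the publication. `mechanistic`: draws geometry and
  velocity (optionally correlated via `rho_vm_r0`) and derives
  `p0 = pi * r0^2` and `VFR = vm * p0/100`, keeping hemodynamics and
  geometry internally consistent for pipeline stress-tests; in this mode
  `r0` and `vm` are clamped at their lower bounds rather than redrawn, to
  preserve the requested correlation.
* **Canonical relabeling.** Branch draws are swapped where `r2 > r1`
  (areas swap along), so individual branch columns are order statistics of
  the two marginals; their pooled sample keeps the mixture moments exactly,
  which is how the recovery test checks them.
* **What the generator does not emulate.** Within-row correlations
  (radii-angle, velocity-calibre, left-right pairing within a patient) are
  absent unless requested; the derived junction exponent consequently has
  a wider spread and a smaller case-control gap than the published one
  (≈2.4 vs 2.85 with ≈20% non-`ok` rows in marginal draws). Passing tests
  therefore demonstrate pipeline correctness and calibration of the
  drawn-marginal discriminators (`alpha`, VFR), not that the generator
  reproduces every joint feature of the real cohort — in particular,
  junction-exponent retention in the final model is not a stable property
  of the synthetic cohort even though it was of the real one.

## The inference stage

* **Group comparisons.** Mann-Whitney U for the five published pairwise
  contrasts per parameter; U is computed from midranks (pairs + half-ties),
  with exact enumeration when the pooled size is ≤ 12 without ties and the
  tie-corrected normal approximation with continuity correction otherwise.
  Paired predicted-vs-observed contrasts use the Wilcoxon signed-rank test
  with the same exact-path rule. No multiplicity adjustment is applied —
  p-values are reported raw, matching the original analysis style.
* **Case-control definition.** Cases are the aneurysmal bifurcations
  (n = 102); controls the pooled right + left control groups (n = 175); the
  contralateral non-aneurysmal group is excluded from the fit. The source
  publication leaves this pooling unstated; this reading reproduces the
  published `alpha` AUC almost exactly (binormal check: 0.851 vs 0.848) and
  is therefore adopted — and kept configurable (`case_groups`,
  `control_groups`).
* **Variable selection.** The published rule, not a generic stepwise:
  univariate entry at `p < 0.1`, then within any retained pair with
  `|r| > r_max` the larger univariate p drops (tie: the later in input
  order). `r_max` defaults to 0.5 — no threshold is published, so every
  drop is written to an audit log to keep the choice transparent.
  Bifurcations are treated as independent observations (two rows may share
  a patient), matching the original unit of analysis.
* **ROC.** Thresholds at midpoints between consecutive unique pooled
  scores; AUC by trapezoid, which equals Mann-Whitney U / (n1·n2) exactly,
  ties counted half — an identity asserted on every tested input. Youden's
  J picks the cut-off, ties toward the smallest threshold. Markers with a
  negative univariate coefficient (junction exponent, PI) are sign-flipped
  before the ROC so higher score always calls a case; the reported cut-off
  is mapped back to the original scale.
* **Tables 2/3 row set.** Predicted-vs-observed summaries and deviation
  summaries are computed on the rows where *both* rule families are valid,
  so the deviation means equal predicted-minus-observed means exactly
  (linearity of the mean); per-rule exclusion counts are reported
  alongside. Whether the original analysis excluded invalid-geometry rows
  is unstated.
* **Deviations for the primed family.** The primed observed angles are
  nowhere separately defined, so primed deviations are taken against the
  same observed `Phi1`, `Phi2`, `alpha` as the unprimed ones.

## Problem sizes and determinism

Everything is seeded and deterministic: identical `(specs, seed, mode)`
give byte-identical cohorts, and identical `(cohort, config)` give
byte-identical report JSON (no timestamps in the payload). The calibration
stage uses 500 replicate cohorts of the published sizes (277 case-control
rows each), which stabilises the replicate means of AUC and OR to ±0.003
(3 SE) — adequate against acceptance bands of ±0.02-0.03. The recovery
check uses 10⁴ rows per group; the null-calibration check of the
Mann-Whitney size uses 10⁴ replicates at n = 25 + 25.

## Known limitations

* Marginal independence is a deliberate simplification; any analysis of
  predictors that are *derived* from several drawn columns (junction
  exponent, ratios) inherits extra variance relative to the real cohort.
* Tortuosity is carried but never computed (no published definition).
* The logistic stage reports Wald intervals; with 102/175 observations and
  the published effect sizes these are accurate, but near-separation rows
  are flagged rather than refitted (no penalised fallback).
* No within-patient random effects: the contralateral design is expressed
  only through subject-id linkage in the generator.
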
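---
title: "Measuring trueness and precision of complete-arch implant scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trueness and precision of complete-arch implant scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanmetry)
```

## The measurement problem

Digital impressions of an edentulous arch with multiple implants are the most
demanding use case for intraoral scanners: the prosthesis spans the whole
arch, so cross-arch dimensional errors accumulate and a misfitting framework
cannot simply be adjusted. The standard in-vitro assessment mounts scan
bodies — posts of deliberately simple geometry, a cylinder with a planar top —
on the implant analogues of a master model, scans the model repeatedly with
each device, and reduces every scan to a small set of unambiguous landmarks.

`scanmetry` implements that reduction and the statistics on top of it:

1. **Feature fitting.** For each scan body, contact points labeled
   *cylinder* (outer wall, 8 by default) and *plane* (top face, 6 by default)
   are fitted by orthogonal least squares: `fit_plane()` minimizes squared
   orthogonal point–plane distances (solved exactly by SVD of the centered
   cloud), and `fit_cylinder()` minimizes
   $\sum_i (\operatorname{dist}(p_i, \text{axis}) - r)^2$ by Gauss–Newton.
2. **Pierce point.** `pierce_point()` intersects the fitted cylinder axis
   with the fitted top plane. This point — the scan body *centroid* — is the
   unit of all downstream measurement.
3. **Distances.** `pairwise_distances()` computes all
   $\binom{k}{2}$ Euclidean inter-centroid distances;
   `classify_distances()` labels pairs adjacent in the scan progression
   *short* and the remaining cross-arch pairs *long* (for bodies 1–4:
   short = D1–2, D2–3, D3–4; long = D1–3, D1–4, D2–4).
4. **Accuracy.** *Trueness* compares each of the $m = 10$ repeated scans
   with a coordinate-measuring-machine (CMM) style reference
   (`trueness_errors()`, signed and absolute errors in µm); *precision*
   compares the repeated scans among themselves — all
   $\binom{m}{2} = 45$ absolute pairwise differences per distance
   (`precision_errors()`). Statistics are computed on absolute values so
   that errors of opposite sign cannot cancel; the signed errors are kept
   because their mean answers a different question (systematic bias).
5. **Inference.** Per metric, absolute errors are Box-Cox transformed and
   modeled as `error ~ scanner * distance_group` under sum-to-zero
   contrasts with Type-III tests (`fit_accuracy_lm()`), followed by
   Tukey-adjusted pairwise comparisons of the scanners' estimated marginal
   means within each distance group and a compact letter display
   (`tukey_posthoc()`).

## Geometric fitting: parameterization and numerics

The cylinder has five effective parameters. We remove the gauge freedom along
the axis by constraining the axis point to the plane through the point-cloud
centroid orthogonal to the current axis; the Gauss–Newton update then acts on
two axis-point offsets, two direction tilts (in a local orthonormal frame
rebuilt every iteration) and the radius. Steps are backtracked until the
objective decreases, so the returned fit never has a larger residual than its
initialization; convergence is declared when the relative step norm falls
below $10^{-10}$ (at most 200 iterations; non-convergence is returned
explicitly in the `converged` flag, never silently).

Initialization matters for so few points. Inside `extract_centroids()` the
cylinder is initialized with the fitted top-plane normal — the scan body's
top face is orthogonal to its axis by construction. A standalone
`fit_cylinder()` call without an initialization tries all three principal
directions of the point cloud and keeps the best converged fit; with two
narrow rings of wall points, the smallest-scatter direction alone can be the
radial one, so a single-candidate start is not reliable.

The plane fit is closed-form (the normal is the smallest right singular
vector of the centered points) and is tested against an independent
eigen-decomposition of the scatter matrix to $10^{-12}$. Normal orientation
follows a fixed convention (non-negative $z$ component, ties broken toward
$+x$ then $+y$). Degenerate inputs — fewer than 4 points, collinear points,
a radius collapsing to zero, an axis parallel to the top plane — raise typed
errors rather than returning garbage.

All geometry is computed in mm; errors are converted to µm only when accuracy
records are built, and the report layer rounds to 0.1 µm only when writing
summary CSVs.

## The reference and its uncertainty

The reference instrument is modeled as a CMM with maximum permissible length
error $\mathrm{MPE}(L) = 3.5\,\mu m + L/250$ ($L$ in mm; `cmm_mpe()`). The
synthetic reference measures each true distance `cmm_replicates = 10` times
with zero-mean Gaussian noise of SD $= \mathrm{MPE}/3$ — the bound read as a
$\approx 3\sigma$ statement — and averages the replicates; whether the
pipeline compares against this CMM-style reference or against the exact
analytic truth is a switch (`reference = "cmm"` / `"truth"`). Averaging the
replicates (rather than picking one) is the package's default.

## What the synthetic generator emulates — and what it does not

`make_master_model()` builds a deterministic idealized master: four scan
bodies (radius 3 mm, top face 10 mm above the base) at the right molar,
right canine, left canine and left molar positions of a mandibular arch,
axes tilted 1° at staggered azimuths so all mutual angles stay within 2°.
The true master distances of the published study are not printed anywhere,
so the default layout is an anatomically plausible synthetic stand-in:
short distances $\{20, 16, 20\}$ mm and long distances
$\{\approx 32.3, \approx 32.3, 40\}$ mm, which puts every short pair below
every long pair.

`scanner_model()` injects three error mechanisms:

* **scale bias** $s$: distances inflated by exactly $1 + s$ (scaling about
  the arch centroid), the signature of a global calibration error;
* **stitching drift**: the body at progression step $k$ is rigidly displaced
  by the sum of $k$ i.i.d. Gaussian steps (SD in µm per step). This random
  walk is the mechanism that reproduces the study-design signature that
  cross-arch (long) distances degrade more than adjacent (short) ones: the
  displacement difference between steps $k$ and $l$ has variance
  proportional to $|k - l|$;
* **point noise**: isotropic Gaussian noise on every contact point.

The nine default scanner models (`default_scanner_models()`) — two
laboratory-grade, seven intraoral-grade — were fixed once to span mean
absolute errors from roughly 10 µm to above 150 µm across the two distance
groups, the range reported for this device class. They are package defaults,
not estimates of any particular commercial device.

Not emulated: scanner optics (confocal/triangulation physics), soft tissue,
saliva and operator effects, tilted-implant scenarios, and mesh-level
artifacts — the generator produces labeled contact points (plus optional
tessellated STL meshes), not photorealistic scans. Passing tests therefore
validate the measurement and inference chain, not any claim about a real
device's accuracy.

## Statistical choices

* **Box-Cox.** Absolute errors can be exactly 0, so a fixed offset of
  +0.5 µm is added before transforming (configurable). When $\lambda$ is not
  supplied it maximizes the profile log-likelihood over the grid
  $[-3, 3]$ in steps of 0.01, profiled against the full
  scanner-by-group design matrix; one $\lambda$ is estimated per metric
  (trueness, precision), since each metric enters a single linear model in
  which distance group is a factor — estimating per group would split the
  response of one model. The in-package profile search is cross-checked
  against `MASS::boxcox` in the test suite.
* **Type-III tests.** `car::Anova(type = 3)` under sum-to-zero contrasts.
  With a balanced design these coincide with sequential sums of squares
  (property-tested to $10^{-8}$). Both the $F$ form and the Wald chi-square
  form ($\chi^2 = F \cdot \mathrm{df}$) of each test are emitted so either
  reporting style can be reproduced. The degrees of freedom are pure
  functions of the design — for $S$ scanners, two groups and $N$ records:
  scanner $S-1$, group $1$, interaction $S-1$, residuals $N - 2S$. At the
  published design size ($S = 9$, $N = 540$ trueness / $2430$ precision
  records) this gives residual df 522 and 2412.
* **Dependence caveat.** The 45 precision comparisons per distance share the
  10 underlying scans and are therefore mutually dependent; the linear model
  nevertheless treats them as observations, replicating the field's standard
  analysis. The residual df of 2412 should be read with that in mind.
* **Post hoc.** Estimated marginal means via `emmeans`, all scanner pairs
  within each distance group, Tukey-adjusted. The compact letter display is
  computed in-package by greedy insert-and-absorb with letters ordered by
  ascending group mean (ties alphabetical); the defining property — two
  scanners share a letter *iff* their adjusted $p \ge \alpha$ — is checked
  exhaustively in the tests.
* **Calibration simulations.** The type-I error check simulates lognormal
  absolute errors under a null of no scanner effect and fixes $\lambda = 0$
  (the exactly normalizing transform) so that the nominal level of the
  $F$-test is the quantity measured; $\lambda$ estimation quality is tested
  separately (lognormal recovery within 0.15 of 0 at $n = 500$).

## Worked example

```{r example, eval = FALSE}
master <- make_master_model()
study <- simulate_study(master, default_scanner_models(),
                        n_scans = 10, seed = 42)
res <- run_pipeline(study, out_dir = "results")

res$fits$trueness          # ANOVA table, Box-Cox lambda
subset(res$summaries$trueness, group == "long")  # Table-style summary + letters
```

The result bundle carries the full-precision distance table, the long-format
accuracy records, descriptive summaries (median, IQR, mean, SD per scanner
and group, with Tukey letters and a >150 µm annotation flag), the two ANOVA
tables and the post hoc contrasts. `run_pipeline()` is deterministic: rerun
with the same study object it writes byte-identical CSVs.

## Problem sizes and reproducibility

The package's own validation runs at the published design size where that is
what is being checked (9 scanners × 10 scans for the design arithmetic;
500 simulations for test calibration; 200 replicates for the drift-variance
ordering) and at reduced sizes elsewhere (e.g. 300–400 Monte-Carlo
replicates for moment checks), chosen so the whole suite runs in about a
minute. Every stochastic check fixes its seed; simulation studies derive
per-scan substreams from one master seed by fixed offsets so any single scan
is independently reproducible.

## Known limitations

* The minimum-zone (Chebyshev) fitting criterion used by some CMM software
  is not implemented; fitting is least-squares throughout, consistent with
  the touch-probe standards the protocol follows.
* Cylinder fits from exactly 6 points are accepted but flagged
  (`few_points`); with so little redundancy the fit is sensitive to the
  point layout.
* Angular deviations between implant axes, best-fit surface superimposition
  and clinical fit verdicts are out of scope; the 150 µm threshold appears
  only as an annotation flag on the summaries.
* Synthetic master distances are placeholders, not the (unpublished) true
  master dimensions; per-device results are not reproducible from this
  package and are not claimed.
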
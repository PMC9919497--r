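---
title: "Quantifying epithelialization and polarization along the presomitic mesoderm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelialization and polarization along the presomitic mesoderm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmet)
```

## The biological measurement problem

During somitogenesis, cells of the presomitic mesoderm (PSM) undergo a
gradual mesenchymal-to-epithelial transition (MET): they elongate, acquire
apico-basal polarity, and assemble into the epithelial walls of somites.
Because the PSM is a spatiotemporally ordered tissue — caudal positions are
developmentally younger — a snapshot of cell shape along the rostro-caudal
axis is a proxy for the time course of MET. `psmet` turns that idea into a
reproducible pipeline:

1. **Cell shape.** Manually traced 2D cell outlines are reduced to an
   aspect ratio (AR), the ratio of the cell's longest to shortest
   dimension.
2. **Axis normalization.** Each section's PSM is straightened along a
   midline and positions are rescaled so the posterior tip is 0% and the
   PSM–somite border 100% (somite levels continue above 100%).
3. **Domains.** Cells are assigned to tissue domains — dorsal, ventral,
   medial, lateral surfaces, or the never-epithelializing core.
4. **Onset profiles.** Per domain, the response (AR, or a polarity index)
   is regressed on axis position with a sigmoid, and two onset landmarks
   are extracted.
5. **Time rescaling.** DiI time-lapse tracks convert axis position into
   hours remaining before the corresponding material segments.

A synthetic-data generator with known ground truth stands in for the raw
microscopy, so every stage is testable end to end.

## Aspect ratio from polygon moments

For a closed polygon with vertices $(x_i, y_i)$ we compute area, centroid
and the area-covariance matrix analytically with Green's theorem (no
rasterization), and define

$$\mathrm{AR} = \sqrt{\lambda_1 / \lambda_2},$$

the axis ratio of the second-moment ellipse, where $\lambda_1 \ge
\lambda_2$ are the covariance eigenvalues. This matches the standard
fitted-ellipse AR shape descriptor of interactive image-analysis tools, is
exactly 1 for circles and $w/h$ for rectangles, and is invariant under
rigid motion and uniform scaling. Because "longest/shortest dimension" is
ambiguous for concave cells, the max/min caliper (Feret) ratio is exposed
as an alternative (`aspect_ratio(..., method = "feret")`); the two agree on
convex shapes and diverge on concave ones, so analyses should state which
was used. The test suite checks the moment implementation against an
independent 10× supersampled rasterization oracle (agreement within 1% on
random star polygons).

## Axis straightening and domain assignment

The midline is supplied as a polyline from the posterior tip to the
PSM–somite border (for synthetic sections it is generated alongside the
cells). Each centroid is projected orthogonally onto the midline; position
is the projection's arc length rescaled to 0–100% per embryo, which
removes between-embryo differences in absolute PSM length. The signed
perpendicular distance (positive = dorsal) is kept as the transverse
offset. A centroid equidistant from two non-adjacent segments — possible on
strongly bent midlines — is deterministically assigned to the smaller arc
length, with a warning. Somite cells are placed at $100 + 10 s$ percent for
somite index $s$, purely for plotting continuity.

A cell is a *surface* cell when its outline touches a band inset from the
section's outer boundary. The band depth operationalises "a single layer of
cells" without tracking adjacency; it defaults to the median cell
minor-axis length and is configurable (`band_depth_px`). Surface cells are
then sectored: sagittal sections into dorsal/ventral by side; transverse
sections into four 90° sectors about the section centroid (rotatable via
`angle_offset_deg`); sagittal somite sections into
dorsal/ventral/anterior/posterior. Which image side is medial or anterior
is anatomy that pixels cannot supply, so it is a per-section configuration
flag. Ties at exact sector corners break in the fixed order dorsal >
medial > ventral > lateral. Everything not on the surface is core, so the
domains always partition the section.

## Sigmoid onset profiles and landmarks

Per domain, the response $y$ (AR or polarity delta) against position $x$ is
fitted with the four-parameter logistic

$$y = a + \frac{b - a}{1 + e^{-k (x - x_0)}}$$

by Levenberg–Marquardt least squares from a fixed 9-point start grid
($x_0 \in \{25, 50, 75\}$, $k \in \{0.05, 0.2, 0.5\}$, asymptotes from the
5th/95th response percentiles), keeping the best-RSS fit — deterministic
given the data. Two onset landmarks are reported: the inflection $x_0$ and
the position at 10% of the curve's height, which has the closed form
$x_{10} = x_0 - \ln(9)/k$ (verified against numeric root finding to
1e-8). Responses are fitted untransformed by default (`log_ar` in the run
configuration enables log-AR fitting).

Evidence for an onset is summarised by the nested F statistic against the
constant-mean model,

$$F = \frac{(\mathrm{RSS}_\text{flat} - \mathrm{RSS}_\text{sig})/3}{\mathrm{RSS}_\text{sig}/(n-4)},$$

with p from $F(3, n-4)$. **Caveat:** under a truly flat profile the
parameters $x_0$ and $k$ are unidentified, so this reference distribution
is approximate and anti-conservative — the achieved RSS reduction behaves
like the supremum of a chi-square process over $(x_0, k)$ rather than a
fixed 3-df drop. In practice the p-values separate flat from sigmoid
profiles by many orders of magnitude (genuine onsets in the default
synthetic fields give $p < 10^{-200}$, flat cores give $p$ of order 0.1–1),
but a flat-truth p-value should not be read as calibrated; treat small p as
descriptive, not inferential. Group contrasts (between domains within a
position bin, along the axis within a domain, left/right,
anterior/posterior) use Welch's t and Wilcoxon rank-sum tests, reporting
raw p alongside Holm-adjusted p.

## Polarity quantification

Transverse optical re-slices carry a PSM cross-section mask and an apical
reference point (the tissue centre). The mask's band is sectored like the
transverse domains; each sector is split into an apical (inner) and basal
(outer) half at the midpoint of the local band thickness, estimated per
angular bin as the mean of the minimal and maximal mask radius. The
polarity index is $\delta$ = apical mean − basal mean pixel intensity, so a
constant background cancels exactly, swapping the halves negates
$\delta$, and the mean (rather than sum) makes $\delta$ independent of
sector area (`stat = "sum"` is available). The split surface is the
parameter-free symmetric choice; no background subtraction or cross-embryo
normalization is applied by default. The mesenchymal core has no
apical/basal sides and is never analysed. Per-domain $\delta$ profiles
feed the same 4PL machinery.

## Position-to-time rescaling

A DiI-labelled cohort entering the caudal PSM is tracked over time; at each
timepoint the front-to-border distance, normalized by the concurrent PSM
length, gives the cohort's position in %. The trajectory is biphasic —
slow progression followed by acceleration to a constant rate — and is
fitted with a continuous two-segment piecewise-linear model, the breakpoint
chosen by exhaustive grid search over observed timepoints (minimum RSS).
The two-segment model must beat a single line in a nested F test
(2 extra parameters, α = 0.05), otherwise a single-phase map is returned,
flagged. Inverting the fitted trajectory expresses any position as hours
remaining before that material reaches the forming-somite border
(`position_to_time()`, 0 h at 100%), and `annotate_landmark_times()`
attaches these times to onset landmarks. The somite formation interval is
computed separately as duration/somites per embryo, cohort-averaged and
reported to the nearest minute.

## The synthetic generator: what it emulates, and what it does not

`synthetic_truth()` holds the generating parameters; its defaults are the
study conditions the pipeline targets:

| quantity | default |
|---|---|
| AR onsets $x_0$ (dorsal, medial, ventral, lateral) | 40, 55, 70, 70 % |
| AR asymptotes $a \to b$; slope $k$ | 1.5 → 6; 0.3 %⁻¹ |
| core AR | constant mean 2.2 |
| AR noise | lognormal, σ = 0.15 (multiplicative) |
| marker onsets | per-marker table, `default_marker_truth()` |
| polarity delta | 0 → 30 intensity units on baseline 20, pixel noise σ = 3 |
| cells per domain / slices | 600 / 40 |
| advection | 1 then 6 %/h, breakpoint 10 h, front noise 3% of PSM length |
| somite clock | 68 min/somite |

Lognormal AR noise keeps AR ≥ a and right-skewed, like real per-cell
scatter; σ = 0.15 was chosen once as a visually realistic spread and is
config-exposed. Cells are 24-vertex ellipse polygons placed tangentially in
their surface band (core cells tilted at random in the interior) — enough
to exercise the moment computation, band contact, sectoring and fitting,
but deliberately not realistic cell shapes: no protrusions, no packing, no
out-of-focus exclusions, no tracing error. Intensity slices are ideal
rings with sector-wise apical enrichment plus Gaussian noise. Passing the
recovery suites therefore shows the *pipeline* is correct and well
conditioned at realistic noise and sample sizes; it does not validate
segmentation of real images, which the pipeline deliberately leaves
upstream.

## Numerical and design choices

- Polygon moments are computed analytically; rasterization exists only as
  a test oracle. Polygons must be simple with positive area; readers
  reject offending records individually and report why.
- The ImageJ ROI-zip dialect stores 16-bit integer vertices (the format's
  own limit); the CSV dialect preserves doubles exactly (17 significant
  digits on write).
- Multi-start fitting is fixed-order with no randomness; ties in bin
  assignment go to the lower bin; sector corner ties follow a fixed
  priority; midline projection ties go to the smaller arc length. Given a
  seed, every generator output is byte-identical across runs.
- The 4PL is reported in canonical orientation ($b \ge a$); decreasing
  profiles carry $k < 0$ and a `"decreasing"` flag. Non-convergence from
  all starts yields a flat fallback flagged `"no_sigmoid"` (p reported
  as 1).
- Problem sizes used by the validation suites: onset-recovery uses 200
  replicate transverse fields at 600 cells/domain; F-test behaviour is
  profiled on 500 flat-truth replicates of 60 points; breakpoint recovery
  uses 100 tracks of 73 timepoints; these sizes give stable medians and
  coverage estimates while the full suite stays conveniently fast.

## Known limitations

- The sigmoid-vs-flat p-value is anti-conservative under flat truth (see
  above); rank orderings of onsets and the landmark positions themselves
  are the robust outputs.
- Straightening assumes the midline is supplied or derivable; it does not
  model out-of-plane curvature of real fractures.
- Domain assignment is geometric; anatomical landmarks (neural tube side,
  rostral direction) must be supplied per section.
- Polarity quantification assumes an annular epithelializing band around a
  single apical reference; it is not meaningful for the core, and slab
  averaging across slices is left to the caller.
- Between-embryo pooling is the default for profile fitting (cells from
  all embryos enter one regression); per-embryo stratification is
  available by grouping before `fit_domain_profiles()`.
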
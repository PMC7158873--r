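---
title: "Models and methods behind ortract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ortract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ortract)
```

`ortract` quantifies how an epilepsy-surgery resection relates to the optic
radiations: where the tract runs, what its microstructure looks like before
and after surgery, how much of it the resection transects, and whether that
transection predicts a visual field deficit. This vignette explains the
models and the choices made where the design was genuinely open. It states
no empirical result beyond what the package's own tests and acceptance
script compute.

## Containers and conventions

Volumes are dense 3-D arrays with a 4×4 affine mapping zero-based voxel
indices to world RAS millimetres (+X right, +Y anterior, +Z superior), the
NIfTI convention; I/O goes through RNifti. "Posterior" therefore always
means smaller world Y, resolved through the affine rather than through
array indices, so oblique acquisitions behave correctly. Streamlines are
polylines in world mm and round-trip through the MRtrix TCK format.

## The synthetic cohort

All pipeline inputs can be generated with known ground truth, which is what
makes every downstream stage testable without patient data.

**Tract phantom.** A smooth spline through a handful of control points
defines the centreline; the default bends anteriorly before sweeping back
to the occipital end, emulating the anterior loop of the optic radiation.
Each streamline is the centreline plus a per-streamline Gaussian radial
offset (sd = half the tract radius, rejection-truncated at the radius, and
projected off the local tangent so it stays radial) — so containment within
the tract radius holds by construction. A label volume anchors a "thalamus"
box at the anterior end (shifted slightly anterior so the centreline's
origin falls in its posterior half), three occipital labels at the
posterior end, and a contralateral grey-matter slab; an ellipsoidal
resection mask completes the phantom. Streamlines are generated directly
rather than by tracking: probabilistic tracking is upstream of this
package's scope, and the phantom only needs to exercise the stages that
consume streamlines.

**Diffusion signals.** Per voxel, the signal of a diffusion-weighted volume
with b-value $b$ and unit direction $\mathbf{g}$ is the orientation average
of axisymmetric microdomain responses
$\exp(-b(\lambda_\perp + (\lambda_\parallel - \lambda_\perp)(\mathbf{g}\cdot\mathbf{n})^2))$
under a Watson distribution with concentration $\kappa$ about a mean axis
(or a mixture of axes for crossing-fibre configurations). Watson is the
standard axisymmetric dispersion model and exposes a single concentration
parameter, which is exactly what the monotonicity tests need. The
orientation integral uses a per-lobe product quadrature — Gauss–Legendre in
the cosine of the polar angle against the Watson weight, times a uniform
azimuth grid — because an equal-area point set under-resolves the density
at high $\kappa$. Rician noise follows the magnitude-MRI convention:
$\sqrt{(S+\sigma\varepsilon_1)^2 + (\sigma\varepsilon_2)^2}$ with
$\sigma = 1/\mathrm{snr}$ defined on the b = 0 signal; `snr = Inf` returns
noise-free signals, and the analytic Rician mean (`rician_mean()`) is the
oracle the noise model is tested against.

**The default protocol** is two shells at b = 1000 and 2200 s/mm² with 60
directions each and 13 interleaved b = 0 volumes. The 60-direction set is
an embedded electrostatically optimized scheme (antipodal Coulomb energy
minimized from a Fibonacci start). This matters more than it may seem: the
spherical mean technique's premise is that the *continuous* spherical mean
is dispersion-invariant, but a pipeline only ever has a discrete
60-direction average. With a well-optimized set the discrete mean tracks
the continuum value to a few 10⁻⁴ even for sharply peaked signals, so the
invariance that the method rests on survives discretization.

**Cohort tables.** One row per subject × timepoint × hemisphere × metric;
patients carry both timepoints with ipsi/contra hemisphere coding, controls
only baseline with left/right. Values are intercept + fixed effects
(group, timepoint, age centred at 12 years, gender) + a subject intercept +
a hemisphere-within-subject deviation + residual noise. The three noise
scales are *relative* (multiplied by the metric's |intercept|), so a single
set of scales spans metrics whose units differ by orders of magnitude
(diffusivities ~10⁻³ mm²/s vs unitless anisotropies). Defaults
(`subject_sd = 0.01`, `hemisphere_sd = 0.005`, `residual_sd = 0.01`, 43
patients, 50 controls) were chosen once to give fixed-effect t-statistics
of the magnitude typical for tract-averaged metrics in a cohort of this
size. The default effect table plants diffusivity increases in patients
(MD, AD, RD, μMD, Long, Trans up; μFA down; FA and ODEntropy null) and a
post-surgical pattern of AD/FA/Long/μFA/ODEntropy down with RD/Trans up —
the canonical signature of oedema-like extracellular water increase at
baseline and post-surgical reorganization. One transcription caveat: the
effect magnitudes derive from a published coefficient table whose group
rows print positive estimates against negative t-values; the accompanying
summary table states the directions unambiguously, and those directions are
what the defaults encode.

What the generator does *not* emulate: realistic anatomy, susceptibility
or eddy artifacts, subject motion, partial volume at tract borders, or any
spatial correlation of microstructure along the tract. Passing tests
therefore demonstrate the correctness of the estimators and scoring
machinery under the stated generative model, not robustness to real-data
artifacts.

## DTI and SMT estimation

The tensor fit is log-linear weighted least squares with squared-signal
weights — the standard variance stabilization for log-transformed Rician
magnitude data — followed by eigendecomposition. Negative eigenvalues from
noisy fits are clamped to zero before scalar computation and flagged; the
scalars follow the usual definitions (MD the eigenvalue mean, AD the
largest, RD the mean of the two smaller, FA the normalized eigenvalue
dispersion). On noise-free single-tensor signals the fit is exact to
numerical precision, which the tests assert at 10⁻¹⁰ relative.

SMT works entirely on per-shell spherical means: the arithmetic mean of
b0-normalized signals over each shell's directions. For an axisymmetric
microdomain the closed form is

$$\bar e(b) = e^{-b\lambda_\perp} \cdot
  \frac{\sqrt{\pi}\,\mathrm{erf}\!\left(\sqrt{b(\lambda_\parallel-\lambda_\perp)}\right)}
       {2\sqrt{b(\lambda_\parallel-\lambda_\perp)}},$$

with the isotropic limit $e^{-b\lambda}$ evaluated through a series when
$b(\lambda_\parallel - \lambda_\perp) < 10^{-9}$ to avoid 0/0. Two shells
give two observations for two parameters; the fit is a 32×32 multi-start
grid over the feasible triangle $0 \le \lambda_\perp \le \lambda_\parallel
\le 3\times10^{-3}$ mm²/s (computed once and shared across voxels)
followed by bounded L-BFGS-B refinement in a
$(\lambda_\perp, \lambda_\parallel - \lambda_\perp)$ parameterization that
keeps the constraint linear. The optimizer runs with tight tolerances
(`factr = 10`, parameters scaled by the box width) because the objective
lives at ~10⁻¹⁰ magnitudes where default stopping rules quit early — this
single setting is the difference between ~2.5% and ~0.05% recovery error
on noise-free signals.

## Orientation dispersion entropy

The package's coherence scalar deconvolves the directional signal with the
voxel's own fitted axisymmetric kernel. By the Funk–Hecke theorem the
kernel acts shell-wise as multiplication by rotational harmonic
coefficients $\Lambda_\ell(b) = 2\pi\int_{-1}^{1} K(t) P_\ell(t)\,dt$
(Gauss–Legendre evaluated), so a linear least-squares problem in an even
real spherical-harmonic basis (order 8) recovers the fibre orientation
distribution $p(\mathbf{n})$; negative lobes are clipped and $p$
renormalized. The reported value is the normalized negentropy
$1 - H/\ln 4\pi$ with $H = -\int p \ln p\, d\Omega$ by sphere quadrature,
clipped to [0, 1]: exactly 0 for a uniform distribution, increasing with
bundle coherence.

Two numerical choices deserve mention. First, the inversion carries a
Laplace–Beltrami penalty (weight 0.02 on $(\ell(\ell+1))^2$, scaled
relative to the design), the standard regularization in spherical
deconvolution: without it, the tiny high-order kernel coefficients amplify
the residual discretization error of the direction set into spurious
high-frequency FOD content that inflates the entropy floor and can even
invert the ordering between concentrations. With it, the measure is
monotone in Watson $\kappa$ across the tested range and a crossing-fibre
voxel scores below a single bundle at equal $\kappa$. Second, voxels whose
fitted kernel is nearly isotropic (second rotational coefficient below 1%
of the zeroth) make the deconvolution ill-conditioned; they are flagged
and assigned 0 rather than fitted. The exact functional form of an
orientation-dispersion-entropy map is not standardized; this definition is
deliberately isolated behind `od_entropy()` so it can be swapped without
touching the rest of the pipeline, and its tested contract is the
qualitative one (higher = more coherent).

## ROIs, visitation maps and tract averages

The seed is the posterior half of the thalamus: voxels strictly posterior
(world Y) to the unweighted voxel centroid. Ties at the centroid plane go
to the anterior half — a deterministic convention consistent with
"retaining the posterior half". The composite occipital target is the
union of three labels, warning (not failing) when one is absent. The
hand-drawn exclusion ROIs of a clinical workflow are parameterized as
world-space half-spaces and slabs, making that subjectivity explicit and
reproducible.

Visitation maps count *distinct streamlines* per voxel (not points), so
step size does not bias the weights; polylines are resampled to half the
smallest voxel edge beforehand so no voxel on the path is skipped. The 5%
threshold is interpreted as "visited by at least 5% of streamlines"
(denominator = total streamline count), with the alternative "5% of the
map maximum" available via `mode = "max"` — the referent of a bare "5%" is
ambiguous and both readings are kept. Tract-weighted averages use the
visitation fractions as weights, with an unweighted mean over the support
available as a flag; voxels with undefined metric values are excluded from
numerator and denominator and counted.

## The disconnection score

The score asks: at the worst coronal slice, how much of the optic
radiation does the resection remove? The thresholded tract's principal
axis (first PC of voxel-centre world coordinates, sign fixed to point
posterior, +X then +Z breaking perpendicular ties) is rotated onto the
anterior–posterior axis by the minimal-angle rotation about the tract
centroid — only the slicing direction matters, so no full PCA frame
alignment is attempted. The same rigid transform is applied to the
resection mask (nearest-neighbour for masks, trilinear for visitation
maps). Slices perpendicular to Y are then coronal by construction, and the
per-slice overlap profile is enumerated exactly.

Two denominators are implemented because the source conventions genuinely
disagree: `whole_volume` divides the slice's overlap count by the total
tract volume (the literal "fraction of optic radiation voxels in common
with the resected area over the whole optic radiation volume"), while
`slice` divides by that slice's own tract cross-section (the "percentage
of the optic radiation disconnection" reading). Neither is declared the
truth; the default is `whole_volume` and every result names its mode. The
slice-mode score is intrinsically less stable under resampling where the
local cross-section is a handful of voxels (near tract ends a one-voxel
change moves the ratio a lot), so the rigid-motion invariance contract
(|Δscore| ≤ 0.02 under joint rigid motion of tract and resection) is
stated for the default whole-volume score, whose denominator is the whole
tract. A one-voxel mask degenerate case is still classified as overlap:
`classify_overlap()` uses a strict threshold at 0 because presence/absence
is what the clinical concordance consumes.

Mask resampling uses `floor(x + 0.5)` rounding — deterministic and
platform-stable; exact half-voxel ties essentially occur only under pure
half-voxel translations, where any fixed convention is equally arbitrary.

## Group statistics

Each metric is fitted separately by REML with lme4/lmerTest:
`value ~ age + gender + group + timepoint + (1|subject) +
(1|subject:hemisphere)`. The hemisphere term is a nested intercept — the
published model description ("a random effect of subject-specific
intercepts and hemisphere") does not distinguish nested intercept, random
slope or crossed term, and the nested intercept is the variant that is
well-defined for both the patients' ipsi/contra and the controls'
left/right coding; `hemisphere_re = FALSE` exposes the alternative.
Reference levels are control / baseline / female, so the group coefficient
is patient − control and the timepoint coefficient after − before. When
the nested term is inestimable (singular fit — typical when hemisphere
variance is truly zero or each subject–hemisphere cell has one
observation), the model is refitted without it and flagged. Inference uses
Satterthwaite degrees of freedom where lmerTest provides them, with a
|t| > 2 fallback otherwise.

`sign_pattern()` reduces the fits to the familiar arrow table: per metric,
the group and timepoint effects are ↑/↓ when significant at `alpha`, else
–. The acceptance suite checks two things at sizes chosen to keep the full
run in minutes: (i) a cohort at the reference scale (43 patients / 50
controls) with planted effects at three times the default magnitudes is
recovered *exactly* — all 18 cells — at `alpha = 0.001` (strong effects
with a strict alpha, so that the four planted-null cells are not lost to
routine 5%-level false positives); and (ii) across 200 null cohorts of
16 + 16 subjects, the per-cell false-call rate stays at the nominal 5%
level within a three-standard-error Monte-Carlo margin — the empirical
rate of a 200-draw binomial cannot be asked to sit below its own mean
almost surely, so the margin is part of an honest statement of type-I
control. Estimator bias for a planted timepoint effect is checked to
within 10% over 25 replicates of a 25 + 25 cohort.

## Clinical fixtures

The per-patient clinical table (43 rows) and the visual-field concordance
table (12 patients with complete pre- and post-operative assessments) ship
as plain TSV, read with all-character columns so that entries like
`"No data"` and `"Unavailable"` round-trip byte-identically. The
transcription is deliberately verbatim: the source text's male count (22)
disagrees with its own table (21 by transcription), and its stated
seizure-freedom rate (75%) with the tabulated 25/36 ≈ 69%; the summary
reports the transcription and carries a note, rather than silently fixing
either. Concordance excludes abandoned and missing assessments from the
denominator, counts acquired deficits (normal before, abnormal after), and
verifies the exact two-way correspondence between overlap and deficit that
holds in the fixture (7 overlap-with-deficit, 5 neither).

## Problem sizes and limitations

Test and acceptance problem sizes are the package's own choices to keep a
full run fast while leaving the contracts meaningful: 1000 random 24³ mask
pairs for exact oracle equivalence of the overlap score, 50 random rigid
motions of a ~700-voxel tract phantom for invariance, 1000 simulated
voxels for the snr = 30 SMT Monte-Carlo, and the cohort sizes above.

Known limitations: the disconnection score ignores brain shift between the
pre-surgical scan and the post-surgical anatomy (registration is consumed,
not estimated, and no shift correction is attempted); the slice-mode
denominator is unstable for very thin tract cross-sections; ODEntropy is
one of several defensible definitions of an orientation-dispersion scalar;
and the synthetic cohort's independence assumptions (no spatial
correlation, Gaussian random effects) are idealizations of real
tract-averaged data.
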
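---
title: "Models and methods behind glymphdti"
author: "glymphdti authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glymphdti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glymphdti is a simulation-and-analysis pipeline for multi-shell diffusion
MRI studies of early neurodegeneration — the kind of study that compares
a patient group (for instance, subjects with isolated REM sleep behavior
disorder, a prodromal synucleinopathy) against healthy controls on
white- and gray-matter microstructure, perivascular (glymphatic) flow,
gait-derived clinical metrics, and data-driven patient phenotypes. No
real cohort ships with the package: every stage is exercised end to end
on digital phantoms and synthetic clinical tables with known ground
truth, so each algorithm can be validated by parameter recovery rather
than by eyeballing.

This vignette documents the models, the tunable parameters, the
numerical choices, and the places where the design was genuinely open.

# The signal model

## Three-compartment forward model

Each tissue voxel mixes three water pools. The normalized
diffusion-weighted signal for b-value $b$ along unit gradient $g$ is

$$S/S_0 \;=\; (1-\mathrm{ISO})\Big[\mathrm{ICVF}\,A_{ic}(b,g)
 + (1-\mathrm{ICVF})\,A_{ec}(b,g)\Big] + \mathrm{ISO}\,e^{-b\,d_{iso}},$$

with

* **intra-neurite** $A_{ic}$: a zero-radius "stick" of parallel
  diffusivity $d_\parallel$ whose orientation $n$ is dispersed around the
  mean axis $\mu$ by a Watson distribution
  $W(n) \propto \exp\big(\kappa\,(\mu^\top n)^2\big)$:
  $A_{ic} = \mathbb{E}_W\big[\exp(-b\,d_\parallel (g^\top n)^2)\big]$;
* **extra-neurite** $A_{ec}$: a Gaussian compartment with the
  Watson-averaged cylindrical tensor whose perpendicular diffusivity is
  tied to neurite density by the tortuosity rule
  $d_\perp = d_\parallel (1-\mathrm{ICVF})$;
* **free water**: isotropic diffusion at $d_{iso}$.

Orientation dispersion is reported as
$\mathrm{ODI} = (2/\pi)\arctan(1/\kappa) \in (0,1]$; ICVF is the neurite
density proxy, ISO the CSF-like fraction. The compartment diffusivities
are fixed at the standard values $d_\parallel = 1.7\times10^{-3}$ and
$d_{iso} = 3.0\times10^{-3}$ mm$^2$/s. In crossing-fiber voxels the
anisotropic compartments are averaged over the two orientations with
equal weight.

## Watson integrals by spherical quadrature

$A_{ic}$ has no convenient closed form, so it is evaluated by numerical
quadrature exploiting axial symmetry: with $\beta$ the angle between $g$
and $\mu$, the spherical average reduces to a 2-D integral over
$(u = \cos\theta, \phi)$, computed with 128 Gauss–Legendre nodes in $u$
crossed with a 96-point uniform (hence spectrally accurate, the
integrand being periodic) rule in $\phi$. The test suite pins this
against nested adaptive 1-D integration: the documented accuracy target
is $10^{-4}$ relative; the rule in fact agrees to $\sim 10^{-14}$ even
at $\kappa = 30$, $b = 2855$ s/mm$^2$. The concentration moment
$\tau_1(\kappa) = \mathbb{E}_W[(\mu^\top n)^2]$ used by the
extra-neurite tensor comes from the same rule.

$\mathrm{ODI} = 0$ has no finite $\kappa$; it is clamped to
$\kappa = 64$ (already indistinguishable from coherent fibers at
clinical b-values), and the clamp can be refused
(`kappa_from_odi(0, clamp = FALSE)` errors) when exactness matters.

# Synthetic data

## The phantom

`make_phantom()` builds a common-space head phantom: a brain box with a
2-voxel cortical GM ribbon, a central CSF block standing in for the
lateral ventricle body, two cylindrical WM tracts crossing at 90°, and
two periventricular slabs in the left (low-$x$) hemisphere — projection
fibers running inferior–superior ($+z$) and association fibers running
anterior–posterior ($+y$). This geometry is an artifact convention: real
anatomy is not (and cannot be) reproduced, but every structural feature
the downstream algorithms rely on is present — a crossing region for the
dispersion model, a GM ribbon for GBSS, tract ridges for
skeletonization, and the projection/association arrangement the ALPS
index requires.

Glymphatic function is encoded by the **perivascular gain**: a
multiplier on the $xx$ entry of the extra-neurite tensor inside the
periventricular labels, i.e. enhanced diffusion along the perivascular
($x$) axis. Controls default to gain 1.6, patients to 1.25, so patients
have lower $D_{xx}$ there and hence a lower ALPS index. The patient
condition additionally lowers ODI by 0.1 in configurable regions
(default: WM tract 1 and the GM ribbon). Directions of these effects
follow the study design the package emulates; their magnitudes are
simulation configuration with no claim about any real cohort.

## The acquisition and the noise

The default scheme mirrors a clinical multi-shell protocol: shells at
$b = 700/1000/2855$ s/mm$^2$ along $6/30/60$ non-collinear directions
plus 10 $b=0$ volumes (106 volumes). Direction tables are deterministic
golden-angle hemisphere spirals. Noise is Rician — the magnitude of the
noiseless signal plus two independent Gaussian channels of scale
`noise_sigma` — which reproduces the positive bias of magnitude MRI
(the $b=0$ sample mean exceeds $S_0$, asserted in the tests). All
randomness is seed-controlled and bit-reproducible.

## The clinical cohort

`make_clinical_table()` generates 52 controls and 44 patients (the
emulated study sizes) with ~20 continuous variables (sleep scores,
MDS-UPDRS parts, timed motor tests, neuropsychology, gait parameters)
and 6 binary non-motor features, each registered with its type, planted
control mean/SD, direction of clinical worsening, and planted shifts.
Patients split into two planted subgroups: "A" (milder) and "B" (older
and globally worse — worse sleep, motor, cognitive and gait values, more
non-motor features). Continuous noise is Gaussian, binary variables
Bernoulli — the simplest model matching mean ± SD reporting. The raw
gait columns (left/right arm swing, single/dual-task timed up-and-go)
are generated so the derived asymmetry and dual-task-cost columns
satisfy their defining formulas *exactly*.

The subgroup-B shifts default to a strong-separation regime (2.5–3 SD on
clinically affected variables, ~1.5 SD on moderately affected ones,
+0.55 on binary prevalences). This is deliberate: the cohort the
generator emulates is one in which internal validation (silhouette and
Calinski–Harabasz) clearly supports two clusters, which requires
separation of this order at $n = 44$; weaker shifts yield a structure no
internal index would endorse. An all-zero `effect_profile` gives an
exchangeable null cohort.

What passing tests on these data do **not** show: robustness to
registration error, eddy/motion artifacts, susceptibility distortion,
field inhomogeneity, non-Rician parallel-imaging noise, missing clinical
data beyond Gower's pairwise deletion, or anatomical variability between
subjects (all subjects share the phantom geometry up to noise).

# Fitting

## Diffusion tensor

Log-linear least squares of $\log S$ on the 7-column design
$(1, -b g_x^2, \dots, -2b g_y g_z)$. The shell filter defaults to the
literal reading $b < 1000$ s/mm$^2$, leaving the 6-direction $b=700$
shell — the exactly determined fit; because 6-direction fits are
noise-fragile, `include_max_b = TRUE` provides the $b \le 1000$ variant
(36 directions), and both modes are contract-tested. Which variant the
emulated study actually used is unknowable from its description, so
neither is asserted as "the" study behavior. Negative eigenvalues are
clipped at zero with a logged count (the refit-with-constraints
alternative was rejected for simplicity). FA uses
$\sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert/\lVert\lambda\rVert$; the
color map encodes $|v_1|$ with red = $x$ (left–right), green = $y$,
blue = $z$ — the convention the ALPS procedure reads.

## NODDI

Per-voxel estimation minimizes the sum of squared residuals of the
normalized signal against the forward model, in two stages:

1. **grid search** over $11 \times 11 \times 6$ points of
   (ICVF, ODI, ISO) crossed with 30 candidate orientations. The
   predicted-signal library is built once per scheme (the stick signal
   interpolated bilinearly from a cached per-shell (ODI, $\cos\beta$)
   table) and reused across subjects;
2. **local refinement** (L-BFGS-B, tolerance $10^{-6}$) of
   (ICVF, ODI, ISO, orientation angles), initialized from the grid
   optimum and from the tensor principal eigenvector, keeping whichever
   start ends lower, and accepting the refined solution only if it
   improves the objective.

On 500 noiseless voxels the median absolute recovery error is well
inside the documented 0.05 for both ICVF and ODI (empirically
$\sim 10^{-4}$). Voxels with non-finite signals are excluded and
reported, never fitted.

# DTI-ALPS

The index is computed exactly as defined: per ROI the per-voxel axis
diffusivities are the diagonal tensor entries ($D_{xx} = e_x^\top D
e_x$, etc.), averaged over the cube, and

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,proj},\, D_{x,assoc})}
 {\mathrm{mean}(D_{y,proj},\, D_{z,assoc})},$$

higher meaning better glymphatic function. Two design departures are
deliberate and config-visible: (1) the study places ROIs per subject on
SWI venograms, which are not simulated, so ROI placement is a
common-space `alps_roi_spec` defaulting to the phantom's periventricular
slab centers; (2) the physical 3-mm cube edge is realized as the odd
voxel count whose extent is closest to 3 mm per axis (one voxel at 2 mm
spacing), with the rounding rule unit-tested. Only the left hemisphere
is analyzed, matching the emulated protocol; no bilateral variant is
offered.

# Skeleton projection (TBSS/GBSS analogues)

The group skeleton is built from the voxelwise mean FA map: a voxel is
on the skeleton iff its mean FA ≥ 0.2 (the standard threshold) and it is
a local maximum within ±1 voxel along the tract-perpendicular direction.
The perpendicular is the principal eigenvector of the Gaussian-smoothed
(σ = 1 voxel) second-moment (structure) tensor of the smoothed-FA
gradient — radial at tract surfaces, cross-sectional on ridge lines, so
tubes thin to their analytic center line (asserted exactly on a tube
phantom). This is a documented re-implementation choice validated by
oracle tests, not claimed identical to FSL's `tbss_skeleton`.

WM projection locates, per skeleton voxel, the subject's maximum-FA
voxel within ±6 mm (default; covers the phantom tract widths) along the
perpendicular, and projects *any* metric from that located voxel — so
ICVF/ODI reuse the FA-derived projection voxel, as `tbss_non_FA` does.
Ties resolve to the nearest candidate. GM projection instead follows
the greatest GM probability; a skeleton voxel is retained iff its
projected GM probability exceeds 0.65 in more than 75% of subjects
(the threshold is applied to the *projected* probability — the reading
most consistent with a per-subject criterion; applying it to raw maps
is the obvious alternative and the retention rule is parameterized).
For a retained voxel where one subject fails the threshold, that
subject's value is filled by the Gaussian-weighted (σ = 2 mm, distances
in mm between skeleton voxels) average of its valid skeleton values
within 3σ; voxels with no donor in range are reported unfillable and
masked for that subject. Nonlinear template registration is bypassed
entirely — synthetic subjects already live in a common space.

# Group statistics

**TFCE.** The enhanced statistic integrates cluster support over
heights: $\mathrm{tfce}(v) = \sum_{h} e(h,v)^{E} h^{H} \, dh$ for
$h = dh, 2dh, \dots \le \mathrm{stat}(v)$, where $e(h,v)$ is the size of
the connected component containing $v$ at threshold $h$. Defaults are
the published recommendation $E = 0.5$, $H = 2$, $dh = \max/100$,
26-connectivity. The implementation (C++, incremental union-find over
voxels sorted by value) is pinned to ≤ $10^{-6}$ against a brute-force
discrete-sum oracle on 100 random maps. Negative maps are enhanced as
the negated positive part and recombined with sign.

**Permutation inference.** Two-group contrasts with nuisance covariates
use the Freedman–Lane scheme (the default of FSL's `randomise`, which
the emulated analysis delegates to; the study text names no scheme):
fit the covariate-only model, permute its residuals, refit, score with
the contrast t-statistic, TFCE-enhance, and take the maximum over
voxels to build the FWER null. p-values are
$(1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$, hence in
$[1/(n_{perm}+1), 1]$ and seed-reproducible; when $n!$ does not exceed
`n_perm` all permutations are enumerated. Confounded designs (group
inside the covariate span) error out. A 200-dataset null calibration at
500 permutations keeps the empirical family-wise false-positive rate
within [0.01, 0.10]. The study setting is 5000 permutations with age,
sex and education as covariates; sex is encoded 0/1, and education
enters only voxelwise analyses while ROI/clinical comparisons adjust
for age and sex — matching the two distinct statements in the emulated
protocol.

**ROI and correlation analyses.** ROI summaries are arithmetic means of
projected values per labeled region per subject, with unlabeled voxels
counted and excluded. Group comparisons are linear-model F tests of the
group effect adjusted for covariates, with an explicitly caller-supplied
Bonferroni family size (the emulated analyses use different families for
groups, ROIs and correlations, so no single multiplier can be baked in).
Partial correlations are Pearson correlations of covariate-residualized
variables with $t$-based p-values on $n - k - 2$ degrees of freedom.

# Gait metrics

$$\mathrm{asymmetry} = \frac{right - left}{\max(right,\, left)} \times 100,
\qquad
\mathrm{DTcost} = \frac{dual - single}{single} \times 100.$$

Asymmetry is antisymmetric and bounded in $[-100, 100]$; DT cost admits
negative values (improvement under dual task), which real cohorts do
exhibit. Both are scale-invariant. The module is parameter-agnostic:
`add_gait_metrics()` derives `<measure>_asym` / `<measure>_dtcost`
columns for any registered measure stems.

# Phenotype clustering

Patient partitioning uses the Gower dissimilarity — range-normalized L1
for continuous variables, mismatch indicator for binary/categorical,
with pairwise deletion of missing values and unit weights (no weighting
is described for the emulated analysis); continuous ranges come from the
observed sample (fixed instrument ranges are the documented
alternative). k-medoids minimizes total point-to-medoid distance:
exhaustively (certified optimum, lexicographic tie-break) whenever
$\binom{n}{k} \le 3000$ — which covers every two-cluster problem at
cohort scale — and by BUILD+SWAP with lowest-index tie-breaking beyond
that. The exhaustive small-case path exists because canonical BUILD+SWAP
demonstrably sticks in local optima on some tiny instances (the
reference implementation in the `cluster` package lands in the same
one), and the package's contract is brute-force equality there. The
SWAP objective is asserted non-increasing per iteration.

$k$ is selected by maximum mean silhouette over $k \in [2, 6]$ (ties
toward smaller $k$), with the Calinski–Harabasz index reported
alongside; since Gower space has no coordinates, CH uses medoid-based
dispersions ($W = \sum_i d(i, m_{c(i)})^2$,
$B = \sum_c n_c\, d(m_c, m_{global})^2$, scaled by $(n-k)/(k-1)$).
Singleton clusters take silhouette width 0 by convention. Subjects with
silhouette width ≤ 0 are moved to an *unassigned* list — an explicit
artifact convention chosen as the simplest internal criterion that can
leave subjects in neither cluster; the emulated study reports such
subjects without stating its mechanism, so this is a documented guess,
prominently flagged as such.

External validation follows the bootstrap: 1000 resamples with
replacement, re-clustering each, and computing the adjusted Rand index
against the full-data solution on the unique subjects present
(duplicates contribute once — ARI is defined on a set of items;
resamples with fewer than $k+1$ unique subjects are redrawn and
counted). ARI uses the standard permutation-model correction from the
contingency table.

# Numerical choices, sizes and limitations

* Problem sizes in the tests and the acceptance script are desk-scale by
  design: phantoms of $24^3$–$40\times48\times40$ voxels at 2 mm,
  imaging cohorts of 10–20 subjects per group, 300–500 permutations,
  200-dataset null calibrations, 500-voxel NODDI recovery, 1000
  bootstrap resamples. Each validates an algorithmic property, not a
  clinical effect size.
* Eigen-decompositions are exact symmetric solves per voxel; the NODDI
  library is cached per acquisition scheme; TFCE and its permutation
  loop are the only compiled hot path.
* t-statistics below $10^{-8}$ are snapped to zero so duplicated-group
  designs yield exact nulls instead of cancellation noise; the ANOVA
  wrapper likewise reports $F = 0, p = 1$ when the group term adds no
  explained variance beyond rounding.
* Degenerate inputs are contracts, not surprises: empty skeletons,
  sub-minimal direction counts, non-positive diffusivities, confounded
  designs, pairs with no jointly observed variables, and single-cluster
  labelings all raise named errors.
* Known limitations: no motion/eddy/susceptibility simulation or
  correction; no multi-fiber models beyond the two-orientation crossing;
  no atlas-based regional parcellation (phantom labels play that role);
  no hierarchical or model-based clustering alternatives; ALPS ROIs are
  common-space by construction rather than vein-guided.
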
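---
title: "Frequency-resolved network estimation: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-resolved network estimation: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A source-space recording is a matrix $X_\mathrm{broad}$ of $n$ voxel time
series (e.g., 3559 beamformed MEG dipole locations on an 8-mm grid, 5 min at
250 Hz). The working assumption is that several brain networks are active
simultaneously, each with a fixed spatial loading pattern and a
frequency-specific time course, superimposed on an aperiodic $1/f^\beta$
background and sensor noise.

For each frequency $f$ on a dense scanning grid, the data are narrowband
filtered — a Gaussian gain in the frequency domain,
$G(\nu) = \exp\!\big(-4\ln 2\,(\nu - f)^2 / \mathrm{FWHM}^2\big)$, applied by
element-wise multiplication of the FFT of each voxel row and inverted back —
giving $X_\mathrm{narrow}$. Two cross-product covariances are formed on
row-mean-centered data,

$$S = X_\mathrm{narrow} X_\mathrm{narrow}^\top,\qquad
  R = X_\mathrm{broad} X_\mathrm{broad}^\top,$$

and the generalized eigenproblem $S w = \lambda R w$ is solved. Each
eigenvector $w$ is a spatial filter maximizing the ratio of narrowband to
broadband variance; its eigenvalue $\lambda$, normalized to
$100\,\lambda_i / \sum_j \lambda_j$, is read as the percent of total variance
explained by that network at that frequency. Three derived products matter
downstream:

* the **eigenspectrum** — top normalized eigenvalues across frequencies;
* **activation patterns** $a = |S w|$, scaled to $[0,1]$ (the forward
  projection through the narrowband covariance, interpretable per voxel,
  unlike the filter weights themselves);
* **network time series** $y = w^\top X_\mathrm{broad}$.

Solving the problem for every grid frequency yields the *network landscape*:
the eigenvalue distribution over the spectrum plus the associated patterns.

The eigenproblem is solved by Cholesky whitening:
$R = LL^\top$, then the symmetric problem
$L^{-1} S L^{-\top} y = \lambda y$, $w = L^{-\top}y$. Filters are scaled to
unit Euclidean norm; the sign is fixed so the largest-magnitude entry of
$S w$ is positive. Both covariances are regularized before the solve —
$S \mathrel{+}= 10^{-6} I$ and
$R \mathrel{+}= 0.01\,(\mathrm{tr}\,R / n)\, I$ — which keeps $R$ positive
definite for rank-deficient data. The mean eigenvalue of $R$ is taken as
$\mathrm{tr}(R)/n$ to avoid a second decomposition. No $1/(T-1)$ factor is
applied to the covariances: the normalized eigenvalues are invariant to it,
and raw eigenvalues are documented as unscaled.

A PCA backend (`method = "pca"` in `scan_frequencies()`) decomposes $S$
alone; it is algebraically GED with $R = I$ and shares every downstream
product, so the two criteria can be compared like for like.

## The frequency grid and the filter schedule

The default grid places six centers below the stimulation frequency
(0.2–1.2 Hz in 0.2 Hz steps, configurable), the stimulation frequency
2.4 Hz itself, and a 1.2 Hz-spaced ladder above it, capped at 97.6 Hz —
86 centers in total, alternating integer multiples of 2.4 Hz (harmonics) with
half-harmonics. A 1.2 Hz ladder anchored at 2.4 Hz cannot land on 97.6 Hz
exactly; the last center is 97.2 Hz, inside the nominal ceiling. The
placement of the sub-stimulation centers is a configuration choice
(`sub_stim_centers`), not a fixed rule: no single spacing rule reproduces all
of count, endpoints, and step simultaneously, so the package fixes count,
step, and start and leaves the rest overridable.

Filter bandwidth follows a log10-linear schedule anchored at 0.3 Hz FWHM at
2.4 Hz: $\mathrm{FWHM}(f) = 0.3 \cdot 10^{s(\log_{10} f - \log_{10} 2.4)}$
with default slope $s = 1$, i.e., constant relative bandwidth — the standard
wavelet convention. Slope 0 gives a constant 0.3 Hz width. The whole epoch is
filtered in one FFT pass (no windowing or segmentation); edge artifacts are
accepted at this stage and handled downstream where they matter (see CFC).

## Cross-frequency coupling

Coupling is estimated **between network time series**, not raw voxels: the
modulator is a low-frequency component (typically the first or second
component at the stimulation frequency), each carrier is the first component
at a higher grid frequency. Both series are narrowband filtered with the same
Gaussian kernels used in the scan; the modulator's instantaneous phase and
the carrier's instantaneous power (squared magnitude) come from the analytic
signal. One second at each edge is discarded before binning to suppress
filter and Hilbert transients. The phase axis is divided into 36 left-closed
bins of 10° from −180°, carrier power is averaged per bin, and a one-cycle
sine $A\sin(\theta + \phi) + c$ is fitted by closed-form least squares on the
sin/cos/constant basis (the model is linear once the period is fixed at one
cycle, so the closed form attains the same optimum as iterative fitting and
is deterministic). The fitted amplitude $A \ge 0$ is the **modulation
strength**.

Carrier power is used raw, not z-scored: strengths then carry carrier power
units, which cancel in the paired within-frequency group contrast. A
consequence worth knowing: in absolute units a high-power carrier shows
larger *random* sine amplitudes than a weak one, so when comparing a single
dataset's carriers against each other (rather than two conditions), the
relative depth `strength / offset` is the scale-free quantity; the package's
tests use it for exactly that comparison. Empty phase bins (possible on
short synthetic inputs, never at 5 min) are filled by circular linear
interpolation, with an error above 25% empty.

## Randomization controls

Two shuffles dissociate spatial from temporal structure. Both operate after
narrowband filtering (shuffling before would change what the filter sees),
and apply the *same* permutation(s) to the broadband and narrowband matrices
so that a single randomization is tested:

* **Label shuffle** — one permutation of voxel indices for the whole
  recording. This conjugates both covariances by a permutation matrix, so
  the eigenspectrum is preserved *exactly* (the package asserts equality to
  1e-10 relative) while patterns are row-permuted: spatial meaning is
  destroyed, temporal structure intact.
* **Point-wise label shuffle** — an independent permutation at every time
  sample. This destroys cross-voxel covariance and each voxel's temporal
  structure; the top normalized eigenvalue collapses to its chance floor.

One algebraic fact informs the second control's interpretation: the sum of
all pairwise products within a time sample is permutation-invariant, so
point-wise shuffling redistributes covariance rather than removing it. A
spatially *signed* pattern (positive and negative loadings) has its
off-diagonal covariance cancelled; an all-positive global pattern keeps its
common-mode covariance, yet still loses its eigenvalue concentration. The
chance floor is therefore measured on the eigenspectrum, not on covariance
magnitudes.

`ged_chance_level()` measures that floor at full scale: a seeded
white-Gaussian surrogate of 3559 voxels × 75,000 samples is filtered at a
10-frequency subsample of the grid, point-wise shuffled, and decomposed. The
surrogate is streamed from a temporary binary file in voxel blocks (peak
memory ≈ 2.6 GB); pairs of real rows are packed into one complex FFT (the
kernel gain is real and Hermitian-symmetric, so real and imaginary parts
stay exactly separated), halving FFT cost; the per-timepoint permutations
are regenerated from a fixed sub-seed so the broadband and narrowband
matrices receive identical permutations without storing 75,000 permutations.
Expect roughly ten minutes on one core. The resulting mean top eigenvalue is
a few hundredths of a percent — the random-matrix edge of an essentially
structureless covariance pair, slightly above the naive $100/n \approx
0.028\%$.

## Group statistics

Paired condition contrasts use the Wilcoxon signed-rank test per
(frequency, component) cell: zeros dropped, mid-ranks for ties,
tie-corrected variance, continuity correction, $z$ reported with positive
sign meaning condition A exceeds B (network emergence). For 12 or fewer
non-zero differences the p-value comes from exact enumeration of all $2^n$
sign assignments; beyond that, the normal approximation (whose worst-case
deviation from the exact distribution at $n = 8$ is 0.0201, two-tailed, at
$W = 11$). Benjamini–Hochberg FDR is applied jointly across all tested cells
of one contrast ("FDR" unqualified is taken as BH, the field default).

The cluster-based permutation test complements FDR for contiguous spectral
effects: per-bin Wilcoxon marks bins at $p < 0.05$ (configurable — the
forming threshold is a convention, not a claim), contiguous marked bins form
clusters scored by the sum of $|z|$, and the null maximum-cluster statistic
is built from seeded within-subject condition flips, with the $+1$
Monte-Carlo correction. Sign flips leave the ranks of $|d|$ untouched, so
per-bin ranks are computed once and reused across permutations. Sharp
single-bin effects (a stimulation-frequency peak) will not form clusters;
that insensitivity is inherent to the method, which is why both procedures
are offered.

## The synthetic generator

`simulate_dataset()` builds $X = L S + B + E$: narrowband sources (white
noise shaped to a Gaussian spectral bump — not pure sinusoids, so Hilbert
phase is non-degenerate and coupling is realistic) mixed through Gaussian
blob loadings on an 8-mm lattice, per-voxel $1/f^\beta$ background
($\beta = 1$ by default), and white noise. Defaults are desk-scale study
conditions: 200 voxels, 120 s at 250 Hz, two networks at grid frequencies
9.6 and 24 Hz with non-overlapping blobs, source RMS twice the background
RMS, unit white noise. Phase–amplitude coupling multiplies the carrier
source by $(1 + \kappa \sin\varphi_\mathrm{mod})/(1 + \kappa)$; the
$1/(1+\kappa)$ normalization keeps carrier power approximately
$\kappa$-invariant, isolating coupling from power confounds.
`simulate_group()` produces paired two-condition subjects sharing loadings
and amplitude jitter within subject, with independent noise, and applies the
condition effect (an added stimulation-frequency network, a $\kappa$
increase, or an amplitude scaling) to one condition only.

What the generator does *not* emulate: leadfield mixing and beamformer
point-spread (loadings here are compact blobs, not reconstructed field
patterns), spatially correlated sensor noise, head movement, and
non-stationarity. Passing recovery tests on this generator therefore
demonstrates the estimator's correctness under its own model assumptions,
not robustness to source leakage in real recordings.

## Numerical choices and degenerate inputs

* Whitening uses `chol()`; regularization guarantees positive definiteness
  even for rank-deficient data, so no pivoting fallback is needed.
* Eigenvector sign is fixed via the activation pattern (largest-magnitude
  entry positive) — reproducible across LAPACK implementations; only the
  time-series polarity depends on it.
* The two-sided Gaussian kernel gain is built on
  $\min(\nu, f_s - \nu)$, giving exact Hermitian symmetry; DC and Nyquist
  receive the Gaussian evaluated there (effectively zero for all default
  centers). A kernel narrower than one FFT bin warns rather than errors.
* Constant (zero-variance) time series: `extract_phase()` errors on a
  degenerate analytic signal; zero-variance voxels warn and are carried by
  the regularization.
* Flat power-over-phase profiles fit $A = 0$; ties in `fit_sine` do not
  arise because the design matrix has full rank for $\ge 4$ bins.
* All randomness is seed-mandatory (`simulate`, shuffles, permutation test,
  chance floor); identical seeds give bit-identical output.

## Problem sizes used in the test suite

The suite exercises the full-scale chance floor (3559 × 75,000, 10
frequencies) once, and otherwise runs desk-scale configurations chosen to
keep the whole suite in tens of minutes on one core: recovery at the
generator defaults (200 voxels, 120 s, full 86-frequency grid), coupling
recovery at 40 voxels × 60 s over 10 seeds × 5 depths, statistics
calibration at 26 subjects with enumeration at $n = 8$, and 20 seeded
cluster-power replicates. Group pipeline tests use 12 subjects at 30 voxels
× 20 s with a 5-frequency grid — enough for the exact signed-rank test to
clear FDR when the effect is planted in every subject.

## Known limitations

* Raw eigenvalue percentages depend on normalizing the *generalized*
  eigenvalues ($\lambda / \sum \lambda$); normalizing component variances
  instead would change absolute percentages (not peak locations or ranks).
* The cluster test's forming threshold, permutation count, and statistic
  (sum of $|z|$) are conventions exposed as configuration, with the
  defaults documented above.
* TSV is the on-disk matrix container; for the full-scale geometry, data are
  expected to be generated or held in memory rather than round-tripped
  through text.
* The lowest grid bins carry an intrinsically high eigenvalue baseline: with
  constant relative bandwidth the 0.2–1.2 Hz filters span only a handful of
  FFT bins, so their narrowband covariance is nearly rank-two and its top
  normalized eigenvalue is large even for unstructured data — the same
  mechanism that makes real resting-state landscapes decay 1/f-like from the
  low end. Planted or physiological networks are therefore read as local
  peaks over that baseline rather than by global argmax.
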
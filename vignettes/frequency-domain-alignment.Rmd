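---
title: "Frequency-domain image alignment and spectral class averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain image alignment and spectral class averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The alignment problem

A single-particle cryo-EM dataset is a stack of square images, each a
noisy 2D projection of the same 3D density along an unknown direction.
Before images showing the same view can be averaged, each pair must be
brought into register: an in-plane rotation $\delta\theta$ and a
translation $(\delta x, \delta y)$. Exhaustive real-space search is
accurate only to the search grid and costs hundreds of correlation
evaluations per pair; this package instead reads the parameters directly
off the peak of a cross-correlation surface computed in Fourier space,
and sharpens the peak position by local spline interpolation.

## Rotational estimator

`polar_resample()` maps an $m \times m$ image onto a polar grid of
$\lfloor m/2\rfloor \times 360$ samples: radii $1 \dots \lfloor
m/2\rfloor$ pixels (the single center sample carries no angular
information and is excluded), angles $0^\circ \dots 359^\circ$ in
$1^\circ$ steps, measured counter-clockwise about the center pixel
$(\lfloor m/2\rfloor + 1, \lfloor m/2\rfloor + 1)$ in 1-based
coordinates. Sampling is bilinear, with zeros outside the frame. On this
grid an in-plane rotation of the image is a circular shift of the
columns, so after a 2D FFT of both polar maps ($F_i$, $F_j$) the surface

$$C = \left|\,\mathrm{ifft2}\!\left(F_i \circ \overline{F_j}\right)\right|$$

peaks at the column encoding the rotation that maps the test image back
onto the reference. The rows of $C$ are circularly shifted by $\lfloor
m/4\rfloor$ positions to center the radial-lag axis; this affects only
where the refinement window sits, not the angle readout. Raw angles in
$[0^\circ, 360^\circ)$ are folded to $[-180^\circ, 180^\circ]$
(`correct_angle()`).

Because the angular axis is periodic, the refinement window wraps around
the $0^\circ/359^\circ$ seam; on the radial axis the window slides
inward at the border instead.

## Translational estimator

`translation_cross_correlation()` computes
$C = \mathrm{Re}\,\mathrm{ifft2}(\mathrm{fft2}(M_i) \circ
\overline{\mathrm{fft2}(M_j)})$ — the imaginary part of the inverse
transform is floating-point noise for real images and is discarded — and
recenters it so zero displacement maps to the center position. The peak
position $(x, y)$ converts to displacements via
$\delta x = \lfloor m/2\rfloor - x + 1$,
$\delta y = \lfloor m/2\rfloor - y + 1$; with this center convention
self-correlation returns exactly zero shift. `estimate_shift()` returns
the *correction* (the shift that maps the test image onto the
reference), which is the negative of the displacement of the test image
relative to the reference.

## Peak refinement

Both coarse peaks are integer grid positions. `refine_peak()` extracts
an $11 \times 11$ patch centered on the integer argmax and interpolates
it onto a $101 \times 101$ grid (0.1-unit steps) with a separable cubic
spline. Interpolation is linear in the patch values, so the upsampling
is precomputed once as a $101 \times 11$ operator $B$ and each
refinement costs two small matrix products, $B\,\hat C\,B^\top$. The
spline uses Forsythe–Malcolm–Moler end conditions (`stats::spline`,
`method = "fmm"`), the closest base-R analogue of the not-a-knot
boundary used by common spline interpolators. Estimates are therefore
exact multiples of $0.1^\circ$ / $0.1$ px — in particular, planted
one-decimal ground truth is representable exactly.

Numerical edge cases are pinned down explicitly:

* ties among equal maxima break to the smallest row, then smallest
  column;
* a constant (flat) patch returns the coarse peak and flags it;
* if spline overshoot ever placed the interpolated maximum more than
  half a grid unit from the coarse peak, the search is restricted to the
  half-unit neighborhood — the refined estimate never leaves the cell
  that the coarse estimate identified;
* constant images are rejected (no unique peak).

## Joint alignment

`align_images()` alternates the two estimators: estimate rotation,
rotate the working image, estimate shift, shift it, for at most
`max_iter = 10` iterations. The accumulated parameters are
composed so that one final `shift(rotate(M, Δθ), Δx, Δy)` applied to the
*original* test image reproduces the iteratively warped image: when an
iteration rotates by $\delta\theta$, the running shift vector is rotated
by $\delta\theta$ before the new increment is added. This avoids
stacking interpolation losses from repeated warps.

Iteration stops early when the alignment parameters stop changing —
either every increment of the current iteration is zero (exact at the
0.1 output resolution) or the increments repeat the previous iteration
exactly (a repeated non-zero increment cannot improve the estimate
either). In benchmark conditions the loop typically converges in 3–6
iterations.

The loop is a local optimizer: the first rotation estimate is computed
on a still-shifted image, so a sufficiently confusable image (one with a
strong joint rotation+shift self-similarity) can start the iteration in
a wrong basin and the cap of 10 iterations will not escape it. This is a
property of the method, visible in practice on hard real data; the
synthetic phantom below is constructed so that, like a natural test
image, it does not exhibit such pseudo-symmetries.

## Class averaging pipeline

`classify_stack()` chains five stages, all exposed individually:

1. **Similarity matrix** — every pair is jointly aligned and the
   post-alignment Pearson correlation over all pixels recorded
   (symmetric, unit diagonal). All pairs are computed; for very large
   stacks this is the quadratic bottleneck and a subsampling or
   reference-based scheme would be the natural extension.
2. **kNN graph** — neighborhood size $k = \lfloor\sqrt N\rfloor +
   N_S$, capped at $N - 1$ (`adaptive_k()`), with $N_S = 5$: the
   neighborhood grows with the square root of the stack size, the
   standard adaptive choice, and is exposed as an override
   (`classify_stack(k = ...)`). Each image's neighbor set excludes the
   image itself; ties break to the lower index.
3. **Shared-nearest-neighbor counts** — $SNN(i,j) = |KNN(i) \cap
   KNN(j)|$; edges kept where $SNN(i,j) > N_S$ (strict), zero diagonal.
4. **Normalized spectral clustering** — eigenvectors of
   $D^{-1/2} A D^{-1/2}$ for the `n_classes` largest eigenvalues,
   row-normalized, clustered with seeded k-means (`nstart = 10`).
   Zero-degree vertices make the normalized Laplacian undefined; they
   are held out of the eigen-decomposition and attached afterwards to
   the class of their most similar connected image. Given the seed the
   partition is deterministic.
5. **Weighted averages** — members of each class are re-aligned to the
   class medoid (the member with the largest total within-class
   similarity) and averaged with weights $S(i, j)$ against the medoid,
   the medoid itself entering with weight 1. The default denominator is
   $1 + \sum_i S(i,j)$ so the weights form a convex combination and a
   single-member class returns its medoid exactly; the literal
   $\sum_i S(i,j)$ normalization (which leaves the medoid term
   uncovered) is available as `literal_norm = TRUE`.

Small stacks interact with the defaults: with $N \le N_S + 1$ images no
pair can share more than $N_S$ neighbors, every vertex is isolated and
classification fails by construction — lower `NS` for toy examples.

## Synthetic data: what it emulates, and what not

`make_phantom()` stands in for a natural test image: `n_blobs`
anisotropic Gaussian blobs plus a dense layer of `20 * n_blobs` small
faint Gaussians over a weak intensity gradient, all tapered by a radial
raised-cosine mask (taper from $0.30m$ to $0.38m$). The design choices
matter for what the tests can show:

* the **fine-texture layer** gives the image structure at all radii and
  orientations, as natural images have; without it a sparse blob image
  can exhibit strong joint rotation+shift self-similarities that trap
  the alignment loop (see above). The phantom's rotational
  self-correlation stays below 0.95 for all rotations in
  $5^\circ$–$355^\circ$;
* the **mask** keeps all content inside the inscribed disc and away
  from the frame edge, so planted shifts up to $m/10$ (circular, via
  Fourier phase modulation) and rotations (zero-filled corners) are
  exactly invertible — benchmark errors measure the estimator, not
  boundary clipping.

`make_volume()` / `project_volume()` generate projection stacks from a
seeded 3D Gaussian mixture: a rotated Gaussian projects to a Gaussian,
so line integrals are evaluated in closed form (the in-plane covariance
block of the rotated 3D covariance, with mass
$a\,(2\pi)^{3/2}\sqrt{\det\Sigma}$). The mixture is a synthetic stand-in
for a real asymmetric particle density. Viewing directions are drawn
uniformly over SO(3) via normalized quaternions. `add_noise()`
implements additive white Gaussian noise at a prescribed
signal-to-noise ratio defined as
$\mathrm{SNR} = \mathrm{var(signal)}/\mathrm{var(noise)}$ (SNR 0.1
means the noise variance is ten times the signal variance).

Deliberately not modeled: the contrast transfer function, detector and
ice-background noise statistics, particle-picking offsets beyond the
stated shift ranges, and structural heterogeneity. Passing tests on
these generators demonstrate the estimators and the pipeline logic under
the stated noise model — not performance on real micrographs, where CTF
and non-white noise dominate.

## Problem sizes and benchmark protocol

`alignment_benchmark()` reproduces the three simulation protocols:
100 trials each on a $256 \times 256$ phantom, with one-decimal ground
truth — rotations uniform in $[-180^\circ, 180^\circ]$; shifts uniform
in $[-m/10, m/10]$ per axis; and shift (in $[-m/20, m/20]$) followed by
rotation, recovered jointly. Absolute errors are binned as
$[0, 0.5)$, $[0.5, 1]$, $(1, 5]$, $> 5$ with the summed absolute error
per parameter, plus the iteration-count distribution for the joint mode.

The classification test uses 3 views $\times$ 30 images at SNR 0.5 and
$m = 64$: the three fixed viewing directions are mutually $\sim 90^\circ$
apart, giving clean cross-view aligned similarity well below the
within-view value, which is what the shared-neighbor graph needs to
separate classes at this noise level; $m = 64$ keeps the
$\binom{90}{2} = 4005$ pairwise alignments affordable. Each member is
the clean view under a random one-decimal in-plane rotation in
$[-180^\circ, 180^\circ]$ and shift in $[-m/20, m/20]$, plus noise.

## Known limitations

* The rotational estimator reads a single global peak; images whose
  best and second-best rotation hypotheses are close in correlation
  (near-symmetric particles) will alias between them.
* All-pairs similarity is $O(N^2)$ alignments; the 10k-image regime is
  reachable but slow in plain R — the per-pair cost is dominated by the
  polar resampling and FFTs.
* The MRC reader covers modes 0/1/2/6, little-endian, which is
  sufficient for common particle stacks; exotic variants are rejected
  rather than guessed.
* CTF handling is out of scope; inputs are assumed phase-corrected (or
  synthetic).
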
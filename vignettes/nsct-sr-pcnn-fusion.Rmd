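---
title: "Methods: multimodal image fusion with NSCT, sparse coding and a PCNN"
author: "nsfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal image fusion with NSCT, sparse coding and a PCNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsfuse)
```

## The problem

Clinical imaging modalities are complementary: CT renders bone sharply but
blurs soft tissue, MRI resolves soft tissue but not bone, PET shows
metabolic activity without anatomical detail.  Image fusion combines two
co-registered acquisitions of the same scene into a single image that keeps
the diagnostically relevant content of both.  `nsfuse` implements a
transform-domain fusion pipeline: decompose both sources with a
shift-invariant multiscale, multidirection transform, merge the
low-frequency (approximation) content with sparse-coding rules, merge the
high-frequency (detail) content with a pulse-coupled neural network, and
invert the transform.

## The nonsubsampled contourlet transform

The decomposition is a nonsubsampled contourlet transform (NSCT): a
nonsubsampled pyramid (NSP) splits the image into one lowpass band and one
highpass band per scale, and a nonsubsampled directional filter bank
(NSDFB) splits each highpass band into $2^k$ wedge-oriented bands.  No
stage downsamples, so every band retains the source size and the transform
is shift-invariant — the property that makes per-pixel fusion rules across
sources meaningful.

Design choices, made once and fixed:

* **Filter construction.**  The pyramid lowpass is a separable 2-D
  interpolating (halfband) maxflat filter — a 7-tap prototype under the
  `"pyrexc"` label, an 11-tap one under `"maxflat"`.  The directional fan
  filter is produced by a McClellan transform of the same halfband
  prototypes onto the diamond contour $(\cos\omega_1+\cos\omega_2)/2$,
  modulated by $\pi$ along one frequency axis (`"vk"`: 7×7;
  `"dmaxflat7"`: 11×11).  In both stages the second channel is the
  complement $\delta - H_0$ and the synthesis filters are unit impulses,
  so analysis followed by synthesis is *identically* the identity:
  perfect reconstruction holds by construction rather than by numerical
  design, and the round-trip error observed in the tests (~1e-15) is pure
  floating-point noise.
* **Directional tree.**  Tree level 1 uses the fan pair, level 2 the fan
  pair upsampled by the quincunx matrix, and deeper levels sheared
  (parallelogram-resampled) fans upsampled by the standard
  $2\,[2^{t-3}, 0; -s, 1]$-type matrices.  Because each split is
  complementary, reconstruction is plain summation of all bands and is
  exact for *any* choice of upsampling matrices; the matrices only shape
  the directional wedges.
* **Boundary handling** is circular (periodic) everywhere in the
  transform, implemented in the frequency domain (one forward FFT, one
  inverse FFT per band).  This makes shift-invariance under circular
  shifts exact and testable, and agrees with direct spatial circular
  convolution to ~1e-15.
* **Scale ordering** in the decomposition object is coarse → fine; the
  default direction plan is `c(4, 4, 8, 8)` (more wedges at finer
  scales), configurable per level.

## Low-frequency fusion by sparse coding

The lowpass bands of the two sources are cut into all overlapping
$n \times n$ patches (default $n = 8$, step 1) after symmetric padding of
$n-1$ pixels per side, so an $M \times N$ band yields
$(M+n-1)(N+n-1)$ patches and interior pixels are covered by exactly
$n^2$ windows.  Patch means are removed and stored.  One overcomplete
dictionary ($K = 256$ atoms for $n=8$; 4× overcomplete) is trained by
K-SVD on the *pooled* zero-mean patches of both images (30 sweeps), and
each image's patches are sparse-coded against it with Batch-OMP
(precomputed-Gram orthogonal matching pursuit).  Coding stops per patch
when the residual reaches `sparse_error` (default 0.01) *relative* to the
patch norm — the tolerance needs a scale, and the relative reading keeps
behaviour invariant under global intensity rescaling — with an absolute
floor of 1e-12 and a sparsity cap of $n^2/2$ atoms.

Fusion is column-wise on the codes: the patch whose coefficient column has
the larger L1 norm wins (columns are averaged on a tie, compared with
relative tolerance 1e-12, since exact float equality is meaningless).
Elements where the two codes disagree in sign are blended instead — the
winning entry plus half the opposing one — which damps cancellation
artifacts where the modalities genuinely conflict.  The removed means are
fused with the same L1 decision.  The fused band is rebuilt as
$D\alpha_F + \hat v_F$ with overlap averaging.

Two implementation decisions worth recording:

* **Monotone K-SVD.**  Textbook K-SVD alternates OMP coding with
  atom-by-atom rank-1 updates.  The update stage can only lower the
  objective, but a fresh OMP pass can *raise* the residual of an
  individual column.  `train_ksvd` therefore keeps the previous
  iteration's coefficients for any column that OMP would worsen; the
  recorded per-sweep representation error is then provably
  non-increasing, which the tests assert.  The atom update itself takes
  the dominant singular pair from the eigendecomposition of the small
  $d \times d$ cross-product — exact, deterministic (fixed sign
  convention), and an order of magnitude faster than a full SVD of the
  restricted error.
* **Distinct-atom initialisation.**  Atoms are initialised from a seeded
  random draw of training columns, skipping any candidate that duplicates
  an accepted atom up to sign.  Without the deduplication, a training set
  with repeated patch directions (the norm, not the exception, in flat
  medical backgrounds) seeds duplicate atoms whose twins go dead;
  with it, a planted 1-sparse dictionary is recovered exactly in one
  sweep.  Dead atoms that still arise are replaced by successive
  worst-represented samples.

## High-frequency fusion by a simplified PCNN

Each directional band pair is fused by comparing, per pixel, how strongly
a simplified pulse-coupled neural network "ignites" for each source.  The
feedback input is the local spatial frequency of the band — the root mean
of squared horizontal and vertical first differences over a 3×3 window —
normalised to $[0,1]$.  The link strength $\beta$, which controls how much
a neuron is excited by firing neighbours, is made adaptive: three maps are
used in parallel — windowed Laplacian energy (EOL), visibility (VI, with
exponent 0.7 and the window mean floored at $10^{-6}$ to avoid division
blow-ups), and windowed standard deviation (SD) — each normalised to
$[0,1]$ so the three runs are comparable (the raw EOL scale would saturate
the firing dynamics).  The network iterates

$$L_n = e^{-\alpha_L}L_{n-1} + V_L (W * Y_{n-1}),\quad
U_n = F(1+\beta L_n),\quad
\theta_n = e^{-\alpha_\theta}\theta_{n-1} + V_\theta Y_{n-1},$$

firing where $U_n > \theta_n$, with $L_0=U_0=0$, $\theta_0=1$, the 3×3
inverse-distance kernel $W$ (0.707 on diagonals, 1 on axes, 0 centre), and
the reference constants $V_L=1$, $V_\theta=20$, $\alpha_L=1$,
$\alpha_\theta=0.2$, $N_{\max}=100$.  The three cumulative ignition-count
maps per source are combined with per-pixel self-weights
$w_i = O_i / \sum_j O_j$ (equal weights where nothing fired; a global
scalar-weight variant is available as a config switch), and the source
with the larger combined count supplies the coefficient; ties average.
An uncoupled neuron ($\beta = 0$) reduces to a scalar recurrence per
pixel, which the test suite replays exactly as an oracle — e.g. constant
input 0.5 first fires at iteration 4, the smallest $n$ with
$e^{-0.2n} < 0.5$.

## Color fusion

Functional images often arrive pseudo-colored.  The default
`luminance-fuse` mode converts the color source to YCbCr (BT.601, chroma
centred at zero), fuses its luminance with the grayscale source, and
recombines the *untouched* chroma planes — color carries no anatomy here,
and pass-through is the one mechanism under which "no color distortion"
is literally true, which the tests assert bit-exactly.  A `per-channel`
mode (fuse each RGB channel with the gray source) is provided for
comparison.  There is no canonical mechanism for fusing grayscale anatomy
with pseudo-color function; chroma pass-through is this package's own
documented choice.

## Quality metrics

The suite reports histogram entropy (IE, 256 bins), global spatial
frequency, average gradient, summed mutual information
$MI(A,F)+MI(B,F)$, standard deviation, SSIM (11×11 Gaussian window,
$\sigma=1.5$, $C_1=(0.01)^2$, $C_2=(0.03)^2$ on unit dynamic range;
reported summed over both sources, the convention under which published
combined-structural scores exceed 1), and the Xydeas–Petrović
edge-transfer index $Q^{AB/F}$ with the customary sigmoid constants
($\Gamma_g=0.9994$, $\kappa_g=-15$, $\sigma_g=0.5$; $\Gamma_\alpha=0.9879$,
$\kappa_\alpha=-22$, $\sigma_\alpha=0.8$).  Two normalisations are the
package's own choices: the Sobel orientation difference is folded to the
orientation distance $\min(d, \pi-d)$ so the agreement term stays in
$[0,1]$, and the per-pixel preservation product is divided by its value at
perfect transfer so that a fused image identical to two identical sources
scores exactly 1 (the literal sigmoid scaling, available via
`normalize = FALSE`, peaks at ≈0.975).  The rescaling is monotone, so
method *orderings* are unchanged.  A mean local contrast summary (windowed
SD over windowed mean) stands in for the "clarity" table column; no
standard formula for that quantity exists and it is labelled
non-canonical.  Visual information fidelity is out of scope.

## Synthetic phantoms

Real atlas image pairs cannot ship with the package, and — more
importantly — carry no ground truth about which modality owns which
feature.  `make_pair()` generates a complementary pair with exactly that
ground truth: a *structural* phantom (flat base, one high-contrast
bone-like ring, thresholded random shapes outside the ring) and a
*functional* phantom (flat where the structural features live, smooth
activity blobs plus low-amplitude band-limited texture strictly inside
the ring), with named boolean masks for every feature.  Defaults: size
128, additive Gaussian noise with σ = 0.005 (a realistic mild sensor
noise that leaves feature contrasts unambiguous), everything a pure
function of the seed.  `make_color_pair()` maps a blobs-only activity map
through a hot-body colormap constructed so that BT.601 luminance equals
the activity exactly, giving an invertible pseudo-color functional image.

What the phantoms do *not* emulate: imaging physics (MR relaxation, PET
counting statistics), anatomical texture, registration error, intensity
inhomogeneity.  Passing the fusion tests on phantoms therefore
demonstrates that the pipeline preserves complementary structure under
controlled conditions, not clinical performance.

## Problem sizes and runtime envelope

The test suite and the acceptance script run phantoms at 64×64 (the
generator's minimum), where one full-default fusion — 25-band NSCT, joint
K-SVD over ~10,000 patches for 30 sweeps, and 144 PCNN runs of 100
iterations — takes on the order of ten seconds on one CPU.  These sizes
were chosen so the complete property suite (including 30 full-default
fusions) runs in minutes; the pipeline itself is size-agnostic and the
demo defaults to 128×128.

## Known limitations

* Directional selectivity of the deep NSDFB levels is approximate: the
  shear-based stage filters partition frequency into wedge-like, not
  ideally wedge-shaped, regions.  Reconstruction exactness is unaffected.
* The transform's circular boundary handling can wrap content across
  opposite edges for images with strong border structure; medical images
  with dark borders are unaffected.
* K-SVD cost grows linearly in patch count; megapixel inputs should use a
  larger step or a subsampled training set.
* Registration is assumed; only shape equality is verified.
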
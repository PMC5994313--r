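# nsfuse

Multimodal medical image fusion in the nonsubsampled contourlet domain,
for imaging scientists and method developers who need a fully testable,
dependency-light reference pipeline: two co-registered acquisitions of the
same scene (CT + MRI, MR + PET, …) are merged into a single image that
keeps the complementary content of both.

## Method

The pipeline works in three transform-domain stages:

1. **Decomposition.** Each source is decomposed with a nonsubsampled
   contourlet transform (NSCT): an à-trous nonsubsampled pyramid
   (filters upsampled by `2^(j-1)` at scale `j`, nothing downsampled)
   followed by a nonsubsampled directional filter bank that splits each
   scale's highpass band into `2^k` wedge-oriented bands. Every subband
   keeps the source size; the transform is linear, exactly invertible,
   and shift-invariant.

2. **Low-frequency fusion (sparse coding).** The lowpass bands are cut
   into all overlapping `8x8` patches (step 1), patch means removed, and
   one overcomplete dictionary `D` (256 atoms) is trained by K-SVD on the
   pooled patches of both images (30 sweeps). Each image's patches are
   sparse-coded with Batch-OMP to residual tolerance `eps = 0.01`;
   per patch, the coefficient column with the larger L1 norm wins
   (`alpha_F = alpha_A` if `||alpha_A||_1 > ||alpha_B||_1`, averaged on a
   tie), with sign-conflicting elements blended as the winning entry plus
   half the opposing one. The fused band is `D alpha_F + v_F` with
   overlap averaging.

3. **High-frequency fusion (PCNN).** Every directional band pair drives a
   simplified pulse-coupled neural network: the feedback input is the
   normalised local spatial frequency `SF = sqrt(RF^2 + CF^2)`; link
   strengths are adaptive maps (Laplacian energy, visibility, local
   standard deviation); neurons fire where the internal activity
   `U = F(1 + beta L)` exceeds a decaying, self-recharging threshold
   (`V_L = 1`, `V_theta = 20`, `alpha_L = 1`, `alpha_theta = 0.2`,
   100 iterations). Per pixel, the source with the larger combined
   ignition count supplies the coefficient.

The inverse NSCT of the fused bands is the result. A quality-metric suite
(entropy, mutual information, edge-transfer `Q^AB/F`, SSIM, spatial
frequency, average gradient) and a seeded phantom generator with
ground-truth feature masks make the whole pipeline testable without any
external image atlas. See `vignettes/nsct-sr-pcnn-fusion.Rmd` for the full
methods account.

## Worked example

```r
library(nsfuse)

pair <- make_pair(size = 64, seed = 3)        # structural + functional phantom
res  <- fuse_gray(pair$structural, pair$functional, fusion_config(),
                  compute_metrics = TRUE)
res$metrics
#> Fusion quality report
#>   ie:       6.288477
#>   sf_global: 0.174132
#>   ag:       0.056419
#>   mi:       2.495681
#>   sd:       0.201156
#>   q_abf:    0.878391
#>   ssim:     1.235518
#>   mc:       0.161837

q_abf(pair$structural, pair$functional,
      fuse_baseline(pair$structural, pair$functional))
#> [1] 0.476687
```

Reading the numbers: the fused image transfers about 88% of the sources'
edge information (`q_abf`), versus about 48% for plain pixel averaging,
which halves every edge that lives in only one modality. `mi` and `ssim`
are the summed two-source forms (`MI(A,F) + MI(B,F)`, likewise SSIM), so
values above 1 are expected; `ie`, `sf_global`, `ag`, `sd` describe the
fused image alone.

The same pipeline is available from the shell (see `inst/exec/nsfuse`):

```sh
nsfuse fuse ct.png mri.png -o fused.png --seed 1
nsfuse metrics ct.png mri.png fused.png --json report.json
nsfuse demo --out demo_dir --seed 7
nsfuse selftest
```

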
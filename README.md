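# gofshrink

Multiscale image denoising by **local goodness-of-fit testing** in the
wavelet domain, for single-channel grayscale images (natural images,
brain-MRI slices, multifocus captures) corrupted by additive white
Gaussian noise.

## The method

The noisy image is modelled as `x = s + η`, `η ~ N(0, σ²)`. After a
multiscale decomposition `W = 𝒲(X)` and normalization by the robust noise
estimate `σ̂ = median(|w_diag⁽¹⁾|)/0.6745`, every detail coefficient is
judged by its neighborhood: the `l × l` window centred on it is compared
with the standard normal reference CDF via the Anderson–Darling statistic

    τ = −L − (1/L) Σ_{t=1..L} (2t−1) [ln F(z₍t₎) + ln(1 − F(z₍L+1−t₎))],

`L = l²`. Under noise the window is an i.i.d. Gaussian sample and τ is
small; signal clusters push the window's empirical distribution away from
the reference, and τ grows. The decision is hard: keep the coefficient
verbatim if `τ > T_j`, zero it otherwise. The threshold `T_j` is
calibrated by Monte Carlo so that a chosen **probability of false alarm**
`P_fa = Pr{τ > T | noise}` (default 0.005) is met exactly on pure noise.

Two pipelines:

* `gofshrink_ti()` — decimated DWT (db8, 5 levels) with **cycle spinning**
  (average over denoised circular shifts; approximates translation
  invariance).
* `gofshrink_dt()` — **dual-tree complex wavelet transform**, six oriented
  complex subbands per scale, tested independently on real and imaginary
  parts; near shift invariance and directional selectivity give it the
  edge over the DWT pipeline.

Because no wavelet library is assumed, the package designs its own
filters: Daubechies filters by spectral factorization, and the dual tree's
q-shift pair by a Thiran-allpass common-factor construction (orthonormal
to machine precision; see the methods vignette).

## Worked example

```r
library(gofshrink)

clean <- make_phantom(phantom_spec("piecewise_constant_shapes", 256, seed = 11))
noisy <- add_gaussian_noise(clean, sigma = 20, seed = 1)
psnr(clean, noisy)
#> [1] 22.07766

res_ti <- gofshrink_ti(noisy, gof_config("dwt_ti"))   # DWT + cycle spinning
res_dt <- gofshrink_dt(noisy, gof_config("dtcwt"))    # dual tree

res_ti$sigma_hat$sigma      # noise level recovered from the data
#> [1] 20.50644
psnr(clean, res_ti$image)
#> [1] 31.18703
psnr(clean, res_dt$image)
#> [1] 31.67536
```

The noisy input sits at 22.1 dB PSNR (exactly what σ = 20 noise predicts:
`10·log10(255²/20²) = 22.11`). Both pipelines recover ~9 dB; the dual-tree
variant is consistently ahead of the translation-invariant DWT by a few
tenths of a dB, and `res$retained` reports the per-band fraction of
coefficients kept by the test (a fraction ≈ `pfa` on pure-noise bands,
more where the phantom has edges).

First use of a pipeline self-calibrates its threshold curve (a few tens of
seconds) and caches it for the session; `estimate_pfa_curve()` /
`write_threshold_curve()` let you precompute and reuse curves explicitly.

## Command line

```sh
Rscript inst/cli/gofshrink.R phantom --kind mri_like_ellipses --size 256 --noise 20 noisy.png
Rscript inst/cli/gofshrink.R denoise --method dt --pfa 0.005 noisy.png denoised.png
Rscript inst/cli/gofshrink.R evaluate clean.png denoised.png
Rscript inst/cli/gofshrink.R calibrate --transform dwt --seed 1 curve
```

`denoise` writes a JSON sidecar with σ̂, the per-scale thresholds and the
retained-coefficient fractions, enough to reproduce the run.

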
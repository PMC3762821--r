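# ctrestore

Restoration of blurred, noisy CT image sequences by sparse and low-rank
matrix decomposition, for researchers working on medical-image
enhancement and for anyone with a stack of highly correlated frames
degraded by convolutional blur plus noise.

## The method

Frames of a CT series share their anatomy: stacking the vectorized frames
as columns of a matrix `D` (one `H*W`-vector per frame) yields a matrix
that is approximately **low-rank plus sparse**,

```
D = A + E            (RPCA / LADMAP:  min ||A||* + lam ||E||_1  s.t.  D = A + E)
X = L + S + G        (GoDec:          rank(L) <= r, card(S) <= k, G = dense noise)
```

The shared background lands in the low-rank part, per-frame structures and
most of the blur/noise energy in the sparse part. Restoration then treats
the two parts separately and recombines them:

```
f_hat_i = f1(S_i) + f2(mean(L))
```

where `f2` is Wiener deconvolution of the *averaged* low-rank frame under
a Gaussian point spread function `h ∝ exp(-(x²+y²)/(2σ²))`, and `f1` is
Wiener deconvolution of each sparse frame under a turbulence transfer
function `H(u,v) = exp(-k (u²+v²)^(5/6))`. The Wiener filter uses the
constant-NSR approximation `W = conj(H) / (|H|² + K)`. Averaging the
low-rank columns is what lets the whole sequence denoise each frame.

Three decomposition solvers are provided: `rpca_alm()` (inexact augmented
Lagrange multipliers), `ladmap_rpca()` (linearized alternating direction
with adaptive penalty — same convex program, faster schedule), and
`godec()` (bilateral random projections with hard rank/cardinality
constraints and an explicit noise term; the right choice for heavily
noisy series). Quality is scored per frame by standard deviation (SD),
256-level information entropy (IE, bits), and the image-quality
measurement function value (IQMFV = SD²).

## Worked example

Generate a ground-truthed phantom (10 correlated 64×64 frames, Gaussian
blur σ = 2, noise std 5), restore it with the RPCA model using
degradation-matched filter parameters, and score the result:

```r
library(ctrestore)

ph <- make_phantom(phantom_spec(seed = 7))
sig_var <- mean(vapply(ph$degraded$frames, function(f) mean((f - mean(f))^2), numeric(1)))
nsr <- ph$spec$noise_std^2 / sig_var          # true noise-to-signal ratio

cfg <- restoration_config("rpca",
  solver_opts = solver_options(seed = 1),
  gauss_sigma = 2, gauss_nsr = nsr / 10,      # low-rank mean averages n=10 frames
  turb_k = match_turbulence_k(2, c(64, 64)), turb_nsr = nsr)
res <- restore_sequence(ph$degraded, cfg)
res
#> restoration_result [rpca]: 10 frame(s) of 64 x 64
#>   mean SD     26.0457 ->  27.8491
#>   mean IE      6.6678 ->   6.7640
#>   mean IQMFV    680.2 ->    777.3
```

All three quality indices rise: deblurring restores contrast (SD, IQMFV)
and detail (IE). Because this is a simulation, fidelity can be checked
against the clean truth:

```r
rmse <- function(a, b) sqrt(mean((unlist(a) - unlist(b))^2))
rmse(ph$degraded$frames, ph$clean$frames)   # 8.987
rmse(res$restored$frames, ph$clean$frames)  # 8.213
```

Real sequences load with `load_sequence("dir/of/frames")` (PNG/TIFF,
RGB converted to gray, intensities on [0, 255]) and save with
`save_sequence()`. Thin command-line wrappers live in `inst/scripts/`
(`simulate.R`, `restore.R`, `metrics.R`).

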
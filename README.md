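# awrct

Statistical iterative reconstruction for sparse-view, low-dose fan-beam
CT, regularized by learned patch dictionaries, with **automatic
selection of the regularization parameter from the projection data**.

## Who this is for

Researchers working on undersampled CT reconstruction who want a
self-contained R implementation of dictionary-learning SIR
(ADSIR/GDSIR-style), its adaptive-weight reformulation, and the
two-pass workflow that replaces the usual trial-and-error search for
the regularization weight λ, plus SART and TV/Barzilai-Borwein (GPBB)
baselines and the NMAD/SNR quality metrics used to compare them.

## The method

A fan-beam scan of an attenuation image μ is modeled through a sparse
system matrix **A** of exact ray-pixel intersection lengths, with
photon statistics y<sub>i</sub> ~ Poisson(b<sub>i</sub>
e<sup>−l<sub>i</sub></sup> + r<sub>i</sub>) giving per-ray weights
ω<sub>i</sub> = (y<sub>i</sub> − r<sub>i</sub>)²/y<sub>i</sub>. The
objective couples the weighted data fidelity with a learned sparse
patch model (K-SVD dictionary **D**, OMP codes α<sub>s</sub>):

    min_{μ,α,D}  Σ_i (ω_i/2)([Aμ]_i − l̂_i)²  +  λ Σ_s ‖E_s μ − D α_s‖²

Replacing the fidelity by a separable paraboloid surrogate and
rescaling the regularizer so both terms share the same pixel curvature
(the *adaptive-weight* reformulation) collapses the image update to

    μ_j ← [ (c_j + λ d_j) / (1 + λ) ]₊

a clamped convex combination of a data-driven target c<sub>j</sub> and
a dictionary-driven target d<sub>j</sub>. λ then has a dimensionless
meaning — parts dictionary per part data — and the method selects it
automatically:

1. reconstruct once with λ → ∞ (pure dictionary step) and measure the
   relative weighted fidelity error δ<sub>λ→∞</sub> of the result
   against the measured sinogram;
2. map δ<sub>G</sub> = 10⁶·δ<sub>λ→∞</sub> through a piecewise
   quadratic fitted over δ<sub>G</sub> ∈ [0.4, 10]:
   λ\* = 1.74485 δ<sub>G</sub>² + 0.58883 δ<sub>G</sub> − 6.88253 for
   δ<sub>G</sub> > 1.96, and
   λ\* = −0.21545 δ<sub>G</sub>² + 1.08602 δ<sub>G</sub> − 0.32634
   otherwise;
3. reconstruct once more at λ\*.

Exactly two reconstruction passes instead of a ten-plus-run manual
sweep. See `vignette("awrct-methods")` for assumptions, parameter
defaults, and design decisions.

## Worked example

The study protocol: a 256×256 Shepp-Logan phantom scanned with 120
views at 3° spacing (a sparse-view, underdetermined system: 61 440
rays for 65 536 pixels), 512 detectors, 0.1% projection noise. SART is
run first as the baseline and reused as the warm start for the
automatic two-pass workflow (about five minutes total on one CPU):

```r
library(awrct)

mu   <- make_shepp_logan(256)
geom <- build_geometry(n_views = 120, angular_step_deg = 3,
                       n_detectors = 512, image_n = 256)
sino <- simulate_scan(mu, geom, noise_level = 0.001, seed = 1)

sart <- sart_reconstruct(sino, geom, recon_config(max_outer_iters = 1000))
quality_report(sart$image, mu)
#> NMAD = 4.6053%   SNR = 27.1890 dB   (65536 pixels)

res <- awr_pipeline(sino, geom, dict_mode = "adaptive",
                    config = recon_config(), init = sart$image, seed = 1)
res
#> AWR two-pass reconstruction (AWR-ADSIR)
#>   delta_inf = 2.03082e-06  (delta_G = 2.0308)
#>   lambda*   = 1.5095   passes = 2
quality_report(res$image, mu)
#> NMAD = 1.1209%   SNR = 33.9065 dB   (65536 pixels)
```

`delta_G` is the fidelity error of the infinite-regularization pass
(×10⁶); `lambda*` is the weight the model selects for the second pass;
NMAD is the normalized mean absolute deviation against the ground
truth (lower is better) and SNR the signal-to-noise ratio in dB
(higher is better). The second pass here runs to its 50-iteration cap
(a warning says so) rather than to the err^δ stopping rule; the
returned last iterate is the reported image.

The dictionary prior needs the image to be large relative to the 8×8
patches and the system to be undersampled to pay off: at 128×128 with
the same 120 views the system is overdetermined and plain SART already
reaches NMAD 0.6%, where extra regularization only hurts.

A thin command-line interface over the same functions lives in
`inst/cli/ctrecon.R` (subcommands `simulate`, `select-lambda`,
`reconstruct`, `evaluate`).

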
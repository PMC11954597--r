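# pafpdd

Simulation and analysis toolkit for **paired-agent fluorescence
pulse-dye densitometry (PAF-PDD)**: measuring the relative plasma input
functions (PIFs) of a co-administered targeted and control imaging agent
from the cardiac-frequency component of a two-channel fluorescence finger
probe, and using them to correct binding-potential estimation in
paired-agent molecular imaging.

## Who this is for

Researchers developing quantitative paired-agent imaging (e.g.
fluorescence-guided surgery with an anti-EGFR affibody plus an untargeted
control dye) who need to know whether a pulse-oximeter-style probe can
recover agent plasma kinetics well enough to de-bias binding-potential
(BP) estimates — before building hardware. Everything is simulated: no
external data are required.

## The models at the core

- **Plasma input functions** — bi-exponential bolus decays,
  `Cp(t) = A1 e^{-λ1 t} + A2 e^{-λ2 t}`, modulated at the heart rate
  `Cp(t)·(1 + α/2 · sin 2πft)` by arterial volume pulsation.
- **Tissue kinetics** — one-compartment exchange
  `dCf/dt = K1·Cp − k2·Cf` for normal tissue; a saturable second
  compartment `dCb/dt = kon(Bmax − Cb)Cf − koff·Cb` for tumor.
- **Photon transport** — voxelized Monte Carlo (Henyey–Greenstein
  scattering, track-length fluence estimator) through a layered
  finger-like cylinder with pulsating arterial vessels; per-voxel
  sensitivity from the adjoint product of excitation and detection
  fluence.
- **Detection** — `S(t) = Iex·η·ε·[Jart(t)·Cp(t) + Jtis(t)·Cf(t)]` at
  20 Hz, scaled to the half-maximum count of a b-bit detector, with
  Poisson shot noise, additive Gaussian noise and integer quantization.
- **Reconstruction** — per-1-min-window FFT; the amplitude of the
  dominant cardiac-band peak traces the relative PIF.
- **Correction and fitting** — truncated-SVD deconvolution estimates the
  kernel `g` with `Cp_tar = Cp_con * g`; the simplified reference tissue
  model (SRTM) `Ctar = R1·C + [k2 − R1·k2/(1+BP)]·C*e^{−k2 t/(1+BP)}`
  (with `C = Ccon*g`) is fit for `(R1, k2, BP)`.

See `vignettes/pafpdd-methods.Rmd` for assumptions, parameter defaults
with units, and the design decisions behind each stage.

## Worked example

```r
library(pafpdd)

cfg <- experiment_config(replicates = 10, seed = 1)
res <- run_bp_comparison(cfg)
aggregate(cbind(BP, rel_error) ~ case, res, mean)
```

```
            case        BP rel_error
1     equivalent  3.571453    0.0008
2      no_deconv 27.386053    6.6680
3  pafpdd_deconv  3.682587    0.0311
4 perfect_deconv  3.678749    0.0300
```

Reading the table: when both tumor channels are driven by the *same*
plasma curve (`equivalent`), the SRTM fit of the noisy tumor curves gives
the reference BP of 3.571. Giving the control agent its own (3.9-fold
larger, faster-clearing) plasma curve and ignoring the difference
(`no_deconv`) inflates BP to 27.4 — a ~670% error. Correcting with a
kernel deconvolved from the true plasma curves (`perfect_deconv`) or from
the PIFs reconstructed end-to-end by the simulated probe at 16-bit noise
(`pafpdd_deconv`) brings BP back within ~3% of the reference.

```r
bp <- function(k) res$BP[res$case == k]
compare_cases(bp("no_deconv"), bp("perfect_deconv"))$p     # 4.1e-25
compare_cases(bp("pafpdd_deconv"), bp("perfect_deconv"))$p # 0.71
```

The uncorrected bias is overwhelmingly significant (paired t-test, 95% CI
of the difference [23.67, 23.75]); the probe-based correction is
statistically indistinguishable from the perfect one (CI
[−0.018, 0.026]).

Reconstruction accuracy by itself:

```r
sig <- forward_channel(pif_aby029(), cfg)                 # 300 min at 20 Hz
noisy <- add_noise(sig, noise_model(16, 0.01, seed = 5))
rec <- reconstruct_pif(noisy)                             # 300 one-min windows
pif_mse(rec, pif_aby029())                                # 4.1e-05
```

`run_bitdepth_sweep(cfg)` tabulates this error across 8/10/12/16-bit
detectors and replicates; the error falls monotonically with bit depth.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pafpdd.R", package = "pafpdd"))')" \
    bp-compare --seed 1 --out out/
```

Subcommands: `simulate-signal`, `reconstruct-pif`, `bitdepth-sweep`,
`bp-compare`, `mc-jacobian`. Configuration is a YAML file
(`write_config()` / `read_config()`); every run records the exact config
and its hash next to its outputs.

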
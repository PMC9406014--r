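# vmdcal — multiscale spectral calibration by VMD-weighted SVR ensembles

`vmdcal` quantifies an adulterant's mass fraction (% g/g) from UV-Vis or
NIR spectra of blended samples — rapeseed oil cut into premium vegetable
oils, one rhizome powder diluted into another. It is aimed at
chemometricians working with small calibration sets (tens of samples,
hundreds-to-thousands of wavelengths) where heavily overlapping bands,
baseline drift and noise at several frequency scales make single-model
calibration fragile.

## The method

Every training spectrum is decomposed into `K` narrow-band modes
u<sub>k</sub> with centre frequencies ω<sub>k</sub> by **variational mode
decomposition** (VMD): minimise the summed analytic-signal bandwidths

min Σ<sub>k</sub> ‖∂<sub>t</sub>[(δ(t) + j/πt) ∗ u<sub>k</sub>(t)] e<sup>−jω<sub>k</sub>t</sup>‖₂²  s.t. Σ<sub>k</sub> u<sub>k</sub> = x,

solved by ADMM in the frequency domain (Wiener-filter mode updates,
power-centroid frequency updates). The k-th modes of all samples are
recombined into a mode matrix U<sub>k</sub>, one **least-squares SVR**
(RBF kernel, one dense linear solve) is fitted per (U<sub>k</sub>, y), and
predictions are combined as ŷ = Σ w<sub>k</sub> ŷ<sub>k</sub> with weights

w<sub>k</sub> ∝ RMSECV<sub>k</sub>⁻⁴,

so sub-models that cross-validate poorly (typically the pure-noise
high-frequency modes) are silenced. The package also ships the full
supporting workflow: Kennard–Stone splitting, a mode-number scan
(`select_k()`), PSO hyperparameter search, a PLS baseline with
MCCV + F-test rank selection, RMSEP/R metrics, CSV/JSON I/O, and a
synthetic mixture-spectra generator so everything is testable end to end.

## Worked example

```r
library(vmdcal)

dat <- synthetic_benchmark(seed = 1)          # 75 NIR-like mixture spectra
sp  <- kennard_stone(dat$X, n_train = 50)     # deterministic 50/25 split

fit <- wmsvr(dat$X[sp$train, ], dat$y[sp$train], K = 5)
summary(fit)
#> VMD-WMSVR sub-model summary
#>  mode mean_omega rmsecv    weight
#>     1  0.0001299  2.606 0.3197429
#>     2  0.0026468  2.158 0.6797796
#>     3  0.1851393 17.444 0.0001592
#>     4  0.2944154 17.428 0.0001597
#>     5  0.4061022 17.459 0.0001586

pred <- predict(fit, dat$X[sp$test, ])
rmsep(dat$y[sp$test], pred)
#> [1] 1.052455
pearson_r(dat$y[sp$test], pred)
#> [1] 0.9972498
```

Reading the summary: the two low-frequency modes (ω ≈ 0.0001 and 0.003
cycles/sample) carry the composition information and take essentially all
the ensemble weight; modes 3–5 sit in the noise band, cross-validate an
order of magnitude worse, and are weighted out by the inverse-fourth-power
rule. The held-out 25 samples are predicted to about 1% (g/g) RMSEP with
R ≈ 0.997.

Real data come in through `read_spectra()` / `read_targets()` (CSV with a
numeric wavelength header); fitted models serialize to JSON with
`write_model()`. A thin command-line wrapper over the same functions is in
`inst/exec/vmdcal.R` (`simulate`, `split`, `decompose`, `train`,
`predict`, `select-k`, `baseline-pls`, `tune`, `run`).

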
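# spafr — smart phasor average filtering for noisy wrapped phase maps

Quantitative phase imaging — off-axis digital holographic microscopy of
cells, interferometry, InSAR-style fringe analysis — measures phase only
modulo 2π. Recovering the continuous phase ("unwrapping") is easy on clean
data but fails in the presence of **phase residues**: points where the sum of
wrapped phase differences around a closed 2×2 pixel loop,

    Σ_{p∈loop} ∇φ_p = 2πn,   n ∈ ℤ,

has nonzero integer charge *n*, making path-following unwrappers
path-dependent. Conventional fixes filter the *entire* phase map until the
residues disappear, destroying exactly the high-spatial-frequency detail
that high-resolution microscopy is after.

`spafr` implements **smart phasor average filtering (SPAF)**: an iterative,
residue-guided scheme that filters *only* small patches around each residue.
Filtering happens in the phasor domain, ψ = arg{L[exp(iφ)]}, where L is a
windowed mean (or marginal median) of the complex exponential — the phasor
has no sawtooth jumps, so smoothing it does not blur the wrap boundaries.
Each iteration

    φ^m = [1 − P_wp(U_R)]·φ^{m−1} + P_wp(U_R)·ℓ_wf[φ^{m−1}]

substitutes filtered values only inside the binary patch mask `P_wp(U_R)`
(wp×wp squares around each residue anchor), recomputes the residue map, and
escalates the filter window `wf` first and the patch size `wp` second
whenever progress stalls, until the map is residue-free or the caps
(`wf ≤ 15`, `wp ≤ 15` by default) are reached. The residue-free wrapped
phase then unwraps correctly with a simple 1D line-scan (Itoh) unwrapper,
while pixels away from residues are **bit-identical** to the input.

The package is aimed at microscopists and image-analysis developers working
with wrapped phase rasters. It also ships the surrounding toolchain: an
off-axis hologram forward model with first-order Fourier demodulation,
synthetic phase/noise generators (Gaussian bump, vortex pairs, textured
phases; multiplicative speckle + additive complex Gaussian noise), and
spectral error metrics (relative square error, phasor spectra, radially
averaged log-spectra) for quantifying resolution preservation.

## Worked example

The standard stress test: a 30-rad Gaussian phase bump on a 400×600 px
grid, corrupted by multiplicative speckle (variance 2) and additive white
Gaussian noise at SNR 6, then filtered and unwrapped.

```r
library(spafr)

sim <- simulated_phase(seed = 7)        # truth, clean wrap, noisy wrap
residue_count(sim$noisy)
#> [1] 57928

fit <- spaf(sim$noisy)                  # defaults: wf 3..15, wp 2..15, mean
fit
#> Smart phasor average filtering
#>   phase map: 400 x 600 px
#>   residues:  57928 -> 0 in 29 iteration(s)
#>   status:    residue-free (final wf = 11, wp = 2, mode = mean)

u <- unwrap_phase(fitted(fit))                           # 1D line-scan
u <- u - 2 * pi * round(median(u[1:5, 1:5]) / (2 * pi))  # anchor background
ctr <- round(sim$center)
median(u[(ctr[1]-2):(ctr[1]+2), (ctr[2]-2):(ctr[2]+2)])
#> [1] 30.18590                          # true peak: 30 rad
100 * rse(u, sim$truth)
#> [1] 1.7                               # percent, vs ground truth
```

Nearly 58,000 residues are eliminated in 29 iterations, the peak height is
recovered to within 0.2 rad, and `plot(fit)` shows the residue count per
iteration (the convergence diagnostic). `summary(fit)` additionally reports
how few pixels were ever modified — the point of the method.

A command-line wrapper with `simulate`, `run`, `unwrap`, `demodulate` and
`metrics` subcommands is installed under `inst/cli/spaf.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/spaf.R", package="spafr"))')" \
    run --input wrapped.tif --out filtered.tif --trace trace.csv --unwrap
```

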
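Package: spafr
Title: Smart Phasor Average Filtering for Phase Unwrapping of Noisy Wrapped Phase Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-guided, locally restricted iterative filtering of noisy
    wrapped phase maps from quantitative phase imaging and off-axis digital
    holographic microscopy. Phase residues (nonzero topological charges on 2x2
    pixel loops) are detected and removed by phasor average filtering applied
    only inside small patches around each residue, with the filter window and
    then the patch size escalated until the map is residue free, so that a
    simple one-dimensional unwrapper succeeds while high-spatial-frequency
    image content is preserved. Includes an off-axis hologram forward model
    with first-order Fourier demodulation, synthetic phase and speckle/white
    noise generators, a simple 1D line-scan unwrapper, and spectral error
    metrics (relative square error, phasor spectra, radial spectral averages).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
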
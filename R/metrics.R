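#' Relative square error between a phase map and its ground truth
#'
#' \deqn{\mathrm{RSE} = \|\varphi - \varphi_{GT}\|^2 / \|\varphi_{GT}\|^2}
#' (squared Frobenius norms). Returned as a fraction; multiply by 100 for
#' the percentage convention used when reporting.
#'
#' @param phase,truth numeric matrices of matching shape; `truth` must not
#'   be identically zero.
#' @return non-negative scalar fraction.
#' @export
rse <- function(phase, truth) {
  if (!identical(dim(phase), dim(truth)))
    stop("'phase' and 'truth' must have the same shape", call. = FALSE)
  denom <- sum(truth^2)
  if (denom == 0) stop("'truth' has zero norm", call. = FALSE)
  sum((phase - truth)^2) / denom
}

#' Phasor power spectrum of a phase map
#'
#' Magnitude of the 2D discrete Fourier transform of the complex exponential
#' \eqn{e^{i\varphi}}, DC-centered. Working on the phasor rather than the
#' raw phase keeps the spectrum insensitive to wrap boundaries, so it
#' measures the spatial-frequency content of the underlying field.
#'
#' @param phase numeric matrix, radians.
#' @return real matrix of spectral magnitudes with the DC bin at
#'   `(floor(nrow/2) + 1, floor(ncol/2) + 1)`.
#' @export
phasor_spectrum <- function(phase) {
  if (!is.matrix(phase)) stop("'phase' must be a matrix", call. = FALSE)
  if (any(!is.finite(phase))) stop("'phase' contains non-finite values", call. = FALSE)
  .fftshift2(Mod(fft(exp(1i * phase))))
}

# move the DC bin from (1,1) to (floor(n/2)+1, floor(m/2)+1), either parity
.fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  pr <- ((seq_len(n) - 1 - floor(n / 2)) %% n) + 1
  pc <- ((seq_len(m) - 1 - floor(m / 2)) %% m) + 1
  x[pr, pc]
}

#' Radially averaged log-spectrum
#'
#' Averages the natural log of a DC-centered spectrum over concentric
#' annuli of uniform thickness `delta = 1/n_bins` in normalized frequency
#' (|k| in units of the Nyquist frequency), producing the 1D spectral
#' profile used to compare how much high-frequency content different
#' filters preserve. Zero bins are floored at machine epsilon times the
#' spectral maximum before the log. Frequencies beyond Nyquist (the
#' spectrum corners) are ignored. An annulus containing no spectral bins
#' inherits the value of its inner neighbor and is flagged.
#'
#' @param spectrum real non-negative matrix from [phasor_spectrum()]
#'   (DC-centered).
#' @param n_bins number of annuli tiling `(0, 1]` (default 64).
#' @return object of class `"radial_spectrum"`: list with `k` (annulus
#'   center frequencies, strictly increasing), `logI` (mean log intensity
#'   per annulus), `delta` (annulus thickness) and `merged` (indices of
#'   empty annuli that inherited a neighbor's value).
#' @export
radial_spectrum <- function(spectrum, n_bins = 64L) {
  if (!is.matrix(spectrum)) stop("'spectrum' must be a matrix", call. = FALSE)
  if (any(spectrum < 0)) stop("'spectrum' must be non-negative", call. = FALSE)
  n <- nrow(spectrum); m <- ncol(spectrum)
  cy <- floor(n / 2) + 1L; cx <- floor(m / 2) + 1L
  ky <- (seq_len(n) - cy) / (n / 2)   # Nyquist units
  kx <- (seq_len(m) - cx) / (m / 2)
  k <- sqrt(outer(ky^2, kx^2, "+"))
  keep <- k <= 1
  lo <- log(pmax(spectrum[keep], .Machine$double.eps * max(spectrum)))
  bin <- pmin(pmax(ceiling(k[keep] * n_bins), 1L), n_bins)
  sums <- tapply(lo, factor(bin, levels = seq_len(n_bins)), mean)
  logI <- as.numeric(sums)
  merged <- which(is.na(logI))
  for (i in merged) logI[i] <- if (i > 1) logI[i - 1] else logI[which(!is.na(logI))[1]]
  delta <- 1 / n_bins
  structure(list(k = (seq_len(n_bins) - 0.5) * delta, logI = logI,
                 delta = delta, merged = merged),
            class = "radial_spectrum")
}

#' @export
print.radial_spectrum <- function(x, ...) {
  cat(sprintf("Radial log-spectrum: %d annuli of thickness %.4g (Nyquist units)\n",
              length(x$k), x$delta))
  if (length(x$merged))
    cat(sprintf("  %d empty annuli inherited a neighbor's value\n", length(x$merged)))
  invisible(x)
}

#' Relative square error between two radial spectra
#'
#' Compares two radially averaged spectral profiles after converting the
#' log-averages back to intensity and normalizing each curve to its own
#' maximum (so a global intensity rescaling of either spectrum has no
#' effect). The second argument is the reference: the returned value is
#' \eqn{\|\bar I_a - \bar I_b\|^2 / \|\bar I_b\|^2} on the normalized
#' curves, as a fraction.
#'
#' @param a `"radial_spectrum"` under evaluation.
#' @param b `"radial_spectrum"` reference (e.g. from the ground-truth
#'   phase); must use the same binning as `a`.
#' @return non-negative scalar fraction.
#' @export
spectral_rse <- function(a, b) {
  if (!inherits(a, "radial_spectrum") || !inherits(b, "radial_spectrum"))
    stop("inputs must be 'radial_spectrum' objects", call. = FALSE)
  if (length(a$k) != length(b$k) || max(abs(a$k - b$k)) > 1e-12)
    stop("radial spectra use different binnings", call. = FALSE)
  ia <- exp(a$logI - max(a$logI))   # normalized to own max, overflow-safe
  ib <- exp(b$logI - max(b$logI))
  sum((ia - ib)^2) / sum(ib^2)
}
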
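#' Simulate an off-axis hologram intensity
#'
#' Forward model of off-axis interferometric recording: the sample field and
#' a tilted reference beam interfere on the sensor, producing
#' \deqn{I = |E_R|^2 + |E_S|^2 + 2|E_R||E_S|\cos(2\pi q x + \varphi_S - \varphi_R),}
#' where \eqn{x} is the column coordinate in pixels and `q` the carrier
#' fringe frequency in cycles/pixel (carrier along x only). The carrier must
#' keep the first diffraction order separable from the DC term:
#' `0 < f_na < q/2` and `q <= 0.5` (Nyquist).
#'
#' @param sample complex matrix, the sample-arm field \eqn{E_S e^{i\varphi_S}}.
#' @param reference complex matrix of the same shape (default: unit-amplitude
#'   plane wave), the reference-arm field.
#' @param q carrier spatial frequency, cycles/pixel along x.
#' @param f_na radius of the first-order crop filter used downstream,
#'   cycles/pixel; checked here for separability.
#' @return real non-negative intensity matrix.
#' @seealso [demodulate_hologram()]
#' @export
simulate_hologram <- function(sample, reference = NULL, q = 0.25, f_na = 0.08) {
  if (!is.matrix(sample)) stop("'sample' must be a matrix", call. = FALSE)
  if (is.null(reference))
    reference <- matrix(1 + 0i, nrow(sample), ncol(sample))
  if (!identical(dim(sample), dim(reference)))
    stop("'sample' and 'reference' must have the same shape", call. = FALSE)
  if (!(q > 0 && q <= 0.5 && f_na > 0 && f_na < q / 2))
    stop("carrier not separable: need 0 < f_na < q/2 and q <= 0.5", call. = FALSE)
  x <- matrix(0:(ncol(sample) - 1), nrow(sample), ncol(sample), byrow = TRUE)
  ar <- Mod(reference); as_ <- Mod(sample)
  ar^2 + as_^2 + 2 * ar * as_ * cos(2 * pi * q * x + Arg(sample) - Arg(reference))
}

#' Demodulate an off-axis hologram by first-order Fourier filtering
#'
#' Recovers the complex object field from a single off-axis hologram: the
#' intensity spectrum is computed, a disk of radius `f_na` around the first
#' diffraction order (the brightest bin near frequency `(+q, 0)`) is cropped
#' out, shifted to the spectrum center, and inverse-transformed. The
#' argument of the returned field is the wrapped phase difference between
#' the sample and reference arms, band-limited by the crop filter.
#'
#' @param intensity real matrix from [simulate_hologram()] or a recorded
#'   hologram.
#' @param q nominal carrier frequency, cycles/pixel along x; the crop center
#'   is refined to the brightest spectral bin within `f_na` of `(+q, 0)`.
#' @param f_na crop-disk radius, cycles/pixel. A hard-edged disk by default.
#' @param soft_edge if `TRUE`, apply a Gaussian roll-off at the disk edge
#'   instead of a hard cut.
#' @return list with `field` (complex matrix, the recovered object field)
#'   and `phase` (its wrapped argument).
#' @export
demodulate_hologram <- function(intensity, q = 0.25, f_na = 0.08,
                                soft_edge = FALSE) {
  if (!is.matrix(intensity)) stop("'intensity' must be a matrix", call. = FALSE)
  n <- nrow(intensity); m <- ncol(intensity)
  if (f_na >= q / 2)
    warning("first order overlaps DC (f_na >= q/2); proceeding", call. = FALSE)
  fy <- .fft_freq(n); fx <- .fft_freq(m)   # unshifted cycles/pixel
  FI <- fft(intensity)

  # locate the first-order peak near (+q, 0)
  d2 <- outer(fy^2, (fx - q)^2, "+")
  search <- d2 <= f_na^2
  if (!any(search)) search <- d2 <= min(d2) + 1e-12
  mag <- Mod(FI); mag[!search] <- -Inf
  pk <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  py <- fy[pk[1]]; px <- fx[pk[2]]

  # crop a disk around the peak and translate it to DC
  rel2 <- outer(.wrap_freq(fy - py)^2, .wrap_freq(fx - px)^2, "+")
  w <- if (soft_edge) exp(-(rel2 / f_na^2)^4) else (rel2 <= f_na^2) * 1
  G <- matrix(0i, n, m)
  src <- which(w > 1e-12, arr.ind = TRUE)
  # destination bin: frequency (fy - py, fx - px) of each source bin
  dy <- ((src[, 1] - pk[1]) %% n) + 1L
  dx <- ((src[, 2] - pk[2]) %% m) + 1L
  G[cbind(dy, dx)] <- FI[src] * w[src]
  field <- fft(G, inverse = TRUE) / (n * m)
  list(field = field, phase = wrap_phase(Arg(field)))
}

# wrap frequency differences into (-0.5, 0.5] cycles/pixel
.wrap_freq <- function(f) f - ceiling(f - 0.5)
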
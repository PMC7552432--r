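# run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic Gaussian-bump phase
#'
#' Generates a smooth, centered 2D Gaussian phase bump and its wrapped
#' version: the canonical ground-truth object for testing filtering and
#' unwrapping. With the default peak height of 30 rad on a 400 x 600 px
#' grid the wrapped map shows several concentric wrap rings; the noise-free
#' wrap is residue-free by construction (the bump is smooth, so all neighbor
#' differences stay below \eqn{\pi}).
#'
#' @param rows,cols image extent in pixels.
#' @param height peak phase in radians.
#' @param sigma Gaussian width in pixels; the default (60) makes the bump
#'   occupy roughly half the shorter image dimension at 400 x 600.
#' @return list with `truth` (unwrapped ground-truth matrix, peak exactly
#'   `height`), `wrapped` (its wrap), and `center` (`c(row, col)` of the
#'   peak).
#' @examples
#' g <- gaussian_phase(100, 150, height = 30)
#' max(g$truth)            # 30
#' residue_count(g$wrapped)  # 0
#' @export
gaussian_phase <- function(rows = 400L, cols = 600L, height = 30, sigma = 60) {
  stopifnot(height > 0, sigma > 0, rows >= 2L, cols >= 2L)
  # center sits on a pixel so the peak value `height` is attained exactly
  r0 <- ceiling(rows / 2); c0 <- ceiling(cols / 2)
  r2 <- outer((seq_len(rows) - r0)^2, (seq_len(cols) - c0)^2, "+")
  truth <- height * exp(-r2 / (2 * sigma^2))
  list(truth = truth, wrapped = wrap_phase(truth), center = c(r0, c0))
}

#' Corrupt a wrapped phase with speckle and additive white Gaussian noise
#'
#' Noise is applied in the phasor domain, where residues actually arise: the
#' complex field \eqn{z = \exp(i\varphi)} first picks up multiplicative
#' speckle, \eqn{z (1 + u)} with \eqn{u} zero-mean uniform of the given
#' variance (the `imnoise` "speckle" convention), then additive complex
#' white Gaussian noise scaled so the ratio of signal power (of the speckled
#' field) to noise power equals `snr`. The returned phase is the argument of
#' the noisy field. Strong speckle flips the sign of the field at some
#' pixels (a \eqn{\pi} phase error), which is what seeds residue pairs.
#'
#' @param phase numeric matrix, wrapped phase.
#' @param speckle_variance variance of the uniform multiplicative noise
#'   (default 2). `0` disables speckle.
#' @param snr signal-to-noise power ratio of the additive noise (default 6,
#'   linear). `Inf` disables the additive term.
#' @param snr_db interpret `snr` in decibels instead of as a linear ratio.
#' @param seed optional integer; when given, the noise is drawn under a
#'   temporary RNG state so results are reproducible and the caller's RNG
#'   stream is untouched.
#' @return noisy wrapped phase matrix in \eqn{(-\pi, \pi]}.
#' @export
add_phase_noise <- function(phase, speckle_variance = 2, snr = 6,
                            snr_db = FALSE, seed = NULL) {
  stopifnot(is.matrix(phase), speckle_variance >= 0, snr > 0)
  .with_seed(seed, {
    z <- exp(1i * phase)
    if (speckle_variance > 0) {
      a <- sqrt(3 * speckle_variance)  # U(-a, a) has variance a^2/3
      z <- z * (1 + runif(length(z), -a, a))
    }
    snr_lin <- if (snr_db) 10^(snr / 10) else snr
    if (is.finite(snr_lin)) {
      p_sig <- mean(Mod(z)^2)
      s <- sqrt(p_sig / snr_lin / 2)
      z <- z + complex(real = rnorm(length(z), sd = s),
                       imaginary = rnorm(length(z), sd = s))
    }
    wrap_phase(atan2(Im(z), Re(z)))
  })
}

#' Wrapped phase of the default noisy simulation
#'
#' Convenience wrapper producing the standard simulation input: the
#' 400 x 600 px, 30-rad Gaussian bump corrupted by speckle of variance 2 and
#' additive white Gaussian noise at SNR 6.
#'
#' @inheritParams gaussian_phase
#' @inheritParams add_phase_noise
#' @return list with `truth`, `wrapped` (noise-free), `noisy` (the corrupted
#'   wrapped phase) and `center`.
#' @export
simulated_phase <- function(rows = 400L, cols = 600L, height = 30, sigma = 60,
                            speckle_variance = 2, snr = 6, snr_db = FALSE,
                            seed = NULL) {
  g <- gaussian_phase(rows, cols, height, sigma)
  g$noisy <- add_phase_noise(g$wrapped, speckle_variance = speckle_variance,
                             snr = snr, snr_db = snr_db, seed = seed)
  g
}

#' Synthetic vortex phase with prescribed residue charges
#'
#' Builds the wrap of \eqn{\sum_k q_k\,\mathrm{atan2}(r - r_k, c - c_k)}: a
#' deterministic fixture whose residue map has exactly the requested
#' charges. Charge centers must lie strictly between pixel centers (e.g.
#' half-integer coordinates) so each winding point falls inside one 2x2
#' loop.
#'
#' @param rows,cols image extent in pixels.
#' @param charges `data.frame` with columns `row`, `col` (non-integer
#'   center coordinates, 1-based pixel units) and `charge` (signed integer).
#' @return wrapped phase matrix whose [residue_map()] has charge
#'   `charge[k]` in the plaquette containing `(row[k], col[k])` and zeros
#'   elsewhere (for well-separated centers).
#' @export
vortex_phase <- function(rows, cols, charges) {
  stopifnot(is.data.frame(charges),
            all(c("row", "col", "charge") %in% names(charges)))
  if (anyDuplicated(charges[c("row", "col")]))
    stop("coincident vortex centers", call. = FALSE)
  if (any(charges$row <= 1 | charges$row >= rows |
          charges$col <= 1 | charges$col >= cols))
    stop("vortex centers must lie strictly inside the grid", call. = FALSE)
  if (any(charges$row == round(charges$row) & charges$col == round(charges$col)))
    stop("vortex centers must not sit on pixel centers", call. = FALSE)
  r <- matrix(seq_len(rows), rows, cols)
  c_ <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  p <- 0
  for (k in seq_len(nrow(charges)))
    p <- p + charges$charge[k] * atan2(r - charges$row[k], c_ - charges$col[k])
  wrap_phase(p)
}

#' Band-limited textured phase
#'
#' Random smooth phase with energy spread across low *and* high spatial
#' frequencies — a stand-in for a high-resolution natural image, used for
#' spectral-preservation tests. A white Gaussian field is shaped in the
#' Fourier domain with a gently decaying isotropic amplitude envelope, then
#' scaled so that (a) values stay inside \eqn{(-\pi, \pi)} (no wrapping) and
#' (b) all neighbor differences stay below \eqn{\pi}, which makes the map
#' residue-free by construction.
#'
#' @param rows,cols image extent in pixels.
#' @param seed integer seed (required: the fixture is meant to be
#'   reproducible).
#' @param k0 knee of the spectral envelope \eqn{1/(1 + k/k_0)}, as a
#'   fraction of the Nyquist frequency.
#' @param kmax optional hard band limit (Nyquist units): spectral content
#'   above it is removed entirely. `NULL` (default) keeps the full band —
#'   use a finite value when a strictly band-limited phase is needed, e.g.
#'   as a hologram sample phase that must survive first-order crop
#'   filtering.
#' @return wrapped (but wrap-free) phase matrix.
#' @export
textured_phase <- function(rows, cols, seed, k0 = 0.1, kmax = NULL) {
  stopifnot(rows >= 4L, cols >= 4L, k0 > 0)
  .with_seed(seed, {
    w <- matrix(rnorm(rows * cols), rows, cols)
    fy <- .fft_freq(rows); fx <- .fft_freq(cols)
    k <- sqrt(outer(fy^2, fx^2, "+")) / 0.5  # |k| in Nyquist units
    env <- 1 / (1 + k / k0)
    if (!is.null(kmax)) env[k > kmax] <- 0
    x <- Re(fft(fft(w) * env, inverse = TRUE)) / (rows * cols)
    dmax <- max(abs(diff(x)), abs(t(diff(t(x)))))
    x <- x * min(0.95 * pi / max(abs(x)), 0.90 * pi / dmax)
    wrap_phase(x)
  })
}

# unshifted DFT frequencies in cycles/pixel
.fft_freq <- function(n) {
  f <- c(0:(n - 1))
  f[f > n / 2] <- f[f > n / 2] - n
  f / n
}
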
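#' Windowed phasor filtering of a wrapped phase
#'
#' Filters a wrapped phase map in the phasor domain: each pixel is replaced
#' by \eqn{\arg L[\exp(i\varphi)]}, where \eqn{L} is a sliding-window
#' statistic of the complex exponential over a `wf[1] x wf[2]` neighborhood.
#' Because the complex exponential has no sawtooth jumps, this smooths noise
#' without destroying the wrap boundaries that unwrapping relies on.
#'
#' Two window statistics are available: `"mean"` (the phasor average) and
#' `"median"` (marginal median — the median of the real and of the imaginary
#' parts taken independently; the true geometric median is not used, for
#' cost). Borders are handled by reflect padding, which avoids the spurious
#' edge residues zero padding would create. If the window statistic of some
#' pixel is (numerically) the zero phasor — antipodal phasors cancelling —
#' that pixel keeps its input value and a message reports how many pixels
#' fell back.
#'
#' @param phase numeric matrix, wrapped phase in radians.
#' @param wf window extent in pixels: a single odd integer, or a length-2
#'   vector `c(rows, cols)` of odd integers for an anisotropic window.
#'   `wf = 1` is the identity.
#' @param mode `"mean"` (default) or `"median"`.
#' @return filtered wrapped phase matrix, values in \eqn{(-\pi, \pi]}.
#' @examples
#' p <- wrap_phase(matrix(seq(0, 6 * pi, length.out = 64^2), 64, 64))
#' f <- phasor_filter(p, wf = 3)
#' @export
phasor_filter <- function(phase, wf = 3L, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  if (!is.matrix(phase) || !is.numeric(phase))
    stop("'phase' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(phase))) stop("'phase' contains non-finite values", call. = FALSE)
  wf <- as.integer(wf)
  if (length(wf) == 1L) wf <- c(wf, wf)
  if (length(wf) != 2L || any(wf < 1L) || any(wf %% 2L == 0L))
    stop("'wf' must be one or two odd integers >= 1", call. = FALSE)
  if (all(wf == 1L)) return(wrap_phase(phase))

  st <- .phasor_window_stat(cos(phase), sin(phase), wf[1], wf[2],
                            mode == "median")
  amp <- sqrt(st$re^2 + st$im^2)
  out <- atan2(st$im, st$re)
  degenerate <- amp < 1e-12
  if (any(degenerate)) {
    out[degenerate] <- phase[degenerate]
    message(sum(degenerate), " pixel(s) had a zero phasor statistic; input value kept")
  }
  wrap_phase(out)
}

#' Global phasor average filtering (PAF baseline)
#'
#' Applies [phasor_filter()] to every pixel of the map — the non-smart
#' baseline. Used for comparison against [spaf()], which filters only patches
#' around residues: global filtering removes residues too, but blurs the
#' whole image and degrades high-spatial-frequency content everywhere.
#'
#' @inheritParams phasor_filter
#' @return filtered wrapped phase matrix.
#' @seealso [spaf()]
#' @export
global_paf <- function(phase, wf = 3L, mode = c("mean", "median")) {
  phasor_filter(phase, wf = wf, mode = match.arg(mode))
}
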
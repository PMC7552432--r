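#' Unwrap a 1D phase sequence
#'
#' Cumulative (Itoh) integration of wrapped neighbor differences:
#' `out[1] = phase[1]`, `out[k] = out[k-1] + wrap_diff(phase[k], phase[k-1])`.
#' Exact whenever the true neighbor differences are below \eqn{\pi} in
#' magnitude; the jump threshold is fixed at \eqn{\pi}.
#'
#' @param phase finite numeric vector, radians.
#' @return numeric vector; differs from `phase` elementwise by integer
#'   multiples of \eqn{2\pi}.
#' @export
unwrap_line <- function(phase) {
  if (any(!is.finite(phase))) stop("'phase' contains non-finite values", call. = FALSE)
  if (length(phase) < 2L) return(phase)
  phase[1] + cumsum(c(0, wrap_diff(phase[-1], phase[-length(phase)])))
}

#' Unwrap a 2D phase map by 1D line scans
#'
#' The simple 2D application of [unwrap_line()]: with
#' `order = "cols-rows"` (the default, matching 1D unwrapping along the
#' first array dimension), every column is unwrapped independently, then the
#' first row of the result is unwrapped and each column is shifted by the
#' resulting offset so rows become consistent. `order = "rows-cols"` is the
#' transposed traversal.
#'
#' Line-scan unwrapping is exact only on residue-free maps; when residues
#' are present the result is path-dependent, and a warning is emitted. On
#' residue-free inputs both traversal orders agree up to one global
#' \eqn{2\pi k} constant.
#'
#' @param phase numeric matrix, wrapped phase.
#' @param order `"cols-rows"` (default) or `"rows-cols"`.
#' @return numeric matrix of unwrapped phase, with attribute `"order"`
#'   recording the traversal. Re-wrapping it with [wrap_phase()] reproduces
#'   `wrap_phase(phase)` exactly up to floating-point roundoff in the
#'   accumulated sums.
#' @export
unwrap_phase <- function(phase, order = c("cols-rows", "rows-cols")) {
  order <- match.arg(order)
  if (!is.matrix(phase)) stop("'phase' must be a matrix", call. = FALSE)
  if (residue_count(phase) > 0L)
    warning("phase map contains residues; line-scan unwrapping is path-dependent",
            call. = FALSE)
  out <- .unwrap2d(if (order == "cols-rows") phase else t(phase))
  if (order == "rows-cols") out <- t(out)
  # snap to input + 2*pi*k, k integer, so the cumulative-sum roundoff cannot
  # drift the pixelwise offset away from an exact multiple of 2*pi
  k <- round((out - phase) / (2 * pi))
  out <- phase + (2 * pi) * k
  attr(out, "order") <- order
  out
}

# unwrap every column, then align columns via the unwrapped first row
.unwrap2d <- function(p) {
  out <- apply(p, 2, unwrap_line)
  first <- unwrap_line(out[1, ])
  sweep(out, 2, first - out[1, ], "+")
}
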
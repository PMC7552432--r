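#' Wrap phase values into (-pi, pi]
#'
#' Reduces phase values modulo \eqn{2\pi} into the half-open interval
#' \eqn{(-\pi, \pi]}. The upper endpoint is included: an input of exactly
#' \eqn{-\pi} maps to \eqn{+\pi}, matching the convention of the argument of
#' a complex exponential. Idempotent on already-wrapped input.
#'
#' @param phase numeric vector or matrix of phase values in radians; must be
#'   finite.
#' @return object of the same shape with all values in \eqn{(-\pi, \pi]}.
#' @examples
#' wrap_phase(3 * pi / 2)   # -pi/2
#' wrap_phase(pi)           # stays pi
#' @export
wrap_phase <- function(phase) {
  if (!is.numeric(phase)) stop("'phase' must be numeric", call. = FALSE)
  if (any(!is.finite(phase))) stop("'phase' contains non-finite values", call. = FALSE)
  phase - 2 * pi * ceiling((phase - pi) / (2 * pi))
}

#' Wrapped (modulo-2pi) difference of two phases
#'
#' Shortest signed arc from `b` to `a`: `wrap_phase(a - b)`, in
#' \eqn{(-\pi, \pi]}. This is the gradient operator used along residue loops;
#' antisymmetric except when the result is exactly \eqn{\pi} (the half-open
#' interval makes both orderings return \eqn{+\pi} there).
#'
#' @param a,b numeric scalars, vectors or matrices of matching shape, radians.
#' @return wrapped difference, same shape as the inputs.
#' @examples
#' wrap_diff(pi - 0.1, -pi + 0.1)  # -0.2: crosses the wrap boundary
#' @export
wrap_diff <- function(a, b) {
  if (length(a) != length(b) && length(a) != 1L && length(b) != 1L)
    stop("'a' and 'b' must have matching shape (or be scalar)", call. = FALSE)
  wrap_phase(a - b)
}

#' Phase residue map on 2x2 pixel loops
#'
#' Sums wrapped phase differences around every closed 2x2 pixel loop and
#' divides by \eqn{2\pi}, yielding an integer topological charge per
#' plaquette. A nonzero charge marks a phase residue: an obstruction that
#' makes path-following unwrapping path-dependent. The loop is traversed
#' counter-clockwise in image coordinates,
#' `(i,j) -> (i,j+1) -> (i+1,j+1) -> (i+1,j) -> (i,j)`, and the charge is
#' anchored at the loop's top-left pixel `(i,j)`. Reversing the orientation
#' only flips all charge signs.
#'
#' @param phase numeric matrix of wrapped (or wrappable) phase, at least 2x2.
#' @return integer matrix of shape `(nrow-1) x (ncol-1)`; entry `(i,j)` is
#'   the charge of the loop anchored at pixel `(i,j)`.
#' @seealso [fpr_mask()], [residue_count()], [residues_to_df()]
#' @examples
#' p <- vortex_phase(16, 16, data.frame(row = 8.5, col = 8.5, charge = 1))
#' sum(residue_map(p) != 0)  # one residue
#' @export
residue_map <- function(phase) {
  if (!is.matrix(phase) || nrow(phase) < 2L || ncol(phase) < 2L)
    stop("'phase' must be a matrix of at least 2x2", call. = FALSE)
  if (any(!is.finite(phase))) stop("'phase' contains non-finite values", call. = FALSE)
  n <- nrow(phase); m <- ncol(phase)
  tl <- phase[-n, -m]; tr <- phase[-n, -1]
  bl <- phase[-1, -m]; br <- phase[-1, -1]
  s <- wrap_diff(tr, tl) + wrap_diff(br, tr) + wrap_diff(bl, br) + wrap_diff(tl, bl)
  ch <- round(s / (2 * pi))
  storage.mode(ch) <- "integer"
  ch
}

#' Count nonzero residues of a phase map
#'
#' @param phase numeric matrix of wrapped phase.
#' @return integer: number of 2x2 loops with nonzero charge.
#' @export
residue_count <- function(phase) sum(residue_map(phase) != 0L)

#' Mask of first pixels in residue loops (FPRs)
#'
#' Converts a residue map into a binary mask over the *phase* grid, marking
#' the anchor (top-left) pixel of every loop with nonzero charge — the "first
#' pixel in a residue loop". The mask has one more row and column than the
#' charge grid so that it aligns with the phase map it came from.
#'
#' @param charges integer matrix from [residue_map()].
#' @return logical matrix of shape `(nrow+1) x (ncol+1)`; `TRUE` exactly at
#'   the anchor pixel of each nonzero charge.
#' @export
fpr_mask <- function(charges) {
  if (!is.matrix(charges)) stop("'charges' must be a matrix", call. = FALSE)
  mask <- matrix(FALSE, nrow(charges) + 1L, ncol(charges) + 1L)
  mask[cbind(1L, 1L)] <- FALSE  # keep shape when no residues
  idx <- which(charges != 0L, arr.ind = TRUE)
  if (nrow(idx)) mask[idx] <- TRUE
  mask
}

#' Residue map as a data frame
#'
#' @param charges integer matrix from [residue_map()].
#' @return `data.frame` with columns `row`, `col` (1-based anchor pixel) and
#'   `charge`, one row per nonzero residue. Suitable for CSV export.
#' @export
residues_to_df <- function(charges) {
  idx <- which(charges != 0L, arr.ind = TRUE)
  data.frame(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
             charge = charges[idx])
}
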
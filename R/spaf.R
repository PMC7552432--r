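#' Binary patch mask around residue pixels
#'
#' Builds the union of `wp x wp` all-ones squares around each marked residue
#' anchor (FPR) pixel, clipped at the image border. Squares are centered on
#' the anchor and extended right/down when `wp` is even, so that `wp = 2`
#' covers exactly the 2x2 residue loop. Overlapping squares merge into one
#' region (no pixel is marked twice).
#'
#' @param fpr logical matrix from [fpr_mask()], same shape as the phase.
#' @param wp patch extent in pixels, `>= 1`.
#' @return logical matrix of the same shape; `TRUE` marks pixels to filter.
#' @export
patch_mask <- function(fpr, wp) {
  if (!is.matrix(fpr) || !is.logical(fpr))
    stop("'fpr' must be a logical matrix", call. = FALSE)
  wp <- as.integer(wp)
  if (length(wp) != 1L || wp < 1L) stop("'wp' must be a single integer >= 1", call. = FALSE)
  n <- nrow(fpr); m <- ncol(fpr)
  out <- matrix(FALSE, n, m)
  idx <- which(fpr, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  lo <- (wp - 1L) %/% 2L      # extent above/left
  hi <- wp - 1L - lo          # extent below/right (ties extend right/down)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    out[max(1L, r - lo):min(n, r + hi), max(1L, c - lo):min(m, c + hi)] <- TRUE
  }
  out
}

#' One locally restricted filtering step
#'
#' The elementary update of smart phasor average filtering: the whole map is
#' phasor-filtered, but only pixels inside the patch mask take the filtered
#' value; every pixel outside is returned bit-identical. The filter windows
#' still read the full previous phase, so values just outside a patch
#' influence values inside it, never the reverse.
#'
#' @param phase numeric matrix, wrapped phase.
#' @param fpr logical matrix marking residue anchor pixels ([fpr_mask()]).
#' @param wf filter window, as in [phasor_filter()].
#' @param wp patch extent in pixels.
#' @param mode filter statistic, `"mean"` or `"median"`.
#' @return updated wrapped phase matrix.
#' @export
spaf_step <- function(phase, fpr, wf, wp, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  if (!identical(dim(phase), dim(fpr)))
    stop("'phase' and 'fpr' must have the same shape", call. = FALSE)
  if (!any(fpr)) return(phase)
  pm <- patch_mask(fpr, wp)
  filtered <- phasor_filter(phase, wf = wf, mode = mode)
  out <- phase
  out[pm] <- filtered[pm]
  out
}

#' Smart phasor average filtering (SPAF)
#'
#' Iteratively removes phase residues from a noisy wrapped phase map by
#' filtering *only* small patches around each residue, so that filtering
#' artifacts stay locally restricted and high-spatial-frequency content away
#' from residues is untouched. Each iteration: (1) locate the residues
#' (nonzero 2x2 loop charges, [residue_map()]); (2) if none remain
#' (or the count is at `target_residues`), stop; (3) phasor-filter the map
#' with the current window `wf` and substitute the filtered values only
#' inside `wp x wp` patches around each residue anchor. Residue locations
#' are recomputed every iteration because filtering can shift residues to
#' neighboring pixels. When progress stalls, the filter window is escalated
#' first (`wf + 2`, keeping it odd), and only when the window is exhausted
#' is the patch enlarged (`wp + 1`) and the window escalation restarted —
#' enlarging patches before strengthening the filter would spread artifacts
#' further than necessary.
#'
#' Termination: residues at or below `target_residues` (status
#' `"residue-free"`), both caps exhausted with no further progress
#' (`"cap-reached"`), or `max_iterations` filtering steps applied
#' (`"max-iter"`). Non-convergence is reported via the status, not as an
#' error. If the target is reached exactly when the iteration cap would
#' trigger, the status is `"residue-free"`. The procedure is deterministic:
#' no randomness is involved.
#'
#' @param phase numeric matrix, wrapped phase in radians (values outside
#'   \eqn{(-\pi, \pi]} are wrapped first).
#' @param wf_start,wf_max odd filter-window extents in pixels; escalation
#'   runs `wf_start, wf_start + 2, ..., wf_max`.
#' @param wp_start,wp_max patch extents in pixels; `wp_start = 2` covers
#'   exactly the 2x2 residue loop, `wp_max = 15` caps patch growth.
#' @param mode phasor statistic, `"mean"` (default) or `"median"`.
#' @param max_iterations cap on the number of filtering steps.
#' @param target_residues stop once the residue count is `<=` this (default
#'   0; raise it when a map's residues cannot all be removed and a small
#'   remainder is acceptable).
#' @param escalation `"stall"` (default): escalate `(wf, wp)` only when the
#'   residue count fails to drop below the best count so far; `"always"`:
#'   escalate every iteration.
#' @return an object of class `"spaf"`: a list with elements
#'   \describe{
#'     \item{phase}{the filtered wrapped phase (matrix).}
#'     \item{input}{the input wrapped phase.}
#'     \item{trace}{`data.frame` with one row per iteration: `iteration`,
#'       `wf_rows`, `wf_cols`, `wp`, `n_residues`. The first row reports the
#'       input's residue count; the last row reports the final count.}
#'     \item{status}{`"residue-free"`, `"cap-reached"` or `"max-iter"`.}
#'     \item{n_residues}{final residue count.}
#'     \item{config}{the schedule parameters used.}
#'   }
#' @seealso [global_paf()] for the non-smart baseline, [unwrap_phase()] for
#'   the subsequent unwrapping step.
#' @examples
#' p <- vortex_phase(48, 48, data.frame(row = c(24.5, 24.5),
#'                                      col = c(22.5, 26.5),
#'                                      charge = c(1, -1)))
#' fit <- spaf(p)
#' fit$status
#' @export
spaf <- function(phase,
                 wf_start = 3L, wf_max = 15L,
                 wp_start = 2L, wp_max = 15L,
                 mode = c("mean", "median"),
                 max_iterations = 1000L,
                 target_residues = 0L,
                 escalation = c("stall", "always")) {
  mode <- match.arg(mode)
  escalation <- match.arg(escalation)
  if (!is.matrix(phase) || nrow(phase) < 2L || ncol(phase) < 2L)
    stop("'phase' must be a numeric matrix of at least 2x2", call. = FALSE)
  wf_start <- as.integer(wf_start); wf_max <- as.integer(wf_max)
  wp_start <- as.integer(wp_start); wp_max <- as.integer(wp_max)
  if (wf_start %% 2L == 0L || wf_max %% 2L == 0L)
    stop("'wf_start' and 'wf_max' must be odd", call. = FALSE)
  if (wf_start > wf_max || wp_start > wp_max)
    stop("window/patch start must not exceed its cap", call. = FALSE)
  if (max_iterations < 1L) stop("'max_iterations' must be >= 1", call. = FALSE)

  input <- wrap_phase(phase)
  cur <- input
  wf <- wf_start; wp <- wp_start
  best <- Inf
  rows <- list()
  status <- NULL
  m <- 0L
  repeat {
    m <- m + 1L
    rm <- residue_map(cur)
    cnt <- sum(rm != 0L)
    if (cnt <= target_residues) {
      rows[[m]] <- c(m, wf, wf, wp, cnt)
      status <- "residue-free"
      break
    }
    if (m > max_iterations) {
      rows[[m]] <- c(m, wf, wf, wp, cnt)
      status <- "max-iter"
      break
    }
    if (m > 1L && (escalation == "always" || cnt >= best)) {
      if (wf + 2L <= wf_max) {
        wf <- wf + 2L
      } else if (wp + 1L <= wp_max) {
        wp <- wp + 1L
        wf <- wf_start
      } else if (escalation == "stall" || cnt >= best) {
        rows[[m]] <- c(m, wf, wf, wp, cnt)
        status <- "cap-reached"
        break
      }
    }
    best <- min(best, cnt)
    rows[[m]] <- c(m, wf, wf, wp, cnt)
    cur <- spaf_step(cur, fpr_mask(rm), wf = wf, wp = wp, mode = mode)
  }
  trace <- as.data.frame(do.call(rbind, rows))
  names(trace) <- c("iteration", "wf_rows", "wf_cols", "wp", "n_residues")
  structure(list(
    phase = cur,
    input = input,
    trace = trace,
    status = status,
    n_residues = trace$n_residues[nrow(trace)],
    config = list(wf_start = wf_start, wf_max = wf_max,
                  wp_start = wp_start, wp_max = wp_max, mode = mode,
                  max_iterations = max_iterations,
                  target_residues = target_residues,
                  escalation = escalation)
  ), class = "spaf")
}

#' @export
print.spaf <- function(x, ...) {
  cat("Smart phasor average filtering\n")
  cat(sprintf("  phase map: %d x %d px\n", nrow(x$phase), ncol(x$phase)))
  cat(sprintf("  residues:  %d -> %d in %d iteration(s)\n",
              x$trace$n_residues[1], x$n_residues, nrow(x$trace)))
  cat(sprintf("  status:    %s (final wf = %d, wp = %d, mode = %s)\n",
              x$status, x$trace$wf_rows[nrow(x$trace)],
              x$trace$wp[nrow(x$trace)], x$config$mode))
  invisible(x)
}

#' @export
summary.spaf <- function(object, ...) {
  tr <- object$trace
  esc <- which(diff(tr$wf_rows) != 0 | diff(tr$wp) != 0)
  out <- list(
    dim = dim(object$phase),
    status = object$status,
    iterations = nrow(tr),
    residues_initial = tr$n_residues[1],
    residues_final = object$n_residues,
    n_escalations = length(esc),
    pixels_touched = sum(object$phase != object$input),
    config = object$config,
    trace = tr
  )
  class(out) <- "summary.spaf"
  out
}

#' @export
print.summary.spaf <- function(x, ...) {
  cat("Smart phasor average filtering\n")
  cat(sprintf("  phase map:       %d x %d px\n", x$dim[1], x$dim[2]))
  cat(sprintf("  status:          %s after %d iteration(s), %d escalation(s)\n",
              x$status, x$iterations, x$n_escalations))
  cat(sprintf("  residues:        %d -> %d\n", x$residues_initial, x$residues_final))
  cat(sprintf("  pixels modified: %d of %d (%.2f%%)\n", x$pixels_touched,
              prod(x$dim), 100 * x$pixels_touched / prod(x$dim)))
  cat(sprintf("  schedule:        wf %d..%d (+2), wp %d..%d (+1), mode %s, escalation on %s\n",
              x$config$wf_start, x$config$wf_max, x$config$wp_start,
              x$config$wp_max, x$config$mode, x$config$escalation))
  invisible(x)
}

#' Filtered wrapped phase of a SPAF fit
#' @param object a `"spaf"` object.
#' @param ... unused.
#' @return the filtered wrapped phase matrix.
#' @export
fitted.spaf <- function(object, ...) object$phase

#' Residue map of the filtered phase
#'
#' For a SPAF fit the natural residual is what the procedure tried to drive
#' to zero: the residue charge map of the filtered phase.
#'
#' @param object a `"spaf"` object.
#' @param ... unused.
#' @return integer charge matrix (see [residue_map()]).
#' @export
residuals.spaf <- function(object, ...) residue_map(object$phase)

#' Plot the residue count across SPAF iterations
#'
#' Residue count per iteration on a (by default) log-scaled y axis, with
#' schedule escalations marked — the diagnostic view of the iterative
#' schedule.
#'
#' @param x a `"spaf"` object.
#' @param log_y plot counts on a log axis (zero counts shown at the axis
#'   floor). Default `TRUE`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spaf <- function(x, log_y = TRUE, ...) {
  tr <- x$trace
  y <- tr$n_residues
  if (log_y) y <- pmax(y, 0.5)
  plot(tr$iteration, y, type = "b", pch = 16,
       log = if (log_y) "y" else "",
       xlab = "iteration", ylab = "number of residues",
       main = "Residue count vs iteration", ...)
  esc <- which(c(FALSE, diff(tr$wp) != 0))
  if (length(esc)) abline(v = tr$iteration[esc], lty = 3, col = "grey50")
  invisible(x)
}
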
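# Independent brute-force oracles. Deliberately scalar/loop-based and kept
# separate from the package implementation paths they check.

# shortest signed arc by explicit minimization of |a - b - 2*pi*k|
bf_wrap_diff <- function(a, b) {
  ks <- -5:5
  cand <- a - b - 2 * pi * ks
  d <- cand[which.min(abs(cand))]
  # half-open interval: an exact -pi result belongs at +pi
  if (isTRUE(all.equal(d, -pi)) && d <= -pi) d <- d + 2 * pi
  d
}

# per-plaquette 4-edge loop sums, no vectorization
bf_residue_map <- function(phase) {
  n <- nrow(phase); m <- ncol(phase)
  ch <- matrix(0L, n - 1, m - 1)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(m - 1)) {
      s <- bf_wrap_diff(phase[i, j + 1], phase[i, j]) +
           bf_wrap_diff(phase[i + 1, j + 1], phase[i, j + 1]) +
           bf_wrap_diff(phase[i + 1, j], phase[i + 1, j + 1]) +
           bf_wrap_diff(phase[i, j], phase[i + 1, j])
      ch[i, j] <- as.integer(round(s / (2 * pi)))
    }
  }
  ch
}

# charge enclosed by the image-boundary loop (counter-clockwise, same
# orientation as the plaquette loops)
bf_boundary_charge <- function(phase) {
  n <- nrow(phase); m <- ncol(phase)
  path <- rbind(
    cbind(1, 1:m),                       # along the top row
    cbind(2:n, m),                       # down the right column
    cbind(n, (m - 1):1),                 # back along the bottom row
    cbind((n - 1):1, 1)                  # up the left column
  )
  s <- 0
  for (t in seq_len(nrow(path) - 1))
    s <- s + bf_wrap_diff(phase[path[t + 1, 1], path[t + 1, 2]],
                          phase[path[t, 1], path[t, 2]])
  s <- s + bf_wrap_diff(phase[path[1, 1], path[1, 2]],
                        phase[path[nrow(path), 1], path[nrow(path), 2]])
  as.integer(round(s / (2 * pi)))
}

bf_reflect <- function(i, n) {
  if (n == 1) return(1L)
  i0 <- i - 1L
  while (i0 < 0L || i0 >= n) {
    if (i0 < 0L) i0 <- -i0 - 1L
    if (i0 >= n) i0 <- 2L * n - i0 - 1L
  }
  i0 + 1L
}

# windowed phasor statistic at one pixel, explicit loops + reflect padding
bf_phasor_stat_at <- function(phase, i, j, wr, wc, mode = "mean") {
  hr <- (wr - 1) / 2; hc <- (wc - 1) / 2
  vals <- complex(0)
  for (dr in -hr:hr) {
    for (dc in -hc:hc) {
      vals <- c(vals, exp(1i * phase[bf_reflect(i + dr, nrow(phase)),
                                     bf_reflect(j + dc, ncol(phase))]))
    }
  }
  z <- if (mode == "mean") mean(vals)
       else complex(real = stats::median(Re(vals)),
                    imaginary = stats::median(Im(vals)))
  Arg(z)
}

# union of wp x wp squares around anchor pixels, via an explicit pixel set
bf_patch_union <- function(anchors, wp, n, m) {
  lo <- (wp - 1) %/% 2; hi <- wp - 1 - lo
  px <- character(0)
  for (k in seq_len(nrow(anchors))) {
    for (r in max(1, anchors[k, 1] - lo):min(n, anchors[k, 1] + hi)) {
      for (cc in max(1, anchors[k, 2] - lo):min(m, anchors[k, 2] + hi)) {
        px <- c(px, paste(r, cc))
      }
    }
  }
  unique(px)
}

# per-pixel annulus assignment for radial averaging
bf_radial_average <- function(spectrum, n_bins) {
  n <- nrow(spectrum); m <- ncol(spectrum)
  cy <- floor(n / 2) + 1; cx <- floor(m / 2) + 1
  acc <- vector("list", n_bins)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      k <- sqrt(((i - cy) / (n / 2))^2 + ((j - cx) / (m / 2))^2)
      if (k > 1) next
      b <- min(max(ceiling(k * n_bins), 1), n_bins)
      acc[[b]] <- c(acc[[b]], log(max(spectrum[i, j],
                                      .Machine$double.eps * max(spectrum))))
    }
  }
  vapply(acc, function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
}

# replay a SPAF fit step by step from its trace; returns TRUE when every
# iteration only changed pixels inside its patch mask and the replayed final
# phase is bit-identical to the fit
replay_spaf_locality <- function(fit) {
  cur <- fit$input
  tr <- fit$trace
  for (m in seq_len(nrow(tr) - 1)) {
    fpr <- fpr_mask(residue_map(cur))
    pm <- patch_mask(fpr, tr$wp[m])
    nxt <- spaf_step(cur, fpr, wf = c(tr$wf_rows[m], tr$wf_cols[m]),
                     wp = tr$wp[m], mode = fit$config$mode)
    if (!identical(nxt[!pm], cur[!pm])) return(FALSE)
    cur <- nxt
  }
  identical(cur, fit$phase)
}

# independent DC-centering for spectra built in tests
.fftshift_for_tests <- function(x) {
  n <- nrow(x); m <- ncol(x)
  # simple roll: DC (1,1) moves to (floor(n/2)+1, floor(m/2)+1)
  pr <- c((n - floor(n / 2) + 1):n, 1:(n - floor(n / 2)))
  pc <- c((m - floor(m / 2) + 1):m, 1:(m - floor(m / 2)))
  x[pr, pc]
}
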
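#' Read a phase map from a grayscale TIFF or PNG
#'
#' Thin wrapper over the \pkg{tiff} / \pkg{png} readers returning a plain
#' numeric matrix (first channel if the file has several). Values are
#' returned as stored; no rescaling to radians is attempted.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return numeric matrix.
#' @export
read_phase <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF files", call. = FALSE)
      tiff::readTIFF(path, as.is = FALSE)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' is required to read PNG files", call. = FALSE)
      png::readPNG(path)
    },
    stop("unsupported file extension: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a phase map to a 32-bit float TIFF
#'
#' @param phase numeric matrix (radians; stored as-is).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase <- function(phase, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write TIFF files", call. = FALSE)
  tiff::writeTIFF(phase, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a PNG overlay of residues on a phase map
#'
#' Renders the wrapped phase as grayscale and marks each residue anchor
#' pixel in red (positive charge) or blue (negative) — a quick visual check
#' of where residues sit.
#'
#' @param phase numeric matrix, wrapped phase.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
residue_overlay_png <- function(phase, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required to write PNG files", call. = FALSE)
  g <- (phase - min(phase)) / max(diff(range(phase)), .Machine$double.eps)
  img <- array(g, c(nrow(phase), ncol(phase), 3))
  ch <- residue_map(phase)
  pos <- which(ch > 0L, arr.ind = TRUE); neg <- which(ch < 0L, arr.ind = TRUE)
  if (nrow(pos)) {
    img[cbind(pos, 1)] <- 1; img[cbind(pos, 2)] <- 0; img[cbind(pos, 3)] <- 0
  }
  if (nrow(neg)) {
    img[cbind(neg, 1)] <- 0; img[cbind(neg, 2)] <- 0; img[cbind(neg, 3)] <- 1
  }
  png::writePNG(img, path)
  invisible(path)
}
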
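# Ensemble of per-seed contours into a boundary probability map (BPM).

#' Ensemble contours into a boundary probability map
#'
#' For every pixel p, let k be the number of contours whose boundary-or-region
#' covers p. The boundary probability is the fraction of those k contours
#' that place p on their boundary:
#' \code{P(p on gland boundary) = (# contours with p on boundary) / k},
#' and 0 where no contour covers p. Accumulation uses two integer counter
#' maps followed by a single division, so the result is independent of
#' contour order and free of floating accumulation error.
#'
#' @param contours list of \code{gs_contour} (see [rasterize_contour()])
#' @param shape image dimensions \code{c(height, width)}
#' @return object of class \code{gs_bpm} with fields \code{prob} (numeric
#'   matrix in \[0, 1\]) and \code{coverage} (integer matrix of k per pixel)
#' @export
ensemble <- function(contours, shape) {
  shape <- as.integer(shape)
  bcount <- matrix(0L, shape[1L], shape[2L])
  cover <- matrix(0L, shape[1L], shape[2L])
  for (ct in contours) {
    if (!is.null(ct$shape) && !identical(as.integer(ct$shape), shape))
      stop("contour shape does not match the requested map shape", call. = FALSE)
    b <- ct$boundary_idx
    r <- ct$region_idx
    if (length(b) > 0L) {
      bcount[b] <- bcount[b] + 1L
      cover[b] <- cover[b] + 1L
    }
    if (length(r) > 0L) cover[r] <- cover[r] + 1L
  }
  prob <- matrix(0, shape[1L], shape[2L])
  nz <- cover > 0L
  prob[nz] <- bcount[nz] / cover[nz]
  structure(list(prob = prob, coverage = cover), class = "gs_bpm")
}

#' @export
print.gs_bpm <- function(x, ...) {
  cat(sprintf("<gs_bpm %d x %d, covered %.1f%%, mean prob %.3f>\n",
              nrow(x$prob), ncol(x$prob), 100 * mean(x$coverage > 0),
              mean(x$prob)))
  invisible(x)
}

#' Export a boundary probability map
#'
#' Writes the probabilities as a grayscale image via [save_image()] (16-bit
#' when TIFF, values scaled by 65535) or, with a \code{.txt} extension, as a
#' whitespace-separated matrix.
#'
#' @param bpm a \code{gs_bpm}
#' @param path output path (.png, .tif/.tiff or .txt)
#' @return the path, invisibly
#' @export
export_bpm <- function(bpm, path) {
  if (tolower(tools::file_ext(path)) == "txt") {
    write.table(bpm$prob, path, row.names = FALSE, col.names = FALSE)
  } else {
    save_image(bpm$prob, path)
  }
  invisible(path)
}
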
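# Segmentation proposals: BPM truncation and watershed partition.

#' Truncate a boundary probability map
#'
#' Values below the threshold T are set to 0; values at or above T are kept.
#' The untruncated probabilities are retained on the returned object so that
#' later stages (proposal pruning, refinement, merging) can read boundary
#' evidence from the original map.
#'
#' @param bpm a \code{gs_bpm} from [ensemble()]
#' @param T truncation threshold in \[0, 1\] (default 0.5)
#' @return a \code{gs_bpm} with truncated \code{prob} and the original map in
#'   \code{untruncated}
#' @export
truncate_bpm <- function(bpm, T = 0.5) {
  stopifnot(T >= 0, T <= 1)
  orig <- if (is.null(bpm$untruncated)) bpm$prob else bpm$untruncated
  p <- orig
  p[p < T] <- 0
  structure(list(prob = p, coverage = bpm$coverage, untruncated = orig),
            class = "gs_bpm")
}

#' Watershed segmentation proposals
#'
#' The truncated BPM is viewed as an elevation map (high probability =
#' ridge). Basins are flooded from the connected plateaus of the minimum
#' elevation (the zeroed sub-threshold area); each catchment basin becomes
#' one proposal. Watershed ridge pixels are assigned to the adjacent basin
#' whose neighboring pixels have the lower mean elevation (ties to the lower
#' basin id), so the proposals partition the image and are pairwise disjoint.
#' Each proposal's contour is the inner 8-connected boundary of its pixel
#' set, and its mean boundary probability is computed over the contour pixels
#' from the untruncated BPM.
#'
#' @param tbpm a truncated \code{gs_bpm} (see [truncate_bpm()]); an
#'   untruncated map is accepted and used as-is
#' @return object of class \code{gs_proposals}: fields \code{regions} (list
#'   of proposal regions with \code{id}, \code{pixels}, \code{contour},
#'   \code{area}, \code{mean_boundary_prob}), \code{labels} (integer matrix,
#'   ridge pixels assigned), \code{basins} (integer matrix, ridges = 0) and
#'   \code{shape}
#' @export
watershed_proposals <- function(tbpm) {
  elev <- tbpm$prob
  orig <- if (is.null(tbpm$untruncated)) tbpm$prob else tbpm$untruncated
  ws <- cpp_watershed(elev)
  labels <- ws$labels
  regions <- regions_from_labels(labels, orig)
  structure(list(regions = regions, labels = labels, basins = ws$basins,
                 shape = dim(elev)),
            class = "gs_proposals")
}

# Inner 8-connected boundary mask of a label matrix: a pixel is on its
# region's contour if any 8-neighbor carries a different label or lies
# outside the image.
contour_mask <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  p <- matrix(-1L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- labels
  out <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
    out <- out | (nb != labels)
  }
  out
}

# Build proposal-region records from a full label matrix.
regions_from_labels <- function(labels, prob) {
  cm <- contour_mask(labels)
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  idx_all <- which(labels > 0L)
  by_label <- split(idx_all, labels[idx_all])
  lapply(ids, function(id) {
    px <- by_label[[as.character(id)]]
    ctr <- px[cm[px]]
    if (length(ctr) == 0L) ctr <- px  # single-pixel or degenerate region
    list(id = id, pixels = px, contour = ctr, area = length(px),
         mean_boundary_prob = mean(prob[ctr]))
  })
}

#' @export
print.gs_proposals <- function(x, ...) {
  cat(sprintf("<gs_proposals %d regions on %d x %d image>\n",
              length(x$regions), x$shape[1L], x$shape[2L]))
  invisible(x)
}

#' Convert proposals (or a list of regions) to an instance mask
#'
#' @param x a \code{gs_proposals} object or a list of proposal regions
#' @param shape image dimensions, required when \code{x} is a plain list
#' @return an integer label matrix of class \code{gs_mask}
#' @export
proposals_to_mask <- function(x, shape = NULL) {
  if (inherits(x, "gs_proposals")) {
    regions <- x$regions
    shape <- x$shape
  } else {
    regions <- x
    if (is.null(shape)) stop("shape is required for a plain region list",
                             call. = FALSE)
  }
  m <- matrix(0L, shape[1L], shape[2L])
  for (k in seq_along(regions)) m[regions[[k]]$pixels] <- k
  as_gs_mask(m)
}
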
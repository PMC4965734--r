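# Post-processing: boundary-resource re-weighting of proposal scores and
# greedy merging of over-segmented neighbors.

# 1-px dilated contour band of a region (8-neighborhood of its contour
# pixels, clipped to the image). Using a dilated band lets neighboring
# regions compete for the same boundary resource pixels.
contour_band <- function(region, shape) {
  rc <- idx_to_rc(region$contour, shape)
  rows <- rep(rc[, 1L], each = 9L) + rep(-1:1, times = 3L)
  cols <- rep(rc[, 2L], each = 9L) + rep(-1:1, each = 3L)
  ok <- rows >= 1L & rows <= shape[1L] & cols >= 1L & cols <= shape[2L]
  unique((cols[ok] - 1L) * shape[1L] + rows[ok])
}

#' Re-weight proposal scores by boundary-resource consumption
#'
#' Gland borders are treated as a consumable resource held in the boundary
#' probability map. Proposals are processed in strictly decreasing score
#' order (ties by region id): each proposal measures the mean remaining
#' resource over its 1-px dilated contour band; if that availability falls
#' below \code{avail_threshold} its score is multiplied by \code{lambda_d},
#' otherwise it is kept; the proposal then consumes (zeroes) the resource on
#' its band. Scores never increase, and a proposal consuming untouched
#' resource at or above the threshold is never down-weighted. Gland flags are
#' refreshed against the detection threshold afterwards.
#'
#' @param scored list of scored proposals (see [score_proposals()])
#' @param bpm a \code{gs_bpm}; its untruncated probabilities are the resource
#' @param cfg a [gs_config] (supplies \code{lambda_d},
#'   \code{avail_threshold}, \code{detect_threshold})
#' @return the scored list with updated \code{score}, \code{is_gland} and an
#'   \code{availability} field, in the original order
#' @export
reweight <- function(scored, bpm, cfg = gs_config()) {
  if (length(scored) == 0L) return(scored)
  shape <- dim(bpm$prob)
  remaining <- if (is.null(bpm$untruncated)) bpm$prob else bpm$untruncated
  scores <- vapply(scored, `[[`, numeric(1L), "score")
  ids <- vapply(scored, function(s) s$region$id, numeric(1L))
  ord <- order(-scores, ids)
  for (k in ord) {
    band <- contour_band(scored[[k]]$region, shape)
    a <- mean(remaining[band])
    if (a < cfg$avail_threshold)
      scored[[k]]$score <- scored[[k]]$score * cfg$lambda_d
    scored[[k]]$availability <- a
    remaining[band] <- 0
  }
  for (k in seq_along(scored))
    scored[[k]]$is_gland <- scored[[k]]$score >= cfg$detect_threshold
  scored
}

# Interface pixels between two disjoint regions: contour pixels of p that
# are 8-adjacent to q, plus contour pixels of q 8-adjacent to p.
interface_pixels <- function(p, q, shape) {
  in_q <- matrix(FALSE, shape[1L], shape[2L])
  in_q[q$pixels] <- TRUE
  in_p <- matrix(FALSE, shape[1L], shape[2L])
  in_p[p$pixels] <- TRUE
  touches <- function(ctr, other) {
    rc <- idx_to_rc(ctr, shape)
    hit <- logical(length(ctr))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- rc[, 1L] + dr; cc <- rc[, 2L] + dc
      ok <- rr >= 1L & rr <= shape[1L] & cc >= 1L & cc <= shape[2L]
      h <- logical(length(ctr))
      h[ok] <- other[(cc[ok] - 1L) * shape[1L] + rr[ok]]
      hit <- hit | h
    }
    ctr[hit]
  }
  c(touches(p$contour, in_q), touches(q$contour, in_p))
}

# Dilate interface pixels by one pixel (8-neighborhood), restricted to the
# pixels of the two regions involved, giving the shared-contour band the
# merge affinity is averaged over.
dilate_within <- function(ifx, allowed_idx, shape) {
  allow <- matrix(FALSE, shape[1L], shape[2L])
  allow[allowed_idx] <- TRUE
  rc <- idx_to_rc(ifx, shape)
  rows <- rep(rc[, 1L], each = 9L) + rep(-1:1, times = 3L)
  cols <- rep(rc[, 2L], each = 9L) + rep(-1:1, each = 3L)
  ok <- rows >= 1L & rows <= shape[1L] & cols >= 1L & cols <= shape[2L]
  cand <- unique((cols[ok] - 1L) * shape[1L] + rows[ok])
  cand[allow[cand]]
}

#' Merge affinity of two neighboring proposals
#'
#' \code{P_pq = 1 - mean(BPM over the shared contour band)}: high when the
#' evidence for a boundary between the two regions is weak. Watershed
#' proposals are disjoint, so the shared contour is realized as the set of
#' contour pixels of either region that are 8-adjacent to the other region,
#' dilated by one pixel within the union of the two regions. Averaging over
#' this band lets full-consensus borders (boundary probability near 1)
#' withstand merging while partial-consensus internal seams do not.
#'
#' @param p,q proposal regions
#' @param bpm a \code{gs_bpm} (untruncated probabilities are used)
#' @return a real in \[0, 1\]
#' @export
merge_score <- function(p, q, bpm) {
  shape <- dim(bpm$prob)
  prob <- if (is.null(bpm$untruncated)) bpm$prob else bpm$untruncated
  ifx <- interface_pixels(p, q, shape)
  if (length(ifx) == 0L)
    stop("regions are not neighbors (no adjacent contour pixels)", call. = FALSE)
  band <- dilate_within(ifx, c(p$pixels, q$pixels), shape)
  1 - mean(prob[band])
}

# All neighboring pairs among the given regions, with their interfaces,
# computed from a label matrix by 8-neighborhood shifts.
neighbor_pairs <- function(regions, shape) {
  L <- matrix(0L, shape[1L], shape[2L])
  for (k in seq_along(regions)) L[regions[[k]]$pixels] <- k
  h <- shape[1L]; w <- shape[2L]
  P <- matrix(0L, h + 2L, w + 2L)
  P[2:(h + 1L), 2:(w + 1L)] <- L
  pairs <- new.env(parent = emptyenv())
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- P[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
    sel <- which(L > 0L & nb > 0L & L != nb)
    if (length(sel) == 0L) next
    a <- L[sel]; b <- nb[sel]
    key <- paste(pmin(a, b), pmax(a, b))
    for (u in unique(key)) {
      px <- sel[key == u]
      if (is.null(pairs[[u]])) pairs[[u]] <- integer(0)
      pairs[[u]] <- c(pairs[[u]], px)
    }
  }
  keys <- ls(pairs)
  if (length(keys) == 0L)
    return(data.frame(p = integer(0), q = integer(0)))
  out <- do.call(rbind, lapply(keys, function(u) {
    pq <- as.integer(strsplit(u, " ")[[1L]])
    data.frame(p = pq[1L], q = pq[2L])
  }))
  out$interface <- lapply(keys, function(u) unique(pairs[[u]]))
  out
}

#' Greedy merging of over-segmented neighbors
#'
#' Among gland-flagged proposals, the neighboring pair with the highest merge
#' affinity \code{P_pq} is merged repeatedly until the best affinity drops
#' below \code{merge_threshold} (default 0.5). A merged region's pixels are
#' the union of the pair; its score is the area-weighted mean of the two
#' scores; its contour, area and mean boundary probability are recomputed,
#' and pair affinities involving the merged region are refreshed. Terminates
#' after at most (number of gland regions - 1) merges. Non-gland proposals
#' pass through untouched.
#'
#' @param scored list of scored proposals
#' @param bpm a \code{gs_bpm}
#' @param cfg a [gs_config]
#' @return list of scored proposals after merging
#' @export
greedy_merge <- function(scored, bpm, cfg = gs_config()) {
  shape <- dim(bpm$prob)
  prob <- if (is.null(bpm$untruncated)) bpm$prob else bpm$untruncated
  gl <- which(vapply(scored, `[[`, logical(1L), "is_gland"))
  if (length(gl) < 2L) return(scored)
  glands <- scored[gl]
  rest <- scored[-gl]
  repeat {
    regions <- lapply(glands, `[[`, "region")
    np <- neighbor_pairs(regions, shape)
    if (nrow(np) == 0L) break
    np$p_pq <- vapply(seq_len(nrow(np)), function(i) {
      band <- dilate_within(np$interface[[i]],
                            c(regions[[np$p[i]]]$pixels,
                              regions[[np$q[i]]]$pixels), shape)
      1 - mean(prob[band])
    }, numeric(1L))
    best <- order(-np$p_pq, np$p, np$q)[1L]
    if (np$p_pq[best] < cfg$merge_threshold) break
    i <- np$p[best]; j <- np$q[best]
    a <- glands[[i]]; b <- glands[[j]]
    px <- c(a$region$pixels, b$region$pixels)
    merged_region <- rebuild_region(px, min(a$region$id, b$region$id),
                                    prob, shape)
    wa <- a$region$area; wb <- b$region$area
    merged <- list(region = merged_region,
                   score = (wa * a$score + wb * b$score) / (wa + wb),
                   is_gland = TRUE)
    glands[[i]] <- merged
    glands[[j]] <- NULL
  }
  c(glands, rest)
}

# Recompute contour, area and mean boundary probability of a pixel set.
rebuild_region <- function(pixels, id, prob, shape) {
  mask <- matrix(0L, shape[1L], shape[2L])
  mask[pixels] <- 1L
  cm <- contour_mask(mask)
  ctr <- pixels[cm[pixels]]
  if (length(ctr) == 0L) ctr <- pixels
  list(id = id, pixels = pixels, contour = ctr, area = length(pixels),
       mean_boundary_prob = mean(prob[ctr]))
}
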
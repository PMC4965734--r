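# End-to-end orchestration: proposal generation, training, segmentation of a
# single image, and leave-one-image-out cross-validation.

#' Compute the boundary probability map of an image
#'
#' Runs the full seeding and searching stage (uniform-grid seeds, per-seed
#' polar graph, divide-and-conquer cyclic shortest path, rasterization) and
#' ensembles all contours into a boundary probability map.
#'
#' @param img a [gs_image]
#' @param cfg a [gs_config]
#' @param keep_contours return the individual contours as well (memory-heavy
#'   on large images)
#' @return a \code{gs_bpm}; with \code{keep_contours = TRUE}, a list
#'   \code{(bpm, contours, seeds)}
#' @export
compute_bpm <- function(img, cfg = gs_config(), keep_contours = FALSE) {
  img <- as_gs_image(img)
  edges <- sobel_edges(img)
  seeds <- sample_seeds(img, cfg)
  shape <- c(img$height, img$width)
  bcount <- matrix(0L, shape[1L], shape[2L])
  cover <- matrix(0L, shape[1L], shape[2L])
  contours <- if (keep_contours) vector("list", nrow(seeds)) else NULL
  for (k in seq_len(nrow(seeds))) {
    g <- build_polar_graph(seeds[k, ], img, edges, cfg)
    ct <- shortest_closed_path_dc(g)
    b <- ct$boundary_idx; r <- ct$region_idx
    if (length(b) > 0L) {
      bcount[b] <- bcount[b] + 1L
      cover[b] <- cover[b] + 1L
    }
    if (length(r) > 0L) cover[r] <- cover[r] + 1L
    if (keep_contours) contours[[k]] <- ct
  }
  prob <- matrix(0, shape[1L], shape[2L])
  nz <- cover > 0L
  prob[nz] <- bcount[nz] / cover[nz]
  bpm <- structure(list(prob = prob, coverage = cover), class = "gs_bpm")
  if (keep_contours) list(bpm = bpm, contours = contours, seeds = seeds)
  else bpm
}

#' Generate pruned, featurized proposals for one image
#'
#' Convenience stage runner: BPM, truncation at \code{bpm_threshold},
#' watershed, pruning, and feature extraction. If a ground-truth mask is
#' given, each kept proposal's Jaccard target (see [iou_score()]) is
#' attached.
#'
#' @param img a [gs_image]
#' @param cfg a [gs_config]
#' @param gt optional instance mask for training targets
#' @return list with \code{bpm}, \code{proposals} (all), \code{kept},
#'   \code{pruned}, \code{features} (matrix for kept), \code{targets}
#'   (numeric or NULL)
#' @export
prepare_image <- function(img, cfg = gs_config(), gt = NULL) {
  img <- as_gs_image(img)
  bpm <- compute_bpm(img, cfg)
  tb <- truncate_bpm(bpm, cfg$bpm_threshold)
  props <- watershed_proposals(tb)
  pr <- prune_proposals(props, cfg)
  features <- feature_matrix(pr$kept, img, cfg)
  targets <- if (is.null(gt)) NULL else
    vapply(pr$kept, iou_score, numeric(1L), gt = gt)
  list(bpm = tb, proposals = props, kept = pr$kept, pruned = pr$pruned,
       features = features, targets = targets)
}

#' Train a proposal scorer from image/mask pairs
#'
#' Proposals of every training image are generated, pruned, and featurized;
#' the random forest regresses the per-proposal Jaccard overlap with the
#' ground truth. Only proposals surviving the pruning step are trained on.
#'
#' @param images list of [gs_image]
#' @param masks list of matching instance masks
#' @param cfg a [gs_config]
#' @param prepared optional precomputed output of [prepare_image()] per image
#' @return a \code{gs_scorer}
#' @export
train_pipeline <- function(images, masks, cfg = gs_config(), prepared = NULL) {
  stopifnot(length(images) == length(masks))
  if (is.null(prepared))
    prepared <- mapply(prepare_image, images, gt = masks,
                       MoreArgs = list(cfg = cfg), SIMPLIFY = FALSE)
  features <- do.call(rbind, lapply(prepared, `[[`, "features"))
  targets <- unlist(lapply(prepared, `[[`, "targets"))
  train_scorer(features, targets, cfg)
}

#' Segment one image
#'
#' Full flow: seeding, searching, ensemble, truncation + watershed, pruning,
#' features, random-forest scoring, boundary-resource re-weighting, and
#' greedy merging. Returns the final gland instance mask and a scored-region
#' table.
#'
#' @param img a [gs_image] (or a path readable by [load_image()])
#' @param scorer a trained \code{gs_scorer} (or a path readable by
#'   [load_scorer()])
#' @param cfg a [gs_config]
#' @param merge apply the merging step (default TRUE)
#' @param prepared optional precomputed output of [prepare_image()]
#' @return list of class \code{gs_segmentation}: \code{mask}
#'   (\code{gs_mask} of detected glands), \code{table} (data.frame of region
#'   id, area, score, availability, gland flag), \code{scored},
#'   \code{scored_unmerged}, \code{bpm}, \code{proposals}
#' @export
segment_image <- function(img, scorer, cfg = gs_config(), merge = TRUE,
                          prepared = NULL) {
  if (is.character(img)) img <- load_image(img)
  if (is.character(scorer)) {
    if (!file.exists(scorer))
      stop("no trained model at ", scorer,
           "; train one with train_pipeline() or the `train` CLI command",
           call. = FALSE)
    scorer <- load_scorer(scorer)
  }
  img <- as_gs_image(img)
  if (is.null(prepared)) prepared <- prepare_image(img, cfg)
  scored <- score_proposals(scorer, prepared$kept, prepared$features, cfg)
  scored <- reweight(scored, prepared$bpm, cfg)
  unmerged <- scored
  if (merge) scored <- greedy_merge(scored, prepared$bpm, cfg)
  glands <- Filter(function(s) isTRUE(s$is_gland), scored)
  mask <- proposals_to_mask(lapply(glands, `[[`, "region"),
                            shape = dim(prepared$bpm$prob))
  tab <- if (length(scored) == 0L)
    data.frame(id = integer(0), area = integer(0), score = numeric(0),
               availability = numeric(0), is_gland = logical(0))
  else do.call(rbind, lapply(scored, function(s) {
    data.frame(id = s$region$id, area = s$region$area, score = s$score,
               availability = if (is.null(s$availability)) NA_real_
                              else s$availability,
               is_gland = s$is_gland)
  }))
  structure(list(mask = mask, table = tab, scored = scored,
                 scored_unmerged = unmerged, bpm = prepared$bpm,
                 proposals = prepared$proposals, features = prepared$features,
                 image = img),
            class = "gs_segmentation")
}

#' @export
print.gs_segmentation <- function(x, ...) {
  cat(sprintf("<gs_segmentation: %d gland regions of %d scored proposals>\n",
              sum(x$table$is_gland), nrow(x$table)))
  invisible(x)
}

gland_regions <- function(scored) {
  lapply(Filter(function(s) isTRUE(s$is_gland), scored), `[[`, "region")
}

#' Leave-one-image-out cross-validation
#'
#' For each fold, the scorer is trained on all images but one and evaluated
#' on the held-out image; no test-image pixels influence training. Detection
#' and pixel metrics are pooled over folds (summed counts), reported both
#' with and without the merging step.
#'
#' @param images list of [gs_image]
#' @param masks list of matching instance masks
#' @param cfg a [gs_config]
#' @return list of class \code{gs_cv}: \code{folds} (per-fold results),
#'   \code{pooled} (with/without merging, detection and pixel metrics)
#' @export
cross_validate <- function(images, masks, cfg = gs_config()) {
  n <- length(images)
  stopifnot(n >= 2L, length(masks) == n)
  prepared <- mapply(prepare_image, images, gt = masks,
                     MoreArgs = list(cfg = cfg), SIMPLIFY = FALSE)
  folds <- vector("list", n)
  for (k in seq_len(n)) {
    tr <- setdiff(seq_len(n), k)
    scorer <- train_pipeline(images[tr], masks[tr], cfg, prepared = prepared[tr])
    seg_m <- segment_image(images[[k]], scorer, cfg, merge = TRUE,
                           prepared = prepared[[k]])
    det_m <- evaluate_detection(gland_regions(seg_m$scored), masks[[k]])
    pix_m <- evaluate_pixels(gland_regions(seg_m$scored), masks[[k]])
    det_u <- evaluate_detection(gland_regions(seg_m$scored_unmerged), masks[[k]])
    pix_u <- evaluate_pixels(gland_regions(seg_m$scored_unmerged), masks[[k]])
    folds[[k]] <- list(fold = k, train_images = tr,
                       merged = list(detection = det_m, pixels = pix_m),
                       unmerged = list(detection = det_u, pixels = pix_u))
  }
  pool <- function(get) {
    res <- lapply(folds, get)
    tp <- sum(vapply(res, `[[`, numeric(1L), "tp"))
    fp <- sum(vapply(res, `[[`, numeric(1L), "fp"))
    fn <- sum(vapply(res, `[[`, numeric(1L), "fn"))
    c(list(tp = tp, fp = fp, fn = fn), prf(tp, fp, fn))
  }
  pooled <- list(
    with_merging = list(detection = pool(function(f) f$merged$detection),
                        pixels = pool(function(f) f$merged$pixels)),
    without_merging = list(detection = pool(function(f) f$unmerged$detection),
                           pixels = pool(function(f) f$unmerged$pixels)))
  structure(list(folds = folds, pooled = pooled, n = n), class = "gs_cv")
}

#' @export
print.gs_cv <- function(x, ...) {
  fmt <- function(m) sprintf("P=%.3f R=%.3f F=%.3f", m$precision, m$recall,
                             m$f_score)
  cat(sprintf("<gs_cv %d folds>\n", x$n))
  cat("  with merging:    detection ", fmt(x$pooled$with_merging$detection),
      " | pixels ", fmt(x$pooled$with_merging$pixels), "\n", sep = "")
  cat("  without merging: detection ", fmt(x$pooled$without_merging$detection),
      " | pixels ", fmt(x$pooled$without_merging$pixels), "\n", sep = "")
  invisible(x)
}
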
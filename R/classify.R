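# Proposal pruning, feature extraction (basic statistics + HOG), and
# random-forest scoring of segmentation proposals.

#' Prune implausible proposals
#'
#' A proposal is removed if its area is below \code{prune_min_area} or its
#' mean boundary probability (over its contour pixels, from the untruncated
#' BPM) is below \code{prune_boundary_prob} (default 0.3). Both lists are
#' returned for audit; kept and pruned partition the input.
#'
#' @param props a \code{gs_proposals} object or list of proposal regions
#' @param cfg a [gs_config]
#' @return list with elements \code{kept} and \code{pruned}
#' @export
prune_proposals <- function(props, cfg = gs_config()) {
  regions <- if (inherits(props, "gs_proposals")) props$regions else props
  drop <- vapply(regions, function(rg) {
    rg$area < cfg$prune_min_area ||
      rg$mean_boundary_prob < cfg$prune_boundary_prob
  }, logical(1L))
  list(kept = regions[!drop], pruned = regions[drop])
}

#' Jaccard overlap of a proposal against the ground truth
#'
#' The score P(R) of a proposal region is its maximum intersection-over-union
#' against any single ground-truth instance:
#' \code{max_gt |R \U2229 R_gt| / |R \U222A R_gt|}; 0 when the ground truth
#' is empty. Equals 1 exactly when the proposal's pixel set equals some
#' instance's pixel set.
#'
#' @param proposal a proposal region (needs \code{pixels} and \code{area})
#' @param gt an instance label matrix (\code{gs_mask})
#' @return a real in \[0, 1\]
#' @export
iou_score <- function(proposal, gt) {
  glab <- gt[proposal$pixels]
  glab <- glab[glab > 0L]
  if (length(glab) == 0L) return(0)
  inter <- table(glab)
  gt_areas <- tabulate(gt[gt > 0L])
  ids <- as.integer(names(inter))
  ious <- as.numeric(inter) / (proposal$area + gt_areas[ids] - as.numeric(inter))
  max(ious)
}

# population standard deviation (0 for constant or single-pixel input)
sd_pop <- function(v) {
  if (length(v) == 0L) return(0)
  sqrt(mean((v - mean(v))^2))
}

#' Extract a feature vector for one proposal region
#'
#' Five basic features (region mean intensity, region intensity standard
#' deviation, region area in pixels, contour mean intensity, contour
#' intensity standard deviation) concatenated with a HOG descriptor of the
#' region's bounding-box patch. The patch is masked outside the region to the
#' region's mean intensity, bilinearly resized to \code{hog_side} pixels
#' square, and described with \code{hog_bins} unsigned orientation bins over
#' \code{hog_cell}-pixel cells grouped into L2-normalized
#' \code{hog_block}x\code{hog_block}-cell blocks (stride one cell).
#'
#' @param region a proposal region
#' @param img a [gs_image]
#' @param cfg a [gs_config]
#' @return named numeric vector (fixed length for a given config)
#' @export
extract_features <- function(region, img, cfg = gs_config()) {
  img <- as_gs_image(img)
  if (length(region$pixels) == 0L) stop("empty proposal region", call. = FALSE)
  rc <- idx_to_rc(region$pixels, c(img$height, img$width))
  if (any(rc[, 1L] < 1L | rc[, 1L] > img$height |
          rc[, 2L] < 1L | rc[, 2L] > img$width))
    stop("region lies outside the image", call. = FALSE)
  vals <- img$intensity[region$pixels]
  cvals <- img$intensity[region$contour]
  basic <- c(region_mean = mean(vals), region_sd = sd_pop(vals),
             area = as.numeric(region$area),
             contour_mean = mean(cvals), contour_sd = sd_pop(cvals))
  patch <- region_patch(region, img, rc, cfg$hog_side)
  hog <- hog_descriptor(patch, bins = cfg$hog_bins, cell = cfg$hog_cell,
                        block = cfg$hog_block)
  out <- c(basic, hog)
  if (any(!is.finite(out))) stop("non-finite feature values", call. = FALSE)
  out
}

# Bounding-box patch of a region, masked to the region mean outside the
# region, resized to side x side.
region_patch <- function(region, img, rc, side) {
  r0 <- min(rc[, 1L]); r1 <- max(rc[, 1L])
  c0 <- min(rc[, 2L]); c1 <- max(rc[, 2L])
  sub <- img$intensity[r0:r1, c0:c1, drop = FALSE]
  inmask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  inmask[cbind(rc[, 1L] - r0 + 1L, rc[, 2L] - c0 + 1L)] <- TRUE
  sub[!inmask] <- mean(sub[inmask])
  resize_bilinear(sub, side, side)
}

# Bilinear resize of a matrix to out_h x out_w (align corners).
resize_bilinear <- function(m, out_h, out_w) {
  src_y <- if (out_h == 1L) (nrow(m) - 1) / 2 else
    (seq_len(out_h) - 1) * (nrow(m) - 1) / (out_h - 1)
  src_x <- if (out_w == 1L) (ncol(m) - 1) / 2 else
    (seq_len(out_w) - 1) * (ncol(m) - 1) / (out_w - 1)
  g <- expand.grid(y = src_y, x = src_x, KEEP.OUT.ATTRS = FALSE)
  matrix(cpp_bilinear_sample(m, g$x, g$y), out_h, out_w)
}

#' Histogram of oriented gradients of a square patch
#'
#' Classic dense HOG: centered \code{[-1, 0, 1]} gradients (replicated
#' borders), unsigned orientations in \[0, 180) with magnitude votes split
#' linearly between the two nearest bin centers, cell histograms, and
#' L2-normalized overlapping blocks (stride one cell). A constant patch
#' yields the all-zero descriptor.
#'
#' @param patch numeric matrix (side divisible by \code{cell})
#' @param bins number of orientation bins
#' @param cell cell side in pixels
#' @param block block side in cells
#' @return numeric vector of length
#'   \code{(ncells - block + 1)^2 * block^2 * bins}
#' @export
hog_descriptor <- function(patch, bins = 9L, cell = 8L, block = 2L) {
  h <- nrow(patch); w <- ncol(patch)
  stopifnot(h %% cell == 0L, w %% cell == 0L)
  # centered gradients with replicated borders
  gx <- patch[, c(2:w, w), drop = FALSE] - patch[, c(1L, 1:(w - 1L)), drop = FALSE]
  gy <- patch[c(2:h, h), , drop = FALSE] - patch[c(1L, 1:(h - 1L)), , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  mag[mag < 1e-12] <- 0  # numerical dust from interpolation is not a gradient
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180  # unsigned orientation
  binw <- 180 / bins
  pos <- ang / binw - 0.5
  b0 <- floor(pos)
  frac <- pos - b0
  b0 <- (as.integer(b0) %% bins) + 1L
  b1 <- (b0 %% bins) + 1L
  cy <- (row(patch) - 1L) %/% cell + 1L
  cx <- (col(patch) - 1L) %/% cell + 1L
  ncy <- h %/% cell; ncx <- w %/% cell
  # accumulate cell histograms: index (cell_y, cell_x, bin)
  acc <- function(b, wgt) {
    idx <- cy + (cx - 1L) * ncy + (b - 1L) * ncy * ncx
    hcount <- tabulate(idx, nbins = ncy * ncx * bins)
    wsum <- rep(0, ncy * ncx * bins)
    t <- tapply(wgt, idx, sum)
    wsum[as.integer(names(t))] <- t
    wsum
  }
  hist3 <- array(acc(b0, as.vector(mag) * (1 - as.vector(frac))) +
                 acc(b1, as.vector(mag) * as.vector(frac)),
                 dim = c(ncy, ncx, bins))
  nby <- ncy - block + 1L; nbx <- ncx - block + 1L
  out <- numeric(nby * nbx * block * block * bins)
  k <- 0L
  blen <- block * block * bins
  for (bx in seq_len(nbx)) for (by in seq_len(nby)) {
    v <- as.vector(hist3[by:(by + block - 1L), bx:(bx + block - 1L), ])
    nrm <- sqrt(sum(v^2) + 1e-12)
    if (sum(v^2) > 0) v <- v / nrm
    out[(k * blen + 1L):((k + 1L) * blen)] <- v
    k <- k + 1L
  }
  names(out) <- paste0("hog", seq_along(out))
  out
}

#' Build the feature matrix for a list of regions
#'
#' @param regions list of proposal regions
#' @param img a [gs_image]
#' @param cfg a [gs_config]
#' @return numeric matrix, one row per region
#' @export
feature_matrix <- function(regions, img, cfg = gs_config()) {
  if (length(regions) == 0L) {
    probe <- length(extract_features(
      list(pixels = 1L, contour = 1L, area = 1L), gs_image(matrix(0.5, 8, 8)), cfg))
    return(matrix(numeric(0), 0L, probe))
  }
  t(vapply(regions, extract_features, numeric(length(
    extract_features(regions[[1L]], img, cfg))), img = img, cfg = cfg))
}

feature_fingerprint <- function(cfg, n_features) {
  paste("glandseg-features", n_features, cfg$hog_side, cfg$hog_bins,
        cfg$hog_cell, cfg$hog_block, as.integer(cfg$use_pca), sep = "-")
}

#' Train the random-forest proposal scorer
#'
#' Fits a regression random forest predicting the Jaccard overlap target
#' P(R) in \[0, 1\] from proposal features, with a fixed random seed for
#' reproducibility. Optionally projects features with PCA (fit on the
#' training data only) retaining \code{pca_var} of the variance. Out-of-bag
#' RMSE is stored and logged.
#'
#' @param features numeric feature matrix (rows = proposals)
#' @param targets numeric vector of regression targets in \[0, 1\]
#' @param cfg a [gs_config]
#' @return object of class \code{gs_scorer}
#' @export
train_scorer <- function(features, targets, cfg = gs_config()) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(targets), nrow(features) >= 10L)
  if (any(targets < 0 | targets > 1))
    stop("targets must lie in [0, 1]", call. = FALSE)
  if (length(unique(targets)) == 1L)
    warning("degenerate constant targets; the scorer will predict a constant",
            call. = FALSE)
  pca <- NULL
  x <- features
  if (isTRUE(cfg$use_pca)) {
    pca_fit <- prcomp(features, center = TRUE, scale. = FALSE)
    cum <- cumsum(pca_fit$sdev^2) / sum(pca_fit$sdev^2)
    ncomp <- max(1L, which(cum >= cfg$pca_var)[1L])
    pca <- list(center = pca_fit$center,
                rotation = pca_fit$rotation[, seq_len(ncomp), drop = FALSE])
    x <- project_pca(features, pca)
  }
  set.seed(cfg$random_seed)
  rf <- randomForest::randomForest(x = x, y = targets, ntree = cfg$rf_ntree)
  oob <- sqrt(mean((rf$predicted - targets)^2))
  gs_log(sprintf("scorer trained on %d proposals, OOB RMSE %.4f",
                 nrow(features), oob))
  structure(list(rf = rf, pca = pca, oob_rmse = oob,
                 fingerprint = feature_fingerprint(cfg, ncol(features)),
                 version = as.character(utils::packageVersion("glandseg"))),
            class = "gs_scorer")
}

project_pca <- function(features, pca) {
  sweep(features, 2L, pca$center) %*% pca$rotation
}

#' @export
print.gs_scorer <- function(x, ...) {
  cat(sprintf("<gs_scorer %s trees=%d OOB RMSE %.4f fingerprint=%s>\n",
              x$version, x$rf$ntree, x$oob_rmse, x$fingerprint))
  invisible(x)
}

#' Persist / restore a trained scorer
#'
#' The scorer is stored with its feature-configuration fingerprint embedded;
#' scoring with a mismatched feature configuration is refused.
#'
#' @param scorer a \code{gs_scorer}
#' @param path file path
#' @return \code{save_scorer}: the path, invisibly; \code{load_scorer}: the
#'   scorer
#' @export
save_scorer <- function(scorer, path) {
  saveRDS(scorer, path)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  s <- readRDS(path)
  if (!inherits(s, "gs_scorer")) stop("not a gs_scorer file: ", path, call. = FALSE)
  s
}

#' Score proposals with a trained scorer
#'
#' Predicted scores are clipped to \[0, 1\]; a proposal is flagged as gland
#' when its score reaches the detection threshold. Sweeping the threshold
#' yields the detection precision-recall curve.
#'
#' @param scorer a \code{gs_scorer}
#' @param props list of proposal regions (kept after pruning)
#' @param features feature matrix matching \code{props} row for row
#' @param cfg a [gs_config]; supplies the detection threshold and the
#'   feature fingerprint check
#' @return list of scored proposals, each with fields \code{region},
#'   \code{score} and \code{is_gland}
#' @export
score_proposals <- function(scorer, props, features, cfg = gs_config()) {
  if (length(props) == 0L) return(list())
  features <- as.matrix(features)
  if (!identical(scorer$fingerprint, feature_fingerprint(cfg, ncol(features))))
    stop("feature configuration does not match the trained scorer (",
         scorer$fingerprint, ")", call. = FALSE)
  x <- if (is.null(scorer$pca)) features else project_pca(features, scorer$pca)
  sc <- as.numeric(predict(scorer$rf, x))
  sc <- pmin(pmax(sc, 0), 1)
  mapply(function(rg, s) {
    list(region = rg, score = s, is_gland = s >= cfg$detect_threshold)
  }, props, sc, SIMPLIFY = FALSE)
}
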
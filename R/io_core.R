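# Image/mask I/O, grayscale conversion, Sobel edges, and pipeline
# configuration shared by all stages.

#' Grayscale image container
#'
#' Wraps a numeric matrix of intensities in \[0, 1\]. Intensities are stored
#' as \code{intensity[row, col]}; see the package help page for the pixel
#' coordinate convention.
#'
#' @param intensity numeric matrix with values in \[0, 1\]
#' @return an object of class \code{gs_image} with fields \code{intensity},
#'   \code{height} and \code{width}
#' @export
gs_image <- function(intensity) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) < 1L || ncol(intensity) < 1L)
    stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(intensity) || min(intensity) < 0 || max(intensity) > 1)
    stop("intensity values must lie in [0, 1]", call. = FALSE)
  structure(list(intensity = intensity,
                 height = nrow(intensity), width = ncol(intensity)),
            class = "gs_image")
}

as_gs_image <- function(x) {
  if (inherits(x, "gs_image")) x else gs_image(x)
}

#' @export
print.gs_image <- function(x, ...) {
  cat(sprintf("<gs_image %d x %d, intensity range [%.3f, %.3f]>\n",
              x$height, x$width, min(x$intensity), max(x$intensity)))
  invisible(x)
}

# BT.601 luminance weights used for RGB -> grayscale conversion.
.luma <- c(r = 0.299, g = 0.587, b = 0.114)

#' Load an image as grayscale
#'
#' Reads a PNG or TIFF image. RGB(A) input is converted to a single luminance
#' channel with the ITU-R BT.601 weights 0.299 R + 0.587 G + 0.114 B;
#' grayscale input is passed through. Output intensities are scaled to
#' \[0, 1\].
#'
#' @param path path to a PNG or TIFF file
#' @return a [gs_image]
#' @export
load_image <- function(path) {
  arr <- read_raster(path, as_integer = FALSE)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      arr <- .luma["r"] * arr[, , 1L] + .luma["g"] * arr[, , 2L] +
        .luma["b"] * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  arr <- pmin(pmax(arr, 0), 1)
  gs_image(arr)
}

read_raster <- function(path, as_integer = FALSE) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = as_integer)
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    if (as_integer) {
      depth <- attr(arr, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      arr <- round(arr * (2^depth - 1))
    }
  } else {
    stop("unsupported image format: ", ext, " (PNG and TIFF are supported)",
         call. = FALSE)
  }
  if (length(arr) == 0L) stop("zero-sized image: ", path, call. = FALSE)
  arr
}

#' Sobel edge magnitude
#'
#' Gradient magnitude of the standard (unnormalized) 3x3 Sobel operator,
#' kernels \code{Gx = [-1 0 1; -2 0 2; -1 0 1]} and \code{Gy = t(Gx)},
#' with replicated borders. A constant image yields an all-zero edge map.
#' The edge map is not renormalized: the region-cost weight \code{lambda}
#' of the search graph absorbs its scale.
#'
#' @param img a [gs_image] or numeric matrix
#' @return numeric matrix of non-negative edge magnitudes, same shape as the
#'   image
#' @export
sobel_edges <- function(img) {
  m <- as_gs_image(img)$intensity
  h <- nrow(m); w <- ncol(m)
  # replicate-pad by one pixel
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  p[1L, ] <- p[2L, ]; p[h + 2L, ] <- p[h + 1L, ]
  p[, 1L] <- p[, 2L]; p[, w + 2L] <- p[, w + 1L]
  sh <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

#' Load a ground-truth instance mask
#'
#' Reads an integer-labeled mask (0 = background, k > 0 = instance k) from a
#' 16-bit TIFF or a PNG file. Non-contiguous positive labels are relabeled to
#' contiguous integers with a warning.
#'
#' @param path path to the mask file
#' @return integer matrix of class \code{gs_mask}
#' @export
load_mask <- function(path) {
  arr <- read_raster(path, as_integer = TRUE)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  if (any(abs(arr - round(arr)) > 1e-9))
    stop("mask contains non-integer pixel values: ", path, call. = FALSE)
  as_gs_mask(matrix(as.integer(round(arr)), nrow(arr), ncol(arr)))
}

#' Coerce an integer matrix to an instance mask
#'
#' @param m matrix of non-negative integer labels
#' @return integer matrix of class \code{gs_mask} with contiguous labels
#' @export
as_gs_mask <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("mask labels must be non-negative", call. = FALSE)
  labs <- sort(unique(m[m > 0L]))
  if (length(labs) > 0L && !identical(labs, seq_along(labs))) {
    warning("non-contiguous mask labels relabeled to 1..",
            length(labs), call. = FALSE)
    m[] <- match(m, c(0L, labs)) - 1L
  }
  structure(m, class = "gs_mask")
}

#' Save an instance mask as a 16-bit single-channel TIFF
#'
#' The save/load round trip is the identity on label values.
#'
#' @param mask integer matrix of labels (at most 65535 instances)
#' @param path output file path (TIFF)
#' @return the path, invisibly
#' @export
save_mask <- function(mask, path) {
  m <- unclass(mask)
  if (max(m) > 65535L) stop("too many instances for a 16-bit mask", call. = FALSE)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Save a grayscale image (or probability map)
#'
#' TIFF output is written at 16 bits (values in \[0, 1\] scaled by 65535);
#' PNG output at 8 bits.
#'
#' @param img a [gs_image] or numeric matrix in \[0, 1\]
#' @param path output path (.png, .tif or .tiff)
#' @return the path, invisibly
#' @export
save_image <- function(img, path) {
  m <- if (inherits(img, "gs_image")) img$intensity else as.matrix(img)
  tiff_ext <- tolower(tools::file_ext(path)) %in% c("tif", "tiff")
  if (tiff_ext) tiff::writeTIFF(m, path, bits.per.sample = 16L)
  else png::writePNG(m, path)
  invisible(path)
}

# -- pipeline configuration ----------------------------------------------------

#' Pipeline configuration
#'
#' All tunable parameters of the segmentation pipeline with their defaults.
#' The reference operating point uses a search radius of 100 px (gland long
#' diameters of 80-160 px), 360 rays (one per degree), boundary-map threshold
#' 0.5, pruning threshold 0.3 on the mean boundary probability, and score
#' decrease factor 1/2 in the refinement step.
#'
#' @param r local search radius in pixels
#' @param n number of rays (columns of the polar graph)
#' @param m radial samples per ray (rows of the polar graph); radial spacing
#'   is r/m pixels
#' @param lambda_region weight of the cumulative edge (region) cost in the
#'   node weights; scale-dependent (intensities here are in \[0, 1\] and the
#'   Sobel magnitude is unnormalized)
#' @param bpm_threshold truncation threshold T on the boundary probability map
#' @param prune_boundary_prob proposals with mean contour boundary probability
#'   below this are pruned as non-gland
#' @param prune_min_area proposals smaller than this (pixels) are pruned
#' @param lambda_d multiplicative score decrease applied by the re-weighting
#'   step when a proposal finds its boundary resource consumed; in (0, 1)
#' @param avail_threshold minimum mean remaining boundary resource on a
#'   proposal's contour band for its score to be kept
#' @param merge_threshold stop merging when the best pair affinity P_pq drops
#'   below this
#' @param detect_threshold predicted score at or above which a proposal is
#'   flagged as gland
#' @param grid_spacing seeding grid spacing in pixels
#' @param seed_intensity_min seeds with intensity below this are pruned (dark)
#' @param hog_side side (pixels) of the square patch HOG is computed on
#' @param hog_bins number of unsigned orientation bins
#' @param hog_cell cell side in pixels
#' @param hog_block block side in cells
#' @param use_pca project HOG features with PCA fit on training data
#' @param pca_var fraction of variance retained when \code{use_pca} is TRUE
#' @param rf_ntree number of random-forest trees
#' @param random_seed seed for all stochastic steps (forest training)
#' @return a list of class \code{gs_config}
#' @export
gs_config <- function(r = 100, n = 360L, m = 50L,
                      lambda_region = 0.05,
                      bpm_threshold = 0.5,
                      prune_boundary_prob = 0.3,
                      prune_min_area = 500L,
                      lambda_d = 0.5,
                      avail_threshold = 0.3,
                      merge_threshold = 0.5,
                      detect_threshold = 0.5,
                      grid_spacing = 20L,
                      seed_intensity_min = 0.05,
                      hog_side = 64L, hog_bins = 9L, hog_cell = 8L,
                      hog_block = 2L,
                      use_pca = FALSE, pca_var = 0.95,
                      rf_ntree = 200L,
                      random_seed = 42L) {
  cfg <- list(r = r, n = as.integer(n), m = as.integer(m),
              lambda_region = lambda_region, bpm_threshold = bpm_threshold,
              prune_boundary_prob = prune_boundary_prob,
              prune_min_area = as.integer(prune_min_area),
              lambda_d = lambda_d, avail_threshold = avail_threshold,
              merge_threshold = merge_threshold,
              detect_threshold = detect_threshold,
              grid_spacing = as.integer(grid_spacing),
              seed_intensity_min = seed_intensity_min,
              hog_side = as.integer(hog_side), hog_bins = as.integer(hog_bins),
              hog_cell = as.integer(hog_cell), hog_block = as.integer(hog_block),
              use_pca = isTRUE(use_pca), pca_var = pca_var,
              rf_ntree = as.integer(rf_ntree),
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "gs_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$r > 0, cfg$n >= 8L, cfg$m >= 2L)
  probs <- c(cfg$bpm_threshold, cfg$prune_boundary_prob, cfg$avail_threshold,
             cfg$merge_threshold, cfg$detect_threshold)
  if (any(probs < 0 | probs > 1))
    stop("probability thresholds must lie in [0, 1]", call. = FALSE)
  if (cfg$lambda_d <= 0 || cfg$lambda_d >= 1)
    stop("lambda_d must lie strictly in (0, 1)", call. = FALSE)
  if (cfg$grid_spacing < 1L) stop("grid_spacing must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Write a configuration to a flat key-value file
#'
#' One \code{key: value} line per field (Debian-control format).
#'
#' @param cfg a [gs_config]
#' @param path output file path
#' @return the path, invisibly
#' @export
write_config <- function(cfg, path) {
  m <- matrix(vapply(cfg, function(v) format(v, digits = 15), ""), nrow = 1,
              dimnames = list(NULL, names(cfg)))
  write.dcf(m, path)
  invisible(path)
}

#' Read a configuration from a flat key-value file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [gs_config()].
#'
#' @param path file written by [write_config()]
#' @return a [gs_config]
#' @export
read_config <- function(path) {
  m <- read.dcf(path)
  vals <- as.list(m[1L, ])
  defaults <- gs_config()
  bad <- setdiff(names(vals), names(defaults))
  if (length(bad) > 0L)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  for (k in names(vals)) {
    v <- vals[[k]]
    vals[[k]] <- if (k == "use_pca") as.logical(v) else as.numeric(v)
  }
  do.call(gs_config, vals)
}

#' @export
print.gs_config <- function(x, ...) {
  cat("<gs_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
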
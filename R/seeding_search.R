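# Seeding and local contour search: uniform-grid seeds, polar multi-column
# graph per seed, and cyclic shortest-path solvers (naive and
# divide-and-conquer) for the optimal closed smooth contour.

#' Sample seeding points on a uniform grid
#'
#' Seeds are placed at \code{grid_spacing} intervals in both axes, offset
#' \code{grid_spacing / 2} from the border (0-based pixel coordinates). Seeds
#' whose (bilinearly interpolated) intensity falls below
#' \code{seed_intensity_min} are pruned as dark. An image smaller than one
#' grid cell yields a single centered seed.
#'
#' @param img a [gs_image]
#' @param cfg a [gs_config]
#' @return data.frame with columns \code{x}, \code{y} (0-based pixel
#'   coordinates, x = column, y = row)
#' @export
sample_seeds <- function(img, cfg = gs_config()) {
  img <- as_gs_image(img)
  s <- cfg$grid_spacing
  axis_seq <- function(extent) {
    if (extent < s) return((extent - 1) / 2)  # single centered coordinate
    seq(s / 2, extent - 1, by = s)
  }
  xs <- axis_seq(img$width)
  ys <- axis_seq(img$height)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  val <- cpp_bilinear_sample(img$intensity, g$x, g$y)
  keep <- val >= cfg$seed_intensity_min
  n_pruned <- sum(!keep)
  if (n_pruned > 0L) gs_log(n_pruned, " dark seeds pruned")
  g[keep, , drop = FALSE]
}

#' Polar sample position of a graph node
#'
#' Position of node (i, j) of the polar graph for a seed at (x, y):
#' \code{(x + (i r / m) cos(2 pi j / n), y + (i r / m) sin(2 pi j / n))}.
#' The raw (unclamped) position is returned; sampling of image values clamps
#' to the nearest border pixel.
#'
#' @param seed list or data.frame row with fields \code{x}, \code{y}
#' @param i radial index, 1..m
#' @param j ray index, 1..n
#' @param cfg a [gs_config]
#' @return named numeric vector \code{c(x, y)}
#' @export
polar_sample_position <- function(seed, i, j, cfg = gs_config()) {
  ang <- 2 * pi * j / cfg$n
  rad <- i * cfg$r / cfg$m
  c(x = seed$x + rad * cos(ang), y = seed$y + rad * sin(ang))
}

#' Build the polar multi-column search graph for one seed
#'
#' Node weights are \code{w[i, j] = I(i, j) + lambda * sum(E(1..i, j))} for
#' columns j = 1..n, where I and E are the image intensity and Sobel edge
#' magnitude bilinearly sampled at the polar positions (the cumulative edge
#' sum is a single prefix-sum pass per column, inclusive of row i). A
#' zero-weight replica of column 1 is appended as column n+1 so that paths
#' ending there close the contour without double-counting column 1.
#' Out-of-image samples are clamped to the nearest border pixel.
#'
#' @param seed list with fields \code{x}, \code{y} (0-based coordinates)
#' @param img a [gs_image]
#' @param edges Sobel edge matrix from [sobel_edges()]
#' @param cfg a [gs_config]
#' @return object of class \code{gs_polar_graph} with fields \code{weights}
#'   (m x (n+1)), \code{seed}, \code{r}, \code{m}, \code{n}
#' @export
build_polar_graph <- function(seed, img, edges, cfg = gs_config()) {
  img <- as_gs_image(img)
  W <- cpp_polar_weights(img$intensity, edges, seed$x, seed$y,
                         cfg$r, cfg$n, cfg$m, cfg$lambda_region)
  structure(list(weights = W, seed = list(x = seed$x, y = seed$y),
                 r = cfg$r, m = cfg$m, n = cfg$n,
                 shape = c(img$height, img$width)),
            class = "gs_polar_graph")
}

#' Optimal closed contour by the naive solver
#'
#' For every start row i, computes the shortest path from node (i, 1) to the
#' replica node (i, n+1) using only edges to the next column with a row
#' change of at most 1 (hard smoothness constraint), then returns the best
#' over all i: O(m^2 n) time. The path cost is the sum of node weights along
#' the path (the replica column carries weight 0). Ties are broken toward the
#' smaller start row, then the lexicographically smallest row sequence.
#'
#' @param g a \code{gs_polar_graph}
#' @param rasterize if TRUE (default) also rasterize boundary and region
#'   pixels; see [rasterize_contour()]
#' @return a \code{gs_contour}; see [rasterize_contour()] for fields
#' @export
shortest_closed_path_naive <- function(g, rasterize = TRUE) {
  res <- cpp_closed_path_naive(g$weights)
  finish_contour(res, g, rasterize)
}

#' Optimal closed contour by divide-and-conquer
#'
#' Same problem and cost as [shortest_closed_path_naive()], solved in
#' O(m n log m): the middle start row is solved first and its path splits the
#' graph into two corridors; start rows above and below recurse inside their
#' corridor, exploiting the non-crossing property of optimal paths in the
#' multi-column graph.
#'
#' @inheritParams shortest_closed_path_naive
#' @return a \code{gs_contour}
#' @export
shortest_closed_path_dc <- function(g, rasterize = TRUE) {
  res <- cpp_closed_path_dc(g$weights)
  finish_contour(res, g, rasterize)
}

finish_contour <- function(res, g, rasterize) {
  cont <- structure(list(rows = res$rows, cost = res$cost,
                         seed = g$seed, r = g$r, m = g$m, n = g$n,
                         shape = g$shape,
                         boundary_idx = NULL, region_idx = NULL),
                    class = "gs_contour")
  if (rasterize) cont <- rasterize_contour(cont, g)
  cont
}

#' Rasterize a closed polar path into boundary and region pixels
#'
#' The chosen row per column is mapped back to image coordinates, forming a
#' closed star-shaped polygon around the seed. Its perimeter is rasterized to
#' 8-connected boundary pixels; pixels strictly inside the polygon (fill
#' minus boundary) form the region. Pixels are stored as 1-based column-major
#' linear indices into the image matrix (see [idx_to_rc()]).
#'
#' @param rows integer vector of length n+1, a legal closed row sequence
#'   (consecutive rows differ by at most 1; \code{rows[1] == rows[n+1]})
#' @param g the \code{gs_polar_graph} the path was computed on
#' @return object of class \code{gs_contour} with fields \code{rows},
#'   \code{cost} (NA when not computed), \code{seed}, \code{boundary_idx},
#'   \code{region_idx}, \code{shape}
#' @export
rasterize_contour <- function(rows, g) {
  cont <- NULL
  if (inherits(rows, "gs_contour")) { cont <- rows; rows <- cont$rows }
  n <- g$n
  stopifnot(length(rows) == n + 1L, rows[1L] == rows[n + 1L],
            all(abs(diff(rows)) <= 1L))
  j <- seq_len(n)
  ang <- 2 * pi * j / n
  rad <- rows[j] * g$r / g$m
  vx <- pmin(pmax(g$seed$x + rad * cos(ang), 0), g$shape[2L] - 1)
  vy <- pmin(pmax(g$seed$y + rad * sin(ang), 0), g$shape[1L] - 1)
  ras <- cpp_rasterize_polygon(vx, vy, g$shape[1L], g$shape[2L])
  structure(list(rows = rows,
                 cost = if (is.null(cont)) NA_real_ else cont$cost,
                 seed = g$seed, r = g$r, m = g$m, n = n, shape = g$shape,
                 boundary_idx = ras$boundary_idx,
                 region_idx = ras$region_idx),
            class = "gs_contour")
}

#' @export
print.gs_contour <- function(x, ...) {
  cat(sprintf("<gs_contour seed=(%.1f, %.1f) cost=%.4f boundary=%d px region=%d px>\n",
              x$seed$x, x$seed$y, x$cost,
              length(x$boundary_idx), length(x$region_idx)))
  invisible(x)
}

#' Search closed contours for a set of seeds
#'
#' Convenience wrapper running [build_polar_graph()] and the
#' divide-and-conquer solver for every seed.
#'
#' @param img a [gs_image]
#' @param cfg a [gs_config]
#' @param seeds optional data.frame from [sample_seeds()]; computed if NULL
#' @param edges optional precomputed edge map
#' @return list of \code{gs_contour}
#' @export
search_contours <- function(img, cfg = gs_config(), seeds = NULL, edges = NULL) {
  img <- as_gs_image(img)
  if (is.null(edges)) edges <- sobel_edges(img)
  if (is.null(seeds)) seeds <- sample_seeds(img, cfg)
  lapply(seq_len(nrow(seeds)), function(k) {
    g <- build_polar_graph(seeds[k, ], img, edges, cfg)
    shortest_closed_path_dc(g)
  })
}

#' Export a contour (or mask) overlay image
#'
#' Debug helper: paints boundary pixels onto a copy of the image (white by
#' default) and writes it with [save_image()]. Accepts a single
#' \code{gs_contour}, a list of them, or an instance mask whose region
#' contours are drawn.
#'
#' @param img a [gs_image]
#' @param what a \code{gs_contour}, list of contours, or \code{gs_mask}
#' @param path output image path (PNG or TIFF)
#' @param value intensity painted on boundary pixels
#' @return the path, invisibly
#' @export
export_overlay <- function(img, what, path, value = 1) {
  img <- as_gs_image(img)
  canvas <- img$intensity
  idx <- if (inherits(what, "gs_contour")) {
    what$boundary_idx
  } else if (inherits(what, "gs_mask") || is.matrix(what)) {
    which(contour_mask(unclass(what)) & unclass(what) > 0L)
  } else {
    unlist(lapply(what, `[[`, "boundary_idx"))
  }
  canvas[idx] <- value
  save_image(canvas, path)
}

#' Export a polar graph weight matrix as a text file
#'
#' Debug helper: writes the m x (n+1) weight matrix as whitespace-separated
#' text.
#'
#' @param g a \code{gs_polar_graph}
#' @param path output path
#' @return the path, invisibly
#' @export
export_graph_weights <- function(g, path) {
  write.table(g$weights, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
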
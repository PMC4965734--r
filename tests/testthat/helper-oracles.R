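# Shared helpers: independent oracles and small fixtures built in code.

# --- brute-force oracle for the cyclic shortest path ------------------------
# Exhaustive enumeration of all legal closed row sequences (|delta| <= 1 per
# column, first row == last row), fully independent of the DP solvers.

.delta_cumsum_cache <- new.env(parent = emptyenv())

delta_cumsums <- function(n_steps) {
  key <- as.character(n_steps)
  got <- .delta_cumsum_cache[[key]]
  if (!is.null(got)) return(got)
  D <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), n_steps)))
  L <- matrix(0L, n_steps, n_steps)
  L[upper.tri(L, diag = TRUE)] <- 1L
  C <- D %*% L  # C[, j] = cumulative row offset after j steps
  .delta_cumsum_cache[[key]] <- C
  C
}

brute_closed_cost <- function(W) {
  m <- nrow(W)
  n <- ncol(W) - 1L  # steps between the n+1 columns
  C <- delta_cumsums(n)
  C <- C[C[, n] == 0L, , drop = FALSE]  # closure: end row == start row
  best <- Inf
  for (s in seq_len(m)) {
    R <- s + C
    valid <- rowSums(R >= 1L & R <= m) == n
    if (!any(valid)) next
    R <- R[valid, , drop = FALSE]
    cost <- rep(W[s, 1L], nrow(R))
    for (j in seq_len(n)) cost <- cost + W[j * m + R[, j]]
    best <- min(best, cost)
  }
  best
}

random_polar_weights <- function(m, n) {
  W <- matrix(runif(m * (n + 1L)), m, n + 1L)
  W[, n + 1L] <- 0
  W
}

fake_graph <- function(W, r = 10, seed = list(x = 16, y = 16),
                       shape = c(48L, 48L)) {
  structure(list(weights = W, seed = seed, r = r, m = nrow(W),
                 n = ncol(W) - 1L, shape = shape),
            class = "gs_polar_graph")
}

# --- small containers --------------------------------------------------------

make_region <- function(pixels, shape, id = 1L, prob = NULL) {
  mask <- matrix(0L, shape[1L], shape[2L])
  mask[pixels] <- 1L
  cm <- glandseg:::contour_mask(mask)
  ctr <- pixels[cm[pixels]]
  if (length(ctr) == 0L) ctr <- pixels
  mb <- if (is.null(prob)) 1 else mean(prob[ctr])
  list(id = id, pixels = as.integer(pixels), contour = as.integer(ctr),
       area = length(pixels), mean_boundary_prob = mb)
}

rect_region <- function(rows, cols, shape, id = 1L, prob = NULL) {
  px <- as.integer(outer(rows, (cols - 1L) * shape[1L], `+`))
  make_region(px, shape, id = id, prob = prob)
}

bpm_from_matrix <- function(prob) {
  structure(list(prob = prob, coverage = matrix(1L, nrow(prob), ncol(prob)),
                 untruncated = prob),
            class = "gs_bpm")
}

# contour with explicit pixel sets (for hand-built ensemble cases)
hand_contour <- function(boundary_idx, region_idx, shape) {
  structure(list(rows = NULL, cost = NA_real_, seed = list(x = 0, y = 0),
                 shape = shape,
                 boundary_idx = as.integer(boundary_idx),
                 region_idx = as.integer(region_idx)),
            class = "gs_contour")
}

# --- downscaled configuration and scenes for fast pipeline tests -------------

small_config <- function(...) {
  gs_config(r = 40, n = 72L, m = 20L, grid_spacing = 16L,
            prune_min_area = 150L, ...)
}

small_scene_params <- function(...) {
  defaults <- list(side = 224L, n_glands = 3L, radius_range = c(26, 38),
                   border_thickness = 6, nucleus_density = 6e-4)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}
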
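test_that("seeds form a uniform grid and dark seeds are pruned", {
  img <- gs_image(matrix(1, 100, 100))
  cfg <- gs_config(grid_spacing = 20)
  s <- sample_seeds(img, cfg)
  expect_equal(nrow(s), 25L)
  expect_setequal(unique(s$x), c(10, 30, 50, 70, 90))
  # all-black image: everything pruned
  expect_equal(nrow(sample_seeds(gs_image(matrix(0, 100, 100)), cfg)), 0L)
  # half black / half white: only white-side seeds survive; enumerate the grid
  half <- cbind(matrix(0, 100, 50), matrix(1, 100, 50))
  sh <- sample_seeds(gs_image(half), cfg)
  grid_x <- c(10, 30, 50, 70, 90)
  expect_setequal(unique(sh$x), grid_x[grid_x >= 50])
  expect_equal(nrow(sh), sum(grid_x >= 50) * 5L)
  # image smaller than one grid cell: single centered seed
  tiny <- sample_seeds(gs_image(matrix(1, 9, 9)), cfg)
  expect_equal(nrow(tiny), 1L)
  expect_equal(tiny$x, 4)
})

test_that("polar sample positions follow the ray geometry", {
  cfg <- gs_config(r = 30, n = 360, m = 50)
  seed <- list(x = 50, y = 50)
  expect_equal(polar_sample_position(seed, cfg$m, cfg$n, cfg),
               c(x = 80, y = 50))
  expect_equal(polar_sample_position(seed, cfg$m, cfg$n / 4, cfg),
               c(x = 50, y = 80))
  # unclamped raw position for an out-of-image sample
  cfg2 <- gs_config(r = 100, n = 360, m = 50)
  p <- polar_sample_position(list(x = 0, y = 0), 1, cfg2$n / 2, cfg2)
  expect_equal(p, c(x = -2, y = 0), tolerance = 1e-12)
})

test_that("polar graph weights equal the literal node-weight formula", {
  set.seed(7)
  img <- gs_image(matrix(runif(400), 20, 20))
  edges <- sobel_edges(img)
  cfg <- gs_config(r = 8, n = 12, m = 5, lambda_region = 10)
  seed <- list(x = 9.5, y = 10.25)
  g <- build_polar_graph(seed, img, edges, cfg)
  expect_equal(dim(g$weights), c(5L, 13L))
  expect_equal(g$weights[, 13], rep(0, 5))
  # recompute every node weight naively: I + lambda * inclusive prefix sum of E
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  bil <- function(m, x, y) {
    x <- clamp(x, ncol(m) - 1); y <- clamp(y, nrow(m) - 1)
    x0 <- pmin(floor(x), ncol(m) - 2); y0 <- pmin(floor(y), nrow(m) - 2)
    fx <- x - x0; fy <- y - y0
    m[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) + m[y0 + 1, x0 + 2] * fx * (1 - fy) +
      m[y0 + 2, x0 + 1] * (1 - fx) * fy + m[y0 + 2, x0 + 2] * fx * fy
  }
  for (j in 1:12) {
    esum <- 0
    for (i in 1:5) {
      pos <- unname(polar_sample_position(seed, i, j, cfg))
      esum <- esum + bil(edges, pos[1L], pos[2L])
      expect_equal(g$weights[i, j],
                   bil(img$intensity, pos[1L], pos[2L]) + 10 * esum,
                   tolerance = 1e-10)
    }
  }
  # lambda = 0: weights are the sampled intensities exactly
  g0 <- build_polar_graph(seed, img, edges, gs_config(r = 8, n = 12, m = 5,
                                                      lambda_region = 0))
  pos <- unname(polar_sample_position(seed, 2, 3, cfg))
  expect_equal(g0$weights[2, 3], bil(img$intensity, pos[1L], pos[2L]),
               tolerance = 1e-10)
})

test_that("uniform-weight graphs give the constant-cost, tie-broken path", {
  W <- matrix(0.5, 6, 13); W[, 13] <- 0
  g <- fake_graph(W)
  for (solve in list(shortest_closed_path_naive, shortest_closed_path_dc)) {
    ct <- solve(g, rasterize = FALSE)
    expect_equal(ct$cost, 12 * 0.5)
  }
  # naive tie-break: smallest start row, then lexicographically smallest
  ct <- shortest_closed_path_naive(g, rasterize = FALSE)
  expect_equal(ct$rows, rep(1L, 13))
  # single zero-weight ring at row 5
  W2 <- matrix(1, 8, 13); W2[5, ] <- 0; W2[, 13] <- 0
  ct2 <- shortest_closed_path_naive(fake_graph(W2), rasterize = FALSE)
  expect_equal(ct2$rows, rep(5L, 13))
  expect_equal(ct2$cost, 0)
  # m = 1: single possible row, both solvers identical
  W3 <- matrix(runif(7), 1, 7); W3[, 7] <- 0
  n3 <- shortest_closed_path_naive(fake_graph(W3), rasterize = FALSE)
  d3 <- shortest_closed_path_dc(fake_graph(W3), rasterize = FALSE)
  expect_equal(n3$cost, d3$cost)
  expect_equal(n3$rows, rep(1L, 7))
})

test_that("solver costs match exhaustive enumeration on random graphs", {
  set.seed(11)
  for (it in 1:60) {
    m <- sample(2:8, 1); n <- sample(3:8, 1)
    W <- random_polar_weights(m, n)
    g <- fake_graph(W)
    cb <- brute_closed_cost(W)
    expect_equal(shortest_closed_path_naive(g, rasterize = FALSE)$cost, cb)
    expect_equal(shortest_closed_path_dc(g, rasterize = FALSE)$cost, cb)
  }
})

test_that("returned paths satisfy smoothness and closure; cost shifts by n*c", {
  set.seed(13)
  for (it in 1:25) {
    m <- sample(2:12, 1); n <- sample(8:30, 1)
    W <- random_polar_weights(m, n)
    g <- fake_graph(W, shape = c(64L, 64L))
    ct <- shortest_closed_path_dc(g, rasterize = FALSE)
    expect_true(all(abs(diff(ct$rows)) <= 1L))
    expect_equal(ct$rows[1L], ct$rows[n + 1L])
    # adding a constant c to all non-replica weights shifts the cost by n*c
    W2 <- W + 0.3; W2[, n + 1L] <- 0
    ct2 <- shortest_closed_path_dc(fake_graph(W2), rasterize = FALSE)
    expect_equal(ct2$cost, ct$cost + n * 0.3, tolerance = 1e-9)
  }
})

test_that("rasterized row-constant paths approximate circles", {
  m <- 40L; n <- 36L
  g <- fake_graph(matrix(0, m, n + 1L), r = 40, seed = list(x = 50, y = 50),
                  shape = c(101L, 101L))
  ct <- rasterize_contour(rep(20L, n + 1L), g)  # radius 20 px
  rc <- idx_to_rc(ct$boundary_idx, g$shape)
  d <- sqrt((rc[, 1L] - 51)^2 + (rc[, 2L] - 51)^2)
  expect_true(all(abs(d - 20) <= 1))
  # region and boundary are disjoint; the seed lies inside the region
  expect_length(intersect(ct$region_idx, ct$boundary_idx), 0L)
  seed_idx <- (51L - 1L) * 101L + 51L
  expect_true(seed_idx %in% ct$region_idx)
})

test_that("rasterization invariants hold for random legal contours", {
  set.seed(17)
  m <- 20L; n <- 24L
  g <- fake_graph(matrix(0, m, n + 1L), r = 18, seed = list(x = 24, y = 24),
                  shape = c(49L, 49L))
  for (it in 1:20) {
    rows <- integer(n + 1L)
    rows[1L] <- sample(5:15, 1L)
    for (j in 2:(n + 1L)) {
      lo <- max(2L, rows[j - 1L] - 1L, rows[1L] - (n + 1L - j))
      hi <- min(m, rows[j - 1L] + 1L, rows[1L] + (n + 1L - j))
      rows[j] <- if (lo >= hi) lo else sample(lo:hi, 1L)
    }
    ct <- rasterize_contour(rows, g)
    expect_length(intersect(ct$region_idx, ct$boundary_idx), 0L)
    seed_idx <- (24L) * 49L + 25L
    expect_true(seed_idx %in% ct$region_idx)
  }
})
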
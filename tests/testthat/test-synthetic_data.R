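test_that("generator is deterministic and respects n_glands = 0", {
  p0 <- small_scene_params(n_glands = 0L, seed = 2L)
  sc0 <- generate_scene(p0)
  expect_equal(max(sc0$gt), 0L)
  p <- small_scene_params(noise_sigma = 0.05, gap_fraction = 0.1,
                          irregularity = 0.3, seed = 9L)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image$intensity, b$image$intensity)
  expect_identical(unclass(a$gt), unclass(b$gt))
})

test_that("clean circular glands produce disk-shaped ground truth", {
  p <- small_scene_params(n_glands = 2L, irregularity = 0, gap_fraction = 0,
                          noise_sigma = 0, nucleus_density = 0, seed = 4L)
  sc <- generate_scene(p)
  expect_gt(nrow(sc$glands), 0L)
  for (k in seq_len(nrow(sc$glands))) {
    px <- which(unclass(sc$gt) == k)
    rc <- idx_to_rc(px, dim(sc$gt))
    d <- sqrt((rc[, 1L] - 1 - sc$glands$y[k])^2 +
              (rc[, 2L] - 1 - sc$glands$x[k])^2)
    rtot <- sc$glands$radius[k] + p$border_thickness
    # every gt pixel within the disk, all boundary-adjacent radii reached
    expect_lt(max(d), rtot + 1)
    expect_gt(max(d), rtot - 1.5)
    # area close to the perfect disk
    expect_lt(abs(length(px) - pi * rtot^2), 0.05 * pi * rtot^2)
  }
})

test_that("ground-truth instances are disjoint and labels contiguous", {
  p <- small_scene_params(n_glands = 3L, irregularity = 0.4, seed = 12L)
  sc <- generate_scene(p)
  labs <- sort(unique(as.integer(sc$gt)))
  expect_identical(labs, 0:max(labs))
  expect_equal(max(labs), nrow(sc$glands))
  # intensity stays in [0, 1] under noise
  p2 <- small_scene_params(noise_sigma = 0.3, seed = 13L)
  im <- generate_scene(p2)$image$intensity
  expect_true(all(im >= 0 & im <= 1))
})

test_that("datasets use consecutive seeds and produce distinct scenes", {
  p <- small_scene_params(noise_sigma = 0.05)
  ds <- generate_dataset(4L, p, base_seed = 100L)
  expect_length(ds, 4L)
  expect_equal(vapply(ds, function(s) s$params$seed, integer(1L)), 100:103)
  imgs <- lapply(ds, function(s) s$image$intensity)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(imgs[[i]], imgs[[j]]))
  total <- sum(vapply(ds, function(s) nrow(s$glands), integer(1L)))
  expect_gte(total, 0.6 * 4L * p$n_glands)  # placement-failure tolerance
  expect_error(generate_dataset(1L, p), "n_scenes")
})

test_that("interior seeds recover clean gland boundaries within the ring band", {
  # no gaps, no irregularity, no noise: every contour started inside a gland
  # must lie on the dark epithelial ring (distance to the band [R, R+t] small)
  p <- scene_params(side = 256L, n_glands = 2L, radius_range = c(40, 55),
                    gap_fraction = 0, irregularity = 0, noise_sigma = 0,
                    seed = 21L)
  sc <- generate_scene(p)
  cfg <- gs_config()
  edges <- sobel_edges(sc$image)
  for (k in seq_len(nrow(sc$glands))) {
    g <- sc$glands[k, ]
    offsets <- rbind(c(0, 0), c(0.3, 0), c(-0.3, 0), c(0, 0.3), c(0, -0.3))
    for (o in seq_len(nrow(offsets))) {
      seed <- list(x = g$x + offsets[o, 1L] * g$radius,
                   y = g$y + offsets[o, 2L] * g$radius)
      gph <- build_polar_graph(seed, sc$image, edges, cfg)
      ct <- shortest_closed_path_dc(gph, rasterize = FALSE)
      j <- seq_len(cfg$n)
      ang <- 2 * pi * j / cfg$n
      rad <- ct$rows[j] * cfg$r / cfg$m
      vx <- seed$x + rad * cos(ang)
      vy <- seed$y + rad * sin(ang)
      dcenter <- sqrt((vx - g$x)^2 + (vy - g$y)^2)
      band_err <- pmax(0, pmax(g$radius - dcenter,
                               dcenter - (g$radius + p$border_thickness)))
      expect_lt(mean(band_err), 2)  # r/m
    }
  }
})
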
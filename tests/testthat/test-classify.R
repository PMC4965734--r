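test_that("pruning removes small or weak-boundary regions and partitions input", {
  shape <- c(40L, 40L)
  prob <- matrix(0.9, shape[1L], shape[2L])
  big <- rect_region(2:30, 2:30, shape, id = 1L, prob = prob)
  weak <- rect_region(32:39, 2:30, shape, id = 2L, prob = matrix(0.2, 40, 40))
  tiny <- make_region(5L, shape, id = 3L, prob = prob)
  cfg <- gs_config(prune_min_area = 100L)
  pr <- prune_proposals(list(big, weak, tiny), cfg)
  expect_equal(vapply(pr$kept, `[[`, integer(1L), "id"), 1L)
  expect_setequal(vapply(pr$pruned, `[[`, integer(1L), "id"), c(2L, 3L))
  # partition property on random proposal sets
  set.seed(31)
  regs <- lapply(1:12, function(k) {
    rg <- make_region(sample(1600L, sample(20:400, 1L)), shape, id = k)
    rg$mean_boundary_prob <- runif(1L)
    rg
  })
  pr2 <- prune_proposals(regs, cfg)
  expect_equal(length(pr2$kept) + length(pr2$pruned), 12L)
  expect_setequal(c(vapply(pr2$kept, `[[`, integer(1L), "id"),
                    vapply(pr2$pruned, `[[`, integer(1L), "id")), 1:12)
})

test_that("pruning is monotone in both thresholds", {
  shape <- c(30L, 30L)
  set.seed(33)
  regs <- lapply(1:20, function(k) {
    rg <- make_region(sample(900L, sample(5:200, 1L)), shape, id = k)
    rg$mean_boundary_prob <- runif(1L)
    rg
  })
  kept_ids <- function(a, p) {
    cfg <- gs_config(prune_min_area = a, prune_boundary_prob = p)
    vapply(prune_proposals(regs, cfg)$kept, `[[`, integer(1L), "id")
  }
  base <- kept_ids(100L, 0.3)
  expect_true(all(base %in% kept_ids(50L, 0.3)))   # relax area
  expect_true(all(base %in% kept_ids(100L, 0.1)))  # relax boundary prob
  expect_true(all(kept_ids(150L, 0.5) %in% base))  # tighten both
})

test_that("iou_score matches a pixel-count oracle", {
  shape <- c(20L, 20L)
  gt <- matrix(0L, 20L, 20L)
  gt[2:11, 2:11] <- 1L   # 100 px
  gt[14:19, 14:19] <- 2L # 36 px
  gt <- as_gs_mask(gt)
  same <- rect_region(2:11, 2:11, shape)
  expect_equal(iou_score(same, gt), 1)
  disj <- rect_region(13:16, 2:5, shape)
  expect_equal(iou_score(disj, gt), 0)
  # 100-px proposal overlapping the 100-px instance by 50 px -> 1/3
  half <- rect_region(7:16, 2:11, shape)
  expect_equal(half$area, 100L)
  expect_equal(iou_score(half, gt), 50 / 150)
  # empty ground truth
  expect_equal(iou_score(same, as_gs_mask(matrix(0L, 20L, 20L))), 0)
  # random pairs against brute-force pixel counting
  set.seed(41)
  for (it in 1:20) {
    rg <- make_region(sample(400L, sample(10:150, 1L)), shape)
    oracle <- 0
    for (k in 1:2) {
      gtpx <- which(unclass(gt) == k)
      i <- length(intersect(rg$pixels, gtpx))
      oracle <- max(oracle, i / (rg$area + length(gtpx) - i))
    }
    expect_equal(iou_score(rg, gt), oracle)
  }
})

test_that("feature vectors behave on constant and translated regions", {
  shape <- c(64L, 64L)
  img <- gs_image(matrix(0.4, 64L, 64L))
  rg <- rect_region(10:25, 10:25, shape)
  cfg <- gs_config(hog_side = 32L)
  f <- extract_features(rg, img, cfg)
  expect_equal(unname(f["region_sd"]), 0)
  expect_equal(unname(f["contour_sd"]), 0)
  expect_true(all(f[grepl("^hog", names(f))] == 0))  # no gradients
  expect_true(all(is.finite(f)))
  # translation invariance: same texture shifted with its region
  set.seed(43)
  tex <- matrix(runif(16L * 16L), 16L, 16L)
  canvas <- matrix(0.5, 64L, 64L)
  canvas[5:20, 5:20] <- tex
  canvas2 <- matrix(0.5, 64L, 64L)
  canvas2[33:48, 29:44] <- tex
  r1 <- rect_region(5:20, 5:20, shape)
  r2 <- rect_region(33:48, 29:44, shape)
  f1 <- extract_features(r1, gs_image(canvas), cfg)
  f2 <- extract_features(r2, gs_image(canvas2), cfg)
  f1["area"] <- f2["area"] <- 0  # equal anyway; drop for clarity
  expect_equal(f1, f2)
})

test_that("hog descriptor has the documented dimensionality and energy", {
  cfg <- gs_config()
  h <- hog_descriptor(matrix(0.5, 64L, 64L), bins = 9L, cell = 8L, block = 2L)
  expect_length(h, 7L * 7L * 4L * 9L)
  expect_true(all(h == 0))
  set.seed(45)
  h2 <- hog_descriptor(matrix(runif(64L * 64L), 64L, 64L), 9L, 8L, 2L)
  expect_true(all(is.finite(h2)) && any(h2 > 0))
  # each block is L2-normalized (norm <= 1 with the stabilizing epsilon)
  blocks <- matrix(h2, nrow = 4L * 9L)
  expect_true(all(colSums(blocks^2) <= 1 + 1e-9))
})

test_that("scorer training is deterministic and learns a perfect feature", {
  set.seed(47)
  n <- 80L
  y <- runif(n)
  X <- cbind(y, matrix(runif(n * 5L), n, 5L))
  cfg <- gs_config(rf_ntree = 100L)
  s1 <- train_scorer(X, y, cfg)
  s2 <- train_scorer(X, y, cfg)
  Xt <- cbind(seq(0.05, 0.95, length.out = 20L), matrix(0.5, 20L, 5L))
  p1 <- as.numeric(predict(s1$rf, Xt))
  p2 <- as.numeric(predict(s2$rf, Xt))
  expect_identical(p1, p2)  # same data + same seed -> identical predictions
  r2 <- 1 - mean((p1 - Xt[, 1L])^2) / var(Xt[, 1L])
  expect_gt(r2, 0.9)
  # constant targets -> constant predictions, with a warning (the forest
  # itself also warns about the degenerate response)
  expect_warning(
    expect_warning(sc <- train_scorer(X, rep(0.7, n), cfg), "degenerate"))
  expect_equal(as.numeric(predict(sc$rf, Xt)), rep(0.7, 20L), tolerance = 1e-9)
})

test_that("scoring clips, thresholds, and enforces the feature fingerprint", {
  set.seed(49)
  shape <- c(40L, 40L)
  img <- gs_image(matrix(runif(1600L), 40L, 40L))
  cfg <- gs_config(hog_side = 16L, rf_ntree = 50L)
  regs <- lapply(1:12, function(k)
    rect_region(sample(1:20, 1L) + 0:14, sample(1:20, 1L) + 0:14, shape, id = k))
  X <- feature_matrix(regs, img, cfg)
  y <- runif(12L)
  sc <- train_scorer(X, y, cfg)
  out <- score_proposals(sc, regs, X, cfg)
  expect_length(out, 12L)
  scores <- vapply(out, `[[`, numeric(1L), "score")
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(vapply(out, `[[`, logical(1L), "is_gland"), scores >= 0.5)
  # empty input, zero threshold, monotone sweep
  expect_length(score_proposals(sc, list(), X[0, , drop = FALSE], cfg), 0L)
  cfg0 <- gs_config(hog_side = 16L, rf_ntree = 50L, detect_threshold = 0)
  out0 <- score_proposals(sc, regs, X, cfg0)
  expect_true(all(vapply(out0, `[[`, logical(1L), "is_gland")))
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    sum(scores >= th), integer(1L))
  expect_true(all(diff(counts) <= 0L))
  # fingerprint mismatch is refused
  cfg_bad <- gs_config(hog_side = 32L, rf_ntree = 50L)
  expect_error(score_proposals(sc, regs, X, cfg_bad), "fingerprint|match")
  # persistence round trip
  td <- withr::local_tempdir()
  f <- file.path(td, "scorer.rds")
  save_scorer(sc, f)
  sc2 <- load_scorer(f)
  expect_identical(sc2$fingerprint, sc$fingerprint)
  out2 <- score_proposals(sc2, regs, X, cfg)
  expect_equal(vapply(out2, `[[`, numeric(1L), "score"), scores)
})
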
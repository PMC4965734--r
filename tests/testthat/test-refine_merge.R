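scored_from <- function(region, score, thr = 0.5) {
  list(region = region, score = score, is_gland = score >= thr)
}

test_that("reweight keeps untouched high-resource proposals and halves starved ones", {
  shape <- c(30L, 30L)
  prob <- matrix(0, shape[1L], shape[2L])
  rg <- rect_region(10:20, 10:20, shape)
  prob[contour_band_idx <- glandseg:::contour_band(rg, shape)] <- 0.8
  bpm <- bpm_from_matrix(prob)
  cfg <- gs_config()
  out <- reweight(list(scored_from(rg, 0.9)), bpm, cfg)
  expect_equal(out[[1L]]$score, 0.9)  # full resource available: unchanged
  # two proposals with identical contours and equal scores-ordering:
  # the higher-scoring one consumes the band, the other is halved
  a <- rg; a$id <- 1L
  b <- rg; b$id <- 2L
  out2 <- reweight(list(scored_from(a, 0.9), scored_from(b, 0.8)), bpm, cfg)
  expect_equal(out2[[1L]]$score, 0.9)
  expect_equal(out2[[2L]]$score, 0.8 * 0.5)  # lambda_d = 1/2
  expect_false(out2[[2L]]$is_gland)
})

test_that("reweight never increases scores and is idempotent on survivors", {
  shape <- c(40L, 40L)
  set.seed(51)
  prob <- matrix(runif(1600L), 40L, 40L)
  bpm <- bpm_from_matrix(prob)
  cfg <- gs_config()
  regs <- lapply(1:8, function(k) {
    r0 <- sample(1:25, 1L); c0 <- sample(1:25, 1L)
    rect_region(r0:(r0 + 10L), c0:(c0 + 10L), shape, id = k)
  })
  scored <- mapply(scored_from, regs, runif(8L), SIMPLIFY = FALSE)
  out <- reweight(scored, bpm, cfg)
  s_in <- vapply(scored, `[[`, numeric(1L), "score")
  s_out <- vapply(out, `[[`, numeric(1L), "score")
  expect_true(all(s_out <= s_in + 1e-12))
  # survivors (unchanged scores) stay unchanged when reweighted again
  surv <- which(s_out == s_in)
  out2 <- reweight(out, bpm, cfg)
  s_out2 <- vapply(out2, `[[`, numeric(1L), "score")
  ord_in <- order(-s_in, seq_along(s_in))
  ord_out <- order(-s_out, seq_along(s_out))
  if (identical(ord_in, ord_out))
    expect_true(all(s_out2[surv] == s_out[surv]))
})

test_that("merge_score reflects boundary evidence on the shared band", {
  # 1 x 2 image: two touching single-pixel regions; the shared band is both
  shape <- c(1L, 2L)
  p <- make_region(1L, shape, id = 1L)
  q <- make_region(2L, shape, id = 2L)
  strong <- bpm_from_matrix(matrix(c(1, 1), 1L, 2L))
  expect_equal(merge_score(p, q, strong), 0)
  none <- bpm_from_matrix(matrix(c(0, 0), 1L, 2L))
  expect_equal(merge_score(p, q, none), 1)
  mixed <- bpm_from_matrix(matrix(c(0.2, 0.4), 1L, 2L))
  expect_equal(merge_score(p, q, mixed), 1 - 0.3)
  # non-neighbors raise an error
  shape2 <- c(8L, 8L)
  far1 <- rect_region(1:2, 1:2, shape2)
  far2 <- rect_region(6:7, 6:7, shape2)
  expect_error(merge_score(far1, far2, bpm_from_matrix(matrix(0, 8L, 8L))),
               "not neighbors")
})

test_that("greedy merging fires iff affinity reaches the threshold and terminates", {
  shape <- c(12L, 30L)
  # three-region chain; seam between 1 and 2 has zero evidence (P ~ 1),
  # seam between 2 and 3 has full evidence (P ~ 0)
  r1 <- rect_region(1:12, 1:10, shape, id = 1L)
  r2 <- rect_region(1:12, 11:20, shape, id = 2L)
  r3 <- rect_region(1:12, 21:30, shape, id = 3L)
  prob <- matrix(0, 12L, 30L)
  prob[, 19:22] <- 1  # strong border around the 2|3 seam
  bpm <- bpm_from_matrix(prob)
  cfg <- gs_config()
  scored <- list(scored_from(r1, 0.9), scored_from(r2, 0.8), scored_from(r3, 0.7))
  out <- greedy_merge(scored, bpm, cfg)
  expect_length(out, 2L)  # exactly one merge
  areas <- sort(vapply(out, function(s) s$region$area, integer(1L)))
  expect_equal(areas, c(120L, 240L))
  # merged score is the area-weighted mean
  big <- out[[which.max(vapply(out, function(s) s$region$area, integer(1L)))]]
  expect_equal(big$score, (120 * 0.9 + 120 * 0.8) / 240)
  # merged region is 8-connected
  lab <- glandseg:::cpp_label_components(
    matrix(seq_len(12L * 30L) %in% big$region$pixels, 12L, 30L), 8L)
  expect_equal(max(lab), 1L)
  # no neighboring gland pairs -> unchanged
  out2 <- greedy_merge(list(scored_from(r1, 0.9), scored_from(r3, 0.7)),
                       bpm, cfg)
  expect_length(out2, 2L)
  expect_setequal(vapply(out2, `[[`, numeric(1L), "score"), c(0.9, 0.7))
  # zero-evidence seam between two gland halves always merges
  out3 <- greedy_merge(list(scored_from(r1, 0.9), scored_from(r2, 0.8)),
                       bpm_from_matrix(matrix(0, 12L, 30L)), cfg)
  expect_length(out3, 1L)
})

test_that("merging leaves regions pairwise disjoint", {
  shape <- c(20L, 20L)
  set.seed(53)
  # random 4-region partition of a square via two straight cuts
  r1 <- rect_region(1:10, 1:10, shape, id = 1L)
  r2 <- rect_region(1:10, 11:20, shape, id = 2L)
  r3 <- rect_region(11:20, 1:10, shape, id = 3L)
  r4 <- rect_region(11:20, 11:20, shape, id = 4L)
  prob <- matrix(runif(400L, 0, 0.4), 20L, 20L)
  bpm <- bpm_from_matrix(prob)
  scored <- list(scored_from(r1, 0.9), scored_from(r2, 0.85),
                 scored_from(r3, 0.8), scored_from(r4, 0.75))
  out <- greedy_merge(scored, bpm, gs_config())
  px <- unlist(lapply(out, function(s) s$region$pixels))
  expect_equal(length(px), length(unique(px)))
  expect_equal(sort(px), 1:400)
})
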
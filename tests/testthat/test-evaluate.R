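test_that("iou counts pixel sets and rejects the empty-empty case", {
  g <- matrix(0L, 4, 4); g[1:2, 1:2] <- 1L            # 2x2 square
  e <- matrix(0L, 4, 4); e[1:2, 1] <- 1L              # its 2x1 half
  expect_equal(iou(g, e), 0.5)
  expect_equal(iou(g, g), 1)
  d <- matrix(0L, 4, 4); d[4, 4] <- 1L
  expect_equal(iou(g, d), 0)
  expect_error(iou(matrix(0L, 2, 2), matrix(0L, 2, 2)), "empty")
})

test_that("mutual-best matching pairs identical maps and resolves asymmetric overlap", {
  m <- matrix(0L, 12, 12)
  m[1:3, 1:3] <- 1L; m[5:7, 5:7] <- 2L; m[9:11, 9:11] <- 3L
  mt <- mutual_best_matching(m, m)
  expect_equal(nrow(mt$pairs), 3)
  expect_true(all(mt$pairs$iou_star == 1))
  expect_equal(mt$pairs$gt_id, mt$pairs$est_id)

  # one gt nucleus split into two equal est halves: exact tie, no pair
  gt <- matrix(0L, 4, 4); gt[1:4, 1:2] <- 1L
  est <- matrix(0L, 4, 4); est[1:2, 1:2] <- 1L; est[3:4, 1:2] <- 2L
  mt2 <- mutual_best_matching(gt, est)
  expect_equal(nrow(mt2$pairs), 0)

  # gt A overlaps est X at IoU 0.6 and est Y at lower IoU: only (A, X)
  gt3 <- matrix(0L, 10, 10); gt3[1:2, 1:5] <- 1L       # 10 px
  est3 <- matrix(0L, 10, 10)
  est3[1:2, 1:3] <- 1L                                 # IoU 6/10
  est3[1, 6:8] <- 2L                                   # disjoint from gt
  mt3 <- mutual_best_matching(gt3, est3)
  expect_equal(nrow(mt3$pairs), 1)
  expect_equal(mt3$pairs$gt_id, 1)
  expect_equal(mt3$pairs$est_id, 1)
  expect_equal(mt3$pairs$iou_star, 0.6)
})

test_that("one-to-one property holds on random maps", {
  set.seed(17)
  for (i in 1:25) {
    gt <- random_instance_map(15, 15)
    est <- random_instance_map(15, 15)
    mt <- mutual_best_matching(gt, est)
    expect_equal(anyDuplicated(mt$pairs$gt_id), 0)
    expect_equal(anyDuplicated(mt$pairs$est_id), 0)
    expect_true(all(mt$pairs$iou_star > 0))
  }
})

test_that("matching equals the exhaustive IoU* oracle on random small maps", {
  set.seed(23)
  for (i in 1:60) {
    gt <- random_instance_map(sample(6:16, 1), sample(6:16, 1))
    est <- random_instance_map(nrow(gt), ncol(gt))
    mt <- mutual_best_matching(gt, est)
    or <- oracle_matching(gt, est)
    expect_equal(mt$pairs$gt_id, or$pairs$gt_id)
    expect_equal(mt$pairs$est_id, or$pairs$est_id)
    expect_equal(mt$pairs$iou_star, or$pairs$iou_star)
  }
})

test_that("F1 curves follow the counting identities and conventions", {
  m <- matrix(0L, 12, 12); m[1:4, 1:4] <- 1L; m[7:10, 7:10] <- 2L
  cv <- f1_curve(m, m)
  expect_true(all(cv$F1 == 1))

  # empty estimate vs 5 gt nuclei
  gt <- matrix(0L, 10, 20)
  for (k in 1:5) gt[2:3, 4 * k - 3:2] <- k
  cv2 <- f1_curve(gt, matrix(0L, 10, 20))
  expect_true(all(cv2$F1 == 0))
  expect_true(all(cv2$FN == n_instances(gt)))
  expect_true(all(cv2$TP == 0) && all(cv2$FP == 0))

  # 10 gt / 10 est with 8 perfect pairs and 2 unmatched per side:
  # F1 = 16/20 = 0.8 below the matched IoU
  gt3 <- matrix(0L, 30, 30); est3 <- matrix(0L, 30, 30)
  for (k in 1:8) {
    r <- 3 * k - 2
    gt3[r, 1:3] <- k; est3[r, 1:3] <- k
  }
  gt3[28:29, 1:2] <- 9L; gt3[28:29, 8:9] <- 10L
  est3[28:29, 14:15] <- 9L; est3[28:29, 20:21] <- 10L
  cv3 <- f1_curve(gt3, est3, thresholds = 0.5)
  expect_equal(cv3$TP, 8L)
  expect_equal(cv3$FN, 2L)
  expect_equal(cv3$FP, 2L)
  expect_equal(cv3$F1, 0.8)

  # both empty: perfect agreement on nothing
  cv4 <- f1_curve(matrix(0L, 5, 5), matrix(0L, 5, 5))
  expect_true(all(cv4$F1 == 1))
})

test_that("F1 is monotone non-increasing, symmetric, and count-consistent", {
  set.seed(41)
  for (i in 1:15) {
    gt <- random_instance_map(18, 18)
    est <- random_instance_map(18, 18)
    cv <- f1_curve(gt, est)
    expect_true(all(diff(cv$F1) <= 1e-12))
    expect_true(all(cv$F1 >= 0 & cv$F1 <= 1))
    expect_true(all(cv$TP + cv$FN == attr(cv, "n_gt")))
    expect_true(all(cv$TP + cv$FP == attr(cv, "n_est")))
    swapped <- f1_curve(est, gt)
    expect_equal(swapped$F1, cv$F1)
    expect_equal(swapped$FN, cv$FP)
  }
})

test_that("aggregate_curves returns per-threshold mean and population sd", {
  m <- matrix(0L, 8, 8); m[2:5, 2:5] <- 1L
  cv <- f1_curve(m, m)
  ag1 <- aggregate_curves(list(cv))
  expect_equal(ag1$mean_f1, cv$F1)
  expect_true(all(ag1$sd_f1 == 0))

  # two synthetic curves at 0.6 and 0.8: mean 0.7, population sd 0.1
  c1 <- cv; c1$F1 <- rep(0.6, nrow(cv))
  c2 <- cv; c2$F1 <- rep(0.8, nrow(cv))
  ag <- aggregate_curves(list(c1, c2))
  expect_equal(ag$mean_f1, rep(0.7, nrow(cv)))
  expect_equal(ag$sd_f1, rep(0.1, nrow(cv)))

  ag2 <- aggregate_curves(list(cv, cv, cv))
  expect_true(all(ag2$sd_f1 == 0))

  c3 <- cv; c3$threshold <- cv$threshold + 0.01
  expect_error(aggregate_curves(list(cv, c3)), "grids")
})

test_that("detection score at t = 0.05 ignores small boundary perturbations", {
  set.seed(53)
  cm <- structure(list(mean = 8, sd = 2), class = "count_model")
  sm <- structure(list(mu = 90, beta = 15), class = "size_model")
  gt <- sample_mask_image(cm, sm, c(64, 64), min_gap = 2, seed = 8)
  jit <- corrupt_instances(gt, corruption_params(boundary_jitter = 1),
                           seed = 9)
  cv <- f1_curve(gt, jit)
  expect_equal(cv$F1[cv$threshold == 0.05], 1)
})
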
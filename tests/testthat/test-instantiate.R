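one_hot_probs <- function(mask, ...) {
  probabilities_from_instances(mask, softness = 0, noise_sd = 0, ...)
}

test_that("seeds are components of inner minus contour above a strict threshold", {
  # uniform foreground: one seed covering the grid
  pr <- probability_maps(matrix(1, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4))
  s <- seeds_from_probabilities(pr)
  expect_true(all(s == 1L))

  # difference exactly at the threshold is excluded (strict >)
  pr2 <- probability_maps(matrix(0.35, 4, 4), matrix(0, 4, 4),
                          matrix(0.65, 4, 4))
  expect_equal(max(seeds_from_probabilities(pr2, 0.35)), 0)

  # two plateaus separated by a contour ridge give two seeds
  inner <- matrix(0.9, 3, 7); contour <- matrix(0, 3, 7)
  inner[, 4] <- 0.1; contour[, 4] <- 0.8
  pr3 <- probability_maps(inner, contour, 1 - inner - contour)
  expect_equal(max(seeds_from_probabilities(pr3, 0.35)), 2)
})

test_that("voronoi_assign matches hand-computed nearest-seed layouts", {
  s <- matrix(0L, 3, 3); s[2, 2] <- 1L
  expect_true(all(voronoi_assign(s) == 1L))

  # 1x10 with seeds at the two ends: 5 columns each
  s2 <- matrix(0L, 1, 10); s2[1, 1] <- 1L; s2[1, 10] <- 2L
  v <- voronoi_assign(s2)
  expect_equal(as.vector(v), rep(c(1L, 2L), each = 5))

  # seed pixels keep their own id
  s3 <- matrix(0L, 5, 5); s3[1, 1] <- 1L; s3[5, 5] <- 2L
  v3 <- voronoi_assign(s3)
  expect_equal(v3[1, 1], 1L)
  expect_equal(v3[5, 5], 2L)

  expect_error(voronoi_assign(matrix(0L, 3, 3)), "no seeds")
})

test_that("voronoi_assign equals the brute-force oracle, ties included", {
  # deterministic tie case: equidistant pixels go to the smaller id
  s <- matrix(0L, 1, 5); s[1, 1] <- 1L; s[1, 5] <- 2L
  v <- voronoi_assign(s)
  expect_equal(v[1, 3], 1L)          # distance 2 both sides
  expect_identical(v, oracle_voronoi(s))

  set.seed(31)
  for (i in 1:30) {
    seeds <- random_seed_map(sample(4:12, 1), sample(4:12, 1))
    if (max(seeds) == 0) next
    expect_identical(voronoi_assign(seeds), oracle_voronoi(seeds))
  }
})

test_that("object_mask thresholds the background channel strictly", {
  bg <- matrix(1, 4, 4)
  pr <- probability_maps(matrix(0, 4, 4), matrix(0, 4, 4), bg)
  expect_false(any(object_mask(pr)))

  bg2 <- matrix(0.95, 4, 4)
  pr2 <- probability_maps(matrix(0.05, 4, 4), matrix(0, 4, 4), bg2)
  expect_false(any(object_mask(pr2, 0.95)))   # strict <

  bg3 <- matrix(0.99, 8, 8); bg3[3:6, 3:6] <- 0.2
  pr3 <- probability_maps(1 - bg3, matrix(0, 8, 8), bg3)
  expect_identical(object_mask(pr3), bg3 < 0.95)
})

test_that("the full pipeline recovers well-separated nuclei and filters small ones", {
  m <- matrix(0L, 24, 24)
  m[3:9, 3:10] <- 1L                  # 56 px
  m[14:20, 12:19] <- 2L               # 56 px
  rec <- instances_from_probabilities(one_hot_probs(m))
  expect_equal(n_instances(rec), 2L)
  expect_true(same_partition(rec, m))

  # a 20-px nucleus disappears under the default 35-px area filter
  small <- matrix(0L, 16, 16); small[5:8, 5:9] <- 1L
  expect_equal(max(instances_from_probabilities(one_hot_probs(small))), 0)

  # uniform background probability: empty map
  pr <- probability_maps(matrix(0, 6, 6), matrix(0, 6, 6), matrix(1, 6, 6))
  expect_equal(max(instances_from_probabilities(pr)), 0)
})

test_that("pipeline outputs respect the object mask, min area and seed origin", {
  set.seed(91)
  cm <- structure(list(mean = 8, sd = 2), class = "count_model")
  sm <- structure(list(mu = 80, beta = 15), class = "size_model")
  for (i in 1:5) {
    m <- sample_mask_image(cm, sm, c(80, 80), min_gap = 1, seed = 100 + i)
    pr <- probabilities_from_instances(m, softness = 0.5, noise_sd = 0)
    params <- postprocess_params()
    rec <- instances_from_probabilities(pr, params)
    seeds <- seeds_from_probabilities(pr, params$seed_threshold)
    obj <- object_mask(pr, params$background_threshold)
    # nuclei are subsets of the object mask
    expect_true(all(obj[rec > 0]))
    # all areas >= min_area, and every nucleus contains a seed pixel
    areas <- instance_areas(rec)
    if (length(areas)) expect_true(all(areas >= params$min_area))
    for (id in unique(rec[rec > 0]))
      expect_gt(sum(seeds[rec == id] > 0), 0)
    # never more nuclei than seed components
    expect_lte(n_instances(rec), max(seeds))
  }
})

test_that("one-hot round trip recovers counts for non-touching nuclei >= 35 px", {
  set.seed(5)
  cm <- structure(list(mean = 10, sd = 2), class = "count_model")
  sm <- structure(list(mu = 90, beta = 18), class = "size_model")
  for (i in 1:5) {
    m <- sample_mask_image(cm, sm, c(96, 96), min_gap = 1, seed = 40 + i)
    rec <- instances_from_probabilities(one_hot_probs(m))
    expect_equal(n_instances(rec), n_instances(m))
  }
})
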
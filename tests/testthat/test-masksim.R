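test_that("count model is the sample mean/sd of per-image nucleus counts", {
  mk <- function(n) {
    m <- matrix(0L, 10, 40)
    for (k in seq_len(n)) m[2:3, (3 * k - 2):(3 * k - 1)] <- k
    m
  }
  cm <- fit_count_model(list(mk(10), mk(10), mk(10)))
  expect_equal(cm$mean, 10)
  expect_equal(cm$sd, 0)

  cm2 <- fit_count_model(list(mk(8), mk(12)))
  expect_equal(cm2$mean, 10)
  expect_equal(cm2$sd, 2 * sqrt(2))

  expect_error(fit_count_model(list(mk(3))), "at least 2")
})

test_that("size model inverts the Gumbel moment equations", {
  # mean 111.54, sd 25.65 correspond to mu ~ 100, beta ~ 20
  areas <- c(111.54 - 25.65, 111.54 + 25.65)
  # use the closed form directly on a vector of areas with those moments
  areas <- rep(areas, 5)                      # n = 10, mean/sd preserved
  sm <- fit_size_model(areas)
  sd_used <- stats::sd(areas)
  expect_equal(sm$beta, sd_used * sqrt(6) / pi)
  expect_equal(sm$mu, mean(areas) - 0.57721566490153286 * sm$beta)
  # and numerically close to the nominal inversion
  sm2 <- fit_size_model(c(111.54 + 25.65 * scale(stats::rnorm(5000))))
  expect_equal(sm2$beta, 20, tolerance = 0.01)
  expect_equal(sm2$mu, 100, tolerance = 0.01)

  expect_error(fit_size_model(rep(100, 20)), "degenerate")
  expect_error(fit_size_model(c(1, 2, 3)), "at least 10")
})

test_that("moment fit recovers generating Gumbel parameters at n = 1e4", {
  set.seed(2024)
  areas <- rgumbel(1e4, mu = 100, beta = 20)
  sm <- fit_size_model(areas)
  expect_equal(sm$mu, 100, tolerance = 2 / 100)   # spec'd +/- 2 absolute
  expect_lt(abs(sm$mu - 100), 2)
  expect_lt(abs(sm$beta - 20), 1)
  # maximum likelihood agrees with moments to within sampling error
  sm_mle <- fit_size_model(areas, method = "mle")
  expect_lt(abs(sm_mle$mu - 100), 2)
  expect_lt(abs(sm_mle$beta - 20), 1)
})

test_that("ellipse specs preserve area exactly and rasterize accurately", {
  set.seed(77)
  errs <- replicate(1000, {
    s <- max(rgumbel(1, 100, 20), 35)
    sp <- draw_ellipse_spec(s)
    expect_equal(pi * sp$a * sp$b, s, tolerance = 1e-12)
    px <- rasterize_ellipse(c(40 + stats::runif(1), 40 + stats::runif(1)),
                            sp$a, sp$b, sp$theta, 80, 80)
    (length(px) - s) / s
  })
  # rasterization error bound, assessed statistically
  expect_lt(mean(abs(errs)), 0.05)
  expect_gte(mean(abs(errs) <= 0.15), 0.99)
})

test_that("mask sampling is deterministic and respects degenerate counts", {
  cm0 <- structure(list(mean = 0, sd = 0), class = "count_model")
  sm <- structure(list(mu = 100, beta = 20), class = "size_model")
  expect_equal(max(sample_mask_image(cm0, sm, c(32, 32), seed = 1)), 0)

  cm <- structure(list(mean = 12, sd = 3), class = "count_model")
  a <- sample_mask_image(cm, sm, c(128, 128), seed = 99)
  b <- sample_mask_image(cm, sm, c(128, 128), seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, sample_mask_image(cm, sm, c(128, 128), seed = 98)))
})

test_that("sampled masks are valid instance maps with disjoint, min-area nuclei", {
  cm <- structure(list(mean = 15, sd = 4), class = "count_model")
  sm <- structure(list(mu = 100, beta = 20), class = "size_model")
  for (i in 1:5) {
    m <- sample_mask_image(cm, sm, c(128, 128), seed = 200 + i)
    expect_true(same_partition(m, m))           # normalize_ids equivalence
    expect_equal(n_instances(normalize_ids(m)), n_instances(m))
    areas <- instance_areas(m)
    if (length(areas)) expect_true(all(areas >= 35))
  }
})

test_that("per-image counts track the count model over a seed batch", {
  cm <- structure(list(mean = 30, sd = 5), class = "count_model")
  sm <- structure(list(mu = 100, beta = 20), class = "size_model")
  counts <- vapply(1:60, function(i)
    n_instances(sample_mask_image(cm, sm, c(256, 256), seed = 1000 + i)),
    integer(1))
  expect_lt(abs(mean(counts) - 30), 1.0)
})

test_that("generate_dataset derives per-image seeds reproducibly", {
  cm <- structure(list(mean = 6, sd = 2), class = "count_model")
  sm <- structure(list(mu = 80, beta = 15), class = "size_model")
  d1 <- generate_dataset(4, cm, sm, shape = c(64, 64), seed = 5)
  d2 <- generate_dataset(4, cm, sm, shape = c(64, 64), seed = 5)
  expect_identical(d1, d2)
  expect_length(d1, 4)
  # image i depends only on seed + i
  expect_identical(d1[[2]],
                   sample_mask_image(cm, sm, c(64, 64), seed = 7))
  # the fit/sample loop closes: parameters recovered within 3 SEs
  set.seed(1)
  big <- generate_dataset(40, cm, sm, shape = c(96, 96), seed = 11)
  areas <- unlist(lapply(big, function(m) as.numeric(instance_areas(m))))
  sm_hat <- fit_size_model(areas)
  n <- length(areas)
  sigma <- 15 * pi / sqrt(6)
  se_beta <- sigma * sqrt((5.4 - 1) / (4 * n)) * sqrt(6) / pi
  se_mu <- sqrt(sigma^2 / n + 0.5772^2 * se_beta^2)
  # truncation at 35 px biases the fit slightly; allow 3 SE + a small bias
  # margin checked against the truncated-Gumbel mean shift
  expect_lt(abs(sm_hat$beta - 15), 3 * se_beta + 1.5)
  expect_lt(abs(sm_hat$mu - 80), 3 * se_mu + 1.5)
})
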
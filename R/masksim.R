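# Parametric nuclei-mask simulator.
#
# Nuclei counts per image follow a Gaussian (truncated at 0, rounded);
# nucleus areas follow a Gumbel distribution, capturing the heavy right
# tail of epithelial nucleus sizes; each nucleus is rendered as a randomly
# oriented ellipse of exactly the drawn area.

EULER_GAMMA <- 0.57721566490153286

#' Gumbel distribution functions
#'
#' Quantile and random generation for the Gumbel (type-I extreme value)
#' distribution with location `mu` and scale `beta`.
#'
#' @param p probabilities; `n` number of draws.
#' @param mu location; `beta` scale (> 0).
#' @return numeric vector.
#' @export
qgumbel <- function(p, mu = 0, beta = 1) {
  stopifnot(beta > 0)
  mu - beta * log(-log(p))
}

#' @rdname qgumbel
#' @param n number of random draws.
#' @export
rgumbel <- function(n, mu = 0, beta = 1) qgumbel(stats::runif(n), mu, beta)

#' Fit the per-image nucleus count model
#'
#' Gaussian model of the number of nuclei per image, estimated as the sample
#' mean and sample standard deviation of the counts over a training set of
#' annotated instance maps.
#'
#' @param instance_maps list of at least two instance matrices.
#' @return object of class `count_model` with fields `mean`, `sd`.
#' @export
fit_count_model <- function(instance_maps) {
  if (is.matrix(instance_maps)) instance_maps <- list(instance_maps)
  if (length(instance_maps) < 2)
    stop("need at least 2 instance maps to fit a count model", call. = FALSE)
  counts <- vapply(instance_maps, n_instances, integer(1))
  structure(list(mean = mean(counts), sd = stats::sd(counts)),
            class = "count_model")
}

#' Fit the nucleus size model
#'
#' Gumbel model of nucleus areas (pixels), fitted by method of moments on
#' the areas pooled over all maps: scale beta = sd * sqrt(6) / pi and
#' location mu = mean - gamma * beta (gamma = Euler-Mascheroni constant).
#' A maximum-likelihood fit is available with `method = "mle"`.
#'
#' @param instance_maps list of instance matrices (>= 10 pooled nuclei), or
#'   a numeric vector of areas.
#' @param method `"moments"` (default, closed form) or `"mle"`.
#' @return object of class `size_model` with fields `mu`, `beta`.
#' @export
fit_size_model <- function(instance_maps, method = c("moments", "mle")) {
  method <- match.arg(method)
  areas <- if (is.numeric(instance_maps) && !is.matrix(instance_maps)) {
    instance_maps
  } else {
    if (is.matrix(instance_maps)) instance_maps <- list(instance_maps)
    unlist(lapply(instance_maps, function(m) as.numeric(instance_areas(m))))
  }
  if (length(areas) < 10)
    stop("need at least 10 pooled nuclei to fit a size model", call. = FALSE)
  s <- stats::sd(areas)
  if (s == 0)
    stop("degenerate size distribution: all areas identical (sd = 0)",
         call. = FALSE)
  beta <- s * sqrt(6) / pi
  mu <- mean(areas) - EULER_GAMMA * beta
  if (method == "mle") {
    nll <- function(par) {
      b <- exp(par[2])
      z <- (areas - par[1]) / b
      sum(log(b) + z + exp(-z))
    }
    opt <- stats::optim(c(mu, log(beta)), nll, method = "BFGS")
    mu <- opt$par[1]; beta <- exp(opt$par[2])
  }
  structure(list(mu = mu, beta = beta), class = "size_model")
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf("<count_model> Gaussian, mean %.2f, sd %.2f nuclei/image\n",
              x$mean, x$sd)); invisible(x)
}
#' @export
print.size_model <- function(x, ...) {
  cat(sprintf("<size_model> Gumbel, mu %.2f, beta %.2f px^2\n",
              x$mu, x$beta)); invisible(x)
}

# Rasterize one ellipse onto the grid: pixel centers (r, c) with
# ((u/a)^2 + (v/b)^2) <= 1 in the rotated frame. Returns column-major pixel
# indices, or integer(0) if fully outside.
rasterize_ellipse <- function(center, a, b, theta, nr, nc) {
  ext_r <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ext_c <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  r0 <- center[1]; c0 <- center[2]
  rs <- max(1, floor(r0 - ext_r)):min(nr, ceiling(r0 + ext_r))
  cs <- max(1, floor(c0 - ext_c)):min(nc, ceiling(c0 + ext_c))
  if (rs[1] > rs[length(rs)] || cs[1] > cs[length(cs)]) return(integer(0))
  dr <- rs - r0
  dc <- cs - c0
  u <- outer(dr, dc, function(x, y) cos(theta) * x + sin(theta) * y)
  v <- outer(dr, dc, function(x, y) -sin(theta) * x + cos(theta) * y)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(integer(0))
  ij <- which(inside, arr.ind = TRUE)
  (cs[ij[, 2]] - 1L) * nr + rs[ij[, 1]]
}

#' Draw one ellipse specification
#'
#' Samples an ellipse of area `s`: orientation uniform on [0, pi), semi-axis
#' a from a positive-truncated Gaussian with mean sqrt(s/pi) and coefficient
#' of variation `ratio_sd_factor`, and b = s / (pi a) so the continuous area
#' is exactly s.
#'
#' @param s target area in pixels^2.
#' @param ratio_sd_factor coefficient of variation of the semi-axis
#'   (default 0.2).
#' @return list with fields a, b, theta, area.
#' @export
draw_ellipse_spec <- function(s, ratio_sd_factor = 0.2) {
  stopifnot(s > 0)
  r_mean <- sqrt(s / pi)
  a <- -1
  for (k in 1:100) {
    a <- stats::rnorm(1, r_mean, ratio_sd_factor * r_mean)
    if (a > 0) break
  }
  if (a <= 0) a <- r_mean
  theta <- stats::runif(1, 0, pi)
  list(a = a, b = s / (pi * a), theta = theta, area = s)
}

#' Simulate one nuclei mask image
#'
#' Draws a nucleus count from the (truncated, rounded) Gaussian count model,
#' then places randomly oriented ellipses with Gumbel-distributed areas at
#' uniform random centers. A placement whose overlap with already-placed
#' nuclei exceeds `max_overlap` (as a fraction of the new nucleus) is
#' rejected and redrawn up to `max_tries` times, then the nucleus is
#' skipped. With `min_gap` > 0 placements are also rejected when any
#' existing nucleus lies within that chebyshev distance, yielding
#' non-touching nuclei. Ellipses are placed fully inside the image.
#'
#' @param count_model `count_model` object (or list with mean, sd).
#' @param size_model `size_model` object (or list with mu, beta).
#' @param shape integer c(height, width), each >= 16.
#' @param ratio_sd_factor semi-axis coefficient of variation (default 0.2).
#' @param max_overlap maximum tolerated overlap fraction (default 0).
#' @param min_area smallest area drawn (Gumbel truncated below; default 35).
#' @param min_gap minimum chebyshev gap in pixels to other nuclei
#'   (default 0 = touching allowed).
#' @param max_tries placement retries per nucleus (default 50).
#' @param seed integer seed; the call is deterministic given the seed.
#' @return integer instance matrix.
#' @export
sample_mask_image <- function(count_model, size_model, shape = c(256L, 256L),
                              ratio_sd_factor = 0.2, max_overlap = 0,
                              min_area = 35L, min_gap = 0L, max_tries = 50L,
                              seed = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 16))
  if (!is.null(seed)) set.seed(seed)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  out <- matrix(0L, nr, nc)
  n <- max(0L, as.integer(round(stats::rnorm(1, count_model$mean,
                                             count_model$sd))))
  if (n == 0) return(out)
  placed <- 0L
  for (k in seq_len(n)) {
    s <- NA_real_
    for (t in 1:100) {
      s <- rgumbel(1, size_model$mu, size_model$beta)
      if (s >= min_area) break
    }
    if (is.na(s) || s < min_area) next
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      spec <- draw_ellipse_spec(s, ratio_sd_factor)
      ext_r <- ceiling(sqrt((spec$a * cos(spec$theta))^2 +
                            (spec$b * sin(spec$theta))^2))
      ext_c <- ceiling(sqrt((spec$a * sin(spec$theta))^2 +
                            (spec$b * cos(spec$theta))^2))
      if (2 * ext_r + 2 > nr || 2 * ext_c + 2 > nc) next
      ctr <- c(stats::runif(1, 1 + ext_r, nr - ext_r),
               stats::runif(1, 1 + ext_c, nc - ext_c))
      px <- rasterize_ellipse(ctr, spec$a, spec$b, spec$theta, nr, nc)
      # drawn areas are truncated at min_area; hold the rasterized pixel
      # count to the same floor so placed nuclei honour the size contract
      if (length(px) < max(1, min_area)) next
      if (sum(out[px] > 0) / length(px) > max_overlap) next
      if (min_gap > 0) {
        halo <- ellipse_halo(px, min_gap, nr, nc)
        if (any(out[halo] > 0)) next
      }
      ok <- TRUE
      break
    }
    if (ok) {
      placed <- placed + 1L
      free <- px[out[px] == 0]
      out[free] <- placed
    }
  }
  out
}

# Chebyshev dilation of a pixel-index set by radius g (indices clipped to
# the image); used for minimum-gap placement checks.
ellipse_halo <- function(px, g, nr, nc) {
  rr <- ((px - 1L) %% nr) + 1L
  cc <- ((px - 1L) %/% nr) + 1L
  offs <- expand.grid(dr = -g:g, dc = -g:g)
  idx <- unlist(lapply(seq_len(nrow(offs)), function(i) {
    r2 <- rr + offs$dr[i]; c2 <- cc + offs$dc[i]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    (c2[ok] - 1L) * nr + r2[ok]
  }))
  unique(idx)
}

#' Simulate a dataset of nuclei mask images
#'
#' Generates `n_images` independent mask images; image i uses seed
#' `seed + i`, so the collection is reproducible and any subset can be
#' regenerated in isolation.
#'
#' @inheritParams sample_mask_image
#' @param n_images number of images (>= 1).
#' @param seed master seed.
#' @return list of integer instance matrices.
#' @export
generate_dataset <- function(n_images, count_model, size_model,
                             shape = c(256L, 256L), ratio_sd_factor = 0.2,
                             max_overlap = 0, min_area = 35L, min_gap = 0L,
                             max_tries = 50L, seed = 1L) {
  stopifnot(n_images >= 1)
  lapply(seq_len(n_images), function(i)
    sample_mask_image(count_model, size_model, shape = shape,
                      ratio_sd_factor = ratio_sd_factor,
                      max_overlap = max_overlap, min_area = min_area,
                      min_gap = min_gap, max_tries = max_tries,
                      seed = seed + i))
}
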
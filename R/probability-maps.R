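# Container for semantic class-probability maps.

#' Construct class-probability maps
#'
#' Bundles the three per-pixel class probability channels produced by a
#' semantic segmentation network (softmax output). Channels must share a
#' shape, lie in [0, 1] and sum to 1 per pixel within `tol`.
#'
#' @param inner,contour,background numeric matrices of identical shape.
#' @param tol allowed deviation of the per-pixel channel sum from 1.
#' @return a `prob_maps` object: an H x W x 3 array with channels named
#'   inner, contour, background.
#' @export
probability_maps <- function(inner, contour, background, tol = 1e-3) {
  if (!is.matrix(inner) || !is.matrix(contour) || !is.matrix(background))
    stop("channels must be matrices", call. = FALSE)
  assert_same_shape(inner, contour)
  assert_same_shape(inner, background)
  x <- array(c(inner, contour, background),
             dim = c(nrow(inner), ncol(inner), 3),
             dimnames = list(NULL, NULL, c("inner", "contour", "background")))
  validate_prob_maps(x, tol = tol)
  class(x) <- c("prob_maps", class(x))
  x
}

validate_prob_maps <- function(x, tol = 1e-3) {
  if (length(dim(x)) != 3 || dim(x)[3] != 3)
    stop("probability maps must have 3 channels", call. = FALSE)
  if (any(x < 0) || any(x > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  s <- x[, , 1] + x[, , 2] + x[, , 3]
  dev <- abs(s - 1)
  if (any(dev > tol)) {
    worst <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "per-pixel channel sum violates softmax contract: sum = %.6f at pixel (row %d, col %d)",
      s[worst[1], worst[2]], worst[1], worst[2]), call. = FALSE)
  }
  invisible(TRUE)
}

p_channel <- function(probs, which) {
  if (inherits(probs, "prob_maps") || (is.array(probs) && length(dim(probs)) == 3))
    return(probs[, , which])
  stop("expected a prob_maps object", call. = FALSE)
}

#' @export
print.prob_maps <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<prob_maps> %d x %d, channels inner/contour/background\n",
              d[1], d[2]))
  invisible(x)
}
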
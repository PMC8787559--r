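# IoU* mutual-best-match F1 evaluation.
#
# A ground-truth and an estimated nucleus are matched only when their IoU is
# strictly the largest in both its row and its column of the pairwise IoU
# matrix; this enforces a one-to-one correspondence without any assignment
# optimisation. TP(t) counts matched pairs with IoU* > t; FN and FP are the
# unmatched remainders of each side.

#' Intersection over union of two pixel sets
#'
#' @param gt_pixels,est_pixels integer vectors of pixel indices (or logical
#'   matrices) on the same grid.
#' @return IoU in [0, 1]. Both sets empty is an error.
#' @export
iou <- function(gt_pixels, est_pixels) {
  if (is.matrix(gt_pixels)) gt_pixels <- which(gt_pixels > 0)
  if (is.matrix(est_pixels)) est_pixels <- which(est_pixels > 0)
  if (length(gt_pixels) == 0 && length(est_pixels) == 0)
    stop("IoU undefined: both pixel sets empty", call. = FALSE)
  inter <- length(intersect(gt_pixels, est_pixels))
  inter / (length(gt_pixels) + length(est_pixels) - inter)
}

# Pairwise intersection counts and areas between two instance maps.
# Returns list(inter = n_gt x n_est integer matrix, a_gt, a_est, ids_gt,
# ids_est); intersections computed on pixels foreground in both maps.
pairwise_overlap <- function(gt, est) {
  ids_gt <- sort(unique(gt[gt > 0]))
  ids_est <- sort(unique(est[est > 0]))
  inter <- matrix(0, length(ids_gt), length(ids_est))
  both <- gt > 0 & est > 0
  if (any(both)) {
    tab <- table(factor(gt[both], levels = ids_gt),
                 factor(est[both], levels = ids_est))
    inter[] <- as.numeric(tab)
  }
  a_gt <- as.numeric(table(factor(gt[gt > 0], levels = ids_gt)))
  a_est <- as.numeric(table(factor(est[est > 0], levels = ids_est)))
  list(inter = inter, a_gt = a_gt, a_est = a_est,
       ids_gt = ids_gt, ids_est = ids_est)
}

# Index of the strict maximum of the fractions num[i]/den[i], or 0 when the
# maximum is tied. Compared by cross-multiplication on integer counts, so
# exact: num1/den1 > num2/den2 <=> num1*den2 > num2*den1.
frac_strict_argmax <- function(num, den) {
  best <- 1L
  tied <- FALSE
  for (i in seq_along(num)[-1]) {
    lhs <- num[i] * den[best]
    rhs <- num[best] * den[i]
    if (lhs > rhs) {
      best <- i; tied <- FALSE
    } else if (lhs == rhs) {
      tied <- TRUE
    }
  }
  if (tied || num[best] == 0) 0L else best
}

#' Mutual-best one-to-one matching between two instance maps
#'
#' Pairs ground-truth nucleus g with estimated nucleus e iff IoU(g, e) > 0
#' and IoU(g, e) is strictly the maximum of both row g and column e of the
#' pairwise IoU matrix. Exact ties (compared as exact integer ratios) break
#' no strict inequality and therefore produce no pair.
#'
#' @param gt,est instance matrices of equal shape.
#' @return list of class `nuclei_matching` with elements `pairs` (data.frame
#'   gt_id, est_id, iou_star), `n_gt`, `n_est`.
#' @export
mutual_best_matching <- function(gt, est) {
  assert_instance_map(gt)
  assert_instance_map(est)
  assert_same_shape(gt, est)
  ov <- pairwise_overlap(gt, est)
  n_gt <- length(ov$ids_gt); n_est <- length(ov$ids_est)
  pairs <- data.frame(gt_id = integer(0), est_id = integer(0),
                      iou_star = numeric(0))
  if (n_gt > 0 && n_est > 0) {
    inter <- ov$inter
    union <- outer(ov$a_gt, ov$a_est, "+") - inter
    row_best <- vapply(seq_len(n_gt),
                       function(i) frac_strict_argmax(inter[i, ], union[i, ]),
                       integer(1))
    col_best <- vapply(seq_len(n_est),
                       function(j) frac_strict_argmax(inter[, j], union[, j]),
                       integer(1))
    for (i in seq_len(n_gt)) {
      j <- row_best[i]
      if (j > 0 && col_best[j] == i) {
        pairs <- rbind(pairs, data.frame(
          gt_id = ov$ids_gt[i], est_id = ov$ids_est[j],
          iou_star = inter[i, j] / union[i, j]))
      }
    }
  }
  structure(list(pairs = pairs, n_gt = n_gt, n_est = n_est),
            class = "nuclei_matching")
}

#' @export
print.nuclei_matching <- function(x, ...) {
  cat(sprintf("<nuclei_matching> %d gt, %d est, %d matched pairs\n",
              x$n_gt, x$n_est, nrow(x$pairs)))
  invisible(x)
}

#' Default IoU threshold grid
#'
#' 0.05 to 0.90 in steps of 0.05. The low end scores detection (was each
#' nucleus found at all); the high end scores contour localization.
#' @export
default_thresholds <- function() seq(0.05, 0.90, by = 0.05)

#' F1 score as a function of the IoU threshold
#'
#' Computes TP(t), FN(t), FP(t) and F1(t) over a threshold grid from the
#' mutual-best matching: TP(t) = number of matched pairs with IoU* strictly
#' above t, FN(t) = n_gt - TP(t), FP(t) = n_est - TP(t), and
#' F1(t) = 2 TP / (2 TP + FN + FP). When both maps are empty F1 is defined
#' as 1 at every threshold (perfect agreement on nothing); when exactly one
#' is empty F1 is 0.
#'
#' @param gt,est instance matrices of equal shape.
#' @param thresholds increasing thresholds in (0, 1).
#' @return data.frame of class `eval_curve` with columns threshold, TP, FN,
#'   FP, F1 and attributes `n_gt`, `n_est`.
#' @export
f1_curve <- function(gt, est, thresholds = default_thresholds()) {
  stopifnot(all(thresholds > 0), all(thresholds < 1),
            !is.unsorted(thresholds))
  m <- mutual_best_matching(gt, est)
  tp <- vapply(thresholds, function(t) sum(m$pairs$iou_star > t), numeric(1))
  fn <- m$n_gt - tp
  fp <- m$n_est - tp
  f1 <- if (m$n_gt == 0 && m$n_est == 0) rep(1, length(thresholds))
        else 2 * tp / (2 * tp + fn + fp)
  out <- data.frame(threshold = thresholds, TP = as.integer(tp),
                    FN = as.integer(fn), FP = as.integer(fp), F1 = f1)
  attr(out, "n_gt") <- m$n_gt
  attr(out, "n_est") <- m$n_est
  class(out) <- c("eval_curve", "data.frame")
  out
}

#' Aggregate F1 curves over images
#'
#' Per-threshold arithmetic mean and population standard deviation of F1
#' over a collection of curves on the same threshold grid, as plotted in
#' multi-image benchmark figures (line = mean, band = sd).
#'
#' @param curves list of `eval_curve` data.frames.
#' @return data.frame with columns threshold, mean_f1, sd_f1.
#' @export
aggregate_curves <- function(curves) {
  if (!is.list(curves) || length(curves) == 0)
    stop("need at least one curve", call. = FALSE)
  thr <- curves[[1]]$threshold
  for (cv in curves)
    if (!isTRUE(all.equal(cv$threshold, thr)))
      stop("curves use different threshold grids", call. = FALSE)
  f1 <- vapply(curves, function(cv) cv$F1, numeric(length(thr)))
  f1 <- matrix(f1, nrow = length(thr))
  mu <- rowMeans(f1)
  sdv <- sqrt(rowMeans(sweep(f1, 1, mu)^2))   # population sd
  data.frame(threshold = thr, mean_f1 = mu, sd_f1 = sdv)
}

#' Plot F1-versus-threshold curves
#'
#' @param curves a named list of `eval_curve` objects (one line each), or a
#'   single curve.
#' @return a ggplot object.
#' @export
plot_f1_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  if (inherits(curves, "eval_curve")) curves <- list(curve = curves)
  nm <- names(curves)
  if (is.null(nm)) nm <- paste0("curve", seq_along(curves))
  df <- do.call(rbind, lapply(seq_along(curves), function(i)
    data.frame(method = nm[i], threshold = curves[[i]]$threshold,
               F1 = curves[[i]]$F1)))
  ggplot2::ggplot(df, ggplot2::aes(x = threshold, y = F1, colour = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "IoU threshold", y = "F1 score") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
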
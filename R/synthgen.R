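# Synthetic network-output generators.
#
# These are test instruments: they render pseudo-fluorescence images from
# masks, fabricate plausible semantic class-probability maps, and corrupt
# instance maps with controlled error modes (drop / merge / split / boundary
# jitter) so the post-processing, fusion and evaluation stages can be
# exercised end-to-end with known ground truth. Their noise models are
# declared knobs, not claims about any trained network's error statistics.

#' Rendering parameters for pseudo-fluorescence images
#'
#' @param fg_mean,bg_mean mean foreground / background intensity in [0, 1]
#'   (fg_mean > bg_mean).
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0).
#' @param noise_sd additive Gaussian noise sd.
#' @param texture_amplitude amplitude of smooth intra-nuclear intensity
#'   variation.
#' @return named list of validated parameters.
#' @export
render_params <- function(fg_mean = 0.6, bg_mean = 0.1, blur_sigma = 1,
                          noise_sd = 0.02, texture_amplitude = 0.1) {
  stopifnot(fg_mean > bg_mean, bg_mean >= 0, blur_sigma >= 0,
            noise_sd >= 0, texture_amplitude >= 0)
  list(fg_mean = fg_mean, bg_mean = bg_mean, blur_sigma = blur_sigma,
       noise_sd = noise_sd, texture_amplitude = texture_amplitude)
}

#' Render a pseudo-fluorescence intensity image from a mask
#'
#' Foreground pixels take fg_mean plus a smooth texture term, background
#' takes bg_mean; the image is Gaussian-blurred and corrupted with additive
#' Gaussian noise, then clipped to [0, 1]. Deterministic given the seed.
#'
#' @param mask instance matrix.
#' @param params list from [render_params()].
#' @param seed integer seed.
#' @return numeric intensity matrix in [0, 1].
#' @export
render_image <- function(mask, params = render_params(), seed = NULL) {
  assert_instance_map(mask)
  if (!is.null(seed)) set.seed(seed)
  fg <- mask > 0
  img <- matrix(params$bg_mean, nrow(mask), ncol(mask))
  img[fg] <- params$fg_mean
  if (params$texture_amplitude > 0 && any(fg)) {
    tex <- matrix(stats::runif(length(mask), -0.5, 0.5),
                  nrow(mask), ncol(mask))
    tex <- gauss_blur(tex, 2)
    img[fg] <- img[fg] + params$texture_amplitude * tex[fg]
  }
  if (params$blur_sigma > 0) img <- gauss_blur(img, params$blur_sigma)
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                        nrow(img), ncol(img))
  pmin(pmax(img, 0), 1)
}

# Gaussian blur with replicated borders (avoids wrap-around leakage).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(3, 2 * ceiling(3 * sigma) + 1)
  if (r %% 2 == 0) r <- r + 1
  # pad by replication so the EBImage circular boundary never mixes edges
  p <- (r - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  big <- m[c(rep(1, p), 1:nr, rep(nr, p)), c(rep(1, p), 1:nc, rep(nc, p))]
  sm <- EBImage::gblur(big, sigma = sigma, radius = r)
  matrix(as.numeric(sm), nrow(big), ncol(big))[p + (1:nr), p + (1:nc)]
}

#' Simulate semantic-network probability maps from an instance map
#'
#' One-hot encodes the three-class representation of the mask, smooths each
#' channel with a Gaussian of sigma `softness`, adds clipped Gaussian noise,
#' and renormalizes per pixel to sum 1. With `softness = 0` and
#' `noise_sd = 0` this is the exact one-hot encoding.
#'
#' @param mask instance matrix.
#' @param contour_width,touching_dilation_radius passed to
#'   [encode_three_class()].
#' @param softness smoothing sigma in pixels.
#' @param noise_sd Gaussian perturbation sd (clipped to keep channels in
#'   [0, 1]).
#' @param seed integer seed.
#' @return a `prob_maps` object.
#' @export
probabilities_from_instances <- function(mask, contour_width = 1L,
                                         touching_dilation_radius = 1L,
                                         softness = 0.5, noise_sd = 0,
                                         seed = NULL) {
  assert_instance_map(mask)
  if (!is.null(seed)) set.seed(seed)
  cls <- encode_three_class(mask, contour_width, touching_dilation_radius)
  ch <- lapply(c(CLASS_INNER, CLASS_CONTOUR, CLASS_BACKGROUND), function(k) {
    x <- matrix(as.numeric(cls == k), nrow(cls), ncol(cls))
    if (softness > 0) x <- gauss_blur(x, softness)
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
    pmin(pmax(x, 0), 1)
  })
  tot <- ch[[1]] + ch[[2]] + ch[[3]]
  dead <- tot <= 0
  if (any(dead)) { ch[[3]][dead] <- 1; tot[dead] <- 1 }
  probability_maps(ch[[1]] / tot, ch[[2]] / tot, ch[[3]] / tot)
}

#' Corruption parameters for simulated instance predictions
#'
#' @param p_drop probability each nucleus is missed entirely.
#' @param p_merge probability an 8-adjacent nucleus pair is merged.
#' @param p_split probability a nucleus is split along a random chord.
#' @param boundary_jitter maximum boundary dilation/erosion in pixels.
#' @return named list of validated parameters.
#' @export
corruption_params <- function(p_drop = 0, p_merge = 0, p_split = 0,
                              boundary_jitter = 0L) {
  stopifnot(p_drop >= 0, p_drop <= 1, p_merge >= 0, p_merge <= 1,
            p_split >= 0, p_split <= 1, boundary_jitter >= 0)
  list(p_drop = p_drop, p_merge = p_merge, p_split = p_split,
       boundary_jitter = as.integer(boundary_jitter))
}

#' Corrupt an instance map with controlled error modes
#'
#' Applies, in order: independent nucleus drops (probability `p_drop`),
#' merges of randomly chosen 8-adjacent pairs (`p_merge`), splits along a
#' random chord through the centroid (`p_split`), and per-nucleus boundary
#' jitter by chebyshev dilation into free background or erosion of up to
#' `boundary_jitter` pixels. Jitter never removes or disconnects a nucleus:
#' an erosion that would empty or split its target is skipped, and dilation
#' never invades neighbouring nuclei, so nucleus count is preserved by
#' jitter alone. Deterministic given the seed.
#'
#' @param mask instance matrix.
#' @param params list from [corruption_params()].
#' @param seed integer seed.
#' @return corrupted integer instance matrix with normalized ids.
#' @export
corrupt_instances <- function(mask, params = corruption_params(),
                              seed = NULL) {
  assert_instance_map(mask)
  if (!is.null(seed)) set.seed(seed)
  lab <- normalize_ids(mask)
  nr <- nrow(lab); nc <- ncol(lab)

  # drop
  ids <- sort(unique(lab[lab > 0]))
  if (params$p_drop > 0 && length(ids)) {
    kill <- ids[stats::runif(length(ids)) < params$p_drop]
    if (length(kill)) lab[lab %in% kill] <- 0L
  }

  # merge 8-adjacent pairs
  if (params$p_merge > 0) {
    prs <- adjacent_pairs(lab)
    if (nrow(prs)) {
      prs <- prs[sample(nrow(prs)), , drop = FALSE]
      for (i in seq_len(nrow(prs))) {
        a <- prs[i, 1]; b <- prs[i, 2]
        if (stats::runif(1) < params$p_merge && any(lab == a) && any(lab == b))
          lab[lab == b] <- a
      }
    }
  }

  # split along a random chord through the centroid
  ids <- sort(unique(lab[lab > 0]))
  if (params$p_split > 0 && length(ids)) {
    nxt <- max(ids)
    for (id in ids) {
      if (stats::runif(1) >= params$p_split) next
      px <- which(lab == id)
      rr <- ((px - 1L) %% nr) + 1L
      cc <- ((px - 1L) %/% nr) + 1L
      phi <- stats::runif(1, 0, pi)
      side <- (rr - mean(rr)) * cos(phi) + (cc - mean(cc)) * sin(phi) > 0
      if (any(side) && any(!side)) {
        nxt <- nxt + 1L
        lab[px[side]] <- nxt
      }
    }
  }

  # boundary jitter
  if (params$boundary_jitter > 0) {
    ids <- sort(unique(lab[lab > 0]))
    for (id in ids) {
      j <- sample(-params$boundary_jitter:params$boundary_jitter, 1)
      if (j == 0) next
      m_id <- lab == id
      if (j > 0) {
        grown <- dilate_box(m_id, j)
        lab[grown & lab == 0] <- id        # only into free background
      } else {
        shrunk <- m_id & !dilate_box(!m_id, -j)  # erosion
        comp <- label_components(shrunk)
        if (max(comp) == 1) {              # keep nuclei intact: no empty/split
          lab[m_id] <- 0L
          lab[shrunk] <- id
        }
      }
    }
  }
  normalize_ids(lab)
}

# Unordered pairs of distinct positive ids with 8-adjacent pixels.
adjacent_pairs <- function(lab) {
  prs <- NULL
  for (i in seq_len(nrow(.nb8))) {
    nb <- shift_mat(lab, .nb8[i, 1], .nb8[i, 2], fill = 0)
    sel <- lab > 0 & nb > 0 & nb != lab
    if (any(sel)) prs <- rbind(prs, cbind(pmin(lab[sel], nb[sel]),
                                          pmax(lab[sel], nb[sel])))
  }
  if (is.null(prs)) return(matrix(integer(0), 0, 2))
  unique(prs)
}
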
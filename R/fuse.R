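# Fusion of an instance-segmentation result with a semantic-derived one.
#
# The fused map starts from the instance-network nuclei. Nuclei whose overlap
# with the semantic foreground is below 20% are treated as hallucinations and
# discarded; semantic nuclei whose overlap with the instance foreground is
# below 33% are added as new nuclei; finally nuclei under 35 px are removed.

#' Fusion parameters
#'
#' @param keep_overlap_min an instance nucleus is kept iff the fraction of
#'   its area overlapping the semantic foreground is >= this value
#'   (default 0.20; discarding is strict `<`).
#' @param add_overlap_max a semantic nucleus is added iff the fraction of its
#'   area overlapping the instance foreground is strictly < this value
#'   (default 0.33).
#' @param min_area fused nuclei smaller than this are dropped (default 35).
#' @return named list of validated parameters.
#' @export
fusion_params <- function(keep_overlap_min = 0.20,
                          add_overlap_max = 0.33,
                          min_area = 35L) {
  stopifnot(keep_overlap_min >= 0, keep_overlap_min <= 1,
            add_overlap_max >= 0, add_overlap_max <= 1,
            min_area >= 0)
  list(keep_overlap_min = keep_overlap_min,
       add_overlap_max = add_overlap_max,
       min_area = as.integer(min_area))
}

#' Fraction of a nucleus overlapping another map's foreground
#'
#' @param nucleus_pixels integer vector of (column-major) pixel indices of
#'   one nucleus, or a logical matrix.
#' @param other instance matrix whose foreground (any id > 0) is tested.
#' @return fraction in [0, 1].
#' @export
overlap_fraction <- function(nucleus_pixels, other) {
  assert_instance_map(other)
  if (is.matrix(nucleus_pixels)) nucleus_pixels <- which(nucleus_pixels > 0)
  if (length(nucleus_pixels) == 0)
    stop("empty nucleus pixel set", call. = FALSE)
  sum(other[nucleus_pixels] > 0) / length(nucleus_pixels)
}

#' Fuse instance and semantic segmentations
#'
#' Keeps instance nuclei supported by the semantic foreground (overlap >=
#' `keep_overlap_min` of the nucleus area), adds semantic nuclei largely
#' unexplained by the instance foreground (overlap < `add_overlap_max`),
#' clipping added nuclei to pixels not occupied by kept nuclei, then removes
#' nuclei under `min_area` and renumbers ids. Overlap fractions are always
#' relative to the area of the nucleus being tested and use the other map's
#' full foreground.
#'
#' @param instance_seg instance matrix from the instance network.
#' @param semantic_seg instance matrix derived from the semantic network
#'   (e.g. [instances_from_probabilities()]).
#' @param params list from [fusion_params()].
#' @return fused integer instance matrix.
#' @export
fuse_instances <- function(instance_seg, semantic_seg,
                           params = fusion_params()) {
  assert_instance_map(instance_seg)
  assert_instance_map(semantic_seg)
  assert_same_shape(instance_seg, semantic_seg)

  out <- matrix(0L, nrow(instance_seg), ncol(instance_seg))
  nxt <- 0L

  # keep rule: instance nuclei with enough semantic support
  for (id in sort(unique(instance_seg[instance_seg > 0]))) {
    px <- which(instance_seg == id)
    if (overlap_fraction(px, semantic_seg) >= params$keep_overlap_min) {
      nxt <- nxt + 1L
      out[px] <- nxt
    }
  }

  # add rule: semantic nuclei mostly outside the instance foreground,
  # clipped against already-kept nuclei
  for (id in sort(unique(semantic_seg[semantic_seg > 0]))) {
    px <- which(semantic_seg == id)
    if (overlap_fraction(px, instance_seg) < params$add_overlap_max) {
      px <- px[out[px] == 0]
      if (length(px)) {
        nxt <- nxt + 1L
        out[px] <- nxt
      }
    }
  }

  out <- drop_small(out, params$min_area)
  normalize_ids(out)
}
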
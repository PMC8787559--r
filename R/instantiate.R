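# Semantic-to-instance post-processing: probability maps -> instance map.
#
# Pipeline (mirrors the classical seeded-tessellation macro):
#   1. seeds: 8-connected components of (p_inner - p_contour > seed_threshold)
#   2. Voronoi assignment of every pixel to its nearest seed component
#   3. restriction to the object mask (p_background < background_threshold)
#   4. repair of unassigned object pixels by iterative adjacency voting
#   5. removal of nuclei smaller than min_area, id renumbering

#' Post-processing parameters
#'
#' @param seed_threshold strict threshold on p_inner - p_contour defining
#'   seeds (default 0.35).
#' @param background_threshold object pixels have p_background strictly below
#'   this value (default 0.95).
#' @param min_area nuclei smaller than this many pixels are removed
#'   (default 35).
#' @param gap_dilation_radius number of 1-pixel adjacency-voting passes used
#'   to attach unassigned object pixels to a neighbouring nucleus (default 1).
#' @return a named list of validated parameters.
#' @export
postprocess_params <- function(seed_threshold = 0.35,
                               background_threshold = 0.95,
                               min_area = 35L,
                               gap_dilation_radius = 1L) {
  stopifnot(seed_threshold > 0, seed_threshold < 1,
            background_threshold > 0, background_threshold < 1,
            min_area >= 0, gap_dilation_radius >= 0)
  list(seed_threshold = seed_threshold,
       background_threshold = background_threshold,
       min_area = as.integer(min_area),
       gap_dilation_radius = as.integer(gap_dilation_radius))
}

#' Seed components from probability maps
#'
#' Labels the 8-connected components of the pixel set where the contour
#' channel subtracted from the inner channel strictly exceeds
#' `seed_threshold`. Each component seeds one nucleus.
#'
#' @param probs a `prob_maps` object.
#' @param seed_threshold strict threshold on p_inner - p_contour.
#' @return integer instance matrix of seed components (possibly empty).
#' @export
seeds_from_probabilities <- function(probs, seed_threshold = 0.35) {
  diff <- p_channel(probs, "inner") - p_channel(probs, "contour")
  label_components(diff > seed_threshold)
}

#' Object mask from the background channel
#'
#' @param probs a `prob_maps` object.
#' @param background_threshold pixels with p_background strictly below this
#'   value belong to the object (nuclei) mask.
#' @return logical matrix.
#' @export
object_mask <- function(probs, background_threshold = 0.95) {
  p_channel(probs, "background") < background_threshold
}

#' Assign every pixel to its nearest seed component
#'
#' Discrete Voronoi tessellation generated by the seed components: each pixel
#' receives the id of the component whose pixel set is nearest in Euclidean
#' distance. Seed pixels keep their id (distance zero). Pixels exactly
#' equidistant between two components take the smaller id, decided on exact
#' squared integer distances so the tie-break is deterministic.
#'
#' @param seeds integer instance matrix of seed components.
#' @return integer instance matrix covering the whole image.
#' @export
voronoi_assign <- function(seeds) {
  assert_instance_map(seeds)
  ids <- sort(unique(seeds[seeds > 0]))
  if (length(ids) == 0) stop("no seeds", call. = FALSE)
  nr <- nrow(seeds); nc <- ncol(seeds)
  best_d2 <- matrix(Inf, nr, nc)
  assign <- matrix(0L, nr, nc)
  for (id in ids) {
    # exact Euclidean distance to this component via the distance transform
    # of its complement; squared distances are integers, so rounding makes
    # the comparison (and the smaller-id tie-break) exact
    d <- EBImage::distmap(matrix(as.numeric(seeds != id), nr, nc),
                          metric = "euclidean")
    d2 <- round(as.numeric(d)^2)
    upd <- d2 < best_d2          # strict: ties keep the earlier (smaller) id
    best_d2[upd] <- d2[upd]
    assign[upd] <- id
  }
  assign
}

#' Reconstruct an instance map from class-probability maps
#'
#' Runs the full semantic-to-instance pipeline: seed extraction, Voronoi
#' assignment, restriction to the object mask, adjacency-voting repair of the
#' thin unassigned bands between nuclei, minimum-area filtering, and id
#' renumbering. Returns an all-zero map when no seed survives.
#'
#' @param probs a `prob_maps` object.
#' @param params list from [postprocess_params()].
#' @return integer instance matrix.
#' @export
#' @examples
#' m <- matrix(0L, 16, 16); m[3:11, 3:11] <- 1L
#' pr <- probabilities_from_instances(m, softness = 0, noise_sd = 0)
#' n_instances(instances_from_probabilities(pr))
instances_from_probabilities <- function(probs, params = postprocess_params()) {
  seeds <- seeds_from_probabilities(probs, params$seed_threshold)
  if (max(seeds) == 0)
    return(matrix(0L, dim(probs)[1], dim(probs)[2]))
  lab <- voronoi_assign(seeds)
  obj <- object_mask(probs, params$background_threshold)
  lab[!obj] <- 0L
  lab <- repair_gaps(lab, obj, params$gap_dilation_radius)
  # masking can break a Voronoi cell into disconnected fragments; nuclei are
  # connected regions, so split components before the area filter judges them
  lab <- normalize_ids(lab)
  lab <- drop_small(lab, params$min_area)
  renumber_raster(lab)
}

# Attach unassigned object pixels (id 0 inside the object mask) to an
# adjacent nucleus: up to `radius` passes, each assigning every unlabeled
# object pixel the modal id among its labeled 8-neighbours (ties -> smaller
# id). Pixels with no labeled neighbour wait for a later pass.
repair_gaps <- function(lab, obj, radius) {
  if (radius <= 0) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  for (pass in seq_len(radius)) {
    todo <- which(obj & lab == 0)
    if (length(todo) == 0) break
    rr <- ((todo - 1) %% nr) + 1
    cc <- ((todo - 1) %/% nr) + 1
    votes <- matrix(0L, length(todo), nrow(.nb8))
    for (i in seq_len(nrow(.nb8))) {
      r2 <- rr + .nb8[i, 1]; c2 <- cc + .nb8[i, 2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      votes[ok, i] <- lab[cbind(r2[ok], c2[ok])]
    }
    new_id <- apply(votes, 1, function(v) {
      v <- v[v > 0]
      if (length(v) == 0) return(0L)
      which.max(tabulate(v))  # first maximum = smaller id on ties
    })
    lab[todo] <- new_id
  }
  lab
}
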
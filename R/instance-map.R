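# ---- internal grid helpers -------------------------------------------------
#
# Instance maps are plain integer matrices: 0 = background, each positive id
# one 8-connected nucleus. Images use a top-left origin; matrix row = image
# row, matrix column = image column. "Raster order" means row-major scanning.

#' Shift a matrix by (dr, dc), filling vacated cells
#'
#' @param m matrix.
#' @param dr,dc integer shift along rows / columns (positive = down / right).
#' @param fill value for cells shifted in from outside the image.
#' @return matrix of the same shape.
#' @keywords internal
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbourhood offsets (chebyshev radius 1)
.nb8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Windowed min/max of a matrix over a (2w+1)^2 box, out-of-image cells
# treated as `fill`. Implemented as w iterations of the 3x3 window.
window_extreme <- function(m, w, which = c("min", "max"), fill = 0) {
  which <- match.arg(which)
  f <- if (which == "min") pmin else pmax
  out <- m
  for (k in seq_len(w)) {
    acc <- out
    for (i in seq_len(nrow(.nb8)))
      acc <- f(acc, shift_mat(out, .nb8[i, 1], .nb8[i, 2], fill = fill))
    out <- acc
  }
  out
}

# Chebyshev binary dilation by radius r (logical matrix in/out).
dilate_box <- function(mask, r) {
  if (r <= 0) return(mask)
  window_extreme(mask * 1L, r, "max", fill = 0L) > 0L
}

assert_instance_map <- function(m, arg = deparse(substitute(m))) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop(sprintf("`%s` must contain non-negative integer labels", arg),
         call. = FALSE)
  invisible(TRUE)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Label 8-connected components of a binary mask
#'
#' Components are numbered 1..K in raster order (row-major) of their first
#' pixel. Connectivity is 8-connected throughout the package.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of component labels, 0 for background.
#' @export
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
#' label_components(m)  # diagonal touch -> one component
label_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  # seed every foreground pixel with its own index, then propagate the
  # minimum over the 8-neighbourhood to a fixed point
  lab[mask] <- which(mask)
  big <- nr * nc + 1L
  cur <- ifelse(mask, lab, big)
  repeat {
    nxt <- window_extreme(cur, 1L, "min", fill = big)
    nxt[!mask] <- big
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  lab[mask] <- cur[mask]
  renumber_raster(lab)
}

# Relabel positive ids to 1..K in raster (row-major) first-appearance order.
renumber_raster <- function(lab) {
  v <- as.vector(t(lab))        # row-major scan
  pos <- v[v > 0]
  if (length(pos) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  first <- unique(pos)
  new <- integer(max(first))
  new[first] <- seq_along(first)
  out <- lab
  out[lab > 0] <- new[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Normalize instance ids
#'
#' Splits any id that occupies several 8-connected components into one id per
#' component, then renumbers ids consecutively 1..K in raster order of first
#' appearance. Idempotent.
#'
#' @param instances instance label matrix.
#' @return integer instance matrix with consecutive ids.
#' @export
normalize_ids <- function(instances) {
  assert_instance_map(instances)
  ids <- sort(unique(instances[instances > 0]))
  if (length(ids) == 0) {
    out <- instances; storage.mode(out) <- "integer"
    return(out)
  }
  nr <- nrow(instances); nc <- ncol(instances)
  out <- matrix(0L, nr, nc)
  nxt <- 0L
  # label each id's own components on its bounding box; offset so ids stay
  # distinct, then renumber globally by raster order
  for (id in ids) {
    px <- which(instances == id)
    rr <- range(((px - 1L) %% nr) + 1L)
    cc <- range(((px - 1L) %/% nr) + 1L)
    sub <- instances[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    comp <- label_components(sub == id)
    sel <- which(comp > 0)
    srow <- ((sel - 1L) %% nrow(comp)) + rr[1]
    scol <- ((sel - 1L) %/% nrow(comp)) + cc[1]
    out[cbind(srow, scol)] <- comp[sel] + nxt
    nxt <- nxt + max(comp)
  }
  renumber_raster(out)
}

#' Per-id pixel areas of an instance map
#'
#' @param instances instance label matrix.
#' @return named integer vector of areas, names = ids present.
#' @export
instance_areas <- function(instances) {
  assert_instance_map(instances)
  fg <- instances[instances > 0]
  if (length(fg) == 0) return(integer(0))
  tab <- table(fg)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Number of nuclei in an instance map
#'
#' @param instances instance label matrix.
#' @return integer count of distinct positive ids.
#' @export
n_instances <- function(instances) {
  assert_instance_map(instances)
  length(unique(instances[instances > 0]))
}

# Drop ids whose area is below `min_area`, in place (no renumbering).
drop_small <- function(instances, min_area) {
  if (min_area <= 0) return(instances)
  areas <- instance_areas(instances)
  small <- as.integer(names(areas)[areas < min_area])
  if (length(small)) instances[instances %in% small] <- 0L
  instances
}
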
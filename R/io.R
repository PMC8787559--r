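# Image and configuration I/O.
#
# Label maps: single-channel 16-bit TIFF (lossless for ids <= 65535) or
# 8-bit PNG (ids <= 255). Probability maps: one 3-page TIFF (page order
# inner, contour, background) or three single-channel files; written as
# 32-bit samples, read as anything readTIFF understands including 32-bit
# float TIFFs from other tools. Image origin is top-left, row-major,
# 0-based in all docs; in R the matrix row/column indices are 1-based but
# the on-disk layout is identical.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop("unsupported image format: .", ext, " (use TIFF or PNG)",
       call. = FALSE)
}

#' Read an instance label map
#'
#' Accepts single-channel integer-valued TIFF or PNG. Float TIFFs whose
#' values are all integral are accepted with a warning and cast; genuinely
#' non-integer data is an error, as is an RGB/multi-channel image.
#'
#' @param path file path.
#' @param normalize if TRUE, apply [normalize_ids()] on read.
#' @return integer instance matrix.
#' @export
read_instance_map <- function(path, normalize = FALSE) {
  fmt <- img_format(path)
  was_float <- FALSE
  if (fmt == "tiff") {
    # as.is returns raw integer samples; float TIFFs refuse it and are read
    # plainly (readTIFF leaves float samples unscaled)
    x <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) {
                    if (grepl("floating point", conditionMessage(e))) {
                      was_float <<- TRUE
                      tiff::readTIFF(path)
                    } else stop(e)
                  })
  } else {
    x <- png::readPNG(path, info = TRUE)
    bits <- attr(x, "info")$bit.depth
    if (is.null(bits)) bits <- 8
    x <- x * (2^bits - 1)
  }
  dims <- dim(x)
  if (length(dims) == 3) {
    if (dims[3] == 1) x <- x[, , 1]
    else stop("expected a single-channel label image, got ",
              dims[3], " channels", call. = FALSE)
  }
  x <- matrix(as.numeric(x), dims[1], dims[2])   # drop reader attributes
  if (any(abs(x - round(x)) > 1e-6))
    stop("non-integer pixel values in label image: ", path, call. = FALSE)
  if (was_float)
    warning("float-valued label image with integral values; casting: ", path)
  x <- round(x)
  if (max(x) > 65535)
    stop("label id overflow (> 65535) in ", path, call. = FALSE)
  storage.mode(x) <- "integer"
  if (normalize) normalize_ids(x) else x
}

#' Write an instance label map
#'
#' 16-bit single-channel TIFF, or 8-bit PNG for ids up to 255.
#'
#' @param instances integer instance matrix (ids <= 65535).
#' @param path output path (.tif/.tiff/.png).
#' @return the path, invisibly.
#' @export
write_instance_map <- function(instances, path) {
  assert_instance_map(instances)
  if (max(instances) > 65535)
    stop("label id overflow: > 65535 nuclei per image unsupported",
         call. = FALSE)
  fmt <- img_format(path)
  if (fmt == "tiff") {
    tiff::writeTIFF(instances / 65535, path, bits.per.sample = 16,
                    compression = "none")
  } else {
    if (max(instances) > 255)
      stop("PNG label maps support ids up to 255; use TIFF", call. = FALSE)
    png::writePNG(instances / 255, path)
  }
  invisible(path)
}

#' Read class-probability maps
#'
#' One 3-page float TIFF or a character vector of three single-channel
#' files, channel order inner, contour, background. Validates the [0, 1]
#' range and the per-pixel sum-to-one contract.
#'
#' @param path one path (3-page TIFF) or three paths.
#' @param tol allowed deviation of per-pixel channel sums from 1.
#' @return a `prob_maps` object.
#' @export
read_probability_maps <- function(path, tol = 1e-3) {
  read_one <- function(p) {
    x <- tiff::readTIFF(p)
    if (length(dim(x)) == 3) {
      if (dim(x)[3] == 1) x <- x[, , 1]
      else stop("expected single-channel pages in ", p, call. = FALSE)
    }
    x
  }
  if (length(path) == 1) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 3)
      stop("expected a 3-page TIFF (inner, contour, background), got ",
           length(pages), " page(s) in ", path, call. = FALSE)
    ch <- lapply(pages, function(x) if (length(dim(x)) == 3) x[, , 1] else x)
  } else if (length(path) == 3) {
    ch <- lapply(path, read_one)
  } else {
    stop("provide one 3-page TIFF or exactly three files", call. = FALSE)
  }
  probability_maps(ch[[1]], ch[[2]], ch[[3]], tol = tol)
}

#' Write class-probability maps as a 3-page float TIFF
#'
#' @param probs a `prob_maps` object.
#' @param path output path (.tif/.tiff).
#' @return the path, invisibly.
#' @export
write_probability_maps <- function(probs, path) {
  validate_prob_maps(probs)
  tiff::writeTIFF(list(p_channel(probs, "inner"),
                       p_channel(probs, "contour"),
                       p_channel(probs, "background")),
                  path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

# ---- plain-text key=value configuration ------------------------------------

#' Serialize a configuration to key=value text
#'
#' @param config named list of scalar values.
#' @param path optional file to write; otherwise the lines are returned.
#' @return character vector of lines, invisibly when written to file.
#' @export
serialize_config <- function(config, path = NULL) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", format(v, digits = 15, scientific = FALSE))
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a key=value configuration
#'
#' @param path file of key=value lines ('#' comments and blank lines
#'   ignored).
#' @param template named list giving the known keys and their types;
#'   unknown keys are rejected.
#' @return named list with values coerced to the template's types.
#' @export
parse_config <- function(path, template = pipeline_config()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- template
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln, call. = FALSE)
    k <- trimws(substr(ln, 1, eq - 1))
    v <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!k %in% names(template))
      stop("unknown config key: ", k, call. = FALSE)
    proto <- template[[k]]
    out[[k]] <- if (is.numeric(proto)) as.numeric(v) else v
  }
  validate_pipeline_config(out)
  out
}
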
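# Umbrella pipeline: instantiate -> fuse -> evaluate on one image.

#' Pipeline configuration
#'
#' All tunable parameters of the instantiate / fuse / evaluate pipeline
#' plus input and output paths, as a flat named list suitable for the
#' key=value config files ([serialize_config()] / [parse_config()]).
#' Path entries left `""` are treated as absent.
#'
#' @param probs_path 3-page float TIFF of class probabilities.
#' @param instance_path instance-network label map (TIFF/PNG).
#' @param gt_path optional ground-truth label map; enables evaluation.
#' @param out_dir output directory.
#' @param seed_threshold,background_threshold,min_area,gap_dilation_radius
#'   see [postprocess_params()].
#' @param keep_overlap_min,add_overlap_max see [fusion_params()].
#' @param threshold_min,threshold_max,threshold_step IoU threshold grid.
#' @param seed master seed recorded in the run log.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(probs_path = "", instance_path = "",
                            gt_path = "", out_dir = ".",
                            seed_threshold = 0.35,
                            background_threshold = 0.95,
                            min_area = 35, gap_dilation_radius = 1,
                            keep_overlap_min = 0.20, add_overlap_max = 0.33,
                            threshold_min = 0.05, threshold_max = 0.90,
                            threshold_step = 0.05, seed = 1) {
  cfg <- list(probs_path = probs_path, instance_path = instance_path,
              gt_path = gt_path, out_dir = out_dir,
              seed_threshold = seed_threshold,
              background_threshold = background_threshold,
              min_area = min_area,
              gap_dilation_radius = gap_dilation_radius,
              keep_overlap_min = keep_overlap_min,
              add_overlap_max = add_overlap_max,
              threshold_min = threshold_min, threshold_max = threshold_max,
              threshold_step = threshold_step, seed = seed)
  class(cfg) <- c("pipeline_config", "list")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  with(cfg, {
    stopifnot(seed_threshold > 0, seed_threshold < 1,
              background_threshold > 0, background_threshold < 1,
              min_area >= 0, gap_dilation_radius >= 0,
              keep_overlap_min >= 0, keep_overlap_min <= 1,
              add_overlap_max >= 0, add_overlap_max <= 1,
              threshold_min > 0, threshold_max < 1,
              threshold_step > 0, threshold_min <= threshold_max)
  })
  invisible(TRUE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full segmentation strategy on one image
#'
#' Reads the semantic class-probability maps and the instance-network label
#' map named in the config, reconstructs instances from the probabilities,
#' fuses the two segmentations, and — when a ground-truth map is supplied —
#' writes F1-versus-IoU-threshold curves for the semantic, instance and
#' fused results. Outputs (fused label map, optional metrics CSV, run log
#' with a config hash) go to `out_dir` and are deterministic given inputs
#' and config.
#'
#' @param config list from [pipeline_config()] or [parse_config()].
#' @return invisibly, a list with the semantic, fused instance maps and
#'   (if ground truth was given) the metrics data.frame.
#' @export
run_strategy <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  probs <- stage("read_probabilities", {
    if (!nzchar(config$probs_path) || !file.exists(config$probs_path))
      stop("probability maps not found: '", config$probs_path, "'")
    read_probability_maps(config$probs_path)
  })
  inst <- stage("read_instance", {
    if (!nzchar(config$instance_path) || !file.exists(config$instance_path))
      stop("instance segmentation not found: '", config$instance_path, "'")
    read_instance_map(config$instance_path)
  })

  pp <- postprocess_params(config$seed_threshold,
                           config$background_threshold,
                           config$min_area, config$gap_dilation_radius)
  semantic <- stage("instantiate", instances_from_probabilities(probs, pp))

  fp <- fusion_params(config$keep_overlap_min, config$add_overlap_max,
                      config$min_area)
  fused <- stage("fuse", fuse_instances(inst, semantic, fp))
  write_instance_map(fused, file.path(config$out_dir, "fused.tif"))
  write_instance_map(semantic, file.path(config$out_dir, "semantic.tif"))

  metrics <- NULL
  if (nzchar(config$gt_path)) {
    gt <- stage("read_ground_truth", read_instance_map(config$gt_path))
    thr <- seq(config$threshold_min, config$threshold_max,
               by = config$threshold_step)
    metrics <- stage("evaluate", {
      res <- lapply(list(semantic = semantic, instance = inst,
                         fused = fused),
                    function(m) f1_curve(gt, m, thr))
      do.call(rbind, lapply(names(res), function(nm)
        cbind(method = nm, as.data.frame(res[[nm]]))))
    })
    write_metrics_csv(metrics, file.path(config$out_dir, "metrics.csv"))
  }

  write_run_log(config, file.path(config$out_dir, "run.log"))
  invisible(list(semantic = semantic, fused = fused, metrics = metrics))
}

# CSV with '.' decimal separator regardless of locale.
write_metrics_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 10,
                                                decimal.mark = ".",
                                                trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_run_log <- function(config, path) {
  tmp <- tempfile()
  serialize_config(unclass(config), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  ver <- tryCatch(as.character(utils::packageVersion("nucleifuse")),
                  error = function(e) "dev")
  writeLines(c(
    paste0("nucleifuse_version=", ver),
    paste0("config_md5=", hash),
    paste0("seed=", config$seed),
    serialize_config(unclass(config))
  ), path)
  invisible(path)
}
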
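# End-to-end pipeline: strides -> gait phases -> per-phase features ->
# fused stride-length estimates, plus the serializable configuration object
# that names every tunable with its default.

#' Full pipeline configuration
#'
#' Collects every tunable of the pipeline stages with its default, so a run
#' is fully described by one object. Round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param channel_map role-to-column map (see [imu_recording()]).
#' @param sdatw an [sdatw_config()].
#' @param gait a [gait_config()].
#' @param gait_mode `"four_ref"` or `"two_ref"`.
#' @param model a [model_config()].
#' @param min_iou segment-matching threshold for evaluation.
#' @param seed integer seed for all seeded stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(channel_map = DEFAULT_CHANNEL_MAP,
                            sdatw = sdatw_config(), gait = gait_config(),
                            gait_mode = c("four_ref", "two_ref"),
                            model = model_config(), min_iou = 0,
                            seed = 1L) {
  gait_mode <- match.arg(gait_mode)
  structure(list(channel_map = channel_map, sdatw = sdatw, gait = gait,
                 gait_mode = gait_mode, model = model, min_iou = min_iou,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  # named character vectors must become maps, not sequences
  plain$channel_map <- lapply(plain$channel_map, as.list)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  restore <- function(x, ctor) do.call(ctor, x[names(x) %in%
                                                 names(formals(ctor))])
  cm <- lapply(raw$channel_map, unlist)
  pipeline_config(
    channel_map = cm,
    sdatw = restore(raw$sdatw, sdatw_config),
    gait = restore(raw$gait, gait_config),
    gait_mode = raw$gait_mode,
    model = restore(raw$model, model_config),
    min_iou = raw$min_iou,
    seed = raw$seed)
}

#' Run the full gait-analysis pipeline on a recording
#'
#' Detects strides with SDATW, divides each stride into gait phases,
#' computes per-phase features, and fuses per-phase regression predictions
#' into stride-length estimates. Stages degrade gracefully: strides whose
#' phases cannot be located are carried through with partial-fusion
#' estimates where possible and reported in the diagnostics.
#'
#' @param recording an `imu_recording` (or a CSV path, loaded with the
#'   config's channel map).
#' @param template a [build_template()] result (or a JSON path).
#' @param model a [train_stride_model()] result, or `NULL` to stop after
#'   segmentation.
#' @param cfg a [pipeline_config()].
#' @param cadence_hz stride rate used for the cadence feature; `NULL`
#'   estimates it from the detected strides.
#' @return An object of class `pipeline_result`: list with `strides`
#'   (data.frame), `segmentation` (a [segment_gait()] result), `lengths`
#'   (data.frame with per-stride estimates, or `NULL`), and `config`.
#' @export
run_pipeline <- function(recording, template, model = NULL,
                         cfg = pipeline_config(), cadence_hz = NULL) {
  if (is.character(recording))
    recording <- load_recording(recording, cfg$channel_map)
  if (is.character(template)) template <- read_template(template)

  matches <- sdatw_match(recording, template, cfg$sdatw)
  strides <- matches$matches[, c("start", "end")]
  seg <- segment_gait(recording, strides, cfg$gait_mode, cfg$gait)

  lengths <- NULL
  if (!is.null(model) && nrow(strides)) {
    if (is.null(cadence_hz)) {
      dur <- (strides$end - strides$start) / recording$sample_rate_hz
      cadence_hz <- 1 / stats::median(dur)
    }
    feats <- build_feature_dataset(recording, strides, seg$phases,
                                   cadence_hz, cfg$model)
    pred <- stats::predict(model, feats)
    lengths <- cbind(strides, pred)
  }
  structure(list(strides = strides, segmentation = seg, lengths = lengths,
                 config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d strides detected, %d segmented>\n",
              nrow(x$strides),
              if (is.null(x$segmentation$boundaries)) 0L
              else nrow(x$segmentation$boundaries)))
  if (!is.null(x$lengths))
    cat(sprintf("  stride length: mean %.3f, total %.2f\n",
                mean(x$lengths$estimate, na.rm = TRUE),
                sum(x$lengths$estimate, na.rm = TRUE)))
  invisible(x)
}
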
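# ---------------------------------------------------------------------------
# Full processing chain: outer pass -> mask -> envelopes -> flatten ->
# inner pass -> unflatten -> two 2D conversions.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. The inner-fingerprint pass reuses
#' the segmentation machinery unchanged, with one addition: its search
#' region excludes a small top margin (`inner_z_margin`, full-resolution
#' voxels) so that the truncation boundary left at the volume top by
#' flattening is never mistaken for a layer edge.
#'
#' @param detection [detection_config()] for the outer pass.
#' @param inner_detection [detection_config()] for the inner pass; defaults
#'   to the outer configuration.
#' @param masking [masking_config()].
#' @param envelope [envelope_config()].
#' @param inner_z_margin Top margin (voxels) excluded from the inner search
#'   region.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            inner_detection = detection,
                            masking = masking_config(),
                            envelope = envelope_config(),
                            inner_z_margin = 16) {
  structure(list(detection = detection, inner_detection = inner_detection,
                 masking = masking, envelope = envelope,
                 inner_z_margin = as.integer(inner_z_margin)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `detection`, `inner_detection`, `masking`, `envelope`
#' (each a key-value block) and `inner_z_margin`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(vals$detection))
    args$detection <- do.call(detection_config, vals$detection)
  if (!is.null(vals$inner_detection))
    args$inner_detection <- do.call(detection_config, vals$inner_detection)
  if (!is.null(vals$masking))
    args$masking <- do.call(masking_config, vals$masking)
  if (!is.null(vals$envelope))
    args$envelope <- do.call(envelope_config, vals$envelope)
  if (!is.null(vals$inner_z_margin))
    args$inner_z_margin <- vals$inner_z_margin
  do.call(pipeline_config, args)
}

# internal: run a stage with a label so failures identify where the chain
# aborted
run_stage <- function(name, expr, log_env) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(structure(class = c(class(e)[1], "error", "condition"),
                   list(message = sprintf("[%s] %s", name,
                                          conditionMessage(e)),
                        call = NULL)))
  })
  log_env$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  res
}

#' Run the full fingerprint-extraction chain on an OCT volume
#'
#' Stages, in order: cast to uint8, intensity roll-off compensation, outer
#' surface segmentation, fingertip masking, outer upper/lower envelopes,
#' volume flattening against the outer upper envelope, inner surface
#' segmentation (mask-restricted, on the truncated volume), unflattening,
#' inner envelopes, and 3D-to-2D conversion of both fingerprints. Every
#' stage's output is retained for inspection.
#'
#' @param v The raw [oct_volume()] (float32 or uint8).
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return An object of class `pipeline_result` with fields `outer_surface`,
#'   `inner_surface`, `mask`, `outer_envelopes`, `inner_envelopes`,
#'   `flatten_record`, `outer_2d`, `inner_2d`, and `log` (configuration,
#'   per-stage timings, per-level diagnostics).
#' @export
run_pipeline <- function(v, cfg = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(v, "oct_volume"), inherits(cfg, "pipeline_config"))
  le <- new.env()
  le$timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  say("cast + roll-off compensation")
  v8 <- run_stage("cast", cast_to_uint8(v), le)
  vc <- run_stage("rolloff", rolloff_compensate(v8), le)
  say("outer segmentation")
  s_outer <- run_stage("outer_segmentation",
                       segment_fingerprint(vc, cfg$detection), le)
  say("masking")
  m <- run_stage("masking", {
    refine_mask(raw_mask(vc, s_outer, cfg$masking$w_n),
                cfg$masking$ridge_px)
  }, le)
  say("outer envelopes")
  eup_o <- run_stage("outer_upper_envelope",
                     upper_envelope(s_outer, m, cfg$envelope), le)
  elow_o <- run_stage("outer_lower_envelope",
                      lower_envelope(s_outer, eup_o, m, cfg$envelope), le)
  say("flattening")
  n_inner <- if (is.null(cfg$inner_detection$N))
    default_pyramid_depth(dim(v$data)) else cfg$inner_detection$N
  fl <- run_stage("flatten",
                  flatten_volume(vc, s_outer, eup_o, m, snap = 2^n_inner),
                  le)
  say("inner segmentation")
  inner_cfg <- cfg$inner_detection
  inner_cfg$z_min <- max(inner_cfg$z_min, cfg$inner_z_margin)
  s_inner_flat <- run_stage("inner_segmentation",
                            segment_fingerprint(fl$volume, inner_cfg, m), le)
  s_inner <- run_stage("unflatten",
                       unflatten_surface(s_inner_flat, fl$record), le)
  say("inner envelopes")
  eup_i <- run_stage("inner_upper_envelope",
                     upper_envelope(s_inner, m, cfg$envelope), le)
  elow_i <- run_stage("inner_lower_envelope",
                      lower_envelope(s_inner, eup_i, m, cfg$envelope), le)
  say("2D conversion")
  fp_o <- run_stage("outer_2d", project_2d(s_outer, eup_o, elow_o, m), le)
  fp_i <- run_stage("inner_2d", project_2d(s_inner, eup_i, elow_i, m), le)
  structure(list(
    outer_surface = s_outer, inner_surface = s_inner, mask = m,
    outer_envelopes = list(upper = eup_o, lower = elow_o),
    inner_envelopes = list(upper = eup_i, lower = elow_i),
    flatten_record = fl$record, flattened_volume = fl$volume,
    outer_2d = fp_o, inner_2d = fp_i,
    log = list(config = cfg, timings = le$timings,
               outer_levels = s_outer$log, inner_levels = s_inner_flat$log)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  d <- dim(x$mask$bits)
  ok <- x$mask$bits & !is.na(x$inner_surface$heights) &
    !is.na(x$outer_surface$heights)
  frac <- mean(x$inner_surface$heights[ok] > x$outer_surface$heights[ok])
  cat(sprintf(paste0(
    "<pipeline_result> %d x %d lateral grid\n",
    "  mask coverage: %.1f%%\n",
    "  inner below outer: %.1f%% of masked lines\n",
    "  total time: %.1f s\n"),
    d[1], d[2], 100 * mean(x$mask$bits), 100 * frac,
    sum(unlist(x$log$timings))))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Surfaces and envelopes as 16-bit TIFF heightmaps (+ JSON scale sidecars),
#' the mask as an 8-bit PNG, both 2D fingerprints as 8-bit PNGs, and the run
#' log as JSON.
#'
#' @param res A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @param to_500ppi Also write 500 ppi resampled fingerprints.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(res, dir, to_500ppi = FALSE) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_surface(res$outer_surface, fp("outer_surface.tiff"))
  write_surface(res$inner_surface, fp("inner_surface.tiff"))
  write_surface(res$outer_envelopes$upper, fp("outer_envelope_upper.tiff"))
  write_surface(res$outer_envelopes$lower, fp("outer_envelope_lower.tiff"))
  write_surface(res$inner_envelopes$upper, fp("inner_envelope_upper.tiff"))
  write_surface(res$inner_envelopes$lower, fp("inner_envelope_lower.tiff"))
  write_mask(res$mask, fp("mask.png"))
  write_image(res$outer_2d, fp("outer_fingerprint.png"))
  write_image(res$inner_2d, fp("inner_fingerprint.png"))
  if (to_500ppi) {
    write_image(resample_fingerprint(res$outer_2d),
                fp("outer_fingerprint_500ppi.png"))
    write_image(resample_fingerprint(res$inner_2d),
                fp("inner_fingerprint_500ppi.png"))
  }
  log <- res$log
  log$config <- rapply(unclass(log$config), unclass, how = "replace")
  jsonlite::write_json(log, fp("run_log.json"), auto_unbox = TRUE,
                       force = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
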
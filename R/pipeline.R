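# End-to-end orchestration: simulate (optional) -> preprocess -> align ->
# detect -> colocalize (optional) -> assign -> annotate -> quantify.
# Stages communicate via on-disk artifacts so any stage can be replayed.

#' Pipeline configuration
#'
#' Collects every stage's parameters with the package defaults. Unknown
#' keys are rejected.
#'
#' @param ... overrides for any of: `sim` (a [sim_config()]), `preprocess`
#'   (list, see [preprocess_params()]), `detection_threshold` (LoG
#'   threshold; required for detection), `coloc_radius_px` (2),
#'   `max_semi_axis` (15), `annotation_radius` (3), `class_cutoff` (1.0),
#'   `cell_cutoff` (0.5), `seed` (1).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(sim = sim_config(), preprocess = preprocess_params(),
              detection_threshold = NA_real_, coloc_radius_px = 2,
              max_semi_axis = 15, annotation_radius = 3,
              class_cutoff = 1.0, cell_cutoff = 0.5, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on a synthetic experiment
#'
#' Simulates an experiment from `config$sim`, preprocesses every stack,
#' registers each round's DAPI projection to round 0 by phase correlation
#' and corrects all channels, detects spots per (round, channel), assembles
#' the joint spot table, assigns transcripts to nuclei with the
#' geometry-weighted Gaussian mixture, annotates nuclei from the simulated
#' coordinates, and quantifies class profiles and detection calls. When
#' `out_dir` is given, stage artifacts (offset CSV, spot CSV, matrix CSV,
#' profile CSV) and a JSON run manifest are written. Re-running with an
#' identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()]; `detection_threshold` must be set.
#' @param out_dir optional artifact directory (created if needed).
#' @return list with `sim` (the simulation), `offsets` (measured drift per
#'   round), `spots` (joint detected `spot_table` in the reference frame),
#'   `assignment` (see [assign_all()]), `matrix` (annotated
#'   `cell_gene_matrix`), `profile`, `detections`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!is.finite(config$detection_threshold))
    stop("config$detection_threshold must be set (manual per experiment)")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  sim <- simulate_experiment(config$sim)
  ref_dapi <- sim$stacks[[1]]$DAPI

  offsets <- list(); all_spots <- list()
  for (r in seq_along(sim$stacks)) {
    round_stacks <- sim$stacks[[r]]
    off <- if (r == 1) list(round_id = 0L, dy = 0L, dx = 0L)
           else register_round(round_stacks$DAPI, ref_dapi)
    offsets[[r]] <- off
    corr <- negate_offset(off)
    for (ch in c("CH_647", "CH_CY3B")) {
      st <- round_stacks[[ch]]
      if (is.null(st)) next
      if (corr$dy != 0 || corr$dx != 0) st <- apply_shift(st, corr)
      # detection input: background-corrected and low-pass filtered; the
      # gamma step is a contrast enhancement for display, not part of the
      # detection chain
      st <- background_correct(st, config$preprocess$bg_sigma)
      st <- lowpass(st, config$preprocess$lowpass_sigma,
                    config$preprocess$lowpass_kernel)
      genes <- sim$gene_map$gene[sim$gene_map$round_id == st$round_id &
                                   sim$gene_map$channel_id == ch]
      if (!length(genes)) next
      dp <- detection_params(intensity_threshold = config$detection_threshold)
      sp <- detect_spots(st, dp, gene = genes[1])
      if (nrow(sp)) sp <- decompose_dense(st, sp, dp)
      all_spots[[paste(r, ch)]] <- as.data.frame(sp)
    }
  }
  offsets <- do.call(rbind, lapply(offsets, as.data.frame))
  spots_df <- do.call(rbind, all_spots)
  if (is.null(spots_df)) spots_df <- as.data.frame(spot_table())
  spots_df$spot_id <- seq_len(nrow(spots_df))
  spots <- spot_table(spots_df)

  assignment <- assign_all(spots, sim$truth$mask,
                           max_semi_axis = config$max_semi_axis,
                           worm_id = "sim_worm", sex = "male")
  mapping <- map_annotations(sim$truth$annotations, sim$truth$mask,
                             config$annotation_radius)
  matrix_ann <- attach_classes(assignment$matrix, mapping)
  profile <- class_profiles(list(matrix_ann))
  detections <- call_detections(profile, list(matrix_ann),
                                config$class_cutoff, config$cell_cutoff)
  manifest <- list(package = "wormfish",
                   version = as.character(utils::packageVersion("wormfish")),
                   seed = config$sim$seed,
                   detection_threshold = config$detection_threshold,
                   n_rounds = length(sim$stacks),
                   n_spots = nrow(spots),
                   n_nuclei = max(0, nrow(sim$truth$nuclei)))

  if (!is.null(out_dir)) {
    utils::write.csv(offsets, file.path(out_dir, "offsets.csv"),
                     row.names = FALSE)
    write_spot_table(spots, file.path(out_dir, "spots.csv"))
    write_matrix(matrix_ann, file.path(out_dir, "cell_gene_matrix.csv"),
                 mtx = TRUE)
    utils::write.csv(profile, file.path(out_dir, "class_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(detections$calls, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(sim = sim, offsets = offsets, spots = spots, assignment = assignment,
       matrix = matrix_ann, profile = profile, detections = detections,
       manifest = manifest)
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]; the `sim` block is passed to
#' [sim_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}
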
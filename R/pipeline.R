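#' Pipeline configuration
#'
#' All tunable parameters of the feature-extraction pipeline with their
#' defaults. Most users only change the ROI sizing when working at
#' non-clinical resolutions, and the seed.
#'
#' @param correlation_threshold valid-frame B-mode correlation threshold.
#' @param margin_factor,min_side,max_side ROI sizing (see [square_roi()]).
#' @param smooth_window_s TIC moving-average window (s).
#' @param rate_denominator wash-in-rate convention
#'   (see [tic_parameters()]).
#' @param ring_r_in_mm,ring_r_out_mm ring-kernel radii (mm).
#' @param similarity_window_s arterial-phase similarity window (s).
#' @param regularize_iterations speckle-regularization iterations.
#' @param texture_window,texture_stride,gray_levels moving-window texture
#'   settings.
#' @param prune_threshold correlation-pruning threshold.
#' @param var_explained PCA explained-variance target of
#'   [adaptive_select()].
#' @param seed seed for the filtering stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(correlation_threshold = 0.8,
                            margin_factor = 2, min_side = 200,
                            max_side = 278, smooth_window_s = 5,
                            rate_denominator = "wash_in_time",
                            ring_r_in_mm = 1, ring_r_out_mm = 2.5,
                            similarity_window_s = 20,
                            regularize_iterations = 10,
                            texture_window = 21, texture_stride = 3,
                            gray_levels = 64, prune_threshold = 0.9,
                            var_explained = 0.95, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Full 137-map stack for one lesion
#'
#' Runs the complete per-lesion processing chain: linearization, square
#' ROI, valid-frame filtering, fiducial frame selection, the 5 perfusion
#' maps, the 3 ring-kernel similarity maps, and the 129 moving-window
#' texture maps at the three fiducial frames.
#'
#' @param cine a `ceus_cine` (gray levels or already linearized).
#' @param annotation a `lesion_annotation`.
#' @param config a [pipeline_config()].
#' @return a `map_stack` of 137 maps; the `analysis_roi` and
#'   `fiducial_frames` are attached as attributes `roi` and `fiducials`.
#' @export
lesion_map_stack <- function(cine, annotation,
                             config = pipeline_config()) {
  validate_annotation(annotation, cine)
  if (!cine$linearized) cine <- linearize(cine)
  roi <- square_roi(annotation, config$margin_factor, config$min_side,
                    config$max_side)
  valid <- valid_frames(cine, roi, annotation$ref_frame,
                        config$correlation_threshold)
  ref_mask <- annotation$masks[[as.character(annotation$ref_frame)]]
  tic <- mean_tic(cine, ref_mask)
  fid <- fiducial_frames(cine, roi, annotation$ref_frame, valid,
                         tic_mean = tic,
                         smooth_window_s = config$smooth_window_s)
  perf <- perfusion_map_stack(cine, roi, config$smooth_window_s,
                              config$rate_denominator)
  kernel <- build_ring_kernel(cine$spacing_mm[1], config$ring_r_in_mm,
                              config$ring_r_out_mm)
  sim <- similarity_map_stack(
    cine, roi, appearance_time = cine$times[fid$appearance_idx],
    window_s = config$similarity_window_s, kernel = kernel,
    regularize_iterations = config$regularize_iterations
  )
  tex <- texture_at_fiducials(cine, roi, fid, config$texture_window,
                              config$texture_stride, config$gray_levels)
  out <- c(perf, sim, tex)
  attr(out, "roi") <- roi
  attr(out, "fiducials") <- fid
  out
}

#' Extract the radiomic feature table for a set of lesions
#'
#' Applies [lesion_map_stack()] and the summary statistics to every
#' lesion and assembles the 411-column feature table. Lesions whose
#' processing fails are skipped and listed in the exclusion manifest
#' (`attr(, "exclusions")`).
#'
#' @param lesions list of lesions, each a list with elements `cine`,
#'   `annotation` (e.g. from [simulate_cohort()]).
#' @param config a [pipeline_config()].
#' @param keep_maps when `TRUE`, the per-lesion map stacks are attached
#'   as `attr(, "map_stacks")`.
#' @return a `feature_table` (411 columns).
#' @export
extract_features <- function(lesions, config = pipeline_config(),
                             keep_maps = FALSE) {
  stacks <- list()
  labels <- character(0)
  exclusions <- data.frame(lesion = integer(0), error = character(0))
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    res <- tryCatch(
      lesion_map_stack(les$cine, les$annotation, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("lesion %d skipped: %s", i, conditionMessage(res)))
      exclusions <- rbind(exclusions,
                          data.frame(lesion = i,
                                     error = conditionMessage(res)))
      next
    }
    stacks[[length(stacks) + 1]] <- res
    labels <- c(labels, les$annotation$label)
  }
  if (length(stacks) == 0) stop("no lesion could be processed")
  ft <- build_feature_table(stacks, labels)
  attr(ft, "exclusions") <- exclusions
  if (keep_maps) attr(ft, "map_stacks") <- stacks
  ft
}

#' Two-stage feature filtering
#'
#' Correlation pruning followed by adaptive per-set univariate selection,
#' applied once to the full table (pooled mode; for leak-free
#' in-fold filtering see [cv_config()]'s `filter_in_folds`). Note that
#' fitting the filter on the full dataset lets label information reach
#' the filter before cross validation.
#'
#' @param ft a `feature_table`.
#' @param config a [pipeline_config()].
#' @return the filtered `feature_table`.
#' @export
filter_features <- function(ft, config = pipeline_config()) {
  message("feature filtering (pooled mode): fit on the full table")
  adaptive_select(correlation_prune(ft, config$prune_threshold),
                  config$var_explained, seed = config$seed)
}

#' Serialize a map stack to CSV (long format)
#'
#' @param stack a `map_stack`.
#' @param path output CSV path (`map, row, col, value`).
#' @return `path`, invisibly.
#' @export
write_map_stack <- function(stack, path) {
  d <- dim(stack[[1]])
  long <- do.call(rbind, lapply(names(stack), function(nm) {
    data.frame(map = nm,
               row = rep(seq_len(d[1]), d[2]),
               col = rep(seq_len(d[2]), each = d[1]),
               value = as.vector(stack[[nm]]))
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' End-to-end run on a simulated cohort
#'
#' Simulate -> extract -> filter -> bench -> report: generates a labelled
#' synthetic cohort, extracts the 411 features, applies the two-stage
#' filtering, runs the repeated nested CV bench, and writes the report
#' (feature CSV, metrics table, permutation importances, t-test matrix,
#' resolved configuration) to a directory.
#'
#' @param out_dir output directory.
#' @param n_lesions cohort size.
#' @param sim a [sim_config()].
#' @param pipeline a [pipeline_config()].
#' @param cv a [cv_config()].
#' @param malignant_fraction cohort class balance
#'   (see [simulate_cohort()]); note the bench's SMOTE stage needs at
#'   least 6 minority-class lesions in every training split.
#' @return the `cv_report`, invisibly; outputs on disk.
#' @export
run_all <- function(out_dir, n_lesions = 60, sim = sim_config(),
                    pipeline = pipeline_config(), cv = cv_config(),
                    malignant_fraction = 74 / 87) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  message("stage 1/4: simulating ", n_lesions, " lesions")
  cohort <- simulate_cohort(n_lesions, sim, malignant_fraction)
  message("stage 2/4: extracting features")
  ft <- extract_features(cohort, pipeline)
  write_feature_table(ft, file.path(out_dir, "features.csv"))
  message("stage 3/4: feature filtering")
  ftf <- if (cv$filter_in_folds) ft else filter_features(ft, pipeline)
  message("stage 4/4: classification bench")
  report <- nested_cv(ftf, config = cv)
  m <- report$metrics$mean
  s <- report$metrics$sd
  tab <- data.frame(model = rownames(m))
  for (met in colnames(m)) {
    tab[[met]] <- sprintf("%.2f(%.2f)", m[, met], s[, met])
  }
  write.csv(tab, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(report$pfi, file.path(out_dir, "pfi.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.csv(report$t_tests, file.path(out_dir, "t_tests.csv"),
            row.names = FALSE)
  yaml::write_yaml(
    list(sim = unclass(sim), pipeline = unclass(pipeline),
         cv = unclass(cv), n_lesions = n_lesions),
    file.path(out_dir, "config.yaml")
  )
  message(sprintf("run_all finished in %.1f min",
                  as.numeric(difftime(Sys.time(), t0, units = "mins"))))
  invisible(report)
}
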
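# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small clean simulated lesion (no motion) used across modules
small_sim_clean <- function() {
  memo("sim_clean", function() {
    cfg <- sim_config(
      n_frames = 70, frame_rate = 1, height = 72, width = 72,
      spacing_mm = 0.3, lesion_center = c(36, 36), lesion_radius_px = 12,
      speckle = list(enabled = FALSE, shape = 4, blur_px = 1.5),
      motion = list(enabled = FALSE, shift_sd_px = 1, dropout_prob = 0),
      seed = 11
    )
    generate_cine(cfg)
  })
}

# same geometry with speckle + motion and forced dropout frames
small_sim_noisy <- function() {
  memo("sim_noisy", function() {
    cfg <- sim_config(
      n_frames = 70, frame_rate = 1, height = 72, width = 72,
      spacing_mm = 0.3, lesion_center = c(36, 36), lesion_radius_px = 12,
      motion = list(enabled = TRUE, shift_sd_px = 1, dropout_prob = 0.07),
      seed = 13
    )
    generate_cine(cfg)
  })
}

test_pipeline_config <- function(...) {
  pipeline_config(min_side = 44, max_side = 52, ...)
}

# a uniform cine in which every pixel shares one known TIC (gray levels)
uniform_cine <- function(tic_power, h = 24, w = 24, spacing_mm = 0.3,
                         dr = 60, gmax = 255) {
  nt <- length(tic_power)
  ceus <- array(rep(log_compress(tic_power, gmax, dr), each = h * w),
                dim = c(h, w, nt))
  set.seed(4)
  bscene <- matrix(runif(h * w, 0.2, 0.8), h, w)
  bmode <- array(rep(round(bscene * gmax), nt), dim = c(h, w, nt))
  ceus_cine(bmode = bmode, ceus = ceus, times = seq_len(nt) - 1,
            spacing_mm = spacing_mm, dynamic_range_db = dr,
            gray_max = gmax)
}

disk_mask <- function(h, w, center, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# the bench-scale labelled cohort and its extracted feature table,
# memoized because several acceptance properties reuse it
bench_cohort_table <- function() {
  memo("bench_ft", function() {
    cfg <- sim_config(n_frames = 70, frame_rate = 1, height = 80,
                      width = 80, spacing_mm = 0.3, lesion_radius_px = 12,
                      seed = 101)
    cohort <- simulate_cohort(60, cfg)
    # individual lesions may be skipped (frame-selection failures under
    # motion); the bench works on the survivors
    suppressWarnings(
      extract_features(cohort, pipeline_config(min_side = 48,
                                               max_side = 56))
    )
  })
}
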
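#' Log-normal bolus time-intensity curve with portal-phase plateau
#'
#' Forward kinetic model used by the cine simulator: an indicator-dilution
#' bolus shaped as a log-normal transit-time distribution (zero before the
#' onset `t0`, peak value `A` at `t0 + exp(mu - sigma^2)`), plus an
#' optional delayed sigmoid plateau emulating the portal-venous inflow
#' that overlaps the late arterial phase. The pipeline itself never fits
#' this model; it only provides ground truth for validation.
#'
#' @param t numeric vector of times (s).
#' @param A bolus peak amplitude (relative echo power).
#' @param t0 bolus onset time (s).
#' @param mu,sigma log-normal shape parameters (`sigma > 0`).
#' @param plateau_amp portal plateau amplitude (0 disables it).
#' @param plateau_onset,plateau_tau sigmoid midpoint (s) and time scale (s).
#' @return numeric vector of noiseless intensities (relative power).
#' @export
bolus_tic <- function(t, A, t0, mu, sigma, plateau_amp = 0,
                      plateau_onset = 40, plateau_tau = 6) {
  stopifnot(sigma > 0)
  tau <- t - t0
  out <- numeric(length(t))
  pos <- tau > 0
  if (any(pos)) {
    mode <- exp(mu - sigma^2)
    peak_dens <- stats::dlnorm(mode, meanlog = mu, sdlog = sigma)
    out[pos] <- A * stats::dlnorm(tau[pos], meanlog = mu, sdlog = sigma) /
      peak_dens
    out[pos] <- out[pos] +
      plateau_amp * stats::plogis((t[pos] - plateau_onset) / plateau_tau)
  }
  out
}

#' Simulator configuration
#'
#' Defaults emulate the acquisition protocol targeted by the pipeline:
#' recordings of about 70 s covering contrast wash-in, peak enhancement and
#' the beginning of wash-out, an arterial bolus peaking around 30 s with a
#' partially overlapping portal-phase plateau from ~40 s, pixel spacing in
#' the clinical range, 60 dB log compression to 8-bit gray levels,
#' multiplicative speckle, and intermittent rigid in-plane motion with
#' occasional out-of-plane dropouts.
#'
#' @param n_frames number of frames `T`.
#' @param frame_rate frames per second; `n_frames / frame_rate` must cover
#'   at least 60 s.
#' @param height,width pane size in pixels.
#' @param spacing_mm pixel spacing (mm).
#' @param dynamic_range_db log-compression dynamic range (dB).
#' @param gray_max maximum gray level.
#' @param lesion_center,lesion_radius_px lesion disk geometry (pixels).
#' @param parenchyma,lesion kinetic parameter lists
#'   (`A`, `t0`, `mu`, `sigma`) for [bolus_tic()].
#' @param lesion_jitter per-pixel kinetic heterogeneity inside the lesion:
#'   list of standard deviations `mu_sd`, `sigma_sd`, `t0_sd` (all 0 =
#'   homogeneous).
#' @param plateau portal-phase plateau list (`amp`, `onset`, `tau`),
#'   shared by both regions.
#' @param speckle list `enabled`, `shape` (gamma shape of the
#'   multiplicative field; mean fixed at 1), `blur_px` (spatial
#'   correlation length as a Gaussian sigma in pixels).
#' @param motion list `enabled`, `shift_sd_px` (per-frame rigid shift sd),
#'   `dropout_prob` (probability that a frame is replaced by out-of-plane
#'   content).
#' @param baseline_power pre-contrast tissue echo floor (relative power).
#' @param seed integer seed; the generated cine is a deterministic
#'   function of the full configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_frames = 70, frame_rate = 1,
                       height = 300, width = 300, spacing_mm = 0.137,
                       dynamic_range_db = 60, gray_max = 255,
                       lesion_center = NULL, lesion_radius_px = 45,
                       parenchyma = list(A = 0.25, t0 = 15, mu = 3.3,
                                         sigma = 0.6),
                       lesion = list(A = 0.35, t0 = 14, mu = 3.3,
                                     sigma = 0.6),
                       lesion_jitter = list(mu_sd = 0, sigma_sd = 0,
                                            t0_sd = 0),
                       plateau = list(amp = 0.12, onset = 40, tau = 6),
                       speckle = list(enabled = TRUE, shape = 4,
                                      blur_px = 1.5),
                       motion = list(enabled = TRUE, shift_sd_px = 1,
                                     dropout_prob = 0.05),
                       baseline_power = 2e-4, seed = 1L) {
  if (is.null(lesion_center)) {
    lesion_center <- c(round(height / 2), round(width / 2))
  }
  cfg <- list(
    n_frames = as.integer(n_frames), frame_rate = frame_rate,
    height = as.integer(height), width = as.integer(width),
    spacing_mm = spacing_mm, dynamic_range_db = dynamic_range_db,
    gray_max = gray_max, lesion_center = lesion_center,
    lesion_radius_px = lesion_radius_px, parenchyma = parenchyma,
    lesion = lesion, lesion_jitter = lesion_jitter, plateau = plateau,
    speckle = speckle, motion = motion, baseline_power = baseline_power,
    seed = as.integer(seed)
  )
  if (cfg$n_frames / cfg$frame_rate < 60) {
    stop("recording must cover at least 60 s")
  }
  if (any(cfg$lesion_center - cfg$lesion_radius_px < 1) ||
      cfg$lesion_center[1] + cfg$lesion_radius_px > cfg$height ||
      cfg$lesion_center[2] + cfg$lesion_radius_px > cfg$width) {
    stop("lesion disk must lie inside the pane")
  }
  stopifnot(cfg$parenchyma$A > 0, cfg$lesion$A > 0, cfg$frame_rate > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Switch a simulator configuration to the malignant phenotype
#'
#' Simulator convention for end-to-end classification tests: malignant
#' lesions receive an earlier bolus onset, a higher peak amplitude, and
#' spatially heterogeneous kinetics (per-pixel jitter of the log-normal
#' shape and onset), while benign lesions remain kinetically homogeneous.
#' This is a testing construct, not a clinical claim.
#'
#' @param config a `sim_config`.
#' @return the modified `sim_config`.
#' @export
malignant_phenotype <- function(config) {
  config$lesion$t0 <- config$parenchyma$t0 - 5
  config$lesion$A <- 2 * config$parenchyma$A
  config$lesion_jitter <- list(mu_sd = 0.2, sigma_sd = 0.1, t0_sd = 1.5)
  config
}

# separable gaussian blur with edge replication
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  m <- mat[pad_idx(nrow(mat)), , drop = FALSE]
  m <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  m <- m[(r + 1):(r + nrow(mat)), , drop = FALSE]
  m <- m[, pad_idx(ncol(mat)), drop = FALSE]
  m <- t(apply(m, 1, function(row) stats::filter(row, k, sides = 2)))
  m[, (r + 1):(r + ncol(mat)), drop = FALSE]
}

# rigid integer shift with edge replication
shift_matrix <- function(mat, dr, dc) {
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  mat[ri, ci, drop = FALSE]
}

speckle_field <- function(h, w, shape, blur_px) {
  f <- matrix(rgamma(h * w, shape = shape, rate = shape), h, w)
  if (blur_px > 0) {
    f <- gaussian_blur(f, blur_px)
    f <- f / mean(f)
  }
  f
}

#' Generate a synthetic dual-view CEUS cine with ground truth
#'
#' Builds a side-by-side B-mode + contrast cine from a [sim_config()]:
#' per-pixel noiseless kinetic fields ([bolus_tic()]), multiplicative
#' spatially-correlated gamma speckle, rigid in-plane translations applied
#' jointly to both panes, out-of-plane dropout frames (texture replaced by
#' an independent draw; the lesion disappears from the contrast pane), and
#' log compression of the contrast pane to integer gray levels. The B-mode
#' pane is a static echo texture (lesion hypoechoic) subjected to the same
#' motion.
#'
#' @param config a `sim_config`.
#' @return a list with elements
#'   * `cine`: a gray-level `ceus_cine`;
#'   * `truth`: a list with `linear_power` (noiseless `H x W x T` kinetic
#'     field, relative power), `lesion_mask`, `tic_lesion_mean` and
#'     `tic_parenchyma` (noiseless TICs), `peak_time` / `appearance_time`
#'     of the noiseless lesion-mean TIC (appearance = first crossing of
#'     10% of peak), `dropout_frames`, and per-frame `shifts`.
#' @export
generate_cine <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  h <- config$height; w <- config$width; nt <- config$n_frames
  times <- seq(0, by = 1 / config$frame_rate, length.out = nt)

  cc <- config$lesion_center
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  lesion_mask <- (rows - cc[1])^2 + (cols - cc[2])^2 <=
    config$lesion_radius_px^2

  pl <- config$plateau
  tic_par <- bolus_tic(times, config$parenchyma$A, config$parenchyma$t0,
                       config$parenchyma$mu, config$parenchyma$sigma,
                       pl$amp, pl$onset, pl$tau)
  # noiseless kinetic field
  power <- array(rep(tic_par, each = h * w), dim = c(h, w, nt))
  jit <- config$lesion_jitter
  idx_lesion <- which(lesion_mask)
  n_les <- length(idx_lesion)
  mu_px <- config$lesion$mu + rnorm(n_les, 0, jit$mu_sd)
  sig_px <- pmax(config$lesion$sigma + rnorm(n_les, 0, jit$sigma_sd), 0.05)
  t0_px <- pmax(config$lesion$t0 + rnorm(n_les, 0, jit$t0_sd), 0)
  les_tics <- matrix(0, n_les, nt)
  for (i in seq_len(n_les)) {
    les_tics[i, ] <- bolus_tic(times, config$lesion$A, t0_px[i],
                               mu_px[i], sig_px[i], pl$amp, pl$onset,
                               pl$tau)
  }
  for (t in seq_len(nt)) {
    frame <- power[, , t]
    frame[idx_lesion] <- les_tics[, t]
    power[, , t] <- frame
  }
  power <- power + config$baseline_power

  tic_lesion_mean <- colMeans(les_tics) + config$baseline_power
  pk <- which.max(tic_lesion_mean)
  app <- which(tic_lesion_mean >= 0.1 * max(tic_lesion_mean))[1]

  # static B-mode scene: speckle texture, hypoechoic lesion
  bscene <- speckle_field(h, w, 4, 2)
  bscene[lesion_mask] <- 0.7 * bscene[lesion_mask]
  bscene <- pmin(pmax(0.45 * bscene, 0), 1)

  mo <- config$motion
  shifts <- matrix(0L, nt, 2)
  dropout <- rep(FALSE, nt)
  if (isTRUE(mo$enabled)) {
    shifts <- matrix(as.integer(round(rnorm(2 * nt, 0, mo$shift_sd_px))),
                     nt, 2)
    dropout <- runif(nt) < mo$dropout_prob
  }
  # the first frame anchors the scene: never a dropout, no shift
  shifts[1, ] <- 0L
  dropout[1] <- FALSE

  sp <- config$speckle
  bmode <- array(0, dim = c(h, w, nt))
  ceus_power <- array(0, dim = c(h, w, nt))
  for (t in seq_len(nt)) {
    if (dropout[t]) {
      # out-of-plane: independent texture, lesion absent from this plane
      bmode[, , t] <- pmin(pmax(0.45 * speckle_field(h, w, 4, 2), 0), 1)
      pf <- matrix(tic_par[t] + config$baseline_power, h, w)
    } else {
      bmode[, , t] <- shift_matrix(bscene, shifts[t, 1], shifts[t, 2])
      pf <- shift_matrix(power[, , t], shifts[t, 1], shifts[t, 2])
    }
    if (isTRUE(sp$enabled)) {
      pf <- pf * speckle_field(h, w, sp$shape, sp$blur_px)
    }
    ceus_power[, , t] <- pf
  }
  ceus_gray <- log_compress(pmin(ceus_power, 1), config$gray_max,
                            config$dynamic_range_db)
  bmode_gray <- round(bmode * config$gray_max)

  cine <- ceus_cine(
    bmode = bmode_gray, ceus = ceus_gray, times = times,
    spacing_mm = config$spacing_mm,
    dynamic_range_db = config$dynamic_range_db,
    gray_max = config$gray_max
  )
  truth <- list(
    linear_power = power, lesion_mask = lesion_mask,
    tic_lesion_mean = tic_lesion_mean, tic_parenchyma = tic_par,
    peak_time = times[pk], peak_frame = pk,
    appearance_time = times[app], appearance_frame = app,
    dropout_frames = which(dropout), shifts = shifts, times = times
  )
  list(cine = cine, truth = truth)
}

#' Build the manual-style annotation for a simulated lesion
#'
#' Uses the simulator's true lesion disk as the manual mask on the first
#' frame (pre-contrast, motion-free by construction), mirroring a
#' radiologist's delineation on a clearly visualized frame.
#'
#' @param sim output of [generate_cine()].
#' @param label lesion label to attach.
#' @return a `lesion_annotation`.
#' @export
annotation_from_sim <- function(sim, label = "unknown") {
  m <- sim$truth$lesion_mask
  lesion_annotation(stats::setNames(list(m), "1"), ref_frame = 1,
                    label = label)
}

#' Simulate a labelled cohort of lesions
#'
#' Generates `n` independent lesions from a base configuration. A fraction
#' (default matching a realistic malignancy-enriched referral cohort,
#' 74/87) receives the malignant phenotype ([malignant_phenotype()]);
#' the rest stay benign. Lesion radius and kinetic amplitudes receive
#' small lesion-level variation so that lesions are not replicas.
#'
#' @param n number of lesions.
#' @param config base `sim_config`; per-lesion seeds derive from
#'   `config$seed`.
#' @param malignant_fraction fraction of malignant lesions.
#' @return a list of lesions, each a list `cine`, `annotation`, `truth`,
#'   `label`.
#' @export
simulate_cohort <- function(n, config = sim_config(),
                            malignant_fraction = 74 / 87) {
  n_mal <- round(n * malignant_fraction)
  labels <- rep(c("malignant", "benign"), c(n_mal, n - n_mal))
  set.seed(config$seed)
  labels <- sample(labels)
  lesion_seeds <- sample.int(2^30, n)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- lesion_seeds[i]
    set.seed(lesion_seeds[i])
    cfg$lesion_radius_px <- max(8, round(config$lesion_radius_px *
                                           runif(1, 0.8, 1.2)))
    if (labels[i] == "malignant") cfg <- malignant_phenotype(cfg)
    cfg$lesion$A <- cfg$lesion$A * runif(1, 0.85, 1.15)
    cfg$lesion$t0 <- max(0, cfg$lesion$t0 + rnorm(1, 0, 1))
    sim <- generate_cine(cfg)
    list(cine = sim$cine, annotation = annotation_from_sim(sim, labels[i]),
         truth = sim$truth, label = labels[i])
  })
}
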
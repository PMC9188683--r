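#' Ring kernel of pixel offsets
#'
#' Annular neighborhood used for spatiotemporal similarity analysis: all
#' pixel displacements `d` with `r_in < ||d||_2 * spacing <= r_out`
#' (Euclidean distance between pixel centers). The default radii (1 mm
#' inner, 2.5 mm outer) bracket the avascular tumor size limit at which
#' the angiogenic switch occurs, so the kernel compares each pixel TIC
#' with tissue just beyond the smallest vascularized-lesion scale.
#'
#' @param spacing_mm pixel spacing in mm.
#' @param r_in_mm,r_out_mm inner and outer ring radii in mm
#'   (`0 <= r_in < r_out`).
#' @return a `ring_kernel`: list with `offsets` (`K x 2` integer matrix of
#'   `(dr, dc)`), the radii, and the spacing.
#' @export
build_ring_kernel <- function(spacing_mm, r_in_mm = 1, r_out_mm = 2.5) {
  if (r_in_mm < 0 || r_out_mm <= r_in_mm) {
    stop("ring radii must satisfy 0 <= r_in < r_out")
  }
  rmax <- ceiling(r_out_mm / spacing_mm)
  d <- expand.grid(dr = -rmax:rmax, dc = -rmax:rmax)
  dist_mm <- sqrt(d$dr^2 + d$dc^2) * spacing_mm
  keep <- dist_mm > r_in_mm & dist_mm <= r_out_mm
  if (!any(keep)) {
    stop("empty ring kernel: pixel spacing too coarse for the radii")
  }
  structure(
    list(offsets = as.matrix(d[keep, c("dr", "dc")]),
         r_in_mm = r_in_mm, r_out_mm = r_out_mm, spacing_mm = spacing_mm),
    class = "ring_kernel"
  )
}

#' @export
print.ring_kernel <- function(x, ...) {
  cat(sprintf("<ring_kernel> %d offsets, %.2g-%.2g mm at %.3g mm/px\n",
              nrow(x$offsets), x$r_in_mm, x$r_out_mm, x$spacing_mm))
  invisible(x)
}

#' Edge-preserving speckle regularization
#'
#' Per-frame diffusion-style smoothing (Perona-Malik, exponential
#' conductance) applied to linearized contrast frames before similarity
#' analysis. The flux formulation conserves total intensity exactly;
#' constant frames are unchanged; step edges are preserved while speckle
#' variance within homogeneous regions is reduced.
#'
#' @param frames `H x W x T` array (or a single matrix) of linearized
#'   intensities.
#' @param iterations number of diffusion iterations (default 10).
#' @param kappa conductance scale; defaults to 10% of the intensity range
#'   of the input.
#' @param lambda integration step (stability requires `<= 0.25`).
#' @return the regularized frames, same shape.
#' @export
speckle_regularize <- function(frames, iterations = 10, kappa = NULL,
                               lambda = 0.2) {
  single <- is.matrix(frames)
  if (single) frames <- array(frames, dim = c(dim(frames), 1L))
  rng <- diff(range(frames))
  if (rng == 0) {
    if (single) return(frames[, , 1]) else return(frames)
  }
  if (is.null(kappa)) kappa <- 0.1 * rng
  nt <- dim(frames)[3]
  for (t in seq_len(nt)) {
    img <- frames[, , t]
    h <- nrow(img); w <- ncol(img)
    for (it in seq_len(iterations)) {
      dn <- rbind(img[1, ], img[-h, ]) - img
      ds <- rbind(img[-1, ], img[h, ]) - img
      de <- cbind(img[, -1], img[, w]) - img
      dw <- cbind(img[, 1], img[, -w]) - img
      img <- img + lambda * (
        exp(-(dn / kappa)^2) * dn + exp(-(ds / kappa)^2) * ds +
          exp(-(de / kappa)^2) * de + exp(-(dw / kappa)^2) * dw
      )
    }
    frames[, , t] <- img
  }
  if (single) frames[, , 1] else frames
}

#' Arterial-phase analysis window
#'
#' Frame indices of the similarity analysis window: from the bolus
#' appearance time to `window_s` seconds later (default 20 s), focusing on
#' the arterial phase and avoiding the overlapping portal phase. A warning
#' is issued when the recording ends before the window does.
#'
#' @param times frame times (s).
#' @param appearance_time lesion-level bolus appearance time (s), from the
#'   lesion-mean TIC.
#' @param window_s window duration (s).
#' @return integer vector of frame indices.
#' @export
similarity_window <- function(times, appearance_time, window_s = 20) {
  idx <- which(times >= appearance_time &
                 times <= appearance_time + window_s)
  if (length(idx) == 0) stop("analysis window is empty")
  if (appearance_time + window_s > times[length(times)] + 1e-9) {
    warning("similarity window truncated by end of recording")
  }
  idx
}

# Welch spectra of a set of TICs: detrended, Hann-tapered, 50%-overlap
# segments of length floor(n/2); DC bin excluded.
# tics: n x P matrix. Returns list(re, im, sxx, nseg, nfreq).
welch_spectra <- function(tics) {
  n <- nrow(tics)
  seg_len <- floor(n / 2)
  if (seg_len < 4) stop("similarity window too short (need >= 8 samples)")
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  nfreq <- floor(seg_len / 2)          # bins 2..nfreq+1 (DC excluded)
  nseg <- length(starts)
  P <- ncol(tics)
  re <- matrix(0, nseg * nfreq, P)
  im <- matrix(0, nseg * nfreq, P)
  for (s in seq_along(starts)) {
    seg <- tics[starts[s]:(starts[s] + seg_len - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    seg <- seg * hann
    ft <- stats::mvfft(seg)[2:(nfreq + 1), , drop = FALSE]
    rows <- ((s - 1) * nfreq + 1):(s * nfreq)
    re[rows, ] <- Re(ft)
    im[rows, ] <- Im(ft)
  }
  pw <- re^2 + im^2
  sxx <- matrix(0, nfreq, P)
  for (s in seq_len(nseg)) {
    rows <- ((s - 1) * nfreq + 1):(s * nfreq)
    sxx <- sxx + pw[rows, , drop = FALSE]
  }
  list(re = re, im = im, sxx = sxx, nseg = nseg, nfreq = nfreq)
}

equal_freq_bins <- function(x, B) {
  ceiling(rank(x, ties.method = "average") * B / length(x))
}

#' Pairwise TIC similarity measures
#'
#' Similarity of two equal-length windowed TICs:
#' * `correlation`: Pearson r (time domain, linear);
#' * `coherence`: Welch magnitude-squared coherence (detrended,
#'   Hann-tapered segments of half the window length at 50% overlap),
#'   averaged over the analysis band below Nyquist, in `[0, 1]`
#'   (frequency domain, linear);
#' * `mutual_information`: plug-in estimate (nats) on equal-frequency
#'   bins with `ceiling(sqrt(n))` bins per variable (nonlinear; the
#'   estimator bias is acceptable because values are used comparatively).
#'
#' @param a,b numeric TICs of equal length `>= 8`.
#' @return named numeric vector
#'   `c(coherence, correlation, mutual_information)`; all `NA` when
#'   either TIC has zero variance.
#' @export
pairwise_similarity <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 8)
  nm <- c("coherence", "correlation", "mutual_information")
  if (sd(a) == 0 || sd(b) == 0) {
    return(setNames(rep(NA_real_, 3), nm))
  }
  correlation <- cor(a, b)
  sp <- welch_spectra(cbind(a, b))
  coh <- 0
  nb <- 0
  for (f in seq_len(sp$nfreq)) {
    sa <- sp$sxx[f, 1]; sb <- sp$sxx[f, 2]
    if (sa <= 0 || sb <= 0) next
    rows <- (seq_len(sp$nseg) - 1) * sp$nfreq + f
    sxy <- sum(complex(real = sp$re[rows, 1], imaginary = sp$im[rows, 1]) *
                 Conj(complex(real = sp$re[rows, 2],
                              imaginary = sp$im[rows, 2])))
    coh <- coh + Mod(sxy)^2 / (sa * sb)
    nb <- nb + 1
  }
  coherence <- if (nb > 0) coh / nb else NA_real_
  B <- ceiling(sqrt(n))
  ba <- equal_freq_bins(a, B)
  bb <- equal_freq_bins(b, B)
  tab <- table(factor(ba, levels = 1:B), factor(bb, levels = 1:B)) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  nzidx <- which(tab > 0, arr.ind = TRUE)
  mi <- sum(apply(nzidx, 1, function(ij) {
    p <- tab[ij[1], ij[2]]
    p * log(p / (pa[ij[1]] * pb[ij[2]]))
  }))
  setNames(c(coherence, correlation, mi), nm)
}

#' Ring-kernel spatiotemporal similarity maps
#'
#' For every pixel of the analysis ROI, averages the three pairwise
#' similarity measures ([pairwise_similarity()]) between the pixel TIC and
#' the TICs at all ring-kernel offsets inside the ROI, after speckle
#' regularization and restriction to the arterial-phase window. Pixels
#' with fewer than half of the kernel offsets inside the ROI are flagged
#' missing.
#'
#' @param cine a linearized `ceus_cine`.
#' @param roi an `analysis_roi`.
#' @param appearance_time lesion-level bolus appearance time (s), e.g.
#'   `cine$times[fiducials$appearance_idx]`.
#' @param window_s arterial analysis window (s), default 20.
#' @param kernel a `ring_kernel`; built from the cine spacing by default.
#' @param regularize_iterations diffusion iterations for
#'   [speckle_regularize()] (0 disables).
#' @return a `map_stack` with maps `Coherence`, `Correlation`,
#'   `MutualInformation`.
#' @export
similarity_map_stack <- function(cine, roi, appearance_time,
                                 window_s = 20, kernel = NULL,
                                 regularize_iterations = 10) {
  if (!cine$linearized) stop("similarity maps require a linearized cine")
  if (is.null(kernel)) kernel <- build_ring_kernel(cine$spacing_mm[1])
  win <- similarity_window(cine$times, appearance_time, window_s)
  crops <- crop_stack(cine$ceus, roi$box)[, , win, drop = FALSE]
  if (regularize_iterations > 0) {
    crops <- speckle_regularize(crops, iterations = regularize_iterations)
  }
  h <- dim(crops)[1]; w <- dim(crops)[2]; n <- dim(crops)[3]
  if (n < 8) stop("similarity window too short (need >= 8 samples)")
  tics <- t(matrix(crops, h * w, n))           # n x P
  sds <- apply(tics, 2, sd)
  valid <- sds > 0
  z <- tics
  z[, valid] <- scale(tics[, valid, drop = FALSE])
  z[, !valid] <- 0
  sp <- welch_spectra(tics)
  B <- ceiling(sqrt(n))
  bins <- apply(tics, 2, equal_freq_bins, B = B)
  res <- ring_similarity_core(z, sp$re, sp$im, sp$sxx,
                              bins, B, valid, kernel$offsets, h, w)
  map_stack(list(
    Coherence = matrix(res[, 1], h, w),
    Correlation = matrix(res[, 2], h, w),
    MutualInformation = matrix(res[, 3], h, w)
  ))
}
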
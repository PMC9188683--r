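#' Automatic square analysis ROI around a lesion
#'
#' Builds the square analysis box used by all parametric maps: centered on
#' the center of mass of the union of the manual masks, with side
#' `clip(ceil(margin_factor * max bounding-box side), min_side, max_side)`
#' so that part of the structures surrounding the lesion is included. The
#' box is clipped to the frame bounds with a warning when the lesion lies
#' near an edge.
#'
#' @param annotation a `lesion_annotation`.
#' @param margin_factor ROI side as a multiple of the largest lesion
#'   bounding-box side (default 2).
#' @param min_side,max_side clamp for the ROI side in pixels; defaults
#'   match the 200-278 px range observed clinically.
#' @return an `analysis_roi`: list with `box` (`c(r0, r1, c0, c1)`,
#'   inclusive), `side_px`, `center`, and `lesion_mask_ref` (the mask at
#'   the reference frame, cropped to the box).
#' @export
square_roi <- function(annotation, margin_factor = 2,
                       min_side = 200, max_side = 278) {
  stopifnot(inherits(annotation, "lesion_annotation"))
  union_mask <- Reduce(`|`, annotation$masks)
  h <- nrow(union_mask); w <- ncol(union_mask)
  px <- which(union_mask, arr.ind = TRUE)
  com <- round(colMeans(px))
  bbox_side <- max(diff(range(px[, 1])), diff(range(px[, 2]))) + 1L
  if (bbox_side > min(h, w)) stop("lesion larger than the frame")
  side <- min(max(ceiling(margin_factor * bbox_side), min_side), max_side)
  half_lo <- floor((side - 1) / 2)
  box <- unname(c(com[1] - half_lo, com[1] - half_lo + side - 1,
                  com[2] - half_lo, com[2] - half_lo + side - 1))
  clipped <- c(max(box[1], 1), min(box[2], h), max(box[3], 1),
               min(box[4], w))
  if (!identical(clipped, box)) {
    warning("analysis ROI clipped to frame bounds")
  }
  box <- do.call(pixel_box, as.list(clipped))
  # the ROI must still cover the lesion bounding box
  if (box[1] > min(px[, 1]) || box[2] < max(px[, 1]) ||
      box[3] > min(px[, 2]) || box[4] < max(px[, 2])) {
    stop("analysis ROI cannot contain the lesion bounding box")
  }
  ref_mask <- annotation$masks[[as.character(annotation$ref_frame)]]
  structure(
    list(box = box, side_px = as.integer(side), center = as.integer(com),
         lesion_mask_ref = ref_mask[box[1]:box[2], box[3]:box[4],
                                    drop = FALSE]),
    class = "analysis_roi"
  )
}

#' @export
print.analysis_roi <- function(x, ...) {
  cat(sprintf("<analysis_roi> rows %d:%d cols %d:%d (side %d px)\n",
              x$box[1], x$box[2], x$box[3], x$box[4], x$side_px))
  invisible(x)
}

# Pearson correlation of every B-mode frame's ROI crop with the reference
# crop; the basis for both valid-frame filtering and fiducial selection
roi_correlations <- function(bmode, roi, ref_frame) {
  crops <- crop_stack(bmode, roi$box)
  nt <- dim(crops)[3]
  ref <- as.vector(crops[, , ref_frame])
  if (sd(ref) == 0) {
    stop("reference frame ROI is constant; cannot assess motion")
  }
  vapply(seq_len(nt), function(t) {
    x <- as.vector(crops[, , t])
    if (sd(x) == 0) return(-1)
    cor(ref, x)
  }, numeric(1))
}

#' Motion-based valid-frame filtering
#'
#' Flags frames whose B-mode ROI crop correlates with the reference
#' frame's crop above a threshold; frames corrupted by large in-plane or
#' out-of-plane motion fall below it and are excluded from all downstream
#' frame selection. The reference frame is always valid.
#'
#' @param cine a `ceus_cine` (B-mode pane is used).
#' @param roi an `analysis_roi`; motion is assessed on the ROI crop to
#'   localize the check to the lesion.
#' @param ref_frame reference frame index.
#' @param threshold correlation threshold (default 0.8, chosen
#'   empirically).
#' @return sorted integer vector of valid frame indices.
#' @export
valid_frames <- function(cine, roi, ref_frame, threshold = 0.8) {
  r <- roi_correlations(cine$bmode, roi, ref_frame)
  # the tolerance keeps frames identical to the reference valid at
  # threshold = 1
  keep <- which(r > threshold | abs(r - threshold) < 1e-12)
  sort(union(keep, as.integer(ref_frame)))
}

#' Lesion-mean time-intensity curve
#'
#' Averages the linearized contrast pane over the manually segmented
#' lesion pixels (at the reference frame) for every frame.
#'
#' @param cine a linearized `ceus_cine`.
#' @param mask binary `H x W` lesion mask on the contrast pane.
#' @return numeric vector of length `T` (relative echo power).
#' @export
mean_tic <- function(cine, mask) {
  if (!cine$linearized) stop("mean_tic requires a linearized cine")
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("empty lesion mask")
  d <- dim(cine$ceus)
  mat <- matrix(cine$ceus, d[1] * d[2], d[3])
  colMeans(mat[idx, , drop = FALSE])
}

#' Fiducial frame selection (wash-in, peak, wash-out)
#'
#' Implements the motion-robust frame-selection procedure. On the 5-s
#' smoothed lesion-mean TIC restricted to valid frames:
#' 1. the appearance frame is the first valid frame reaching 10% of the
#'    TIC maximum;
#' 2. straight lines are least-squares fit to the wash-in (valid samples
#'    with intensity between 5% and 50% of peak, on the rising limb) and
#'    to the wash-out (valid samples in the second half of the window from
#'    appearance to the end of the recording);
#' 3. their intersection gives an initial peak-time guess (falling back to
#'    the TIC argmax when the lines are parallel or underdetermined);
#' 4. the peak frame is the TIC argmax over valid frames within 20 samples
#'    before to 50 samples after the guess (ties: earliest);
#' 5. the wash-in frame is the valid frame with highest B-mode ROI
#'    correlation to the reference frame between 5 samples after
#'    appearance and 5 samples before the peak; the wash-out frame is the
#'    same criterion from 10 samples after the peak to the end.
#'
#' All windows are frame-index windows clipped to the recording;
#' thresholds are relative, so the selection is invariant to affine
#' rescaling of the TIC.
#'
#' @param cine a linearized `ceus_cine`.
#' @param roi an `analysis_roi`.
#' @param ref_frame reference frame index.
#' @param valid valid frame indices from [valid_frames()].
#' @param tic_mean lesion-mean TIC (computed from
#'   `roi$lesion_mask_ref` if omitted).
#' @param appearance_fraction relative threshold for the appearance frame
#'   (default 0.10).
#' @param washin_band relative intensity band for the wash-in line fit
#'   (default `c(0.05, 0.50)`).
#' @param peak_window frame window around the initial guess searched for
#'   the peak (default `c(-20, 50)`).
#' @param washin_offsets samples after appearance / before peak bounding
#'   the wash-in frame search (default `c(5, 5)`).
#' @param washout_offset samples after the peak starting the wash-out
#'   frame search (default 10).
#' @param smooth_window_s moving-average window in seconds applied to the
#'   TIC before selection (default 5).
#' @return a `fiducial_frames` object: list with `wash_in`, `peak`,
#'   `wash_out`, `appearance_idx`, `guess_idx`, `valid`, `tic_mean`,
#'   `tic_smooth`.
#' @export
fiducial_frames <- function(cine, roi, ref_frame, valid,
                            tic_mean = NULL,
                            appearance_fraction = 0.10,
                            washin_band = c(0.05, 0.50),
                            peak_window = c(-20, 50),
                            washin_offsets = c(5, 5),
                            washout_offset = 10,
                            smooth_window_s = 5) {
  nt <- n_frames(cine)
  times <- cine$times
  if (is.null(tic_mean)) {
    full_mask <- matrix(FALSE, dim(cine$ceus)[1], dim(cine$ceus)[2])
    full_mask[roi$box[1]:roi$box[2], roi$box[3]:roi$box[4]] <-
      roi$lesion_mask_ref
    tic_mean <- mean_tic(cine, full_mask)
  }
  valid <- sort(unique(as.integer(valid)))
  sm <- smooth_tic(tic_mean, times, window_s = smooth_window_s)
  if (sd(sm[valid]) == 0) stop("lesion-mean TIC is constant")

  peak_val <- max(sm[valid])
  app_candidates <- valid[sm[valid] >= appearance_fraction * peak_val]
  if (length(app_candidates) == 0) stop("frame selection failed: appearance")
  appearance_idx <- app_candidates[1]
  argmax_idx <- valid[which.max(sm[valid])]

  # wash-in line: rising limb within the relative band
  wi_pts <- valid[sm[valid] >= washin_band[1] * peak_val &
                    sm[valid] <= washin_band[2] * peak_val &
                    valid <= argmax_idx]
  # wash-out line: second half of [appearance, end]
  t_half <- (times[appearance_idx] + times[nt]) / 2
  wo_pts <- valid[times[valid] >= t_half]

  guess_idx <- argmax_idx
  if (length(wi_pts) >= 2 && length(wo_pts) >= 2) {
    f1 <- stats::lm.fit(cbind(1, times[wi_pts]), sm[wi_pts])$coefficients
    f2 <- stats::lm.fit(cbind(1, times[wo_pts]), sm[wo_pts])$coefficients
    dslope <- f1[2] - f2[2]
    if (is.finite(dslope) && abs(dslope) > 1e-12 * max(abs(c(f1[2], f2[2], 1)))) {
      t_star <- (f2[1] - f1[1]) / dslope
      if (is.finite(t_star) && t_star >= times[1] && t_star <= times[nt]) {
        guess_idx <- which.min(abs(times - t_star))
      } else {
        message("line intersection outside recording; using TIC argmax")
      }
    } else {
      message("parallel wash-in/wash-out fits; using TIC argmax")
    }
  }

  pk_set <- valid[valid >= guess_idx + peak_window[1] &
                    valid <= guess_idx + peak_window[2]]
  if (length(pk_set) == 0) stop("frame selection failed: peak")
  peak <- pk_set[which.max(sm[pk_set])]

  bcorr <- roi_correlations(cine$bmode, roi, ref_frame)
  wi_set <- valid[valid >= appearance_idx + washin_offsets[1] &
                    valid <= peak - washin_offsets[2]]
  if (length(wi_set) == 0) stop("frame selection failed: wash-in")
  wash_in <- wi_set[which.max(bcorr[wi_set])]
  wo_set <- valid[valid >= peak + washout_offset]
  if (length(wo_set) == 0) stop("frame selection failed: wash-out")
  wash_out <- wo_set[which.max(bcorr[wo_set])]

  structure(
    list(wash_in = wash_in, peak = peak, wash_out = wash_out,
         appearance_idx = appearance_idx, guess_idx = guess_idx,
         valid = valid, tic_mean = tic_mean, tic_smooth = sm),
    class = "fiducial_frames"
  )
}

#' @export
print.fiducial_frames <- function(x, ...) {
  cat(sprintf(
    "<fiducial_frames> appearance %d, wash-in %d, peak %d, wash-out %d (%d valid)\n",
    x$appearance_idx, x$wash_in, x$peak, x$wash_out, length(x$valid)
  ))
  invisible(x)
}
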
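#' Named stack of parametric maps
#'
#' A `map_stack` is a named list of equally sized numeric matrices, one
#' per parametric map, all defined on the analysis ROI pixel grid
#' (missing pixels are `NA`).
#'
#' @param maps named list of `H x W` matrices.
#' @return a `map_stack`.
#' @export
map_stack <- function(maps) {
  stopifnot(is.list(maps), !is.null(names(maps)), all(nzchar(names(maps))))
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1) stop("all maps must share one shape")
  structure(maps, class = "map_stack")
}

#' @export
c.map_stack <- function(...) {
  parts <- lapply(list(...), unclass)
  map_stack(do.call(c, parts))
}

#' @export
print.map_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<map_stack> %d maps, %d x %d px\n", length(x), d[1], d[2]))
  cat(" ", paste(utils::head(names(x), 8), collapse = ", "),
      if (length(x) > 8) ", ...\n" else "\n")
  invisible(x)
}

#' Moving-average TIC smoothing
#'
#' Centered moving-average filter of a fixed duration in seconds (default
#' 5 s), the standard preprocessing before semiquantitative TIC parameter
#' extraction. The span is `round(window_s * frame_rate)` samples, forced
#' odd; at the edges the window shrinks symmetrically so constant inputs
#' are preserved exactly.
#'
#' @param tic numeric vector (length `T`) or a `T x P` matrix of TICs in
#'   columns.
#' @param times frame times (s), used to infer the frame rate.
#' @param window_s window duration in seconds; must be at least one frame
#'   interval.
#' @return smoothed object of the same shape.
#' @export
smooth_tic <- function(tic, times, window_s = 5) {
  dt <- median(diff(times))
  if (window_s < dt) stop("smoothing window shorter than a frame interval")
  n <- round(window_s / dt)
  if (n %% 2 == 0) n <- n + 1
  half <- (n - 1) / 2
  vec <- is.null(dim(tic))
  x <- if (vec) matrix(tic, ncol = 1) else tic
  nt <- nrow(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  lo <- pmax(seq_len(nt) - half, 1L)
  hi <- pmin(seq_len(nt) + half, nt)
  # shrink symmetrically at the edges so the window stays centered
  shrink <- pmin(seq_len(nt) - lo, hi - seq_len(nt))
  lo <- seq_len(nt) - shrink
  hi <- seq_len(nt) + shrink
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1)
  if (vec) as.vector(out) else out
}

#' Semiquantitative TIC parameters
#'
#' Model-free parameters of a (smoothed) time-intensity curve:
#' * peak intensity `PI`: maximum intensity;
#' * peak time `PT`: time of the (first) maximum;
#' * appearance time `AT`: time at which 10% of the peak intensity is
#'   first reached;
#' * wash-in time `WIT = PT - AT`;
#' * wash-in rate `WIR = PI / WIT` (ratio of peak intensity to the
#'   wash-in time; set `rate_denominator = "peak_time"` for the `PI / PT`
#'   variant).
#'
#' @param tic numeric TIC (already smoothed; see [smooth_tic()]).
#' @param times frame times (s).
#' @param rate_denominator `"wash_in_time"` (default) or `"peak_time"`.
#' @return named numeric vector
#'   `c(PeakIntensity, PeakTime, AppearanceTime, WashInTime, WashInRate)`;
#'   all `NA` for an all-zero TIC, and `WashInRate` `NA` when `WIT = 0`.
#' @export
tic_parameters <- function(tic, times,
                           rate_denominator = c("wash_in_time",
                                                "peak_time")) {
  rate_denominator <- match.arg(rate_denominator)
  nm <- c("PeakIntensity", "PeakTime", "AppearanceTime", "WashInTime",
          "WashInRate")
  pi_ <- max(tic)
  if (pi_ <= 0) return(setNames(rep(NA_real_, 5), nm))
  pk <- which.max(tic)
  at <- which(tic >= 0.1 * pi_)[1]
  pt <- times[pk]; att <- times[at]
  wit <- pt - att
  denom <- if (rate_denominator == "wash_in_time") wit else pt
  wir <- if (denom > 0) pi_ / denom else NA_real_
  setNames(c(pi_, pt, att, wit, wir), nm)
}

#' Pixel-wise perfusion parametric maps
#'
#' Applies [smooth_tic()] and [tic_parameters()] to the TIC of every
#' pixel in the analysis ROI, at fixed pixel coordinates (no motion
#' tracking), yielding the five semiquantitative perfusion maps.
#'
#' @param cine a linearized `ceus_cine`.
#' @param roi an `analysis_roi`.
#' @param smooth_window_s moving-average window (s).
#' @param rate_denominator see [tic_parameters()].
#' @return a `map_stack` with maps `PeakIntensity`, `PeakTime`,
#'   `AppearanceTime`, `WashInTime`, `WashInRate`.
#' @export
perfusion_map_stack <- function(cine, roi, smooth_window_s = 5,
                                rate_denominator = "wash_in_time") {
  if (!cine$linearized) stop("perfusion maps require a linearized cine")
  crops <- crop_stack(cine$ceus, roi$box)
  h <- dim(crops)[1]; w <- dim(crops)[2]; nt <- dim(crops)[3]
  tics <- t(matrix(crops, h * w, nt))          # T x P
  tics <- smooth_tic(tics, cine$times, smooth_window_s)
  px <- t(tics)                                # P x T
  pk_idx <- max.col(px, ties.method = "first")
  pi_ <- px[cbind(seq_along(pk_idx), pk_idx)]
  above <- px >= 0.1 * pi_
  at_idx <- max.col(above, ties.method = "first")
  bad <- pi_ <= 0
  pt <- cine$times[pk_idx]
  at <- cine$times[at_idx]
  wit <- pt - at
  denom <- if (rate_denominator == "wash_in_time") wit else pt
  wir <- ifelse(denom > 0, pi_ / denom, NA_real_)
  pi_[bad] <- pt[bad] <- at[bad] <- wit[bad] <- wir[bad] <- NA_real_
  map_stack(list(
    PeakIntensity = matrix(pi_, h, w),
    PeakTime = matrix(pt, h, w),
    AppearanceTime = matrix(at, h, w),
    WashInTime = matrix(wit, h, w),
    WashInRate = matrix(wir, h, w)
  ))
}
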
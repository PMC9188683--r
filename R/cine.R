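#' CEUS cine container
#'
#' A dual-view contrast-enhanced ultrasound cine: the B-mode pane and the
#' contrast-specific pane of a side-by-side acquisition, stored as
#' `H x W x T` arrays, together with the acquisition metadata needed for
#' quantification (frame times, pixel spacing, dynamic range).
#'
#' Contrast pixel values are either scanner gray levels (log-compressed,
#' `linearized = FALSE`) or relative echo power in `(0, 1]`
#' (`linearized = TRUE`). All downstream quantification expects linearized
#' data; see [linearize()].
#'
#' @param bmode numeric `H x W x T` array of B-mode gray levels.
#' @param ceus numeric `H x W x T` array of contrast-pane values, same
#'   dimensions as `bmode`.
#' @param times numeric vector of frame times in seconds, strictly
#'   increasing, length `T`.
#' @param spacing_mm pixel spacing in mm; a single value (isotropic) or
#'   `c(row, col)`. Both are recorded.
#' @param dynamic_range_db acquisition dynamic range in dB (> 0).
#' @param gray_max maximum representable gray level `G` (e.g. 255 for
#'   8-bit data). Defaults to 255.
#' @param linearized logical; `TRUE` when `ceus` already holds linear
#'   relative echo power.
#' @return an object of class `ceus_cine`.
#' @export
ceus_cine <- function(bmode, ceus, times, spacing_mm, dynamic_range_db,
                      gray_max = 255, linearized = FALSE) {
  bmode <- as_frame_stack(bmode, "bmode")
  ceus <- as_frame_stack(ceus, "ceus")
  if (!identical(dim(bmode), dim(ceus))) {
    stop("bmode and ceus panes must have identical H x W x T dimensions")
  }
  times <- as.numeric(times)
  if (length(times) != dim(bmode)[3]) {
    stop("length(times) must equal the number of frames")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- c(spacing_mm, spacing_mm)
  if (length(spacing_mm) != 2 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("spacing_mm must be one or two positive values")
  }
  if (!is.finite(dynamic_range_db) || dynamic_range_db <= 0) {
    stop("dynamic_range_db must be positive")
  }
  if (!is.finite(gray_max) || gray_max <= 0) {
    stop("gray_max must be positive")
  }
  if (isTRUE(linearized) && any(ceus < 0)) {
    stop("linearized ceus values must be non-negative")
  }
  structure(
    list(
      bmode = bmode, ceus = ceus, times = times,
      spacing_mm = spacing_mm,
      dynamic_range_db = as.numeric(dynamic_range_db),
      gray_max = as.numeric(gray_max),
      linearized = isTRUE(linearized)
    ),
    class = "ceus_cine"
  )
}

as_frame_stack <- function(x, what) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3) {
    stop(sprintf("%s must be an H x W x T array", what))
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop(sprintf("%s contains non-finite values", what))
  x
}

#' @export
print.ceus_cine <- function(x, ...) {
  d <- dim(x$bmode)
  cat(sprintf(
    "<ceus_cine> %d x %d px, %d frames (%.1f s), %.3f mm/px, DR %.0f dB, %s\n",
    d[1], d[2], d[3], diff(range(x$times)), x$spacing_mm[1],
    x$dynamic_range_db,
    if (x$linearized) "linearized" else "gray levels"
  ))
  invisible(x)
}

#' @export
dim.ceus_cine <- function(x) dim(x$bmode)

n_frames <- function(cine) dim(cine$bmode)[3]

#' Invert scanner log compression
#'
#' Converts log-compressed gray levels `g` in `[0, G]` to linear relative
#' echo power via `power(g) = 10^(DR * (g / G - 1) / 10)`, so the maximum
#' gray level maps to unit power and gray level 0 maps to `10^(-DR / 10)`.
#' The echo-power convention (divisor 10, not 20) is used because
#' downstream time-intensity-curve features are computed on relative power;
#' an amplitude convention can be obtained by halving `dynamic_range_db`.
#'
#' @param x a `ceus_cine` (its contrast pane is linearized in place) or a
#'   numeric vector/array of gray levels.
#' @param gray_max maximum gray level `G`; taken from the cine when `x` is
#'   a `ceus_cine`.
#' @param dynamic_range_db dynamic range in dB; taken from the cine when
#'   `x` is a `ceus_cine`.
#' @return the linearized cine, or a numeric object of relative powers in
#'   `(0, 1]`.
#' @seealso [log_compress()] for the inverse.
#' @export
linearize <- function(x, gray_max = 255, dynamic_range_db = 60) {
  if (inherits(x, "ceus_cine")) {
    if (x$linearized) stop("cine is already linearized")
    x$ceus <- linearize(x$ceus, x$gray_max, x$dynamic_range_db)
    x$linearized <- TRUE
    return(x)
  }
  check_gray_range(x, gray_max)
  10^(dynamic_range_db * (x / gray_max - 1) / 10)
}

#' Apply scanner log compression
#'
#' Inverse of [linearize()]: maps linear relative echo power in
#' `(0, 1]` back to gray levels in `[0, G]`. Powers below the dynamic-range
#' floor `10^(-DR/10)` clip to gray level 0.
#'
#' @param power numeric vector/array of relative echo powers (> 0), or a
#'   linearized `ceus_cine`.
#' @param quantize round to integer gray levels (default `TRUE`, matching
#'   scanner output).
#' @inheritParams linearize
#' @return gray levels in `[0, gray_max]`, or a gray-level cine.
#' @export
log_compress <- function(power, gray_max = 255, dynamic_range_db = 60,
                         quantize = TRUE) {
  if (inherits(power, "ceus_cine")) {
    if (!power$linearized) stop("cine is not linearized")
    power$ceus <- log_compress(power$ceus, power$gray_max,
                               power$dynamic_range_db, quantize)
    power$linearized <- FALSE
    return(power)
  }
  if (any(power <= 0)) {
    power <- pmax(power, 10^(-dynamic_range_db / 10 - 6))
  }
  g <- gray_max * (1 + 10 * log10(power) / dynamic_range_db)
  g <- pmin(pmax(g, 0), gray_max)
  if (quantize) g <- round(g)
  g
}

check_gray_range <- function(g, gray_max) {
  if (any(g < 0) || any(g > gray_max)) {
    stop(sprintf("gray levels must lie in [0, %g]", gray_max))
  }
  invisible(TRUE)
}

#' Manual lesion annotation
#'
#' Holds 1-3 manual lesion masks drawn on named frames of the B-mode pane,
#' the radiologist's reference frame, and the lesion-level label.
#'
#' @param masks a named list of binary `H x W` matrices; names are the
#'   1-based frame indices the masks were drawn on.
#' @param ref_frame the reference frame index (the frame used to indicate
#'   the lesion); must have a mask.
#' @param label `"benign"`, `"malignant"`, or `"unknown"`.
#' @return an object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(masks, ref_frame, label = "unknown") {
  if (!is.list(masks) || length(masks) < 1 || length(masks) > 3) {
    stop("masks must be a list of 1-3 binary matrices")
  }
  if (is.null(names(masks)) || any(!nzchar(names(masks)))) {
    stop("masks must be named by frame index")
  }
  frames <- as.integer(names(masks))
  if (any(is.na(frames)) || any(frames < 1)) {
    stop("mask names must be positive frame indices")
  }
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) stop("each mask must be an H x W matrix")
    m <- m != 0
    if (!any(m)) stop("empty lesion mask")
    m
  })
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1) stop("all masks must share one H x W shape")
  ref_frame <- as.integer(ref_frame)
  if (!ref_frame %in% frames) stop("ref_frame must have a mask")
  label <- match.arg(label, c("benign", "malignant", "unknown"))
  structure(
    list(masks = masks, frames = frames, ref_frame = ref_frame,
         label = label),
    class = "lesion_annotation"
  )
}

#' @export
print.lesion_annotation <- function(x, ...) {
  cat(sprintf(
    "<lesion_annotation> %d mask(s) on frame(s) %s, ref %d, label %s\n",
    length(x$masks), paste(x$frames, collapse = "/"), x$ref_frame, x$label
  ))
  invisible(x)
}

# validate an annotation against a cine's geometry
validate_annotation <- function(annotation, cine) {
  d <- dim(cine$bmode)
  md <- dim(annotation$masks[[1]])
  if (md[1] != d[1] || md[2] != d[2]) {
    stop("mask shape does not match cine frames")
  }
  if (any(annotation$frames > d[3])) {
    stop("mask frame index out of range")
  }
  invisible(TRUE)
}
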
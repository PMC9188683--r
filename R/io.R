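#' @useDynLib ceusradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor fft median prcomp quantile rgamma rnorm runif
#'   sd var glm predict binomial qt setNames dist
#' @importFrom utils head tail write.csv read.csv combn
NULL

# pixel boxes are length-4 integer vectors c(r0, r1, c0, c1), 1-based and
# inclusive at both ends
pixel_box <- function(r0, r1, c0, c1) {
  b <- as.integer(c(r0, r1, c0, c1))
  if (any(is.na(b)) || b[1] > b[2] || b[3] > b[4] || any(b < 1)) {
    stop("invalid pixel box")
  }
  b
}

box_in_frame <- function(box, h, w) {
  box[1] >= 1 && box[2] <= h && box[3] >= 1 && box[4] <= w
}

boxes_overlap <- function(a, b) {
  a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
}

crop_stack <- function(stack, box) {
  stack[box[1]:box[2], box[3]:box[4], , drop = FALSE]
}

#' Write a cine to a side-by-side TIFF stack with YAML metadata
#'
#' Serializes a gray-level `ceus_cine` as a multi-page 16-bit TIFF holding
#' the side-by-side view (B-mode pane left, contrast pane right) plus a
#' `meta.yaml` sidecar carrying frame times, pixel spacing, dynamic range,
#' gray maximum, and the two pane boxes. Integer gray levels round-trip
#' exactly through [load_cine()].
#'
#' @param cine a non-linearized `ceus_cine`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cine <- function(cine, dir) {
  stopifnot(inherits(cine, "ceus_cine"))
  if (cine$linearized) {
    stop("write_cine stores gray levels; log_compress() the cine first")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(cine$bmode)
  frames <- lapply(seq_len(d[3]), function(t) {
    cbind(cine$bmode[, , t], cine$ceus[, , t]) / cine$gray_max
  })
  tiff::writeTIFF(frames, file.path(dir, "frames.tif"),
                  bits.per.sample = 16L, compression = "none")
  meta <- list(
    times = as.numeric(cine$times),
    spacing_mm = as.numeric(cine$spacing_mm),
    dynamic_range_db = cine$dynamic_range_db,
    gray_max = cine$gray_max,
    bmode_box = as.integer(c(1, d[1], 1, d[2])),
    ceus_box = as.integer(c(1, d[1], d[2] + 1, 2 * d[2]))
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Load a side-by-side cine stack
#'
#' Reads a multi-page TIFF written by [write_cine()] (or any compatible
#' side-by-side stack) and splits the B-mode and contrast panes according
#' to the layout. The layout comes from a `meta.yaml` sidecar next to the
#' stack, or can be passed directly.
#'
#' @param path a directory containing `frames.tif` + `meta.yaml`, or a
#'   TIFF file path (then `layout` is required unless a sidecar exists).
#' @param layout optional list overriding the sidecar: fields `times`,
#'   `spacing_mm`, `dynamic_range_db`, `gray_max`, `bmode_box`,
#'   `ceus_box` (boxes are `c(r0, r1, c0, c1)`, 1-based inclusive).
#' @return a `ceus_cine` with `linearized = FALSE`.
#' @export
load_cine <- function(path, layout = NULL) {
  if (dir.exists(path)) {
    tif <- file.path(path, "frames.tif")
    sidecar <- file.path(path, "meta.yaml")
  } else {
    tif <- path
    sidecar <- file.path(dirname(path), "meta.yaml")
  }
  if (!file.exists(tif)) stop("cine stack not found: ", tif)
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  if (!is.null(layout)) meta[names(layout)] <- layout
  for (field in c("times", "spacing_mm", "dynamic_range_db", "gray_max",
                  "bmode_box", "ceus_box")) {
    if (is.null(meta[[field]])) {
      stop("cine metadata is missing required field '", field, "'")
    }
  }
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  full <- array(unlist(pages), dim = c(h, w, length(pages)))
  full <- round(full * meta$gray_max)
  bb <- do.call(pixel_box, as.list(meta$bmode_box))
  cb <- do.call(pixel_box, as.list(meta$ceus_box))
  if (!box_in_frame(bb, h, w) || !box_in_frame(cb, h, w)) {
    stop("pane box exceeds frame bounds")
  }
  if (boxes_overlap(bb, cb)) stop("pane boxes overlap")
  ceus_cine(
    bmode = crop_stack(full, bb),
    ceus = crop_stack(full, cb),
    times = meta$times,
    spacing_mm = meta$spacing_mm,
    dynamic_range_db = meta$dynamic_range_db,
    gray_max = meta$gray_max
  )
}

#' Write a binary lesion mask as PNG
#'
#' @param mask binary `H x W` matrix (nonzero = lesion).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Read a binary lesion mask (PNG or TIFF; nonzero = lesion)
#'
#' @param path mask file path.
#' @return logical `H x W` matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", ext)
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' Load a lesion annotation from mask files
#'
#' @param paths character vector of 1-3 mask file paths.
#' @param frames integer vector of frame indices the masks were drawn on
#'   (same length as `paths`).
#' @param ref_frame reference frame index; must appear in `frames`.
#' @param label lesion label: `"benign"`, `"malignant"`, `"unknown"`.
#' @param cine optional `ceus_cine` to validate mask geometry against.
#' @return a `lesion_annotation`.
#' @export
load_annotation <- function(paths, frames, ref_frame, label = "unknown",
                            cine = NULL) {
  if (length(paths) != length(frames)) {
    stop("paths and frames must have equal length")
  }
  masks <- lapply(paths, read_mask)
  names(masks) <- as.character(frames)
  ann <- lesion_annotation(masks, ref_frame, label)
  if (!is.null(cine)) validate_annotation(ann, cine)
  ann
}
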
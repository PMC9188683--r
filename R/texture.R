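#' Uniform gray-level quantization of a window
#'
#' Quantizes a raw intensity window to `L` gray levels over its own
#' min-max range: `q = floor(L * (x - min) / (max - min + eps)) + 1`, so a
#' non-constant window always uses levels 1 and `L`, and every texture
#' feature (except the Global moments) is invariant to affine rescaling
#' of the raw intensities. A constant window maps to all ones.
#'
#' @param window numeric matrix.
#' @param L number of gray levels (default 64).
#' @return integer matrix with values in `[1, L]`.
#' @export
quantize_window <- function(window, L = 64) {
  rng <- max(window) - min(window)
  if (rng == 0) {
    return(matrix(1L, nrow(window), ncol(window)))
  }
  q <- floor(L * (window - min(window)) / (rng * (1 + 1e-9))) + 1
  q <- pmin(pmax(q, 1), L)
  storage.mode(q) <- "integer"
  q
}

#' Global histogram features of a raw window
#'
#' Central-moment statistics of the raw intensity values: population
#' variance, moment skewness, and non-excess kurtosis (normal = 3).
#' A constant window returns `(0, 0, 0)` by convention.
#'
#' @param window numeric matrix of raw intensities.
#' @return named vector `c(Variance, Skewness, Kurtosis)`.
#' @export
global_features <- function(window) {
  x <- as.vector(window)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(c(Variance = 0, Skewness = 0, Kurtosis = 0))
  }
  c(Variance = m2,
    Skewness = mean((x - m)^3) / m2^1.5,
    Kurtosis = mean((x - m)^4) / m2^2)
}

#' Gray-level co-occurrence matrix features
#'
#' Nine Haralick-family statistics from the distance-1 co-occurrence
#' matrix pooled over the four in-plane directions (0/45/90/135 degrees),
#' symmetrized and normalized to sum 1. Entropy uses log2; Correlation is
#' defined as 0 when the marginal variance degenerates (constant window).
#'
#' @param qwin quantized integer window (see [quantize_window()]).
#' @param L number of gray levels.
#' @return named vector of 9 features.
#' @export
glcm_features <- function(qwin, L = max(qwin)) {
  P <- glcm_pooled(qwin, L)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  correlation <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0
  nz <- P[P > 0]
  c(Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Correlation = correlation,
    Homogeneity = sum(P / (1 + abs(i - j))),
    Variance = sig2,
    SumAverage = sum((i + j) * P),
    Entropy = -sum(nz * log2(nz)),
    Dissimilarity = sum(abs(i - j) * P),
    AutoCorrelation = sum(i * j * P))
}

# shared statistics for run-length and size-zone matrices: counts is an
# L x M matrix over (gray level g, run length / zone size s)
gl_matrix_stats <- function(counts, n_pixels, n_dir, zone = FALSE) {
  nr <- sum(counts)
  p <- counts / nr
  g <- matrix(seq_len(nrow(counts)), nrow(counts), ncol(counts))
  s <- matrix(seq_len(ncol(counts)), nrow(counts), ncol(counts),
              byrow = TRUE)
  mu_g <- sum(g * p)
  mu_s <- sum(s * p)
  out <- c(
    sum(p / s^2),                      # SRE / SZE
    sum(p * s^2),                      # LRE / LZE
    sum(rowSums(counts)^2) / nr,       # GLN
    sum(colSums(counts)^2) / nr,       # RLN / ZSN
    nr / (n_dir * n_pixels),           # RP / ZP
    sum(p / g^2),                      # LGRE / LGZE
    sum(p * g^2),                      # HGRE / HGZE
    sum(p / (g^2 * s^2)),              # SRLGE / SZLGE
    sum(p * g^2 / s^2),                # SRHGE / SZHGE
    sum(p * s^2 / g^2),                # LRLGE / LZLGE
    sum(p * g^2 * s^2),                # LRHGE / LZHGE
    sum((g - mu_g)^2 * p),             # GLV
    sum((s - mu_s)^2 * p)              # RLV / ZSV
  )
  names(out) <- if (zone) {
    c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE",
      "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")
  } else {
    c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE",
      "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")
  }
  out
}

#' Gray-level run-length matrix features
#'
#' Thirteen statistics of the run-length matrix pooled over the four
#' in-plane directions. Run percentage is normalized by
#' `n_directions * n_pixels` so it lies in `(0, 1]`.
#'
#' @inheritParams glcm_features
#' @return named vector of 13 features.
#' @export
glrlm_features <- function(qwin, L = max(qwin)) {
  counts <- glrlm_pooled(qwin, L)
  gl_matrix_stats(counts, length(qwin), n_dir = 4, zone = FALSE)
}

#' Gray-level size-zone matrix features
#'
#' Thirteen statistics of the size-zone matrix built from 8-connected
#' constant-level components (a single pooled matrix; zones have no
#' direction). Zone percentage is `n_zones / n_pixels`.
#'
#' @inheritParams glcm_features
#' @return named vector of 13 features.
#' @export
glszm_features <- function(qwin, L = max(qwin)) {
  zones <- glszm_zones(qwin)
  maxsize <- max(zones[, 2])
  counts <- matrix(0, L, maxsize)
  for (k in seq_len(nrow(zones))) {
    counts[zones[k, 1], zones[k, 2]] <- counts[zones[k, 1], zones[k, 2]] + 1
  }
  gl_matrix_stats(counts, length(qwin), n_dir = 1, zone = TRUE)
}

#' Neighborhood gray-tone difference matrix features
#'
#' The five Amadasun-King statistics computed over interior pixels with a
#' full 8-neighborhood. A small epsilon (1e-6) guards the Coarseness and
#' Strength denominators against division by zero on constant windows.
#'
#' @inheritParams glcm_features
#' @return named vector of 5 features.
#' @export
ngtdm_features <- function(qwin, L = max(qwin)) {
  eps <- 1e-6
  cnt <- ngtdm_counts(qwin, L)
  n_i <- cnt[, 1]
  s_i <- cnt[, 2]
  N <- sum(n_i)
  nm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  if (N == 0) return(setNames(rep(0, 5), nm))
  p <- n_i / N
  pres <- which(p > 0)
  ngp <- length(pres)
  lev <- seq_len(L)
  coarseness <- 1 / (eps + sum(p * s_i))
  contrast <- 0
  if (ngp > 1) {
    pij <- outer(p[pres], p[pres])
    dij2 <- outer(lev[pres], lev[pres], function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (ngp * (ngp - 1)) * sum(s_i) / N
  }
  ip <- lev[pres] * p[pres]
  denom_busy <- sum(abs(outer(ip, ip, `-`)))
  busyness <- if (denom_busy > 0) sum(p * s_i) / denom_busy else 0
  ps <- p[pres] * s_i[pres]
  complexity <- 0
  strength <- 0
  if (ngp > 0) {
    dij <- outer(lev[pres], lev[pres], function(a, b) abs(a - b))
    psum <- outer(p[pres], p[pres], `+`)
    complexity <- sum(dij * (outer(ps, ps, `+`)) / (N * psum))
    strength <- sum(psum * dij^2) / (eps + sum(s_i))
  }
  setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}

#' Full 43-feature texture vector of one raw window
#'
#' Quantizes the window ([quantize_window()]) and concatenates the Global
#' (3), GLCM (9), GLRLM (13), GLSZM (13) and NGTDM (5) features, named
#' `<Family>_<FeatureName>`.
#'
#' @param window numeric matrix of raw intensities.
#' @param L number of gray levels.
#' @return named numeric vector of length 43.
#' @export
texture_vector <- function(window, L = 64) {
  q <- quantize_window(window, L)
  out <- c(global_features(window), glcm_features(q, L),
           glrlm_features(q, L), glszm_features(q, L),
           ngtdm_features(q, L))
  names(out) <- texture_feature_names()
  out
}

#' Names of the 43 texture features
#' @return character vector `<Family>_<FeatureName>`, length 43.
#' @export
texture_feature_names <- function() {
  c(paste0("Global_", c("Variance", "Skewness", "Kurtosis")),
    paste0("GLCM_", c("Energy", "Contrast", "Correlation", "Homogeneity",
                      "Variance", "SumAverage", "Entropy", "Dissimilarity",
                      "AutoCorrelation")),
    paste0("GLRLM_", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                       "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")),
    paste0("GLSZM_", c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                       "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")),
    paste0("NGTDM_", c("Coarseness", "Contrast", "Busyness", "Complexity",
                       "Strength")))
}

#' Moving-window texture parametric maps of one frame
#'
#' Slides a `window x window` box with the given stride over the analysis
#' ROI of one linearized frame, computes the 43 texture features at each
#' position (after per-window 64-level quantization), and upsamples the
#' stride grid back to the ROI pixel grid by nearest-neighbor so all maps
#' share one support. Window size 21 and stride 3 balance map noise
#' against smoothing of distinct textures.
#'
#' @param frame `H x W` matrix (full contrast pane, linearized).
#' @param roi an `analysis_roi`.
#' @param window odd window side in pixels (default 21).
#' @param stride stride in pixels (default 3).
#' @param L gray levels for quantization.
#' @return a `map_stack` of 43 maps on the ROI pixel grid; the stride-grid
#'   values are kept in `attr(, "grid")`.
#' @export
texture_map <- function(frame, roi, window = 21, stride = 3, L = 64) {
  stopifnot(window %% 2 == 1)
  crop <- frame[roi$box[1]:roi$box[2], roi$box[3]:roi$box[4], drop = FALSE]
  sh <- nrow(crop); sw <- ncol(crop)
  if (sh < window || sw < window) stop("ROI smaller than texture window")
  starts_r <- seq(1, sh - window + 1, by = stride)
  starts_c <- seq(1, sw - window + 1, by = stride)
  nr <- length(starts_r); nc <- length(starts_c)
  feat_names <- texture_feature_names()
  grid <- array(NA_real_, dim = c(nr, nc, 43),
                dimnames = list(NULL, NULL, feat_names))
  for (ci in seq_len(nc)) {
    for (ri in seq_len(nr)) {
      win <- crop[starts_r[ri]:(starts_r[ri] + window - 1),
                  starts_c[ci]:(starts_c[ci] + window - 1)]
      grid[ri, ci, ] <- texture_vector(win, L)
    }
  }
  # nearest-neighbor upsampling: each ROI pixel takes the value of the
  # window whose center is closest
  centers_r <- starts_r + (window - 1) / 2
  centers_c <- starts_c + (window - 1) / 2
  near_r <- pmin(pmax(round((seq_len(sh) - centers_r[1]) / stride) + 1, 1),
                 nr)
  near_c <- pmin(pmax(round((seq_len(sw) - centers_c[1]) / stride) + 1, 1),
                 nc)
  maps <- lapply(seq_len(43), function(k) {
    grid[, , k][cbind(rep(near_r, times = sw),
                      rep(near_c, each = sh))] |>
      matrix(sh, sw)
  })
  names(maps) <- feat_names
  out <- map_stack(maps)
  attr(out, "grid") <- grid
  out
}

#' Texture maps at the three fiducial frames
#'
#' Runs [texture_map()] on the wash-in, peak, and wash-out frames and
#' prefixes the map names with `WiIm_`, `PkIm_`, `WoIm_` respectively,
#' yielding the 129 texture parametric maps.
#'
#' @param cine a linearized `ceus_cine`.
#' @param roi an `analysis_roi`.
#' @param fiducials a `fiducial_frames` object.
#' @inheritParams texture_map
#' @return a `map_stack` of `3 * 43 = 129` maps.
#' @export
texture_at_fiducials <- function(cine, roi, fiducials, window = 21,
                                 stride = 3, L = 64) {
  frames <- c(WiIm = fiducials$wash_in, PkIm = fiducials$peak,
              WoIm = fiducials$wash_out)
  stacks <- lapply(seq_along(frames), function(k) {
    m <- texture_map(cine$ceus[, , frames[k]], roi, window, stride, L)
    attr(m, "grid") <- NULL
    names(m) <- paste0(names(frames)[k], "_", names(m))
    m
  })
  do.call(c, stacks)
}
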
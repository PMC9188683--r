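#' Summary statistics of a parametric map over the ROI
#'
#' Condenses one parametric map to the three radiomic summary statistics
#' used as scalar features: median, interquartile range (Q3 - Q1,
#' linear-interpolation quantiles), and moment skewness (0 for a constant
#' map), computed over the non-missing ROI pixels.
#'
#' @param map numeric matrix (`NA` = missing pixel).
#' @param min_valid minimum number of non-missing pixels required
#'   (default 8); below it all three statistics are `NA`.
#' @return named vector `c(median, iqr, skew)`.
#' @export
summarize_map <- function(map, min_valid = 8) {
  x <- map[!is.na(map)]
  if (length(x) < min_valid) {
    return(c(median = NA_real_, iqr = NA_real_, skew = NA_real_))
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  c(median = q[2], iqr = q[3] - q[1], skew = skew)
}

# feature set of a map name: texture prefixes or spatiotemporal
feature_set_of <- function(map_names) {
  ifelse(grepl("^WiIm_", map_names), "WiIm",
         ifelse(grepl("^PkIm_", map_names), "PkIm",
                ifelse(grepl("^WoIm_", map_names), "WoIm",
                       "spatiotemporal")))
}

#' Assemble the lesion-by-feature table
#'
#' Applies [summarize_map()] to every parametric map of every lesion and
#' concatenates the results into the radiomic feature table: one row per
#' lesion, one column per (map, statistic) pair named `<Map>_<stat>`
#' (e.g. `Coherence_iqr`, `PkIm_GLCM_Energy_median`). With the full
#' 137-map stack this yields 411 columns. Column order is deterministic
#' (map-stack order, statistics median/iqr/skew within each map).
#'
#' @param stacks list of `map_stack`s, one per lesion, with identical map
#'   names.
#' @param labels character/factor of lesion labels (`benign`,
#'   `malignant`), one per lesion.
#' @return a `feature_table`: list with `features` (data.frame), `labels`
#'   (factor), and `sets` (named character vector mapping each column to
#'   its feature set: spatiotemporal, WiIm, PkIm, WoIm).
#' @export
build_feature_table <- function(stacks, labels) {
  stopifnot(length(stacks) == length(labels), length(stacks) >= 1)
  nm <- names(stacks[[1]])
  for (s in stacks) {
    if (!identical(names(s), nm)) {
      stop("inconsistent map names across lesions")
    }
  }
  rows <- lapply(stacks, function(s) {
    unlist(lapply(s, summarize_map))
  })
  feats <- as.data.frame(do.call(rbind, rows))
  names(feats) <- as.vector(t(outer(nm, c("median", "iqr", "skew"),
                                    paste, sep = "_")))
  sets <- setNames(rep(feature_set_of(nm), each = 3), names(feats))
  feature_table(feats, labels, sets)
}

#' Construct a feature table
#'
#' @param features data.frame of numeric features (rows = lesions).
#' @param labels lesion labels, coerced to a factor with levels
#'   `benign < malignant`.
#' @param sets named character vector assigning each column to a feature
#'   set; inferred from the column names when omitted.
#' @return a `feature_table`.
#' @export
feature_table <- function(features, labels, sets = NULL) {
  features <- as.data.frame(features)
  labels <- factor(as.character(labels), levels = c("benign", "malignant"))
  stopifnot(nrow(features) == length(labels), !anyNA(labels))
  if (is.null(sets)) {
    base <- sub("_(median|iqr|skew)$", "", names(features))
    sets <- setNames(feature_set_of(base), names(features))
  }
  stopifnot(identical(sort(names(sets)), sort(names(features))))
  structure(list(features = features, labels = labels,
                 sets = sets[names(features)]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d lesions x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s: %d", names(table(x$sets)),
                            table(x$sets)), collapse = ", ")))
  cat(sprintf("  labels: %d benign / %d malignant\n",
              sum(x$labels == "benign"), sum(x$labels == "malignant")))
  invisible(x)
}

# median imputation of missing feature values (column-wise); columns that
# are entirely missing become 0
impute_median <- function(features, medians = NULL) {
  if (is.null(medians)) {
    medians <- vapply(features, function(col) {
      m <- median(col, na.rm = TRUE)
      if (is.na(m)) 0 else m
    }, numeric(1))
  }
  for (j in seq_along(features)) {
    miss <- is.na(features[[j]])
    if (any(miss)) features[[j]][miss] <- medians[j]
  }
  list(features = features, medians = medians)
}

#' Redundancy pruning by pairwise correlation
#'
#' Removes highly correlated features: feature pairs are visited in
#' descending absolute Pearson correlation, and for every pair still
#' present with `|r|` above the threshold, the member with the lower
#' absolute point-biserial correlation with the benign/malignant label is
#' dropped (ties: the later column). Missing values are median-imputed
#' before correlations are computed.
#'
#' @param ft a `feature_table`.
#' @param threshold correlation threshold (default 0.9).
#' @return the pruned `feature_table`; dropped column names are recorded
#'   in `attr(, "dropped")`.
#' @export
correlation_prune <- function(ft, threshold = 0.9) {
  stopifnot(inherits(ft, "feature_table"))
  X <- impute_median(ft$features)$features
  p <- ncol(X)
  if (p < 2) return(ft)
  cm <- suppressWarnings(cor(as.matrix(X)))
  cm[!is.finite(cm)] <- 0
  y <- as.numeric(ft$labels == "malignant")
  ycor <- abs(suppressWarnings(cor(as.matrix(X), y)))
  ycor[!is.finite(ycor)] <- 0
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(ft)
  ord <- order(-abs(cm[pairs]))
  pairs <- pairs[ord, , drop = FALSE]
  alive <- rep(TRUE, p)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!alive[i] || !alive[j]) next
    # keep the member more correlated with the label; ties keep the
    # earlier column
    drop <- if (ycor[i] >= ycor[j]) j else i
    alive[drop] <- FALSE
  }
  out <- feature_table(ft$features[, alive, drop = FALSE], ft$labels,
                       ft$sets[alive])
  attr(out, "dropped") <- names(ft$features)[!alive]
  out
}

# save/restore the RNG state around a deterministic operation
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mutual information between a continuous feature and a binary label
#'
#' Nearest-neighbor (Ross) estimator of I(X; Y) for continuous X and
#' discrete Y, avoiding an arbitrary binning of small cohorts: for each
#' sample, the distance to its k-th neighbor within the same class sets a
#' radius, and the number of samples of any class inside that radius
#' enters a digamma identity. A fixed-seed sub-resolution jitter breaks
#' ties. The estimate is clipped at 0.
#'
#' @param x numeric vector.
#' @param y factor with two levels.
#' @param k neighbor count (default 3, reduced for tiny classes).
#' @param seed jitter seed.
#' @return non-negative scalar MI estimate (nats).
#' @export
mi_feature_label <- function(x, y, k = 3, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  y <- factor(y)
  sdx <- sd(x)
  if (!is.finite(sdx) || sdx == 0) return(0)
  x <- with_local_seed(seed, x + rnorm(n, 0, 1e-10 * sdx))
  nxy <- table(y)
  if (any(nxy < 2)) return(0)
  dig_m <- numeric(n)
  dig_ny <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    same <- same[same != i]
    ki <- min(k, length(same))
    d <- sort(abs(x[same] - x[i]))[ki]
    m_i <- sum(abs(x - x[i]) <= d) - 1  # exclude self
    dig_m[i] <- digamma(max(m_i, 1))
    dig_ny[i] <- digamma(as.numeric(nxy[y[i]]))
  }
  mi <- digamma(n) + digamma(k) - mean(dig_m) - mean(dig_ny)
  max(mi, 0)
}

#' Adaptive univariate feature selection per feature set
#'
#' For each feature set (spatiotemporal, WiIm, PkIm, WoIm) separately:
#' standardizes the columns, finds the smallest number of principal
#' components `N` explaining 95% of the variance, and keeps the `N`
#' features with the highest mutual information with the label
#' ([mi_feature_label()]). The selected sets are concatenated. Constant
#' columns carry no information and are excluded before the PCA.
#'
#' @param ft a `feature_table` (typically after [correlation_prune()]).
#' @param var_explained cumulative explained-variance target (default
#'   0.95).
#' @param seed seed for the MI estimator.
#' @return the filtered `feature_table`.
#' @export
adaptive_select <- function(ft, var_explained = 0.95, seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  X <- impute_median(ft$features)$features
  keep <- character(0)
  for (set in unique(ft$sets)) {
    cols <- names(ft$sets)[ft$sets == set]
    Xs <- X[, cols, drop = FALSE]
    nonconst <- vapply(Xs, function(v) sd(v) > 0, logical(1))
    Xs <- Xs[, nonconst, drop = FALSE]
    if (ncol(Xs) == 0) {
      warning(sprintf("feature set '%s' has no usable features", set))
      next
    }
    pc <- prcomp(as.matrix(Xs), center = TRUE, scale. = TRUE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_keep <- min(which(cum >= var_explained))
    mi <- vapply(seq_len(ncol(Xs)), function(j) {
      mi_feature_label(Xs[[j]], ft$labels, seed = seed)
    }, numeric(1))
    ord <- order(-mi, seq_along(mi))
    keep <- c(keep, names(Xs)[ord[seq_len(min(n_keep, ncol(Xs)))]])
  }
  if (length(keep) == 0) stop("no features survived adaptive selection")
  keep <- names(ft$features)[names(ft$features) %in% keep]
  feature_table(ft$features[, keep, drop = FALSE], ft$labels,
                ft$sets[keep])
}

#' Write / read a feature table as CSV + JSON schema sidecar
#'
#' @param ft a `feature_table`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- cbind(label = as.character(ft$labels), ft$features)
  write.csv(df, path, row.names = FALSE)
  schema <- list(columns = lapply(names(ft$features), function(nm) {
    list(name = nm, set = unname(ft$sets[nm]),
         map = sub("_(median|iqr|skew)$", "", nm),
         statistic = sub("^.*_(median|iqr|skew)$", "\\1", nm))
  }))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  feature_table(df[, setdiff(names(df), "label"), drop = FALSE],
                df$label)
}
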
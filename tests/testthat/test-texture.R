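test_that("quantization spans 1..L and ignores affine rescaling", {
  expect_true(all(quantize_window(matrix(3.3, 5, 5)) == 1L))
  # linear ramp over 64 columns: one level per column
  ramp <- matrix(rep(seq(0, 1, length.out = 64), each = 4), 4, 64)
  q <- quantize_window(ramp, 64)
  expect_equal(q[1, ], 1:64)
  set.seed(2)
  w <- matrix(runif(25), 5, 5)
  expect_identical(quantize_window(w, 8),
                   quantize_window(5 * w - 2, 8))
  q2 <- quantize_window(w, 8)
  expect_equal(min(q2), 1L)
  expect_equal(max(q2), 8L)
})

test_that("global moments follow their conventions", {
  expect_equal(global_features(matrix(7, 5, 5)),
               c(Variance = 0, Skewness = 0, Kurtosis = 0))
  two <- matrix(c(1, 5), 4, 4)  # equal weights of two values
  expect_equal(unname(global_features(two)["Skewness"]), 0)
  set.seed(14)
  g <- global_features(matrix(rnorm(441), 21, 21))
  expect_equal(unname(g["Kurtosis"]), 3, tolerance = 0.5)
  expect_equal(unname(g["Variance"]), 1, tolerance = 0.25)
})

test_that("all four matrix families match brute-force enumeration", {
  set.seed(77)
  for (rep in 1:12) {
    dims <- sample(4:5, 2, replace = TRUE)
    L <- sample(2:4, 1)
    q <- matrix(sample.int(L, prod(dims), replace = TRUE),
                dims[1], dims[2])
    # GLCM: normalized symmetric pooled matrix
    expect_equal(ceusradiomics:::glcm_pooled(q, L), oracle_glcm(q, L))
    # GLRLM counts (compare the populated sub-matrix)
    got_rl <- ceusradiomics:::glrlm_pooled(q, L)
    want_rl <- oracle_glrlm(q, L)
    expect_equal(got_rl[, seq_len(ncol(want_rl))], want_rl)
    expect_true(all(got_rl[, -seq_len(ncol(want_rl))] == 0))
    # GLSZM zones as multisets of (level, size)
    got_z <- ceusradiomics:::glszm_zones(q)
    want_z <- oracle_zones(q)
    expect_equal(
      sort(paste(got_z[, 1], got_z[, 2])),
      sort(paste(want_z[, 1], want_z[, 2]))
    )
    # NGTDM counts and summed deviations
    expect_equal(unname(ceusradiomics:::ngtdm_counts(q, L)),
                 unname(oracle_ngtdm(q, L)))
    # run/zone statistics from the counts
    expect_equal(unname(glrlm_features(q, L)),
                 oracle_gl_stats(want_rl, prod(dims), 4))
    expect_equal(unname(glszm_features(q, L)),
                 oracle_gl_stats(oracle_glszm_counts(q, L),
                                 prod(dims), 1))
  }
})

test_that("degenerate and structured windows give their known values", {
  const <- matrix(1L, 21, 21)
  g <- glcm_features(const, 4)
  expect_equal(unname(g["Energy"]), 1)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["Dissimilarity"]), 0)
  # i.i.d. uniform 64-level noise: energy collapses toward zero
  set.seed(3)
  noise <- matrix(sample.int(64, 441, replace = TRUE), 21, 21)
  expect_lt(unname(glcm_features(noise, 64)["Energy"]), 0.01)
  # 4x4 two-level checkerboard against a hand-enumerated GLCM
  cb <- matrix(rep(c(1L, 2L), 8), 4, 4)
  cb[, c(2, 4)] <- 3L - cb[, c(2, 4)]
  P <- oracle_glcm(cb, 2)
  i <- matrix(1:2, 2, 2); j <- t(i)
  expect_equal(unname(glcm_features(cb, 2)["Contrast"]),
               sum((i - j)^2 * P))
  expect_equal(unname(glcm_features(cb, 2)["Energy"]), sum(P^2))

  # constant window runs: one run of full length per line
  rl <- glrlm_features(const, 4)
  expect_equal(unname(rl["RP"]),
               sum(ceusradiomics:::glrlm_pooled(const, 4)) / (4 * 441))
  # single-column alternation: all horizontal runs are length 1
  alt <- matrix(rep(c(1L, 2L), length.out = 21), 21, 21, byrow = FALSE)
  rl_alt <- glrlm_features(alt, 2)
  expect_true(rl_alt["RP"] > rl["RP"])
  expect_true(rl["RP"] > 0 && rl["RP"] <= 1)
  expect_true(rl_alt["RP"] > 0 && rl_alt["RP"] <= 1)

  # constant window zones: one zone of size 441
  z <- glszm_features(const, 4)
  expect_equal(unname(z["ZP"]), 1 / 441)
  expect_equal(unname(z["LZE"]), 441^2)
  # under 8-connectivity a two-level checkerboard is two diagonal zones
  rows <- matrix(seq_len(20), 20, 20)
  cb <- ((rows + t(rows)) %% 2L) + 1L
  zcb <- ceusradiomics:::glszm_zones(cb)
  expect_equal(nrow(zcb), 2)
  # a 4-level tiling has no same-level neighbors: every zone is a pixel
  tile <- matrix(0L, 20, 20)
  tile[] <- ifelse(rows %% 2 == 1, ((t(rows) %% 2) + 1L),
                   ((t(rows) %% 2) + 3L))
  zc <- glszm_features(tile, 4)
  expect_equal(unname(zc["SZE"]), 1)
  expect_equal(unname(zc["ZP"]), 1)
  # zone sizes always partition the window
  set.seed(4)
  qr <- matrix(sample.int(3, 100, replace = TRUE), 10, 10)
  expect_equal(sum(ceusradiomics:::glszm_zones(qr)[, 2]), 100)

  # NGTDM: constant window hits the epsilon guard
  n <- ngtdm_features(const, 4)
  expect_equal(unname(n["Coarseness"]), 1e6)
  expect_equal(unname(n["Contrast"]), 0)
  # level shift leaves NGTDM contrast unchanged
  set.seed(6)
  q5 <- matrix(sample.int(3, 25, replace = TRUE), 5, 5)
  expect_equal(unname(ngtdm_features(q5, 5)["Contrast"]),
               unname(ngtdm_features(q5 + 1L, 5)["Contrast"]))
})

test_that("NGTDM matches a hand-worked 5x5 two-level step", {
  q <- matrix(1L, 5, 5)
  q[, 4:5] <- 2L
  # interior pixels: 9; by hand, column 2 neighbors all level 1;
  # column 3 has 3 of 8 neighbors at level 2; column 4 has 5 of 8
  n_i <- c(6, 3)
  s_i <- c(3 * abs(1 - (5 + 3 * 2) / 8), 3 * abs(2 - (3 + 5 * 2) / 8))
  got <- ngtdm_features(q, 2)
  N <- 9; p <- n_i / N
  coarseness <- 1 / (1e-6 + sum(p * s_i))
  contrast <- (p[1] * p[2] * 2 / 2) * sum(s_i) / N
  expect_equal(unname(got["Coarseness"]), coarseness)
  expect_equal(unname(got["Contrast"]), contrast)
})

test_that("moving-window maps tile the ROI on the stride grid", {
  # ROI side 200 with window 21, stride 3: a 60 x 60 grid
  expect_equal(floor((200 - 21) / 3) + 1, 60)
  set.seed(10)
  frame <- matrix(runif(60 * 60), 60, 60)
  m <- disk_mask(60, 60, c(30, 30), 6)
  roi <- square_roi(lesion_annotation(list(`1` = m), 1),
                    min_side = 33, max_side = 36)
  maps <- texture_map(frame, roi, window = 21, stride = 3)
  expect_length(maps, 43)
  expect_identical(names(maps), texture_feature_names())
  grid <- attr(maps, "grid")
  expect_equal(dim(grid)[1:2], rep(floor((33 - 21) / 3) + 1, 2))
  expect_equal(dim(maps[[1]]), c(33, 33))
  # constant frame: every map constant
  mapsc <- texture_map(matrix(4, 60, 60), roi)
  for (nm in names(mapsc)) {
    expect_lt(diff(range(mapsc[[nm]])), 1e-12)
  }
  expect_error(texture_map(frame, roi, window = 35), "smaller")
})

test_that("fiducial texture stacks carry the naming contract", {
  sim <- small_sim_clean()
  cine <- linearize(sim$cine)
  ann <- annotation_from_sim(sim)
  roi <- square_roi(ann, min_side = 44, max_side = 52)
  v <- valid_frames(cine, roi, 1)
  fid <- fiducial_frames(cine, roi, 1, v)
  tex <- texture_at_fiducials(cine, roi, fid)
  expect_length(tex, 129)
  expect_equal(sum(grepl("^WiIm_", names(tex))), 43)
  expect_equal(sum(grepl("^PkIm_", names(tex))), 43)
  expect_equal(sum(grepl("^WoIm_", names(tex))), 43)
  expect_true("WiIm_Global_Kurtosis" %in% names(tex))
  expect_true("PkIm_GLCM_Energy" %in% names(tex))
  # identical wash-in and peak frames give identical maps
  fid2 <- fid
  fid2$wash_in <- fid2$peak
  tex2 <- texture_at_fiducials(cine, roi, fid2)
  expect_equal(unname(tex2[["WiIm_GLCM_Energy"]]),
               unname(tex2[["PkIm_GLCM_Energy"]]))
})
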
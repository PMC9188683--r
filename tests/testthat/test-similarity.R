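test_that("ring kernel offsets match brute-force enumeration", {
  k <- build_ring_kernel(0.5, 1, 2.5)
  # brute force: every displacement on a generous grid
  grid <- expand.grid(dr = -20:20, dc = -20:20)
  d <- sqrt(grid$dr^2 + grid$dc^2) * 0.5
  expected <- grid[d > 1 & d <= 2.5, ]
  expect_equal(nrow(k$offsets), nrow(expected))
  have <- paste(k$offsets[, 1], k$offsets[, 2])
  want <- paste(expected$dr, expected$dc)
  expect_setequal(have, want)
  # pixel distances in (2, 5] px
  dist_px <- sqrt(rowSums(k$offsets^2))
  expect_true(all(dist_px > 2 & dist_px <= 5))
})

test_that("degenerate ring kernels are rejected, small rings recovered", {
  # r_in 0, r_out = one pixel: the 4-neighborhood, center excluded
  k <- build_ring_kernel(1, 0, 1)
  expect_setequal(paste(k$offsets[, 1], k$offsets[, 2]),
                  c("-1 0", "1 0", "0 -1", "0 1"))
  expect_error(build_ring_kernel(1, 2.5, 1), "r_in < r_out")
  expect_error(build_ring_kernel(10, 1, 2.5), "empty ring")
})

test_that("speckle regularization smooths but preserves mass and edges", {
  const <- matrix(5, 30, 30)
  expect_equal(speckle_regularize(const), const)
  set.seed(3)
  noisy <- matrix(rgamma(900, 4, 4), 30, 30)
  reg <- speckle_regularize(noisy)
  expect_lt(var(as.vector(reg)), var(as.vector(noisy)))
  expect_lt(abs(sum(reg) - sum(noisy)) / sum(noisy), 1e-3)
  # a step edge: half-max crossing moves less than one pixel
  step <- matrix(0, 30, 30)
  step[, 16:30] <- 1
  regs <- speckle_regularize(step, iterations = 10)
  mid <- regs[15, ]
  crossing <- (max(which(mid < 0.5)) + min(which(mid >= 0.5))) / 2
  expect_lt(abs(crossing - 15.5), 1)
})

test_that("the similarity window starts at appearance and truncates", {
  times <- 0:59
  expect_identical(similarity_window(times, 12, 20), 13:33)
  expect_warning(idx <- similarity_window(times, 50, 20), "truncated")
  expect_identical(idx, 51:60)
  expect_identical(suppressWarnings(similarity_window(times, 0, 59)),
                   1:60)
})

test_that("pairwise similarity behaves on affine, identical, noise pairs", {
  set.seed(5)
  a <- bolus_tic(0:19, 1, 2, 2, 0.5) + rnorm(20, 0, 0.01)
  s <- pairwise_similarity(a, 2 * a + 3)
  expect_equal(unname(s["correlation"]), 1)
  expect_equal(unname(s["coherence"]), 1)
  # identical TICs: MI equals the binned self-entropy
  s2 <- pairwise_similarity(a, a)
  B <- ceiling(sqrt(20))
  bins <- ceiling(rank(a, ties.method = "average") * B / 20)
  pb <- table(bins) / 20
  expect_equal(unname(s2["mutual_information"]), -sum(pb * log(pb)))
  # independent white noise: r near zero against a permutation null
  set.seed(9)
  nulls <- replicate(1000, {
    cor(a, rnorm(20))
  })
  b <- rnorm(20)
  s3 <- pairwise_similarity(a, b)
  expect_lt(abs(s3["correlation"]), quantile(abs(nulls), 0.999))
  # MI of independent noise sits near the estimator's bias floor
  mi_null <- replicate(200, {
    unname(pairwise_similarity(a, rnorm(20))["mutual_information"])
  })
  expect_lt(abs(s3["mutual_information"] - median(mi_null)),
            3 * sd(mi_null) + 1e-12)
  # zero-variance input flags all three missing
  expect_true(all(is.na(pairwise_similarity(a, rep(1, 20)))))
})

test_that("similarity is invariant to a common time shift", {
  set.seed(6)
  a <- cumsum(rnorm(24)); b <- cumsum(rnorm(24))
  expect_equal(pairwise_similarity(a, b),
               pairwise_similarity(a + 7, b + 7))
})

test_that("map aggregation agrees with the scalar pairwise reference", {
  # tiny ROI, no regularization: the compiled kernel loop must equal
  # averaging pairwise_similarity() over in-bounds offsets
  set.seed(12)
  h <- 7; w <- 7; nt <- 16
  tics <- array(rnorm(h * w * nt, 10, 2), dim = c(h, w, nt))
  cine <- ceus_cine(
    bmode = array(1, dim = c(h, w, nt)) * rep(1, nt),
    ceus = tics, times = seq_len(nt) - 1, spacing_mm = 1,
    dynamic_range_db = 60
  )
  cine$linearized <- TRUE
  m <- matrix(FALSE, h, w); m[4, 4] <- TRUE
  roi <- structure(list(box = c(1L, h, 1L, w), side_px = h,
                        lesion_mask_ref = m), class = "analysis_roi")
  kernel <- build_ring_kernel(1, 0, 1.5)  # 8-neighborhood
  maps <- similarity_map_stack(cine, roi, appearance_time = 0,
                               window_s = nt - 1, kernel = kernel,
                               regularize_iterations = 0)
  # reference at the center pixel
  ref <- rowMeans(vapply(seq_len(nrow(kernel$offsets)), function(k) {
    dr <- kernel$offsets[k, 1]; dc <- kernel$offsets[k, 2]
    pairwise_similarity(tics[4, 4, ], tics[4 + dr, 4 + dc, ])
  }, numeric(3)))
  expect_equal(maps$Coherence[4, 4], unname(ref["coherence"]))
  expect_equal(maps$Correlation[4, 4], unname(ref["correlation"]))
  expect_equal(maps$MutualInformation[4, 4],
               unname(ref["mutual_information"]))
  # corner pixels have under half the kernel in-ROI: flagged missing
  expect_true(is.na(maps$Coherence[1, 1]))
})

test_that("uniform-TIC cines give coherence = correlation = 1", {
  nt <- 30
  tic <- bolus_tic(seq_len(nt) - 1, 0.5, 3, 2.2, 0.5) + 0.01
  cine <- linearize(uniform_cine(tic, h = 20, w = 20, spacing_mm = 0.5))
  # remove quantization differences: force truly identical pixel TICs
  cine$ceus <- array(rep(tic, each = 400), dim = c(20, 20, nt))
  m <- disk_mask(20, 20, c(10, 10), 3)
  roi <- square_roi(lesion_annotation(list(`1` = m), 1),
                    min_side = 16, max_side = 18)
  maps <- similarity_map_stack(cine, roi, appearance_time = 0,
                               window_s = nt - 1,
                               regularize_iterations = 0)
  inner <- maps$Coherence[6:11, 6:11]
  expect_true(all(abs(inner - 1) < 1e-9))
  expect_true(all(abs(maps$Correlation[6:11, 6:11] - 1) < 1e-9))
  expect_true(all(maps$MutualInformation >= 0, na.rm = TRUE))
})

test_that("kinetic heterogeneity inside the lesion lowers coherence", {
  cfg <- sim_config(
    n_frames = 70, frame_rate = 1, height = 72, width = 72,
    spacing_mm = 0.3, lesion_center = c(36, 36), lesion_radius_px = 14,
    lesion_jitter = list(mu_sd = 0.25, sigma_sd = 0.12, t0_sd = 2),
    motion = list(enabled = FALSE, shift_sd_px = 0, dropout_prob = 0),
    seed = 31
  )
  sim <- generate_cine(cfg)
  cine <- linearize(sim$cine)
  ann <- annotation_from_sim(sim)
  roi <- square_roi(ann, min_side = 56, max_side = 60)
  v <- valid_frames(cine, roi, 1)
  fid <- fiducial_frames(cine, roi, 1, v)
  maps <- similarity_map_stack(
    cine, roi, appearance_time = cine$times[fid$appearance_idx]
  )
  lesion <- roi$lesion_mask_ref
  coh_lesion <- mean(maps$Coherence[lesion], na.rm = TRUE)
  coh_par <- mean(maps$Coherence[!lesion], na.rm = TRUE)
  expect_lt(coh_lesion, coh_par)
})
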
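test_that("square ROI follows the sizing rule and centering", {
  # 40-px-diameter disk at (100,100): bbox side 41, margin 2 -> 82,
  # clamped up to min_side 200
  m <- disk_mask(300, 300, c(100, 100), 20)
  ann <- lesion_annotation(list(`1` = m), 1)
  roi <- square_roi(ann, margin_factor = 2, min_side = 200,
                    max_side = 278)
  expect_equal(roi$side_px, 200L)
  expect_equal(roi$center, c(100L, 100L))
  expect_equal(roi$box[2] - roi$box[1] + 1, 200)
  expect_equal(roi$box[4] - roi$box[3] + 1, 200)
  # two masks symmetric about (80, 90) center the ROI there
  m1 <- disk_mask(300, 300, c(70, 80), 8)
  m2 <- disk_mask(300, 300, c(90, 100), 8)
  ann2 <- lesion_annotation(list(`1` = m1, `2` = m2), 1)
  roi2 <- square_roi(ann2, min_side = 100, max_side = 278)
  expect_equal(roi2$center, c(80L, 90L))
  # margin factor drives the side when between the clamps
  roi3 <- square_roi(ann, margin_factor = 2, min_side = 10,
                     max_side = 278)
  expect_equal(roi3$side_px, 82L)
})

test_that("edge lesions clip the ROI with a warning", {
  m <- disk_mask(120, 120, c(12, 60), 10)
  ann <- lesion_annotation(list(`1` = m), 1)
  expect_warning(roi <- square_roi(ann, min_side = 60, max_side = 80),
                 "clipped")
  expect_gte(roi$box[1], 1)
  # a clamp too small to cover the lesion bounding box is refused
  expect_error(square_roi(lesion_annotation(
    list(`1` = disk_mask(50, 50, c(25, 25), 20)), 1),
    min_side = 20, max_side = 30), "contain")
})

test_that("valid-frame filtering matches the simulator's motion truth", {
  sim <- small_sim_clean()
  ann <- annotation_from_sim(sim)
  roi <- square_roi(ann, min_side = 44, max_side = 52)
  v <- valid_frames(sim$cine, roi, ann$ref_frame)
  expect_identical(v, seq_len(dim(sim$cine$bmode)[3]))  # motionless

  noisy <- small_sim_noisy()
  annn <- annotation_from_sim(noisy)
  roin <- square_roi(annn, min_side = 44, max_side = 52)
  vn <- valid_frames(noisy$cine, roin, annn$ref_frame)
  # every out-of-plane frame is excluded
  expect_length(intersect(vn, noisy$truth$dropout_frames), 0)

  # threshold 1: only frames identical to the reference survive
  v1 <- valid_frames(sim$cine, roi, annn$ref_frame, threshold = 1)
  expect_identical(v1, seq_len(dim(sim$cine$bmode)[3]))  # static scene
  vn1 <- valid_frames(noisy$cine, roin, 1, threshold = 1)
  crops <- noisy$cine$bmode[roin$box[1]:roin$box[2],
                            roin$box[3]:roin$box[4], ]
  same <- which(vapply(seq_len(dim(crops)[3]), function(t) {
    identical(crops[, , t], crops[, , 1])
  }, logical(1)))
  expect_identical(vn1, sort(union(same, 1L)))
})

test_that("constant reference crop is a degenerate input", {
  cine <- uniform_cine(c(0.01, 0.05, 0.2), h = 32, w = 32)
  cine$bmode[] <- 7
  m <- disk_mask(32, 32, c(16, 16), 5)
  ann <- lesion_annotation(list(`1` = m), 1)
  roi <- square_roi(ann, min_side = 20, max_side = 24)
  expect_error(valid_frames(cine, roi, 1), "constant")
})

test_that("lesion-mean TIC averages the masked pixels", {
  nt <- 12
  cine <- uniform_cine(seq(0.01, 0.12, length.out = nt), h = 16, w = 16)
  lin <- linearize(cine)
  # two-pixel mask: mean of the two TICs
  m <- matrix(FALSE, 16, 16)
  m[4, 4] <- TRUE; m[10, 11] <- TRUE
  f <- lin$ceus[4, 4, ]; g <- lin$ceus[10, 11, ]
  expect_equal(mean_tic(lin, m), (f + g) / 2)
  # uniform region: identical to any pixel TIC
  expect_equal(mean_tic(lin, matrix(TRUE, 16, 16)), f)
  expect_error(mean_tic(lin, matrix(FALSE, 16, 16)), "empty")
  expect_error(mean_tic(cine, m), "linearized")
})

test_that("fiducial selection follows the stated rules on a clean TIC", {
  # triangular lesion-mean TIC rising frames 11-31 then falling
  nt <- 70
  tic <- c(rep(0, 10), seq(0, 10, length.out = 21),
           seq(10, 2, length.out = 39))[1:nt]
  sim <- small_sim_clean()
  cine <- linearize(sim$cine)
  roi <- square_roi(annotation_from_sim(sim), min_side = 44,
                    max_side = 52)
  fid <- fiducial_frames(cine, roi, ref_frame = 1,
                         valid = seq_len(nt), tic_mean = tic,
                         smooth_window_s = 1)  # keep the TIC unsmoothed
  expect_equal(fid$peak, 31)
  expect_equal(fid$appearance_idx, which(tic >= 1)[1])
  expect_lt(fid$wash_in, fid$peak)
  expect_gt(fid$wash_out, fid$peak)
  expect_true(all(c(fid$wash_in, fid$peak, fid$wash_out) %in% fid$valid))
  # selection is invariant to affine rescaling of the TIC
  fid2 <- fiducial_frames(cine, roi, 1, seq_len(nt),
                          tic_mean = 3.7 * tic, smooth_window_s = 1)
  expect_equal(fid2[c("wash_in", "peak", "wash_out", "appearance_idx")],
               fid[c("wash_in", "peak", "wash_out", "appearance_idx")])
})

test_that("peak recovery on the simulator is within one frame", {
  sim <- small_sim_clean()
  cine <- linearize(sim$cine)
  ann <- annotation_from_sim(sim)
  roi <- square_roi(ann, min_side = 44, max_side = 52)
  v <- valid_frames(cine, roi, 1)
  fid <- fiducial_frames(cine, roi, 1, v)
  expect_lte(abs(fid$peak - sim$truth$peak_frame), 1)
})

test_that("a lone valid frame after the peak is forced as wash-out", {
  sim <- small_sim_clean()
  cine <- linearize(sim$cine)
  roi <- square_roi(annotation_from_sim(sim), min_side = 44,
                    max_side = 52)
  v <- valid_frames(cine, roi, 1)
  fid0 <- fiducial_frames(cine, roi, 1, v)
  keep <- c(v[v <= fid0$peak], fid0$peak + 12)
  fid <- fiducial_frames(cine, roi, 1, keep)
  expect_equal(fid$wash_out, fid0$peak + 12)
  # empty wash-out window errors with the stage name
  expect_error(fiducial_frames(cine, roi, 1, v[v <= fid0$peak]),
               "wash-out")
})
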
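make_test_stack <- function(frames, scale = 1) {
  structure(list(frames = frames, scale_um_per_px = scale,
                 n_frames = length(frames),
                 motion_log = NULL, field_size = dim(frames[[1]]) * scale,
                 config = NULL, seed = 0L),
            class = "frame_stack")
}

test_that("registration of identical frames yields zero shifts", {
  mos <- generate_mosaic(12000, c(120, 120), seed = 1)
  st <- render_frames(mos, render_config(noise_sd = 0, motion_sd = 0,
                                         reflectance_cv = 0, n_frames = 5))
  reg <- register_frames(st)
  expect_equal(reg$registration$dx_px, rep(0, 5))
  expect_equal(reg$registration$dy_px, rep(0, 5))
  expect_false(any(reg$registration$flagged))
})

test_that("known integer-pixel shifts are recovered exactly", {
  roll_matrix <- function(m, dy, dx) {  # circular translation of content
    ny <- nrow(m); nx <- ncol(m)
    m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
  }
  mos <- generate_mosaic(12000, c(120, 120), seed = 2)
  base <- render_frames(mos, render_config(noise_sd = 0, motion_sd = 0,
                                           reflectance_cv = 0,
                                           n_frames = 1))$frames[[1]]
  shifts <- rbind(c(0, 0), c(3, -2), c(-4, 5), c(1, 1))
  frames <- lapply(seq_len(nrow(shifts)), function(k) {
    roll_matrix(base, shifts[k, 1], shifts[k, 2])
  })
  reg <- register_frames(make_test_stack(frames))
  ref <- reg$ref_frame
  # estimates are relative to the chosen reference frame
  rel_dy <- -(shifts[, 1] - shifts[ref, 1])
  rel_dx <- -(shifts[, 2] - shifts[ref, 2])
  expect_equal(reg$registration$dy_px, rel_dy, tolerance = 1e-6)
  expect_equal(reg$registration$dx_px, rel_dx, tolerance = 1e-6)
  # applying the shifts restores alignment with the reference
  interior <- 20:100
  for (k in seq_along(frames)) {
    expect_equal(reg$frames[[k]][interior, interior],
                 reg$frames[[ref]][interior, interior], tolerance = 1e-9)
  }
})

test_that("subpixel motion is recovered within a quarter pixel", {
  mos <- generate_mosaic(12000, c(150, 150), jitter_sd = 1, seed = 3)
  st <- render_frames(mos, render_config(noise_sd = 0.01, motion_sd = 0.4,
                                         reflectance_cv = 0, n_frames = 6))
  reg <- register_frames(st)
  ref <- reg$ref_frame
  true_dx <- -(st$motion_log$dx_um - st$motion_log$dx_um[ref]) / st$scale_um_per_px
  true_dy <- -(st$motion_log$dy_um - st$motion_log$dy_um[ref]) / st$scale_um_per_px
  expect_lt(max(abs(reg$registration$dx_px - true_dx)), 0.25)
  expect_lt(max(abs(reg$registration$dy_px - true_dy)), 0.25)
})

test_that("frame selection averages the best frames and drops corrupt ones", {
  mos <- generate_mosaic(12000, c(120, 120), seed = 4)
  st <- render_frames(mos, render_config(noise_sd = 0, motion_sd = 0,
                                         reflectance_cv = 0, n_frames = 4))
  img <- select_and_average(st, keep_frac = 1)
  expect_equal(img$pixels, st$frames[[1]], tolerance = 1e-12)
  expect_equal(img$provenance$n_averaged, 4)

  # a pure-noise frame among ten is ranked last and excluded at 0.9
  st2 <- render_frames(mos, render_config(noise_sd = 0.05, motion_sd = 0,
                                          reflectance_cv = 0, n_frames = 10))
  st2$frames[[7]] <- matrix(rnorm(length(st2$frames[[7]]), sd = 0.5),
                            nrow(st2$frames[[7]]))
  img2 <- select_and_average(st2, keep_frac = 0.9)
  expect_true(7 %in% img2$provenance$excluded_frames)
  expect_equal(img2$provenance$n_averaged, 9)

  expect_warning(select_and_average(st, keep_frac = 0.1), "single best frame")
})

test_that("structureless images yield no detections", {
  flat <- image_patch(matrix(0.5, 100, 100), 1)
  expect_equal(nrow(detect_cones(flat, detection_config(threshold_quantile = 0.99))), 0)
})

test_that("detection recovers a rendered lattice and respects edits", {
  mos <- generate_mosaic(12375, c(200, 200), jitter_sd = 1.1, seed = 6)
  st <- render_frames(mos, render_config())
  img <- select_and_average(register_frames(st))
  det <- detect_cones(img)
  m <- match_points(coords_mat(mos$points), coords_mat(det), radius = 2)
  expect_gte(m$recall, 0.98)
  expect_gte(m$precision, 0.98)

  # removals then additions are applied verbatim
  kill <- coords_mat(det)[10, , drop = FALSE]
  add <- cbind(55.25, 77.75)
  det2 <- detect_cones(img, edits = edit_list(additions = add,
                                              removals = kill))
  expect_equal(nrow(det2), nrow(det))
  expect_false(any(det2$x_um == kill[1] & det2$y_um == kill[2]))
  expect_true(any(det2$x_um == add[1] & det2$y_um == add[2]))
})

test_that("detection is equivariant to whole-pixel translation and affine intensity", {
  mos <- generate_mosaic(12000, c(150, 150), jitter_sd = 1, seed = 8)
  st <- render_frames(mos, render_config(motion_sd = 0, n_frames = 1))
  img <- select_and_average(st)
  det <- detect_cones(img)

  shifted <- image_patch(conemosaic:::shift_matrix(img$pixels, 5, 3),
                         img$scale_um_per_px)
  det_s <- detect_cones(shifted, detection_config())
  # compare on the interior (points not created/destroyed at the edges)
  keep <- det$x_um > 15 & det$x_um < 135 & det$y_um > 15 & det$y_um < 135
  truth <- cbind(det$x_um[keep] + 3, det$y_um[keep] + 5)
  m <- match_points(truth, coords_mat(det_s), radius = 0.01)
  expect_equal(m$recall, 1)

  bright <- image_patch(3.7 * img$pixels + 12, img$scale_um_per_px)
  det_b <- detect_cones(bright)
  expect_equal(nrow(det_b), nrow(det))
  expect_equal(coords_mat(det_b), coords_mat(det), tolerance = 1e-6)
})

test_that("an image without scale metadata is rejected", {
  img <- image_patch(matrix(runif(100), 10), 1)
  img$scale_um_per_px <- NA_real_
  expect_error(detect_cones(img), "scale")
  expect_error(detection_config(threshold_quantile = 1), "threshold_quantile")
})
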
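test_that("load_timelapse stacks sorted frames with index-derived times", {
  dir <- withr::local_tempdir()
  for (i in 0:2) {
    img <- array(i / 255, dim = c(64, 64, 3))
    png::writePNG(img, file.path(dir, sprintf("img_%05d.png", i)))
  }
  st <- load_timelapse(dir, "img_*.png", frame_interval_h = 0.5)
  expect_s3_class(st, "timelapse")
  expect_equal(dim(st$frames), c(3L, 64L, 64L, 3L))
  expect_equal(st$times, c(0, 0.5, 1.0))
  expect_equal(st$bit_depth, 8L)
  expect_equal(unique(as.vector(st$frames[2, , , ])), 1)
})

test_that("load_timelapse reads times from a timestamps file", {
  dir <- withr::local_tempdir()
  for (i in 0:2)
    png::writePNG(array(0.1, c(8, 8, 3)),
                  file.path(dir, sprintf("f_%02d.png", i)))
  write.csv(data.frame(frame_name = sprintf("f_%02d.png", 0:2),
                       time_h = c(0, 0.7, 2.1)),
            file.path(dir, "times.csv"), row.names = FALSE)
  st <- load_timelapse(dir, "f_*.png",
                       timestamps_file = file.path(dir, "times.csv"))
  expect_equal(st$times, c(0, 0.7, 2.1))
})

test_that("load_timelapse rejects bad inputs", {
  dir <- withr::local_tempdir()
  expect_error(load_timelapse(dir, "*.png", frame_interval_h = 1),
               "no frames found")
  png::writePNG(array(0, c(64, 64, 3)), file.path(dir, "a_00.png"))
  png::writePNG(array(0, c(64, 65, 3)), file.path(dir, "a_01.png"))
  expect_error(load_timelapse(dir, "a_*.png", frame_interval_h = 1),
               "shape mismatch")
  dir2 <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 16, 16), file.path(dir2, "g_00.png"))
  expect_error(load_timelapse(dir2, "g_*.png", frame_interval_h = 1),
               "grayscale|RGB")
  expect_error(load_timelapse(dir, "a_*.png", frame_interval_h = 1,
                              timestamps_file = "x.csv"),
               "exactly one")
  # non-monotone timestamps
  dir3 <- withr::local_tempdir()
  for (i in 0:1)
    png::writePNG(array(0, c(8, 8, 3)),
                  file.path(dir3, sprintf("b_%02d.png", i)))
  write.csv(data.frame(frame_name = sprintf("b_%02d.png", 0:1),
                       time_h = c(1, 0.5)),
            file.path(dir3, "t.csv"), row.names = FALSE)
  expect_error(load_timelapse(dir3, "b_*.png",
                              timestamps_file = file.path(dir3, "t.csv")),
               "increasing")
})

test_that("written synthetic plates round-trip exactly through the loader", {
  spec <- grid_plate(2, 96, 96, spacing = 48, seed = 11, n_frames = 4,
                     Amax_rng = c(300, 400), noise_sigma = 1.5)
  rp <- render_plate(spec, quantize = TRUE)
  dir <- withr::local_tempdir()
  write_plate(rp, dir)
  st <- load_timelapse(dir, "img_*.png", frame_interval_h = 0.5)
  expect_equal(st$frames, rp$stack$frames)
  expect_equal(st$times, rp$stack$times)
  expect_equal(st$bit_depth, 8L)
  # 16-bit TIFF route
  spec16 <- plate_spec(c(32, 32), n_frames = 2, frame_interval_h = 1,
                       background = c(1000, 900, 800), noise_sigma = 20,
                       bit_depth = 16, seed = 5,
                       colonies = list(colony_spec(c(16, 16), Amax = 200,
                                                   mu_max = 0.5, t0 = 1,
                                                   KF = 50)))
  rp16 <- render_plate(spec16, quantize = TRUE)
  dir16 <- withr::local_tempdir()
  write_plate(rp16, dir16)
  st16 <- load_timelapse(dir16, "img_*.tif", frame_interval_h = 1)
  expect_equal(st16$frames, rp16$stack$frames)
  expect_equal(st16$bit_depth, 16L)
})

test_that("background subtraction removes a uniform level and clips", {
  frames <- array(10, dim = c(2, 16, 16, 3))
  st <- timelapse(frames, c(0, 1))
  out <- subtract_background(st, "first_frame_median")
  expect_true(all(out$frames == 0))
  expect_equal(out$background, c(10, 10, 10))
  expect_equal(out$times, st$times)

  # value below the estimate clips to zero
  frames[2, 3, 3, 1] <- 5
  st2 <- timelapse(frames, c(0, 1))
  out2 <- subtract_background(st2, "first_frame_median")
  expect_equal(out2$frames[2, 3, 3, 1], 0)
  out3 <- subtract_background(st2, "first_frame_median", clip = FALSE)
  expect_equal(out3$frames[2, 3, 3, 1], -5)
})

test_that("estimated background is within 1 digital level of ground truth", {
  spec <- grid_plate(2, 128, 128, spacing = 64, seed = 21, n_frames = 6,
                     Amax_rng = c(300, 500), background = c(12, 9, 6))
  rp <- render_plate(spec)   # colonies cover far below 10% of frame 0
  est <- subtract_background(rp$stack)$background
  expect_true(all(abs(est - c(12, 9, 6)) <= 1))
})

test_that("re-subtraction after correction is a no-op (idempotence)", {
  spec <- grid_plate(2, 96, 96, spacing = 48, seed = 31, n_frames = 5,
                     Amax_rng = c(300, 400))
  rp <- render_plate(spec)
  once <- subtract_background(rp$stack)
  twice <- subtract_background(once)
  # the second estimate is at most one digital level
  expect_true(all(abs(twice$background - once$background) <= 1))
  expect_true(max(abs(twice$frames - once$frames)) <= 1)
})

test_that("per-pixel temporal minimum subtraction removes static background", {
  frames <- array(0, dim = c(3, 8, 8, 3))
  static <- array(runif(8 * 8 * 3, 5, 15), dim = c(8, 8, 3))
  for (t in 1:3) frames[t, , , ] <- static + (t - 1)
  st <- timelapse(frames, 0:2)
  out <- subtract_background(st, "per_pixel_temporal_min")
  expect_equal(out$frames[1, , , ], array(0, c(8, 8, 3)))
  expect_equal(out$frames[3, , , ], array(2, c(8, 8, 3)))
})
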
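test_that("channel totals equal the per-pixel loop oracle exactly", {
  spec <- grid_plate(1, 64, 64, spacing = 64, seed = 88, n_frames = 6,
                     Amax_rng = c(500, 500), t0_rng = c(1, 1),
                     noise_sigma = 1.2)
  rp <- render_plate(spec)
  st <- subtract_background(rp$stack)
  tru <- rp$truth
  fit <- fake_fit(tru$Amax, tru$mu_max, tru$t0)
  roi <- data.frame(colony_id = 0L, row = round(tru$row),
                    col = round(tru$col), sigma = 5, half_width = 20,
                    row0 = round(tru$row) - 20, row1 = round(tru$row) + 21,
                    col0 = round(tru$col) - 20, col1 = round(tru$col) + 21)
  ct <- channel_totals(st, roi, fit)
  oracle <- channel_totals_loop_oracle(st, roi, fit,
                                       c(round(tru$row), round(tru$col)))
  expect_identical(c(ct$R_total, ct$G_total, ct$B_total), oracle)
})

test_that("uniform masks and background-only ROIs give the expected totals", {
  frames <- array(0, dim = c(2, 40, 40, 3))
  frames[, , , 1] <- 10; frames[, , , 2] <- 20
  st <- timelapse(frames, 0:1)
  fit <- fake_fit(pi * 36, 1, -5)   # radius ~6 at both frames
  roi <- data.frame(colony_id = 0L, row = 20, col = 20, sigma = 3,
                    half_width = 10, row0 = 10, row1 = 31, col0 = 10,
                    col1 = 31)
  ct <- channel_totals(st, roi, fit)
  n <- ct$R_total / 10
  expect_equal(ct$G_total, 20 * n)
  expect_equal(ct$B_total, 0)
  # background-only ROI after clipped subtraction: totals 0
  st0 <- timelapse(array(0, dim = c(2, 40, 40, 3)), 0:1)
  ct0 <- channel_totals(st0, roi, fit)
  expect_equal(c(ct0$R_total, ct0$G_total, ct0$B_total), c(0, 0, 0))
  # time_sum accumulates both frames
  ct_ts <- channel_totals(st, roi, fit, reference = "time_sum")
  expect_equal(ct_ts$R_total, 2 * ct$R_total)
})

test_that("signature fitting recovers exact and noisy slopes", {
  tot <- data.frame(colony_id = 0:4, R_total = c(1, 2, 3, 4, 5) * 100,
                    G_total = c(2, 4, 6, 8, 10) * 100,
                    B_total = 0)
  sig <- fit_signature(tot, "gfp")
  expect_equal(sig$slope, 2)
  expect_equal(sig$angle, atan(2))
  expect_equal(sig$n_colonies, 5L)
  expect_error(fit_signature(tot[1, ], "gfp"), "insufficient colonies")
  zero <- data.frame(colony_id = 0:1, R_total = 0, G_total = 0, B_total = 0)
  expect_error(fit_signature(zero, "gfp"), "insufficient colonies")
})

test_that("colonies on a signature line classify to it with zero distance", {
  sigs <- rbind(fit_signature(data.frame(R_total = 1:3, G_total = 2 * (1:3)),
                              "hi"),
                fit_signature(data.frame(R_total = 1:3, G_total = 0.5 * (1:3)),
                              "lo"))
  tot <- data.frame(colony_id = 0L, R_total = 10, G_total = 20, B_total = 0)
  cls <- classify_colonies(tot, sigs)
  expect_equal(cls$label, "hi")
  expect_equal(cls$angular_distance_rad, 0)
  expect_gt(cls$runner_up_margin_rad, 0)
})

test_that("exact ties break to the lexicographically first label", {
  sigs <- rbind(fit_signature(data.frame(R_total = 1:2, G_total = 2 * (1:2)),
                              "beta"),
                fit_signature(data.frame(R_total = 1:2, G_total = 0.5 * (1:2)),
                              "alpha"))
  # the bisector of atan(2) and atan(0.5)
  a_mid <- (atan(2) + atan(0.5)) / 2
  tot <- data.frame(colony_id = 0L, R_total = cos(a_mid) * 100,
                    G_total = sin(a_mid) * 100, B_total = 0)
  cls <- classify_colonies(tot, sigs)
  expect_equal(cls$label, "alpha")
  expect_equal(cls$runner_up_margin_rad, 0, tolerance = 1e-12)
  # zero-signal colony is unclassifiable
  tot0 <- data.frame(colony_id = 1L, R_total = 0, G_total = 0, B_total = 0)
  expect_true(is.na(classify_colonies(tot0, sigs)$label))
})

test_that("classification is invariant to brightness and signature order", {
  set.seed(5)
  sigs <- rbind(fit_signature(data.frame(R_total = 1:5,
                                         G_total = 2.5 * (1:5)), "a"),
                fit_signature(data.frame(R_total = 1:5,
                                         G_total = 1.0 * (1:5)), "b"),
                fit_signature(data.frame(R_total = 1:5,
                                         G_total = 0.35 * (1:5)), "c"))
  tot <- data.frame(colony_id = 0:9, R_total = runif(10, 50, 500),
                    G_total = runif(10, 50, 500), B_total = 0)
  base <- classify_colonies(tot, sigs)
  for (c_scale in c(0.01, 1, 137)) {
    tot2 <- tot
    tot2$R_total <- tot2$R_total * c_scale
    tot2$G_total <- tot2$G_total * c_scale
    expect_equal(classify_colonies(tot2, sigs)$label, base$label)
  }
  perm <- classify_colonies(tot, sigs[c(3, 1, 2), ])
  expect_equal(perm$label, base$label)
  expect_error(classify_colonies(tot, sigs[c(1, 1), ]), "distinct")
})

test_that("signature tables survive a CSV round trip", {
  sigs <- rbind(fit_signature(data.frame(R_total = 1:5,
                                         G_total = 2.5 * (1:5)), "a"),
                fit_signature(data.frame(R_total = 1:5,
                                         G_total = 0.4 * (1:5)), "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signatures(sigs, path)
  back <- read_signatures(path)
  expect_equal(back$label, sigs$label)
  expect_equal(back$slope, sigs$slope)
  expect_equal(back$angle, sigs$angle)
  expect_equal(back$n_colonies, sigs$n_colonies)
})

test_that("training colonies of separated signatures classify to themselves", {
  set.seed(6)
  slopes <- c(a = 2.5, b = 1.0, c = 0.35)   # pairwise angle gap >= 0.2 rad
  tots <- list(); sigs <- NULL
  for (s in names(slopes)) {
    R <- runif(8, 100, 400)
    G <- slopes[[s]] * R + rnorm(8, sd = 2)
    df <- data.frame(colony_id = seq_along(R) - 1L, R_total = R,
                     G_total = pmax(0, G), B_total = 0)
    tots[[s]] <- df
    sigs <- rbind(sigs, fit_signature(df, s))
  }
  for (s in names(slopes)) {
    cls <- classify_colonies(tots[[s]], sigs)
    expect_true(all(cls$label == s))
  }
})
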
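# Rigid-transform estimation, clap detection and clock alignment.

grid12 <- function() as.matrix(chessboard_grid(3, 4, 0.1))

test_that("identical point sets give the identity transform", {
  fit <- estimate_rigid_transform(grid12(), grid12())
  expect_lt(max(abs(fit$transform$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(fit$transform$translation)), 1e-12)
  expect_lt(fit$rmse, 1e-12)
})

test_that("a known roto-translation is recovered to 1e-9", {
  theta <- pi / 2
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3)  # 90 deg about y
  tv <- c(0.1, 0, -0.3)
  src <- grid12()
  dst <- src %*% t(R) + matrix(tv, 12, 3, byrow = TRUE)
  fit <- estimate_rigid_transform(src, dst)
  expect_lt(max(abs(fit$transform$rotation - R)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - tv)), 1e-9)
  expect_lt(fit$rmse, 1e-9)
})

test_that("recovery under 5 mm noise stays within 1 degree (Monte Carlo)", {
  sigma <- 0.005
  # 12-corner 3D target: a planar board this small cannot pin the
  # out-of-plane tilt to 1 degree at 5 mm noise
  src <- as.matrix(expand.grid(x = c(-0.3, 0.3), y = c(-0.3, 0.3),
                               z = c(-0.3, 0, 0.3)))
  for (seed in 1:100) {
    set.seed(seed)
    R <- random_rotation()
    tv <- stats::rnorm(3)
    dst <- src %*% t(R) + matrix(tv, 12, 3, byrow = TRUE) +
      matrix(stats::rnorm(36, 0, sigma), 12, 3)
    fit <- estimate_rigid_transform(src, dst)
    expect_lte(fit$rmse, 3 * sigma)
    expect_lt(rotation_angle_deg(fit$transform$rotation, R), 1)
  }
})

test_that("estimation is exactly invariant to permuting correspondences", {
  set.seed(4)
  R <- random_rotation(); tv <- stats::rnorm(3)
  src <- grid12() + matrix(stats::rnorm(36, 0, 0.2), 12, 3)
  dst <- src %*% t(R) + matrix(tv, 12, 3, byrow = TRUE) +
    matrix(stats::rnorm(36, 0, 0.01), 12, 3)
  fit1 <- estimate_rigid_transform(src, dst)
  perm <- sample(12)
  fit2 <- estimate_rigid_transform(src[perm, ], dst[perm, ])
  # invariant up to LAPACK summation order (~1e-15)
  expect_equal(fit1$transform$rotation, fit2$transform$rotation,
               tolerance = 1e-12)
  expect_equal(fit1$transform$translation, fit2$transform$translation,
               tolerance = 1e-12)
})

test_that("noiseless recovery is exact for random proper transforms", {
  set.seed(9)
  for (i in 1:20) {
    R <- random_rotation(); tv <- stats::rnorm(3, 0, 2)
    src <- matrix(stats::rnorm(30), 10, 3)
    dst <- src %*% t(R) + matrix(tv, 10, 3, byrow = TRUE)
    fit <- estimate_rigid_transform(src, dst)
    expect_lt(max(abs(fit$transform$rotation - R)), 1e-9)
    expect_lt(max(abs(fit$transform$translation - tv)), 1e-9)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(estimate_rigid_transform(line, line),
               class = "DegenerateConfiguration")
  expect_error(estimate_rigid_transform(grid12()[1:2, ], grid12()[1:2, ]),
               class = "DegenerateConfiguration")
  bad <- grid12(); bad[1, 1] <- NaN
  expect_error(estimate_rigid_transform(bad, grid12()), class = "InvalidPoint")
})

test_that("apply_transform maps streams, composes and inverts", {
  st <- const_stream(5)
  idt <- rigid_transform()
  expect_equal(apply_transform(idt, st)$pos, st$pos)
  shift <- rigid_transform(diag(3), c(1, 0, 0))
  shifted <- apply_transform(shift, st)
  expect_equal(shifted$pos[, , 1], st$pos[, , 1] + 1)
  expect_equal(shifted$pos[, , 2:3], st$pos[, , 2:3])
  expect_identical(shifted$time, st$time)
  set.seed(2)
  T1 <- rigid_transform(random_rotation(), stats::rnorm(3))
  back <- apply_transform(invert_transform(T1), apply_transform(T1, st))
  expect_lt(max(abs(back$pos - st$pos)), 1e-9)
})

test_that("missing joints stay missing through a transform", {
  st <- const_stream(3)
  st$pos[2, 1, ] <- NA
  st$state[2, 1] <- "missing"
  out <- apply_transform(rigid_transform(random_rotation(), c(1, 2, 3)), st)
  expect_true(all(is.na(out$pos[2, 1, ])))
  expect_identical(out$state, st$state)
})

test_that("detect_clap finds the first impulse at the right time", {
  rate <- 16000
  sig <- stats::rnorm(4 * rate, 0, 5e-4)
  idx <- as.integer(1.5 * rate) + seq_len(0.02 * rate)
  sig[idx] <- 0.95 * sign(stats::rnorm(length(idx)))
  expect_gte(detect_clap(sig, rate), 1.49)
  expect_lte(detect_clap(sig, rate), 1.51)
  # second impulse later is ignored ("for the first time")
  sig2 <- sig
  sig2[idx + as.integer(1.5 * rate)] <- 0.95
  expect_equal(detect_clap(sig2, rate), detect_clap(sig, rate))
  expect_error(detect_clap(numeric(1000), 16000), class = "NoClapFound")
})

test_that("detect_clap commutes with a time shift (within one window)", {
  rate <- 16000
  set.seed(21)
  sig <- stats::rnorm(2 * rate, 0, 5e-4)
  sig[rate + 1:200] <- 0.9
  shifted <- c(stats::rnorm(0.5 * rate, 0, 5e-4), sig)
  expect_lte(abs(detect_clap(shifted, rate) - (detect_clap(sig, rate) + 0.5)),
             0.010)
})

test_that("align_clocks shifts all timestamps and preserves intervals", {
  b <- generate_recording(quick_profile(), duration = 6, seed = 13)
  recB <- b$recordings$B
  sync <- list(clap_time_A = 1, clap_time_B = 3, offset = 2,
               detection_window = 0.01)
  out <- align_clocks(sync, recB)
  expect_equal(out$skeletons[[1]]$time, recB$skeletons[[1]]$time - 2)
  expect_equal(diff(out$skeletons[[1]]$time), diff(recB$skeletons[[1]]$time))
  expect_equal(out$audio_start, recB$audio_start - 2)
  expect_equal(align_clocks(list(offset = 0), recB)$image_timestamps,
               recB$image_timestamps)
})

test_that("the injected clock offset is recovered within 20 ms", {
  for (seed in c(5, 17)) {
    b <- generate_recording(quick_profile(), duration = 8, seed = seed)
    sync <- sync_from_clap(b$recordings$A, b$recordings$B)
    expect_lte(abs(sync$offset - b$ground_truth$offset_B_minus_A), 0.020)
    expect_identical(sync$offset, sync$clap_time_B - sync$clap_time_A)
  }
})

test_that("calibrate_sensor recovers each sensor's world pose", {
  b <- generate_recording(quick_profile(), duration = 6, seed = 23)
  gt_R <- matrix(unlist(b$ground_truth$sensor_A_to_world)[1:9], 3, 3,
                 byrow = TRUE)
  fit <- calibrate_sensor(b$recordings$A$calibration)
  expect_lt(rotation_angle_deg(fit$transform$rotation, gt_R), 1)
  expect_lt(fit$rmse, 0.005)
})
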
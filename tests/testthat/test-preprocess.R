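test_that("median filter matches the brute-force oracle and handles edges", {
  expect_equal(median_filter(c(0, 3, 7, 5, 0), 3), c(0, 3, 5, 5, 0))
  expect_equal(median_filter(c(4, 4, 4), 3), c(4, 4, 4))
  x <- c(2, 9, 1)
  expect_identical(median_filter(x, 1), x)
  expect_error(median_filter(x, 2), "odd")
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:80, 1)
    w <- sample(c(3, 5, 7, 9), 1)
    if (w > 2 * n + 1) w <- 3
    x <- rnorm(n)
    expect_equal(median_filter(x, w), oracle_median_filter(x, w),
                 tolerance = 1e-12)
  }
})

test_that("median filter never widens the range and is idempotent on monotone series", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(50)
    f <- median_filter(x, 5)
    expect_true(all(f >= min(x) - 1e-12 & f <= max(x) + 1e-12))
    mono <- sort(rnorm(40))
    expect_equal(median_filter(median_filter(mono, 3), 3),
                 median_filter(mono, 3))
  }
})

test_that("speed normalization collapses stationary stretches and hits the frame target", {
  # stationary 45 frames, then 5 mm/frame for 45 frames
  wrist <- rbind(matrix(rep(c(0, 0, 2), each = 45), 45),
                 cbind(0, seq(0.005, by = 0.005, length.out = 45), 2))
  sk <- make_skeleton(wrist)
  p <- preprocess_params(target_frames = 30, movement_threshold = 0.002)
  out <- normalize_speed(sk, "right", p)
  expect_equal(n_frames(out), 30)
  # stationary prefix collapses to at most one frame
  ys <- out$joints[, "wrist_r", 2]
  expect_lte(sum(ys == 0), 1)
  # frame-by-frame agreement with the brute-force trace of the rule
  idx <- oracle_normalize_indices(wrist, 0.002, 30)
  expect_equal(out$joints[, "wrist_r", ], wrist[idx, ], tolerance = 1e-12)
})

test_that("speed normalization fixed point and degenerate cases", {
  wrist <- cbind(0, seq(0, by = 0.01, length.out = 30), 2)
  sk <- make_skeleton(wrist)
  p <- preprocess_params(target_frames = 30, movement_threshold = 0.002)
  out <- normalize_speed(sk, "right", p)
  expect_equal(out$joints, sk$joints)

  still <- make_skeleton(matrix(rep(c(0, 0, 2), each = 40), 40))
  out2 <- normalize_speed(still, "right", p)
  expect_equal(n_frames(out2), 30)
  expect_equal(unique(out2$joints[, "wrist_r", 2]), 0)

  one <- make_skeleton(matrix(c(0, 0, 2), 1))
  expect_error(normalize_speed(one, "right", p), "fewer than 2")
})

test_that("speed normalization always returns exactly target_frames", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:500, 1)
    target <- sample(2:60, 1)
    wrist <- cbind(cumsum(runif(n, 0, 0.01)), rnorm(n, 0, 0.002), 2)
    sk <- make_skeleton(wrist)
    p <- preprocess_params(target_frames = target)
    out <- normalize_speed(sk, "right", p)
    expect_equal(n_frames(out), target)
    # full agreement with the brute-force trace of the two-stage rule
    idx <- oracle_normalize_indices(wrist, p$movement_threshold, target)
    expect_equal(matrix(out$joints[, "wrist_r", ], ncol = 3), wrist[idx, ],
                 tolerance = 1e-12)
  }
})

test_that("prepending stationary frames only shifts the resampling phase", {
  wrist <- cbind(0, seq(0, by = 0.01, length.out = 60), 2)
  pre <- rbind(matrix(rep(c(0, 0, 2), each = 20), 20), wrist)
  p <- preprocess_params(target_frames = 25, movement_threshold = 0.003)
  a <- normalize_speed(make_skeleton(wrist), "right", p)
  b <- normalize_speed(make_skeleton(pre), "right", p)
  expect_equal(n_frames(a), n_frames(b))
  expect_equal(a$joints[1, "wrist_r", ], b$joints[1, "wrist_r", ],
               tolerance = 1e-12)
  expect_equal(a$joints[25, "wrist_r", ], b$joints[25, "wrist_r", ],
               tolerance = 1e-12)
})

test_that("extreme wrist frame agrees with an exhaustive scan", {
  wrist <- cbind(0, c(0.1, 0.5, 0.3), 2)
  sk <- make_skeleton(wrist)
  expect_equal(find_extreme_wrist_frame(sk, "right", "highest"), 2L)
  expect_equal(find_extreme_wrist_frame(sk, "right", "lowest"), 1L)

  flat <- make_skeleton(matrix(rep(c(0, 0.2, 2), each = 6), 6))
  expect_equal(find_extreme_wrist_frame(flat, "right", "highest"), 1L)

  set.seed(13)
  y <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, 0, 0.05)
  sk2 <- make_skeleton(cbind(0, y, 2))
  expect_equal(find_extreme_wrist_frame(sk2, "right", "highest"),
               which.max(y))
  expect_equal(find_extreme_wrist_frame(sk2, "right", "lowest"),
               which.min(y))
})

test_that("limb vectors are unit length, translation invariant and rotation equivariant", {
  sk <- make_skeleton(cbind(0, seq(0, 0.3, length.out = 4), 2))
  fr <- skeleton_frame(sk, 2)
  v <- limb_vector(fr, "elbow_r", "wrist_r")
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)

  # hand-computed example: elbow (1,1,1), wrist (2,3,1)
  fr2 <- fr
  fr2$joints["elbow_r", ] <- c(1, 1, 1)
  fr2$joints["wrist_r", ] <- c(2, 3, 1)
  expect_equal(limb_vector(fr2, "elbow_r", "wrist_r"),
               c(1, 2, 0) / sqrt(5), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    shift <- rnorm(3)
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rx %*% Rz
    frt <- fr
    frt$joints <- sweep(fr$joints, 2, -shift)
    expect_equal(limb_vector(frt, "elbow_r", "wrist_r"), v,
                 tolerance = 1e-9)
    frr <- fr
    frr$joints <- fr$joints %*% t(R)
    expect_equal(limb_vector(frr, "elbow_r", "wrist_r"),
                 as.numeric(R %*% v), tolerance = 1e-9)
  }

  frc <- fr
  frc$joints["wrist_r", ] <- frc$joints["elbow_r", ]
  expect_error(limb_vector(frc, "elbow_r", "wrist_r"), "degenerate")
})

test_that("movement-end segmentation trims at the rest onset", {
  # gyro motion for 3 s then 2 s of rest, 100 Hz
  tt <- seq(0, 5, by = 0.01)
  g <- ifelse(tt < 3, 80, 0)
  b <- recording_bundle("forearm_supination", "s", "right",
                        imu = imu_trace(tt, matrix(0, length(tt), 3),
                                        cbind(g, 0, 0)))
  p <- preprocess_params(end_quiet_time = 1)
  out <- segment_movement(b, p)
  t_last <- max(out$streams$imu$timestamps)
  expect_lte(abs(t_last - 3), 0.02 + 1e-9)

  # continuous motion: unchanged
  b2 <- recording_bundle("forearm_supination", "s", "right",
                         imu = imu_trace(tt, matrix(0, length(tt), 3),
                                         cbind(rep(80, length(tt)), 0, 0)))
  out2 <- segment_movement(b2, p)
  expect_equal(length(out2$streams$imu$timestamps), length(tt))

  # all rest: trimmed to the initial quiet window
  b3 <- recording_bundle("forearm_supination", "s", "right",
                         imu = imu_trace(tt, matrix(0, length(tt), 3),
                                         matrix(0, length(tt), 3)))
  out3 <- segment_movement(b3, p)
  expect_lte(max(out3$streams$imu$timestamps), 1 + 0.02)
})

test_that("parameter validation rejects malformed preprocessing settings", {
  expect_error(preprocess_params(target_frames = 1), ">= 2")
  expect_error(preprocess_params(filter_window = 4), "odd")
  expect_error(preprocess_params(end_quiet_time = 0), "> 0")
})
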
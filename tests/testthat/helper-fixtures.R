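# Programmatic fixtures: minimal skeleton sequences, IMU/glove/pressure
# traces and separable toy datasets used across the test files.

# Skeleton with a prescribed right-wrist path; the rest of the joint chain
# is rigidly attached so limb features stay well defined.
make_skeleton <- function(wrist, rate = 30, confidence = NULL) {
  wrist <- as.matrix(wrist)
  n <- nrow(wrist)
  tt <- (seq_len(n) - 1) / rate
  jn <- c("neck", "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
          "wrist_l", "wrist_r")
  joints <- array(0, c(n, length(jn), 3), dimnames = list(NULL, jn, NULL))
  joints[, "neck", ] <- matrix(rep(c(0, 0.5, 2), each = n), n)
  joints[, "shoulder_l", ] <- matrix(rep(c(0.18, 0.47, 2), each = n), n)
  joints[, "shoulder_r", ] <- matrix(rep(c(-0.18, 0.47, 2), each = n), n)
  joints[, "elbow_l", ] <- matrix(rep(c(0.18, 0.17, 2), each = n), n)
  joints[, "wrist_l", ] <- matrix(rep(c(0.18, -0.09, 2), each = n), n)
  joints[, "elbow_r", ] <- sweep(wrist, 2, c(0, 0.26, 0), "+")
  joints[, "wrist_r", ] <- wrist
  skeleton_sequence(tt, joints, confidence, rate)
}

make_imu <- function(accel, gyro = NULL, rate = 100) {
  accel <- as.matrix(accel)
  if (ncol(accel) == 1) accel <- cbind(0 * accel, 0 * accel, accel)
  n <- nrow(accel)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  imu_trace((seq_len(n) - 1) / rate, accel, gyro)
}

make_gyro_imu <- function(gyro, rate = 100) {
  gyro <- as.matrix(gyro)
  if (ncol(gyro) == 1) gyro <- cbind(gyro, 0 * gyro, 0 * gyro)
  n <- nrow(gyro)
  imu_trace((seq_len(n) - 1) / rate, matrix(0, n, 3), gyro)
}

# Three well-separated Gaussian clusters (one per score), multiple subjects.
make_cluster_dataset <- function(n_per_class = 5, d = 3, sd = 0.01,
                                 sep = 10, seed = 1, subjects = NULL,
                                 test_id = "toy") {
  set.seed(seed)
  centers <- rbind(rep(0, d), rep(sep, d), rep(2 * sep, d))
  x <- do.call(rbind, lapply(0:2, function(k)
    matrix(rnorm(n_per_class * d, mean = centers[k + 1, 1], sd = sd),
           n_per_class, d)))
  labels <- rep(0:2, each = n_per_class)
  if (is.null(subjects))
    subjects <- rep(paste0("s", seq_len(n_per_class)), times = 3)
  colnames(x) <- paste0("f", seq_len(d))
  labeled_dataset(x, labels, subjects, test_id)
}

quiet_subject <- function() {
  subject_params(tremor_amplitude = 0, position_noise_sd = 0,
                 occlusion_rate = 0)
}
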
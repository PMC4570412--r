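# Multi-sensor data model: skeleton sequences, IMU / glove / pressure traces
# and the recording bundle that groups the streams of one test performance.

# Controlled joint vocabulary (camera frame, meters). Unknown names rejected.
JOINT_NAMES <- c("neck",
                 "shoulder_l", "shoulder_r",
                 "elbow_l", "elbow_r",
                 "wrist_l", "wrist_r",
                 "hand_l", "hand_r")

# Joints that any upper-limb skeleton must carry.
REQUIRED_JOINTS <- c("neck", "shoulder_l", "shoulder_r",
                     "elbow_l", "elbow_r", "wrist_l", "wrist_r")

CONFIDENCE_LEVELS <- c("tracked", "inferred", "missing")

SENSOR_NAMES <- c("skeleton", "imu", "glove", "pressure")

#' Construct a skeleton sequence
#'
#' A skeleton sequence holds timestamped frames of named-joint 3D positions
#' (camera frame, meters, +Y up, +Z from sensor toward subject) with a
#' per-joint tracking status.
#'
#' @param timestamps numeric vector, seconds since recording start,
#'   non-decreasing.
#' @param joints numeric array `frames x joints x 3`; `dimnames[[2]]` must be
#'   joint names from the controlled vocabulary (`neck`, `shoulder_l/r`,
#'   `elbow_l/r`, `wrist_l/r`, `hand_l/r`).
#' @param confidence character matrix `frames x joints` with entries
#'   `tracked`, `inferred` or `missing`. Defaults to all `tracked`.
#' @param nominal_rate nominal frame rate in Hz (default 30).
#' @return an object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(timestamps, joints, confidence = NULL,
                              nominal_rate = 30) {
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (!is.array(joints) || length(dim(joints)) != 3 || dim(joints)[3] != 3)
    stop("skeleton: 'joints' must be a frames x joints x 3 array")
  if (dim(joints)[1] != n)
    stop("skeleton: frame count of 'joints' must match timestamps")
  jn <- dimnames(joints)[[2]]
  if (is.null(jn))
    stop("skeleton: joint dimension must be named")
  bad <- setdiff(jn, JOINT_NAMES)
  if (length(bad))
    stop("skeleton: unknown joint name(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(REQUIRED_JOINTS, jn)
  if (length(miss))
    stop("skeleton: missing required joint(s): ", paste(miss, collapse = ", "))
  if (n > 1 && any(diff(timestamps) < 0))
    stop("skeleton: timestamps must be non-decreasing")
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1 ||
      nominal_rate <= 0)
    stop("skeleton: nominal_rate must be a positive number")
  if (is.null(confidence)) {
    confidence <- matrix("tracked", n, length(jn), dimnames = list(NULL, jn))
  }
  if (!is.matrix(confidence) || nrow(confidence) != n ||
      !identical(colnames(confidence), jn))
    stop("skeleton: confidence must be a frames x joints matrix matching 'joints'")
  if (!all(confidence %in% CONFIDENCE_LEVELS))
    stop("skeleton: confidence entries must be tracked/inferred/missing")
  tracked <- confidence != "missing"
  pos_ok <- apply(is.finite(joints), c(1, 2), all)
  if (any(tracked & !pos_ok))
    stop("skeleton: non-finite position for a joint not flagged missing")
  dimnames(joints) <- list(NULL, jn, NULL)   # canonical form
  structure(list(timestamps = timestamps, joints = joints,
                 confidence = confidence, nominal_rate = nominal_rate),
            class = "skeleton_sequence")
}

#' Number of frames in a skeleton sequence
#' @param seq a [skeleton_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$timestamps)

#' Extract one skeleton frame
#'
#' @param seq a [skeleton_sequence()].
#' @param i frame index (1-based).
#' @return list with `timestamp`, `joints` (named `joints x 3` matrix) and
#'   `confidence` (named character vector), class `skeleton_frame`.
#' @export
skeleton_frame <- function(seq, i) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (i < 1 || i > n_frames(seq)) stop("frame index out of range")
  structure(list(timestamp = seq$timestamps[i],
                 joints = seq$joints[i, , , drop = TRUE],
                 confidence = seq$confidence[i, ]),
            class = "skeleton_frame")
}

# Subset a skeleton sequence by frame indices (order preserved, duplicates
# allowed -- used by speed normalization to repeat frames).
skeleton_subset <- function(seq, idx) {
  structure(list(timestamps = seq$timestamps[idx],
                 joints = seq$joints[idx, , , drop = FALSE],
                 confidence = seq$confidence[idx, , drop = FALSE],
                 nominal_rate = seq$nominal_rate),
            class = "skeleton_sequence")
}

wrist_joint <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") "wrist_l" else "wrist_r"
}

side_joint <- function(joint, side) {
  # Resolve a side-agnostic recipe joint name ("wrist") to the recorded side.
  if (joint == "neck") return("neck")
  suffix <- if (match.arg(side, c("left", "right")) == "left") "_l" else "_r"
  paste0(joint, suffix)
}

#' Construct an IMU trace
#'
#' @param timestamps numeric vector, seconds, non-decreasing.
#' @param accel numeric matrix `n x 3` of accelerometer readings in g
#'   (columns X, Y, Z).
#' @param gyro numeric matrix `n x 3` of gyroscope readings in deg/s.
#' @param placement sensor placement, `"wrist"` or `"hand_dorsum"`.
#' @return an object of class `imu_trace`.
#' @export
imu_trace <- function(timestamps, accel, gyro, placement = "wrist") {
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (nrow(accel) != n || ncol(accel) != 3)
    stop("imu: accel must be an n x 3 matrix matching timestamps")
  if (nrow(gyro) != n || ncol(gyro) != 3)
    stop("imu: gyro must be an n x 3 matrix matching timestamps")
  if (n > 1 && any(diff(timestamps) < 0))
    stop("imu: timestamps must be non-decreasing")
  placement <- match.arg(placement, c("wrist", "hand_dorsum"))
  colnames(accel) <- c("x", "y", "z")
  colnames(gyro) <- c("x", "y", "z")
  structure(list(timestamps = timestamps, accel = accel, gyro = gyro,
                 placement = placement),
            class = "imu_trace")
}

#' Construct a glove trace
#'
#' Five finger-flexion channels of raw sensor counts (thumb to little
#' finger); larger values mean more flexed.
#'
#' @param timestamps numeric vector, seconds, non-decreasing.
#' @param flexion numeric matrix `n x 5` of raw counts in `[0, raw_max]`.
#' @param raw_max full-scale raw count (default 1023).
#' @param imu optional embedded [imu_trace()].
#' @return an object of class `glove_trace`.
#' @export
glove_trace <- function(timestamps, flexion, raw_max = 1023, imu = NULL) {
  timestamps <- as.numeric(timestamps)
  flexion <- as.matrix(flexion)
  if (ncol(flexion) != 5)
    stop("glove: flexion must have exactly 5 channels (thumb..little)")
  if (nrow(flexion) != length(timestamps))
    stop("glove: flexion length must match timestamps")
  if (length(timestamps) > 1 && any(diff(timestamps) < 0))
    stop("glove: timestamps must be non-decreasing")
  if (any(flexion < 0) || any(flexion > raw_max))
    stop("glove: flexion values must lie in [0, raw_max]")
  if (!is.null(imu) && !inherits(imu, "imu_trace"))
    stop("glove: embedded imu must be an imu_trace")
  colnames(flexion) <- c("thumb", "index", "middle", "ring", "little")
  structure(list(timestamps = timestamps, flexion = flexion,
                 raw_max = raw_max, imu = imu),
            class = "glove_trace")
}

#' Construct a pressure trace
#'
#' @param timestamps numeric vector, seconds, non-decreasing.
#' @param value numeric vector of raw sensor counts, all `>= 0`.
#' @return an object of class `pressure_trace`.
#' @export
pressure_trace <- function(timestamps, value) {
  timestamps <- as.numeric(timestamps)
  value <- as.numeric(value)
  if (length(value) != length(timestamps))
    stop("pressure: value length must match timestamps")
  if (length(timestamps) > 1 && any(diff(timestamps) < 0))
    stop("pressure: timestamps must be non-decreasing")
  if (any(value < 0))
    stop("pressure: values must be >= 0")
  structure(list(timestamps = timestamps, value = value),
            class = "pressure_trace")
}

#' Construct a recording bundle
#'
#' One test-movement performance: any subset of the four sensor streams plus
#' metadata. When a registry is supplied (the default), the streams present
#' are checked against the test's required sensors.
#'
#' @param test_id registry key of the test movement.
#' @param subject_id subject identifier.
#' @param side `"left"` or `"right"`.
#' @param skeleton,imu,glove,pressure optional sensor streams.
#' @param true_score optional generating score 0/1/2 (synthetic recordings).
#' @param registry test registry used to validate required streams, or `NULL`
#'   to skip that check.
#' @return an object of class `recording_bundle`.
#' @export
recording_bundle <- function(test_id, subject_id, side,
                             skeleton = NULL, imu = NULL, glove = NULL,
                             pressure = NULL, true_score = NULL,
                             registry = fma_registry()) {
  side <- match.arg(side, c("left", "right"))
  if (!is.null(skeleton) && !inherits(skeleton, "skeleton_sequence"))
    stop("bundle: skeleton must be a skeleton_sequence")
  if (!is.null(imu) && !inherits(imu, "imu_trace"))
    stop("bundle: imu must be an imu_trace")
  if (!is.null(glove) && !inherits(glove, "glove_trace"))
    stop("bundle: glove must be a glove_trace")
  if (!is.null(pressure) && !inherits(pressure, "pressure_trace"))
    stop("bundle: pressure must be a pressure_trace")
  if (!is.null(true_score) && !(true_score %in% 0:2))
    stop("bundle: true_score must be 0, 1 or 2")
  streams <- list(skeleton = skeleton, imu = imu, glove = glove,
                  pressure = pressure)
  streams <- streams[!vapply(streams, is.null, logical(1))]
  if (!length(streams))
    stop("bundle: at least one sensor stream is required")
  if (!is.null(registry)) {
    def <- registry_lookup(registry, test_id, error = FALSE)
    if (!is.null(def)) {
      miss <- setdiff(def$required_sensors, names(streams))
      if (length(miss))
        stop(sprintf("bundle: test '%s' requires missing sensor(s): %s",
                     test_id, paste(miss, collapse = ", ")))
    }
  }
  structure(list(test_id = as.character(test_id),
                 subject_id = as.character(subject_id),
                 side = side, streams = streams,
                 true_score = if (is.null(true_score)) NULL
                              else as.integer(true_score)),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> test=%s subject=%s side=%s\n",
              x$test_id, x$subject_id, x$side))
  for (nm in names(x$streams)) {
    s <- x$streams[[nm]]
    n <- length(s$timestamps)
    dur <- if (n) diff(range(s$timestamps)) else 0
    cat(sprintf("  %-8s %5d samples over %.2f s\n", nm, n, dur))
  }
  if (!is.null(x$true_score))
    cat("  true_score:", x$true_score, "\n")
  invisible(x)
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> %d frames, %d joints, %.0f Hz nominal\n",
              n_frames(x), dim(x$joints)[2], x$nominal_rate))
  invisible(x)
}
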
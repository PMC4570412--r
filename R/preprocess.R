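# Preprocessing: movement-speed normalization of skeleton sequences,
# extreme-wrist-frame finding, median filtering with boundary replication,
# limb unit vectors, and automatic movement-end segmentation.

#' Preprocessing parameters
#'
#' @param target_frames number of frames every skeleton sequence is resampled
#'   to before frame-based features are taken (per-test constant, `>= 2`).
#' @param movement_threshold wrist displacement (meters) between adjacent
#'   frames below which a frame counts as stationary. Default 3 mm.
#' @param filter_window odd median-filter window (samples).
#' @param end_quiet_time seconds of sub-threshold motion that terminate a
#'   movement during segmentation.
#' @param gyro_rest_threshold gyroscope magnitude (deg/s) below which an IMU
#'   sample counts as rest during segmentation.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(target_frames = 30, movement_threshold = 0.003,
                              filter_window = 5, end_quiet_time = 1,
                              gyro_rest_threshold = 5) {
  target_frames <- as.integer(target_frames)
  if (is.na(target_frames) || target_frames < 2)
    stop("preprocess: target_frames must be an integer >= 2")
  if (movement_threshold < 0)
    stop("preprocess: movement_threshold must be >= 0")
  filter_window <- as.integer(filter_window)
  if (is.na(filter_window) || filter_window < 1 || filter_window %% 2 == 0)
    stop("preprocess: filter_window must be an odd positive integer")
  if (end_quiet_time <= 0)
    stop("preprocess: end_quiet_time must be > 0")
  structure(list(target_frames = target_frames,
                 movement_threshold = movement_threshold,
                 filter_window = filter_window,
                 end_quiet_time = end_quiet_time,
                 gyro_rest_threshold = gyro_rest_threshold),
            class = "preprocess_params")
}

#' Median-filter a series with boundary replication
#'
#' Element `i` of the output is the median of the window centered at `i`;
#' windows that overhang an edge are completed by replicating the boundary
#' sample.
#'
#' @param series numeric vector.
#' @param window odd positive window length, at most `2 * length(series) + 1`.
#' @return filtered numeric vector of the same length.
#' @export
#' @examples
#' median_filter(c(0, 3, 7, 5, 0), 3)   # c(0, 3, 5, 5, 0)
median_filter <- function(series, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1 || window %% 2 == 0)
    stop("median_filter: window must be an odd positive integer")
  n <- length(series)
  if (n == 0) stop("median_filter: empty series")
  if (window > 2 * n + 1)
    stop("median_filter: window exceeds 2 * length + 1")
  if (window == 1 || n == 1) return(as.numeric(series))
  h <- (window - 1L) %/% 2L
  padded <- c(rep(series[1], h), as.numeric(series), rep(series[n], h))
  # interior of runmed over the padded series = replicated-edge medians
  sm <- stats::runmed(padded, window, endrule = "keep")
  sm[(h + 1L):(h + n)]
}

#' Find the frame where the wrist is highest or lowest
#'
#' Vertical position is the +Y camera coordinate. Frames whose wrist status
#' is `missing` are ignored; ties break to the earliest frame.
#'
#' @param seq a [skeleton_sequence()].
#' @param side `"left"` or `"right"`.
#' @param direction `"highest"` or `"lowest"`.
#' @return frame index into `seq`.
#' @export
find_extreme_wrist_frame <- function(seq, side,
                                     direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  wj <- wrist_joint(side)
  ok <- seq$confidence[, wj] != "missing"
  if (!any(ok)) stop("find_extreme_wrist_frame: no tracked wrist frames")
  y <- seq$joints[, wj, 2]
  y[!ok] <- NA
  idx <- if (direction == "highest") which.max(y) else which.min(y)
  as.integer(idx)
}

#' Normalize movement speed of a skeleton sequence
#'
#' Two-stage rule. Stage 1 removes frames whose wrist has moved less than
#' `movement_threshold` from the previously retained frame, so playback
#' appears at a uniform, sped-up pace. Stage 2 resamples to exactly
#' `target_frames` frames by deleting or repeating frames at even intervals;
#' the first and last retained postures are always preserved. Frames whose
#' wrist status is `missing` are dropped before stage 1.
#'
#' @param seq a [skeleton_sequence()].
#' @param side `"left"` or `"right"` (selects the reference wrist).
#' @param params a [preprocess_params()].
#' @return a [skeleton_sequence()] with exactly `params$target_frames` frames.
#' @export
normalize_speed <- function(seq, side, params = preprocess_params()) {
  wj <- wrist_joint(side)
  usable <- which(seq$confidence[, wj] != "missing")
  if (length(usable) < 2)
    stop("normalize_speed: fewer than 2 frames with a tracked wrist")
  seq <- skeleton_subset(seq, usable)
  pos <- matrix(seq$joints[, wj, ], ncol = 3)
  n <- nrow(pos)
  keep <- integer(n)
  keep[1] <- 1L
  m <- 1L
  last <- 1L
  for (i in 2:n) {
    d <- sqrt(sum((pos[i, ] - pos[last, ])^2))
    if (d >= params$movement_threshold) {
      m <- m + 1L
      keep[m] <- i
      last <- i
    }
  }
  keep <- keep[seq_len(m)]
  out <- skeleton_subset(seq, keep)
  skeleton_subset(out, resample_indices(m, params$target_frames))
}

# Even-interval resampling to `target` frames: repeatedly delete (or repeat)
# every floor(n/k)-th frame starting at index floor(n/(2k)), k = |n - target|,
# never touching the first or last frame on deletion. Deterministic.
resample_indices <- function(n, target) {
  idx <- seq_len(n)
  while (length(idx) > target) {
    m <- length(idx)
    k <- m - target
    step <- max(1L, m %/% k)
    start <- (m %/% (2L * k)) + 1L
    cand <- seq.int(start, m, by = step)
    cand <- cand[cand != 1L & cand != m]
    if (!length(cand)) cand <- 2L
    cand <- cand[seq_len(min(k, length(cand)))]
    idx <- idx[-cand]
  }
  while (length(idx) < target) {
    m <- length(idx)
    k <- target - m
    step <- max(1L, m %/% k)
    start <- min((m %/% (2L * k)) + 1L, m)
    cand <- seq.int(start, m, by = step)
    cand <- cand[seq_len(min(k, length(cand)))]
    pos <- sort(c(seq_len(m), cand))
    idx <- idx[pos]
  }
  idx
}

#' Limb unit vector between two joints
#'
#' Represents the limb from `proximal` to `distal` as a 3D unit vector
#' (normalized to remove variation from noise or differing subject heights).
#'
#' @param frame a [skeleton_frame()].
#' @param proximal,distal joint names present in the frame.
#' @return numeric length-3 unit vector.
#' @export
#' @examples
#' fr <- structure(list(
#'   joints = rbind(elbow_r = c(0, 0, 0), wrist_r = c(0, 2, 0)),
#'   confidence = c(elbow_r = "tracked", wrist_r = "tracked")),
#'   class = "skeleton_frame")
#' limb_vector(fr, "elbow_r", "wrist_r")   # c(0, 1, 0)
limb_vector <- function(frame, proximal, distal) {
  jn <- rownames(frame$joints)
  for (j in c(proximal, distal)) {
    if (!(j %in% jn))
      stop("limb_vector: joint not present: ", j)
    if (identical(unname(frame$confidence[j]), "missing"))
      stop("limb_vector: joint missing in frame: ", j)
  }
  v <- frame$joints[distal, ] - frame$joints[proximal, ]
  len <- sqrt(sum(v^2))
  if (len < 1e-12)
    stop("limb_vector: degenerate limb, joints coincide: ",
         proximal, " / ", distal)
  unname(v / len)
}

#' Trim a recording at the detected end of movement
#'
#' Finds the first instant after which the motion signal -- wrist speed for
#' skeleton streams, gyroscope magnitude for IMU streams -- stays below the
#' movement threshold for `end_quiet_time` seconds, and trims all streams
#' there (an initial all-rest recording is trimmed to the first quiet
#' window). Returns the bundle unchanged when no such instant exists.
#'
#' @param bundle a [recording_bundle()].
#' @param params a [preprocess_params()].
#' @return the trimmed [recording_bundle()].
#' @export
segment_movement <- function(bundle, params = preprocess_params()) {
  t_end <- NULL
  sk <- bundle$streams$skeleton
  if (!is.null(sk) && n_frames(sk) > 2) {
    wj <- wrist_joint(bundle$side)
    ok <- sk$confidence[, wj] != "missing"
    idx <- which(ok)
    if (length(idx) > 2) {
      pos <- matrix(sk$joints[idx, wj, ], ncol = 3)
      tt <- sk$timestamps[idx]
      disp <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-nrow(pos), , drop = FALSE])^2))
      dt <- pmax(diff(tt), 1e-9)
      speed <- disp / dt                       # m/s
      thr <- params$movement_threshold * sk$nominal_rate
      t_end <- quiet_onset(tt[-1], speed < thr, params$end_quiet_time)
    }
  }
  if (is.null(t_end)) {
    im <- bundle$streams$imu
    if (!is.null(im) && length(im$timestamps) > 2) {
      mag <- sqrt(rowSums(im$gyro^2))
      t_end <- quiet_onset(im$timestamps, mag < params$gyro_rest_threshold,
                           params$end_quiet_time)
    }
  }
  if (is.null(t_end)) return(bundle)
  cut <- max(t_end, params$end_quiet_time)
  trim <- function(s) {
    keep <- s$timestamps <= cut + 1e-9
    if (all(keep) || sum(keep) < 2) return(s)
    if (inherits(s, "skeleton_sequence")) skeleton_subset(s, which(keep))
    else if (inherits(s, "imu_trace"))
      imu_trace(s$timestamps[keep], s$accel[keep, , drop = FALSE],
                s$gyro[keep, , drop = FALSE], s$placement)
    else if (inherits(s, "glove_trace"))
      glove_trace(s$timestamps[keep], s$flexion[keep, , drop = FALSE],
                  s$raw_max, s$imu)
    else pressure_trace(s$timestamps[keep], s$value[keep])
  }
  bundle$streams <- lapply(bundle$streams, trim)
  bundle
}

# Earliest time t* such that `quiet` holds for every sample in
# [t*, t* + quiet_time]; NULL when no quiet run is long enough.
quiet_onset <- function(times, quiet, quiet_time) {
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(times)
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    t0 <- times[starts[k]]
    t1 <- times[ends[k]]
    # a run reaching the end of the trace counts if it spans quiet_time
    if (t1 - t0 >= quiet_time) return(t0)
  }
  NULL
}
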
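# Feature-extraction primitives and per-test feature assembly. Each test
# movement owns a declarative recipe (an ordered list of primitive calls);
# the resulting values are concatenated into one feature vector that feeds
# the classifier. Feature values are deliberately left unscaled.

#' Angle between two limb unit vectors
#'
#' `theta = arccos(S . I)` for the superior limb vector `S` and the inferior
#' limb vector `I` (e.g. upper arm and forearm for the elbow angle). The dot
#' product is clamped to `[-1, 1]` to absorb rounding.
#'
#' @param S,I unit 3-vectors (length 1 within 1e-6).
#' @return the joint angle in radians, in `[0, pi]`.
#' @export
#' @examples
#' joint_angle(c(1, 0, 0), c(0.6, 0.8, 0))   # acos(0.6)
joint_angle <- function(S, I) {
  if (length(S) != 3 || length(I) != 3)
    stop("joint_angle: inputs must be 3-vectors")
  if (abs(sqrt(sum(S^2)) - 1) > 1e-6 || abs(sqrt(sum(I^2)) - 1) > 1e-6)
    stop("joint_angle: inputs must be unit vectors")
  acos(min(1, max(-1, sum(S * I))))
}

#' Rotation range from the Z accelerometer
#'
#' Quantifies supination/pronation (and wrist circumduction or dorsiflexion)
#' range as the max-minus-min of the median-filtered Z accelerometer channel:
#' as the forearm rotates, gravity sweeps across the sensor Z axis.
#'
#' @param trace an [imu_trace()].
#' @param window odd median-filter window.
#' @return range in g, `>= 0`; invariant to constant offsets.
#' @export
rotation_range <- function(trace, window = 5) {
  stopifnot(inherits(trace, "imu_trace"))
  if (!length(trace$timestamps)) stop("rotation_range: empty trace")
  z <- median_filter(trace$accel[, 3], window)
  max(z) - min(z)
}

#' Movement smoothness (shakiness) statistic
#'
#' Compares the accelerometer channels with a median-filtered version of
#' themselves: the summed absolute difference is higher for shaky movements
#' and zero for constant signals.
#'
#' @param trace an [imu_trace()].
#' @param window odd median-filter window.
#' @return nonnegative shakiness statistic (g-sample units).
#' @export
smoothness <- function(trace, window = 5) {
  stopifnot(inherits(trace, "imu_trace"))
  if (!length(trace$timestamps)) stop("smoothness: empty trace")
  tot <- 0
  for (j in 1:3) {
    raw <- trace$accel[, j]
    tot <- tot + sum(abs(raw - median_filter(raw, window)))
  }
  tot
}

#' Amount of movement from the gyroscope
#'
#' Establishes a per-axis resting value from the initial rest window (the
#' median of the absolute gyroscope readings), then integrates the part of
#' `|gyro|` above that baseline over time, summed across the three axes.
#' Useful when the skeleton view is partly occluded.
#'
#' @param trace an [imu_trace()] beginning with at least `rest_window`
#'   seconds of rest.
#' @param rest_window baseline-estimation window in seconds (default 0.5).
#' @return integrated angular excursion proxy in degrees; 0 for all-rest.
#' @export
movement_amount <- function(trace, rest_window = 0.5) {
  stopifnot(inherits(trace, "imu_trace"))
  tt <- trace$timestamps
  if (length(tt) < 2 || tt[length(tt)] - tt[1] <= rest_window)
    stop("movement_amount: trace shorter than the rest window")
  rest <- tt <= tt[1] + rest_window
  tot <- 0
  for (j in 1:3) {
    g <- abs(trace$gyro[, j])
    base <- stats::median(g[rest])
    y <- pmax(0, g - base)
    tot <- tot + trapezoid(tt, y)
  }
  tot
}

# composite trapezoid rule
trapezoid <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Grip strength from a pressure trace
#'
#' @param trace a [pressure_trace()].
#' @param window odd median-filter window.
#' @return maximum of the median-filtered series (raw counts).
#' @export
grip_strength <- function(trace, window = 5) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (!length(trace$timestamps)) stop("grip_strength: empty trace")
  max(median_filter(trace$value, window))
}

#' Finger flexion/extension state
#'
#' Median-filters each of the five flexion channels, locates the sample where
#' the fingers are most flexed (maximal filtered channel sum) or most
#' extended (minimal sum; ties break to the earliest sample) and returns the
#' five filtered values at that point.
#'
#' @param trace a [glove_trace()].
#' @param mode `"flexion"` or `"extension"`.
#' @param window odd median-filter window.
#' @return named numeric 5-vector of raw counts (thumb..little).
#' @export
finger_state <- function(trace, mode = c("flexion", "extension"), window = 5) {
  stopifnot(inherits(trace, "glove_trace"))
  mode <- match.arg(mode)
  if (ncol(trace$flexion) != 5)
    stop("finger_state: glove must have 5 channels")
  filt <- apply(trace$flexion, 2, median_filter, window = window)
  if (is.null(dim(filt))) filt <- matrix(filt, nrow = 1)
  s <- rowSums(filt)
  i <- if (mode == "flexion") which.max(s) else which.min(s)
  stats::setNames(filt[i, ], colnames(trace$flexion))
}

# Dimensionality of each recipe primitive.
PRIMITIVE_DIMS <- c(joint_angle = 1L, limb_orientation = 3L,
                    rotation_range = 1L, smoothness = 1L,
                    movement_amount = 1L, grip_strength = 1L,
                    finger_state = 5L)

recipe_dimension <- function(recipe) {
  sum(vapply(recipe, function(e) PRIMITIVE_DIMS[[e$feature]], integer(1)))
}

# Drop skeleton frames in which any upper-limb joint of the recorded side is
# occluded (status "missing"); angle features need the full joint chain.
drop_occluded_frames <- function(seq, side) {
  need <- c("neck", side_joint("shoulder", side), side_joint("elbow", side),
            side_joint("wrist", side))
  need <- intersect(need, colnames(seq$confidence))
  ok <- rowSums(seq$confidence[, need, drop = FALSE] == "missing") == 0
  if (!any(ok)) stop("extract_features: all frames occluded")
  if (all(ok)) seq else skeleton_subset(seq, which(ok))
}

#' Extract the feature vector for a test recording
#'
#' Runs preprocessing (movement-end segmentation; speed normalization when
#' the recipe uses skeleton frames), evaluates the test's recipe -- an
#' ordered list of primitive feature calls, frame-based primitives evaluated
#' at their designated frame (e.g. the extreme-wrist frame) -- and
#' concatenates the results.
#'
#' @param bundle a [recording_bundle()].
#' @param test a test definition from [fma_registry()], or a test id.
#' @param params preprocessing parameter overrides; defaults to the test's
#'   own parameters.
#' @param registry registry used to resolve `test` when it is an id.
#' @return an object of class `feature_vector` with fields `values`, `names`
#'   and `test_id`.
#' @export
extract_features <- function(bundle, test = NULL, params = NULL,
                             registry = fma_registry()) {
  if (is.null(test)) test <- bundle$test_id
  if (is.character(test)) test <- registry_lookup(registry, test)
  if (!length(test$recipe)) stop("extract_features: empty recipe")
  miss <- setdiff(test$required_sensors, names(bundle$streams))
  if (length(miss))
    stop(sprintf("extract_features: test '%s' requires missing stream(s): %s",
                 test$test_id, paste(miss, collapse = ", ")))
  if (is.null(params)) params <- test$preprocess
  bundle <- segment_movement(bundle, params)
  side <- bundle$side

  uses_skeleton <- any(vapply(test$recipe, function(e)
    e$feature %in% c("joint_angle", "limb_orientation"), logical(1)))
  sk <- NULL
  if (uses_skeleton) {
    if (is.null(bundle$streams$skeleton))
      stop("extract_features: recipe needs a skeleton stream")
    sk <- drop_occluded_frames(bundle$streams$skeleton, side)
    sk <- normalize_speed(sk, side, params)
  }

  frame_at <- function(which_frame) {
    idx <- switch(which_frame,
      extreme_high = find_extreme_wrist_frame(sk, side, "highest"),
      extreme_low = find_extreme_wrist_frame(sk, side, "lowest"),
      first = 1L,
      last = n_frames(sk),
      stop("extract_features: unknown recipe frame: ", which_frame))
    skeleton_frame(sk, idx)
  }

  values <- numeric(0)
  labels <- character(0)
  for (e in test$recipe) {
    v <- switch(e$feature,
      joint_angle = {
        fr <- frame_at(e$frame)
        vertex <- e$vertex
        if (vertex == "elbow") {
          S <- limb_vector(fr, side_joint("shoulder", side),
                           side_joint("elbow", side))
          I <- limb_vector(fr, side_joint("elbow", side),
                           side_joint("wrist", side))
        } else if (vertex == "shoulder") {
          S <- limb_vector(fr, "neck", side_joint("shoulder", side))
          I <- limb_vector(fr, side_joint("shoulder", side),
                           side_joint("elbow", side))
        } else stop("extract_features: unknown angle vertex: ", vertex)
        stats::setNames(joint_angle(S, I),
                        paste0(vertex, "_angle_", e$frame))
      },
      limb_orientation = {
        fr <- frame_at(e$frame)
        joints <- switch(e$limb,
          upper_arm = c(side_joint("shoulder", side),
                        side_joint("elbow", side)),
          forearm = c(side_joint("elbow", side), side_joint("wrist", side)),
          stop("extract_features: unknown limb: ", e$limb))
        stats::setNames(limb_vector(fr, joints[1], joints[2]),
                        paste0(e$limb, "_", c("x", "y", "z")))
      },
      rotation_range = {
        need_stream(bundle, "imu", test$test_id)
        c(rotation_range = rotation_range(bundle$streams$imu,
                                          recipe_window(e, params)))
      },
      smoothness = {
        need_stream(bundle, "imu", test$test_id)
        c(smoothness = smoothness(bundle$streams$imu,
                                  recipe_window(e, params)))
      },
      movement_amount = {
        need_stream(bundle, "imu", test$test_id)
        c(movement_amount = movement_amount(bundle$streams$imu))
      },
      grip_strength = {
        need_stream(bundle, "pressure", test$test_id)
        c(grip_strength = grip_strength(bundle$streams$pressure,
                                        recipe_window(e, params)))
      },
      finger_state = {
        need_stream(bundle, "glove", test$test_id)
        v <- finger_state(bundle$streams$glove, e$mode,
                          recipe_window(e, params))
        stats::setNames(v, paste0("finger_", e$mode, "_", names(v)))
      },
      stop("extract_features: unknown recipe primitive: ", e$feature))
    values <- c(values, unname(v))
    labels <- c(labels, names(v))
  }
  if (!all(is.finite(values)))
    stop("extract_features: non-finite feature value")
  structure(list(values = values, names = labels, test_id = test$test_id),
            class = "feature_vector")
}

recipe_window <- function(e, params) {
  if (!is.null(e$window)) e$window else params$filter_window
}

need_stream <- function(bundle, stream, test_id) {
  if (is.null(bundle$streams[[stream]]))
    stop(sprintf("extract_features: test '%s' recipe needs stream '%s'",
                 test_id, stream))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> test=%s dim=%d\n", x$test_id,
              length(x$values)))
  print(stats::setNames(x$values, x$names))
  invisible(x)
}

#' Assemble feature vectors into a matrix
#'
#' @param fvs list of `feature_vector` objects of one test.
#' @return numeric matrix, one row per recording, columns named by feature.
#' @export
feature_matrix <- function(fvs) {
  stopifnot(length(fvs) > 0)
  d <- length(fvs[[1]]$values)
  if (!all(vapply(fvs, function(f) length(f$values), integer(1)) == d))
    stop("feature_matrix: inconsistent feature dimensions")
  m <- do.call(rbind, lapply(fvs, function(f) f$values))
  colnames(m) <- fvs[[1]]$names
  m
}
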
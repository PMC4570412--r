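# Recording container I/O. One JSON document per recording (metadata block
# plus one block per stream), or a directory of per-stream CSVs with a
# meta.json sidecar. All timestamps are seconds relative to recording start.

CONTAINER_FORMAT <- "fma-recording"
CONTAINER_VERSION <- 1L

#' Write a recording bundle to disk
#'
#' Serializes a validated [recording_bundle()] either as a single JSON
#' document (default) or as a directory of per-stream CSV files with a
#' `meta.json` sidecar. Floats are written at full precision so that
#' [read_recording()] reproduces the bundle field-for-field.
#'
#' @param bundle a [recording_bundle()].
#' @param path output file (JSON) or directory (CSV).
#' @param format `"json"` or `"csv"`; defaults to `"csv"` when `path` is an
#'   existing directory or has no `.json` extension and `format` is missing.
#' @return `path`, invisibly.
#' @export
write_recording <- function(bundle, path, format = c("json", "csv")) {
  if (!inherits(bundle, "recording_bundle"))
    stop("write_recording: not a recording_bundle")
  if (!length(bundle$streams))
    stop("write_recording: bundle has no streams")
  format <- if (missing(format) && (dir.exists(path) || !grepl("\\.json$", path)))
    "csv" else match.arg(format)
  if (format == "json") write_recording_json(bundle, path)
  else write_recording_csv(bundle, path)
  invisible(path)
}

write_recording_json <- function(bundle, path) {
  streams <- list()
  sk <- bundle$streams$skeleton
  if (!is.null(sk)) {
    jn <- dimnames(sk$joints)[[2]]
    streams$skeleton <- list(
      nominal_rate = sk$nominal_rate,
      joint_names = jn,
      timestamps = sk$timestamps,
      positions = setNames(lapply(jn, function(j)
        matrix(sk$joints[, j, ], ncol = 3)), jn),
      confidence = setNames(lapply(jn, function(j)
        unname(sk$confidence[, j])), jn))
  }
  im <- bundle$streams$imu
  if (!is.null(im))
    streams$imu <- list(placement = im$placement,
                        timestamps = im$timestamps,
                        accel = unname(im$accel), gyro = unname(im$gyro))
  gl <- bundle$streams$glove
  if (!is.null(gl))
    streams$glove <- list(raw_max = gl$raw_max,
                          timestamps = gl$timestamps,
                          flexion = unname(gl$flexion))
  pr <- bundle$streams$pressure
  if (!is.null(pr))
    streams$pressure <- list(timestamps = pr$timestamps, value = pr$value)
  doc <- list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
              test_id = bundle$test_id, subject_id = bundle$subject_id,
              side = bundle$side, true_score = bundle$true_score,
              streams = streams)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE, null = "null")
}

write_recording_csv <- function(bundle, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta <- list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
               test_id = bundle$test_id, subject_id = bundle$subject_id,
               side = bundle$side, true_score = bundle$true_score)
  sk <- bundle$streams$skeleton
  if (!is.null(sk)) {
    meta$skeleton_nominal_rate <- sk$nominal_rate
    jn <- dimnames(sk$joints)[[2]]
    df <- data.frame(timestamp = sk$timestamps)
    for (j in jn) {
      df[[paste0(j, "_x")]] <- sk$joints[, j, 1]
      df[[paste0(j, "_y")]] <- sk$joints[, j, 2]
      df[[paste0(j, "_z")]] <- sk$joints[, j, 3]
      df[[paste0(j, "_status")]] <- sk$confidence[, j]
    }
    write.csv(df, file.path(path, "skeleton.csv"), row.names = FALSE)
  }
  im <- bundle$streams$imu
  if (!is.null(im)) {
    meta$imu_placement <- im$placement
    df <- data.frame(timestamp = im$timestamps,
                     accel_x = im$accel[, 1], accel_y = im$accel[, 2],
                     accel_z = im$accel[, 3],
                     gyro_x = im$gyro[, 1], gyro_y = im$gyro[, 2],
                     gyro_z = im$gyro[, 3])
    write.csv(df, file.path(path, "imu.csv"), row.names = FALSE)
  }
  gl <- bundle$streams$glove
  if (!is.null(gl)) {
    meta$glove_raw_max <- gl$raw_max
    df <- data.frame(timestamp = gl$timestamps)
    df[colnames(gl$flexion)] <- as.data.frame(gl$flexion)
    write.csv(df, file.path(path, "glove.csv"), row.names = FALSE)
  }
  pr <- bundle$streams$pressure
  if (!is.null(pr))
    write.csv(data.frame(timestamp = pr$timestamps, value = pr$value),
              file.path(path, "pressure.csv"), row.names = FALSE)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Read a recording bundle from disk
#'
#' Accepts either the JSON container written by [write_recording()] or a
#' directory of per-stream CSVs with a `meta.json` sidecar. Every malformed
#' input yields a diagnostic error naming the offending stream; a bundle is
#' only returned after full validation.
#'
#' @param path container file or directory.
#' @param registry registry used to validate required streams (`NULL` skips).
#' @return a [recording_bundle()].
#' @export
read_recording <- function(path, registry = fma_registry()) {
  if (dir.exists(path)) read_recording_csv(path, registry)
  else if (file.exists(path)) read_recording_json(path, registry)
  else stop("read_recording: no such file or directory: ", path)
}

stream_ctx <- function(stream, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("read_recording: stream '%s': %s", stream,
                 conditionMessage(e)), call. = FALSE))
}

read_recording_json <- function(path, registry) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("read_recording: malformed JSON container: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, CONTAINER_FORMAT))
    stop("read_recording: not an ", CONTAINER_FORMAT, " container")
  st <- doc$streams
  skeleton <- imu <- glove <- pressure <- NULL
  if (!is.null(st$skeleton)) skeleton <- stream_ctx("skeleton", {
    s <- st$skeleton
    jn <- s$joint_names
    n <- length(s$timestamps)
    joints <- array(NA_real_, c(n, length(jn), 3),
                    dimnames = list(NULL, jn, c("x", "y", "z")))
    conf <- matrix("tracked", n, length(jn), dimnames = list(NULL, jn))
    for (j in jn) {
      pos <- s$positions[[j]]
      if (is.null(pos)) stop("no positions for joint ", j)
      pos <- matrix(as.numeric(pos), ncol = 3)
      if (nrow(pos) != n) stop("position count mismatch for joint ", j)
      joints[, j, ] <- pos
      conf[, j] <- s$confidence[[j]]
    }
    skeleton_sequence(s$timestamps, joints, conf, s$nominal_rate)
  })
  if (!is.null(st$imu)) imu <- stream_ctx("imu", {
    s <- st$imu
    imu_trace(s$timestamps, matrix(as.numeric(s$accel), ncol = 3),
              matrix(as.numeric(s$gyro), ncol = 3), s$placement)
  })
  if (!is.null(st$glove)) glove <- stream_ctx("glove", {
    s <- st$glove
    fx <- s$flexion
    if (is.null(dim(fx))) fx <- matrix(fx, nrow = length(s$timestamps))
    if (ncol(fx) != 5) stop("glove block must have 5 flexion channels, found ",
                            ncol(fx))
    glove_trace(s$timestamps, fx, s$raw_max)
  })
  if (!is.null(st$pressure)) pressure <- stream_ctx("pressure", {
    s <- st$pressure
    pressure_trace(s$timestamps, s$value)
  })
  recording_bundle(doc$test_id, doc$subject_id, doc$side,
                   skeleton = skeleton, imu = imu, glove = glove,
                   pressure = pressure, true_score = doc$true_score,
                   registry = registry)
}

read_recording_csv <- function(path, registry) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf))
    stop("read_recording: directory container lacks meta.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  skeleton <- imu <- glove <- pressure <- NULL
  f <- file.path(path, "skeleton.csv")
  if (file.exists(f)) skeleton <- stream_ctx("skeleton", {
    df <- read.csv(f, stringsAsFactors = FALSE)
    jn <- unique(sub("_(x|y|z|status)$", "",
                     grep("_(x|y|z|status)$", names(df), value = TRUE)))
    n <- nrow(df)
    joints <- array(NA_real_, c(n, length(jn), 3),
                    dimnames = list(NULL, jn, c("x", "y", "z")))
    conf <- matrix("tracked", n, length(jn), dimnames = list(NULL, jn))
    for (j in jn) {
      joints[, j, ] <- as.matrix(df[paste0(j, c("_x", "_y", "_z"))])
      conf[, j] <- df[[paste0(j, "_status")]]
    }
    rate <- meta$skeleton_nominal_rate
    skeleton_sequence(df$timestamp, joints, conf,
                      if (is.null(rate)) 30 else rate)
  })
  f <- file.path(path, "imu.csv")
  if (file.exists(f)) imu <- stream_ctx("imu", {
    df <- read.csv(f)
    imu_trace(df$timestamp,
              as.matrix(df[c("accel_x", "accel_y", "accel_z")]),
              as.matrix(df[c("gyro_x", "gyro_y", "gyro_z")]),
              if (is.null(meta$imu_placement)) "wrist" else meta$imu_placement)
  })
  f <- file.path(path, "glove.csv")
  if (file.exists(f)) glove <- stream_ctx("glove", {
    df <- read.csv(f)
    ch <- setdiff(names(df), "timestamp")
    if (length(ch) != 5)
      stop("glove block must have 5 flexion channels, found ", length(ch))
    glove_trace(df$timestamp, as.matrix(df[ch]),
                if (is.null(meta$glove_raw_max)) 1023 else meta$glove_raw_max)
  })
  f <- file.path(path, "pressure.csv")
  if (file.exists(f)) pressure <- stream_ctx("pressure", {
    df <- read.csv(f)
    pressure_trace(df$timestamp, df$value)
  })
  recording_bundle(meta$test_id, meta$subject_id, meta$side,
                   skeleton = skeleton, imu = imu, glove = glove,
                   pressure = pressure, true_score = meta$true_score,
                   registry = registry)
}
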
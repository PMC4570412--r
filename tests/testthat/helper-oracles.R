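# Independent brute-force oracles and small fixture builders. Oracles are
# written as plain loops, separately from the package implementations they
# check.

oracle_median_filter <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  padded <- c(rep(x[1], h), x, rep(x[n], h))
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- sort(padded[i:(i + 2 * h)])
    out[i] <- win[h + 1]
  }
  out
}

oracle_joint_angle <- function(S, I) {
  dp <- 0
  for (k in 1:3) dp <- dp + S[k] * I[k]
  if (dp > 1) dp <- 1
  if (dp < -1) dp <- -1
  acos(dp)
}

oracle_rotation_range <- function(accel_z, window) {
  f <- oracle_median_filter(accel_z, window)
  mx <- f[1]; mn <- f[1]
  for (v in f) {
    if (v > mx) mx <- v
    if (v < mn) mn <- v
  }
  mx - mn
}

oracle_smoothness <- function(accel, window) {
  tot <- 0
  for (j in 1:3) {
    f <- oracle_median_filter(accel[, j], window)
    for (i in seq_along(f)) tot <- tot + abs(accel[i, j] - f[i])
  }
  as.numeric(tot)
}

oracle_movement_amount <- function(times, gyro, rest_window = 0.5) {
  tot <- 0
  for (j in 1:3) {
    g <- abs(gyro[, j])
    base <- median(g[times <= times[1] + rest_window])
    y <- g - base
    y[y < 0] <- 0
    for (i in 2:length(times))
      tot <- tot + (times[i] - times[i - 1]) * (y[i] + y[i - 1]) / 2
  }
  as.numeric(tot)
}

oracle_grip_strength <- function(value, window) {
  max(oracle_median_filter(value, window))
}

oracle_finger_state <- function(flexion, mode, window) {
  filt <- flexion
  for (j in 1:5) filt[, j] <- oracle_median_filter(flexion[, j], window)
  s <- rowSums(filt)
  best <- 1
  for (i in seq_len(nrow(filt))) {
    better <- if (mode == "flexion") s[i] > s[best] else s[i] < s[best]
    if (better) best <- i
  }
  filt[best, ]
}

# Frame-by-frame trace of the two-stage speed-normalization rule, written as
# plain loops over wrist displacements and resampling passes.
oracle_normalize_indices <- function(wrist, threshold, target) {
  n <- nrow(wrist)
  keep <- 1
  last <- 1
  for (i in 2:n) {
    d <- sqrt(sum((wrist[i, ] - wrist[last, ])^2))
    if (d >= threshold) {
      keep <- c(keep, i)
      last <- i
    }
  }
  idx <- keep
  while (length(idx) > target) {
    m <- length(idx)
    k <- m - target
    step <- max(1, m %/% k)
    start <- m %/% (2 * k) + 1
    del <- c()
    j <- start
    while (j <= m && length(del) < k) {
      if (j != 1 && j != m) del <- c(del, j)
      j <- j + step
    }
    if (!length(del)) del <- 2
    idx <- idx[-del]
  }
  while (length(idx) < target) {
    m <- length(idx)
    k <- target - m
    step <- max(1, m %/% k)
    start <- min(m %/% (2 * k) + 1, m)
    dup <- c()
    j <- start
    while (j <= m && length(dup) < k) {
      dup <- c(dup, j)
      j <- j + step
    }
    out <- c()
    for (j in seq_len(m)) {
      out <- c(out, idx[j])
      if (j %in% dup) out <- c(out, idx[j])
    }
    idx <- out
  }
  idx
}

# Loop-based full-batch backpropagation with the same sizing, seeding and
# standardization contract as train_bnn.
oracle_bnn_weights <- function(x, labels, seed, epochs, lr, hidden) {
  d <- ncol(x); n <- nrow(x); h <- hidden
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  set.seed(seed)
  r1 <- sqrt(6 / (d + h)); r2 <- sqrt(6 / (h + 3))
  W1 <- matrix(runif(d * h, -r1, r1), d, h)
  b1 <- rep(0, h)
  W2 <- matrix(runif(h * 3, -r2, r2), h, 3)
  b2 <- rep(0, 3)
  sig <- function(v) 1 / (1 + exp(-v))
  for (ep in seq_len(epochs)) {
    gW1 <- matrix(0, d, h); gb1 <- rep(0, h)
    gW2 <- matrix(0, h, 3); gb2 <- rep(0, 3)
    for (i in seq_len(n)) {
      hi <- sig(as.numeric(z[i, ] %*% W1) + b1)
      oi <- sig(as.numeric(hi %*% W2) + b2)
      ti <- c(0, 0, 0); ti[labels[i] + 1] <- 1
      do_ <- (oi - ti) * oi * (1 - oi) / n
      gW2 <- gW2 + outer(hi, do_)
      gb2 <- gb2 + do_
      dh_ <- as.numeric(W2 %*% do_) * hi * (1 - hi)
      gW1 <- gW1 + outer(z[i, ], dh_)
      gb1 <- gb1 + dh_
    }
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}
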
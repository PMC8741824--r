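# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised/compiled code paths: per-pixel loops, R-level flood
# fill, brute-force local means and exhaustive matching.

# per-pixel loop evaluation of the two greenness indices
loopExg <- function(frame) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- 2 * frame[i, j, 2] - frame[i, j, 1] - frame[i, j, 3]
    out[i, j] <- min(max(v, 0), 255)
  }
  out
}

loopNexg <- function(frame) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- frame[i, j, 1] + frame[i, j, 2] + frame[i, j, 3]
    if (s == 0) next
    r <- frame[i, j, 1] / s; g <- frame[i, j, 2] / s; b <- frame[i, j, 3] / s
    out[i, j] <- round(min(max(255 * (2 * g - r - b), 0), 255))
  }
  out
}

# per-pixel HSV banding on the OpenCV byte convention
loopHsvMask <- function(frame, profile) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- frame[i, j, 1]; g <- frame[i, j, 2]; b <- frame[i, j, 3]
    mx <- max(r, g, b); mn <- min(r, g, b)
    V <- mx
    S <- if (mx == 0) 0 else round(255 * (mx - mn) / mx)
    H <- if (mx == mn) 0 else {
      d <- mx - mn
      ang <- if (mx == r) 60 * (((g - b) / d) %% 6)
      else if (mx == g) 60 * ((b - r) / d + 2)
      else 60 * ((r - g) / d + 4)
      round(ang / 2) %% 180
    }
    if (H >= profile@hueMin && H <= profile@hueMax &&
        S >= profile@satMin && S <= profile@satMax &&
        V >= profile@valMin && V <= profile@valMax)
      out[i, j] <- 255
  }
  out
}

# 8-connected component count by R-level flood fill
floodFillCount <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] == 0 || seen[i, j]) next
    count <- count + 1
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r < 1 || r > h || c < 1 || c > w) next
        if (mask[r, c] != 0 && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# brute-force Gaussian-weighted local mean with replicated borders,
# matching the adaptive threshold's window convention
refLocalMean <- function(index, block) {
  sigma <- 0.3 * ((block - 1) * 0.5 - 1) + 0.8
  half <- (block - 1) / 2
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  h <- nrow(index); w <- ncol(index)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      r <- min(max(i + di, 1), h); c <- min(max(j + dj, 1), w)
      acc <- acc + k[di + half + 1, dj + half + 1] * index[r, c]
    }
    out[i, j] <- acc
  }
  out
}

# exhaustive optimal one-to-one matching (max matches within tolerance);
# feasible for a handful of detections/truths
optimalMatchCount <- function(det, tru, tolerance) {
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(0L)
  ok <- outer(seq_len(nd), seq_len(nt), function(a, b) {
    sqrt((det$cx[a] - tru$cx[b])^2 + (det$cy[a] - tru$cy[b])^2) <= tolerance
  })
  best <- 0L
  assign <- function(d, used) {
    if (d > nd) return(sum(used))
    most <- assign(d + 1, used)  # leave detection d unmatched
    for (t in which(ok[d, ] & !used)) {
      used2 <- used; used2[t] <- TRUE
      most <- max(most, assign(d + 1, used2))
    }
    most
  }
  assign(1L, rep(FALSE, nt))
}

# small random frame with integer channels
randomFrame <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}
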
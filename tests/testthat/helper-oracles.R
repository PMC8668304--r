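# Independent brute-force oracles, deliberately written as literal per-pixel
# loops so they share no code with the implementation.

# median filter: sort the replicated-border 3x3 neighborhood, take the middle
oracleMedian3x3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- numeric(9); m <- 0
    for (di in -1:1) for (dj in -1:1) {
      m <- m + 1
      v[m] <- img[min(max(i + di, 1), h), min(max(j + dj, 1), w)]
    }
    out[i, j] <- sort(v)[5]
  }
  out
}

# direct correlation with a 3x3 mask under edge replication
oracleCorrelate3x3 <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1)
      acc <- acc + k[di + 2, dj + 2] *
        img[min(max(i + di, 1), h), min(max(j + dj, 1), w)]
    out[i, j] <- acc
  }
  out
}

# queue-based flood fill component labeling
oracleFloodFill <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          r <- p[1] + o[1]; c <- p[2] + o[2]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] == 1 && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# independent plain cross-entropy: mean of -sum_k l_k [t==k] ln p_k
oracleCrossEntropy <- function(probArr, target, weights) {
  h <- dim(probArr)[1]; w <- dim(probArr)[2]
  tot <- 0; m <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    t <- target[i, j]
    if (t == 255) next
    m <- m + 1
    tot <- tot - weights[t + 1] * log(max(probArr[i, j, t + 1], 1e-7))
  }
  tot / m
}

diceOf <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  100 * 2 * tp / max(2 * tp + sum(pred == 1 & truth == 0) +
                       sum(pred == 0 & truth == 1), 1)
}
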
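# Independent brute-force oracles used to validate the vectorized /
# compiled implementations. These deliberately use naive double loops.

# Non-local attention evaluated literally over all position pairs.
oracle_attention <- function(X, params, normalization = "softmax",
                             mode = "three_conv_residual") {
  n <- ncol(X)
  Y <- X
  for (i in seq_len(n)) {
    th_i <- params$Wt %*% X[, i] + params$bt
    f <- vapply(seq_len(n), function(j)
      sum(th_i * (params$Wp %*% X[, j] + params$bp)), numeric(1))
    w <- if (normalization == "softmax") {
      e <- exp(f - max(f))
      e / sum(e)
    } else {
      f / n
    }
    acc <- 0
    for (j in seq_len(n))
      acc <- acc + w[j] * (params$Wg %*% X[, j] + params$bg)
    if (mode == "bottleneck_nonlocal")
      acc <- params$Wo %*% acc + params$bo
    Y[, i] <- Y[, i] + acc
  }
  Y
}

# 18-neighborhood surface scan, one voxel at a time.
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  offs <- list()
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    if (ox == 0 && oy == 0 && oz == 0) next
    if (abs(ox) + abs(oy) + abs(oz) == 3) next
    offs[[length(offs) + 1]] <- c(ox, oy, oz)
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    for (o in offs) {
      p <- c(i, j, k) + o
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

cross_min_dist <- function(a, b, spacing) {
  # minimum scaled Euclidean distance from each row of a to the set b
  vapply(seq_len(nrow(a)), function(i) {
    dd <- sweep(b, 2, a[i, ]) %*% diag(spacing, 3)
    sqrt(min(rowSums(dd^2)))
  }, numeric(1))
}

oracle_adb <- function(r, g, spacing = c(1, 1, 1)) {
  sr <- which(oracle_surface(r), arr.ind = TRUE)
  sg <- which(oracle_surface(g), arr.ind = TRUE)
  (sum(cross_min_dist(sr, sg, spacing)) + sum(cross_min_dist(sg, sr, spacing))) /
    (nrow(sr) + nrow(sg))
}

oracle_hausdorff <- function(r, g, spacing = c(1, 1, 1)) {
  pr <- which(r, arr.ind = TRUE)
  pg <- which(g, arr.ind = TRUE)
  max(max(cross_min_dist(pr, pg, spacing)), max(cross_min_dist(pg, pr, spacing)))
}

# Random blobby nonempty mask: a thresholded superposition of 1-3 balls.
random_mask <- function(extent = 12) {
  d <- rep(extent, 3)
  m <- array(FALSE, dim = d)
  for (b in seq_len(sample(1:3, 1))) {
    ctr <- runif(3, 2, extent - 1)
    rad <- runif(1, 1.5, extent / 3)
    co <- seq_len(extent)
    q <- outer(outer((co - ctr[1])^2, (co - ctr[2])^2, "+"), (co - ctr[3])^2, "+")
    m <- m | (q <= rad^2)
  }
  if (!any(m)) m[sample(extent, 1), sample(extent, 1), sample(extent, 1)] <- TRUE
  m
}

# Small network configuration used by structural and gradient tests.
tiny_config <- function(crop = 8L, dropout = 0) {
  network_config(stem_channels = 2L, growth_rate = 1L, block_layers = 2L,
                 dilations = c(1L, 2L), decoder_channels = 2L,
                 crop_size = crop, dropout_rate = dropout)
}

make_batch <- function(crop = 8L, batch = 1L, seed = 5) {
  set.seed(seed)
  list(x = array(rnorm(crop^3 * batch), dim = c(1, crop, crop, crop, batch)),
       lab = array(sample(0:2, crop^3 * batch, TRUE),
                   dim = c(crop, crop, crop, batch)))
}
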
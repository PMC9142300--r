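# Low-level differentiable operations. Feature maps are 5-D numeric arrays
# with dim (channels, depth, height, width, batch) — channel fastest, so a
# per-sample slice is already a (C x voxels) column-major matrix and a
# length-C vector recycles per-channel across the whole array. The heavy
# lifting (im2col convolution, fused batch-norm/ReLU, dropout, loss) lives
# in compiled kernels; these wrappers validate shapes.

check_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 5L)
    stop("feature map must be a 5-D array (channels, depth, height, width, batch)")
  if (any(d <= 0L)) stop("all feature-map extents must be positive")
  invisible(d)
}

as_dbl <- function(x) {
  if (!is.double(x)) storage.mode(x) <- "double"
  x
}

conv_pad <- function(kernel, dilation) {
  p <- dilation * (kernel - 1) / 2
  if (p != floor(p)) stop("kernel must be odd for size-preserving padding")
  as.integer(p)
}

conv_forward <- function(x, W, b, kernel, stride = 1L, dilation = 1L) {
  d <- check_feature_map(x)
  if (stride > 1L && any(d[2:4] %% stride != 0L))
    stop(sprintf("spatial extents (%s) must be divisible by stride %d",
                 paste(d[2:4], collapse = "x"), stride))
  cpp_conv3d_fwd(as_dbl(x), as.integer(d), W,
                 if (is.null(b)) numeric(0) else b,
                 as.integer(kernel), as.integer(stride),
                 conv_pad(kernel, dilation), as.integer(dilation))
}

conv_backward <- function(x, W, dy, kernel, stride = 1L, dilation = 1L,
                          has_bias = TRUE, need_dx = TRUE) {
  cpp_conv3d_bwd(as_dbl(x), as.integer(dim(x)), W, as_dbl(dy),
                 as.integer(kernel), as.integer(stride),
                 conv_pad(kernel, dilation), as.integer(dilation),
                 has_bias, need_dx)
}

deconv_forward <- function(x, W, b, kernel = 4L, stride = 2L, pad = 1L) {
  d <- check_feature_map(x)
  cpp_convT3d_fwd(as_dbl(x), as.integer(d), W,
                  if (is.null(b)) numeric(0) else b,
                  as.integer(kernel), as.integer(stride), as.integer(pad))
}

deconv_backward <- function(x, W, dy, kernel = 4L, stride = 2L, pad = 1L,
                            has_bias = TRUE, need_dx = TRUE) {
  cpp_convT3d_bwd(as_dbl(x), as.integer(dim(x)), W, as_dbl(dy),
                  as.integer(dim(dy)), as.integer(kernel),
                  as.integer(stride), as.integer(pad), has_bias, need_dx)
}

upsample_forward <- function(x, factor) {
  d <- check_feature_map(x)
  cpp_upsample3d_fwd(as_dbl(x), as.integer(d), factor)
}

upsample_backward <- function(dy, xdim, factor) {
  cpp_upsample3d_bwd(as_dbl(dy), as.integer(dim(dy)), as.integer(xdim), factor)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# Voxel-mean softmax cross-entropy. `logits` is (C, D, H, W, N); `labels`
# has classes 0..C-1 over the remaining extents.
softmax_ce <- function(logits, labels, need_grad = TRUE) {
  d <- dim(logits)
  C <- d[1L]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= C))
    stop(sprintf("labels outside 0..%d: %s", C - 1L,
                 paste(sort(unique(lab[lab < 0L | lab >= C])), collapse = ", ")))
  if (length(lab) * C != length(logits))
    stop("label extents do not match logits")
  out <- cpp_softmax_ce(as_dbl(logits), C, lab, need_grad)
  if (!need_grad) out$grad <- NULL
  out
}

# Per-voxel class probabilities from logits.
softmax_volume <- function(logits) {
  d <- dim(logits)
  cpp_softmax_ce(as_dbl(logits), d[1L], integer(length(logits) / d[1L]),
                 FALSE)$prob
}

# Channel-wise concatenation of 5-D feature maps.
concat_channels <- function(maps) {
  dims <- lapply(maps, dim)
  Cs <- vapply(dims, `[`, integer(1), 1L)
  rest <- dims[[1]][-1]
  out <- array(0, dim = c(sum(Cs), rest))
  at <- 0L
  for (i in seq_along(maps)) {
    out[at + seq_len(Cs[i]), , , , ] <- maps[[i]]
    at <- at + Cs[i]
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    y <- x[at + seq_len(s), , , , , drop = FALSE]
    at <<- at + s
    y
  })
}
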
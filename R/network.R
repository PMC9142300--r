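#' Network configuration
#'
#' All architectural hyperparameters of SparseVoxNet. The defaults
#' reproduce the reference architecture: a two-stage strided stem (16
#' channels), spatial self-attention at the coarsest resolution, two
#' 7-layer sparse blocks with growth rate 12 and dilation stack
#' 1,1,1,1,2,3,5, a 64-channel sequential decoder of two stride-2
#' deconvolutions, a deeply supervised skip branch from the transition
#' layer, and three-mapping pointwise heads.
#'
#' @param in_channels Input image channels (1 for MR volumes).
#' @param num_classes Segmentation classes (3: background, myocardium,
#'   blood pool).
#' @param stem_channels Channels after each stem convolution.
#' @param growth_rate Sparse-block growth rate.
#' @param block_layers Convolution units per sparse block.
#' @param dilations Per-unit dilation stack inside each sparse block.
#' @param decoder_channels Channels carried by the decoder.
#' @param crop_size Training-time cube edge; must be divisible by 4 (two
#'   stride-2 stages).
#' @param dropout_rate Dropout after every convolution.
#' @param use_attention If `FALSE`, the attention block is omitted (the
#'   dilation-only ablation variant).
#' @param use_dilation If `FALSE`, all sparse-block dilations are 1 (the
#'   attention-only ablation variant); parameter counts are unaffected.
#' @param width_multiplier Uniform channel scaling for desk-scale
#'   experiments; scaled channel counts must remain integers.
#' @param topology Sparse-block connectivity (see [sparse_block_spec()]).
#' @param attention_mode,attention_normalization Passed to
#'   [attention_spec()].
#' @return An `svn_network_config`.
#' @export
network_config <- function(in_channels = 1L, num_classes = 3L,
                           stem_channels = 16L, growth_rate = 12L,
                           block_layers = 7L,
                           dilations = c(1L, 1L, 1L, 1L, 2L, 3L, 5L),
                           decoder_channels = 64L, crop_size = 64L,
                           dropout_rate = 0.2, use_attention = TRUE,
                           use_dilation = TRUE, width_multiplier = 1,
                           topology = "chain",
                           attention_mode = "three_conv_residual",
                           attention_normalization = "softmax") {
  m <- width_multiplier
  sc <- stem_channels * m
  gr <- growth_rate * m
  dc <- decoder_channels * m
  if (any(c(sc, gr, dc) != floor(c(sc, gr, dc))))
    stop("width_multiplier must scale all channel counts to integers")
  if (crop_size %% 4L != 0L)
    stop("crop_size must be divisible by 4 (two stride-2 stages)")
  if (length(dilations) != block_layers)
    stop("dilations must have one entry per block layer")
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 stem_channels = as.integer(sc), growth_rate = as.integer(gr),
                 block_layers = as.integer(block_layers),
                 dilations = as.integer(dilations),
                 decoder_channels = as.integer(dc),
                 crop_size = as.integer(crop_size),
                 dropout_rate = dropout_rate, use_attention = use_attention,
                 use_dilation = use_dilation, width_multiplier = m,
                 topology = topology, attention_mode = attention_mode,
                 attention_normalization = attention_normalization),
            class = "svn_network_config")
}

#' Build a SparseVoxNet
#'
#' Assembles the network: stem (two stride-2 convolution units), spatial
#' self-attention, two sparse blocks separated by a pointwise transition,
#' a pointwise compression, two stride-2 deconvolutions back to full
#' resolution, a three-mapping pointwise main head, and a deeply
#' supervised skip branch (pointwise mapping from the transition output,
#' parameter-free x4 trilinear upsampling, its own three-mapping head).
#' Both heads return logits; softmax is applied by the loss and by
#' inference.
#'
#' @param config An `svn_network_config`.
#' @param init_std Gaussian weight-initialization standard deviation
#'   (biases start at zero); uses the session RNG.
#' @return An object of class `sparsevoxnet`.
#' @export
build_sparsevoxnet <- function(config = network_config(), init_std = 0.01) {
  stopifnot(inherits(config, "svn_network_config"))
  cfg <- config
  dil <- if (cfg$use_dilation) cfg$dilations else rep(1L, cfg$block_layers)
  sc <- cfg$stem_channels
  dc <- cfg$decoder_channels
  dr <- cfg$dropout_rate
  b1_out <- sc + cfg$block_layers * cfg$growth_rate
  b2_out <- b1_out + cfg$block_layers * cfg$growth_rate
  u <- function(...) conv_unit(conv_spec(...), init_std)
  layers <- list(
    conv1 = u(cfg$in_channels, sc, kernel = 3L, stride = 2L, dropout_rate = dr),
    conv2 = u(sc, sc, kernel = 3L, stride = 2L, dropout_rate = dr),
    attn = if (cfg$use_attention)
      attention_block(attention_spec(sc, mode = cfg$attention_mode,
                                     normalization = cfg$attention_normalization),
                      init_std),
    block1 = sparse_block(sparse_block_spec(sc, cfg$block_layers,
                                            cfg$growth_rate, dil,
                                            topology = cfg$topology,
                                            dropout_rate = dr), init_std),
    conv3 = u(b1_out, b1_out, kernel = 1L, dropout_rate = dr),
    block2 = sparse_block(sparse_block_spec(b1_out, cfg$block_layers,
                                            cfg$growth_rate, dil,
                                            topology = cfg$topology,
                                            dropout_rate = dr), init_std),
    conv4 = u(b2_out, dc, kernel = 1L, dropout_rate = dr),
    deconv1 = u(dc, dc, kernel = 4L, stride = 2L, transposed = TRUE,
                dropout_rate = dr),
    deconv2 = u(dc, dc, kernel = 4L, stride = 2L, transposed = TRUE,
                dropout_rate = dr),
    head_u1 = u(dc, dc, kernel = 1L, dropout_rate = dr),
    head_u2 = u(dc, dc, kernel = 1L, dropout_rate = dr),
    head_out = u(dc, cfg$num_classes, kernel = 1L, preact = FALSE,
                 dropout_rate = 0),
    skip_conv = u(b1_out, dc, kernel = 1L, dropout_rate = dr),
    skip_u1 = u(dc, dc, kernel = 1L, dropout_rate = dr),
    skip_u2 = u(dc, dc, kernel = 1L, dropout_rate = dr),
    skip_out = u(dc, cfg$num_classes, kernel = 1L, preact = FALSE,
                 dropout_rate = 0)
  )
  structure(list(config = cfg, layers = layers), class = "sparsevoxnet")
}

# Unit-chain helper: runs `names` sequentially, recording caches.
chain_forward <- function(net, names, x, train, caches, bn_batch = FALSE) {
  for (nm in names) {
    f <- unit_forward(net$layers[[nm]], x, train, bn_batch)
    net$layers[[nm]] <- f$unit
    caches[[nm]] <- f$cache
    x <- f$y
  }
  list(y = x, net = net, caches = caches)
}

# Full forward pass; caches every intermediate needed for backprop.
svn_fwd <- function(net, x, train = FALSE, need_cache = train,
                    bn_batch = FALSE) {
  cfg <- net$config
  d <- check_feature_map(x)
  if (d[1L] != cfg$in_channels)
    stop(sprintf("network expects %d input channel(s), got %d",
                 cfg$in_channels, d[1L]))
  if (any(d[2:4] %% 4L != 0L))
    stop("input extents must be divisible by 4")
  caches <- list()
  cf <- chain_forward(net, c("conv1", "conv2"), x, train, caches, bn_batch)
  net <- cf$net; caches <- cf$caches; h <- cf$y
  if (cfg$use_attention) {
    af <- attn_forward(net$layers$attn, h, need_cache)
    caches$attn <- af$caches
    h <- af$y
  }
  bf <- sb_forward(net$layers$block1, h, train, bn_batch)
  net$layers$block1 <- bf$block; caches$block1 <- bf$caches
  cf <- chain_forward(net, "conv3", bf$y, train, caches, bn_batch)
  net <- cf$net; caches <- cf$caches
  t1 <- cf$y
  bf <- sb_forward(net$layers$block2, t1, train, bn_batch)
  net$layers$block2 <- bf$block; caches$block2 <- bf$caches
  cf <- chain_forward(net, c("conv4", "deconv1", "deconv2",
                             "head_u1", "head_u2", "head_out"),
                      bf$y, train, caches, bn_batch)
  net <- cf$net; caches <- cf$caches
  main_logits <- cf$y
  cf <- chain_forward(net, "skip_conv", t1, train, caches, bn_batch)
  net <- cf$net; caches <- cf$caches
  caches$skip_dim <- dim(cf$y)
  up <- upsample_forward(cf$y, 4)
  cf <- chain_forward(net, c("skip_u1", "skip_u2", "skip_out"), up, train,
                      caches, bn_batch)
  net <- cf$net; caches <- cf$caches
  aux_logits <- cf$y
  list(main_logits = main_logits, aux_logits = aux_logits,
       net = net, caches = if (need_cache) caches)
}

chain_backward <- function(net, names, caches, dy, grads, need_dx = TRUE) {
  for (i in rev(seq_along(names))) {
    nm <- names[i]
    ub <- unit_backward(net$layers[[nm]], caches[[nm]], dy,
                        need_dx = need_dx || i > 1L)
    grads[[nm]] <- ub$grads
    dy <- ub$dx
  }
  list(dx = dy, grads = grads)
}

# Backward pass given gradients of the two heads' logits; returns grads in
# the same nested structure as the parameters.
svn_bwd <- function(net, caches, d_main, d_aux) {
  cfg <- net$config
  grads <- list()
  cb <- chain_backward(net, c("skip_u1", "skip_u2", "skip_out"), caches,
                       d_aux, grads)
  grads <- cb$grads
  dskip <- upsample_backward(cb$dx, caches$skip_dim, 4)
  cb <- chain_backward(net, "skip_conv", caches, dskip, grads)
  grads <- cb$grads
  dt1_skip <- cb$dx
  cb <- chain_backward(net, c("conv4", "deconv1", "deconv2",
                              "head_u1", "head_u2", "head_out"),
                       caches, d_main, grads)
  grads <- cb$grads
  sb <- sb_backward(net$layers$block2, caches$block2, cb$dx)
  grads$block2 <- sb$grads
  dt1 <- sb$dx + dt1_skip
  cb <- chain_backward(net, "conv3", caches, dt1, grads)
  grads <- cb$grads
  sb <- sb_backward(net$layers$block1, caches$block1, cb$dx)
  grads$block1 <- sb$grads
  dh <- sb$dx
  if (cfg$use_attention) {
    ab <- attn_backward(net$layers$attn, caches$attn, dh)
    grads$attn <- ab$grads
    dh <- ab$dx
  }
  cb <- chain_backward(net, c("conv1", "conv2"), caches, dh, grads,
                       need_dx = FALSE)
  cb$grads
}

#' Forward pass of a SparseVoxNet
#'
#' @param net A `sparsevoxnet`.
#' @param x A 5-D input `(in_channels, depth, height, width, batch)` with
#'   extents divisible by 4.
#' @param train Training mode (batch statistics and dropout active).
#' @return A list with `main_logits` and `aux_logits`, both
#'   `(num_classes, depth, height, width, batch)`.
#' @export
network_forward <- function(net, x, train = FALSE) {
  stopifnot(inherits(net, "sparsevoxnet"))
  f <- svn_fwd(net, x, train = train, need_cache = FALSE)
  list(main_logits = f$main_logits, aux_logits = f$aux_logits)
}

#' @export
count_parameters.sparsevoxnet <- function(unit, include_bn = FALSE) {
  sum(vapply(unit$layers, function(l) {
    if (is.null(l)) 0L else count_parameters(l, include_bn = include_bn)
  }, integer(1)))
}

#' Architecture report
#'
#' One row per named stage of the network (the layout of the reference
#' parameter table): kernel, stride, input/output shapes at the
#' configured crop size, and the trainable-parameter count of the stage
#' (weights and biases; batch-normalization scalars excluded by default).
#'
#' @param net A `sparsevoxnet`.
#' @param include_bn Include batch-normalization scalars in the counts.
#' @return A `data.frame` with one row per stage.
#' @export
architecture_report <- function(net, include_bn = FALSE) {
  stopifnot(inherits(net, "sparsevoxnet"))
  cfg <- net$config
  s0 <- cfg$crop_size
  s1 <- s0 %/% 2L
  s2 <- s0 %/% 4L
  sc <- cfg$stem_channels
  dc <- cfg$decoder_channels
  b1 <- sc + cfg$block_layers * cfg$growth_rate
  b2 <- b1 + cfg$block_layers * cfg$growth_rate
  nc <- cfg$num_classes
  shp <- function(s, c) sprintf("%dx%dx%dx%d", s, s, s, c)
  cnt <- function(nm) count_parameters(net$layers[[nm]], include_bn = include_bn)
  rows <- list(
    list("Conv_1", "convolution", 2L, 3L, shp(s0, cfg$in_channels), shp(s1, sc), cnt("conv1")),
    list("Conv_2", "convolution", 2L, 3L, shp(s1, sc), shp(s2, sc), cnt("conv2")),
    if (cfg$use_attention)
      list("Spatial attention", "self-attention", 1L, 1L, shp(s2, sc), shp(s2, sc), cnt("attn")),
    list("Sparse Block_1", "sparse block", 1L, 3L, shp(s2, sc), shp(s2, b1), cnt("block1")),
    list("Conv_3", "convolution", 1L, 1L, shp(s2, b1), shp(s2, b1), cnt("conv3")),
    list("Sparse Block_2", "sparse block", 1L, 3L, shp(s2, b1), shp(s2, b2), cnt("block2")),
    list("Conv_4", "convolution", 1L, 1L, shp(s2, b2), shp(s2, dc), cnt("conv4")),
    list("Deconv_1", "deconvolution", 2L, 4L, shp(s2, dc), shp(s1, dc), cnt("deconv1")),
    list("Deconv_2", "deconvolution", 2L, 4L, shp(s1, dc), shp(s0, dc), cnt("deconv2")),
    list("Skip connection", "convolution + upsample", 1L, 1L, shp(s2, b1), shp(s0, dc), cnt("skip_conv")),
    list("Main head", "convolution x3", 1L, 1L, shp(s0, dc), shp(s0, nc),
         cnt("head_u1") + cnt("head_u2") + cnt("head_out")),
    list("Aux head", "convolution x3", 1L, 1L, shp(s0, dc), shp(s0, nc),
         cnt("skip_u1") + cnt("skip_u2") + cnt("skip_out"))
  )
  rows <- rows[!vapply(rows, is.null, logical(1))]
  data.frame(name = vapply(rows, `[[`, character(1), 1L),
             kind = vapply(rows, `[[`, character(1), 2L),
             stride = vapply(rows, `[[`, integer(1), 3L),
             kernel = vapply(rows, `[[`, integer(1), 4L),
             input_shape = vapply(rows, `[[`, character(1), 5L),
             output_shape = vapply(rows, `[[`, character(1), 6L),
             parameters = vapply(rows, function(r) as.integer(r[[7L]]), integer(1)),
             stringsAsFactors = FALSE)
}

#' @export
print.sparsevoxnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("SparseVoxNet (width multiplier %g%s%s)\n", cfg$width_multiplier,
              if (cfg$use_attention) "" else ", no attention",
              if (cfg$use_dilation) "" else ", no dilation"))
  rep <- architecture_report(x)
  print(rep, row.names = FALSE)
  cat(sprintf("Total trainable parameters: %d (+%d batch-norm)\n",
              count_parameters(x),
              count_parameters(x, include_bn = TRUE) - count_parameters(x)))
  invisible(x)
}

#' @export
summary.sparsevoxnet <- function(object, ...) {
  rep <- architecture_report(object)
  structure(list(config = object$config, report = rep,
                 total = count_parameters(object)),
            class = "summary.sparsevoxnet")
}

#' @export
print.summary.sparsevoxnet <- function(x, ...) {
  print(x$report, row.names = FALSE)
  cat(sprintf("Total trainable parameters: %d\n", x$total))
  invisible(x)
}
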
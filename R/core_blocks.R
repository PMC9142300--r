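#' Convolution unit specification
#'
#' Describes one convolution unit: a pre-activation composite applying batch
#' normalization, rectification, an isotropic 3-D (de)convolution, and
#' dropout. Padding is always derived as `dilation * (kernel - 1) / 2` so
#' that stride-1 units preserve spatial extents; at stride `s` every extent
#' is divided exactly by `s`.
#'
#' @param in_channels,out_channels Positive channel counts.
#' @param kernel Positive odd kernel edge (isotropic); transposed units use
#'   even kernels (default 4) with fixed padding 1.
#' @param stride Positive integer stride.
#' @param dilation Positive integer dilation rate (spacing between kernel
#'   taps); does not change the parameter count.
#' @param has_bias Whether the convolution carries a bias term.
#' @param dropout_rate Dropout fraction applied after the convolution
#'   during training.
#' @param transposed If `TRUE` the unit is a deconvolution (kernel 4,
#'   stride 2, padding 1: exact x2 upsampling).
#' @param preact If `FALSE` the batch-norm/ReLU/dropout stages are omitted
#'   and the unit is a bare linear convolution (used for logit heads).
#' @return An object of class `svn_conv_spec`.
#' @export
conv_spec <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                      dilation = 1L, has_bias = TRUE, dropout_rate = 0.2,
                      transposed = FALSE, preact = TRUE) {
  stopifnot(in_channels >= 1, out_channels >= 1, kernel >= 1, stride >= 1,
            dilation >= 1, dropout_rate >= 0, dropout_rate <= 1)
  if (!transposed && kernel %% 2 == 0)
    stop("ordinary convolution units require an odd kernel")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 dilation = as.integer(dilation), has_bias = has_bias,
                 dropout_rate = dropout_rate, transposed = transposed,
                 preact = preact),
            class = "svn_conv_spec")
}

#' Closed-form trainable-parameter count of a convolution spec
#'
#' `kernel^3 * in * out + out` (bias included when present); dilation never
#' changes the count and batch-normalization scalars are not part of it.
#'
#' @param spec An `svn_conv_spec`.
#' @return Integer parameter count.
#' @export
conv_param_count <- function(spec) {
  stopifnot(inherits(spec, "svn_conv_spec"))
  spec$kernel^3 * spec$in_channels * spec$out_channels +
    if (spec$has_bias) spec$out_channels else 0L
}

#' Construct a convolution unit
#'
#' Builds the unit described by [conv_spec()]: batch norm, ReLU, 3-D
#' convolution, dropout, applied in that order (pre-activation ordering).
#' Weights are drawn from N(0, 0.01^2) using the session RNG; biases start
#' at zero.
#'
#' @param spec An `svn_conv_spec`.
#' @param init_std Standard deviation of the Gaussian weight
#'   initialization.
#' @return An object of class `svn_conv_unit` holding parameters and
#'   batch-norm running statistics.
#' @export
conv_unit <- function(spec, init_std = 0.01) {
  stopifnot(inherits(spec, "svn_conv_spec"))
  k3 <- spec$kernel^3
  W <- if (spec$transposed) {
    matrix(stats::rnorm(spec$in_channels * spec$out_channels * k3, 0, init_std),
           spec$in_channels, spec$out_channels * k3)
  } else {
    matrix(stats::rnorm(spec$out_channels * spec$in_channels * k3, 0, init_std),
           spec$out_channels, spec$in_channels * k3)
  }
  params <- list(W = W,
                 b = if (spec$has_bias) numeric(spec$out_channels) else NULL)
  if (spec$preact) {
    params$gamma <- rep(1, spec$in_channels)
    params$beta <- numeric(spec$in_channels)
  }
  structure(list(spec = spec, params = params,
                 buffers = if (spec$preact)
                   list(rmean = numeric(spec$in_channels),
                        rvar = rep(1, spec$in_channels)) else NULL),
            class = "svn_conv_unit")
}

# Forward pass of a unit; returns y, the cache needed for backprop, and the
# unit itself (running statistics advance in training mode). Batch norm and
# ReLU run as one fused kernel; the cache keeps the unit input and the
# post-activation map only.
unit_forward <- function(unit, x, train = FALSE, bn_batch = FALSE,
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  sp <- unit$spec
  d <- check_feature_map(x)
  if (d[1L] != sp$in_channels)
    stop(sprintf("unit expects %d input channels, got %d", sp$in_channels, d[1L]))
  cache <- list(xdim = d)
  h <- x
  if (sp$preact) {
    x <- as_dbl(x)
    if (train || bn_batch) {
      st <- cpp_channel_stats(x, d[1L])
      mu <- st$mean
      va <- st$var
      if (train) {
        unit$buffers$rmean <- (1 - bn_momentum) * unit$buffers$rmean + bn_momentum * mu
        unit$buffers$rvar <- (1 - bn_momentum) * unit$buffers$rvar + bn_momentum * va
      }
    } else {
      mu <- unit$buffers$rmean
      va <- unit$buffers$rvar
    }
    invstd <- 1 / sqrt(va + bn_eps)
    h <- cpp_bn_relu_fwd(x, d[1L], unit$params$gamma, unit$params$beta, mu, invstd)
    cache$x <- x
    cache$mu <- mu
    cache$invstd <- invstd
    cache$bn_train <- train
  }
  cache$conv_in <- h
  h <- if (sp$transposed) {
    deconv_forward(h, unit$params$W, unit$params$b, sp$kernel, sp$stride, 1L)
  } else {
    conv_forward(h, unit$params$W, unit$params$b, sp$kernel, sp$stride, sp$dilation)
  }
  if (sp$preact && sp$dropout_rate > 0 && train) {
    dr <- cpp_dropout_fwd(h, sp$dropout_rate)
    cache$drop <- dr$mask
    h <- dr$y
  }
  list(y = h, cache = cache, unit = unit)
}

unit_backward <- function(unit, cache, dy, need_dx = TRUE) {
  sp <- unit$spec
  dy <- dropout_backward(dy, cache$drop)
  cb <- if (sp$transposed) {
    deconv_backward(cache$conv_in, unit$params$W, dy, sp$kernel, sp$stride, 1L,
                    has_bias = sp$has_bias, need_dx = need_dx || sp$preact)
  } else {
    conv_backward(cache$conv_in, unit$params$W, dy, sp$kernel, sp$stride,
                  sp$dilation, has_bias = sp$has_bias,
                  need_dx = need_dx || sp$preact)
  }
  grads <- list(W = cb$dW, b = if (sp$has_bias) cb$db else NULL)
  dx <- NULL
  if (sp$preact) {
    bb <- cpp_bn_relu_bwd(cb$dx, cache$conv_in, cache$x, dim(cache$x)[1L],
                          unit$params$gamma, cache$mu, cache$invstd,
                          cache$bn_train)
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
    if (need_dx) dx <- bb$dx
  } else if (need_dx) {
    dx <- cb$dx
  }
  list(dx = dx, grads = grads)
}

#' Sparse block specification
#'
#' A sparse block is a chain of `num_layers` convolution units, each
#' emitting `growth_rate` channels; the block output concatenates the block
#' input with every unit output, so the transition layer sees
#' `in_channels + num_layers * growth_rate` channels. The default layer
#' stack mixes four ordinary convolutions with three dilated convolutions
#' (rates 2, 3, 5) to enlarge the receptive field without extra parameters.
#'
#' @param in_channels Block input channels.
#' @param num_layers Number of convolution units (default 7).
#' @param growth_rate Channels added per unit (default 12).
#' @param dilations Integer vector of per-unit dilation rates, length
#'   `num_layers`.
#' @param topology `"chain"` (each unit consumes only its predecessor's
#'   output), `"input_plus_previous"` (block input concatenated with the
#'   predecessor), or `"dense"` (all previous outputs).
#' @param dropout_rate Dropout for every unit.
#' @return An `svn_sparse_block_spec`.
#' @export
sparse_block_spec <- function(in_channels, num_layers = 7L, growth_rate = 12L,
                              dilations = c(1L, 1L, 1L, 1L, 2L, 3L, 5L),
                              topology = c("chain", "input_plus_previous", "dense"),
                              dropout_rate = 0.2) {
  topology <- match.arg(topology)
  stopifnot(in_channels >= 1, num_layers >= 1, growth_rate >= 1)
  if (length(dilations) != num_layers)
    stop(sprintf("dilations has length %d but num_layers is %d",
                 length(dilations), num_layers))
  structure(list(in_channels = as.integer(in_channels),
                 num_layers = as.integer(num_layers),
                 growth_rate = as.integer(growth_rate),
                 dilations = as.integer(dilations), topology = topology,
                 dropout_rate = dropout_rate),
            class = "svn_sparse_block_spec")
}

sparse_block_out_channels <- function(spec) {
  spec$in_channels + spec$num_layers * spec$growth_rate
}

# Indices (0 = block input, i = unit i output) concatenated as unit i's input.
sb_input_indices <- function(spec, i) {
  switch(spec$topology,
         chain = i - 1L,
         input_plus_previous = if (i == 1L) 0L else c(0L, i - 1L),
         dense = 0L:(i - 1L))
}

#' Construct a sparse block
#'
#' @param spec An `svn_sparse_block_spec`.
#' @param init_std Gaussian weight-initialization standard deviation.
#' @return An `svn_sparse_block`: a list of convolution units plus the spec.
#' @export
sparse_block <- function(spec, init_std = 0.01) {
  stopifnot(inherits(spec, "svn_sparse_block_spec"))
  widths <- c(spec$in_channels, rep(spec$growth_rate, spec$num_layers))
  units <- vector("list", spec$num_layers)
  for (i in seq_len(spec$num_layers)) {
    cin <- sum(widths[sb_input_indices(spec, i) + 1L])
    units[[i]] <- conv_unit(conv_spec(cin, spec$growth_rate, kernel = 3L,
                                      dilation = spec$dilations[i],
                                      dropout_rate = spec$dropout_rate),
                            init_std)
  }
  structure(list(spec = spec, units = units), class = "svn_sparse_block")
}

sb_forward <- function(block, x, train = FALSE, bn_batch = FALSE) {
  sp <- block$spec
  if (dim(x)[1L] != sp$in_channels)
    stop(sprintf("sparse block expects %d input channels, got %d",
                 sp$in_channels, dim(x)[1L]))
  ts <- vector("list", sp$num_layers + 1L)
  ts[[1L]] <- x
  caches <- vector("list", sp$num_layers)
  for (i in seq_len(sp$num_layers)) {
    idx <- sb_input_indices(sp, i)
    xin <- if (length(idx) == 1L) ts[[idx + 1L]] else
      concat_channels(ts[idx + 1L])
    f <- unit_forward(block$units[[i]], xin, train, bn_batch)
    block$units[[i]] <- f$unit
    caches[[i]] <- f$cache
    ts[[i + 1L]] <- f$y
  }
  list(y = concat_channels(ts), caches = caches, block = block)
}

sb_backward <- function(block, caches, dy) {
  sp <- block$spec
  widths <- c(sp$in_channels, rep(sp$growth_rate, sp$num_layers))
  dts <- split_channels(dy, widths)
  grads <- vector("list", sp$num_layers)
  for (i in rev(seq_len(sp$num_layers))) {
    ub <- unit_backward(block$units[[i]], caches[[i]], dts[[i + 1L]])
    grads[[i]] <- ub$grads
    idx <- sb_input_indices(sp, i)
    parts <- split_channels(ub$dx, widths[idx + 1L])
    for (j in seq_along(idx))
      dts[[idx[j] + 1L]] <- dts[[idx[j] + 1L]] + parts[[j]]
  }
  list(dx = dts[[1L]], grads = grads)
}

#' Forward pass of a sparse block
#'
#' Applies the block in evaluation mode (dropout inactive, batch norm on
#' running statistics) and returns the concatenated feature map
#' `[T0, T1, ..., TL]`.
#'
#' @param x A 5-D feature map `(channels, depth, height, width, batch)`.
#' @param block An `svn_sparse_block`.
#' @param train Training mode (batch statistics + dropout).
#' @return Feature map with `in_channels + num_layers * growth_rate`
#'   channels and unchanged spatial extents.
#' @export
sparse_block_forward <- function(x, block, train = FALSE) {
  sb_forward(block, x, train)$y
}

#' Spatial self-attention specification
#'
#' Non-local block: every position's output aggregates the mapped features
#' of all positions, weighted by the similarity of pointwise embeddings,
#' and is added back onto the input (residual). With the default
#' `three_conv_residual` mode and `inner_channels = channels`, the block
#' has exactly `3 * (channels^2 + channels)` trainable parameters.
#'
#' @param channels Input/output channel count.
#' @param inner_channels Embedding width for the similarity maps; defaults
#'   to `channels` (`three_conv_residual`) or `channels / 2`
#'   (`bottleneck_nonlocal`).
#' @param mode `"three_conv_residual"` (three biased pointwise mappings,
#'   parameter-free residual) or `"bottleneck_nonlocal"` (reduced embedding
#'   plus an output mapping back to `channels`).
#' @param normalization `"softmax"` over source positions, or `"count"`
#'   (division by the number of positions).
#' @return An `svn_attention_spec`.
#' @export
attention_spec <- function(channels, inner_channels = NULL,
                           mode = c("three_conv_residual", "bottleneck_nonlocal"),
                           normalization = c("softmax", "count")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  if (is.null(inner_channels))
    inner_channels <- if (mode == "three_conv_residual") channels
                      else max(1L, channels %/% 2L)
  stopifnot(channels >= 1, inner_channels >= 1)
  structure(list(channels = as.integer(channels),
                 inner_channels = as.integer(inner_channels),
                 mode = mode, normalization = normalization),
            class = "svn_attention_spec")
}

#' Construct a spatial self-attention block
#'
#' @param spec An `svn_attention_spec`.
#' @param init_std Gaussian weight-initialization standard deviation.
#' @return An `svn_attention` block.
#' @export
attention_block <- function(spec, init_std = 0.01) {
  stopifnot(inherits(spec, "svn_attention_spec"))
  C <- spec$channels
  ic <- spec$inner_channels
  gw <- if (spec$mode == "three_conv_residual") C else ic
  rn <- function(r, c) matrix(stats::rnorm(r * c, 0, init_std), r, c)
  params <- list(Wt = rn(ic, C), bt = numeric(ic),
                 Wp = rn(ic, C), bp = numeric(ic),
                 Wg = rn(gw, C), bg = numeric(gw))
  if (spec$mode == "bottleneck_nonlocal") {
    params$Wo <- rn(C, ic)
    params$bo <- numeric(C)
  }
  structure(list(spec = spec, params = params), class = "svn_attention")
}

attn_forward <- function(block, x, need_cache = TRUE) {
  sp <- block$spec
  p <- block$params
  d <- check_feature_map(x)
  if (d[1L] != sp$channels)
    stop(sprintf("attention block expects %d channels, got %d", sp$channels, d[1L]))
  n <- prod(d[2:4])
  N <- d[5L]
  y <- x
  caches <- if (need_cache) vector("list", N) else NULL
  for (s in seq_len(N)) {
    X <- matrix(x[, , , , s], sp$channels, n)
    theta <- p$Wt %*% X + p$bt
    phi <- p$Wp %*% X + p$bp
    G <- p$Wg %*% X + p$bg
    S <- crossprod(theta, phi)            # S[i, j] = theta_i . phi_j
    if (sp$normalization == "softmax") {
      A <- exp(S - apply(S, 1L, max))
      A <- A / rowSums(A)
    } else {
      A <- S / n
    }
    Yt <- G %*% t(A)
    if (sp$mode == "bottleneck_nonlocal") {
      Yres <- p$Wo %*% Yt + p$bo
    } else {
      Yres <- Yt
    }
    y[, , , , s] <- y[, , , , s] + as.vector(Yres)
    if (need_cache)
      caches[[s]] <- list(X = X, theta = theta, phi = phi, G = G, A = A, Yt = Yt)
  }
  list(y = y, caches = caches)
}

attn_backward <- function(block, caches, dy) {
  sp <- block$spec
  p <- block$params
  d <- dim(dy)
  n <- prod(d[2:4])
  dx <- dy  # residual path
  zeros <- function(m) array(0, dim = dim(m))
  g <- list(Wt = zeros(p$Wt), bt = numeric(length(p$bt)),
            Wp = zeros(p$Wp), bp = numeric(length(p$bp)),
            Wg = zeros(p$Wg), bg = numeric(length(p$bg)))
  if (sp$mode == "bottleneck_nonlocal") {
    g$Wo <- zeros(p$Wo)
    g$bo <- numeric(length(p$bo))
  }
  for (s in seq_len(d[5L])) {
    cc <- caches[[s]]
    dYres <- matrix(dy[, , , , s], d[1L], n)
    if (sp$mode == "bottleneck_nonlocal") {
      g$Wo <- g$Wo + dYres %*% t(cc$Yt)
      g$bo <- g$bo + rowSums(dYres)
      dYt <- crossprod(p$Wo, dYres)
    } else {
      dYt <- dYres
    }
    dG <- dYt %*% cc$A
    dA <- crossprod(dYt, cc$G)            # dA[i, j] = dYt[, i] . G[, j]
    if (sp$normalization == "softmax") {
      dS <- cc$A * (dA - rowSums(dA * cc$A))
    } else {
      dS <- dA / n
    }
    dtheta <- cc$phi %*% t(dS)
    dphi <- cc$theta %*% dS
    g$Wt <- g$Wt + dtheta %*% t(cc$X); g$bt <- g$bt + rowSums(dtheta)
    g$Wp <- g$Wp + dphi %*% t(cc$X);   g$bp <- g$bp + rowSums(dphi)
    g$Wg <- g$Wg + dG %*% t(cc$X);     g$bg <- g$bg + rowSums(dG)
    dXs <- crossprod(p$Wt, dtheta) + crossprod(p$Wp, dphi) + crossprod(p$Wg, dG)
    dx[, , , , s] <- dx[, , , , s] + as.vector(dXs)
  }
  list(dx = dx, grads = g)
}

#' Forward pass of the spatial self-attention block
#'
#' For input positions i and j (flattened voxels), similarity
#' `f(x_i, x_j) = theta(x_i) . phi(x_j)` weights the aggregation of
#' `g(x_j)`; the normalized aggregate is added back onto the input, so the
#' output shape equals the input shape exactly.
#'
#' @param x A 5-D feature map whose channel extent matches the spec.
#' @param block An `svn_attention` block.
#' @return Feature map of identical shape.
#' @export
attention_forward <- function(x, block) {
  stopifnot(inherits(block, "svn_attention"))
  attn_forward(block, x, need_cache = FALSE)$y
}

#' Count trainable parameters
#'
#' Totals every trainable scalar (convolution/mapping weights and biases).
#' Batch-normalization scale/shift parameters are excluded by default,
#' matching the convention of the architecture report; set
#' `include_bn = TRUE` to count them.
#'
#' @param unit A constructed unit, block, or network.
#' @param include_bn Include batch-normalization scalars.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(unit, include_bn = FALSE) {
  UseMethod("count_parameters")
}

param_list_count <- function(params, include_bn) {
  n <- 0L
  for (nm in names(params)) {
    if (!include_bn && nm %in% c("gamma", "beta")) next
    if (!is.null(params[[nm]])) n <- n + length(params[[nm]])
  }
  n
}

#' @export
count_parameters.svn_conv_unit <- function(unit, include_bn = FALSE) {
  param_list_count(unit$params, include_bn)
}

#' @export
count_parameters.svn_attention <- function(unit, include_bn = FALSE) {
  param_list_count(unit$params, include_bn)
}

#' @export
count_parameters.svn_sparse_block <- function(unit, include_bn = FALSE) {
  sum(vapply(unit$units, count_parameters, integer(1), include_bn = include_bn))
}

#' Receptive field of a stride-1 convolution stack
#'
#' Standard composition for stride-1 stacks:
#' `1 + sum((kernel_i - 1) * dilation_i)` per axis.
#'
#' @param specs A list of `svn_conv_spec` objects, or an
#'   `svn_sparse_block_spec` (its internal 3x3x3 stack is analyzed).
#' @return Integer receptive-field edge length per axis.
#' @export
receptive_field <- function(specs) {
  if (inherits(specs, "svn_sparse_block_spec"))
    specs <- lapply(specs$dilations, function(d) conv_spec(1L, 1L, 3L, dilation = d))
  if (inherits(specs, "svn_conv_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "svn_conv_spec")))
  if (any(vapply(specs, `[[`, integer(1), "stride") != 1L))
    stop("receptive_field analyzes stride-1 stacks only")
  1L + sum(vapply(specs, function(s) (s$kernel - 1L) * s$dilation, integer(1)))
}
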
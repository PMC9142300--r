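test_that("convolution parameter counts follow the closed form", {
  # stem convolution 1 -> 16, kernel 3: 27*16 + 16
  expect_identical(conv_param_count(conv_spec(1, 16, kernel = 3, stride = 2)), 448)
  expect_identical(conv_param_count(conv_spec(16, 16, kernel = 3, stride = 2)), 6928)
  # pointwise 100 -> 100 and 184 -> 64
  expect_identical(conv_param_count(conv_spec(100, 100, kernel = 1)), 10100)
  expect_identical(conv_param_count(conv_spec(184, 64, kernel = 1)), 11840)
  # deconvolution kernel 4, 64 -> 64
  expect_identical(
    conv_param_count(conv_spec(64, 64, kernel = 4, stride = 2, transposed = TRUE)),
    262208)
  # dilation never changes the count; dropping the bias removes out_channels
  expect_identical(conv_param_count(conv_spec(16, 16, kernel = 3, dilation = 5)),
                   conv_param_count(conv_spec(16, 16, kernel = 3, dilation = 1)))
  expect_identical(
    conv_param_count(conv_spec(16, 16, kernel = 3)) -
      conv_param_count(conv_spec(16, 16, kernel = 3, has_bias = FALSE)),
    16)
  # closed form equals the actual number of stored scalars
  set.seed(1)
  for (sp in list(conv_spec(3, 5, kernel = 3), conv_spec(7, 2, kernel = 1),
                  conv_spec(4, 6, kernel = 4, stride = 2, transposed = TRUE))) {
    expect_identical(count_parameters(conv_unit(sp)), as.integer(conv_param_count(sp)))
  }
  expect_error(conv_spec(4, 0), "out_channels")
})

test_that("stride-1 units preserve spatial extents and stride divides them", {
  set.seed(2)
  for (rep in 1:5) {
    d <- sample(4:9, 3, replace = TRUE)
    dil <- sample(1:3, 1)
    u <- conv_unit(conv_spec(2, 3, kernel = 3, dilation = dil))
    x <- array(rnorm(2 * prod(d)), dim = c(2, d, 1))
    y <- unit_forward(u, x)$y
    expect_identical(dim(y), c(3L, d, 1L))
  }
  # kernel 3, dilation 5 on a 16-cube: padding 5 preserves 16
  u <- conv_unit(conv_spec(16, 16, kernel = 3, dilation = 5))
  x <- array(rnorm(16 * 16^3), dim = c(16, 16, 16, 16, 1))
  expect_identical(dim(unit_forward(u, x)$y), c(16L, 16L, 16L, 16L, 1L))
  # stride 2 halves extents; odd extents are an explicit shape error
  u2 <- conv_unit(conv_spec(1, 4, kernel = 3, stride = 2))
  x2 <- array(rnorm(8^3), dim = c(1, 8, 8, 8, 1))
  expect_identical(dim(unit_forward(u2, x2)$y), c(4L, 4L, 4L, 4L, 1L))
  x3 <- array(rnorm(7^3), dim = c(1, 7, 7, 7, 1))
  expect_error(unit_forward(u2, x3), "divisible")
})

test_that("sparse block concatenates input and all layer outputs", {
  set.seed(3)
  # reference channel transitions 16 -> 100 and 100 -> 184
  b1 <- sparse_block(sparse_block_spec(16, 7, 12))
  x <- array(rnorm(16 * 6^3), dim = c(16, 6, 6, 6, 1))
  y <- sparse_block_forward(x, b1)
  expect_identical(dim(y), c(100L, 6L, 6L, 6L, 1L))
  b2 <- sparse_block(sparse_block_spec(100, 7, 12))
  x2 <- array(rnorm(100 * 4^3), dim = c(100, 4, 4, 4, 1))
  expect_identical(dim(sparse_block_forward(x2, b2))[1], 184L)
  # random channel bookkeeping: out = in + L * k for every topology
  for (rep in 1:6) {
    ci <- sample(1:8, 1); L <- sample(1:4, 1); k <- sample(1:5, 1)
    topo <- sample(c("chain", "input_plus_previous", "dense"), 1)
    sp <- sparse_block_spec(ci, L, k, dilations = rep(1L, L), topology = topo)
    b <- sparse_block(sp)
    xx <- array(rnorm(ci * 5^3), dim = c(ci, 5, 5, 5, 1))
    expect_identical(dim(sparse_block_forward(xx, b))[1], as.integer(ci + L * k))
  }
  expect_error(sparse_block_spec(4, 3, 2, dilations = c(1, 2)), "length")
})

test_that("zero-weight sparse block passes the input through untouched", {
  set.seed(4)
  sp <- sparse_block_spec(4, 2, 3, dilations = c(1L, 1L), dropout_rate = 0)
  b <- sparse_block(sp, init_std = 0)   # all-zero convolutions, zero biases
  x <- array(rnorm(4 * 4^3), dim = c(4, 4, 4, 4, 1))
  y <- sparse_block_forward(x, b)
  expect_equal(y[1:4, , , , , drop = FALSE], x)
  expect_true(all(y[5:10, , , , ] == 0))
})

test_that("attention block matches the literal pairwise-sum oracle", {
  set.seed(5)
  for (norm in c("softmax", "count")) {
    spec <- attention_spec(2, normalization = norm)
    blk <- attention_block(spec, init_std = 0.4)
    x <- array(rnorm(2 * 2 * 2 * 2), dim = c(2, 2, 2, 2, 1))
    y <- attention_forward(x, blk)
    Yb <- oracle_attention(matrix(x, 2, 8), blk$params, norm)
    expect_lt(max(abs(matrix(y, 2, 8) - Yb)), 1e-10)
  }
  # bottleneck variant against its oracle
  spec <- attention_spec(4, mode = "bottleneck_nonlocal")
  blk <- attention_block(spec, init_std = 0.4)
  x <- array(rnorm(4 * 27), dim = c(4, 3, 3, 3, 1))
  y <- attention_forward(x, blk)
  Yb <- oracle_attention(matrix(x, 4, 27), blk$params, "softmax",
                         "bottleneck_nonlocal")
  expect_lt(max(abs(matrix(y, 4, 27) - Yb)), 1e-10)
})

test_that("attention with zero g-mapping is the identity", {
  set.seed(6)
  blk <- attention_block(attention_spec(3), init_std = 0.3)
  blk$params$Wg[] <- 0
  blk$params$bg[] <- 0
  x <- array(rnorm(3 * 4^3), dim = c(3, 4, 4, 4, 2))
  expect_equal(attention_forward(x, blk), x)
})

test_that("attention is equivariant under spatial permutations", {
  set.seed(7)
  blk <- attention_block(attention_spec(2), init_std = 0.3)
  d <- c(2L, 2L, 3L, 2L, 1L)
  n <- prod(d[2:4])
  for (rep in 1:20) {
    x <- array(rnorm(prod(d)), dim = d)
    perm <- sample(n)
    xp <- array(matrix(x, 2, n)[, perm], dim = d)
    y <- matrix(attention_forward(x, blk), 2, n)
    yp <- matrix(attention_forward(xp, blk), 2, n)
    expect_lt(max(abs(y[, perm] - yp)), 1e-10)
  }
})

test_that("attention parameter counts match the configuration", {
  set.seed(8)
  expect_identical(count_parameters(attention_block(attention_spec(16))), 816L)
  expect_identical(
    count_parameters(attention_block(attention_spec(16, mode = "bottleneck_nonlocal"))),
    552L)
})

test_that("receptive field follows the stride-1 composition rule", {
  expect_identical(receptive_field(conv_spec(1, 1, kernel = 3)), 3L)
  expect_identical(
    receptive_field(sparse_block_spec(16, 7, 12)),  # dilations 1,1,1,1,2,3,5
    29L)
  expect_identical(
    receptive_field(list(conv_spec(1, 1, 3), conv_spec(1, 1, 3))), 5L)
  expect_error(receptive_field(list(conv_spec(1, 1, 3, stride = 2))), "stride-1")
})

test_that("unit and attention backward passes match finite differences", {
  ns <- asNamespace("sparsevoxnet")
  set.seed(9)
  # conv unit (train mode, dropout off for determinism)
  u <- conv_unit(conv_spec(2, 3, kernel = 3, dropout_rate = 0), init_std = 0.3)
  x <- array(rnorm(2 * 5^3), dim = c(2, 5, 5, 5, 1))
  fwd <- function(u, x) sum(sin(unit_forward(u, x, train = TRUE)$y))
  f <- unit_forward(u, x, train = TRUE)
  bk <- ns$unit_backward(u, f$cache, cos(f$y))
  eps <- 1e-6
  for (pn in c("W", "b", "gamma", "beta")) {
    j <- sample(length(u$params[[pn]]), 1)
    up <- u; up$params[[pn]][j] <- up$params[[pn]][j] + eps
    um <- u; um$params[[pn]][j] <- um$params[[pn]][j] - eps
    num <- (fwd(up, x) - fwd(um, x)) / (2 * eps)
    expect_lt(abs(num - bk$grads[[pn]][j]) / max(1e-6, abs(num)), 1e-4)
  }
  j <- sample(length(x), 1)
  xp <- x; xp[j] <- xp[j] + eps
  xm <- x; xm[j] <- xm[j] - eps
  num <- (fwd(u, xp) - fwd(u, xm)) / (2 * eps)
  expect_lt(abs(num - bk$dx[j]) / max(1e-6, abs(num)), 1e-4)
  # attention
  blk <- attention_block(attention_spec(2), init_std = 0.3)
  xa <- array(rnorm(2 * 8), dim = c(2, 2, 2, 2, 1))
  fa <- ns$attn_forward(blk, xa)
  ba <- ns$attn_backward(blk, fa$caches, cos(fa$y))
  fwda <- function(b, x) sum(sin(ns$attn_forward(b, x, need_cache = FALSE)$y))
  for (pn in c("Wt", "Wp", "Wg", "bt", "bg")) {
    j <- sample(length(blk$params[[pn]]), 1)
    bp <- blk; bp$params[[pn]][j] <- bp$params[[pn]][j] + eps
    bm <- blk; bm$params[[pn]][j] <- bm$params[[pn]][j] - eps
    num <- (fwda(bp, xa) - fwda(bm, xa)) / (2 * eps)
    expect_lt(abs(num - ba$grads[[pn]][j]) / max(1e-6, abs(num)), 1e-4)
  }
})
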
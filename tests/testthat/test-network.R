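test_that("architecture report reproduces the reference parameter counts", {
  set.seed(1)
  net <- build_sparsevoxnet(network_config())
  rep <- architecture_report(net)
  counts <- setNames(rep$parameters, rep$name)
  expect_identical(counts[["Conv_1"]], 448L)
  expect_identical(counts[["Conv_2"]], 6928L)
  expect_identical(counts[["Spatial attention"]], 816L)
  expect_identical(counts[["Conv_3"]], 10100L)
  expect_identical(counts[["Conv_4"]], 11840L)
  expect_identical(counts[["Deconv_1"]], 262208L)
  expect_identical(counts[["Deconv_2"]], 262208L)
  expect_identical(counts[["Skip connection"]], 6464L)
  # sparse-block channel transitions 16 -> 100 and 100 -> 184
  expect_match(rep$output_shape[rep$name == "Sparse Block_1"], "x100$")
  expect_match(rep$output_shape[rep$name == "Sparse Block_2"], "x184$")
  # conservation: the report covers every trainable parameter exactly once
  expect_identical(sum(rep$parameters), count_parameters(net))
})

test_that("ablation variants change parameters exactly as expected", {
  set.seed(2)
  full <- build_sparsevoxnet(network_config())
  no_attn <- build_sparsevoxnet(network_config(use_attention = FALSE))
  no_dil <- build_sparsevoxnet(network_config(use_dilation = FALSE))
  expect_identical(count_parameters(full) - count_parameters(no_attn), 816L)
  expect_identical(count_parameters(full), count_parameters(no_dil))
  expect_false("Spatial attention" %in% architecture_report(no_attn)$name)
})

test_that("forward pass yields full-resolution dual logits and is deterministic", {
  set.seed(3)
  net <- build_sparsevoxnet(network_config(crop_size = 32L))
  x <- array(rnorm(32^3), dim = c(1, 32, 32, 32, 1))
  out <- network_forward(net, x)
  expect_identical(dim(out$main_logits), c(3L, 32L, 32L, 32L, 1L))
  expect_identical(dim(out$aux_logits), c(3L, 32L, 32L, 32L, 1L))
  out2 <- network_forward(net, x)
  expect_identical(out$main_logits, out2$main_logits)
  expect_identical(out$aux_logits, out2$aux_logits)
  # per-voxel softmax normalization
  ns <- asNamespace("sparsevoxnet")
  p <- ns$softmax_volume(out$main_logits)
  sums <- colSums(matrix(p, 3, length(p) / 3))
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_error(network_forward(net, array(0, dim = c(2, 32, 32, 32, 1))), "channel")
  expect_error(network_forward(net, array(0, dim = c(1, 30, 30, 30, 1))), "divisible")
  expect_error(network_config(crop_size = 30L), "divisible")
})

test_that("input extent scales the output extent through the stated strides", {
  set.seed(4)
  net <- build_sparsevoxnet(tiny_config())
  x <- array(rnorm(12^3 * 2), dim = c(1, 12, 12, 12, 2))
  out <- network_forward(net, x)
  expect_identical(dim(out$main_logits), c(3L, 12L, 12L, 12L, 2L))
})

test_that("every trainable tensor receives gradient through the full graph", {
  ns <- asNamespace("sparsevoxnet")
  set.seed(5)
  # default dropout: without it, a convolution bias feeding straight into
  # the next stage's batch norm is exactly absorbed and gets zero gradient
  net <- build_sparsevoxnet(tiny_config(dropout = 0.2), init_std = 0.1)
  b <- make_batch(8L, 1L)
  f <- ns$svn_fwd(net, b$x, train = TRUE)
  ls <- svn_loss(list(main_logits = f$main_logits, aux_logits = f$aux_logits),
                 b$lab, aux_weight = 0.5, need_grad = TRUE)
  grads <- ns$svn_bwd(f$net, f$caches, ls$d_main, ls$d_aux)
  walk <- function(g, path) {
    if (is.list(g)) {
      for (nm in seq_along(g)) {
        if (is.null(g[[nm]])) next
        walk(g[[nm]], paste(path, if (is.null(names(g))) nm else names(g)[nm]))
      }
    } else {
      expect_true(any(g != 0), label = sprintf("nonzero gradient at %s", path))
    }
  }
  walk(grads, "")
})

test_that("whole-network analytic gradients match finite differences", {
  ns <- asNamespace("sparsevoxnet")
  set.seed(6)
  net <- build_sparsevoxnet(tiny_config(), init_std = 0.2)
  b <- make_batch(8L, 1L, seed = 7)
  lossfn <- function(net) {
    f <- ns$svn_fwd(net, b$x, train = TRUE)
    svn_loss(list(main_logits = f$main_logits, aux_logits = f$aux_logits),
             b$lab, 0.5)$loss
  }
  f <- ns$svn_fwd(net, b$x, train = TRUE)
  ls <- svn_loss(list(main_logits = f$main_logits, aux_logits = f$aux_logits),
                 b$lab, 0.5, need_grad = TRUE)
  grads <- ns$svn_bwd(net, f$caches, ls$d_main, ls$d_aux)
  eps <- 1e-5
  spots <- list(
    list(function(n) n$layers$conv1$params$W,
         function(n, v) { n$layers$conv1$params$W[] <- v; n }, grads$conv1$W),
    list(function(n) n$layers$attn$params$Wt,
         function(n, v) { n$layers$attn$params$Wt[] <- v; n }, grads$attn$Wt),
    list(function(n) n$layers$block1$units[[2]]$params$W,
         function(n, v) { n$layers$block1$units[[2]]$params$W[] <- v; n },
         grads$block1[[2]]$W),
    list(function(n) n$layers$deconv1$params$W,
         function(n, v) { n$layers$deconv1$params$W[] <- v; n }, grads$deconv1$W),
    list(function(n) n$layers$skip_conv$params$W,
         function(n, v) { n$layers$skip_conv$params$W[] <- v; n },
         grads$skip_conv$W),
    list(function(n) n$layers$head_out$params$b,
         function(n, v) { n$layers$head_out$params$b[] <- v; n },
         grads$head_out$b))
  for (s in spots) {
    v <- s[[1]](net)
    j <- sample(length(v), 1)
    vp <- v; vp[j] <- vp[j] + eps
    vm <- v; vm[j] <- vm[j] - eps
    num <- (lossfn(s[[2]](net, vp)) - lossfn(s[[2]](net, vm))) / (2 * eps)
    expect_lt(abs(num - s[[3]][j]) / max(1e-6, abs(num) + abs(s[[3]][j])), 1e-3)
  }
})

test_that("print and summary surface the architecture table", {
  set.seed(8)
  net <- build_sparsevoxnet(network_config())
  out <- capture.output(print(net))
  expect_true(any(grepl("Conv_1", out)))
  expect_true(any(grepl("448", out)))
  s <- summary(net)
  expect_s3_class(s, "summary.sparsevoxnet")
  expect_identical(s$total, count_parameters(net))
})
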
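# Whole-volume prediction by tiling overlapping crops and soft voting:
# softmax probabilities of every crop (and of both decoder heads) are
# accumulated per voxel and averaged before the argmax.

#' Tile a volume with crop origins
#'
#' Regular grid of 0-based origins with the given stride; the final
#' origin per axis is clamped so the last crop ends exactly at the
#' boundary, guaranteeing full coverage.
#'
#' @param extent Integer volume extents (length 3, or a scalar for
#'   cubes).
#' @param crop_size Crop edge length (must not exceed any extent).
#' @param stride Positive step between origins.
#' @return Integer matrix with one 0-based origin per row.
#' @export
tile_crops <- function(extent, crop_size, stride) {
  if (stride <= 0) stop("stride must be positive")
  if (length(extent) == 1L) extent <- rep(extent, 3L)
  if (any(extent < crop_size))
    stop(sprintf("crop size %d exceeds volume extents (%s)",
                 crop_size, paste(extent, collapse = "x")))
  axis_origins <- lapply(extent, function(e) {
    o <- seq.int(0L, e - crop_size, by = stride)
    if (o[length(o)] != e - crop_size) o <- c(o, e - crop_size)
    as.integer(o)
  })
  g <- expand.grid(axis_origins[[1]], axis_origins[[2]], axis_origins[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)
  dimnames(m) <- NULL
  m
}

#' Segment a whole volume by crop voting
#'
#' Tiles the volume with overlapping crops, runs the network in
#' evaluation mode on each, and accumulates per-voxel softmax
#' probabilities from the selected head(s); accumulated probabilities are
#' divided by the per-voxel coverage, and the label is the per-voxel
#' argmax with ties broken toward the smaller class index.
#'
#' @param net A `sparsevoxnet`.
#' @param volume 3-D numeric array, already z-score normalized (set
#'   `normalize = TRUE` to standardize here).
#' @param crop_size Crop edge (defaults to the network's configured crop
#'   size, shrunk to the volume if needed).
#' @param stride Tiling stride (default half the crop: overlapping
#'   voting).
#' @param head_mode `"mean"` (average both decoder heads), `"main"`, or
#'   `"aux"`.
#' @param hard_vote Accumulate one-hot argmax votes per crop instead of
#'   probabilities.
#' @param bn `"running"` (default): batch-norm stages use the running
#'   estimates accumulated during training ([recalibrate_bn()] refreshes
#'   them after small-batch training); `"batch"`: normalize each crop with
#'   its own statistics (still deterministic, but unreliable for tiles that
#'   contain little anatomy).
#' @param normalize Z-score the volume before prediction.
#' @return List with `label` (3-D integer array over \{0, 1, 2\}) and
#'   `prob` (`(num_classes, dim)` array of averaged probabilities,
#'   summing to 1 per voxel).
#' @export
predict_volume <- function(net, volume, crop_size = NULL, stride = NULL,
                           head_mode = c("mean", "main", "aux"),
                           hard_vote = FALSE, bn = c("running", "batch"),
                           normalize = FALSE) {
  stopifnot(inherits(net, "sparsevoxnet"))
  head_mode <- match.arg(head_mode)
  bn <- match.arg(bn)
  if (inherits(volume, "svn_volume")) volume <- volume$data
  d <- dim(volume)
  if (is.null(crop_size)) crop_size <- min(net$config$crop_size, min(d) %/% 4L * 4L)
  if (is.null(stride)) stride <- max(crop_size %/% 2L, 1L)
  if (any(d < crop_size))
    stop(sprintf("volume extents (%s) below crop size %d; pad the volume first",
                 paste(d, collapse = "x"), crop_size))
  if (normalize) volume <- normalize_volume(volume)
  nc <- net$config$num_classes
  acc <- array(0, dim = c(nc, d))
  cov <- array(0, dim = d)
  origins <- tile_crops(d, crop_size, stride)
  for (r in seq_len(nrow(origins))) {
    org <- origins[r, ]
    ix <- lapply(1:3, function(a) org[a] + seq_len(crop_size))
    x <- array(volume[ix[[1]], ix[[2]], ix[[3]]], dim = c(1L, rep(crop_size, 3L), 1L))
    f <- svn_fwd(net, x, train = FALSE, need_cache = FALSE,
                 bn_batch = bn == "batch")
    p <- switch(head_mode,
                mean = (softmax_volume(f$main_logits) +
                        softmax_volume(f$aux_logits)) / 2,
                main = softmax_volume(f$main_logits),
                aux = softmax_volume(f$aux_logits))
    p <- array(p, dim = c(nc, rep(crop_size, 3L)))
    if (hard_vote) {
      pm <- matrix(p, nc, crop_size^3)
      lab <- max.col(t(pm), ties.method = "first")
      p <- array(0, dim = dim(p))
      pm <- matrix(p, nc, crop_size^3)
      pm[cbind(lab, seq_along(lab))] <- 1
      p <- array(pm, dim = c(nc, rep(crop_size, 3L)))
    }
    acc[, ix[[1]], ix[[2]], ix[[3]]] <- acc[, ix[[1]], ix[[2]], ix[[3]]] + p
    cov[ix[[1]], ix[[2]], ix[[3]]] <- cov[ix[[1]], ix[[2]], ix[[3]]] + 1
  }
  stopifnot(all(cov >= 1))
  prob <- acc / rep(as.vector(cov), each = nc)
  pm <- matrix(prob, nc, prod(d))
  label <- array(max.col(t(pm), ties.method = "first") - 1L, dim = d)
  list(label = label, prob = prob)
}

#' Predict method for SparseVoxNet
#'
#' Convenience wrapper around [predict_volume()]; the input volume is
#' z-score normalized by default.
#'
#' @param object A `sparsevoxnet`.
#' @param volume 3-D numeric array or `svn_volume`.
#' @param ... Passed to [predict_volume()].
#' @param normalize Standardize the volume first.
#' @return See [predict_volume()].
#' @export
predict.sparsevoxnet <- function(object, volume, ..., normalize = TRUE) {
  predict_volume(object, volume, ..., normalize = normalize)
}

#' @export
predict.svn_fit <- function(object, volume, ...) {
  predict.sparsevoxnet(object$net, volume, ...)
}
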
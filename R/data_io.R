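# NIfTI volume I/O, intensity normalization, rotation augmentation, and
# random crop sampling. Volumes are carried as plain 3-D arrays plus a
# 4x4 affine (NIfTI-1 convention, via RNifti); labels use the HVSMR
# encoding 0 = background, 1 = myocardium, 2 = blood pool.

#' Read a NIfTI image volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `svn_volume`: list with `data` (3-D numeric array), `affine`
#'   (4x4 matrix), and `spacing` (voxel edge lengths per axis).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  aff <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(aff, "try-error")) aff <- diag(4)
  data <- array(as.double(img), dim = dim(img))
  if (length(dim(data)) != 3L)
    stop(sprintf("%s: expected a 3-D volume, got %d dimensions",
                 path, length(dim(data))))
  if (!all(is.finite(data)))
    stop(sprintf("%s: volume contains non-finite values", path))
  structure(list(data = data, affine = unclass(aff),
                 spacing = abs(RNifti::pixdim(img))[1:3]),
            class = "svn_volume")
}

#' Read and validate a NIfTI label volume
#'
#' @param path Path to a label file; values must lie in \{0, 1, 2\}.
#' @param allowed Permitted label values.
#' @return An `svn_labels`: list with `data` (3-D integer array), `affine`,
#'   `spacing`.
#' @export
read_labels <- function(path, allowed = 0:2) {
  v <- read_volume(path)
  lab <- round(v$data)
  if (max(abs(lab - v$data)) > 1e-6)
    stop(sprintf("%s: label volume contains non-integer values", path))
  bad <- setdiff(unique(as.vector(lab)), allowed)
  if (length(bad))
    stop(sprintf("%s: unknown label value(s): %s", path,
                 paste(sort(bad), collapse = ", ")))
  structure(list(data = array(as.integer(lab), dim = dim(lab)),
                 affine = v$affine, spacing = v$spacing),
            class = "svn_labels")
}

#' Write a 3-D array as NIfTI
#'
#' @param data 3-D array (numeric image or integer labels).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing per axis; the affine is the corresponding
#'   diagonal scaling.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L)
  img <- RNifti::asNifti(array(as.double(data), dim = dim(data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Z-score intensity normalization
#'
#' Per-volume standardization to mean 0 and unit variance (population
#' convention, denominator `n`).
#'
#' @param v An `svn_volume` or a plain 3-D numeric array.
#' @return Same type as the input, standardized.
#' @export
normalize_volume <- function(v) {
  arr <- if (inherits(v, "svn_volume")) v$data else v
  mu <- mean(arr)
  sd_pop <- sqrt(mean((arr - mu)^2))
  if (sd_pop == 0) stop("cannot normalize a constant-intensity volume")
  out <- (arr - mu) / sd_pop
  if (inherits(v, "svn_volume")) {
    v$data <- out
    v
  } else out
}

# The 24 orientation-preserving axis-aligned cube rotations, enumerated as
# (axis permutation, per-axis reversal) pairs with determinant +1.
rotations24 <- function() {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  perm_sign <- c(1, -1, -1, 1, 1, -1)
  rots <- list()
  for (p in seq_along(perms)) {
    for (f in 0:7) {
      flips <- c(bitwAnd(f, 1L) > 0L, bitwAnd(f, 2L) > 0L, bitwAnd(f, 4L) > 0L)
      if (perm_sign[p] * prod(ifelse(flips, -1, 1)) == 1)
        rots[[length(rots) + 1L]] <- list(perm = perms[[p]], flip = flips)
    }
  }
  rots
}

apply_rotation <- function(arr, rot) {
  out <- aperm(arr, rot$perm)
  d <- dim(out)
  idx <- lapply(1:3, function(a) if (rot$flip[a]) rev(seq_len(d[a])) else seq_len(d[a]))
  out[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Rotation augmentation of a crop sample
#'
#' Applies one of the 24 orientation-preserving 90-degree cube rotations,
#' drawn uniformly, jointly to image and label (a pure index permutation:
#' labels need no interpolation). Cubic crops are required so the rotated
#' sample keeps its shape.
#'
#' @param sample A crop sample: list with `image` and `label` 3-D arrays
#'   (equal cubic shape) and optionally `origin`.
#' @param seed Optional integer; when given, the draw is made reproducible
#'   by seeding the session RNG.
#' @param rotation Optional fixed rotation index 1..24 (overrides the
#'   random draw; 1 is the identity).
#' @return The rotated sample.
#' @export
augment_crop <- function(sample, seed = NULL, rotation = NULL) {
  stopifnot(is.list(sample), !is.null(sample$image), !is.null(sample$label))
  if (length(unique(dim(sample$image))) != 1L)
    stop("rotation augmentation requires cubic crops")
  rots <- rotations24()
  if (!is.null(seed)) set.seed(seed)
  k <- if (is.null(rotation)) sample.int(length(rots), 1L) else as.integer(rotation)
  rot <- rots[[k]]
  sample$image <- apply_rotation(sample$image, rot)
  sample$label <- apply_rotation(sample$label, rot)
  sample$rotation <- k
  sample
}

#' Sample random axis-aligned cubic crops
#'
#' Draws `n` uniformly positioned, fully contained cubes from a paired
#' image/label volume.
#'
#' @param image 3-D numeric array.
#' @param label 3-D integer array of the same shape.
#' @param crop_size Cube edge length; every extent must be at least this
#'   large (zero-pad smaller volumes explicitly with [pad_volume()]).
#' @param n Number of crops.
#' @param seed Optional integer seed for reproducible placement.
#' @return List of crop samples: `image`, `label`, `origin` (0-based
#'   integer offsets satisfying `origin + crop_size <= extent`).
#' @export
sample_crops <- function(image, label, crop_size, n, seed = NULL) {
  d <- dim(image)
  stopifnot(identical(d, dim(label)))
  if (any(d < crop_size))
    stop(sprintf(paste("volume extents (%s) are smaller than crop size %d;",
                       "pad the volume first (pad_volume)"),
                 paste(d, collapse = "x"), crop_size))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    org <- vapply(d, function(e) sample.int(e - crop_size + 1L, 1L) - 1L, integer(1))
    ix <- lapply(1:3, function(a) org[a] + seq_len(crop_size))
    list(image = image[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
         label = label[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
         origin = org)
  })
}

#' Zero-pad a volume symmetrically to a minimum extent
#'
#' @param arr 3-D array.
#' @param min_extent Target minimum edge length per axis.
#' @param value Fill value (0 for images, 0 = background for labels).
#' @return The padded array.
#' @export
pad_volume <- function(arr, min_extent, value = 0) {
  d <- dim(arr)
  target <- pmax(d, min_extent)
  if (all(target == d)) return(arr)
  out <- array(value, dim = target)
  lo <- (target - d) %/% 2L
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- arr
  out
}

#' Read a train/test manifest
#'
#' A manifest is a CSV with columns `image`, `label`, `split` (values
#' `train` or `test`); relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return A `data.frame` with absolute `image`/`label` paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "label", "split")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest %s must have columns: %s", path,
                 paste(need, collapse = ", ")))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$image <- fix(m$image)
  m$label <- fix(m$label)
  m
}
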
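# Synthetic cardiac phantom: a bright ellipsoidal blood pool enclosed by a
# mid-intensity myocardial shell on a dark noisy background, written as
# paired NIfTI image/label volumes so the full pipeline is exercisable
# without external data.

#' Phantom configuration
#'
#' Geometry and intensity model of one synthetic cardiac phantom. The
#' blood pool is an ellipsoid (label 2), the myocardium a surrounding
#' shell of randomized thickness (label 1), the rest background (label 0).
#' Image intensities are the class means plus Gaussian noise, optionally
#' modulated by a smooth multiplicative bias field.
#'
#' @param extent Cube edge length in voxels.
#' @param intensities Class mean intensities `(background, myocardium,
#'   blood pool)`, strictly increasing.
#' @param noise_std Gaussian noise standard deviation on the same
#'   intensity scale.
#' @param thickness_range Myocardial shell thickness bounds in voxels
#'   (drawn uniformly).
#' @param axis_range Blood-pool semi-axis bounds as fractions of the
#'   extent.
#' @param center_jitter Maximal displacement of the phantom center from
#'   the volume center, as a fraction of the extent.
#' @param bias_field Add a smooth multiplicative intensity bias (a mild
#'   large-scale gradient, emulating coil shading).
#' @param seed Integer seed; the phantom is a deterministic function of
#'   the config.
#' @return An `svn_phantom_config`.
#' @export
phantom_config <- function(extent = 96L, intensities = c(0.2, 0.5, 0.9),
                           noise_std = 0.05, thickness_range = c(3, 6),
                           axis_range = c(0.20, 0.32), center_jitter = 0.06,
                           bias_field = FALSE, seed = 1L) {
  stopifnot(extent >= 16, length(intensities) == 3,
            all(diff(intensities) > 0), noise_std >= 0,
            thickness_range[1] >= 1, diff(thickness_range) >= 0,
            axis_range[1] > 0, axis_range[2] < 0.5)
  structure(list(extent = as.integer(extent), intensities = intensities,
                 noise_std = noise_std, thickness_range = thickness_range,
                 axis_range = axis_range, center_jitter = center_jitter,
                 bias_field = bias_field, seed = as.integer(seed)),
            class = "svn_phantom_config")
}

#' Generate one synthetic cardiac phantom
#'
#' @param config An `svn_phantom_config`.
#' @return List with `image` (3-D numeric array), `label` (3-D integer
#'   array over \{0, 1, 2\}), `spacing`, and the `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "svn_phantom_config"))
  set.seed(config$seed)
  e <- config$extent
  coords <- seq_len(e)
  for (attempt in 1:10) {
    ctr <- e / 2 + stats::runif(3, -1, 1) * config$center_jitter * e
    ax <- stats::runif(3, config$axis_range[1], config$axis_range[2]) * e
    th <- stats::runif(1, config$thickness_range[1], config$thickness_range[2])
    # squared normalized radius fields for inner and outer ellipsoids
    q <- function(axes) {
      rx <- ((coords - ctr[1]) / axes[1])^2
      ry <- ((coords - ctr[2]) / axes[2])^2
      rz <- ((coords - ctr[3]) / axes[3])^2
      outer(outer(rx, ry, "+"), rz, "+")
    }
    inner <- q(ax) <= 1
    outer_e <- q(ax + th) <= 1
    label <- array(0L, dim = c(e, e, e))
    label[outer_e] <- 1L
    label[inner] <- 2L
    if (any(label == 1L) && any(label == 2L)) break
    if (attempt == 10)
      stop("degenerate phantom shell after 10 attempts; enlarge the extent")
  }
  img <- config$intensities[label + 1L]
  dim(img) <- dim(label)
  if (config$bias_field) {
    g <- outer(outer(coords / e, coords / e, "+"), coords / e, "+") / 3
    img <- img * (0.9 + 0.2 * g)
  }
  if (config$noise_std > 0)
    img <- img + stats::rnorm(length(img), 0, config$noise_std)
  list(image = img, label = label, spacing = c(1, 1, 1), config = config)
}

#' Generate a phantom dataset with manifest
#'
#' Writes `n` randomized phantoms as paired NIfTI files plus a CSV
#' manifest with a 70/30 train/test split.
#'
#' @param n Number of phantoms.
#' @param out_dir Output directory (created if missing).
#' @param config_template An `svn_phantom_config`; each phantom uses a
#'   seed derived from `seed` and its index.
#' @param seed Master seed for the dataset.
#' @return Path of the written manifest CSV.
#' @export
generate_dataset <- function(n, out_dir, config_template = phantom_config(),
                             seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_train <- ceiling(0.7 * n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config_template
    cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    ph <- generate_phantom(cfg)
    img_path <- file.path(out_dir, sprintf("phantom_%03d_image.nii.gz", i))
    lab_path <- file.path(out_dir, sprintf("phantom_%03d_label.nii.gz", i))
    write_volume(ph$image, img_path, ph$spacing)
    write_volume(ph$label, lab_path, ph$spacing)
    rows[[i]] <- data.frame(image = basename(img_path), label = basename(lab_path),
                            split = if (i <= n_train) "train" else "test",
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  mpath
}
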
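# Segmentation metrics: Dice overlap, average symmetric surface distance
# (ADB) with 18-neighborhood surface extraction, and Hausdorff distance.
# Distances are exact Euclidean nearest-point distances computed through a
# separable squared distance transform, scaled by voxel spacing.

check_mask_pair <- function(r, g) {
  if (!identical(dim(r), dim(g)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(r), collapse = "x"), paste(dim(g), collapse = "x")))
}

as_mask <- function(m) {
  if (is.null(dim(m)) || length(dim(m)) != 3L)
    stop("masks must be 3-D arrays")
  storage.mode(m) <- "logical"
  m
}

#' Dice coefficient
#'
#' `2 |R intersect G| / (|R| + |G|)`; 1 when both masks are empty.
#'
#' @param r,g 3-D logical arrays of identical shape (prediction and ground
#'   truth).
#' @return Overlap fraction in `[0, 1]`.
#' @export
dice <- function(r, g) {
  r <- as_mask(r); g <- as_mask(g)
  check_mask_pair(r, g)
  denom <- sum(r) + sum(g)
  if (denom == 0L) return(1)
  2 * sum(r & g) / denom
}

# Logical array marking voxels of `mask` with at least one 18-neighbor
# (face or edge adjacency) outside the mask; out-of-bounds counts as
# outside.
surface_mask <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("surface of an empty mask is undefined")
  d <- dim(mask)
  all_in <- array(TRUE, dim = d)
  idx_src <- function(n, s) {             # source indices for offset s, FALSE beyond
    if (s == 0L) seq_len(n) else if (s == 1L) c(seq_len(n - 1L) + 1L, NA) else
      c(NA, seq_len(n - 1L))
  }
  for (ox in -1L:1L) for (oy in -1L:1L) for (oz in -1L:1L) {
    if (ox == 0L && oy == 0L && oz == 0L) next
    if (abs(ox) + abs(oy) + abs(oz) == 3L) next  # corners excluded
    ix <- idx_src(d[1L], ox); iy <- idx_src(d[2L], oy); iz <- idx_src(d[3L], oz)
    nb <- mask[ix, iy, iz, drop = FALSE]
    nb[is.na(nb)] <- FALSE
    all_in <- all_in & nb
  }
  mask & !all_in
}

#' Surface voxels under the 18-neighborhood rule
#'
#' A mask voxel is a surface voxel when one or more of its 18 neighbors
#' (26-neighborhood minus the 8 corner offsets) lies outside the mask;
#' voxels touching the array border are surface voxels.
#'
#' @param mask Nonempty 3-D logical array.
#' @return Integer matrix of 1-based voxel coordinates, one row per
#'   surface voxel.
#' @export
surface_voxels <- function(mask) {
  which(surface_mask(mask), arr.ind = TRUE)
}

#' Average symmetric surface distance (ADB)
#'
#' Mean Euclidean distance from every surface voxel of each mask to the
#' nearest surface voxel of the other, averaged over both surfaces.
#' Zero when the boundaries match exactly.
#'
#' @param r,g Nonempty 3-D logical arrays of identical shape.
#' @param spacing Voxel spacing per axis (distances are in spacing units;
#'   the default 1,1,1 gives voxel units).
#' @return Non-negative length.
#' @export
adb <- function(r, g, spacing = c(1, 1, 1)) {
  r <- as_mask(r); g <- as_mask(g)
  check_mask_pair(r, g)
  if (!any(r)) stop("ADB is undefined for an empty prediction mask")
  if (!any(g)) stop("ADB is undefined for an empty ground-truth mask")
  sr <- surface_mask(r)
  sg <- surface_mask(g)
  dg <- cpp_edt3d(sg, dim(sg), as.double(spacing))
  dr <- cpp_edt3d(sr, dim(sr), as.double(spacing))
  (sum(dg[sr]) + sum(dr[sg])) / (sum(sr) + sum(sg))
}

#' Hausdorff distance
#'
#' Directed: `max_{r in R} min_{g in G} d(r, g)` over full voxel
#' coordinate sets (not surfaces). The symmetric default takes the larger
#' of both directions. `surface = TRUE` restricts both sets to their
#' 18-neighborhood surfaces for comparison with surface-based toolkits.
#'
#' @param r,g Nonempty 3-D logical arrays of identical shape.
#' @param mode `"symmetric"` (default) or `"directed"` (R towards G).
#' @param spacing Voxel spacing per axis.
#' @param surface Use surface voxel sets instead of full voxel sets.
#' @return Non-negative length.
#' @export
hausdorff <- function(r, g, mode = c("symmetric", "directed"),
                      spacing = c(1, 1, 1), surface = FALSE) {
  mode <- match.arg(mode)
  r <- as_mask(r); g <- as_mask(g)
  check_mask_pair(r, g)
  if (!any(r) || !any(g)) stop("Hausdorff distance is undefined for empty masks")
  if (surface) {
    r <- surface_mask(r)
    g <- surface_mask(g)
  }
  dg <- cpp_edt3d(g, dim(g), as.double(spacing))
  d_rg <- max(dg[r])
  if (mode == "directed") return(d_rg)
  dr <- cpp_edt3d(r, dim(r), as.double(spacing))
  max(d_rg, max(dr[g]))
}

#' Per-class segmentation report
#'
#' Dice, ADB, and symmetric Hausdorff distance for each foreground class
#' of a 3-class label volume (1 = myocardium, 2 = blood pool); background
#' is never scored.
#'
#' @param pred,truth 3-D integer label arrays over \{0, 1, 2\}.
#' @param spacing Voxel spacing per axis.
#' @param classes Named integer vector of class codes to score.
#' @return A `data.frame` with columns `class`, `label`, `dice`, `adb`,
#'   `hausdorff`.
#' @export
evaluate_segmentation <- function(pred, truth, spacing = c(1, 1, 1),
                                  classes = c(myocardium = 1L, blood_pool = 2L)) {
  check_mask_pair(pred, truth)
  rows <- lapply(seq_along(classes), function(i) {
    cl <- classes[i]
    r <- pred == cl
    g <- truth == cl
    data.frame(class = names(classes)[i], label = as.integer(cl),
               dice = dice(r, g),
               adb = if (any(r) && any(g)) adb(r, g, spacing) else NA_real_,
               hausdorff = if (any(r) && any(g)) hausdorff(r, g, spacing = spacing)
                           else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
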
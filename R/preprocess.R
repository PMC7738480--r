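# Image conditioning and volume <-> slice plumbing.
#
# Volumes are R arrays indexed (x, y, z) with x running left -> right,
# y posterior -> anterior, z inferior -> superior. Plane conventions:
#   axial    = fixed z, slice matrix (x, y)
#   coronal  = fixed y, slice matrix (x, z)
#   sagittal = fixed x, slice matrix (y, z)
# so the first in-plane axis of axial and coronal slices is the left-right
# axis, which is what a "horizontal" flip inverts.

PLANES <- c("axial", "coronal", "sagittal")

plane_axes <- function(plane) {
  switch(plane,
         axial = list(slice_axis = 3L, inplane = c(1L, 2L)),
         coronal = list(slice_axis = 2L, inplane = c(1L, 3L)),
         sagittal = list(slice_axis = 1L, inplane = c(2L, 3L)),
         stop("unknown plane: ", plane))
}

#' Apply a brain mask to an intensity volume
#'
#' Voxels outside the mask become exactly zero.
#'
#' @param vol 3D intensity array.
#' @param mask binary 3D array of the same shape.
#' @return masked volume.
#' @export
apply_brain_mask <- function(vol, mask) {
  if (!identical(dim(vol), dim(mask)))
    stop("volume and mask shapes differ")
  mv <- as.vector(mask)
  if (!all(mv %in% c(0, 1)))
    stop("mask must be binary")
  vol * array(mv, dim(vol))
}

# mask = brain voxels dilated by `dilate_vox` (Euclidean), the analogue of
# the dilated template mask used to strip non-brain voxels
brain_mask <- function(labels, dilate_vox = 2) {
  d2 <- cpp_edt3(as.vector(labels > 0), dim(labels))
  array(as.numeric(d2 <= dilate_vox^2), dim(labels))
}

#' Z-score intensity normalization
#'
#' Centers and scales the intensity distribution to mean 0, sd 1. The
#' statistics are computed over the in-mask (nonzero) voxels by default so
#' that masked-out background and later zero padding do not shift them;
#' out-of-support voxels are left at zero, which is the post-transform
#' background level.
#'
#' @param vol 3D intensity array (brain-masked).
#' @param support "nonzero" (default) or "all".
#' @return normalized volume.
#' @export
zscore_normalize <- function(vol, support = c("nonzero", "all")) {
  support <- match.arg(support)
  sel <- if (support == "nonzero") vol != 0 else array(TRUE, dim(vol))
  x <- vol[sel]
  if (length(unique(x)) < 2L)
    stop("degenerate input: fewer than 2 distinct intensity values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))  # population sd: the z-transform proper
  if (s == 0) stop("degenerate input: zero variance")
  vol[sel] <- (x - m) / s
  vol
}

#' Slice a volume into a padded 2D stack
#'
#' Crops the two in-plane axes to the brain bounding box, then pads
#' symmetrically with a constant to `target x target`. Every index along
#' the slicing axis is kept (background-only slices included), so a
#' `96^3` volume yields 96 slices in each plane. The recorded geometry
#' makes [reassemble_stack()] an exact inverse.
#'
#' @param vol 3D array (intensity or labels).
#' @param plane one of "axial", "coronal", "sagittal".
#' @param target in-plane output size (default 128).
#' @param bbox optional 3x2 matrix of 1-based inclusive bounds per axis
#'   (e.g. from the mask); defaults to the bounding box of nonzero voxels.
#' @param background constant used for padding (0 for intensity and for the
#'   background label).
#' @param label_scheme "full5" or "sagittal3"; recorded for downstream
#'   checks.
#' @return an object of class `slice_stack`: list(plane, slices
#'   `(target, target, n)`, geometry, label_scheme, target).
#' @export
slice_stack <- function(vol, plane = PLANES, target = 128L, bbox = NULL,
                        background = 0, label_scheme = "full5") {
  plane <- match.arg(plane)
  target <- as.integer(target)
  d <- dim(vol)
  if (is.null(bbox)) bbox <- volume_bbox(vol)
  ax <- plane_axes(plane)
  lo <- bbox[ax$inplane, 1]
  hi <- bbox[ax$inplane, 2]
  w <- hi - lo + 1L
  if (any(w > target))
    stop("brain bounding box exceeds ", target,
         " in-plane; resample the volume first")
  pad_lo <- (target - w) %/% 2L
  ns <- d[ax$slice_axis]

  slices <- array(background, c(target, target, ns))
  idx1 <- lo[1]:hi[1]
  idx2 <- lo[2]:hi[2]
  for (s in seq_len(ns)) {
    m <- extract_slice(vol, plane, s)
    slices[pad_lo[1] + seq_len(w[1]), pad_lo[2] + seq_len(w[2]), s] <-
      m[idx1, idx2]
  }
  geometry <- list(plane = plane, orig_dim = d, crop_lo = lo, crop_hi = hi,
                   pad_lo = pad_lo, target = target, n_slices = ns,
                   background = background)
  structure(list(plane = plane, slices = slices, geometry = geometry,
                 label_scheme = label_scheme, target = target),
            class = "slice_stack")
}

volume_bbox <- function(vol) {
  nz <- which(vol != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L)
    return(cbind(rep(1L, 3), dim(vol)))
  cbind(apply(nz, 2, min), apply(nz, 2, max))
}

extract_slice <- function(vol, plane, s) {
  switch(plane,
         axial = vol[, , s],
         coronal = vol[, s, ],
         sagittal = vol[s, , ])
}

insert_slice <- function(vol, plane, s, m) {
  switch(plane,
         axial = vol[, , s] <- m,
         coronal = vol[, s, ] <- m,
         sagittal = vol[s, , ] <- m)
  vol
}

#' Reassemble a slice stack onto the original grid
#'
#' Exact inverse of [slice_stack()]: drops the padding, restores the
#' in-plane crop, and fills voxels outside the crop box with the stack's
#' background constant.
#'
#' @param stack a `slice_stack` (its `slices` may have been replaced by
#'   maps of identical shape).
#' @return 3D array on the original grid.
#' @export
reassemble_stack <- function(stack) {
  g <- stack$geometry
  vol <- array(g$background, g$orig_dim)
  w <- g$crop_hi - g$crop_lo + 1L
  for (s in seq_len(g$n_slices)) {
    m <- array(g$background, g$orig_dim[plane_axes(g$plane)$inplane])
    m[g$crop_lo[1]:g$crop_hi[1], g$crop_lo[2]:g$crop_hi[2]] <-
      stack$slices[g$pad_lo[1] + seq_len(w[1]), g$pad_lo[2] + seq_len(w[2]), s]
    vol <- insert_slice(vol, g$plane, s, m)
  }
  vol
}

#' Remap labels for a plane's scheme
#'
#' Axial and coronal networks use the full 5-label scheme. Sagittal slices
#' carry no left/right information, so both inner labels collapse to 1 and
#' both cortical-plate labels to 2.
#'
#' @param labels integer 3D array with values 0..4.
#' @param plane one of "axial", "coronal", "sagittal".
#' @return remapped label array.
#' @export
remap_labels_for_plane <- function(labels, plane = PLANES) {
  plane <- match.arg(plane)
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:4))
    stop("labels out of range 0..4")
  if (plane != "sagittal") return(labels)
  map <- c(0L, 1L, 1L, 2L, 2L)
  array(map[labels + 1L], dim(labels))
}

#' Reassemble per-slice probability maps into a probability volume
#'
#' Takes the per-slice softmax maps of a plane network (shape
#' `(target, target, labels, n_slices)`) and the geometry of the stack they
#' were predicted from, and rebuilds a 4D probability volume on the
#' original grid. Voxels outside the in-plane crop box were never
#' predicted; they receive `background_weight` on the background channel
#' (1 for a single softmax prediction, `n` for a sum of `n` predictions),
#' so per-voxel label sums stay consistent.
#'
#' @param maps 4D array of per-slice label maps.
#' @param geometry geometry record of the source [slice_stack()].
#' @param background_weight value for the background channel outside the
#'   predicted region.
#' @return 4D array `(nx, ny, nz, labels)`.
#' @export
reassemble_probabilities <- function(maps, geometry, background_weight = 1) {
  g <- geometry
  dm <- dim(maps)
  if (length(dm) != 4L || dm[1] != g$target || dm[2] != g$target ||
      dm[4] != g$n_slices)
    stop("maps shape inconsistent with geometry")
  L <- dm[3]
  vol <- array(0, c(g$orig_dim, L))
  vol[, , , 1] <- background_weight
  w <- g$crop_hi - g$crop_lo + 1L
  ax <- plane_axes(g$plane)
  for (l in seq_len(L)) {
    st <- list(slices = maps[, , l, , drop = TRUE], geometry = g)
    st$geometry$background <- if (l == 1L) background_weight else 0
    dim(st$slices) <- c(g$target, g$target, g$n_slices)
    st$geometry$background <- st$geometry$background
    class(st) <- "slice_stack"
    vol[, , , l] <- reassemble_stack(st)
  }
  vol
}

# JSON sidecar for the slicing geometry
geometry_to_json <- function(geometry, path = NULL) {
  js <- jsonlite::toJSON(geometry, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

geometry_from_json <- function(path) {
  g <- jsonlite::fromJSON(path)
  g$orig_dim <- as.integer(g$orig_dim)
  g$crop_lo <- as.integer(g$crop_lo)
  g$crop_hi <- as.integer(g$crop_hi)
  g$pad_lo <- as.integer(g$pad_lo)
  g
}
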
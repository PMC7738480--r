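# Test-time augmentation, multi-view aggregation and their combination.
#
# Flip-based TTA predicts on flipped copies of each slice and undoes the
# flip on the softmax output. When the flip inverts the left-right in-plane
# axis of an axial or coronal slice, anatomical left and right exchange, so
# the paired label channels (left/right inner, left/right cortical plate)
# are swapped on inversion. Sagittal slices carry no left/right labels and
# never swap.

#' Flip transform for test-time augmentation
#'
#' @param axes character subset of `c("horizontal", "vertical")`;
#'   `character(0)` is the identity. "horizontal" is the left-right
#'   in-plane axis for axial and coronal slices.
#' @param plane the plane the transform acts on.
#' @param label_scheme "full5" or "sagittal3".
#' @return object of class `flip_transform` with a `swaps_lr` flag.
#' @export
flip_transform <- function(axes = character(0),
                           plane = c("axial", "coronal", "sagittal"),
                           label_scheme = NULL) {
  plane <- match.arg(plane)
  stopifnot(all(axes %in% c("horizontal", "vertical")))
  if (is.null(label_scheme))
    label_scheme <- if (plane == "sagittal") "sagittal3" else "full5"
  swaps <- ("horizontal" %in% axes) && plane %in% c("axial", "coronal")
  structure(list(axes = axes, plane = plane, label_scheme = label_scheme,
                 swaps_lr = swaps),
            class = "flip_transform")
}

default_flips <- function(plane) {
  if (plane == "sagittal") {
    # three augmentations: identity, horizontal, vertical (the combined
    # flip is the one omitted, keeping 4 + 4 + 3 = 11 predictions)
    list(flip_transform(character(0), plane),
         flip_transform("horizontal", plane),
         flip_transform("vertical", plane))
  } else {
    list(flip_transform(character(0), plane),
         flip_transform("horizontal", plane),
         flip_transform("vertical", plane),
         flip_transform(c("horizontal", "vertical"), plane))
  }
}

# flip the first two dims of a (H, W[, L][, S]) array
flip_spatial <- function(x, axes) {
  if (length(axes) == 0L) return(x)
  d <- dim(x)
  args <- rep(list(quote(expr = )), length(d))
  if ("horizontal" %in% axes) args[[1]] <- rev(seq_len(d[1]))
  if ("vertical" %in% axes) args[[2]] <- rev(seq_len(d[2]))
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

swap_lr_channels <- function(maps) {
  d <- dim(maps)
  if (d[3] != 5L)
    stop("left-right label swap requested on a non 5-label map")
  maps[, , c(1L, 3L, 2L, 5L, 4L), , drop = FALSE]
}

#' Invert a TTA transform on predicted probability maps
#'
#' Undoes the spatial flip and, when the flip inverted the left-right axis
#' of a 5-label plane, swaps the paired left/right channels.
#'
#' @param maps 4D array `(H, W, labels, n_slices)` of softmax maps
#'   predicted from flipped inputs.
#' @param flip the [flip_transform()] that was applied to the inputs.
#' @return maps registered back to the original orientation.
#' @export
tta_transform_inverse <- function(maps, flip) {
  stopifnot(inherits(flip, "flip_transform"))
  out <- flip_spatial(maps, flip$axes)
  if (flip$swaps_lr) out <- swap_lr_channels(out)
  out
}

#' Sum of flip-augmented predictions for one plane
#'
#' Predicts every slice of `stack` under each flip, inverse-transforms each
#' output (with the left-right label swap where required) and sums the
#' probability maps; the result is reassembled onto the original grid.
#' Per-voxel channel sums equal the number of predictions.
#'
#' @param model a trained plane network (or mock; dispatched via
#'   [predict_stack()]).
#' @param stack the plane's intensity [slice_stack()].
#' @param flips list of [flip_transform()]; must contain the identity.
#'   Default: all four flip variants for axial/coronal, three for sagittal.
#' @return object of class `plane_probability`: list(plane, prob 4D volume
#'   `(nx, ny, nz, labels)`, n_predictions).
#' @export
tta_sum <- function(model, stack, flips = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  if (is.null(flips)) flips <- default_flips(stack$plane)
  if (length(flips) == 0L) stop("flip list must not be empty")
  if (!any(vapply(flips, function(f) length(f$axes) == 0L, logical(1))))
    stop("flip list must include the identity transform")
  acc <- NULL
  for (fl in flips) {
    fstack <- stack
    fstack$slices <- flip_spatial(stack$slices, fl$axes)
    maps <- predict_stack(model, fstack)
    maps <- tta_transform_inverse(maps, fl)
    acc <- if (is.null(acc)) maps else acc + maps
  }
  prob <- reassemble_probabilities(acc, stack$geometry,
                                   background_weight = length(flips))
  structure(list(plane = stack$plane, prob = prob,
                 n_predictions = length(flips)),
            class = "plane_probability")
}

#' Broadcast a sagittal 3-label probability volume to 5 labels
#'
#' The sagittal plane cannot separate hemispheres, so its inner-volume
#' probability is added to both the left and right inner channels and its
#' cortical-plate probability to both left and right plate channels (the
#' duplication is intentional: aggregation sums raw probabilities).
#'
#' @param pp a 3-label `plane_probability`.
#' @return a 5-label `plane_probability`.
#' @export
broadcast_sagittal <- function(pp) {
  stopifnot(inherits(pp, "plane_probability"))
  d <- dim(pp$prob)
  if (d[4] != 3L) stop("expected a 3-label probability volume")
  out <- array(0, c(d[1:3], 5L))
  out[, , , 1] <- pp$prob[, , , 1]
  out[, , , 2] <- pp$prob[, , , 2]
  out[, , , 3] <- pp$prob[, , , 2]
  out[, , , 4] <- pp$prob[, , , 3]
  out[, , , 5] <- pp$prob[, , , 3]
  pp$prob <- out
  pp
}

#' Aggregate probability volumes into a label map
#'
#' Sums the given 5-label probability volumes voxel-wise and assigns each
#' voxel the label with the highest summed probability; ties break toward
#' the lowest label index (background first).
#'
#' @param prob_volumes list of 4D arrays `(nx, ny, nz, 5)` (or 5-label
#'   `plane_probability` objects) on the same grid.
#' @return integer 3D label array with values 0..4.
#' @export
aggregate_probabilities <- function(prob_volumes) {
  vols <- lapply(prob_volumes, function(v) {
    if (inherits(v, "plane_probability")) v$prob else v
  })
  d <- dim(vols[[1]])
  if (!all(vapply(vols, function(v) identical(dim(v), d), logical(1))))
    stop("probability volumes are on different grids")
  if (d[4] != 5L) stop("expected 5-label probability volumes")
  s <- Reduce(`+`, vols)
  m <- matrix(s, ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), d[1:3])
}

#' Multi-view / TTA prediction of a preprocessed volume
#'
#' Runs the per-plane networks over a preprocessed intensity volume and
#' combines them according to `mode`:
#' \describe{
#'   \item{`mvt`}{TTA on all three planes (4 axial + 4 coronal + 3
#'     sagittal = 11 predictions), summed and argmaxed.}
#'   \item{`multiview`}{one prediction per plane (3 predictions).}
#'   \item{`tta-axi`, `tta-cor`}{four flip predictions of a single plane.}
#'   \item{`single-axi`, `single-cor`}{one prediction of a single plane.}
#' }
#'
#' @param models named list with elements `axial`, `coronal`, `sagittal`
#'   (sagittal may be omitted for single-plane modes).
#' @param volume preprocessed (masked, z-scored) 3D intensity array.
#' @param mode aggregation mode.
#' @param target in-plane slice size expected by the networks.
#' @param bbox optional precomputed 3x2 bounding box (from the brain mask).
#' @return integer label volume; attribute `n_predictions` records how many
#'   softmax predictions were aggregated.
#' @export
mvt_predict <- function(models, volume,
                        mode = c("mvt", "multiview", "tta-axi", "tta-cor",
                                 "single-axi", "single-cor"),
                        target = 128L, bbox = NULL) {
  mode <- match.arg(mode)
  if (is.null(bbox)) bbox <- volume_bbox(volume)

  planes <- switch(mode,
                   "mvt" = , "multiview" = c("axial", "coronal", "sagittal"),
                   "tta-axi" = , "single-axi" = "axial",
                   "tta-cor" = , "single-cor" = "coronal")
  tta <- mode %in% c("mvt", "tta-axi", "tta-cor")
  for (pl in planes) {
    if (is.null(models[[pl]]))
      stop("missing model for plane: ", pl)
  }

  pps <- lapply(planes, function(pl) {
    st <- slice_stack(volume, pl, target = target, bbox = bbox,
                      label_scheme = if (pl == "sagittal") "sagittal3" else "full5")
    flips <- if (tta) default_flips(pl) else list(flip_transform(character(0), pl))
    pp <- tta_sum(models[[pl]], st, flips)
    if (pl == "sagittal") pp <- broadcast_sagittal(pp)
    pp
  })
  labels <- aggregate_probabilities(pps)
  attr(labels, "n_predictions") <- sum(vapply(pps, function(p)
    p$n_predictions, numeric(1)))
  labels
}
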
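# Volume-overlap and boundary-distance evaluation metrics.

REGIONS <- c(in_L = 1L, in_R = 2L, CP_L = 3L, CP_R = 4L)

region_mask <- function(labels, region) {
  if (is.character(region)) {
    if (!region %in% names(REGIONS)) stop("unknown region: ", region)
    region <- REGIONS[[region]]
  }
  array(labels %in% region, dim(labels))
}

#' 3D Dice coefficient of a region
#'
#' `2|A n B| / (|A| + |B|)` on the binarized region. Both-empty regions
#' score 1 (perfect agreement on absence); exactly one empty scores 0.
#'
#' @param a,b integer label volumes on the same grid.
#' @param region region label(s), by id (1..4) or name
#'   (`"in_L"`, `"in_R"`, `"CP_L"`, `"CP_R"`).
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' a <- array(0L, c(8, 8, 8)); a[2:5, 2:5, 2:5] <- 3L
#' b <- array(0L, c(8, 8, 8)); b[3:6, 2:5, 2:5] <- 3L
#' dice3d(a, b, "CP_L")
#' mean_surface_distance(a, b, "CP_L", voxel_mm = 0.75)
#' @export
dice3d <- function(a, b, region) {
  if (!identical(dim(a), dim(b))) stop("label volumes are on different grids")
  A <- region_mask(a, region)
  B <- region_mask(b, region)
  na <- sum(A)
  nb <- sum(B)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(A & B) / (na + nb)
}

# face-adjacent boundary voxels of a binary mask (out-of-grid counts as
# outside)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  inside <- mask
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    n <- d[ax]
    if (by == 1L) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1L) }
    else { dst[[ax]] <- 1:(n - 1L); src[[ax]] <- 2:n }
    out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
    out
  }
  all_nb <- array(TRUE, d)
  for (ax in 1:3) for (by in c(1L, -1L)) {
    nb <- shift_and(inside, ax, by)
    all_nb <- all_nb & nb
  }
  mask & !all_nb
}

#' Symmetric mean surface distance
#'
#' Boundary voxels are region voxels with at least one face-adjacent
#' non-region neighbor. The metric averages, over the boundary voxels of
#' each volume, the Euclidean distance (exact distance transform, in mm)
#' to the other volume's boundary, and returns the mean of the two
#' directions.
#'
#' @inheritParams dice3d
#' @param voxel_mm isotropic voxel size in mm.
#' @return mean surface distance in mm.
#' @export
mean_surface_distance <- function(a, b, region, voxel_mm = 0.75) {
  if (!identical(dim(a), dim(b))) stop("label volumes are on different grids")
  A <- region_mask(a, region)
  B <- region_mask(b, region)
  if (sum(A) == 0 || sum(B) == 0)
    stop("mean surface distance undefined: empty region")
  ba <- boundary_voxels(A)
  bb <- boundary_voxels(B)
  da <- sqrt(cpp_edt3(as.vector(bb), dim(a)))  # distance to B's boundary
  db <- sqrt(cpp_edt3(as.vector(ba), dim(a)))
  msd_ab <- mean(da[as.vector(ba)])
  msd_ba <- mean(db[as.vector(bb)])
  voxel_mm * (msd_ab + msd_ba) / 2
}

#' Region volume in cubic centimeters
#'
#' @inheritParams dice3d
#' @param labels integer label volume.
#' @param voxel_mm isotropic voxel size in mm.
#' @return voxel count times voxel volume, in cc.
#' @export
region_volume_cc <- function(labels, region, voxel_mm = 0.75) {
  sum(region_mask(labels, region)) * voxel_mm^3 / 1000
}

#' Per-case segmentation metrics
#'
#' Dice coefficient and mean surface distance for the four regions.
#'
#' @param pred,truth integer label volumes.
#' @param voxel_mm voxel size in mm.
#' @return data.frame with columns region, dice, msd_mm.
#' @export
evaluate_segmentation <- function(pred, truth, voxel_mm = 0.75) {
  rows <- lapply(names(REGIONS), function(rn) {
    msd <- tryCatch(mean_surface_distance(pred, truth, rn, voxel_mm),
                    error = function(e) NA_real_)
    data.frame(region = rn, dice = dice3d(pred, truth, rn), msd_mm = msd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Agreement between automatic and manual morphometry
#'
#' Ordinary least-squares fit of the manually derived index on the
#' automatically derived one, per index column; slope near 1 and high R^2
#' indicate that automatic segmentation reproduces the manual measurement.
#'
#' @param auto,manual data.frames of paired numeric index columns (same
#'   column names, cases in the same order).
#' @return data.frame with columns index, slope, r_squared.
#' @export
index_agreement <- function(auto, manual) {
  cols <- intersect(names(auto), names(manual))
  cols <- cols[vapply(cols, function(cn) is.numeric(auto[[cn]]), logical(1))]
  if (length(cols) == 0L) stop("no shared numeric index columns")
  if (nrow(auto) < 3L) stop("need at least 3 paired cases")
  rows <- lapply(cols, function(cn) {
    fit <- stats::lm(manual[[cn]] ~ auto[[cn]])
    # exact agreement triggers summary.lm's perfect-fit warning; R^2 = 1
    # is the correct answer there
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(index = cn, slope = unname(stats::coef(fit)[2]),
               r_squared = r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
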
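#' Parametric folded-shell phantom specification
#'
#' Describes a synthetic two-hemisphere volume that mimics the geometry of a
#' preprocessed, template-aligned fetal brain MRI: for each hemisphere a
#' smooth ellipsoidal "inner" compartment is wrapped in a thin corrugated
#' shell standing in for the cortical plate. The shell's outer boundary is
#' an ellipsoid whose radius is perturbed by
#' `fold_amplitude_mm * sin(f * theta) * sin(f * phi)` in spherical angles,
#' a simple area-increasing corrugation whose amplitude plays the role of
#' folding complexity (the gestational-age surrogate).
#'
#' @param grid_shape voxel counts per axis (default `c(96, 96, 96)`).
#' @param voxel_mm isotropic voxel spacing in mm (default 0.75, the
#'   reconstruction grid).
#' @param hemisphere_centers 2 x 3 matrix of centers in mm; default places
#'   the hemispheres symmetrically about the mid-sagittal plane.
#' @param hemisphere_radii 2 x 3 matrix of ellipsoid semi-axes in mm.
#' @param shell_thickness_mm radial thickness of the cortical shell.
#' @param fold_amplitude_mm corrugation amplitude in mm.
#' @param fold_frequency integer angular frequency of the corrugation.
#' @param intensity_means mean intensities `c(background, inner, shell)`.
#' @param noise_sd additive i.i.d. Gaussian noise standard deviation.
#' @param blur_fwhm_mm partial-volume smoothing FWHM in mm.
#' @param seed integer seed; a fixed seed gives bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 48, 48), fold_amplitude_mm = 1)
#' spec
#' case <- generate_phantom(spec)
#' table(case$labels)
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L), voxel_mm = 0.75,
                         hemisphere_centers = NULL, hemisphere_radii = NULL,
                         shell_thickness_mm = 1.5, fold_amplitude_mm = 1.5,
                         fold_frequency = 5L,
                         intensity_means = c(0, 1, 0.45),
                         noise_sd = 0.1, blur_fwhm_mm = 1.2, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L), voxel_mm > 0)
  box <- grid_shape * voxel_mm
  if (is.null(hemisphere_radii))
    hemisphere_radii <- rbind(box * c(0.16, 0.25, 0.20),
                              box * c(0.16, 0.25, 0.20))
  if (is.null(hemisphere_centers)) {
    off <- 0.23 * box[1]
    hemisphere_centers <- rbind(c(box[1] / 2 - off, box[2] / 2, box[3] / 2),
                                c(box[1] / 2 + off, box[2] / 2, box[3] / 2))
  }
  hemisphere_centers <- as.matrix(hemisphere_centers)
  hemisphere_radii <- as.matrix(hemisphere_radii)
  stopifnot(identical(dim(hemisphere_centers), c(2L, 3L)),
            identical(dim(hemisphere_radii), c(2L, 3L)))

  spec <- structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm,
                         hemisphere_centers = hemisphere_centers,
                         hemisphere_radii = hemisphere_radii,
                         shell_thickness_mm = shell_thickness_mm,
                         fold_amplitude_mm = fold_amplitude_mm,
                         fold_frequency = as.integer(fold_frequency),
                         intensity_means = intensity_means,
                         noise_sd = noise_sd, blur_fwhm_mm = blur_fwhm_mm,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  r <- spec$hemisphere_radii
  cx <- spec$hemisphere_centers[, 1]
  t <- spec$shell_thickness_mm
  if (t <= 0) stop("shell_thickness_mm must be positive")
  if (any(r <= t)) stop("hemisphere radii must exceed the shell thickness")
  if (spec$noise_sd < 0 || spec$blur_fwhm_mm < 0)
    stop("noise_sd and blur_fwhm_mm must be non-negative")
  a <- spec$fold_amplitude_mm
  if (a < 0) stop("fold_amplitude_mm must be non-negative")
  if (a >= min(r) - t)
    stop("fold_amplitude_mm must be smaller than the inner radius")
  lo <- which.min(cx)
  hi <- which.max(cx)
  if (cx[lo] + r[lo, 1] + a > cx[hi] - r[hi, 1] - a)
    stop("hemispheres overlap: increase center separation or shrink radii")
  mid <- spec$grid_shape[1] * spec$voxel_mm / 2
  if (cx[lo] + r[lo, 1] + a > mid || cx[hi] - r[hi, 1] - a < mid)
    stop("a hemisphere crosses the mid-sagittal plane")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Folded-shell phantom: grid %s @ %.2f mm, shell %.2f mm, fold %.2f mm (f=%d), seed %d\n",
    paste(x$grid_shape, collapse = "x"), x$voxel_mm, x$shell_thickness_mm,
    x$fold_amplitude_mm, x$fold_frequency, x$seed))
  invisible(x)
}

# folding complexity in [0, 1]: amplitude relative to the largest amplitude
# that keeps the corrugation well inside the inner compartment and clear of
# the mid-sagittal plane
max_fold_amplitude <- function(spec) {
  mid <- spec$grid_shape[1] * spec$voxel_mm / 2
  margin <- min(abs(spec$hemisphere_centers[, 1] - mid) -
                  spec$hemisphere_radii[, 1])
  min(0.35 * (min(spec$hemisphere_radii) - spec$shell_thickness_mm),
      0.9 * margin)
}

phantom_complexity <- function(spec) {
  min(1, spec$fold_amplitude_mm / max_fold_amplitude(spec))
}

# separable Gaussian blur on a 3D array, zero padding, sigma in voxels
gauss_blur3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  rad <- max(1L, ceiling(3 * sigma_vox))
  for (ax in 1:3) {
    n <- d[ax]
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma_vox^2)))
    K[abs(row(K) - col(K)) > rad] <- 0
    K <- K / sum(exp(-(-rad:rad)^2 / (2 * sigma_vox^2)))
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Generate a phantom volume
#'
#' Builds the label volume geometrically from a [phantom_spec()] (inner
#' compartment = corrugated ellipsoid interior eroded radially by the shell
#' thickness; cortical-plate shell = the remainder of the corrugated
#' interior), splits left/right at the mid-sagittal grid plane (plane voxels
#' go left), then renders intensity as the label-mean image blurred to
#' `blur_fwhm_mm` plus additive Gaussian noise.
#'
#' Labels: 0 background, 1 left inner, 2 right inner, 3 left cortical
#' plate, 4 right cortical plate.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_case`: list with `intensity` (3D
#'   array), `labels` (3D integer array), `complexity` (scalar in
#'   `[0, 1]`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape
  v <- spec$voxel_mm
  set.seed(spec$seed)

  co <- lapply(1:3, function(a) (seq_len(gs[a]) - 0.5) * v)
  labels <- array(0L, gs)

  for (h in 1:2) {
    ctr <- spec$hemisphere_centers[h, ]
    ax <- spec$hemisphere_radii[h, ]
    dx <- array(rep(co[[1]] - ctr[1], times = gs[2] * gs[3]), gs)
    dy <- array(rep(rep(co[[2]] - ctr[2], each = gs[1]), times = gs[3]), gs)
    dz <- array(rep(co[[3]] - ctr[3], each = gs[1] * gs[2]), gs)
    r <- sqrt(dx^2 + dy^2 + dz^2)
    rho <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2 + (dz / ax[3])^2)
    re <- ifelse(rho > 1e-9, r / rho, min(ax))  # ray radius of the ellipsoid
    theta <- acos(pmin(pmax(ifelse(r > 1e-9, dz / r, 1), -1), 1))
    phi <- atan2(dy, dx)
    f <- spec$fold_frequency
    R_out <- re + spec$fold_amplitude_mm * sin(f * theta) * sin(f * phi)
    R_in <- R_out - spec$shell_thickness_mm
    inner <- r <= R_in
    shell <- !inner & r <= R_out
    labels[inner] <- if (h == 1L) 1L else 2L
    labels[shell] <- if (h == 1L) 3L else 4L
  }

  # enforce the mid-sagittal half-space rule (plane voxels belong left)
  left_cols <- seq_len(ceiling(gs[1] / 2))
  is_left <- array(FALSE, gs)
  is_left[left_cols, , ] <- TRUE
  labels[is_left & labels == 2L] <- 1L
  labels[is_left & labels == 4L] <- 3L
  labels[!is_left & labels == 1L] <- 2L
  labels[!is_left & labels == 3L] <- 4L

  mu <- spec$intensity_means
  intensity <- array(mu[1], gs)
  intensity[labels %in% c(1L, 2L)] <- mu[2]
  intensity[labels %in% c(3L, 4L)] <- mu[3]
  if (spec$blur_fwhm_mm > 0)
    intensity <- gauss_blur3(intensity, fwhm_to_sigma(spec$blur_fwhm_mm) / v)
  if (spec$noise_sd > 0)
    intensity <- intensity + array(stats::rnorm(prod(gs), 0, spec$noise_sd), gs)

  structure(list(intensity = intensity, labels = labels,
                 complexity = phantom_complexity(spec), spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  counts <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf(
    "Phantom case (complexity %.2f): grid %s, voxels bg/inL/inR/cpL/cpR = %s\n",
    x$complexity, paste(dim(x$labels), collapse = "x"),
    paste(counts, collapse = "/")))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Samples `n` phantom specifications from per-field ranges under one
#' master seed. Folding complexity is sampled uniformly from
#' `ranges$complexity` and converted to a corrugation amplitude; it is
#' recorded per case for stratification, standing in for gestational age.
#'
#' @param n number of cases (>= 1).
#' @param ranges named list of `c(lo, hi)` intervals; recognized names:
#'   `complexity`, `shell_thickness_mm`, `noise_sd`, `blur_fwhm_mm`,
#'   `size_scale` (multiplies the default radii), `fold_frequency`.
#' @param seed master seed.
#' @param grid_shape,voxel_mm grid geometry passed to [phantom_spec()].
#' @return list with `cases` (list of `phantom_case`) and `metadata`
#'   (data.frame: case id, seed, complexity and sampled spec fields).
#' @export
generate_cohort <- function(n, ranges = list(), seed = 1L,
                            grid_shape = c(96L, 96L, 96L), voxel_mm = 0.75) {
  stopifnot(n >= 1L)
  defaults <- list(complexity = c(0.25, 0.95),
                   shell_thickness_mm = c(1.5, 1.5),
                   noise_sd = c(0.1, 0.1),
                   blur_fwhm_mm = c(1.2, 1.2),
                   size_scale = c(0.95, 1.05),
                   fold_frequency = c(5, 5))
  for (nm in names(ranges)) {
    if (!nm %in% names(defaults)) stop("unknown range field: ", nm)
    rg <- ranges[[nm]]
    if (length(rg) != 2L || rg[2] < rg[1]) stop("empty range for ", nm)
    defaults[[nm]] <- rg
  }
  rg <- defaults
  set.seed(as.integer(seed))
  draw <- function(r, n) stats::runif(n, r[1], r[2])
  compl <- draw(rg$complexity, n)
  shell <- draw(rg$shell_thickness_mm, n)
  noise <- draw(rg$noise_sd, n)
  blur <- draw(rg$blur_fwhm_mm, n)
  scale <- draw(rg$size_scale, n)
  freq <- round(draw(rg$fold_frequency, n))
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  base <- phantom_spec(grid_shape = grid_shape, voxel_mm = voxel_mm)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    radii <- base$hemisphere_radii * scale[i]
    sp <- phantom_spec(grid_shape = grid_shape, voxel_mm = voxel_mm,
                       hemisphere_radii = radii,
                       shell_thickness_mm = shell[i],
                       fold_amplitude_mm = 0, fold_frequency = freq[i],
                       noise_sd = noise[i], blur_fwhm_mm = blur[i],
                       seed = seeds[i])
    sp$fold_amplitude_mm <- compl[i] * max_fold_amplitude(sp)
    validate_phantom_spec(sp)
    cases[[i]] <- generate_phantom(sp)
  }
  metadata <- data.frame(case_id = sprintf("case%03d", seq_len(n)),
                         seed = seeds, complexity = compl,
                         fold_amplitude_mm = vapply(cases, function(cs)
                           cs$spec$fold_amplitude_mm, numeric(1)),
                         fold_frequency = freq,
                         shell_thickness_mm = shell, noise_sd = noise,
                         blur_fwhm_mm = blur, size_scale = scale,
                         stringsAsFactors = FALSE)
  list(cases = cases, metadata = metadata)
}

#' Write a phantom case as paired NIfTI files
#'
#' @param case a `phantom_case`.
#' @param prefix output path prefix; writes `<prefix>_T2w.nii` and
#'   `<prefix>_labels.nii` with the voxel spacing in the header.
#' @return invisibly, the two file paths.
#' @export
write_phantom_nifti <- function(case, prefix) {
  v <- case$spec$voxel_mm
  fi <- paste0(prefix, "_T2w.nii")
  fl <- paste0(prefix, "_labels.nii")
  img <- structure(case$intensity, pixdim = c(v, v, v), pixunits = "mm")
  RNifti::writeNifti(RNifti::asNifti(img), fi)
  lab <- structure(array(as.integer(case$labels), dim(case$labels)),
                   pixdim = c(v, v, v), pixunits = "mm")
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"), fl)
  invisible(c(intensity = fi, labels = fl))
}
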
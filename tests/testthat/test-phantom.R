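test_that("smooth-shell phantom volumes match the analytic ellipsoid values", {
  sp <- phantom_spec(grid_shape = c(64L, 64L, 64L), fold_amplitude_mm = 0,
                     noise_sd = 0, blur_fwhm_mm = 0, seed = 1)
  case <- generate_phantom(sp)
  vv <- sp$voxel_mm^3
  a <- sp$hemisphere_radii[1, ]
  t <- sp$shell_thickness_mm
  V_out <- 4 / 3 * pi * prod(a)
  V_in <- 4 / 3 * pi * prod(a - t)

  left_total <- sum(case$labels %in% c(1L, 3L)) * vv
  shell <- sum(case$labels == 3L) * vv
  expect_lt(abs(left_total - V_out) / V_out, 0.05)
  expect_lt(abs(shell - (V_out - V_in)) / (V_out - V_in), 0.05)

  # no blur, no noise: exactly the three class intensities
  expect_equal(sort(unique(as.vector(case$intensity))),
               sort(sp$intensity_means))
})

test_that("phantom generation is deterministic and respects the label contract", {
  case <- fixture_phantom()
  case2 <- generate_phantom(case$spec)
  expect_identical(case$intensity, case2$intensity)
  expect_identical(case$labels, case2$labels)

  # label partition
  expect_true(all(case$labels %in% 0:4))
  expect_equal(sum(tabulate(case$labels + 1L, 5L)), length(case$labels))

  # left labels only in the left half-space, right labels only in the right
  nx <- dim(case$labels)[1]
  left_cols <- seq_len(ceiling(nx / 2))
  expect_true(all(case$labels[-left_cols, , ] %in% c(0L, 2L, 4L)))
  expect_true(all(case$labels[left_cols, , ] %in% c(0L, 1L, 3L)))

  # every cortical-plate voxel lies within the shell thickness of an inner
  # voxel of its own side
  t_vox <- ceiling(case$spec$shell_thickness_mm / case$spec$voxel_mm) + 1L
  for (side in 1:2) {
    cp <- case$labels == (side + 2L)
    d2 <- cpseg:::cpp_edt3(as.vector(case$labels == side), dim(case$labels))
    expect_true(all(sqrt(d2[as.vector(cp)]) <= t_vox + 1e-9))
  }
})

test_that("the shell separates the inner compartment from the background", {
  case <- fixture_phantom()
  lab <- case$labels
  d <- dim(lab)
  # no inner voxel may touch background across a face
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  inner <- array(lab %in% c(1L, 2L), d)
  bg <- lab == 0L
  touches <- FALSE
  for (s in shifts) {
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst <- src
    for (ax in 1:3) {
      if (s[ax] == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
      if (s[ax] == -1) { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    }
    ia <- inner[dst[[1]], dst[[2]], dst[[3]]]
    ba <- bg[src[[1]], src[[2]], src[[3]]]
    touches <- touches || any(ia & ba)
  }
  expect_false(touches)
})

test_that("increasing the fold amplitude strictly increases inner surface area", {
  areas <- vapply(c(0.5, 1.2, 2.0), function(am) {
    cc <- small_phantom(seed = 3, fold = am, noise = 0)
    surface_area(extract_inner_surface(cc$labels, "left",
                                       voxel_mm = cc$spec$voxel_mm))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("cohorts are reproducible, span the requested ranges, and validate inputs", {
  co <- generate_cohort(10, ranges = list(complexity = c(0.2, 0.9)),
                        seed = 5, grid_shape = c(48L, 48L, 48L))
  co2 <- generate_cohort(10, ranges = list(complexity = c(0.2, 0.9)),
                         seed = 5, grid_shape = c(48L, 48L, 48L))
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$cases[[4]]$intensity, co2$cases[[4]]$intensity)
  expect_equal(nrow(co$metadata), 10)
  expect_equal(length(unique(co$metadata$seed)), 10)

  cx <- co$metadata$complexity
  expect_true(all(cx >= 0.2 & cx <= 0.9))
  expect_gt(diff(range(cx)), 0.3)  # samples spread over the interval

  # degenerate (single-point) ranges: identical geometry, different noise
  cd <- generate_cohort(4, ranges = list(complexity = c(0.5, 0.5),
                                         size_scale = c(1, 1)),
                        seed = 2, grid_shape = c(48L, 48L, 48L))
  labs <- lapply(cd$cases, function(x) x$labels)
  expect_true(all(vapply(labs[-1], identical, logical(1), labs[[1]])))
  expect_false(identical(cd$cases[[1]]$intensity, cd$cases[[2]]$intensity))

  expect_error(generate_cohort(4, ranges = list(complexity = c(0.9, 0.2))),
               "empty range")
  expect_error(generate_cohort(4, ranges = list(bogus = c(0, 1))), "unknown")
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(shell_thickness_mm = 0), "positive")
  expect_error(phantom_spec(grid_shape = c(48, 48, 48),
                            hemisphere_centers = rbind(c(17, 18, 18),
                                                       c(19, 18, 18))),
               "overlap")
  expect_error(phantom_spec(fold_amplitude_mm = 50), "amplitude")
})

test_that("phantom NIfTI round-trips with voxel spacing", {
  case <- small_phantom(seed = 9, fold = 0.8)
  pre <- file.path(tempdir(), "ph")
  files <- write_phantom_nifti(case, pre)
  img <- RNifti::readNifti(files[["intensity"]])
  lab <- RNifti::readNifti(files[["labels"]])
  expect_equal(dim(img), dim(case$intensity))
  expect_equal(RNifti::pixdim(img), rep(case$spec$voxel_mm, 3))
  expect_equal(as.vector(lab), as.vector(case$labels))
  expect_equal(max(abs(img - case$intensity)), 0, tolerance = 1e-6)
  unlink(files)
})
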
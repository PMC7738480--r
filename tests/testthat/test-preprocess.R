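test_that("brain masking zeroes exactly the out-of-mask voxels", {
  case <- fixture_phantom()
  vol <- abs(case$intensity) + 1  # strictly positive
  d <- dim(vol)
  ones <- array(1, d)
  zeros <- array(0, d)
  expect_identical(apply_brain_mask(vol, ones), vol)
  expect_true(all(apply_brain_mask(vol, zeros) == 0))

  half <- array(0, d)
  half[1:(d[1] %/% 2), , ] <- 1
  masked <- apply_brain_mask(vol, half)
  expect_equal(sum(masked != 0), sum(half))

  expect_error(apply_brain_mask(vol, ones[1:10, , ]), "shape")
  expect_error(apply_brain_mask(vol, ones * 2), "binary")
})

test_that("z-score normalization is affine invariant with exact closed forms", {
  set.seed(8)
  v <- array(rnorm(20^3), c(20, 20, 20))
  v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  expect_equal(zscore_normalize(v, support = "all"), v, tolerance = 1e-10)

  w <- 3.2 * v + 7
  expect_equal(zscore_normalize(w, support = "all"),
               zscore_normalize(v, support = "all"), tolerance = 1e-10)

  two <- array(c(0, 2), c(10, 10, 10))  # half 0, half 2
  z <- zscore_normalize(two, support = "all")
  expect_equal(sort(unique(as.vector(z))), c(-1, 1))

  expect_error(zscore_normalize(array(1, c(4, 4, 4)), support = "all"),
               "degenerate")
})

test_that("slice stacks keep every slice and invert exactly", {
  case <- fixture_phantom()
  d <- dim(case$intensity)
  for (pl in c("axial", "coronal", "sagittal")) {
    st <- slice_stack(case$intensity, pl, target = 64L)
    expect_s3_class(st, "slice_stack")
    expect_equal(dim(st$slices), c(64L, 64L, d[1]))
    expect_equal(reassemble_stack(st), case$intensity)
  }

  # a centered object maps to the slice center within one voxel
  v <- array(0, c(48, 48, 48))
  v[20:29, 20:29, 20:29] <- 1
  st <- slice_stack(v, "axial", target = 64L)
  nz <- which(st$slices[, , 24] > 0, arr.ind = TRUE)
  ctr <- colMeans(nz)
  expect_true(all(abs(ctr - 32.5) <= 1))

  big <- array(1, c(200, 200, 4))
  expect_error(slice_stack(big, "axial", target = 128L), "resample")
})

test_that("label remapping collapses hemispheres only in the sagittal scheme", {
  lab <- array(rep(0:4, length.out = 4^3), c(4, 4, 4))
  expect_identical(remap_labels_for_plane(lab, "axial"), lab)
  expect_identical(remap_labels_for_plane(lab, "coronal"), lab)
  sag <- remap_labels_for_plane(lab, "sagittal")
  expect_equal(sort(unique(as.vector(sag))), 0:2)
  expect_true(all(sag[lab %in% c(1, 2)] == 1))
  expect_true(all(sag[lab %in% c(3, 4)] == 2))

  bg <- array(0L, c(4, 4, 4))
  expect_identical(remap_labels_for_plane(bg, "sagittal"), bg)
  expect_error(remap_labels_for_plane(lab + 3L, "axial"), "range")
})

test_that("probability reassembly preserves the simplex and slice bookkeeping", {
  case <- fixture_phantom()
  st <- slice_stack(case$intensity, "coronal", target = 64L)
  g <- st$geometry
  L <- 5L

  maps <- array(1 / L, c(64, 64, L, g$n_slices))
  vol <- reassemble_probabilities(maps, g)
  sums <- apply(vol, c(1, 2, 3), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)

  # a single marked slice reappears at its recorded index
  maps2 <- maps
  maps2[, , , 17] <- 0
  maps2[, , 3, 17] <- 1
  vol2 <- reassemble_probabilities(maps2, g)
  marked <- which(apply(vol2[, , , 3] == 1, 2, any))
  inplane <- g$crop_lo[1]:g$crop_hi[1]
  expect_equal(sort(unique(marked)), 17)

  # round-trip of probability-valued slices is exact inside the crop box
  set.seed(3)
  pv <- array(runif(prod(dim(case$intensity))), dim(case$intensity))
  stp <- slice_stack(pv, "axial", target = 64L,
                     bbox = cbind(rep(1L, 3), dim(pv)))
  expect_equal(reassemble_stack(stp), pv)

  expect_error(reassemble_probabilities(maps[, , , 1:3], g), "inconsistent")
})

test_that("slicing geometry survives a JSON sidecar round-trip", {
  case <- fixture_phantom()
  st <- slice_stack(case$intensity, "sagittal", target = 64L)
  path <- tempfile(fileext = ".json")
  cpseg:::geometry_to_json(st$geometry, path)
  g2 <- cpseg:::geometry_from_json(path)
  for (fld in c("plane", "orig_dim", "crop_lo", "crop_hi", "pad_lo",
                "target", "n_slices"))
    expect_equal(g2[[fld]], st$geometry[[fld]],
                 ignore_attr = TRUE)
  unlink(path)
})
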
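test_that("flip transforms know when left and right swap", {
  expect_false(flip_transform(character(0), "axial")$swaps_lr)
  expect_true(flip_transform("horizontal", "axial")$swaps_lr)
  expect_true(flip_transform(c("horizontal", "vertical"), "coronal")$swaps_lr)
  expect_false(flip_transform("vertical", "coronal")$swaps_lr)
  expect_false(flip_transform("horizontal", "sagittal")$swaps_lr)
})

test_that("inverse TTA transforms are involutive and swap channels correctly", {
  set.seed(6)
  maps <- array(runif(4 * 4 * 5 * 2), c(4, 4, 5, 2))
  id <- flip_transform(character(0), "axial")
  expect_identical(tta_transform_inverse(maps, id), maps)

  h <- flip_transform("horizontal", "axial")
  once <- tta_transform_inverse(maps, h)
  # inverse(inverse(x)) == x : flip+swap is an involution
  expect_identical(tta_transform_inverse(once, h), maps)

  # a left-only cortical-plate map becomes a mirrored right-only map
  m <- array(0, c(4, 4, 5, 1))
  m[, , 1, ] <- 1
  m[2, 3, 4, 1] <- 0.9  # left CP at row 2
  m[2, 3, 1, 1] <- 0.1
  out <- tta_transform_inverse(m, h)
  expect_equal(out[3, 3, 5, 1], 0.9)  # mirrored row, right-CP channel
  expect_equal(sum(out[, , 4, ]), 0)

  m3 <- array(runif(4 * 4 * 3), c(4, 4, 3, 1))
  expect_error(tta_transform_inverse(m3, h), "5-label")
})

test_that("tta_sum adds the expected number of equivariant predictions", {
  case <- fixture_phantom()
  vol <- class_coded_volume(case$labels)
  st <- slice_stack(vol, "axial", target = 64L)
  models <- equivariant_models()

  single <- tta_sum(models$axial, st,
                    list(flip_transform(character(0), "axial")))
  expect_equal(single$n_predictions, 1)
  sums <- apply(single$prob, c(1, 2, 3), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-9)

  full <- tta_sum(models$axial, st)
  expect_equal(full$n_predictions, 4)
  sums4 <- apply(full$prob, c(1, 2, 3), sum)
  expect_equal(range(sums4), c(4, 4), tolerance = 1e-9)
  # equivariant model: the TTA sum is 4 x the single prediction
  expect_equal(full$prob, 4 * single$prob, tolerance = 1e-9)

  # permutation safety: flip order never matters
  flips <- cpseg:::default_flips("axial")
  rev_sum <- tta_sum(models$axial, st, rev(flips))
  expect_equal(rev_sum$prob, full$prob, tolerance = 1e-12)

  expect_error(tta_sum(models$axial, st, list()), "empty")
  expect_error(tta_sum(models$axial, st,
                       list(flip_transform("horizontal", "axial"))),
               "identity")
})

test_that("sagittal broadcasting duplicates inner and plate probabilities", {
  d <- c(6, 6, 6)
  prob <- array(0, c(d, 3))
  prob[, , , 1] <- 1
  pp <- structure(list(plane = "sagittal", prob = prob, n_predictions = 1),
                  class = "plane_probability")
  out <- broadcast_sagittal(pp)
  expect_equal(dim(out$prob), c(d, 5))
  expect_true(all(out$prob[, , , 1] == 1) && all(out$prob[, , , 2:5] == 0))

  prob[3, 4, 5, ] <- c(0, 1, 0)
  pp$prob <- prob
  out <- broadcast_sagittal(pp)
  expect_equal(out$prob[3, 4, 5, 2], 1)
  expect_equal(out$prob[3, 4, 5, 3], 1)

  set.seed(2)
  pp$prob <- array(runif(prod(d) * 3), c(d, 3))
  out <- broadcast_sagittal(pp)
  expect_identical(out$prob[, , , 2], out$prob[, , , 3])
  expect_identical(out$prob[, , , 4], out$prob[, , , 5])

  expect_error(broadcast_sagittal(out), "3-label")
})

test_that("probability aggregation argmaxes the channel sum with background-first ties", {
  d <- c(3, 3, 3)
  set.seed(9)
  v <- array(runif(prod(d) * 5), c(d, 5))
  lab <- aggregate_probabilities(list(v))
  expect_equal(lab[2, 2, 2],
               which.max(v[2, 2, 2, ]) - 1L)

  uni <- array(0.2, c(d, 5))
  expect_true(all(aggregate_probabilities(list(uni)) == 0L))

  # hand-summed conflict: axial favors left CP 0.6, coronal right CP 0.7,
  # sagittal broadcast adds 0.5 to both -> right CP wins
  a <- array(0, c(d, 5)); a[, , , 4] <- 0.6
  b <- array(0, c(d, 5)); b[, , , 5] <- 0.7
  s <- array(0, c(d, 5)); s[, , , 4] <- 0.5; s[, , , 5] <- 0.5
  expect_true(all(aggregate_probabilities(list(a, b, s)) == 4L))

  expect_error(aggregate_probabilities(list(v, array(0, c(4, 4, 4, 5)))),
               "grids")
})

test_that("aggregation modes consume the documented number of predictions", {
  case <- fixture_phantom()
  vol <- class_coded_volume(case$labels)
  counter <- new.env()

  counts <- list()
  for (md in c("mvt", "multiview", "tta-axi", "tta-cor", "single-axi",
               "single-cor")) {
    counter$calls <- 0L
    models <- equivariant_models(counter)
    lab <- mvt_predict(models, vol, mode = md, target = 64L)
    counts[[md]] <- c(calls = counter$calls,
                      preds = attr(lab, "n_predictions"))
    expect_true(all(lab %in% 0:4))
  }
  expect_equal(unname(counts$mvt), c(11, 11))
  expect_equal(unname(counts$multiview), c(3, 3))
  expect_equal(unname(counts$`tta-axi`), c(4, 4))
  expect_equal(unname(counts$`tta-cor`), c(4, 4))
  expect_equal(unname(counts$`single-axi`), c(1, 1))
  expect_equal(unname(counts$`single-cor`), c(1, 1))

  expect_error(mvt_predict(models["axial"], vol, mode = "mvt", target = 64L),
               "missing model")
})

test_that("all aggregation modes agree voxel-wise for a flip-equivariant model", {
  case <- fixture_phantom()
  vol <- class_coded_volume(case$labels)
  models <- equivariant_models()
  outs <- lapply(c("single-axi", "single-cor", "tta-axi", "tta-cor",
                   "multiview", "mvt"),
                 function(md) mvt_predict(models, vol, mode = md, target = 64L))
  for (i in 2:length(outs)) {
    expect_identical(array(outs[[i]], dim(vol)), array(outs[[1]], dim(vol)))
  }
  # and the mock pipeline reproduces the phantom labels exactly
  expect_identical(array(outs[[1]], dim(vol)), array(case$labels, dim(vol)))
})
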
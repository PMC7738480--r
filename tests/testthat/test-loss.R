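test_that("per-label Dice matches the integer-arithmetic oracle on binary masks", {
  eps <- 1e-5
  for (trial in 1:25) {
    set.seed(trial)
    g <- array(as.numeric(runif(64) < 0.4), c(8, 8, 1))
    p <- array(as.numeric(runif(64) < 0.4), c(8, 8, 1))
    pair <- batch_pair(g, p)
    expect_equal(dice_per_label(pair, eps),
                 dice_oracle_binary(g > 0, p > 0, eps),
                 tolerance = 1e-12)
  }
})

test_that("Dice loss reproduces hand-counted overlap cases", {
  # |g| = 4, |p| = 4, overlap 2: D = (2*2 + eps) / (8 + eps) ~ 0.5
  g <- array(0, c(4, 4, 1)); g[1:2, 1:2, 1] <- 1
  p <- array(0, c(4, 4, 1)); p[2:3, 1:2, 1] <- 1
  pair <- batch_pair(g, p)
  expect_equal(dice_per_label(pair, 1e-5), 0.5, tolerance = 1e-4)
  expect_equal(dice_loss(pair), 0.5, tolerance = 1e-4)

  # perfect and fully disjoint predictions
  expect_equal(dice_loss(batch_pair(g, g)), 0, tolerance = 1e-5)
  q <- array(0, c(4, 4, 1)); q[3:4, 3:4, 1] <- 1
  expect_equal(dice_per_label(batch_pair(g, q), 1e-12), 0, tolerance = 1e-9)

  # loss decreases monotonically as the overlap grows 0 -> 4
  losses <- sapply(0:4, function(k) {
    pk <- array(0, c(4, 4, 1))
    if (k > 0) pk[1:2, 1:2, 1][seq_len(k)] <- 1
    pk[3:4, 3:4, 1][seq_len(4 - k)] <- 1
    dice_loss(batch_pair(g, pk))
  })
  expect_true(all(diff(losses) < 0))
})

test_that("focal loss takes its closed-form values", {
  cfg <- loss_config("focal", gamma = 0.3)
  # all labels perfect -> 0
  r <- random_pair(L = 2, seed = 4)
  expect_equal(focal_dice_loss(batch_pair(r$g, r$g), cfg), 0, tolerance = 1e-3)

  # single label, constant prediction c chosen so D = e^-1 -> loss = 1
  N <- 64
  D <- exp(-1)
  cval <- D / (2 - D)
  g <- array(1, c(8, 8, 1))
  p <- array(cval, c(8, 8, 1))
  expect_equal(focal_dice_loss(batch_pair(g, p), cfg), 1, tolerance = 1e-4)

  # two labels with D = e^-1 and D = e^-8 -> mean(1, 8^0.3)
  D2 <- exp(-8)
  g2 <- array(0, c(8, 8, 2)); g2[, , 1] <- 1
  p2 <- array(0, c(8, 8, 2))
  p2[, , 1] <- cval
  # label 2 absent in g: D_2 = (0 + eps)/(sum p + eps); pick p to hit e^-8
  s2 <- (1e-5 / D2) - 1e-5
  p2[, , 2] <- s2 / N
  pair2 <- batch_pair(g2, p2)
  expect_equal(dice_per_label(pair2), c(exp(-1), exp(-8)), tolerance = 1e-3)
  expect_equal(focal_dice_loss(pair2, cfg), mean(c(1, 8^0.3)),
               tolerance = 1e-3)
})

test_that("boundary residual equals brute-force grayscale erosion", {
  # binary 20x20 filled square inside a 32x32 map: 3-pixel frame
  x <- matrix(0, 32, 32); x[7:26, 7:26] <- 1
  res <- boundary_residual(x, 7L)
  oracle <- x - erode_disk_oracle(x, 7L)
  expect_identical(res, oracle)
  inb <- res[7:26, 7:26]
  frame <- matrix(TRUE, 20, 20); frame[4:17, 4:17] <- FALSE
  expect_true(all(inb[frame] == 1) && all(inb[!frame] == 0))

  # constant maps have zero residual under replicate-padded erosion
  expect_true(all(boundary_residual(matrix(0.7, 16, 16), 7L) == 0))
  expect_true(all(boundary_residual(matrix(0, 16, 16), 7L) == 0))

  # random probability maps, several trials, exact agreement
  for (trial in 1:6) {
    set.seed(100 + trial)
    x <- matrix(runif(32 * 32), 32, 32)
    expect_identical(boundary_residual(x, 7L), x - erode_disk_oracle(x, 7L))
  }
  expect_error(boundary_residual(x, 6L), "odd")
})

test_that("hybrid loss combines whole-map and boundary focal terms", {
  r <- random_pair(L = 3, seed = 7)
  pair <- batch_pair(r$g, r$p)

  # perfect prediction -> 0 (epsilon-limit)
  expect_equal(hybrid_loss(batch_pair(r$g, r$g)), 0, tolerance = 1e-3)

  # lambda = 0 reduces exactly to the focal loss
  cfg0 <- loss_config("hybrid", lambda = 0)
  expect_equal(hybrid_loss(pair, cfg0),
               focal_dice_loss(pair, loss_config("focal")), tolerance = 1e-12)

  # a one-pixel contour shift keeps the whole-map Dice high but degrades
  # the erosion-residual band sharply, so the boundary term reacts to
  # contour misplacement much more strongly than the whole-map term
  g <- array(0, c(32, 32, 2))
  sq <- matrix(0, 32, 32); sq[9:24, 9:24] <- 1
  g[, , 2] <- sq
  g[, , 1] <- 1 - sq
  p <- array(0, c(32, 32, 2))
  shifted <- matrix(0, 32, 32); shifted[10:25, 9:24] <- 1
  p[, , 2] <- shifted
  p[, , 1] <- 1 - shifted
  D_full <- dice_per_label(batch_pair(g, p))
  gb <- boundary_residual(g, 7L)
  pb <- boundary_residual(p, 7L)
  D_band <- dice_per_label(batch_pair(gb, pb))
  expect_gt(min(D_full), 0.9)          # volume overlap barely moves
  expect_lt(min(D_band), min(D_full) - 0.05)  # band overlap drops hard
  cfg <- loss_config("hybrid")
  expect_gt(hybrid_loss(batch_pair(g, p), cfg),
            focal_dice_loss(batch_pair(g, p), loss_config("focal")))
})

test_that("analytic loss gradients match central differences", {
  r <- random_pair(H = 8, W = 8, L = 3, B = 1, seed = 21)
  pair <- batch_pair(r$g, r$p)
  h <- 1e-6
  for (ty in c("dice", "focal", "hybrid")) {
    cfg <- loss_config(ty)
    lg <- cpseg:::loss_with_grad(pair, cfg)
    set.seed(33)
    for (ii in sample(length(pair$p), 20)) {
      pp <- pair
      pp$p[ii] <- pp$p[ii] + h
      lp <- cpseg:::loss_with_grad(pp, cfg, want_grad = FALSE)$loss
      pp$p[ii] <- pp$p[ii] - 2 * h
      lm <- cpseg:::loss_with_grad(pp, cfg, want_grad = FALSE)$loss
      expect_equal(lg$dp[ii], (lp - lm) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("focal reweighting boosts poorly segmented labels in the training regime", {
  cfg <- loss_config("focal", gamma = 0.3)
  # in the under-segmentation regime the weaker label receives the larger
  # gradient magnitude (the log term's derivative diverges as D -> 1, so
  # the comparison is made where the reweighting is meant to act)
  dd <- cpseg:::focal_dD(c(0.2, 0.5), cfg, 2)
  expect_gt(abs(dd[1]), abs(dd[2]))
  # and relative to the flat per-label gradient of the basic Dice loss the
  # weak label is up-weighted
  flat <- 1 / 2
  expect_gt(abs(dd[1]) / flat, 1)
})
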
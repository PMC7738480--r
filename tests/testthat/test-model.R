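# independent parameter-count oracle for the encoder-decoder contract
expected_param_count <- function(base, depth, dims, out_labels,
                                 convs_per_block = 3) {
  kvol <- if (dims == 3) 27 else 9
  w <- base * 2^(0:depth)
  n <- 0
  conv <- function(cin, cout) cin * kvol * cout + cout
  bn <- function(c) 2 * c
  block <- function(cin, cout) {
    cs <- c(cin, rep(cout, convs_per_block - 1))
    sum(sapply(cs, bn)) + sum(sapply(cs, conv, cout = cout))
  }
  cin <- 1
  for (j in 0:depth) {
    n <- n + block(cin, w[j + 1])
    cin <- w[j + 1]
  }
  for (j in (depth - 1):0) {
    n <- n + w[j + 2] * w[j + 1] * kvol + w[j + 1]  # transposed conv
    n <- n + block(2 * w[j + 1], w[j + 1])
  }
  n + w[1] * out_labels + out_labels  # final 1x1
}

test_that("network widths and parameter counts follow the config exactly", {
  # full-scale 2D config: first block 32 maps, deepest 512
  cfg <- unet_config(32L, 4L, 128L, 5L)
  net <- build_unet(cfg, seed = 1)
  expect_equal(nrow(net$params$enc4_conv3_W), 512L)
  expect_equal(nrow(net$params$enc0_conv1_W), 32L)
  expect_equal(n_parameters(net),
               expected_param_count(32, 4, 2, 5))

  # 3D comparison variant: starts at 8, peaks at 128
  cfg3 <- unet_config(8L, 4L, 64L, 5L, dims = 3L)
  net3 <- build_unet(cfg3, seed = 1)
  expect_equal(nrow(net3$params$enc4_conv3_W), 128L)
  expect_equal(n_parameters(net3),
               expected_param_count(8, 4, 3, 5))

  # tiny preset
  cfgt <- unet_config(8L, 3L, 64L, 3L)
  expect_equal(n_parameters(build_unet(cfgt, seed = 2)),
               expected_param_count(8, 3, 2, 3))

  expect_error(unet_config(8L, 3L, 60L), "divisible")
  expect_error(unet_config(8L, 3L, 64L, out_labels = 4L), "out_labels")
})

test_that("forward pass keeps spatial shape and emits per-pixel softmax", {
  for (depth in 1:3) {
    cfg <- unet_config(4L, depth, 16L, 5L)
    net <- build_unet(cfg, seed = 3)
    set.seed(4)
    B <- 2L
    x <- matrix(rnorm(16 * 16 * B), nrow = 1)
    fw <- cpseg:::unet_forward(net, x, cpseg:::dims2d(16L, 16L, B))
    expect_equal(dim(fw$probs), c(5L, 16L * 16L * B))
    expect_equal(range(colSums(fw$probs)), c(1, 1), tolerance = 1e-12)
  }
  # 3D variant: shape contract on a small volume
  cfg3 <- unet_config(2L, 1L, 8L, 3L, dims = 3L)
  net3 <- build_unet(cfg3, seed = 5)
  x3 <- matrix(rnorm(8^3), nrow = 1)
  fw3 <- cpseg:::unet_forward(net3, x3,
                              list(H = 8L, W = 8L, D = 8L, B = 1L))
  expect_equal(dim(fw3$probs), c(3L, 8L^3))
  expect_equal(range(colSums(fw3$probs)), c(1, 1), tolerance = 1e-12)
})

test_that("inference is deterministic and reproducible from the seed", {
  cfg <- unet_config(4L, 2L, 32L, 5L)
  net <- build_unet(cfg, seed = 11)
  net2 <- build_unet(cfg, seed = 11)
  expect_identical(net$params, net2$params)
  net3 <- build_unet(cfg, seed = 12)
  expect_false(identical(net$params, net3$params))

  case <- fixture_phantom()
  st <- slice_stack(zscore_normalize(case$intensity, "all"), "axial",
                    target = 32L,
                    bbox = cbind(rep(20L, 3), rep(43L, 3)))
  st$slices <- st$slices[, , 20:23]
  st$geometry$n_slices <- 4L
  # duplicate slices produce identical outputs
  st$slices[, , 2] <- st$slices[, , 1]
  maps <- predict_stack(net, st)
  expect_equal(dim(maps)[4], 4L)
  expect_identical(maps[, , , 1], maps[, , , 2])
  maps2 <- predict_stack(net, st)
  expect_identical(maps, maps2)
})

test_that("training-mode gradients match finite differences through the full net", {
  cfg <- unet_config(2L, 1L, 8L, 3L)
  net <- build_unet(cfg, seed = 42)
  set.seed(5)
  B <- 2L; H <- 8L
  x <- matrix(rnorm(H * H * B), nrow = 1)
  lab <- sample(0:2, H * H * B, TRUE)
  goh <- matrix(0, 3, H * H * B)
  goh[lab + 1 + (0:(H * H * B - 1)) * 3] <- 1
  lcfg <- loss_config("hybrid")
  fwd_loss <- function(net) {
    fw <- cpseg:::unet_forward(net, x, cpseg:::dims2d(H, H, B), training = TRUE)
    pair <- structure(list(g = goh, p = fw$probs, H = H, W = H, L = 3L, B = B),
                      class = "batch_pair")
    list(fw = fw, pair = pair,
         loss = cpseg:::loss_with_grad(pair, lcfg, want_grad = FALSE)$loss)
  }
  r <- fwd_loss(net)
  lg <- cpseg:::loss_with_grad(r$pair, lcfg)
  dz <- cpseg:::softmax_bwd(lg$dp, r$fw$probs)
  grads <- cpseg:::unet_backward(net, dz, cpseg:::dims2d(H, H, B), r$fw$cache)
  h <- 1e-5
  set.seed(9)
  for (nm in sample(names(grads), 10)) {
    i <- sample(length(net$params[[nm]]), 1)
    n2 <- net
    n2$params[[nm]][i] <- n2$params[[nm]][i] + h
    lp <- fwd_loss(n2)$loss
    n2$params[[nm]][i] <- n2$params[[nm]][i] - 2 * h
    lm <- fwd_loss(n2)$loss
    num <- (lp - lm) / (2 * h)
    denom <- max(1e-6, abs(num), abs(grads[[nm]][i]))
    expect_lt(abs(num - grads[[nm]][i]) / denom, 1e-4)
  }
})
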
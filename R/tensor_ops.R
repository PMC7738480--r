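# Internal tensor primitives for the network engine.
#
# A batch of feature maps is a channel-major matrix (C x N); columns are
# pixels/voxels in R array order i + H*(j + W*(d + D*n)). `dims` is
# list(H, W, D, B); batches of 2D slices use D = 1, 3D volumes use B
# volumes with D > 1. All heavy lifting is done by consolidated C++
# kernels (src/conv_ops.cpp); the wrappers here only keep the caches the
# backward pass needs.

dims2d <- function(H, W, B) list(H = H, W = W, D = 1L, B = B)

ncols_of <- function(dims) dims$H * dims$W * dims$D * dims$B

# ---- convolution (stride 1, zero padding (k-1)/2) --------------------------

conv_fwd <- function(x, W, b, dims, k, dims3 = FALSE) {
  y <- cpp_conv_fwd(x, W, as.numeric(b), dims$H, dims$W, dims$D, dims$B,
                    k, dims3)
  list(y = y, x = x)
}

conv_bwd <- function(dy, cache, W, dims, k, dims3 = FALSE) {
  r <- cpp_conv_bwd(cache$x, W, dy, dims$H, dims$W, dims$D, dims$B, k, dims3)
  list(dx = r$dx, dW = r$dW, db = matrix(r$db, ncol = 1))
}

# ---- transposed convolution, kernel 3, stride 2 ----------------------------
# Weight W has shape (C_in, C_out * K): it is the weight of the adjoint
# stride-2 convolution mapping the upsampled grid back down.

convt_fwd <- function(x, W, b, dims_small, dims3 = FALSE) {
  db <- dims_small
  dims_big <- list(H = 2L * db$H, W = 2L * db$W,
                   D = if (dims3) 2L * db$D else db$D, B = db$B)
  y <- cpp_convt_fwd(x, W, as.numeric(b), db$H, db$W, db$D, db$B, dims3)
  list(y = y, x = x, dims_big = dims_big)
}

convt_bwd <- function(dy, cache, W, dims3 = FALSE) {
  ds <- cache$dims_small
  r <- cpp_convt_bwd(cache$x, W, dy, ds$H, ds$W, ds$D, ds$B, dims3)
  list(dx = r$dx, dW = r$dW, db = matrix(r$db, ncol = 1))
}

# ---- max pooling 2x2 stride 2 ---------------------------------------------

pool_fwd <- function(x, dims, dims3 = FALSE) {
  r <- cpp_maxpool(x, dims$H, dims$W, dims$D, dims$B, dims3)
  dims_out <- list(H = dims$H %/% 2L, W = dims$W %/% 2L,
                   D = if (dims3) dims$D %/% 2L else dims$D, B = dims$B)
  list(y = r$y, idx = r$idx, ncol_in = ncol(x), dims_out = dims_out)
}

pool_bwd <- function(dy, cache) cpp_maxpool_bwd(dy, cache$idx, cache$ncol_in)

# ---- batch normalization (per channel = per row) ---------------------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  r <- cpp_bn_fwd(x, as.numeric(gamma), as.numeric(beta),
                  run_mean, run_var, training, eps)
  if (training) {
    new_mean <- (1 - momentum) * run_mean + momentum * as.numeric(r$m)
    new_var <- (1 - momentum) * run_var + momentum * as.numeric(r$v)
  } else {
    new_mean <- run_mean
    new_var <- run_var
  }
  list(y = r$y, xhat = r$xhat, inv = as.numeric(r$inv),
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(dy, cache, gamma) {
  r <- cpp_bn_bwd(dy, cache$xhat, cache$inv, as.numeric(gamma))
  list(dx = r$dx, dgamma = matrix(r$dgamma, ncol = 1),
       dbeta = matrix(r$dbeta, ncol = 1))
}

# ---- ELU (alpha = 1) -------------------------------------------------------

elu_fwd <- function(x) {
  y <- cpp_elu_fwd(x)
  list(y = y)
}

elu_bwd <- function(dy, cache) cpp_elu_bwd(dy, cache$y)

# ---- softmax over channels (rows) ------------------------------------------

softmax_fwd <- function(z) cpp_softmax(z)

# dL/dz given dL/dp where p = softmax(z)
softmax_bwd <- function(dp, p) cpp_softmax_bwd(dp, p)
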
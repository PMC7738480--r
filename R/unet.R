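#' Network configuration
#'
#' Describes the per-plane encoder--decoder segmentation network. The
#' contracting path has `depth + 1` blocks whose widths double per level,
#' starting at `base_features`; each block is three repetitions of
#' batch-norm, ELU and a 3x3 zero-padded convolution (pre-activation order).
#' Downsampling is 2x2 max-pooling with stride 2; the expansive path
#' upsamples with 3x3 transposed convolutions (stride 2), concatenates the
#' last feature map of the same-size contracting block, and a final 1x1
#' convolution followed by softmax yields per-label probabilities.
#'
#' The default (`base_features = 32`, `depth = 4`) reaches 512 feature maps
#' in the deepest block; the 3D comparison variant conventionally uses
#' `base_features = 8`, peaking at 128.
#'
#' @param base_features feature maps in the first block (default 32).
#' @param depth number of pooling levels (default 4).
#' @param in_shape spatial input size (scalar, square/cubic grids).
#' @param out_labels number of output labels: 5 (axial/coronal) or 3 (sagittal).
#' @param convs_per_block convolutions per block (default 3).
#' @param dims 2 for slice networks, 3 for the volumetric variant.
#' @return an object of class `unet_config`.
#' @examples
#' cfg <- unet_config(base_features = 8, depth = 3, in_shape = 64,
#'                    out_labels = 5)
#' net <- build_unet(cfg, seed = 1)
#' n_parameters(net)
#' @export
unet_config <- function(base_features = 32L, depth = 4L, in_shape = 128L,
                        out_labels = 5L, convs_per_block = 3L, dims = 2L) {
  stopifnot(depth >= 1L, base_features >= 1L, convs_per_block >= 1L,
            dims %in% c(2L, 3L))
  if (!out_labels %in% c(3L, 5L))
    stop("out_labels must be 3 or 5")
  if (in_shape %% (2L^depth) != 0L)
    stop("in_shape must be divisible by 2^depth")
  structure(list(base_features = as.integer(base_features),
                 depth = as.integer(depth),
                 in_shape = as.integer(in_shape),
                 out_labels = as.integer(out_labels),
                 convs_per_block = as.integer(convs_per_block),
                 dims = as.integer(dims)),
            class = "unet_config")
}

#' @export
print.unet_config <- function(x, ...) {
  w <- x$base_features * 2L^(0:x$depth)
  cat(sprintf("U-Net config: %dD, input %d^%d, widths %s, %d labels\n",
              x$dims, x$in_shape, x$dims, paste(w, collapse = "-"),
              x$out_labels))
  invisible(x)
}

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

block_channels <- function(config) {
  widths <- config$base_features * 2L^(0:config$depth)
  k3 <- if (config$dims == 3L) 3L else 1L
  list(widths = widths, kvol = 9L * k3)
}

#' Build a segmentation network
#'
#' Instantiates the network described by a [unet_config()] with seeded
#' He-uniform weight initialization. The returned object holds all
#' parameters, batch-norm running statistics and the config; it is trained
#' with [train_plane()] and applied with [predict_stack()].
#'
#' @param config a [unet_config()].
#' @param seed integer seed for the weight initialization.
#' @return an object of class `unet`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  set.seed(as.integer(seed))
  bc <- block_channels(config)
  widths <- bc$widths
  kvol <- bc$kvol
  depth <- config$depth
  ncv <- config$convs_per_block

  params <- list()
  state <- list()

  add_conv <- function(name, cin, cout, kv) {
    params[[paste0(name, "_W")]] <<- he_uniform(cout, cin * kv, cin * kv)
    params[[paste0(name, "_b")]] <<- matrix(0, cout, 1)
  }
  add_bn <- function(name, c) {
    params[[paste0(name, "_gamma")]] <<- matrix(1, c, 1)
    params[[paste0(name, "_beta")]] <<- matrix(0, c, 1)
    state[[paste0(name, "_mean")]] <<- rep(0, c)
    state[[paste0(name, "_var")]] <<- rep(1, c)
  }
  add_block <- function(prefix, cin, cout) {
    cs <- c(cin, rep(cout, ncv - 1L))
    for (t in seq_len(ncv)) {
      add_bn(sprintf("%s_bn%d", prefix, t), cs[t])
      add_conv(sprintf("%s_conv%d", prefix, t), cs[t], cout, kvol)
    }
  }

  # encoder blocks 0..depth (block `depth` is the bottleneck)
  cin <- 1L
  for (j in 0:depth) {
    add_block(sprintf("enc%d", j), cin, widths[j + 1L])
    cin <- widths[j + 1L]
  }
  # decoder: transposed conv from level j+1 to j, then a block on the concat
  for (j in (depth - 1L):0) {
    # transposed conv weight is the adjoint stride-2 conv weight:
    # (C_small, C_big * K)
    params[[sprintf("up%d_W", j)]] <-
      he_uniform(widths[j + 2L], widths[j + 1L] * kvol, widths[j + 2L] * kvol)
    params[[sprintf("up%d_b", j)]] <- matrix(0, widths[j + 1L], 1)
    add_block(sprintf("dec%d", j), 2L * widths[j + 1L], widths[j + 1L])
  }
  add_conv("out", widths[1L], config$out_labels, 1L)

  structure(list(config = config, params = params, state = state,
                 seed = as.integer(seed)),
            class = "unet")
}

#' Number of trainable parameters
#'
#' @param net a `unet` object.
#' @return integer count of trainable scalars (batch-norm running statistics
#'   excluded).
#' @export
n_parameters <- function(net) {
  stopifnot(inherits(net, "unet"))
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.unet <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %s trainable parameters, init seed %d\n",
              format(n_parameters(x), big.mark = ","), x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# forward / backward
# ---------------------------------------------------------------------------

unet_block_fwd <- function(net, prefix, x, dims, training, cache, d3) {
  ncv <- net$config$convs_per_block
  p <- net$params
  for (t in seq_len(ncv)) {
    bn <- sprintf("%s_bn%d", prefix, t)
    cv <- sprintf("%s_conv%d", prefix, t)
    b <- bn_fwd(x, p[[paste0(bn, "_gamma")]], p[[paste0(bn, "_beta")]],
                net$state[[paste0(bn, "_mean")]], net$state[[paste0(bn, "_var")]],
                training)
    if (training) {
      net$state[[paste0(bn, "_mean")]] <- b$run_mean
      net$state[[paste0(bn, "_var")]] <- b$run_var
    }
    e <- elu_fwd(b$y)
    cc <- conv_fwd(e$y, p[[paste0(cv, "_W")]], p[[paste0(cv, "_b")]], dims, 3L, d3)
    cache[[bn]] <- list(xhat = b$xhat, inv = b$inv)
    cache[[cv]] <- list(x = cc$x)
    cache[[paste0(prefix, "_elu", t)]] <- list(y = e$y)
    x <- cc$y
  }
  list(y = x, net = net, cache = cache)
}

unet_block_bwd <- function(net, prefix, dy, dims, cache, grads, d3) {
  ncv <- net$config$convs_per_block
  p <- net$params
  for (t in rev(seq_len(ncv))) {
    bn <- sprintf("%s_bn%d", prefix, t)
    cv <- sprintf("%s_conv%d", prefix, t)
    cb <- conv_bwd(dy, cache[[cv]], p[[paste0(cv, "_W")]], dims, 3L, d3)
    grads[[paste0(cv, "_W")]] <- cb$dW
    grads[[paste0(cv, "_b")]] <- cb$db
    de <- elu_bwd(cb$dx, cache[[paste0(prefix, "_elu", t)]])
    bb <- bn_bwd(de, cache[[bn]], p[[paste0(bn, "_gamma")]])
    grads[[paste0(bn, "_gamma")]] <- bb$dgamma
    grads[[paste0(bn, "_beta")]] <- bb$dbeta
    dy <- bb$dx
  }
  list(dx = dy, grads = grads)
}

# x: (1, N) matrix; dims: list(H, W, D, B). Returns probabilities and (when
# training) the caches needed for the backward pass.
unet_forward <- function(net, x, dims, training = FALSE) {
  cfg <- net$config
  d3 <- cfg$dims == 3L
  depth <- cfg$depth
  cache <- list()
  skips <- vector("list", depth)
  dims_j <- dims

  for (j in 0:depth) {
    r <- unet_block_fwd(net, sprintf("enc%d", j), x, dims_j, training, cache, d3)
    net <- r$net
    cache <- r$cache
    x <- r$y
    if (j < depth) {
      skips[[j + 1L]] <- x
      pl <- pool_fwd(x, dims_j, d3)
      cache[[sprintf("pool%d", j)]] <- pl
      x <- pl$y
      dims_j <- pl$dims_out
    }
  }

  for (j in (depth - 1L):0) {
    up <- convt_fwd(x, net$params[[sprintf("up%d_W", j)]],
                    net$params[[sprintf("up%d_b", j)]], dims_j, d3)
    cache[[sprintf("up%d", j)]] <- list(x = up$x, dims_big = up$dims_big,
                                        dims_small = dims_j)
    dims_j <- up$dims_big
    x <- rbind(up$y, skips[[j + 1L]])
    r <- unet_block_fwd(net, sprintf("dec%d", j), x, dims_j, training, cache, d3)
    net <- r$net
    cache <- r$cache
    x <- r$y
  }

  z <- net$params$out_W %*% x + as.vector(net$params$out_b)
  cache$out <- list(x = x)
  probs <- softmax_fwd(z)
  list(probs = probs, z = z, cache = if (training) cache else NULL,
       net = net, dims = dims)
}

# dz: gradient w.r.t. pre-softmax logits, shape (L, N)
unet_backward <- function(net, dz, dims, cache) {
  cfg <- net$config
  d3 <- cfg$dims == 3L
  depth <- cfg$depth
  grads <- list()

  grads$out_W <- tcrossprod(dz, cache$out$x)
  grads$out_b <- matrix(rowSums(dz), ncol = 1)
  dy <- crossprod(net$params$out_W, dz)

  dims_j <- dims
  for (j in 0:(depth - 1L)) {
    r <- unet_block_bwd(net, sprintf("dec%d", j), dy, dims_j, cache, grads, d3)
    grads <- r$grads
    w <- cfg$base_features * 2L^j
    dup <- r$dx[seq_len(w), , drop = FALSE]
    dskip <- r$dx[w + seq_len(w), , drop = FALSE]
    ub <- convt_bwd(dup, cache[[sprintf("up%d", j)]],
                    net$params[[sprintf("up%d_W", j)]], d3)
    grads[[sprintf("up%d_W", j)]] <- ub$dW
    grads[[sprintf("up%d_b", j)]] <- ub$db
    if (j == 0L) {
      denc <- list()
    }
    # stash: gradient entering encoder level j has two sources: skip + pooled
    assign(sprintf(".dskip%d", j), dskip)
    assign(sprintf(".dx_from_up%d", j), ub$dx)
    dy <- ub$dx
    dims_j <- cache[[sprintf("up%d", j)]]$dims_small
  }

  # bottleneck block
  r <- unet_block_bwd(net, sprintf("enc%d", depth), dy, dims_j, cache, grads, d3)
  grads <- r$grads
  dy <- r$dx

  for (j in (depth - 1L):0) {
    pl <- cache[[sprintf("pool%d", j)]]
    dpool <- pool_bwd(dy, pl)
    dtot <- dpool + get(sprintf(".dskip%d", j))
    dims_up <- cache[[sprintf("up%d", j)]]$dims_big
    r <- unet_block_bwd(net, sprintf("enc%d", j), dtot, dims_up, cache, grads, d3)
    grads <- r$grads
    dy <- r$dx
  }
  grads
}

#' Predict per-slice label probabilities
#'
#' Runs a network (or a mock standing in for one, via S3 dispatch) over the
#' slices of a [slice_stack()] in inference mode, returning one softmax map
#' per slice.
#'
#' @param model a trained `unet` (or any object providing a `predict_stack`
#'   method).
#' @param stack a `slice_stack` of intensity slices.
#' @param batch_size slices per forward pass.
#' @return a 4D array `(H, W, labels, n_slices)` of probabilities.
#' @export
predict_stack <- function(model, stack, batch_size = 32L) {
  UseMethod("predict_stack")
}

#' @export
predict_stack.unet <- function(model, stack, batch_size = 32L) {
  stopifnot(inherits(stack, "slice_stack"))
  cfg <- model$config
  tgt <- stack$target
  if (tgt != cfg$in_shape)
    stop("slice size does not match the network input shape")
  L <- cfg$out_labels
  if (stack$label_scheme == "sagittal3" && L != 3L)
    stop("label scheme mismatch: stack is 3-label, network is not")
  ns <- dim(stack$slices)[3]
  out <- array(0, c(tgt, tgt, L, ns))
  for (start in seq(1L, ns, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, ns)
    xb <- matrix(stack$slices[, , idx], nrow = 1)
    fw <- unet_forward(model, xb, dims2d(tgt, tgt, length(idx)), training = FALSE)
    out[, , , idx] <- aperm(array(fw$probs, c(L, tgt, tgt, length(idx))),
                            c(2, 3, 1, 4))
  }
  out
}

# ---------------------------------------------------------------------------
# Adam optimizer
# ---------------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
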
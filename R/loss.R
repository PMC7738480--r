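#' Loss configuration
#'
#' Collects the tunable constants of the Dice-based loss family: the
#' smoothing term `epsilon` shared by numerator and denominator of the
#' Dice coefficient, the focal exponent `gamma` applied to the
#' log-transformed per-label Dice, the boundary weight `lambda`, and the
#' diameter of the flat disk used to erode each label map when forming the
#' boundary residual.
#'
#' @param type one of "hybrid", "dice", "focal".
#' @param epsilon Dice smoothing term (> 0).
#' @param gamma focal exponent (> 0); 0.3 balances easy and hard labels.
#' @param lambda boundary-term weight (>= 0).
#' @param kernel_diameter odd disk diameter (>= 3) for the erosion.
#' @param include_background include the background label in the label mean.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(type = c("hybrid", "dice", "focal"),
                        epsilon = 1e-5, gamma = 0.3, lambda = 0.1,
                        kernel_diameter = 7L, include_background = TRUE) {
  type <- match.arg(type)
  stopifnot(epsilon > 0, gamma > 0, lambda >= 0)
  kernel_diameter <- as.integer(kernel_diameter)
  if (kernel_diameter < 3L || kernel_diameter %% 2L == 0L)
    stop("kernel_diameter must be odd and >= 3")
  structure(list(type = type, epsilon = epsilon, gamma = gamma,
                 lambda = lambda, kernel_diameter = kernel_diameter,
                 include_background = isTRUE(include_background)),
            class = "loss_config")
}

#' Ground-truth / prediction batch pair
#'
#' Canonicalizes a pair of label-probability tensors for the loss
#' functions. Inputs are arrays of shape `(H, W, labels)` or
#' `(H, W, labels, batch)`; `g` holds one-hot ground truth, `p` softmax
#' probabilities in `[0, 1]`.
#'
#' @param g one-hot ground-truth array.
#' @param p prediction array of the same shape.
#' @return an object of class `batch_pair`.
#' @export
batch_pair <- function(g, p) {
  if (!identical(dim(g), dim(p)))
    stop("g and p must have identical dimensions")
  d <- dim(g)
  if (length(d) == 3L) {
    dim(g) <- c(d, 1L)
    dim(p) <- c(d, 1L)
    d <- dim(g)
  }
  if (length(d) != 4L)
    stop("expected (H, W, labels) or (H, W, labels, batch) arrays")
  L <- d[3]
  gm <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = L)
  pm <- matrix(aperm(p, c(3, 1, 2, 4)), nrow = L)
  structure(list(g = gm, p = pm, H = d[1], W = d[2], L = L, B = d[4]),
            class = "batch_pair")
}

as_batch_pair <- function(pair) {
  if (inherits(pair, "batch_pair")) pair
  else stop("expected a batch_pair")
}

# per-label smoothed Dice on (L, N) matrices; returns value and the pieces
# needed for the gradient
dice_terms <- function(gm, pm, epsilon) {
  num <- 2 * rowSums(gm * pm) + epsilon
  den <- rowSums(gm + pm) + epsilon
  list(D = num / den, num = num, den = den)
}

#' Per-label smoothed Dice coefficients
#'
#' For each label l, computes
#' `D_l = (2 * sum_i g_li p_li + eps) / (sum_i (g_li + p_li) + eps)`,
#' pooling pixels over the whole batch.
#'
#' @param pair a [batch_pair()].
#' @param epsilon smoothing term.
#' @return numeric vector of per-label Dice coefficients in (0, 1].
#' @export
dice_per_label <- function(pair, epsilon = 1e-5) {
  pair <- as_batch_pair(pair)
  dice_terms(pair$g, pair$p, epsilon)$D
}

#' Basic Dice loss
#'
#' One minus the label-mean smoothed Dice coefficient.
#'
#' @param pair a [batch_pair()].
#' @param config a [loss_config()].
#' @return scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(pair, config = loss_config("dice")) {
  pair <- as_batch_pair(pair)
  D <- dice_terms(pair$g, pair$p, config$epsilon)$D
  1 - mean(D[label_mask(pair$L, config)])
}

label_mask <- function(L, config) {
  if (config$include_background) rep(TRUE, L) else c(FALSE, rep(TRUE, L - 1L))
}

# focal transform of per-label Dice: mean_l (-ln clamp(D))^gamma
focal_from_dice <- function(D, config) {
  Dc <- pmin(pmax(D, config$epsilon), 1)
  mean((-log(Dc))^config$gamma)
}

#' Focal (exponential-logarithmic) Dice loss
#'
#' Label-mean of `(-ln D_l)^gamma`. With `gamma < 1` the loss assigns a
#' larger gradient to labels with a lower Dice coefficient, rebalancing
#' easy and hard labels. The logarithm argument is clamped to
#' `[epsilon, 1]`.
#'
#' @inheritParams dice_loss
#' @return scalar loss, 0 when every per-label Dice equals 1.
#' @export
focal_dice_loss <- function(pair, config = loss_config("focal")) {
  pair <- as_batch_pair(pair)
  D <- dice_terms(pair$g, pair$p, config$epsilon)$D
  m <- label_mask(pair$L, config)
  focal_from_dice(D[m], config)
}

#' Boundary residual of label maps
#'
#' Subtracts from each per-label map its grayscale erosion by a flat disk
#' (offsets at Euclidean distance `<= (d-1)/2`), computed per 2D slice with
#' replicated borders. For a binary map the residual is the band of
#' thickness ~d/2 inside the region boundary; for probability maps it is
#' the pointwise difference `x - (x erode B)`, always in `[0, 1]`.
#'
#' @param x matrix `(H, W)` or array `(H, W, labels[, batch])` with values
#'   in `[0, 1]`.
#' @param kernel_diameter odd disk diameter (default 7).
#' @return residual of the same shape as `x`.
#' @examples
#' x <- matrix(0, 20, 20); x[6:15, 6:15] <- 1
#' res <- boundary_residual(x, 7)
#' sum(res)  # the 3-pixel band inside the square's boundary
#' @export
boundary_residual <- function(x, kernel_diameter = 7L) {
  kernel_diameter <- as.integer(kernel_diameter)
  if (kernel_diameter %% 2L == 0L) stop("kernel_diameter must be odd")
  radius <- (kernel_diameter - 1L) %/% 2L
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    xm <- matrix(as.vector(x), nrow = 1)
    er <- cpp_erode_disk(xm, nrow(x), ncol(x), 1L, radius)
    out <- x - matrix(er$y, nrow(x), ncol(x))
    return(out)
  }
  was3d <- length(d) == 3L
  if (was3d) dim(x) <- c(d, 1L)
  d <- dim(x)
  xm <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
  er <- cpp_erode_disk(xm, d[1], d[2], d[4], radius)
  res <- xm - er$y
  out <- aperm(array(res, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  if (was3d) dim(out) <- d[1:3]
  out
}

#' Hybrid (focal + boundary) Dice loss
#'
#' `L_hyb(g, p) = L_focal(g, p) + lambda * L_focal(g - g?B, p - p?B)`:
#' the focal Dice loss on the full maps plus `lambda` times the focal Dice
#' loss on the erosion residuals, which emphasizes a band around each
#' region boundary.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
hybrid_loss <- function(pair, config = loss_config("hybrid")) {
  pair <- as_batch_pair(pair)
  lv <- loss_with_grad(pair, config, want_grad = FALSE)
  lv$loss
}

# ---------------------------------------------------------------------------
# Values + analytic gradients w.r.t. p (used by training and gradient tests)
# ---------------------------------------------------------------------------

# gradient of mean_l (-ln Dc_l)^gamma w.r.t. D (vector over labels)
focal_dD <- function(D, config, n_lab) {
  Dc <- pmin(pmax(D, config$epsilon), 1)
  dd <- numeric(length(D))
  ok <- D > config$epsilon & D < 1 - 1e-12
  dd[ok] <- -config$gamma * (-log(Dc[ok]))^(config$gamma - 1) / (n_lab * Dc[ok])
  dd
}

# dD_l/dp on (L, N): rows scaled independently
dice_dp <- function(gm, terms) {
  (2 * gm * terms$den - terms$num) / terms$den^2
}

# Compute loss value and gradient w.r.t. p for a batch_pair.
# type: "dice", "focal", "hybrid".
loss_with_grad <- function(pair, config, want_grad = TRUE) {
  gm <- pair$g
  pm <- pair$p
  L <- pair$L
  m <- label_mask(L, config)
  n_lab <- sum(m)

  terms <- dice_terms(gm, pm, config$epsilon)

  if (config$type == "dice") {
    loss <- 1 - mean(terms$D[m])
    if (!want_grad) return(list(loss = loss))
    dD <- ifelse(m, -1 / n_lab, 0)
    dp <- dice_dp(gm, terms) * dD
    return(list(loss = loss, dp = dp))
  }

  focal_part <- function(gm, pm) {
    tt <- dice_terms(gm, pm, config$epsilon)
    loss <- focal_from_dice(tt$D[m], config)
    if (!want_grad) return(list(loss = loss))
    dD <- numeric(L)
    dD[m] <- focal_dD(tt$D[m], config, n_lab)
    list(loss = loss, dp = dice_dp(gm, tt) * dD)
  }

  f1 <- focal_part(gm, pm)
  if (config$type == "focal" || config$lambda == 0) {
    return(f1)
  }

  # hybrid: focal on erosion residuals, gradient routed through the
  # pointwise min of the erosion
  radius <- (config$kernel_diameter - 1L) %/% 2L
  eg <- cpp_erode_disk(gm, pair$H, pair$W, pair$B, radius)
  ep <- cpp_erode_disk(pm, pair$H, pair$W, pair$B, radius)
  gb <- gm - eg$y
  pb <- pm - ep$y
  tb <- dice_terms(gb, pb, config$epsilon)
  loss2 <- focal_from_dice(tb$D[m], config)
  loss <- f1$loss + config$lambda * loss2
  if (!want_grad) return(list(loss = loss))

  dD2 <- numeric(L)
  dD2[m] <- focal_dD(tb$D[m], config, n_lab)
  dpb <- dice_dp(gb, tb) * dD2
  # pb = p - erode(p): d/dp = dpb - scatter(dpb at argmin)
  dp2 <- dpb - cpp_maxpool_bwd(dpb, ep$idx, ncol(pm))
  list(loss = loss, dp = f1$dp + config$lambda * dp2)
}
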
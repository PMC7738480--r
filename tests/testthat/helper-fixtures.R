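# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small phantom on a 48^3 grid (36 mm box), quick to generate
small_phantom <- function(seed = 11L, fold = 1.0, noise = 0.1) {
  generate_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L),
                                fold_amplitude_mm = fold,
                                noise_sd = noise, seed = seed))
}

fixture_phantom <- function() fixture("phantom48", function() small_phantom())

# binary sphere label volume: radius mm, voxel mm
sphere_labels <- function(radius_mm, voxel_mm = 0.75, margin_mm = 4) {
  n <- ceiling(2 * (radius_mm + margin_mm) / voxel_mm)
  co <- (seq_len(n) - 0.5) * voxel_mm
  ctr <- n * voxel_mm / 2
  r <- sqrt(outer(outer((co - ctr)^2, (co - ctr)^2, "+"), (co - ctr)^2, "+"))
  lab <- array(0L, c(n, n, n))
  lab[r <= radius_mm] <- 1L
  lab
}

# brute-force grayscale disk erosion with replicated borders (oracle)
erode_disk_oracle <- function(x, diameter) {
  radius <- (diameter - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  out <- x
  for (i in seq_len(H)) for (j in seq_len(W)) {
    si <- pmin(pmax(i + offs$di, 1), H)
    sj <- pmin(pmax(j + offs$dj, 1), W)
    out[i, j] <- min(x[cbind(si, sj)])
  }
  out
}

# exact integer-arithmetic Dice oracle for binary masks
dice_oracle_binary <- function(g, p, eps) {
  (2 * sum(g & p) + eps) / (sum(g) + sum(p) + eps)
}

# random one-hot ground truth + random soft prediction pair
random_pair <- function(H = 8L, W = 8L, L = 3L, B = 1L, seed = 1L) {
  set.seed(seed)
  g <- array(0, c(H, W, L, B))
  lab <- array(sample(0:(L - 1L), H * W * B, TRUE), c(H, W, B))
  for (l in seq_len(L)) g[, , l, ][lab == (l - 1L)] <- 1
  p <- array(stats::runif(H * W * L * B, 0.05, 1), c(H, W, L, B))
  psum <- apply(p, c(1, 2, 4), sum)
  pa <- aperm(p, c(1, 2, 4, 3))
  pa <- pa / as.vector(psum)
  p <- aperm(array(pa, c(H, W, B, L)), c(1, 2, 4, 3))
  list(g = g, p = p, lab = lab)
}
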
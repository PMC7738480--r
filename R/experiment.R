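# Training protocol and ablation orchestration at desk scale.

#' Experiment configuration
#'
#' Bundles the cohort, cross-validation, optimizer, network and loss
#' settings of a segmentation experiment. Defaults follow the full-scale
#' protocol (ten folds, Adam with learning rate 1e-4, early-stopping
#' patience of 100 epochs, 128 x 128 slices, 32 base features); the tiny
#' preset returned by [tiny_experiment_config()] scales everything to a
#' single CPU.
#'
#' @param n_cases cohort size.
#' @param grid voxel counts per axis of the phantom grid.
#' @param voxel_mm voxel spacing in mm.
#' @param ranges cohort sampling ranges (see [generate_cohort()]).
#' @param k_folds number of cross-validation folds.
#' @param val_fraction fraction of training cases held out for validation.
#' @param target in-plane slice size fed to the networks.
#' @param base_features,depth network size (see [unet_config()]).
#' @param learning_rate Adam learning rate.
#' @param batch_size training slices per optimizer step.
#' @param max_epochs upper bound on training epochs.
#' @param patience_epochs early-stopping patience (epochs without
#'   validation-Dice improvement).
#' @param loss a [loss_config()].
#' @param augment_flips apply flip augmentation (with left-right label
#'   swap) during training.
#' @param empty_slice_keep fraction of background-only training slices
#'   retained per epoch (1 keeps all; smaller values subsample them to cut
#'   epoch cost while still exposing the network to empty slices).
#' @param seed master seed; every random choice in the experiment derives
#'   from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_cases = 52L, grid = c(128L, 128L, 128L),
                              voxel_mm = 0.75, ranges = list(),
                              k_folds = 10L, val_fraction = 0.10,
                              target = 128L, base_features = 32L, depth = 4L,
                              learning_rate = 1e-4, batch_size = 32L,
                              max_epochs = 500L, patience_epochs = 100L,
                              loss = loss_config("hybrid"),
                              augment_flips = TRUE, empty_slice_keep = 1,
                              seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, k_folds >= 2L,
            empty_slice_keep > 0, empty_slice_keep <= 1)
  structure(list(n_cases = as.integer(n_cases), grid = as.integer(grid),
                 voxel_mm = voxel_mm, ranges = ranges,
                 k_folds = as.integer(k_folds), val_fraction = val_fraction,
                 target = as.integer(target),
                 base_features = as.integer(base_features),
                 depth = as.integer(depth), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 loss = loss, augment_flips = isTRUE(augment_flips),
                 empty_slice_keep = empty_slice_keep,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Tiny desk-scale experiment preset
#'
#' 16 phantoms on a 64^3 grid, a base-8 depth-3 network on 64 x 64 slices
#' and 3 folds: small enough to train on one CPU in minutes. The learning
#' rate is raised to 1e-3 because the scaled-down run takes two orders of
#' magnitude fewer optimizer steps than the full protocol.
#'
#' @param seed master seed.
#' @param ... overrides passed to [experiment_config()].
#' @examples
#' \donttest{
#' cfg <- tiny_experiment_config(seed = 1, max_epochs = 2L)
#' run <- run_experiment(cfg, modes = c("mvt", "single-axi"), max_eval = 2)
#' aggregate(dice ~ mode + region, run$results, mean)
#' }
#' @export
tiny_experiment_config <- function(seed = 1L, ...) {
  args <- list(n_cases = 16L, grid = c(64L, 64L, 64L), k_folds = 3L,
               target = 64L, base_features = 8L, depth = 3L,
               learning_rate = 2e-3, batch_size = 8L, max_epochs = 20L,
               patience_epochs = 10L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}

#' Stratified k-fold assignment
#'
#' Cases are binned into tertiles of the stratification variable (the
#' folding-complexity surrogate for gestational age) and dealt to folds in
#' a seeded rotating order, so each fold's tertile composition matches the
#' cohort within one case and fold sizes differ by at most one.
#'
#' @param strat numeric stratification variable, one value per case.
#' @param k number of folds.
#' @param seed seed for the shuffling.
#' @return integer vector of fold ids (1..k).
#' @export
stratified_kfold <- function(strat, k, seed = 1L) {
  n <- length(strat)
  if (k > n) stop("k exceeds the number of cases")
  set.seed(as.integer(seed))
  tert <- tertile_bins(strat)
  fold <- integer(n)
  fold_cycle <- sample.int(k)
  ptr <- 0L
  for (tb in 1:3) {
    ids <- which(tert == tb)
    ids <- ids[sample.int(length(ids))]
    for (i in ids) {
      fold[i] <- fold_cycle[(ptr %% k) + 1L]
      ptr <- ptr + 1L
    }
  }
  fold
}

tertile_bins <- function(x) {
  r <- rank(x, ties.method = "first")
  as.integer(cut(r, breaks = 3, labels = FALSE))
}

# ---------------------------------------------------------------------------
# case preparation: mask, z-score, per-plane stacks
# ---------------------------------------------------------------------------

#' Preprocess a phantom case for the plane networks
#'
#' Applies the dilated brain mask, z-scores the in-mask intensities and
#' slices the volume (and remapped labels) into padded stacks for each
#' plane.
#'
#' @param case a `phantom_case` (or list with `intensity` and `labels`).
#' @param target in-plane slice size.
#' @return list with `intensity` (preprocessed volume), `mask`, `bbox`,
#'   and per-plane `x` (intensity stacks) / `y` (label stacks).
#' @export
prepare_case <- function(case, target = 128L) {
  mask <- brain_mask(case$labels, dilate_vox = 2)
  img <- apply_brain_mask(case$intensity, mask)
  img <- zscore_normalize(img)
  bbox <- volume_bbox(mask)
  x <- list()
  y <- list()
  for (pl in PLANES) {
    scheme <- if (pl == "sagittal") "sagittal3" else "full5"
    x[[pl]] <- slice_stack(img, pl, target = target, bbox = bbox,
                           label_scheme = scheme)
    y[[pl]] <- slice_stack(remap_labels_for_plane(case$labels, pl), pl,
                           target = target, bbox = bbox, background = 0L,
                           label_scheme = scheme)
  }
  list(intensity = img, mask = mask, bbox = bbox, x = x, y = y)
}

# pooled hard Dice over foreground labels of predicted vs true slice
# stacks; used to monitor validation performance
hard_dice_foreground <- function(pred_lab, true_lab, n_labels) {
  ds <- vapply(seq_len(n_labels - 1L), function(l) {
    A <- pred_lab == l
    B <- true_lab == l
    na <- sum(A); nb <- sum(B)
    if (na + nb == 0) return(NA_real_)
    2 * sum(A & B) / (na + nb)
  }, numeric(1))
  mean(ds, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# plane training
# ---------------------------------------------------------------------------

#' Train one plane network
#'
#' Trains a 2D network on the plane's slices of the training cases with
#' flip augmentation (left-right flips swap the paired labels on 5-label
#' planes), Adam optimization and the configured Dice-family loss; after
#' every epoch the mean foreground Dice on the validation cases is
#' computed, the best-scoring weights are kept, and training stops when
#' `patience_epochs` pass without improvement (or at `max_epochs`).
#'
#' @param train_prep,val_prep lists of prepared cases ([prepare_case()]).
#' @param plane "axial", "coronal" or "sagittal".
#' @param config an [experiment_config()].
#' @return object of class `plane_fit`: the best network, the plane, and a
#'   per-epoch history (train loss, validation Dice).
#' @export
train_plane <- function(train_prep, val_prep, plane, config) {
  stopifnot(length(train_prep) >= 1L)
  n_labels <- if (plane == "sagittal") 3L else 5L
  tgt <- config$target

  xs <- lapply(train_prep, function(p) p$x[[plane]]$slices)
  ys <- lapply(train_prep, function(p) p$y[[plane]]$slices)
  X <- array(unlist(xs), c(tgt, tgt, sum(vapply(xs, function(a) dim(a)[3], 0))))
  Y <- array(as.integer(unlist(ys)), dim(X))
  ns <- dim(X)[3]

  plane_id <- match(plane, PLANES)
  seed0 <- config$seed * 13L + plane_id
  net <- build_unet(unet_config(config$base_features, config$depth, tgt,
                                n_labels),
                    seed = seed0)
  opt <- adam_init(net$params)
  lcfg <- config$loss

  set.seed(seed0 + 7L)
  best <- list(dice = -Inf, epoch = 0L, params = net$params,
               state = net$state)
  history <- NULL
  empty_slice <- vapply(seq_len(ns), function(s) all(Y[, , s] == 0L),
                        logical(1))

  for (epoch in seq_len(config$max_epochs)) {
    keep <- !empty_slice |
      stats::runif(ns) < config$empty_slice_keep
    ord <- which(keep)[sample.int(sum(keep))]
    flips <- if (config$augment_flips) sample.int(4L, ns, replace = TRUE)
             else rep(1L, ns)
    losses <- numeric(0)
    ne <- length(ord)
    for (start in seq(1L, ne, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, ne)]
      B <- length(sel)
      xb <- array(0, c(tgt, tgt, B))
      yb <- array(0L, c(tgt, tgt, B))
      for (bi in seq_len(B)) {
        fx <- X[, , sel[bi]]
        fy <- Y[, , sel[bi]]
        fv <- flips[sel[bi]]
        if (fv == 2L || fv == 4L) {  # left-right flip
          fx <- fx[rev(seq_len(tgt)), ]
          fy <- fy[rev(seq_len(tgt)), ]
          if (n_labels == 5L) {
            swap <- c(0L, 2L, 1L, 4L, 3L)
            fy <- array(swap[fy + 1L], dim(fy))
          }
        }
        if (fv == 3L || fv == 4L) {  # vertical flip
          fx <- fx[, rev(seq_len(tgt))]
          fy <- fy[, rev(seq_len(tgt))]
        }
        xb[, , bi] <- fx
        yb[, , bi] <- fy
      }
      xm <- matrix(xb, nrow = 1)
      N <- length(yb)
      goh <- matrix(0, n_labels, N)
      goh[as.vector(yb) + 1L + (0:(N - 1L)) * n_labels] <- 1

      fw <- unet_forward(net, xm, dims2d(tgt, tgt, B), training = TRUE)
      net <- fw$net
      pair <- structure(list(g = goh, p = fw$probs, H = tgt, W = tgt,
                             L = n_labels, B = B),
                        class = "batch_pair")
      lg <- loss_with_grad(pair, lcfg)
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      dz <- softmax_bwd(lg$dp, fw$probs)
      grads <- unet_backward(net, dz, dims2d(tgt, tgt, B), fw$cache)
      upd <- adam_step(net$params, grads, opt, config$learning_rate)
      net$params <- upd$params
      opt <- upd$opt
      losses <- c(losses, lg$loss)
    }

    vd <- validation_dice(net, val_prep, plane, n_labels)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = mean(losses),
                                val_dice = vd))
    if (vd > best$dice) {
      best <- list(dice = vd, epoch = epoch, params = net$params,
                   state = net$state)
    }
    if (epoch - best$epoch >= config$patience_epochs) break
  }

  net$params <- best$params
  net$state <- best$state
  structure(list(net = net, plane = plane, history = history,
                 best_val_dice = best$dice, best_epoch = best$epoch),
            class = "plane_fit")
}

validation_dice <- function(net, val_prep, plane, n_labels) {
  if (length(val_prep) == 0L) return(NA_real_)
  preds <- integer(0)
  truths <- integer(0)
  for (p in val_prep) {
    maps <- predict_stack(net, p$x[[plane]])
    d <- dim(maps)
    lab <- max.col(matrix(aperm(maps, c(1, 2, 4, 3)), ncol = d[3]),
                   ties.method = "first") - 1L
    preds <- c(preds, lab)
    truths <- c(truths, as.integer(p$y[[plane]]$slices))
  }
  hard_dice_foreground(preds, truths, n_labels)
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("Plane fit (%s): best validation Dice %.3f at epoch %d/%d\n",
              x$plane, x$best_val_dice, x$best_epoch, nrow(x$history)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# the fitted multi-view model
# ---------------------------------------------------------------------------

#' Fit the three plane networks of a multi-view segmentation model
#'
#' Splits the training cases into train/validation (stratified by
#' complexity), preprocesses them once, and trains the axial, coronal and
#' sagittal networks. The result is the fitted model applied to new
#' volumes with [predict.mvt_model()].
#'
#' @param cases list of `phantom_case` training cases.
#' @param config an [experiment_config()].
#' @param planes planes to train (default all three).
#' @return object of class `mvt_model`.
#' @export
fit_mvt <- function(cases, config, planes = PLANES) {
  compl <- vapply(cases, function(cs) cs$complexity, numeric(1))
  n <- length(cases)
  n_val <- max(1L, round(config$val_fraction * n))
  ord <- order(compl)
  val_pick <- ord[round(seq(1, n, length.out = n_val))]
  tr_idx <- setdiff(seq_len(n), val_pick)

  prep <- lapply(cases, prepare_case, target = config$target)
  fits <- list()
  for (pl in planes) {
    fits[[pl]] <- train_plane(prep[tr_idx], prep[val_pick], pl, config)
  }
  structure(list(fits = fits, config = config,
                 n_train = length(tr_idx), n_val = n_val),
            class = "mvt_model")
}

#' @export
print.mvt_model <- function(x, ...) {
  cat(sprintf("Multi-view segmentation model (%d train / %d val cases)\n",
              x$n_train, x$n_val))
  for (pl in names(x$fits)) print(x$fits[[pl]])
  invisible(x)
}

#' @export
summary.mvt_model <- function(object, ...) {
  h <- do.call(rbind, lapply(names(object$fits), function(pl) {
    hh <- object$fits[[pl]]$history
    hh$plane <- pl
    hh
  }))
  cat("Training history (per plane):\n")
  print(h, row.names = FALSE)
  invisible(h)
}

#' Predict the segmentation of a new case
#'
#' Preprocesses the case like the training data and applies the requested
#' aggregation mode (see [mvt_predict()]).
#'
#' @param object a fitted `mvt_model`.
#' @param newdata a `phantom_case`, or a list with `intensity` and `labels`
#'   (labels are only used to derive the brain mask).
#' @param mode aggregation mode (default `"mvt"`).
#' @param ... unused.
#' @return integer label volume (0..4) with an `n_predictions` attribute.
#' @export
predict.mvt_model <- function(object, newdata, mode = "mvt", ...) {
  prep <- prepare_case(newdata, target = object$config$target)
  models <- lapply(object$fits, function(f) f$net)
  mvt_predict(models, prep$intensity, mode = mode,
              target = object$config$target, bbox = prep$bbox)
}

# ---------------------------------------------------------------------------
# experiment drivers
# ---------------------------------------------------------------------------

#' Run the scaled-down segmentation experiment
#'
#' Generates a phantom cohort, assigns stratified folds, trains a
#' multi-view model on one fold's training split and evaluates the
#' requested aggregation modes on that fold's held-out cases. The whole
#' run is a deterministic function of `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param modes aggregation modes to evaluate.
#' @param fold which test fold to evaluate (default 1).
#' @param max_eval optional cap on the number of evaluated held-out cases.
#' @param planes planes to train (all three by default; single-plane
#'   ablations only need the plane they evaluate).
#' @return list with `model`, `results` (per case x mode x region metrics)
#'   and `cohort` metadata.
#' @export
run_experiment <- function(config,
                           modes = c("mvt", "multiview", "single-axi",
                                     "single-cor"),
                           fold = 1L, max_eval = Inf, planes = PLANES) {
  cohort <- generate_cohort(config$n_cases, ranges = config$ranges,
                            seed = config$seed, grid_shape = config$grid,
                            voxel_mm = config$voxel_mm)
  folds <- stratified_kfold(cohort$metadata$complexity, config$k_folds,
                            seed = config$seed + 1L)
  test_idx <- which(folds == fold)
  train_idx <- which(folds != fold)
  model <- fit_mvt(cohort$cases[train_idx], config, planes = planes)

  if (is.finite(max_eval)) test_idx <- test_idx[seq_len(min(max_eval, length(test_idx)))]
  rows <- list()
  for (ti in test_idx) {
    case <- cohort$cases[[ti]]
    for (md in modes) {
      pred <- predict(model, case, mode = md)
      ev <- evaluate_segmentation(pred, case$labels, config$voxel_mm)
      ev$case_id <- cohort$metadata$case_id[ti]
      ev$mode <- md
      rows[[length(rows) + 1L]] <- ev
    }
  }
  results <- do.call(rbind, rows)
  results <- results[, c("case_id", "mode", "region", "dice", "msd_mm")]
  list(model = model, results = results, cohort = cohort$metadata,
       folds = folds, test_idx = test_idx)
}

#' Loss-function and aggregation ablation
#'
#' Trains one multi-view model per loss type on the same fold split and
#' evaluates each under every aggregation mode, mirroring the loss x
#' aggregation comparison of the full protocol.
#'
#' @param config an [experiment_config()]; its `loss` field is overridden.
#' @param losses loss types to compare.
#' @param modes aggregation modes to evaluate.
#' @param fold test fold.
#' @param max_eval optional cap on evaluated held-out cases.
#' @return data.frame of per case x loss x mode x region metrics.
#' @export
run_ablation <- function(config, losses = c("hybrid", "dice"),
                         modes = c("mvt", "multiview", "tta-axi", "tta-cor",
                                   "single-axi", "single-cor"),
                         fold = 1L, max_eval = Inf) {
  out <- NULL
  for (ls in losses) {
    cfg <- config
    cfg$loss <- loss_config(ls, epsilon = config$loss$epsilon,
                            gamma = config$loss$gamma,
                            lambda = config$loss$lambda,
                            kernel_diameter = config$loss$kernel_diameter)
    run <- run_experiment(cfg, modes = modes, fold = fold,
                          max_eval = max_eval)
    run$results$loss <- ls
    out <- rbind(out, run$results)
  }
  out
}

#' Write experiment results as CSV
#'
#' @param results results data.frame from [run_experiment()].
#' @param path output path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
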
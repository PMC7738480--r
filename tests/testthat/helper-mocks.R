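# Mock plane models for the aggregation tests.
#
# A mock is a list with class "mock_model"; its `rule` turns one intensity
# slice into an (H, W, L) probability map. A shared environment counts
# predict_stack() calls so tests can assert how many predictions each
# aggregation mode consumes.

mock_model <- function(rule, n_labels, counter = NULL) {
  structure(list(rule = rule, n_labels = n_labels, counter = counter),
            class = "mock_model")
}

predict_stack.mock_model <- function(model, stack, batch_size = 32L) {
  if (!is.null(model$counter))
    model$counter$calls <- model$counter$calls + 1L
  d <- dim(stack$slices)
  out <- array(0, c(d[1], d[2], model$n_labels, d[3]))
  for (s in seq_len(d[3])) out[, , , s] <- model$rule(stack$slices[, , s])
  out
}

registerS3method("predict_stack", "mock_model", predict_stack.mock_model,
                 envir = asNamespace("cpseg"))

# Flip-equivariant pixel-rule mocks. The test volume encodes tissue class
# in the intensity value (0 background, 1 inner, 2 cortical plate); the
# left/right side is read off the slice row (the left-right axis), so a
# horizontal flip moves a pixel to the other side and the mock's output
# commutes with flip + label swap exactly.
pixel_rule_5label <- function(slice) {
  H <- nrow(slice); W <- ncol(slice)
  out <- array(0.05, c(H, W, 5))
  left <- matrix(seq_len(H) <= H / 2, H, W)
  inner <- abs(slice - 1) < 0.25
  cp <- abs(slice - 2) < 0.25
  bg <- !(inner | cp)
  out[, , 1][bg] <- 0.8
  out[, , 2][inner & left] <- 0.8
  out[, , 3][inner & !left] <- 0.8
  out[, , 4][cp & left] <- 0.8
  out[, , 5][cp & !left] <- 0.8
  out
}

pixel_rule_3label <- function(slice) {
  H <- nrow(slice); W <- ncol(slice)
  out <- array(0.1, c(H, W, 3))
  inner <- abs(slice - 1) < 0.25
  cp <- abs(slice - 2) < 0.25
  bg <- !(inner | cp)
  out[, , 1][bg] <- 0.8
  out[, , 2][inner] <- 0.8
  out[, , 3][cp] <- 0.8
  out
}

# class-coded volume for the mock pipeline: intensity equals the merged
# class label (0 bg, 1 inner, 2 cortical plate)
class_coded_volume <- function(labels) {
  code <- c(0, 1, 1, 2, 2)
  array(code[labels + 1L], dim(labels))
}

equivariant_models <- function(counter = NULL) {
  list(axial = mock_model(pixel_rule_5label, 5L, counter),
       coronal = mock_model(pixel_rule_5label, 5L, counter),
       sagittal = mock_model(pixel_rule_3label, 3L, counter))
}

# a mock that emits the ground truth as (almost) one-hot maps, keyed by the
# class-coded intensity; side from the row position
truth_models <- function(counter = NULL) equivariant_models(counter)
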
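# Shared fixtures: tiny configurations and mock models used across files.

tiny_unet_cfg <- function(seed = 7L) {
  unet_config(input_size = 16L, encoder_features = c(2L, 3L, 5L),
              base_seed = seed)
}

small_phantom_cfg <- function(...) {
  phantom_config(...)
}

random_mask_array <- function(dim, p = 0.3, seed = 1) {
  rodentstrip:::with_seed(seed, array(rbinom(prod(dim), 1, p), dim = dim))
}

# Mock model that always predicts a constant probability.
constant_model <- function(value, patch = 4L) {
  structure(list(value = value,
                 config = list(input_size = patch)),
            class = c("constant_model"))
}

predict.constant_model <- function(object, newdata, ...) {
  array(object$value, dim = dim(rodentstrip:::as_batch(newdata))[c(1, 2, 4)])
}

# Mock model whose k-th patch in a batch predicts k/10 everywhere; used to
# hand-verify coverage-weighted averaging. Stateful across calls so patch
# indices keep counting within one predict_slice() call sequence.
indexed_model <- function(patch = 4L) {
  env <- new.env()
  env$count <- 0L
  structure(list(env = env, config = list(input_size = patch)),
            class = "indexed_model")
}

predict.indexed_model <- function(object, newdata, ...) {
  d <- dim(rodentstrip:::as_batch(newdata))
  out <- array(0, dim = d[c(1, 2, 4)])
  for (j in seq_len(d[4])) {
    object$env$count <- object$env$count + 1L
    out[, , j] <- object$env$count / 10
  }
  out
}

# Mock predict methods must be visible to dispatch from inside the
# package, not just from the test environment.
registerS3method("predict", "constant_model", predict.constant_model,
                 envir = environment(stats::predict))
registerS3method("predict", "indexed_model", predict.indexed_model,
                 envir = environment(stats::predict))

# Exhaustive all-pairs symmetric Hausdorff oracle over every mask voxel of
# every slice (no boundary optimization), O(n^2) per slice.
hausdorff_oracle <- function(a, b) {
  n_slices <- dim(a)[1]
  vals <- c()
  for (s in seq_len(n_slices)) {
    pa <- which(a[s, , ] > 0, arr.ind = TRUE)
    pb <- which(b[s, , ] > 0, arr.ind = TRUE)
    if (nrow(pa) == 0 || nrow(pb) == 0) next
    d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
    h_ab <- sqrt(max(apply(d2, 1, min)))
    h_ba <- sqrt(max(apply(d2, 2, min)))
    vals <- c(vals, max(h_ab, h_ba))
  }
  if (length(vals) == 0) NA_real_ else max(vals)
}

# 4-neighborhood binary erosion of each axial slice.
erode_inplane <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (s in seq_len(d[1])) {
    sl <- mask[s, , ]
    pad <- matrix(0, d[2] + 2, d[3] + 2)
    pad[2:(d[2] + 1), 2:(d[3] + 1)] <- sl
    kept <- pmin(sl,
                 pad[1:d[2], 2:(d[3] + 1)], pad[3:(d[2] + 2), 2:(d[3] + 1)],
                 pad[2:(d[2] + 1), 1:d[3]], pad[2:(d[2] + 1), 3:(d[3] + 2)])
    out[s, , ] <- kept
  }
  out
}

# 4-neighborhood binary dilation of each axial slice.
dilate_inplane <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (s in seq_len(d[1])) {
    sl <- mask[s, , ]
    pad <- matrix(0, d[2] + 2, d[3] + 2)
    pad[2:(d[2] + 1), 2:(d[3] + 1)] <- sl
    grown <- pmax(sl,
                  pad[1:d[2], 2:(d[3] + 1)], pad[3:(d[2] + 2), 2:(d[3] + 1)],
                  pad[2:(d[2] + 1), 1:d[3]], pad[2:(d[2] + 1), 3:(d[3] + 2)])
    out[s, , ] <- grown
  }
  out
}
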
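#' Plan overlapping tiles across one axial slice
#'
#' Patch origins advance by `stride` along each in-plane axis; the final
#' origin is clamped to `dim - patch_size` so the last pixels are covered
#' without padding. The plan is the Cartesian product of the per-axis
#' origins, together with the per-pixel overlap count used to average the
#' overlapped predictions.
#'
#' @param slice_shape Integer `(rows, cols)`, both `>= patch_size` (pad the
#'   slice first if smaller).
#' @param patch_size Patch side length in pixels (default 128).
#' @param stride In-plane step between patch origins (default 16).
#' @return A `tile_plan`: `offsets` (n x 2 matrix of 0-based origins),
#'   `patch_size`, `stride`, `slice_shape` and `coverage` matrix.
#' @export
plan_tiles <- function(slice_shape, patch_size = 128L, stride = 16L) {
  slice_shape <- as.integer(slice_shape)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (any(slice_shape < patch_size))
    stop2(sprintf("slice shape (%s) smaller than patch size %d; pad first",
                  paste(slice_shape, collapse = " x "), patch_size),
          "rodentstrip_geometry_error")
  axis_offsets <- function(dim) {
    last <- dim - patch_size
    off <- seq.int(0L, last, by = stride)
    if (off[length(off)] != last) off <- c(off, last)
    off
  }
  or <- axis_offsets(slice_shape[1L])
  oc <- axis_offsets(slice_shape[2L])
  offsets <- cbind(row = rep(or, times = length(oc)),
                   col = rep(oc, each = length(or)))
  coverage <- matrix(0L, slice_shape[1L], slice_shape[2L])
  for (i in seq_len(nrow(offsets))) {
    rr <- offsets[i, 1L] + seq_len(patch_size)
    cc <- offsets[i, 2L] + seq_len(patch_size)
    coverage[rr, cc] <- coverage[rr, cc] + 1L
  }
  structure(list(offsets = offsets, patch_size = patch_size,
                 stride = stride, slice_shape = slice_shape,
                 coverage = coverage),
            class = "tile_plan")
}

#' Tiled prediction of one slice with overlap averaging
#'
#' Every planned patch is predicted independently and the per-pixel output
#' is the mean of all patch predictions covering that pixel.
#'
#' @param model A `seg_model` (or any object with a `predict` method taking
#'   an `(H, W, N)` patch stack and returning `(H, W, N)` probabilities).
#' @param slice_image Normalized 2D matrix matching `plan$slice_shape`.
#' @param plan A [plan_tiles()] plan.
#' @param chunk Maximum number of patches per forward pass (memory bound).
#' @return Probability matrix of shape `plan$slice_shape`, values in
#'   `[0, 1]`.
#' @export
predict_slice <- function(model, slice_image, plan, chunk = 16L) {
  if (!identical(as.integer(dim(slice_image)), plan$slice_shape))
    stop2("slice shape does not match the tile plan",
          "rodentstrip_geometry_error")
  p <- plan$patch_size
  n <- nrow(plan$offsets)
  acc <- matrix(0, plan$slice_shape[1L], plan$slice_shape[2L])
  for (start in seq.int(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    patches <- array(0, dim = c(p, p, length(sel)))
    for (j in seq_along(sel)) {
      off <- plan$offsets[sel[j], ]
      patches[, , j] <- slice_image[off[1L] + seq_len(p),
                                    off[2L] + seq_len(p)]
    }
    probs <- predict(model, patches)
    probs <- array(probs, dim = c(p, p, length(sel)))
    for (j in seq_along(sel)) {
      off <- plan$offsets[sel[j], ]
      rr <- off[1L] + seq_len(p); cc <- off[2L] + seq_len(p)
      acc[rr, cc] <- acc[rr, cc] + probs[, , j]
    }
  }
  acc / plan$coverage
}

#' Threshold a probability map into a binary mask
#'
#' Strictly greater than: a pixel equal to the threshold maps to 0.
#'
#' @param prob Probability array (any shape) with values in `[0, 1]`, or an
#'   `mri_volume` of probabilities.
#' @param threshold Cut point in `[0, 1]` (default 0.5).
#' @return 0/1 array of the same shape (a `brain_mask` when `prob` is a
#'   volume).
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop2("threshold must be a single value in [0, 1]",
          "rodentstrip_config_error")
  if (inherits(prob, "mri_volume")) {
    return(new_brain_mask(array(as.numeric(prob$data > threshold),
                                dim = dim(prob$data)),
                          spacing = prob$spacing, affine = prob$affine))
  }
  out <- as.numeric(prob > threshold)
  dim(out) <- dim(prob)
  out
}

# 26-connected components by breadth-first search over linear voxel
# indices; returns the largest component of a 3D binary array.
largest_component_3d <- function(mask) {
  d <- dim(mask)
  active <- which(mask > 0)
  if (length(active) == 0) return(mask)
  # 26-neighborhood linear-index offsets with an in-bounds check per axis
  nb <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$ds == 0 & nb$dr == 0 & nb$dc == 0), ]
  comp <- integer(length(mask))
  is_active <- logical(length(mask)); is_active[active] <- TRUE
  next_id <- 0L
  best_id <- 0L; best_size <- 0L
  for (seed_pos in seq_along(active)) {
    start <- active[seed_pos]
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    comp[start] <- next_id
    frontier <- start
    size <- 1L
    while (length(frontier) > 0) {
      fc <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (j in seq_len(nrow(nb))) {
        s <- fc[, 1] + nb$ds[j]; r <- fc[, 2] + nb$dr[j]
        cc <- fc[, 3] + nb$dc[j]
        ok <- s >= 1 & s <= d[1] & r >= 1 & r <= d[2] & cc >= 1 & cc <= d[3]
        if (!any(ok)) next
        lin <- (cc[ok] - 1L) * d[1] * d[2] + (r[ok] - 1L) * d[1] + s[ok]
        lin <- lin[is_active[lin] & comp[lin] == 0L]
        if (length(lin) > 0) {
          comp[lin] <- next_id
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
      size <- size + length(frontier)
    }
    if (size > best_size) { best_size <- size; best_id <- next_id }
  }
  out <- array(as.numeric(comp == best_id), dim = d)
  out
}

#' Skull-strip a native-resolution volume
#'
#' The full inference pipeline: min-max intensity normalization, slice-wise
#' nearest-neighbor resampling to the working resolution, symmetric zero
#' padding up to the patch size, strided overlapping-tile prediction with
#' averaging on every axial slice, thresholding, and nearest-neighbor
#' restoration to the native grid.
#'
#' @param model A trained `seg_model`.
#' @param native An `mri_volume` on its acquisition grid.
#' @param target_mm Working in-plane resolution (default 0.1 mm).
#' @param threshold Binarization cut (default 0.5, strictly greater than).
#' @param stride Tile stride in pixels (default 16).
#' @param largest_component Keep only the largest 26-connected component of
#'   the final mask (off by default; the network output is used as is).
#' @return List with `mask` (`brain_mask` on the native grid) and `prob`
#'   (`mri_volume` of probabilities on the working grid).
#' @export
strip_skull <- function(model, native, target_mm = 0.1, threshold = 0.5,
                        stride = 16L, largest_component = FALSE) {
  stopifnot(inherits(model, "seg_model"), inherits(native, "mri_volume"))
  patch <- model$config$input_size
  norm <- minmax_normalize(native)
  work <- resample_inplane(norm, target_mm)
  pad <- pad_inplane(work$data, patch)
  dpad <- dim(pad$data)
  plan <- plan_tiles(dpad[2:3], patch_size = patch, stride = stride)
  prob_pad <- array(0, dim = dpad)
  for (s in seq_len(dpad[1L])) {
    prob_pad[s, , ] <- predict_slice(model, pad$data[s, , ], plan)
  }
  prob_work <- unpad_inplane(prob_pad, pad)
  prob_vol <- new_volume(prob_work, spacing = work$spacing,
                         dtype_tag = "float32")
  mask_work_data <- binarize(prob_work, threshold)
  if (largest_component && any(mask_work_data > 0))
    mask_work_data <- largest_component_3d(mask_work_data)
  mask_work <- new_brain_mask(mask_work_data, spacing = work$spacing)
  mask_native <- restore_resolution(mask_work, native)
  list(mask = mask_native, prob = prob_vol)
}
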
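mask_data <- function(x, arg = "mask") {
  if (inherits(x, "mri_volume")) x <- x$data
  if (!all(x %in% c(0, 1)))
    stop2(sprintf("%s contains values other than 0/1", arg),
          "rodentstrip_format_error")
  x
}

#' Volumetric overlap metrics between two binary masks
#'
#' Computes, with `A` the reference (manual) voxel set and `B` the
#' predicted set: `Dice = 2|A n B| / (|A| + |B|)`,
#' `Jaccard = |A n B| / |A u B|`, `PPV = |A n B| / |B|` and
#' `SEN = |A n B| / |A|`. An empty prediction makes PPV undefined; it is
#' reported as 0 with a warning so batch evaluation stays total.
#'
#' @param ref Reference `brain_mask` (or 0/1 array); must be nonempty.
#' @param pred Predicted `brain_mask` (or 0/1 array) of identical shape.
#' @return Named list with `dice`, `jaccard`, `ppv`, `sen` and the counts
#'   `n_ref_voxels`, `n_pred_voxels`, `n_overlap`.
#' @export
overlap_metrics <- function(ref, pred) {
  a <- mask_data(ref, "ref"); b <- mask_data(pred, "pred")
  if (!identical(dim(a), dim(b)))
    stop2("ref and pred shapes differ", "rodentstrip_dim_error")
  n_a <- sum(a); n_b <- sum(b)
  if (n_a == 0)
    stop2("reference mask is empty (must contain brain)",
          "rodentstrip_format_error")
  n_ov <- sum(a * b)
  if (n_b == 0)
    warning("empty prediction: PPV undefined, reported as 0")
  list(dice = 2 * n_ov / (n_a + n_b),
       jaccard = n_ov / (n_a + n_b - n_ov),
       ppv = if (n_b == 0) 0 else n_ov / n_b,
       sen = n_ov / n_a,
       n_ref_voxels = n_a, n_pred_voxels = n_b, n_overlap = n_ov)
}

#' Directed Hausdorff distance between two 2D point sets
#'
#' `h(P, Q) = max over p of min over q of d(p, q)` with `d` the Euclidean
#' distance in voxel units. Note `h` is not symmetric; the symmetric
#' distance is `max(h(P, Q), h(Q, P))`.
#'
#' @param p,q Two-column matrices of (row, col) coordinates; both nonempty.
#' @return The directed distance, a nonnegative scalar.
#' @export
directed_hausdorff_2d <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) == 0 || nrow(q) == 0)
    stop2("point sets must be nonempty", "rodentstrip_format_error")
  d2 <- outer(p[, 1L], q[, 1L], "-")^2 + outer(p[, 2L], q[, 2L], "-")^2
  sqrt(max(apply(d2, 1L, min)))
}

# Coordinates (row, col) of nonzero pixels of a 2D slice; boundary_only
# keeps pixels with at least one 4-neighbor outside the mask (the Hausdorff
# maximum is always attained on such pixels).
mask_points <- function(sl, boundary_only = TRUE) {
  if (boundary_only && any(sl > 0)) {
    nr <- nrow(sl); nc <- ncol(sl)
    pad <- matrix(0, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- sl
    core <- pad[2:(nr + 1L), 2:(nc + 1L)]
    nbr_min <- pmin(pad[1:nr, 2:(nc + 1L)], pad[3:(nr + 2L), 2:(nc + 1L)],
                    pad[2:(nr + 1L), 1:nc], pad[2:(nr + 1L), 3:(nc + 2L)])
    sl <- core * (nbr_min == 0)
  }
  which(sl > 0, arr.ind = TRUE)
}

#' Slice-wise in-plane Hausdorff distance for one subject
#'
#' The Hausdorff distance is estimated only in-plane (within axial slices)
#' to avoid confounds from anisotropic through-plane sampling. For every
#' slice where both masks are nonempty the symmetric distance
#' `max(h(A_s, B_s), h(B_s, A_s))` is computed in voxel units; the subject
#' value is the maximum (worst-matching slice). Slices where exactly one
#' mask is empty are skipped and counted.
#'
#' @param ref,pred `brain_mask` objects (or 0/1 arrays) of identical shape.
#' @param boundary_only Compute distances on mask boundary pixels only
#'   (default). The value is identical to the all-pixel definition, just
#'   cheaper; set `FALSE` to use every mask pixel.
#' @return List with `hausdorff` (subject maximum), `per_slice` (one value
#'   per slice, `NA` where skipped or empty-empty) and `n_skipped_slices`.
#' @export
hausdorff_subject <- function(ref, pred, boundary_only = TRUE) {
  a <- mask_data(ref, "ref"); b <- mask_data(pred, "pred")
  if (!identical(dim(a), dim(b)))
    stop2("ref and pred shapes differ", "rodentstrip_dim_error")
  n_slices <- dim(a)[1L]
  per_slice <- rep(NA_real_, n_slices)
  n_skipped <- 0L
  for (s in seq_len(n_slices)) {
    as <- a[s, , ]; bs <- b[s, , ]
    ea <- !any(as > 0); eb <- !any(bs > 0)
    if (ea && eb) next
    if (ea || eb) { n_skipped <- n_skipped + 1L; next }
    pa <- mask_points(as, boundary_only)
    pb <- mask_points(bs, boundary_only)
    per_slice[s] <- max(directed_hausdorff_2d(pa, pb),
                        directed_hausdorff_2d(pb, pa))
  }
  if (all(is.na(per_slice)))
    stop2("no slice has both masks nonempty", "rodentstrip_format_error")
  if (n_skipped > 0)
    message(sprintf("hausdorff_subject: skipped %d slice(s) where exactly %s",
                    n_skipped, "one mask was empty"))
  list(hausdorff = max(per_slice, na.rm = TRUE),
       per_slice = per_slice,
       n_skipped_slices = n_skipped)
}

#' Full five-metric evaluation of a predicted mask
#'
#' Combines [overlap_metrics()] and [hausdorff_subject()] into one report:
#' Dice, Jaccard, PPV, SEN and the slice-maximum in-plane Hausdorff
#' distance (voxels). Higher overlap metrics and lower Hausdorff indicate
#' better segmentation.
#'
#' @inheritParams hausdorff_subject
#' @return A `metrics_report` list; `as.data.frame()` turns it into a
#'   one-row table suitable for a CSV report.
#' @export
evaluate_pair <- function(ref, pred, boundary_only = TRUE) {
  ov <- overlap_metrics(ref, pred)
  hd <- hausdorff_subject(ref, pred, boundary_only = boundary_only)
  structure(c(ov,
              list(hausdorff_voxels = hd$hausdorff,
                   per_slice_hausdorff = hd$per_slice,
                   n_skipped_slices = hd$n_skipped_slices)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> dice %.4f | jaccard %.4f | ",
                     "ppv %.4f | sen %.4f | hausdorff %.2f voxels\n"),
              x$dice, x$jaccard, x$ppv, x$sen, x$hausdorff_voxels))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(dice = x$dice, jaccard = x$jaccard, ppv = x$ppv, sen = x$sen,
             hausdorff_voxels = x$hausdorff_voxels,
             n_ref_voxels = x$n_ref_voxels,
             n_pred_voxels = x$n_pred_voxels,
             n_overlap = x$n_overlap,
             n_skipped_slices = x$n_skipped_slices)
}

#' Evaluate a batch of reference/prediction mask pairs
#'
#' @param manifest Data frame with columns `ref_path` and `pred_path`
#'   (NIfTI masks) and optionally `subject_id`.
#' @param boundary_only Passed to [evaluate_pair()].
#' @return A tibble with one row per pair: the five metrics plus counts.
#' @export
evaluate_batch <- function(manifest, boundary_only = TRUE) {
  stopifnot(all(c("ref_path", "pred_path") %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    rep <- evaluate_pair(load_volume(manifest$ref_path[i]),
                         load_volume(manifest$pred_path[i]),
                         boundary_only = boundary_only)
    df <- as.data.frame(rep)
    df$subject_id <- if ("subject_id" %in% names(manifest))
      manifest$subject_id[i] else as.character(i)
    df
  })
  out <- do.call(rbind, rows)
  tibble::as_tibble(out[, c("subject_id",
                            setdiff(names(out), "subject_id"))])
}
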
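#' @useDynLib rodentstrip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif predict
#' @importFrom utils read.csv write.csv tail packageVersion
NULL

stop2 <- function(message, class) {
  stop(errorCondition(message, class = c(class, "rodentstrip_error")))
}

# Snap doubles to the nearest IEEE single-precision value so that what we
# hold in memory is exactly what a float32 NIfTI stores on disk.
as_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 what = "numeric", size = 4L, n = length(x))
  dim(out) <- d
  out
}

#' MR volume and brain-mask containers
#'
#' A `mri_volume` is a 3D scalar image indexed `(slice, row, col)` — the
#' slice axis is the acquisition's through-plane axis — together with the
#' per-axis voxel spacing in millimetres and a 4x4 voxel-to-world affine.
#' A `brain_mask` is a volume whose voxels are restricted to \{0, 1\}, with
#' 1 marking brain tissue.
#'
#' @param data 3D numeric array, axis order `(slice, row, col)`.
#' @param spacing Numeric length-3 vector of voxel sizes in mm,
#'   `(slice_mm, row_mm, col_mm)`; all components must be positive.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaling
#'   by `(col_mm, row_mm, slice_mm)`.
#' @param dtype_tag Storage precision label: `"float32"` (images; values are
#'   snapped to single precision) or `"uint8"` (masks).
#' @return An object of class `mri_volume` (or `c("brain_mask",
#'   "mri_volume")` for [new_brain_mask()]).
#' @export
new_volume <- function(data, spacing, affine = NULL, dtype_tag = "float32") {
  if (length(dim(data)) != 3L)
    stop2(sprintf("volume data must have exactly 3 axes, got %d",
                  length(dim(data))), "rodentstrip_dim_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop2("spacing must be 3 positive finite numbers",
          "rodentstrip_format_error")
  if (is.null(affine)) {
    affine <- diag(c(spacing[3L], spacing[2L], spacing[1L], 1))
  }
  if (identical(dtype_tag, "float32")) data <- as_float32(data)
  structure(list(data = data, spacing = spacing, affine = affine,
                 dtype_tag = dtype_tag),
            class = "mri_volume")
}

#' @rdname new_volume
#' @export
new_brain_mask <- function(data, spacing, affine = NULL) {
  d <- dim(data)
  data <- as.numeric(data)       # may arrive logical or integer
  dim(data) <- d
  if (!all(data %in% c(0, 1)))
    stop2("mask voxels must all be 0 or 1", "rodentstrip_format_error")
  v <- new_volume(data, spacing, affine, dtype_tag = "uint8")
  class(v) <- c("brain_mask", "mri_volume")
  v
}

#' @export
print.mri_volume <- function(x, ...) {
  kind <- if (inherits(x, "brain_mask")) "brain_mask" else "mri_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm (slice, row, col), %s\n",
              kind, paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "), x$dtype_tag))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

is_binary_data <- function(data) all(data %in% c(0, 1))

#' Read a 3D NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file and normalizes the axis order to
#' `(slice, row, col)`: the axis with the largest voxel spacing is taken as
#' the through-plane (slice) axis and moved first; when all spacings are
#' equal the stored order is kept. Files whose voxels are all 0/1 are
#' returned as a [new_brain_mask()].
#'
#' @param path Path to a readable 3D NIfTI file.
#' @return An `mri_volume` (or `brain_mask` if the data are binary).
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop2(sprintf("file not found: %s", path), "rodentstrip_io_error")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop2(sprintf("expected a 3D volume, got %d axes (%s) in %s",
                  length(d), paste(d, collapse = " x "), path),
          "rodentstrip_dim_error")
  sp <- RNifti::pixdim(img)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop2(sprintf("non-positive header spacing (%s) in %s",
                  paste(sp, collapse = ", "), path),
          "rodentstrip_format_error")
  slice_axis <- which.max(sp)                  # first axis on ties
  perm <- c(slice_axis, setdiff(1:3, slice_axis))
  data <- array(as.numeric(img), dim = d)
  if (!identical(perm, 1:3)) {
    data <- aperm(data, perm)
    sp <- sp[perm]
  }
  aff <- tryCatch(structure(RNifti::xform(img), dim = c(4L, 4L)),
                  error = function(e) NULL)
  if (is_binary_data(data)) {
    new_brain_mask(data, spacing = sp, affine = aff)
  } else {
    new_volume(data, spacing = sp, affine = aff, dtype_tag = "float32")
  }
}

#' Write a volume or mask to NIfTI
#'
#' Masks are stored as 8-bit unsigned integers, images as 32-bit floats;
#' a [load_volume()] round trip reproduces the voxel data bit-exactly and
#' the spacing exactly.
#'
#' @param v An `mri_volume` or `brain_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  stopifnot(inherits(v, "mri_volume"))
  if (!dir.exists(dirname(path)))
    stop2(sprintf("output directory does not exist: %s", dirname(path)),
          "rodentstrip_io_error")
  is_mask <- inherits(v, "brain_mask")
  data <- v$data
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

rhu <- function(x) floor(x + 0.5)   # round half up, deterministically

# Nearest-neighbor source index (0-based) for each of `n_out` output pixels
# whose grid refines/coarsens `n_in` pixels by `factor` = in_mm / out_mm,
# with pixel-center alignment: src(i) = floor((i + 0.5) / factor).
nn_source_index <- function(n_out, factor, n_in) {
  src <- floor(((seq_len(n_out) - 0.5)) / factor)
  pmin(pmax(src, 0), n_in - 1) + 1L
}

#' Resample each axial slice to a target in-plane resolution
#'
#' Every axial slice is independently resampled to `target_mm x target_mm`
#' using nearest-neighbor interpolation; the slice count and slice spacing
#' are untouched. The output in-plane dimension is
#' `round(dim * spacing / target_mm)` (half-up), and the source pixel for
#' output pixel `i` (0-based) is `floor((i + 0.5) / factor)` with
#' `factor = spacing / target_mm` — pixel-center alignment, exactly
#' invertible for integer factors. Masks stay binary because labels are
#' copied, never blended.
#'
#' @param v An `mri_volume` or `brain_mask`.
#' @param target_mm Target in-plane voxel size in mm (default 0.1, the
#'   working resolution of the segmentation network).
#' @return Same class as `v`, on the resampled grid.
#' @export
resample_inplane <- function(v, target_mm = 0.1) {
  stopifnot(inherits(v, "mri_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop2("target_mm must be a single positive number",
          "rodentstrip_config_error")
  d <- dim(v$data)
  fr <- v$spacing[2L] / target_mm
  fc <- v$spacing[3L] / target_mm
  nr <- as.integer(rhu(d[2L] * fr))
  nc <- as.integer(rhu(d[3L] * fc))
  src_r <- nn_source_index(nr, fr, d[2L])
  src_c <- nn_source_index(nc, fc, d[3L])
  data <- v$data[, src_r, src_c, drop = FALSE]
  sp <- c(v$spacing[1L], target_mm, target_mm)
  if (inherits(v, "brain_mask")) {
    new_brain_mask(data, spacing = sp)
  } else {
    new_volume(data, spacing = sp, dtype_tag = v$dtype_tag)
  }
}

#' Map a working-resolution mask back onto a native-resolution grid
#'
#' The inverse of [resample_inplane()] for masks: each native-grid pixel
#' takes the label of the working-grid pixel containing its centre
#' (nearest-neighbor). When the grids already match this is the identity.
#'
#' @param m `brain_mask` on the working (resampled) grid.
#' @param reference `mri_volume` on the native grid `m` was derived from;
#'   must have the same slice count.
#' @return `brain_mask` with the shape and spacing of `reference`.
#' @export
restore_resolution <- function(m, reference) {
  stopifnot(inherits(m, "brain_mask"), inherits(reference, "mri_volume"))
  dm <- dim(m$data); dr <- dim(reference$data)
  if (dm[1L] != dr[1L])
    stop2(sprintf("slice count mismatch: mask has %d, reference has %d",
                  dm[1L], dr[1L]), "rodentstrip_geometry_error")
  fr <- reference$spacing[2L] / m$spacing[2L]
  fc <- reference$spacing[3L] / m$spacing[3L]
  src_r <- nn_source_index(dr[2L], 1 / fr, dm[2L])
  src_c <- nn_source_index(dr[3L], 1 / fc, dm[3L])
  data <- m$data[, src_r, src_c, drop = FALSE]
  new_brain_mask(data, spacing = reference$spacing,
                 affine = reference$affine)
}

#' Min-max intensity normalization
#'
#' Rescales the whole 3D image (not per slice) to `[0, 1]` via
#' `(x - min) / (max - min)` and stores the result at single precision.
#' A constant image has no contrast to rescale; it is mapped to all zeros
#' with a warning so downstream training never sees NaN.
#'
#' @param v An `mri_volume`.
#' @return A normalized `mri_volume` with `dtype_tag = "float32"`.
#' @export
minmax_normalize <- function(v) {
  stopifnot(inherits(v, "mri_volume"))
  rng <- range(v$data)
  if (rng[1L] == rng[2L]) {
    warning("constant image: min-max normalization returns all zeros")
    data <- array(0, dim = dim(v$data))
  } else {
    data <- (v$data - rng[1L]) / (rng[2L] - rng[1L])
  }
  new_volume(data, spacing = v$spacing, affine = v$affine,
             dtype_tag = "float32")
}

# Symmetric zero padding of the in-plane axes up to at least `size`.
# Returns the padded array plus the offsets needed to undo it.
pad_inplane <- function(data, size = 128L) {
  d <- dim(data)
  nr <- max(d[2L], size); nc <- max(d[3L], size)
  r0 <- (nr - d[2L]) %/% 2L
  c0 <- (nc - d[3L]) %/% 2L
  out <- array(0, dim = c(d[1L], nr, nc))
  out[, r0 + seq_len(d[2L]), c0 + seq_len(d[3L])] <- data
  list(data = out, row_offset = r0, col_offset = c0, orig_dim = d)
}

unpad_inplane <- function(data, pad) {
  d <- pad$orig_dim
  data[, pad$row_offset + seq_len(d[2L]), pad$col_offset + seq_len(d[3L]),
       drop = FALSE]
}
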
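#' Synthetic rodent-head phantom configuration
#'
#' Parameters of the procedural phantom: an ellipsoidal brain with an
#' anterior olfactory-bulb lobe and a posterior, ventrally shifted
#' brainstem extension, wrapped by a scalp/muscle shell that is separated
#' from the brain by a low-signal skull gap. The inferior third of the
#' brain is attenuated to reproduce the weak-signal regions (brainstem,
#' olfactory bulb, inferior brain) where intensity-driven skull strippers
#' fail. A smooth multiplicative bias field and Rician noise complete the
#' image model. Geometry is procedural, not atlas-derived: the goal is the
#' failure-mode structure, not anatomical fidelity.
#'
#' @param preset `"rare_aniso"` — anatomical-like grid, 0.1 x 0.1 x 1 mm,
#'   96 x 96 in-plane; or `"epi_coarse"` — functional-like grid,
#'   0.32 x 0.32 x 1 mm, 40 x 40 in-plane.
#' @param n_slices Number of 1 mm axial slices (default 12).
#' @param brain_axes_mm Semi-axes (slice, row, col) of the main brain
#'   ellipsoid in mm.
#' @param scalp_thickness_mm,skull_gap_mm Scalp shell thickness and
#'   brain-to-scalp gap, mm (in-plane).
#' @param intensity_levels Named numeric `(brain, scalp, background)`
#'   noise-free tissue intensities; the skull gap renders at background.
#' @param inferior_attenuation Multiplicative signal loss in `[0, 1]`
#'   applied to the inferior third of the brain (0 = none).
#' @param bias_amplitude Amplitude of the log-scale quadratic bias field
#'   (field is `exp(q)` with `max |q| = bias_amplitude`).
#' @param noise_sigma Rician noise scale, on the tissue-intensity scale.
#' @param seed Integer; the phantom is fully determined by it.
#' @return A `phantom_config` list (with derived `spacing` and `inplane`).
#' @export
phantom_config <- function(preset = c("rare_aniso", "epi_coarse"),
                           n_slices = 12L,
                           brain_axes_mm = c(3.0, 2.4, 3.0),
                           scalp_thickness_mm = 0.8,
                           skull_gap_mm = 0.3,
                           intensity_levels = c(brain = 1.0, scalp = 0.55,
                                                background = 0.08),
                           inferior_attenuation = 0.3,
                           bias_amplitude = 0.2,
                           noise_sigma = 0.04,
                           seed = 1L) {
  preset <- match.arg(preset)
  grid <- switch(preset,
                 rare_aniso = list(spacing = c(1, 0.1, 0.1), inplane = 96L),
                 epi_coarse = list(spacing = c(1, 0.32, 0.32), inplane = 40L))
  if (length(brain_axes_mm) != 3L || any(brain_axes_mm <= 0))
    stop2("brain_axes_mm must be 3 positive numbers",
          "rodentstrip_config_error")
  if (length(unique(intensity_levels)) != 3L)
    stop2("intensity_levels must be 3 distinct values",
          "rodentstrip_config_error")
  if (noise_sigma < 0 || inferior_attenuation < 0 || inferior_attenuation > 1)
    stop2("noise_sigma must be >= 0 and inferior_attenuation in [0, 1]",
          "rodentstrip_config_error")
  structure(list(preset = preset, n_slices = as.integer(n_slices),
                 spacing = grid$spacing, inplane = grid$inplane,
                 brain_axes_mm = brain_axes_mm,
                 scalp_thickness_mm = scalp_thickness_mm,
                 skull_gap_mm = skull_gap_mm,
                 intensity_levels = intensity_levels,
                 inferior_attenuation = inferior_attenuation,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# The three brain components as (center offset from FOV center, semi-axes),
# all in mm. Offsets/axes scale with the configured brain axes so subject
# jitter moves everything coherently.
phantom_shapes <- function(axes) {
  list(main      = list(center = c(0, 0, 0), semi = axes),
       olfactory = list(center = c(-0.95 * axes[1L], 0, 0),
                        semi = c(0.35, 0.45, 0.45) * axes),
       brainstem = list(center = c(0.85 * axes[1L], 0.40 * axes[2L], 0),
                        semi = c(0.45, 0.50, 0.40) * axes))
}

#' Generate one synthetic rodent-head phantom
#'
#' @param cfg A [phantom_config()].
#' @return List with `volume` (`mri_volume`) and `mask` (`brain_mask`,
#'   the exact voxelization of the brain shape at voxel centres).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  sp <- cfg$spacing
  d <- c(cfg$n_slices, cfg$inplane, cfg$inplane)
  fov <- d * sp
  ctr <- fov / 2
  s_mm <- (seq_len(d[1L]) - 0.5) * sp[1L]
  r_mm <- (seq_len(d[2L]) - 0.5) * sp[2L]
  c_mm <- (seq_len(d[3L]) - 0.5) * sp[3L]

  shapes <- phantom_shapes(cfg$brain_axes_mm)
  inside <- array(FALSE, dim = d)
  for (sh in shapes) {
    cc <- ctr + sh$center
    rho2 <- outer(outer(((s_mm - cc[1L]) / sh$semi[1L])^2,
                        ((r_mm - cc[2L]) / sh$semi[2L])^2, "+"),
                  ((c_mm - cc[3L]) / sh$semi[3L])^2, "+")
    inside <- inside | (rho2 <= 1)
  }
  mask <- array(as.numeric(inside), dim = d)

  # Brain must stay >= 2 background voxels away from every border.
  margin_ok <- all(mask[1:2, , ] == 0) && all(mask[(d[1L] - 1L):d[1L], , ] == 0) &&
    all(mask[, 1:2, ] == 0) && all(mask[, (d[2L] - 1L):d[2L], ] == 0) &&
    all(mask[, , 1:2] == 0) && all(mask[, , (d[3L] - 1L):d[3L]] == 0)
  if (!margin_ok || sum(mask) == 0)
    stop2("phantom geometry violates the 2-voxel background margin",
          "rodentstrip_config_error")

  lv <- cfg$intensity_levels
  img <- array(lv[["background"]], dim = d)

  # Scalp shell from the in-plane distance to the brain (skull gap between).
  gap_px <- cfg$skull_gap_mm / sp[2L]
  scalp_px <- cfg$scalp_thickness_mm / sp[2L]
  for (s in seq_len(d[1L])) {
    sl <- mask[s, , ]
    if (!any(sl > 0)) next
    dist <- EBImage::distmap(1 - sl)
    img[s, , ][dist > gap_px & dist <= gap_px + scalp_px] <- lv[["scalp"]]
    img[s, , ][sl > 0] <- lv[["brain"]]
  }

  # Weak-signal inferior third of the brain (rows below 1/3 of the brain's
  # dorsoventral semi-axis, measured from the FOV centre).
  if (cfg$inferior_attenuation > 0) {
    inferior <- r_mm > ctr[2L] + cfg$brain_axes_mm[2L] / 3
    att <- mask * 0
    att[, inferior, ] <- mask[, inferior, ]
    img <- img * (1 - cfg$inferior_attenuation * att)
  }

  with_seed(cfg$seed, {
    if (cfg$bias_amplitude > 0) {
      co <- rnorm(9L)
      xs <- 2 * (s_mm - ctr[1L]) / fov[1L]
      xr <- 2 * (r_mm - ctr[2L]) / fov[2L]
      xc <- 2 * (c_mm - ctr[3L]) / fov[3L]
      gs <- array(rep(xs, times = d[2L] * d[3L]), dim = d)
      gr <- array(rep(rep(xr, each = d[1L]), times = d[3L]), dim = d)
      gc <- array(rep(xc, each = d[1L] * d[2L]), dim = d)
      q <- co[1L] * gs + co[2L] * gr + co[3L] * gc +
        co[4L] * gs^2 + co[5L] * gr^2 + co[6L] * gc^2 +
        co[7L] * gs * gr + co[8L] * gs * gc + co[9L] * gr * gc
      q <- q / max(abs(q)) * cfg$bias_amplitude
      img <- img * exp(q)
    }
    if (cfg$noise_sigma > 0) {
      n1 <- array(rnorm(length(img), sd = cfg$noise_sigma), dim = d)
      n2 <- array(rnorm(length(img), sd = cfg$noise_sigma), dim = d)
      img <- sqrt((img + n1)^2 + n2^2)     # magnitude (Rician) noise
    }
  })

  list(volume = new_volume(img, spacing = sp),
       mask = new_brain_mask(mask, spacing = sp))
}

#' Generate a reproducible multi-subject phantom dataset
#'
#' Subjects alternate between the high-resolution anatomical preset and the
#' coarse EPI preset, with per-subject geometry jitter (semi-axes scaled by
#' up to +/-10%) and per-subject bias-field orientation. Subject `i` is
#' generated from seed `seed + i`, so any subject is reproducible in
#' isolation.
#'
#' @param n_subjects Number of phantoms (>= 1).
#' @param cfg_template A [phantom_config()] supplying everything except the
#'   preset and seed.
#' @param seed Integer base seed.
#' @param dir Optional output directory; when given, image/mask NIfTI pairs
#'   and a `manifest.csv` are written there.
#' @param preset `"alternate"` (default; odd subjects anatomical, even
#'   subjects EPI) or one fixed preset name for every subject.
#' @return List with `manifest` (tibble: subject_id, contrast_tag, stratum,
#'   seed, and file paths when `dir` is given) and `subjects` (list of
#'   `volume`/`mask` pairs).
#' @export
generate_dataset <- function(n_subjects, cfg_template = phantom_config(),
                             seed = 1L, dir = NULL,
                             preset = c("alternate", "rare_aniso",
                                        "epi_coarse")) {
  stopifnot(n_subjects >= 1)
  preset_mode <- match.arg(preset)
  subjects <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sub_seed <- as.integer(seed) + i
    preset <- if (preset_mode == "alternate") {
      if (i %% 2L == 1L) "rare_aniso" else "epi_coarse"
    } else preset_mode
    jitter <- with_seed(sub_seed * 2L + 1L, runif(3L, 0.9, 1.1))
    cfg <- cfg_template
    cfg$preset <- preset
    grid <- switch(preset,
                   rare_aniso = list(spacing = c(1, 0.1, 0.1), inplane = 96L),
                   epi_coarse = list(spacing = c(1, 0.32, 0.32),
                                     inplane = 40L))
    cfg$spacing <- grid$spacing
    cfg$inplane <- grid$inplane
    cfg$brain_axes_mm <- cfg_template$brain_axes_mm * jitter
    cfg$seed <- sub_seed
    pair <- generate_phantom(cfg)
    subjects[[i]] <- pair
    id <- sprintf("sub-%02d", i)
    row <- data.frame(subject_id = id,
                      contrast_tag = if (preset == "rare_aniso") "rare"
                                     else "epi",
                      stratum = preset, seed = sub_seed,
                      stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      row$image_path <- file.path(dir, paste0(id, "_img.nii.gz"))
      row$mask_path <- file.path(dir, paste0(id, "_mask.nii.gz"))
      save_volume(pair$volume, row$image_path)
      save_volume(pair$mask, row$mask_path)
    }
    rows[[i]] <- row
  }
  manifest <- tibble::as_tibble(do.call(rbind, rows))
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, subjects = subjects)
}
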
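#' Training hyperparameters
#'
#' Houses the optimizer and sampling constants: Adam with initial learning
#' rate 1e-3, batch size 16, and all parameter gradients clipped to a
#' global norm of 1. One epoch draws one random 128 x 128 patch per
#' training slice.
#'
#' @param learning_rate Adam initial learning rate (default 1e-3).
#' @param batch_size Patches per optimization step (default 16).
#' @param grad_clip_norm Maximum global gradient norm (default 1).
#' @param epochs Training epochs (default 50; no early stopping).
#' @param patch_size Square patch side in pixels (default 128).
#' @param repeats Independent training/validation repeats for model
#'   selection (default 5).
#' @param split_fraction Fraction of subjects assigned to training in each
#'   inner split (default 0.8).
#' @param seed Integer seed governing splits, patch sampling and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                         grad_clip_norm = 1.0, epochs = 50L,
                         patch_size = 128L, repeats = 5L,
                         split_fraction = 0.8, seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop2("split_fraction must be in (0, 1)", "rodentstrip_config_error")
  if (batch_size < 1L || grad_clip_norm <= 0)
    stop2("batch_size must be >= 1 and grad_clip_norm > 0",
          "rodentstrip_config_error")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 grad_clip_norm = grad_clip_norm,
                 epochs = as.integer(epochs),
                 patch_size = as.integer(patch_size),
                 repeats = as.integer(repeats),
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-level (optionally stratified) train/validation split
#'
#' Splitting is always by subject, never by slice, so no subject's slices
#' can leak across the split. Within each stratum (e.g. strain),
#' `round(n * fraction)` subjects go to training. A stratum with fewer than
#' two subjects cannot be split and goes wholly to training, with a
#' warning.
#'
#' @param ids Character/integer vector of subject identifiers (>= 2).
#' @param fraction Training fraction in (0, 1) (default 0.8).
#' @param seed Integer seed; the split is a deterministic function of
#'   `ids`, `fraction`, `seed` and `strata`.
#' @param strata Optional per-subject stratum labels (same length as
#'   `ids`).
#' @param repeat_index Bookkeeping index of the repeat this split belongs
#'   to.
#' @return A `subject_split` with disjoint `train_ids` and `val_ids`
#'   covering all subjects.
#' @export
split_subjects <- function(ids, fraction = 0.8, seed = 1L, strata = NULL,
                           repeat_index = 1L) {
  if (length(ids) < 2L)
    stop2("need at least 2 subjects to split", "rodentstrip_config_error")
  if (anyDuplicated(ids))
    stop2("subject ids must be unique", "rodentstrip_config_error")
  if (fraction <= 0 || fraction >= 1)
    stop2("fraction must be in (0, 1)", "rodentstrip_config_error")
  if (is.null(strata)) strata <- rep("all", length(ids))
  stopifnot(length(strata) == length(ids))
  train_ids <- character(0)
  with_seed(seed, {
    for (st in unique(strata)) {
      sub <- ids[strata == st]
      if (length(sub) < 2L) {
        warning(sprintf("stratum '%s' has < 2 subjects; assigned to train",
                        st))
        train_ids <- c(train_ids, as.character(sub))
        next
      }
      n_train <- as.integer(rhu(length(sub) * fraction))
      n_train <- min(max(n_train, 1L), length(sub) - 1L)
      picked <- sample(sub, n_train)
      train_ids <- c(train_ids, as.character(picked))
    }
  })
  val_ids <- setdiff(as.character(ids), train_ids)
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 repeat_index = as.integer(repeat_index)),
            class = "subject_split")
}

#' Draw one random patch from an axial slice
#'
#' A uniformly random `patch_size` x `patch_size` crop, with the identical
#' offset applied to image and mask. Slices smaller than the patch are
#' first symmetrically zero-padded (mask padded with background).
#' Randomness comes from R's global RNG; seed the caller for
#' reproducibility.
#'
#' @param slice_image 2D numeric matrix.
#' @param slice_mask 2D 0/1 matrix of the same shape.
#' @param patch_size Crop side length in pixels (default 128).
#' @return List with `image`, `mask` (both `patch_size` square) and the
#'   0-based `offset` used.
#' @export
sample_patch <- function(slice_image, slice_mask, patch_size = 128L) {
  stopifnot(identical(dim(slice_image), dim(slice_mask)))
  d <- dim(slice_image)
  if (any(d < patch_size)) {
    pi <- pad_inplane(array(slice_image, dim = c(1L, d)), patch_size)
    pm <- pad_inplane(array(slice_mask, dim = c(1L, d)), patch_size)
    slice_image <- pi$data[1L, , ]
    slice_mask <- pm$data[1L, , ]
    d <- dim(slice_image)
  }
  r0 <- sample.int(d[1L] - patch_size + 1L, 1L) - 1L
  c0 <- sample.int(d[2L] - patch_size + 1L, 1L) - 1L
  list(image = slice_image[r0 + seq_len(patch_size),
                           c0 + seq_len(patch_size)],
       mask = slice_mask[r0 + seq_len(patch_size),
                         c0 + seq_len(patch_size)],
       offset = c(r0, c0))
}

# Normalize, resample to the working grid and pad one subject; returns the
# padded working image/mask stacks used for slice sampling and validation.
prepare_subject <- function(volume, mask, target_mm = 0.1,
                            patch_size = 128L) {
  work_img <- resample_inplane(minmax_normalize(volume), target_mm)
  work_msk <- resample_inplane(mask, target_mm)
  pi <- pad_inplane(work_img$data, patch_size)
  pm <- pad_inplane(work_msk$data, patch_size)
  list(image = pi$data, mask = pm$data, pad = pi,
       spacing = work_img$spacing)
}

# Flatten prepared subjects into per-slice training records.
training_slices <- function(prepped, ids) {
  out <- list()
  for (i in seq_along(prepped)) {
    img <- prepped[[i]]$image; msk <- prepped[[i]]$mask
    for (s in seq_len(dim(img)[1L])) {
      out[[length(out) + 1L]] <- list(image = img[s, , ],
                                      mask = msk[s, , ],
                                      subject_id = ids[i])
    }
  }
  out
}

subject_val_dice <- function(model, prepped_subject, threshold = 0.5) {
  img <- prepped_subject$image; msk <- prepped_subject$mask
  d <- dim(img)
  patch <- model$config$input_size
  plan <- plan_tiles(d[2:3], patch_size = patch, stride = patch)
  pred <- array(0, dim = d)
  for (s in seq_len(d[1L])) {
    pred[s, , ] <- predict_slice(model, img[s, , ], plan)
  }
  pm <- binarize(pred, threshold)
  n_ov <- sum(pm * msk)
  2 * n_ov / (sum(pm) + sum(msk))
}

#' Train a segmentation model on phantom or real slices
#'
#' Adam optimization of the Dice loss over randomly sampled patches. One
#' epoch shuffles the training slices and draws one random patch per slice
#' (so every slice contributes once per epoch in expectation), stepping on
#' mini-batches of `cfg$batch_size`. Gradients are clipped to a global norm
#' of `cfg$grad_clip_norm` before each step. After every epoch the
#' validation subjects are segmented with the full-slice tiled-inference
#' path and their mean Dice recorded.
#'
#' @param model A `seg_model` (see [build_unet()]).
#' @param train_set Per-slice records as produced internally from prepared
#'   subjects: each a list with `image` and `mask` matrices.
#' @param val_set List of prepared subjects (padded working-grid `image`
#'   and `mask` stacks); may be empty, in which case `val_dice` is `NA`.
#' @param cfg A [train_config()].
#' @return The trained `seg_model`; `$history` is a tibble with columns
#'   `epoch`, `train_loss`, `val_dice`, and `$grad_norms` records the
#'   pre-clipping global gradient norm of every step.
#' @export
train_model <- function(model, train_set, val_set = list(),
                        cfg = train_config()) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  if (length(train_set) == 0L)
    stop2("training set is empty", "rodentstrip_config_error")
  params <- model$params
  state <- adam_init(params)
  n <- length(train_set)
  history <- vector("list", cfg$epochs)
  grad_norms <- numeric(0)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq.int(1L, n, by = cfg$batch_size)) {
        sel <- perm[start:min(start + cfg$batch_size - 1L, n)]
        nb <- length(sel)
        x <- array(0, dim = c(cfg$patch_size, cfg$patch_size, 1L, nb))
        y <- array(0, dim = dim(x))
        for (j in seq_len(nb)) {
          sl <- train_set[[sel[j]]]
          pt <- sample_patch(sl$image, sl$mask, cfg$patch_size)
          x[, , 1L, j] <- pt$image
          y[, , 1L, j] <- pt$mask
        }
        lg <- unet_loss_grad(params, model$config, x, y)
        if (!is.finite(lg$loss))
          stop2(sprintf(
            "non-finite loss at epoch %d, batch starting at slice %d",
            epoch, start), "rodentstrip_numeric_error")
        cl <- clip_grads(lg$grads, cfg$grad_clip_norm)
        grad_norms <- c(grad_norms, cl$norm)
        upd <- adam_step(params, cl$grads, state, lr = cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, lg$loss)
      }
      model$params <- params
      val_dice <- if (length(val_set) > 0) {
        mean(vapply(val_set, function(vs) subject_val_dice(model, vs),
                    numeric(1)))
      } else NA_real_
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = mean(losses),
                                     val_dice = val_dice)
    }
  })
  model$params <- params
  model$history <- tibble::as_tibble(do.call(rbind, history))
  model$grad_norms <- grad_norms
  model
}

#' Select the best of several training runs
#'
#' @param runs List of runs, each a list with `model` and `score`
#'   (averaged validation accuracy). Ties break toward the earliest run.
#' @return The `model` of the highest-scoring run.
#' @export
select_best <- function(runs) {
  if (length(runs) == 0L)
    stop2("no runs to select from", "rodentstrip_config_error")
  scores <- vapply(runs, function(r) r$score, numeric(1))
  runs[[which.max(scores)]]$model          # which.max takes the first tie
}

#' Repeated-split training with model selection
#'
#' Repeats the inner train/validation split `cfg$repeats` times (each
#' repeat re-seeds both the split and the weight initialization), trains a
#' model per repeat, and keeps the one with the highest averaged validation
#' Dice.
#'
#' @param subjects List of `list(volume, mask)` pairs (e.g.
#'   `generate_dataset()$subjects`).
#' @param ids Subject identifiers aligned with `subjects`.
#' @param unet_cfg A [unet_config()].
#' @param cfg A [train_config()].
#' @param strata Optional per-subject stratum labels for the splits.
#' @param target_mm Working in-plane resolution (default 0.1 mm).
#' @return List with `model` (the selected `seg_model`), `runs` (tibble:
#'   repeat_index, score) and `splits`.
#' @export
train_repeats <- function(subjects, ids, unet_cfg = unet_config(),
                          cfg = train_config(), strata = NULL,
                          target_mm = 0.1) {
  stopifnot(length(subjects) == length(ids))
  prepped <- lapply(subjects, function(p)
    prepare_subject(p$volume, p$mask, target_mm, cfg$patch_size))
  names(prepped) <- ids
  runs <- vector("list", cfg$repeats)
  splits <- vector("list", cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    split <- split_subjects(ids, cfg$split_fraction,
                            seed = cfg$seed + r, strata = strata,
                            repeat_index = r)
    splits[[r]] <- split
    train_set <- training_slices(prepped[split$train_ids], split$train_ids)
    val_set <- prepped[split$val_ids]
    ucfg <- unet_cfg
    ucfg$base_seed <- unet_cfg$base_seed + r
    rcfg <- cfg
    rcfg$seed <- cfg$seed + 1000L * r
    model <- train_model(build_unet(ucfg), train_set, val_set, rcfg)
    score <- model$history$val_dice[nrow(model$history)]
    runs[[r]] <- list(model = model, score = score, repeat_index = r)
  }
  best <- select_best(runs)
  list(model = best,
       runs = tibble::tibble(
         repeat_index = vapply(runs, function(r) r$repeat_index, integer(1)),
         score = vapply(runs, function(r) r$score, numeric(1))),
       splits = splits)
}
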
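#' End-to-end phantom recovery study
#'
#' The package's desk-scale validation experiment: simulate a phantom
#' cohort, train the slice-wise U-Net on the training portion with an
#' inner subject-level split, skull-strip the held-out phantoms through
#' the full native-resolution pipeline, and score them with the
#' five-metric evaluation suite. Everything is a deterministic function
#' of `seed`.
#'
#' The default problem size (24 subjects, 4 held out, ~190 training
#' slices, 18 epochs, a 8-16-24-32-48 feature schedule) is chosen so the
#' study trains a meaningful model on one CPU in a few minutes; learning
#' rate, batch size, gradient clipping, patch size and inference stride
#' keep their standard defaults.
#'
#' @param seed Integer seed driving phantom generation, the subject
#'   split, weight initialization and patch sampling.
#' @param n_subjects Cohort size (alternating anatomical / EPI presets).
#' @param n_test Number of subjects held out for final testing.
#' @param epochs Training epochs.
#' @param encoder_features Feature schedule of the contracting path.
#' @param split_fraction Inner train/validation fraction.
#' @return List with `metrics` (tibble, one row per held-out subject),
#'   `history` (per-epoch training loss and validation Dice), `model`
#'   (the trained `seg_model`) and `test_ids`.
#' @export
phantom_recovery_study <- function(seed = 1L, n_subjects = 24L,
                                   n_test = 4L, epochs = 18L,
                                   encoder_features = c(8L, 16L, 24L,
                                                        32L, 48L),
                                   split_fraction = 0.8) {
  seed <- as.integer(seed)
  ds <- generate_dataset(n_subjects, seed = seed)
  ids <- ds$manifest$subject_id
  test_ids <- utils::tail(ids, n_test)
  pool_ids <- setdiff(ids, test_ids)
  pool_idx <- match(pool_ids, ids)

  prepped <- lapply(ds$subjects[pool_idx], function(p)
    prepare_subject(p$volume, p$mask))
  names(prepped) <- pool_ids
  split <- split_subjects(pool_ids, split_fraction, seed = seed + 1L)
  train_set <- training_slices(prepped[split$train_ids], split$train_ids)

  ucfg <- unet_config(encoder_features = encoder_features,
                      base_seed = seed + 2L)
  tcfg <- train_config(epochs = as.integer(epochs), seed = seed + 3L)
  model <- train_model(build_unet(ucfg), train_set,
                       prepped[split$val_ids], tcfg)

  rows <- lapply(test_ids, function(id) {
    sub <- ds$subjects[[match(id, ids)]]
    res <- strip_skull(model, sub$volume)
    rep <- suppressMessages(evaluate_pair(sub$mask, res$mask))
    df <- as.data.frame(rep)
    df$subject_id <- id
    df
  })
  metrics <- tibble::as_tibble(do.call(rbind, rows))
  metrics <- metrics[, c("subject_id",
                         setdiff(names(metrics), "subject_id"))]
  list(metrics = metrics, history = model$history, model = model,
       test_ids = test_ids)
}
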
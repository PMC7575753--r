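test_that("overlap metrics match the worked example and limits", {
  # |A| = 6, |B| = 4, overlap 3
  a <- array(0, c(1, 4, 4)); a[1, 1, 1:4] <- 1; a[1, 2, 1:2] <- 1
  b <- array(0, c(1, 4, 4)); b[1, 1, 1:3] <- 1; b[1, 3, 4] <- 1
  ov <- overlap_metrics(a, b)
  expect_equal(ov$dice, 0.6, tolerance = 1e-12)
  expect_equal(ov$jaccard, 3 / 7, tolerance = 1e-12)
  expect_equal(ov$ppv, 0.75, tolerance = 1e-12)
  expect_equal(ov$sen, 0.5, tolerance = 1e-12)

  # identity: all ones
  m <- random_mask_array(c(2, 8, 8), p = 0.4, seed = 21)
  idd <- overlap_metrics(m, m)
  expect_equal(unlist(idd[c("dice", "jaccard", "ppv", "sen")]),
               c(dice = 1, jaccard = 1, ppv = 1, sen = 1))

  # disjoint: all zeros
  d1 <- array(0, c(1, 4, 4)); d1[1, 1, 1] <- 1
  d2 <- array(0, c(1, 4, 4)); d2[1, 4, 4] <- 1
  dj <- overlap_metrics(d1, d2)
  expect_equal(unlist(dj[c("dice", "jaccard", "ppv", "sen")]),
               c(dice = 0, jaccard = 0, ppv = 0, sen = 0))

  expect_error(overlap_metrics(array(0, c(1, 4, 4)), d2),
               class = "rodentstrip_format_error")
  expect_error(overlap_metrics(d1, array(0, c(1, 5, 5))),
               class = "rodentstrip_dim_error")
  expect_warning(e <- overlap_metrics(d1, array(0, c(1, 4, 4))), "PPV")
  expect_equal(e$ppv, 0)
})

test_that("directed Hausdorff matches hand-computed cases", {
  p <- cbind(c(0, 10), c(0, 0))
  q <- cbind(0, 0)
  expect_equal(directed_hausdorff_2d(p, p), 0)
  expect_equal(directed_hausdorff_2d(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(directed_hausdorff_2d(p, q), 10)
  expect_equal(directed_hausdorff_2d(q, p), 0)
  expect_error(directed_hausdorff_2d(p[0, , drop = FALSE], q),
               class = "rodentstrip_format_error")
})

test_that("subject Hausdorff aggregates the worst slice", {
  a <- array(0, c(3, 8, 8)); b <- array(0, c(3, 8, 8))
  a[1, 4, 4] <- 1; b[1, 4, 4] <- 1                 # slice value 0
  a[2, 2, 2] <- 1; b[2, 2, 4] <- 1                 # slice value 2
  a[3, 1, 1] <- 1; b[3, 4, 5] <- 1                 # slice value 5
  h <- hausdorff_subject(a, b)
  expect_equal(h$per_slice, c(0, 2, 5))
  expect_equal(h$hausdorff, 5)
  expect_identical(hausdorff_subject(a, a)$hausdorff, 0)
  # slice with exactly one empty mask is skipped and counted
  b2 <- b; b2[2, , ] <- 0
  expect_message(h2 <- hausdorff_subject(a, b2), "skipped 1")
  expect_equal(h2$n_skipped_slices, 1L)
  expect_equal(h2$hausdorff, 5)
  expect_error(hausdorff_subject(array(1, c(1, 2, 2)),
                                 array(0, c(1, 2, 2))),
               class = "rodentstrip_format_error")
})

test_that("Hausdorff equals the exhaustive all-pairs oracle on random masks", {
  for (s in 1:100) {
    a <- random_mask_array(c(2, 16, 16), p = 0.25, seed = s)
    b <- random_mask_array(c(2, 16, 16), p = 0.25, seed = 1000 + s)
    oracle <- hausdorff_oracle(a, b)
    if (is.na(oracle)) next
    skip_empty <- any(vapply(1:2, function(sl)
      xor(any(a[sl, , ] > 0), any(b[sl, , ] > 0)), logical(1)))
    h_boundary <- suppressMessages(hausdorff_subject(a, b))
    h_full <- suppressMessages(
      hausdorff_subject(a, b, boundary_only = FALSE))
    expect_identical(h_boundary$hausdorff, oracle)
    expect_identical(h_full$hausdorff, oracle)
  }
})

test_that("evaluate_pair satisfies the algebraic identities", {
  set.seed(77)
  for (s in 1:10) {
    a <- random_mask_array(c(3, 12, 12), p = 0.35, seed = 300 + s)
    b <- random_mask_array(c(3, 12, 12), p = 0.35, seed = 400 + s)
    if (sum(a) == 0 || sum(b) == 0) next
    rep <- suppressMessages(evaluate_pair(a, b))
    # dice = 2J / (1 + J)
    expect_equal(rep$dice, 2 * rep$jaccard / (1 + rep$jaccard),
                 tolerance = 1e-12)
    # count consistency: ppv * |B| = sen * |A| = |A n B|
    expect_equal(rep$ppv * rep$n_pred_voxels, rep$n_overlap,
                 tolerance = 1e-12)
    expect_equal(rep$sen * rep$n_ref_voxels, rep$n_overlap,
                 tolerance = 1e-12)
    # symmetry of dice/jaccard, ppv(a,b) = sen(b,a)
    rev <- suppressMessages(evaluate_pair(b, a))
    expect_equal(rep$dice, rev$dice, tolerance = 1e-12)
    expect_equal(rep$jaccard, rev$jaccard, tolerance = 1e-12)
    expect_equal(rep$ppv, rev$sen, tolerance = 1e-12)
  }
  idp <- evaluate_pair(random_mask_array(c(2, 8, 8), p = 0.5, seed = 6),
                       random_mask_array(c(2, 8, 8), p = 0.5, seed = 6))
  expect_equal(c(idp$dice, idp$jaccard, idp$ppv, idp$sen,
                 idp$hausdorff_voxels), c(1, 1, 1, 1, 0))
  df <- as.data.frame(idp)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("dice", "hausdorff_voxels", "n_overlap") %in% names(df)))
})

test_that("dilating the prediction never lowers SEN, eroding never lowers PPV", {
  for (s in 1:3) {
    cfg <- phantom_config(preset = "epi_coarse", seed = 500 + s)
    ref <- generate_phantom(cfg)$mask$data
    # under-prediction: dilating it can only recover reference voxels
    under <- erode_inplane(ref)
    sen_before <- overlap_metrics(ref, under)$sen
    sen_after <- overlap_metrics(ref, dilate_inplane(under))$sen
    expect_gte(sen_after, sen_before)
    expect_lt(sen_before, 1)
    # over-prediction: eroding it strips (mostly false-positive) rind
    over <- dilate_inplane(ref)
    ppv_before <- overlap_metrics(ref, over)$ppv
    ppv_after <- overlap_metrics(ref, erode_inplane(over))$ppv
    expect_gte(ppv_after, ppv_before)
    expect_lt(ppv_before, 1)
  }
})

test_that("batch evaluation produces one tidy row per subject", {
  td <- withr::local_tempdir()
  paths <- list()
  for (i in 1:2) {
    m <- new_brain_mask(random_mask_array(c(2, 8, 8), p = 0.4,
                                          seed = 600 + i),
                        spacing = c(1, 0.1, 0.1))
    rp <- file.path(td, sprintf("ref%d.nii.gz", i))
    pp <- file.path(td, sprintf("pred%d.nii.gz", i))
    save_volume(m, rp); save_volume(m, pp)
    paths[[i]] <- c(rp, pp)
  }
  man <- data.frame(subject_id = c("s1", "s2"),
                    ref_path = vapply(paths, `[`, "", 1),
                    pred_path = vapply(paths, `[`, "", 2))
  out <- evaluate_batch(man)
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 2L)
  expect_true(all(out$dice == 1))
})
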
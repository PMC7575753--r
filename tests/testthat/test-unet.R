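test_that("configuration invariants are enforced", {
  cfg <- unet_config()
  expect_equal(cfg$encoder_features, c(32L, 64L, 96L, 128L, 256L))
  expect_equal(cfg$levels, 5L)
  expect_error(unet_config(input_size = 100L),
               class = "rodentstrip_config_error")
  expect_error(unet_config(encoder_features = c(32L, 32L, 64L)),
               class = "rodentstrip_config_error")
  expect_error(unet_config(batch_norm = TRUE),
               class = "rodentstrip_config_error")
})

test_that("the network maps patches to same-shape probability maps", {
  cfg <- tiny_unet_cfg()
  m <- build_unet(cfg)
  set.seed(1)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p <- predict(m, x)
  expect_equal(dim(p), c(16L, 16L, 3L))
  expect_true(all(p >= 0 & p <= 1))
  # single 2D patch in, matrix out
  p1 <- predict(m, x[, , 1])
  expect_true(is.matrix(p1))
  expect_equal(p1, p[, , 1], tolerance = 1e-12)
  # spatial shape preserved for another valid input size
  x2 <- array(runif(32 * 32), c(32, 32))
  expect_equal(dim(predict(m, x2)), c(32L, 32L))
  expect_error(predict(m, array(runif(15 * 15), c(15, 15))),
               class = "rodentstrip_config_error")
})

test_that("weight initialization is deterministic and follows the schedule", {
  a <- build_unet(tiny_unet_cfg(seed = 99))
  b <- build_unet(tiny_unet_cfg(seed = 99))
  expect_identical(a$params, b$params)
  c2 <- build_unet(tiny_unet_cfg(seed = 100))
  expect_false(identical(a$params, c2$params))
  # the k-th encoder block's feature count matches the config
  cfg <- unet_config(input_size = 32L,
                     encoder_features = c(4L, 6L, 9L))
  m <- build_unet(cfg)
  for (k in 1:3) {
    expect_equal(dim(m$params[[sprintf("enc%d_w1", k)]])[4],
                 cfg$encoder_features[k])
    expect_equal(dim(m$params[[sprintf("enc%d_w2", k)]])[3],
                 cfg$encoder_features[k])
  }
  # decoder mirrors the encoder
  expect_equal(dim(m$params$dec2_wu)[4], 6L)
  expect_equal(dim(m$params$dec1_wu)[4], 4L)
})

test_that("dice loss matches closed forms and stays in [0, 1]", {
  t <- random_mask_array(c(8, 8), p = 0.4, seed = 2)
  expect_lt(dice_loss(t, t), 1e-3)
  # all-0.5 prediction against all-ones target: soft dice 2/3, loss 1/3
  n <- 64 * 64
  p <- matrix(0.5, 64, 64); o <- matrix(1, 64, 64)
  expect_equal(dice_loss(p, o, eps = 0), 1 / 3, tolerance = 1e-12)
  expect_equal(dice_loss(p, o), 1 - (n + 1) / (1.5 * n + 1),
               tolerance = 1e-12)
  # empty vs empty: the smoothing term makes the loss exactly 0
  z <- matrix(0, 8, 8)
  expect_equal(dice_loss(z, z), 0)
  expect_error(dice_loss(matrix(0, 4, 4), matrix(0, 5, 5)),
               class = "rodentstrip_dim_error")
  # range and binary symmetry
  for (s in 1:5) {
    a <- random_mask_array(c(6, 6), p = 0.5, seed = s)
    b <- random_mask_array(c(6, 6), p = 0.5, seed = s + 50)
    l1 <- dice_loss(a, b); l2 <- dice_loss(b, a)
    expect_true(l1 >= 0 && l1 <= 1)
    expect_equal(l1, l2, tolerance = 1e-12)
  }
})

test_that("dice loss decreases monotonically with growing overlap", {
  # 4x4 maps, |target| = 4, |pred| = 4; enumerate overlaps 0..4 by brute
  # force over predictions and verify loss is decreasing in the overlap
  target <- matrix(0, 4, 4); target[1:2, 1:2] <- 1
  losses <- sapply(0:4, function(k) {
    pred <- matrix(0, 4, 4)
    if (k > 0) pred[which(target == 1)[seq_len(k)]] <- 1
    extra <- setdiff(which(target == 0), integer(0))[seq_len(4 - k)]
    pred[extra] <- 1
    dice_loss(pred, target)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("analytic gradients match directional finite differences", {
  cfg <- tiny_unet_cfg()
  m <- build_unet(cfg)
  params <- m$params
  # nudge biases off zero so no ReLU pre-activation sits exactly on the
  # kink (where two-sided differences measure half the one-sided slope)
  set.seed(9)
  for (nm in grep("_b", names(params), value = TRUE)) {
    if (nm != "out_b") params[[nm]] <- rnorm(length(params[[nm]]), sd = 0.05)
  }
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 1, 2))
  lg <- rodentstrip:::unet_loss_grad(params, cfg, x, y)
  expect_true(is.finite(lg$loss))
  dirs <- lapply(params, function(p) {
    d <- rnorm(length(p)); dim(d) <- dim(p); d
  })
  dot <- sum(mapply(function(g, d) sum(g * d),
                    lg$grads, dirs[names(lg$grads)]))
  eps <- 1e-3
  pp <- mapply(function(p, d) p + eps * d, params, dirs, SIMPLIFY = FALSE)
  pm <- mapply(function(p, d) p - eps * d, params, dirs, SIMPLIFY = FALSE)
  fp <- dice_loss(rodentstrip:::unet_forward_full(pp, cfg, x)$pred, y)
  fm <- dice_loss(rodentstrip:::unet_forward_full(pm, cfg, x)$pred, y)
  fd <- (fp - fm) / (2 * eps)
  expect_equal(dot, fd, tolerance = 2e-2)
})

test_that("gradient clipping caps the global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 5))
  cl <- rodentstrip:::clip_grads(g, 1)
  expect_equal(cl$norm, sqrt(sum(9 * 4) + sum(16 * 5)))
  nrm_after <- sqrt(sum(unlist(cl$grads)^2))
  expect_equal(nrm_after, 1, tolerance = 1e-12)
  # already small gradients are untouched
  g2 <- list(a = matrix(1e-3, 2, 2))
  expect_identical(rodentstrip:::clip_grads(g2, 1)$grads, g2)
})

test_that("checkpoints round-trip with a plain-text config sidecar", {
  td <- withr::local_tempdir()
  m <- build_unet(tiny_unet_cfg())
  f <- file.path(td, "model.rds")
  save_unet(m, f)
  expect_true(file.exists(paste0(f, ".cfg")))
  cfg_lines <- readLines(paste0(f, ".cfg"))
  expect_true(any(grepl("encoder_features = 2,3,5", cfg_lines)))
  m2 <- load_unet(f)
  expect_identical(m2$params, m$params)
  set.seed(4)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(predict(m, x), predict(m2, x))
})
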
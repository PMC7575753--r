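#' U-Net architecture configuration
#'
#' Describes the slice-wise segmentation network: a contracting path of
#' convolutional blocks whose feature counts default to 32, 64, 96, 128 and
#' 256, a mirrored expanding path with copy skip connections, and a
#' single-channel sigmoid output. Each block is two 3x3 "same" convolutions
#' with ReLU; levels are joined by 2x2 max pooling on the way down and
#' nearest-neighbor 2x upsampling (followed by a 3x3 convolution) on the
#' way up.
#'
#' @param input_size Side length in pixels of the square input patch
#'   (default 128). Must be divisible by `2^(levels - 1)`.
#' @param encoder_features Strictly increasing feature-map counts of the
#'   contracting blocks; the decoder mirrors them.
#' @param base_seed Integer seed for deterministic weight initialization.
#' @param batch_norm Must be `FALSE`; plain convolution + ReLU blocks are
#'   the only supported variant.
#' @return A `unet_config` list.
#' @export
unet_config <- function(input_size = 128L,
                        encoder_features = c(32L, 64L, 96L, 128L, 256L),
                        base_seed = 42L,
                        batch_norm = FALSE) {
  encoder_features <- as.integer(encoder_features)
  levels <- length(encoder_features)
  if (levels < 2L || any(diff(encoder_features) <= 0))
    stop2("encoder_features must be strictly increasing with >= 2 levels",
          "rodentstrip_config_error")
  input_size <- as.integer(input_size)
  if (input_size %% 2L^(levels - 1L) != 0L)
    stop2(sprintf("input_size %d is not divisible by 2^%d = %d",
                  input_size, levels - 1L, 2L^(levels - 1L)),
          "rodentstrip_config_error")
  if (isTRUE(batch_norm))
    stop2("batch_norm = TRUE is not supported", "rodentstrip_config_error")
  structure(list(input_size = input_size,
                 encoder_features = encoder_features,
                 levels = levels,
                 base_seed = as.integer(base_seed),
                 batch_norm = FALSE),
            class = "unet_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

he_weight <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Build a randomly initialized U-Net segmentation model
#'
#' Weights are He-normal, drawn deterministically from
#' `cfg$base_seed`: two builds from the same configuration are identical
#' parameter for parameter.
#'
#' @param cfg A [unet_config()].
#' @return A `seg_model` holding the parameter list, the configuration and
#'   an (initially empty) training history.
#' @export
build_unet <- function(cfg = unet_config()) {
  stopifnot(inherits(cfg, "unet_config"))
  f <- cfg$encoder_features
  L <- cfg$levels
  params <- list()
  with_seed(cfg$base_seed, {
    cin <- 1L
    for (k in seq_len(L)) {
      params[[sprintf("enc%d_w1", k)]] <- he_weight(3L, cin, f[k])
      params[[sprintf("enc%d_b1", k)]] <- numeric(f[k])
      params[[sprintf("enc%d_w2", k)]] <- he_weight(3L, f[k], f[k])
      params[[sprintf("enc%d_b2", k)]] <- numeric(f[k])
      cin <- f[k]
    }
    above <- f[L]
    for (k in rev(seq_len(L - 1L))) {
      dk <- f[k]                      # decoder mirrors the encoder
      params[[sprintf("dec%d_wu", k)]] <- he_weight(3L, above, dk)
      params[[sprintf("dec%d_bu", k)]] <- numeric(dk)
      params[[sprintf("dec%d_w1", k)]] <- he_weight(3L, dk + f[k], dk)
      params[[sprintf("dec%d_b1", k)]] <- numeric(dk)
      params[[sprintf("dec%d_w2", k)]] <- he_weight(3L, dk, dk)
      params[[sprintf("dec%d_b2", k)]] <- numeric(dk)
      above <- dk
    }
    params[["out_w"]] <- matrix(rnorm(f[1L], sd = sqrt(2 / f[1L])),
                                ncol = 1L)
    params[["out_b"]] <- 0
  })
  structure(list(params = params, config = cfg, history = NULL),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  n <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<seg_model> U-Net, %d levels, features [%s], %s parameters%s\n",
              x$config$levels,
              paste(x$config$encoder_features, collapse = ", "),
              format(n, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    x <- array(x, dim = c(dim(as.matrix(x)), 1L, 1L))
  } else if (length(d) == 3L) {
    dim(x) <- c(d[1L], d[2L], 1L, d[3L])    # stack of single-channel maps
  } else if (length(d) != 4L) {
    stop2("input must be 2D, 3D or 4D", "rodentstrip_dim_error")
  }
  x
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

conv1x1_forward <- function(a, w, b) {
  d <- dim(a)
  z <- array(0, dim = c(d[1L], d[2L], 1L, d[4L]))
  hw <- d[1L] * d[2L]
  for (n in seq_len(d[4L])) {
    am <- matrix(a[, , , n], nrow = hw, ncol = d[3L])
    z[, , 1L, n] <- matrix(am %*% w + b, nrow = d[1L])
  }
  z
}

# Forward pass; when cache = TRUE every activation needed by the backward
# pass is retained.
unet_forward_full <- function(params, cfg, x, cache = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  if (d[1L] %% 2L^(cfg$levels - 1L) != 0L ||
      d[2L] %% 2L^(cfg$levels - 1L) != 0L)
    stop2("input spatial dims must be divisible by 2^(levels-1)",
          "rodentstrip_config_error")
  L <- cfg$levels
  cc <- if (cache) list(x = x) else NULL
  a <- x
  skips <- vector("list", L - 1L)
  for (k in seq_len(L)) {
    in1 <- a
    a <- .conv3x3_forward(in1, params[[sprintf("enc%d_w1", k)]],
                          params[[sprintf("enc%d_b1", k)]], TRUE)
    in2 <- a
    a <- .conv3x3_forward(in2, params[[sprintf("enc%d_w2", k)]],
                          params[[sprintf("enc%d_b2", k)]], TRUE)
    if (cache) { cc[[sprintf("enc%d_in1", k)]] <- in1
                 cc[[sprintf("enc%d_in2", k)]] <- in2
                 cc[[sprintf("enc%d_out", k)]] <- a }
    if (k < L) {
      skips[[k]] <- a
      mp <- .maxpool2_forward(a)
      if (cache) cc[[sprintf("pool%d_idx", k)]] <- mp$idx
      a <- mp$y
    }
  }
  for (k in rev(seq_len(L - 1L))) {
    a <- .upsample2_forward(a)
    upc_in <- a
    a <- .conv3x3_forward(upc_in, params[[sprintf("dec%d_wu", k)]],
                          params[[sprintf("dec%d_bu", k)]], TRUE)
    cat_a <- a
    a <- concat_channels(a, skips[[k]])
    in1 <- a
    a <- .conv3x3_forward(in1, params[[sprintf("dec%d_w1", k)]],
                          params[[sprintf("dec%d_b1", k)]], TRUE)
    in2 <- a
    a <- .conv3x3_forward(in2, params[[sprintf("dec%d_w2", k)]],
                          params[[sprintf("dec%d_b2", k)]], TRUE)
    if (cache) { cc[[sprintf("dec%d_upc_in", k)]] <- upc_in
                 cc[[sprintf("dec%d_cat_a", k)]] <- cat_a
                 cc[[sprintf("dec%d_in1", k)]] <- in1
                 cc[[sprintf("dec%d_in2", k)]] <- in2
                 cc[[sprintf("dec%d_out", k)]] <- a }
  }
  final_in <- a
  z <- conv1x1_forward(a, params$out_w, params$out_b)
  p <- 1 / (1 + exp(-z))
  if (cache) { cc$final_in <- final_in; cc$pred <- p }
  list(pred = p, cache = cc)
}

#' Run the network on normalized image patches
#'
#' @param object A `seg_model`.
#' @param newdata A 2D matrix (one patch), a 3D `(H, W, N)` stack, or a 4D
#'   `(H, W, 1, N)` tensor of intensity-normalized patches whose spatial
#'   dims are divisible by `2^(levels - 1)`.
#' @param ... Unused.
#' @return Probability maps in `[0, 1]` with the same spatial shape;
#'   `(H, W, N)` array (or a matrix when a single 2D patch was supplied).
#' @export
predict.seg_model <- function(object, newdata, ...) {
  was_2d <- is.null(dim(newdata)) || length(dim(newdata)) == 2L
  p <- unet_forward_full(object$params, object$config, newdata)$pred
  d <- dim(p)
  if (was_2d) matrix(p, nrow = d[1L]) else array(p, dim = d[c(1L, 2L, 4L)])
}

#' Dice-coefficient loss
#'
#' The soft Dice loss `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`
#' computed per patch and averaged over the batch. The smoothing term `eps`
#' keeps the loss defined (and zero) when both prediction and target are
#' empty, which protects training on background-only patches.
#'
#' @param pred Probability map(s) in `[0, 1]`; 2D, 3D `(H, W, N)` or 4D.
#' @param target Binary map(s) of the same shape.
#' @param eps Smoothing constant on the summed-counts scale (default 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1) {
  if (!identical(dim(as_batch(pred)), dim(as_batch(target))))
    stop2("pred and target shapes differ", "rodentstrip_dim_error")
  p <- as_batch(pred); t <- as_batch(target)
  n <- dim(p)[4L]
  per <- vapply(seq_len(n), function(i) {
    pi <- p[, , , i]; ti <- t[, , , i]
    1 - (2 * sum(pi * ti) + eps) / (sum(pi) + sum(ti) + eps)
  }, numeric(1))
  mean(per)
}

# Loss + full gradient for one batch. Returns loss, prediction and the
# gradient list (same names/shapes as params).
unet_loss_grad <- function(params, cfg, x, y, eps = 1) {
  x <- as_batch(x); y <- as_batch(y)
  fw <- unet_forward_full(params, cfg, x, cache = TRUE)
  p <- fw$pred; cc <- fw$cache
  d <- dim(p); N <- d[4L]; L <- cfg$levels
  grads <- list()

  # Dice loss and its gradient w.r.t. the logit z (through the sigmoid).
  dz <- array(0, dim = d)
  loss <- 0
  for (n in seq_len(N)) {
    pn <- p[, , 1L, n]; tn <- y[, , 1L, n]
    s_pt <- sum(pn * tn); s_p <- sum(pn); s_t <- sum(tn)
    denom <- s_p + s_t + eps
    loss <- loss + 1 - (2 * s_pt + eps) / denom
    dLdp <- -(2 * tn * denom - (2 * s_pt + eps)) / denom^2
    dz[, , 1L, n] <- (dLdp / N) * pn * (1 - pn)
  }
  loss <- loss / N

  # Output 1x1 convolution.
  a <- cc$final_in; da <- dim(a); hw <- da[1L] * da[2L]
  dW_out <- matrix(0, nrow = da[3L], ncol = 1L)
  db_out <- 0
  dA <- array(0, dim = da)
  for (n in seq_len(N)) {
    am <- matrix(a[, , , n], nrow = hw, ncol = da[3L])
    dzn <- as.numeric(dz[, , 1L, n])
    dW_out <- dW_out + crossprod(am, dzn)
    db_out <- db_out + sum(dzn)
    dA[, , , n] <- array(tcrossprod(dzn, params$out_w),
                         dim = c(da[1L], da[2L], da[3L]))
  }
  grads$out_w <- dW_out; grads$out_b <- db_out

  # Each conv backward receives its own ReLU output so the ReLU gradient
  # mask is applied inside the kernel.
  d_skip <- vector("list", L - 1L)
  for (k in seq_len(L - 1L)) {
    bw <- .conv3x3_backward(cc[[sprintf("dec%d_in2", k)]],
                            params[[sprintf("dec%d_w2", k)]], dA,
                            cc[[sprintf("dec%d_out", k)]])
    grads[[sprintf("dec%d_w2", k)]] <- bw$dw
    grads[[sprintf("dec%d_b2", k)]] <- bw$db
    bw <- .conv3x3_backward(cc[[sprintf("dec%d_in1", k)]],
                            params[[sprintf("dec%d_w1", k)]], bw$dx,
                            cc[[sprintf("dec%d_in2", k)]])
    grads[[sprintf("dec%d_w1", k)]] <- bw$dw
    grads[[sprintf("dec%d_b1", k)]] <- bw$db
    dcat <- bw$dx
    nc_up <- dim(cc[[sprintf("dec%d_cat_a", k)]])[3L]
    d_up <- dcat[, , seq_len(nc_up), , drop = FALSE]
    d_skip[[k]] <- dcat[, , (nc_up + 1L):dim(dcat)[3L], , drop = FALSE]
    bw <- .conv3x3_backward(cc[[sprintf("dec%d_upc_in", k)]],
                            params[[sprintf("dec%d_wu", k)]], d_up,
                            cc[[sprintf("dec%d_cat_a", k)]])
    grads[[sprintf("dec%d_wu", k)]] <- bw$dw
    grads[[sprintf("dec%d_bu", k)]] <- bw$db
    dA <- .upsample2_backward(bw$dx)
  }

  for (k in rev(seq_len(L))) {
    if (k < L) {
      dA <- .maxpool2_backward(dA, cc[[sprintf("pool%d_idx", k)]])
      dA <- dA + d_skip[[k]]
    }
    bw <- .conv3x3_backward(cc[[sprintf("enc%d_in2", k)]],
                            params[[sprintf("enc%d_w2", k)]], dA,
                            cc[[sprintf("enc%d_out", k)]])
    grads[[sprintf("enc%d_w2", k)]] <- bw$dw
    grads[[sprintf("enc%d_b2", k)]] <- bw$db
    bw <- .conv3x3_backward(cc[[sprintf("enc%d_in1", k)]],
                            params[[sprintf("enc%d_w1", k)]], bw$dx,
                            cc[[sprintf("enc%d_in2", k)]])  # = conv1 ReLU out
    grads[[sprintf("enc%d_w1", k)]] <- bw$dw
    grads[[sprintf("enc%d_b1", k)]] <- bw$db
    dA <- bw$dx
  }

  list(loss = loss, grads = grads[names(params)], pred = p)
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

clip_grads <- function(grads, max_norm) {
  nrm <- global_grad_norm(grads)
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  list(grads = grads, norm = nrm)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
  }
  list(params = params, state = state)
}

#' Save / load a segmentation model
#'
#' The model (parameters, configuration, training history) is serialized
#' with R's native format; the architecture configuration is additionally
#' written next to it as a plain-text `key = value` file so a checkpoint is
#' self-describing without R.
#'
#' @param model A `seg_model`.
#' @param path Checkpoint path (conventionally `.rds`); the config text
#'   file is written at `paste0(path, ".cfg")`.
#' @return `save_unet()` returns `path` invisibly; `load_unet()` the model.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  cfg <- model$config
  lines <- c(sprintf("input_size = %d", cfg$input_size),
             sprintf("encoder_features = %s",
                     paste(cfg$encoder_features, collapse = ",")),
             sprintf("levels = %d", cfg$levels),
             sprintf("base_seed = %d", cfg$base_seed))
  writeLines(lines, paste0(path, ".cfg"))
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  if (!file.exists(path))
    stop2(sprintf("checkpoint not found: %s", path), "rodentstrip_io_error")
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}
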
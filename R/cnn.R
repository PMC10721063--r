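#' Backbone registry
#'
#' The feature-extraction stage is backbone-agnostic: any image classifier
#' whose final fully connected layer is replaced to match the class count can
#' supply per-image features. The bundled, fully implemented backbone is
#' `reference-small`, a compact 3-conv-block network (8/16/32 channels, 3x3
#' kernels, 2x2 max pooling after each block, flattened into a linear head)
#' that trains on a CPU in seconds. The final pooled map is flattened rather
#' than globally averaged: bispectrum images encode their information in
#' *where* magnitude concentrates on the frequency plane, and a spatially
#' invariant pooling would discard exactly that.
#' The five large ImageNet architectures are registered
#' as optional plug-ins: their pretrained weights are not bundled and
#' constructing them signals an error.
#'
#' @return Tibble with columns `name`, `input_size`, `available`.
#' @export
backbone_registry <- function() {
  tibble(
    name = c("reference-small", "squeezenet", "shufflenet", "resnet101",
             "darknet19", "nasnet-mobile"),
    input_size = c(32L, 227L, 224L, 224L, 256L, 224L),
    available = c(TRUE, rep(FALSE, 5))
  )
}

#' Training configuration for a classification head
#'
#' Defaults mirror the transfer-learning recipe used throughout the package:
#' RMSProp, mini-batch 128, 20 epochs, learning rate 0.01. The squared
#' gradient decay (0.9) and epsilon (1e-8) are the optimizer's conventional
#' defaults.
#'
#' @param optimizer Only `"rmsprop"` is implemented.
#' @param batch_size Mini-batch size (default 128).
#' @param epochs Number of epochs (default 20).
#' @param learning_rate Step size (default 0.01).
#' @param seed Integer seed controlling shuffling (default 1).
#' @param decay,epsilon RMSProp squared-gradient decay and stabilizer.
#' @param weight_decay L2 penalty on weight matrices (not biases), default 0.
#' @param mixup_alpha Beta-distribution parameter for mixup augmentation
#'   (convex combinations of image pairs and their soft labels); 0 (default)
#'   disables it.
#' @param augment_noise Standard deviation of seeded Gaussian pixel jitter
#'   added to each training batch; 0 (default) disables it.
#' @param head_decay Additional L2 penalty applied to the final fully
#'   connected layer's weights only (default 0).
#' @param swa_start Fraction of epochs after which parameters are averaged
#'   into a running mean that becomes the final model (stochastic weight
#'   averaging); 1 (default) disables averaging.
#' @param lr_drop,lr_drop_at Step learning-rate schedule: multiply the rate
#'   by `lr_drop` once `lr_drop_at` of the epochs are done (defaults 1 and 1
#'   disable the drop).
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "rmsprop", batch_size = 128L,
                         epochs = 20L, learning_rate = 0.01, seed = 1L,
                         decay = 0.9, epsilon = 1e-8, weight_decay = 0,
                         mixup_alpha = 0, augment_noise = 0, head_decay = 0,
                         swa_start = 1, lr_drop = 1, lr_drop_at = 1) {
  stopifnot(identical(optimizer, "rmsprop"), epochs >= 0, weight_decay >= 0,
            mixup_alpha >= 0, augment_noise >= 0, head_decay >= 0,
            swa_start >= 0, swa_start <= 1)
  structure(list(optimizer = optimizer, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), decay = decay, epsilon = epsilon,
                 weight_decay = weight_decay, mixup_alpha = mixup_alpha,
                 augment_noise = augment_noise, head_decay = head_decay,
                 swa_start = swa_start, lr_drop = lr_drop,
                 lr_drop_at = lr_drop_at),
            class = "train_config")
}

#' Construct a backbone model
#'
#' @param name Backbone name from [backbone_registry()].
#' @param n_classes Output width of the classification head (>= 2).
#' @param input_size Square input edge in pixels (reference-small default 32;
#'   must be divisible by 8).
#' @param seed Integer seed for weight initialization.
#' @return A `ref_cnn` model object.
#' @export
build_backbone <- function(name = "reference-small", n_classes,
                           input_size = 32L, seed = 1L,
                           channels = c(8L, 16L, 32L)) {
  reg <- backbone_registry()
  if (!name %in% reg$name) abort(paste0("unknown backbone: ", name))
  if (!reg$available[match(name, reg$name)]) {
    abort(paste0("backbone `", name, "` is an optional plug-in: its ",
                 "pretrained weights are not bundled with this package. ",
                 "Use `reference-small`."))
  }
  if (n_classes < 2) abort("`n_classes` must be at least 2")
  if (input_size %% 8 != 0) abort("`input_size` must be divisible by 8")
  stopifnot(length(channels) == 3L)
  channels <- as.integer(channels)
  params <- with_seed(derive_seed(seed, 11L), {
    init_conv <- function(k, cin) {
      fan <- 9L * cin
      list(W = matrix(rnorm(k * fan, sd = sqrt(2 / fan)), k, fan),
           b = numeric(k))
    }
    p <- list(conv1 = init_conv(channels[1], 3L),
              conv2 = init_conv(channels[2], channels[1]),
              conv3 = init_conv(channels[3], channels[2]))
    n_flat <- channels[3] * (input_size / 8L)^2
    p$fc <- list(W = matrix(rnorm(n_classes * n_flat,
                                  sd = sqrt(2 / n_flat)),
                            n_classes, n_flat),
                 b = numeric(n_classes))
    p
  })
  structure(list(backbone = name, input_size = as.integer(input_size),
                 channels = channels, n_classes = as.integer(n_classes),
                 params = params, class_order = NULL, trained = FALSE,
                 seed = as.integer(seed)),
            class = "ref_cnn")
}

#' Replace the classification head of a model
#'
#' Re-initializes only the final fully connected layer to output `n_classes`
#' scores; all other layers keep their current parameter values.
#'
#' @param model A `ref_cnn`.
#' @param n_classes New output width (>= 2).
#' @param seed Seed for the new head's initialization.
#' @return The model with a fresh head.
#' @export
replace_head <- function(model, n_classes, seed = model$seed) {
  if (n_classes < 2) abort("`n_classes` must be at least 2")
  n_flat <- ncol(model$params$fc$W)
  model$params$fc <- with_seed(derive_seed(seed, 13L), {
    list(W = matrix(rnorm(n_classes * n_flat, sd = sqrt(2 / n_flat)),
                    n_classes, n_flat),
         b = numeric(n_classes))
  })
  model$n_classes <- as.integer(n_classes)
  model$class_order <- NULL
  model$trained <- FALSE
  model
}

#' @export
print.ref_cnn <- function(x, ...) {
  cat("<ref_cnn>", x$backbone, "| input", x$input_size, "x", x$input_size,
      "x 3 | head width", x$n_classes,
      if (x$trained) "| trained\n" else "| untrained\n")
  invisible(x)
}

# ---- internal numeric kernels -------------------------------------------

# Patch-gather index matrix for 3x3 "same" convolution on an (H+2)x(W+2)xC
# zero-padded input; rows ordered (di, dj, channel), columns scan (i, j)
# column-major like R arrays.
patch_index <- function(H, W, C) {
  Hp <- H + 2L
  grid <- expand.grid(i = seq_len(H), j = seq_len(W))
  off <- expand.grid(di = 0:2, dj = 0:2, c = seq_len(C))
  P <- matrix(0L, nrow(off), nrow(grid))
  plane <- Hp * (W + 2L)
  for (r in seq_len(nrow(off))) {
    P[r, ] <- (grid$i + off$di[r]) + (grid$j + off$dj[r] - 1L) * Hp +
      (off$c[r] - 1L) * plane
  }
  P
}

# x: (H, W, C, N) -> columns (9C, H*W*N)
im2col <- function(x, P) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xpad <- array(0, c(H + 2L, W + 2L, C, N))
  xpad[2:(H + 1L), 2:(W + 1L), , ] <- x
  per <- (H + 2L) * (W + 2L) * C
  idx <- rep.int(as.vector(P), N) +
    rep((seq_len(N) - 1L) * per, each = length(P))
  matrix(xpad[idx], nrow(P), ncol(P) * N)
}

# Scatter-add column gradients back to the (unpadded) input gradient.
col2im <- function(dcols, P, H, W, C, N) {
  per <- (H + 2L) * (W + 2L) * C
  dxpad <- numeric(per * N)
  offs <- rep((seq_len(N) - 1L) * per, each = ncol(P))
  for (r in seq_len(nrow(P))) {
    idx <- rep.int(P[r, ], N) + offs
    dxpad[idx] <- dxpad[idx] + dcols[r, ]
  }
  dim(dxpad) <- c(H + 2L, W + 2L, C, N)
  dxpad[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

maxpool2 <- function(a) {
  d <- dim(a)  # (K, H, W, N)
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  p1 <- a[, io, jo, , drop = FALSE]; p2 <- a[, io + 1L, jo, , drop = FALSE]
  p3 <- a[, io, jo + 1L, , drop = FALSE]; p4 <- a[, io + 1L, jo + 1L, , drop = FALSE]
  out <- pmax(p1, p2, p3, p4)
  m1 <- p1 == out
  m2 <- (p2 == out) & !m1
  m3 <- (p3 == out) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(out = out, masks = list(m1, m2, m3, m4))
}

maxpool2_back <- function(dout, masks, d) {
  da <- array(0, d)
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  da[, io, jo, ] <- dout * masks[[1]]
  da[, io + 1L, jo, ] <- dout * masks[[2]]
  da[, io, jo + 1L, ] <- dout * masks[[3]]
  da[, io + 1L, jo + 1L, ] <- dout * masks[[4]]
  da
}

# Full forward pass; returns logits and, when `keep = TRUE`, the
# intermediates the backward pass needs.
cnn_forward <- function(model, x, keep = FALSE) {
  S <- model$input_size
  K <- model$channels
  N <- dim(x)[4]
  geom <- list(c(S, S, 3L), c(S / 2L, S / 2L, K[1]), c(S / 4L, S / 4L, K[2]))
  P1 <- patch_index(geom[[1]][1], geom[[1]][2], geom[[1]][3])
  P2 <- patch_index(geom[[2]][1], geom[[2]][2], geom[[2]][3])
  P3 <- patch_index(geom[[3]][1], geom[[3]][2], geom[[3]][3])

  conv <- function(x, P, layer) {
    cols <- im2col(x, P)
    z <- layer$W %*% cols + layer$b
    list(cols = cols, z = z)
  }
  to_arr <- function(z, H, W, N) array(z, c(nrow(z), H, W, N))

  c1 <- conv(x, P1, model$params$conv1)
  a1 <- to_arr(pmax(c1$z, 0), S, S, N)
  pl1 <- maxpool2(a1)
  x2 <- aperm(pl1$out, c(2, 3, 1, 4))

  c2 <- conv(x2, P2, model$params$conv2)
  a2 <- to_arr(pmax(c2$z, 0), S / 2L, S / 2L, N)
  pl2 <- maxpool2(a2)
  x3 <- aperm(pl2$out, c(2, 3, 1, 4))

  c3 <- conv(x3, P3, model$params$conv3)
  a3 <- to_arr(pmax(c3$z, 0), S / 4L, S / 4L, N)
  pl3 <- maxpool2(a3)
  # flatten (K3, S/8, S/8, N) -> (K3 * (S/8)^2, N), channel fastest
  n_flat <- K[3] * (S / 8L)^2
  feats <- matrix(pl3$out, n_flat, N)
  logits <- model$params$fc$W %*% feats + model$params$fc$b

  if (!keep) return(list(logits = logits, feats = feats))
  list(logits = logits, feats = feats, x = x, x2 = x2, x3 = x3,
       c1 = c1, c2 = c2, c3 = c3, pl1 = pl1, pl2 = pl2, pl3 = pl3,
       P1 = P1, P2 = P2, P3 = P3, N = N, n_flat = n_flat)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# `target` is a class x N matrix of (possibly soft) label probabilities.
cnn_backward <- function(model, fw, target) {
  S <- model$input_size
  K <- model$channels
  N <- fw$N
  probs <- softmax_cols(fw$logits)
  loss <- -mean(colSums(target * log(pmax(probs, 1e-12))))
  dlogits <- (probs - target) / N

  g <- list()
  g$fc <- list(W = dlogits %*% t(fw$feats), b = rowSums(dlogits))
  dfeats <- t(model$params$fc$W) %*% dlogits            # (n_flat, N)

  dpool3 <- array(dfeats, c(K[3], S / 8L, S / 8L, N))
  da3 <- maxpool2_back(dpool3, fw$pl3$masks, c(K[3], S / 4L, S / 4L, N))
  dz3 <- matrix(da3, K[3], (S / 4L)^2 * N) * (fw$c3$z > 0)
  g$conv3 <- list(W = dz3 %*% t(fw$c3$cols), b = rowSums(dz3))
  dcols3 <- t(model$params$conv3$W) %*% dz3
  dx3 <- col2im(dcols3, fw$P3, S / 4L, S / 4L, K[2], N)

  dpool2 <- aperm(dx3, c(3, 1, 2, 4))
  da2 <- maxpool2_back(dpool2, fw$pl2$masks, c(K[2], S / 2L, S / 2L, N))
  dz2 <- matrix(da2, K[2], (S / 2L)^2 * N) * (fw$c2$z > 0)
  g$conv2 <- list(W = dz2 %*% t(fw$c2$cols), b = rowSums(dz2))
  dcols2 <- t(model$params$conv2$W) %*% dz2
  dx2 <- col2im(dcols2, fw$P2, S / 2L, S / 2L, K[1], N)

  dpool1 <- aperm(dx2, c(3, 1, 2, 4))
  da1 <- maxpool2_back(dpool1, fw$pl1$masks, c(K[1], S, S, N))
  dz1 <- matrix(da1, K[1], S^2 * N) * (fw$c1$z > 0)
  g$conv1 <- list(W = dz1 %*% t(fw$c1$cols), b = rowSums(dz1))

  list(grads = g, loss = loss)
}

# Images are scaled to [0, 1] and centered at 0.5 before entering the net;
# centering keeps the first-layer pre-activations balanced.
images_to_array <- function(images, input_size) {
  if (is.list(images)) {
    N <- length(images)
    x <- array(0, c(input_size, input_size, 3L, N))
    for (n in seq_len(N)) x[, , , n] <- images[[n]]
  } else if (is.array(images) && length(dim(images)) == 4L) {
    x <- images
  } else {
    abort("`images` must be a list of HxWx3 arrays or an (H, W, 3, N) array")
  }
  d <- dim(x)
  if (d[1] != input_size || d[2] != input_size || d[3] != 3L) {
    abort(paste0("image size ", d[1], "x", d[2], "x", d[3],
                 " does not match backbone input ", input_size,
                 "x", input_size, "x3"))
  }
  if (max(x) > 1) x <- x / 255
  x - 0.5
}

#' Train a classification head by RMSProp
#'
#' Trains the whole network (all layers receive gradient; the "transfer"
#' aspect is the replaced head) with mini-batch RMSProp on softmax
#' cross-entropy. Deterministic for a fixed `cfg$seed`: initial shuffling and
#' batching are seeded, and the arithmetic is single-threaded base R.
#'
#' @param model A `ref_cnn`.
#' @param images List of HxWx3 arrays or an `(H, W, 3, N)` array; pixel values
#'   in `[0, 1]` or `[0, 255]`.
#' @param labels Factor (or character) of length N; every model class must be
#'   present.
#' @param cfg A [train_config()].
#' @return The trained model, with a per-epoch `loss_trace` attribute and the
#'   class order recorded. `epochs = 0` returns the model unchanged with an
#'   empty trace.
#' @export
train_head <- function(model, images, labels, cfg = train_config()) {
  y <- factor(labels)
  if (nlevels(y) != model$n_classes) {
    abort(paste0("labels cover ", nlevels(y), " classes but the head has ",
                 model$n_classes, " outputs"))
  }
  if (any(table(y) == 0)) abort("every class must appear in the training labels")
  model$class_order <- levels(y)
  if (cfg$epochs == 0L) {
    attr(model, "loss_trace") <- numeric(0)
    return(model)
  }
  x <- images_to_array(images, model$input_size)
  N <- dim(x)[4]
  if (N != length(y)) abort("images and labels disagree in length")
  y_idx <- as.integer(y)
  onehot <- matrix(0, model$n_classes, N)
  onehot[cbind(y_idx, seq_len(N))] <- 1

  v <- rapply(model$params, function(p) p * 0, how = "replace")
  trace <- numeric(cfg$epochs)
  swa_from <- if (cfg$swa_start >= 1) Inf else max(1L, ceiling(cfg$swa_start * cfg$epochs))
  swa_sum <- NULL
  swa_n <- 0L
  with_seed(derive_seed(cfg$seed, 17L), {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate *
        if (ep > cfg$lr_drop_at * cfg$epochs) cfg$lr_drop else 1
      ord <- sample.int(N)
      batch_starts <- seq(1L, N, by = cfg$batch_size)
      losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        take <- ord[batch_starts[bi]:min(batch_starts[bi] + cfg$batch_size - 1L, N)]
        xb <- x[, , , take, drop = FALSE]
        tb <- onehot[, take, drop = FALSE]
        if (cfg$mixup_alpha > 0 && length(take) > 1) {
          lam <- rbeta(1, cfg$mixup_alpha, cfg$mixup_alpha)
          perm <- sample.int(length(take))
          xb <- lam * xb + (1 - lam) * xb[, , , perm, drop = FALSE]
          tb <- lam * tb + (1 - lam) * tb[, perm, drop = FALSE]
        }
        if (cfg$augment_noise > 0) {
          xb <- xb + rnorm(length(xb), sd = cfg$augment_noise)
        }
        fw <- cnn_forward(model, xb, keep = TRUE)
        bw <- cnn_backward(model, fw, tb)
        losses[bi] <- bw$loss
        for (ly in names(bw$grads)) {
          for (pn in names(bw$grads[[ly]])) {
            gr <- bw$grads[[ly]][[pn]]
            if (pn == "W" && cfg$weight_decay > 0) {
              gr <- gr + cfg$weight_decay * model$params[[ly]][[pn]]
            }
            if (pn == "W" && ly == "fc" && cfg$head_decay > 0) {
              gr <- gr + cfg$head_decay * model$params[[ly]][[pn]]
            }
            v[[ly]][[pn]] <- cfg$decay * v[[ly]][[pn]] + (1 - cfg$decay) * gr^2
            model$params[[ly]][[pn]] <- model$params[[ly]][[pn]] -
              lr * gr / (sqrt(v[[ly]][[pn]]) + cfg$epsilon)
          }
        }
      }
      trace[ep] <- mean(losses)
      if (ep >= swa_from) {
        swa_n <- swa_n + 1L
        swa_sum <- if (is.null(swa_sum)) model$params else {
          mapply(function(acc, cur) mapply(function(a, c) a + c, acc, cur,
                                           SIMPLIFY = FALSE),
                 swa_sum, model$params, SIMPLIFY = FALSE)
        }
      }
    }
  })
  if (swa_n > 0L) {
    model$params <- rapply(swa_sum, function(p) p / swa_n, how = "replace")
  }
  model$trained <- TRUE
  attr(model, "loss_trace") <- trace
  model
}

#' Extract per-image features from the classification head
#'
#' Runs the forward pass and returns the pre-softmax activations of the final
#' fully connected layer, one row per image — a pure function of the model
#' weights and pixels. With a head of width c this yields c features per
#' backbone; concatenating k backbones gives k*c columns.
#'
#' @param model A (typically trained) `ref_cnn`.
#' @param images As in [train_head()].
#' @return Numeric matrix, `N` rows x `n_classes` columns, column names
#'   `<backbone>_f<j>`.
#' @export
extract_features <- function(model, images) {
  x <- images_to_array(images, model$input_size)
  fw <- cnn_forward(model, x, keep = FALSE)
  out <- t(fw$logits)
  colnames(out) <- paste0(gsub("[^a-z0-9]+", "", model$backbone), "_f",
                          seq_len(ncol(out)))
  out
}
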
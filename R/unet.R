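## A compact CPU U-Net: encoder/decoder with skip connections, trained
## with the log-cosh-dice loss and Adam under gradient-norm clipping.
## Convolutions run through im2col GEMM kernels in compiled code; the
## network orchestration, Adam and the training protocol live here.
##
## Feature maps are arrays of dim (H, W, C, N); weights (kh, kw, Cin, Cout).

#' Soft Dice coefficient
#'
#' `(2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)` between a
#' probability map and a binary target.
#'
#' @param pred_probs numeric array, values in `[0, 1]`.
#' @param target_mask binary array of the same shape.
#' @param smooth additive smoothing term.
#' @export
soft_dice <- function(pred_probs, target_mask, smooth = 1e-6) {
  if (!all(dim(pred_probs) == dim(target_mask)) &&
      length(pred_probs) != length(target_mask)) {
    stop("prediction and target shapes differ")
  }
  (2 * sum(pred_probs * target_mask) + smooth) /
    (sum(pred_probs) + sum(target_mask) + smooth)
}

#' Log-cosh-dice loss
#'
#' `log(cosh(1 - soft_dice))`: a smooth, non-negative relaxation of the
#' Dice loss, zero exactly at a perfect prediction.
#'
#' @inheritParams soft_dice
#' @export
log_cosh_dice_loss <- function(pred_probs, target_mask, smooth = 1e-6) {
  x <- 1 - soft_dice(pred_probs, target_mask, smooth)
  # numerically stable log(cosh(x))
  abs(x) + log1p(exp(-2 * abs(x))) - log(2)
}

#' U-Net architecture specification
#'
#' `levels` counts encoder/decoder resolution levels (so `levels - 1`
#' poolings and skip connections). Filters double per level from
#' `base_filters`. Each level applies two 3x3 convolution + ReLU blocks;
#' decoder levels additionally apply a 3x3 convolution after nearest
#' upsampling; a final 1x1 convolution with sigmoid yields the
#' probability map. The realized convolution-layer count is reported in
#' the spec object.
#'
#' @param input_shape `(H, W, C)` with `C` 1 or 2 (2 only for the crinU
#'   secondary segmentation network); `H`, `W` divisible by
#'   `2^(levels - 1)`.
#' @param levels resolution levels, >= 2.
#' @param base_filters filters at the top level.
#' @export
unet_spec <- function(input_shape, levels = 3L, base_filters = 8L) {
  stopifnot(length(input_shape) == 3, input_shape[3] %in% c(1L, 2L),
            levels >= 2, base_filters >= 1)
  div <- 2^(levels - 1)
  if (input_shape[1] %% div != 0 || input_shape[2] %% div != 0) {
    stop("input H and W must be divisible by 2^(levels - 1)")
  }
  structure(list(input_shape = as.integer(input_shape),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 n_conv_layers = 2L * levels + 3L * (levels - 1L) + 1L,
                 n_skip_connections = levels - 1L),
            class = "caseg_unet_spec")
}

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

#' Build an untrained U-Net
#'
#' He-normal weight initialization; deterministic given `seed`.
#'
#' @param spec a [unet_spec()].
#' @param seed integer init seed.
#' @return a `caseg_unet` model object.
#' @export
build_unet <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  L <- spec$levels
  f <- spec$base_filters * 2^(0:(L - 1))
  cin <- spec$input_shape[3]
  enc <- vector("list", L)
  prev <- cin
  for (l in seq_len(L)) {
    enc[[l]] <- list(W1 = he_init(3, 3, prev, f[l]), b1 = numeric(f[l]),
                     W2 = he_init(3, 3, f[l], f[l]), b2 = numeric(f[l]))
    prev <- f[l]
  }
  dec <- vector("list", L - 1)
  for (l in rev(seq_len(L - 1))) {
    dec[[l]] <- list(Wu = he_init(3, 3, f[l + 1], f[l]), bu = numeric(f[l]),
                     W1 = he_init(3, 3, 2 * f[l], f[l]), b1 = numeric(f[l]),
                     W2 = he_init(3, 3, f[l], f[l]), b2 = numeric(f[l]))
  }
  out <- list(W = he_init(1, 1, f[1], 1), b = numeric(1))
  structure(list(spec = spec, enc = enc, dec = dec, out = out),
            class = "caseg_unet")
}

#' @export
print.caseg_unet <- function(x, ...) {
  np <- sum(vapply(unet_params(x), length, 0L))
  cat(sprintf(paste0("<caseg_unet> input %dx%dx%d, %d levels ",
                     "(%d skip connections), %d conv layers, %d parameters\n"),
              x$spec$input_shape[1], x$spec$input_shape[2],
              x$spec$input_shape[3], x$spec$levels,
              x$spec$n_skip_connections, x$spec$n_conv_layers, np))
  invisible(x)
}

# Flatten parameters to a named list of arrays (stable order).
unet_params <- function(model) {
  p <- list()
  for (l in seq_along(model$enc)) {
    for (nm in names(model$enc[[l]])) p[[sprintf("enc%d.%s", l, nm)]] <- model$enc[[l]][[nm]]
  }
  for (l in seq_along(model$dec)) {
    for (nm in names(model$dec[[l]])) p[[sprintf("dec%d.%s", l, nm)]] <- model$dec[[l]][[nm]]
  }
  p[["out.W"]] <- model$out$W
  p[["out.b"]] <- model$out$b
  p
}

unet_set_params <- function(model, p) {
  for (l in seq_along(model$enc)) {
    for (nm in names(model$enc[[l]])) model$enc[[l]][[nm]] <- p[[sprintf("enc%d.%s", l, nm)]]
  }
  for (l in seq_along(model$dec)) {
    for (nm in names(model$dec[[l]])) model$dec[[l]][[nm]] <- p[[sprintf("dec%d.%s", l, nm)]]
  }
  model$out$W <- p[["out.W"]]
  model$out$b <- p[["out.b"]]
  model
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

concat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

# Forward pass; with cache = TRUE retains every intermediate needed for
# backpropagation.
unet_forward <- function(model, X, cache = FALSE) {
  L <- model$spec$levels
  cc <- list(enc = vector("list", L), dec = vector("list", L - 1))
  A <- X
  skips <- vector("list", L - 1)
  for (l in seq_len(L)) {
    e <- model$enc[[l]]
    Z1 <- .cg_conv2d_fwd(A, e$W1, e$b1); A1 <- relu(Z1)
    Z2 <- .cg_conv2d_fwd(A1, e$W2, e$b2); A2 <- relu(Z2)
    if (cache) cc$enc[[l]] <- list(X = A, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2)
    if (l < L) {
      skips[[l]] <- A2
      mp <- .cg_maxpool_fwd(A2)
      if (cache) cc$enc[[l]]$pool_idx <- mp$idx
      A <- mp$y
    } else A <- A2
  }
  for (l in rev(seq_len(L - 1))) {
    d <- model$dec[[l]]
    U <- .cg_upsample2_fwd(A)
    Zu <- .cg_conv2d_fwd(U, d$Wu, d$bu); Au <- relu(Zu)
    Cc <- concat_ch(Au, skips[[l]])
    Z1 <- .cg_conv2d_fwd(Cc, d$W1, d$b1); A1 <- relu(Z1)
    Z2 <- .cg_conv2d_fwd(A1, d$W2, d$b2); A2 <- relu(Z2)
    if (cache) cc$dec[[l]] <- list(U = U, Zu = Zu, Au = Au, C = Cc,
                                   Z1 = Z1, A1 = A1, Z2 = Z2, Ain = A)
    A <- A2
  }
  Zo <- .cg_conv2d_fwd(A, model$out$W, model$out$b)
  P <- sigmoid(Zo)
  if (cache) { cc$head <- list(Ain = A, P = P); list(P = P, cache = cc) }
  else P
}

# Backward pass: dP is dLoss/dP. Returns gradients in unet_params() order.
unet_backward <- function(model, cc, dP) {
  g <- list()
  P <- cc$head$P
  dZo <- dP * P * (1 - P)
  bo <- .cg_conv2d_bwd(cc$head$Ain, model$out$W, dZo)
  g[["out.W"]] <- bo$dW; g[["out.b"]] <- bo$db
  dA <- bo$dX
  L <- model$spec$levels
  dskips <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    d <- model$dec[[l]]; c2 <- cc$dec[[l]]
    dZ2 <- dA * (c2$Z2 > 0)
    b2 <- .cg_conv2d_bwd(c2$A1, d$W2, dZ2)
    g[[sprintf("dec%d.W2", l)]] <- b2$dW; g[[sprintf("dec%d.b2", l)]] <- b2$db
    dZ1 <- b2$dX * (c2$Z1 > 0)
    b1 <- .cg_conv2d_bwd(c2$C, d$W1, dZ1)
    g[[sprintf("dec%d.W1", l)]] <- b1$dW; g[[sprintf("dec%d.b1", l)]] <- b1$db
    nAu <- dim(c2$Au)[3]
    dAu <- b1$dX[, , seq_len(nAu), , drop = FALSE]
    dskips[[l]] <- b1$dX[, , nAu + seq_len(dim(b1$dX)[3] - nAu), , drop = FALSE]
    dZu <- dAu * (c2$Zu > 0)
    bu <- .cg_conv2d_bwd(c2$U, d$Wu, dZu)
    g[[sprintf("dec%d.Wu", l)]] <- bu$dW; g[[sprintf("dec%d.bu", l)]] <- bu$db
    dA <- .cg_upsample2_bwd(bu$dX)   # gradient flowing into the level below
  }
  for (l in rev(seq_len(L))) {
    e <- model$enc[[l]]; c1 <- cc$enc[[l]]
    if (l < L) {
      dim_in <- dim(c1$A2)
      dA2 <- .cg_maxpool_bwd(dA, c1$pool_idx, dim_in[1], dim_in[2]) +
        dskips[[l]]
    } else {
      dA2 <- dA
    }
    dZ2 <- dA2 * (c1$Z2 > 0)
    b2 <- .cg_conv2d_bwd(c1$A1, e$W2, dZ2)
    g[[sprintf("enc%d.W2", l)]] <- b2$dW; g[[sprintf("enc%d.b2", l)]] <- b2$db
    dZ1 <- b2$dX * (c1$Z1 > 0)
    b1 <- .cg_conv2d_bwd(c1$X, e$W1, dZ1)
    g[[sprintf("enc%d.W1", l)]] <- b1$dW; g[[sprintf("enc%d.b1", l)]] <- b1$db
    dA <- b1$dX
  }
  g
}

# Per-sample log-cosh-dice loss over a batch; returns mean loss and dP.
batch_loss_grad <- function(P, Y, smooth = 1e-6) {
  N <- dim(P)[4]
  dP <- array(0, dim(P))
  loss <- 0
  for (n in seq_len(N)) {
    p <- P[, , , n]; t <- Y[, , , n]
    sp <- sum(p); st <- sum(t); spt <- sum(p * t)
    d <- (2 * spt + smooth) / (sp + st + smooth)
    x <- 1 - d
    loss <- loss + (abs(x) + log1p(exp(-2 * abs(x))) - log(2))
    # d(loss)/dd = -tanh(1 - d); dd/dp = (2 t (sp+st+s) - (2 spt + s)) / (sp+st+s)^2
    den <- (sp + st + smooth)
    dd_dp <- (2 * t * den - (2 * spt + smooth)) / den^2
    dP[, , , n] <- -tanh(x) * dd_dp / N
  }
  list(loss = loss / N, dP = dP)
}

#' Training protocol configuration
#'
#' Mirrors the shared protocol of all networks in the cascade study:
#' Adam with gradient-norm clipping, early stopping on the validation
#' Dice coefficient and a halving learning-rate schedule.
#'
#' @param initial_lr initial (maximum) Adam learning rate.
#' @param grad_norm_clip global gradient-norm bound.
#' @param batch_size samples per optimizer step.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs of no validation-DSC improvement
#'   before training stops.
#' @param lr_patience epochs of no improvement per learning-rate halving.
#' @param lr_factor multiplicative learning-rate decay (0.5 = halving).
#' @param seed training seed (shuffling, augmentation).
#' @export
train_config <- function(initial_lr = 0.001, grad_norm_clip = 0.001,
                         batch_size = 10L, max_epochs = 1000L,
                         early_stop_patience = 50L, lr_patience = 25L,
                         lr_factor = 0.5, seed = 1L) {
  stopifnot(early_stop_patience >= 1, lr_patience >= 1,
            lr_factor > 0, lr_factor < 1, batch_size >= 1)
  structure(list(initial_lr = initial_lr, grad_norm_clip = grad_norm_clip,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor, seed = as.integer(seed)),
            class = "caseg_train_config")
}

# Hard Dice of a thresholded prediction (both empty counts as 1).
hard_dice <- function(prob, mask, threshold = 0.5) {
  p <- prob >= threshold
  t <- mask == 1
  if (!any(p) && !any(t)) return(1)
  2 * sum(p & t) / (sum(p) + sum(t))
}

#' Train a U-Net
#'
#' Mini-batch Adam with global gradient-norm clipping; after every epoch
#' the hard (thresholded at 0.5) Dice coefficient over the validation
#' cases is computed, the learning rate is halved after `lr_patience`
#' epochs without improvement, training stops after `early_stop_patience`
#' epochs without improvement (both counters reset on improvement, and
#' improvement means strictly exceeding the best value so far), and the
#' parameters achieving the best validation DSC are returned.
#'
#' @param model a `caseg_unet` from [build_unet()].
#' @param train_cases,val_cases lists of training/validation items; each
#'   item is passed through `sample_fn` / `val_fn` to obtain a list
#'   `(x = H x W x C array, y = binary H x W matrix)` at the model shape.
#' @param config a [train_config()].
#' @param sample_fn function(case) called once per epoch per training
#'   case (stochastic augmentation happens here). Defaults to identity.
#' @param val_fn deterministic counterpart for validation cases.
#' @return a `caseg_fit`: list with the best `model`, a `history` data
#'   frame (per-epoch loss, validation DSC, learning rate, post-clip
#'   gradient norm), `best_epoch` and `best_val_dsc`.
#' @export
unet_train <- function(model, train_cases, val_cases, config = train_config(),
                       sample_fn = identity, val_fn = sample_fn) {
  stopifnot(length(train_cases) > 0, length(val_cases) > 0)
  set.seed(config$seed)
  shp <- model$spec$input_shape
  params <- unet_params(model)
  m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$initial_lr
  tstep <- 0
  best_dsc <- -Inf; best_params <- params; best_epoch <- 0L
  hist <- list()
  val_xy <- lapply(val_cases, val_fn)
  to_batch <- function(items) {
    N <- length(items)
    X <- array(0, c(shp[1], shp[2], shp[3], N))
    Y <- array(0, c(shp[1], shp[2], 1, N))
    for (i in seq_len(N)) {
      X[, , , i] <- items[[i]]$x
      Y[, , 1, i] <- items[[i]]$y
    }
    list(X = X, Y = Y)
  }
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(seq_along(train_cases))
    epoch_loss <- 0; nb <- 0; max_gnorm <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      items <- lapply(train_cases[idx], sample_fn)
      ba <- to_batch(items)
      model <- unet_set_params(model, params)
      fw <- unet_forward(model, ba$X, cache = TRUE)
      lg <- batch_loss_grad(fw$P, ba$Y)
      if (!is.finite(lg$loss)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
      }
      g <- unet_backward(model, fw$cache, lg$dP)
      gnorm <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
      if (gnorm > config$grad_norm_clip && gnorm > 0) {
        scl <- config$grad_norm_clip / gnorm
        g <- lapply(g, function(x) x * scl)
        gnorm <- config$grad_norm_clip
      }
      max_gnorm <- max(max_gnorm, gnorm)
      tstep <- tstep + 1
      corr <- sqrt(1 - beta2^tstep) / (1 - beta1^tstep)
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        params[[nm]] <- params[[nm]] - lr * corr * m[[nm]] /
          (sqrt(v[[nm]]) + eps)
      }
      epoch_loss <- epoch_loss + lg$loss; nb <- nb + 1
    }
    model <- unet_set_params(model, params)
    vd <- vapply(val_xy, function(it) {
      p <- unet_forward(model, array(it$x, c(shp, 1)))
      hard_dice(p[, , 1, 1], it$y)
    }, 0)
    val_dsc <- mean(vd)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = epoch_loss / nb,
                                val_dsc = val_dsc, lr = lr,
                                grad_norm = max_gnorm)
    if (val_dsc > best_dsc) {
      best_dsc <- val_dsc; best_params <- params; best_epoch <- epoch
    } else {
      since <- epoch - best_epoch
      if (since %% config$lr_patience == 0) lr <- lr * config$lr_factor
      if (since >= config$early_stop_patience) break
    }
  }
  structure(list(model = unet_set_params(model, best_params),
                 history = do.call(rbind, hist),
                 best_epoch = best_epoch, best_val_dsc = best_dsc,
                 config = config),
            class = "caseg_fit")
}

#' @export
print.caseg_fit <- function(x, ...) {
  cat(sprintf("<caseg_fit> %d epochs, best validation DSC %.4f at epoch %d\n",
              nrow(x$history), x$best_val_dsc, x$best_epoch))
  invisible(x)
}

#' @export
plot.caseg_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "log-cosh-dice loss", main = "training loss", ...)
  plot(x$history$epoch, x$history$val_dsc, type = "l", xlab = "epoch",
       ylab = "validation DSC", main = "validation Dice", ...)
  invisible(x)
}

#' Predict a probability map for one input
#'
#' @param model a `caseg_unet`.
#' @param x matrix (1-channel) or H x W x C array at the model input shape.
#' @return probability matrix of the model's spatial shape.
#' @export
unet_predict <- function(model, x) {
  shp <- model$spec$input_shape
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!all(dim(x) == shp)) {
    stop(sprintf("input shape (%s) does not match model input (%s)",
                 paste(dim(x), collapse = "x"),
                 paste(shp, collapse = "x")))
  }
  p <- unet_forward(model, array(x, c(shp, 1L)))
  p[, , 1, 1]
}

#' @export
predict.caseg_unet <- function(object, x, ...) unet_predict(object, x)
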
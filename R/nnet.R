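# A configurable 3D U-Net used twice in the pipeline: with a softmax head and
# cross-entropy loss for hemispheric white-matter segmentation, and with a
# plain convolutional head and mean-squared-error loss for level-set
# regression. Encoder/decoder with 3x3x3 conv + leaky-ReLU pairs, 2x2x2 max
# pooling, 2x upsampling + convolution, and copy-and-concatenate skips.
# Convolutions run through im2col + BLAS (see src/nnet.cpp).

#' U-Net architecture configuration
#'
#' @param n_stages number of resolution stages (1 = a plain conv stack).
#' @param base_channels feature channels at full resolution; doubled per
#'   stage.
#' @param in_channels input channels (1 for segmentation: the normalized
#'   image; 2 for level-set regression: image + hemispheric mask).
#' @param out_channels output channels (segmentation classes, or 1).
#' @param patch_size integer 3-vector; each axis must be divisible by
#'   `2^(n_stages - 1)`.
#' @param head `"segmentation"` (softmax) or `"regression"` (plain
#'   convolution, unbounded outputs).
#' @param lrelu_slope negative slope of the leaky rectifier.
#' @param head_bias initial head bias. For level-set regression, starting at
#'   the scaled truncation clamp (+1, the value of almost all target voxels)
#'   lets training carve the interior immediately instead of first learning
#'   the background constant.
#' @return A `cortrec_net_config`.
#' @export
net_config <- function(n_stages = 3, base_channels = 8, in_channels = 1,
                       out_channels = 1, patch_size = c(32, 32, 32),
                       head = c("regression", "segmentation"),
                       lrelu_slope = 0.01, head_bias = 0) {
  head <- match.arg(head)
  patch_size <- as.integer(patch_size)
  div <- 2^(n_stages - 1)
  for (ax in 1:3) {
    if (patch_size[ax] %% div != 0) {
      stopf("patch_size axis %d (%d) is not divisible by 2^(n_stages-1) = %d",
            ax, patch_size[ax], div)
    }
  }
  structure(list(n_stages = as.integer(n_stages),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 patch_size = patch_size, head = head,
                 lrelu_slope = lrelu_slope, head_bias = head_bias),
            class = "cortrec_net_config")
}

stage_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$n_stages) - 1)

#' Build an untrained U-Net
#'
#' He-initialised weights, deterministic for a fixed seed. The segmentation
#' head ends in a channel-wise softmax (outputs sum to 1 at every voxel);
#' the regression head is a plain convolution with unbounded outputs.
#'
#' @param cfg a [net_config()].
#' @param seed initialisation seed.
#' @return A `cortrec_net` model object.
#' @export
build_network <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "cortrec_net_config"))
  ch <- stage_channels(cfg)
  S <- cfg$n_stages
  w <- list()
  mk <- function(k, ci, co) {
    sd <- sqrt(2 / (k^3 * ci))
    list(w = array(rnorm(k^3 * ci * co, 0, sd), c(k, k, k, ci, co)),
         b = numeric(co), k = k)
  }
  with_stream(seed, "init", {
    cin <- cfg$in_channels
    for (i in seq_len(S)) {
      w[[sprintf("enc%d", i)]] <- mk(3, cin, ch[i])
      cin <- ch[i]
    }
    if (S > 1) {
      for (i in (S - 1):1) {
        # "up-convolution of 2x2x2 with stride 2": one input voxel per output
        # position after nearest upsampling, i.e. a 1x1x1 convolution
        w[[sprintf("up%d", i)]] <- mk(1, ch[i + 1], ch[i])
        w[[sprintf("dec%d", i)]] <- mk(3, 2 * ch[i], ch[i])
      }
    }
    w[["head"]] <- mk(1, ch[1], cfg$out_channels)
    w[["head"]]$b[] <- cfg$head_bias
  })
  structure(list(config = cfg, weights = w, opt = NULL,
                 training_log = NULL, provenance = NULL),
            class = "cortrec_net")
}

#' @export
print.cortrec_net <- function(x, ...) {
  np <- sum(vapply(x$weights, function(l) length(l$w) + length(l$b), numeric(1)))
  cat(sprintf("<cortrec_net> %s head, %d stages, base %d channels, %s parameters%s\n",
              x$config$head, x$config$n_stages, x$config$base_channels,
              format(np, big.mark = ","),
              if (is.null(x$training_log)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$training_log))))
  invisible(x)
}

lrelu_fw <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
lrelu_bw <- function(x, g, slope) g * ifelse(x > 0, 1, slope)

# Forward pass. x: array (D,H,W,Cin). Returns raw head output (before
# softmax); with cache = TRUE also every intermediate needed for backward.
net_forward <- function(model, x, cache = FALSE) {
  cfg <- model$config
  W <- model$weights
  S <- cfg$n_stages
  cc <- if (cache) new.env(parent = emptyenv()) else NULL
  conv <- function(name, h) {
    L <- W[[name]]
    y <- cpp_conv3d_fw(h, dim(h), L$w, L$b, L$k)
    if (cache) assign(paste0(name, ".x"), h, envir = cc)
    y
  }
  act <- function(name, y) {
    if (cache) assign(paste0(name, ".pre"), y, envir = cc)
    lrelu_fw(y, cfg$lrelu_slope)
  }
  skips <- vector("list", S)
  h <- x
  for (i in seq_len(S)) {
    h <- act(sprintf("enc%d", i), conv(sprintf("enc%d", i), h))
    skips[[i]] <- h
    if (i < S) {
      p <- cpp_maxpool_fw(h, dim(h))
      if (cache) assign(sprintf("pool%d", i), list(arg = p$arg, xdim = dim(h)), envir = cc)
      h <- p$y
    }
  }
  if (S > 1) {
    for (i in (S - 1):1) {
      if (cache) assign(sprintf("updim%d", i), dim(h), envir = cc)
      u <- cpp_upsample_fw(h, dim(h))
      u <- act(sprintf("up%d", i), conv(sprintf("up%d", i), u))
      h <- array(c(u, skips[[i]]), c(dim(u)[1:3], dim(u)[4] + dim(skips[[i]])[4]))
      if (cache) assign(sprintf("cat%d", i), dim(u)[4], envir = cc)
      h <- act(sprintf("dec%d", i), conv(sprintf("dec%d", i), h))
    }
  }
  out <- conv("head", h)
  list(out = out, cache = cc)
}

# Backward pass: gradient of the loss wrt every weight, given d loss / d out.
net_backward <- function(model, cache, gout) {
  cfg <- model$config
  W <- model$weights
  S <- cfg$n_stages
  grads <- list()
  conv_bw <- function(name, gy) {
    L <- W[[name]]
    x <- get(paste0(name, ".x"), envir = cache)
    r <- cpp_conv3d_bw(x, dim(x), L$w, gy, L$k, length(L$b))
    grads[[name]] <<- list(w = r$gw, b = r$gb)
    r$gx
  }
  act_bw <- function(name, g) {
    pre <- get(paste0(name, ".pre"), envir = cache)
    lrelu_bw(pre, g, cfg$lrelu_slope)
  }
  g <- conv_bw("head", gout)
  gskips <- vector("list", S)
  if (S > 1) {
    for (i in seq_len(S - 1)) {
      g <- conv_bw(sprintf("dec%d", i), act_bw(sprintf("dec%d", i), g))
      cu <- get(sprintf("cat%d", i), envir = cache)
      d <- dim(g)
      gu <- array(g[, , , seq_len(cu)], c(d[1:3], cu))
      gskips[[i]] <- array(g[, , , (cu + 1):d[4]], c(d[1:3], d[4] - cu))
      gu <- conv_bw(sprintf("up%d", i), act_bw(sprintf("up%d", i), gu))
      g <- cpp_upsample_bw(gu, get(sprintf("updim%d", i), envir = cache))
    }
  }
  for (i in S:1) {
    if (i < S) {
      p <- get(sprintf("pool%d", i), envir = cache)
      g <- cpp_maxpool_bw(g, p$arg, p$xdim)
      g <- g + gskips[[i]]
    }
    g <- conv_bw(sprintf("enc%d", i), act_bw(sprintf("enc%d", i), g))
  }
  grads
}

softmax_channels <- function(x) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  m <- xm[, 1]
  for (k in seq_len(d[4])[-1]) m <- pmax(m, xm[, k])
  e <- exp(xm - m)
  array(e / rowSums(e), d)
}

# Loss value and gradient wrt the raw head output. For segmentation,
# class_weights = "balanced" weights voxels inversely to their class
# frequency in the sample, which is essential when the foreground occupies
# a small fraction of the volume.
net_loss <- function(cfg, out, target, class_weights = NULL) {
  n <- prod(dim(out)[1:3])
  if (cfg$head == "regression") {
    r <- as.vector(out) - as.vector(target)
    list(loss = mean(r^2), gout = array(2 * r / length(r), dim(out)))
  } else {
    K <- dim(out)[4]
    p <- softmax_channels(out)
    pm <- matrix(p, ncol = K)
    tgt <- as.integer(target)
    sel <- cbind(seq_len(n), tgt)
    if (identical(class_weights, "balanced")) {
      freq <- tabulate(tgt, nbins = K)
      class_weights <- ifelse(freq > 0, n / (K * freq), 0)
    }
    w <- if (is.null(class_weights)) rep(1, n) else class_weights[tgt]
    sw <- sum(w)
    loss <- -sum(w * log(pm[sel] + 1e-12)) / sw
    pm[sel] <- pm[sel] - 1
    list(loss = loss, gout = array(pm * (w / sw), dim(out)))
  }
}

#' Training configuration
#'
#' The learning rate at (0-based) epoch `e` is
#' `initial_lr - e * lr_decrement_per_epoch` (never below 0); training stops
#' at `max_epochs` or once the relative epoch-loss change stays below
#' `convergence_tolerance` for `convergence_window` consecutive epochs.
#' Augmentation (random flips along the non-lateral axes) is off by default:
#' exact regression targets lose precision under resampling.
#'
#' @param batch_size samples per optimiser step.
#' @param initial_lr,lr_decrement_per_epoch Adam learning-rate schedule.
#' @param max_epochs maximum epochs (0 returns the model unchanged).
#' @param convergence_window,convergence_tolerance early-stopping rule.
#' @param seed training-time randomness (shuffling, crops, augmentation).
#' @param augment logical.
#' @param class_weights for segmentation: `NULL` (uniform), `"balanced"`
#'   (inverse class frequency per sample), or a numeric per-class vector.
#' @return A `cortrec_train_config`.
#' @export
train_config <- function(batch_size = 2, initial_lr = 1e-3,
                         lr_decrement_per_epoch = 1e-6, max_epochs = 1000,
                         convergence_window = 50, convergence_tolerance = 1e-4,
                         seed = 1, augment = FALSE, class_weights = NULL) {
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (convergence_window > max_epochs && max_epochs > 0) {
    stopf("convergence_window must not exceed max_epochs")
  }
  structure(list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
                 lr_decrement_per_epoch = lr_decrement_per_epoch,
                 max_epochs = as.integer(max_epochs),
                 convergence_window = as.integer(convergence_window),
                 convergence_tolerance = convergence_tolerance,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 class_weights = class_weights),
            class = "cortrec_train_config")
}

sample_patch <- function(input, target, patch, rng_biased) {
  d <- dim(input)[1:3]
  if (all(d == patch)) return(list(input = input, target = target))
  lo <- integer(3)
  zc <- NULL
  if (rng_biased && runif(1) < 0.75) {
    # bias crops towards the surface band: centre on a random near-zero voxel
    zc <- which(abs(target) == min(abs(target)))
  }
  centre <- if (!is.null(zc)) arrayInd(sample(zc, 1), d) else
    vapply(d, function(n) sample.int(n, 1), integer(1))
  for (ax in 1:3) {
    lo[ax] <- min(max(centre[ax] - patch[ax] %/% 2, 1), d[ax] - patch[ax] + 1)
  }
  list(input = input[lo[1]:(lo[1] + patch[1] - 1), lo[2]:(lo[2] + patch[2] - 1),
                     lo[3]:(lo[3] + patch[3] - 1), , drop = FALSE],
       target = target[lo[1]:(lo[1] + patch[1] - 1), lo[2]:(lo[2] + patch[2] - 1),
                       lo[3]:(lo[3] + patch[3] - 1)])
}

#' Train a U-Net
#'
#' Adam optimisation with the linear learning-rate schedule and early
#' stopping described in [train_config()]. Loss is cross-entropy for the
#' segmentation head and mean squared error for the regression head. The
#' per-epoch mean loss and learning rate are recorded in
#' `model$training_log` (epochs numbered from 0).
#'
#' @param model a `cortrec_net` from [build_network()].
#' @param dataset list of samples, each `list(input = , target = )`: `input`
#'   an array `(D, H, W, in_channels)`, `target` `(D, H, W)` (integer class
#'   ids `1..out_channels` for segmentation, numeric for regression). Volumes
#'   larger than the patch size are randomly cropped (crops biased towards
#'   the target's zero-crossing band).
#' @param tc a [train_config()].
#' @return The trained `cortrec_net` with `training_log` and `provenance`.
#' @export
train_network <- function(model, dataset, tc = train_config()) {
  stopifnot(inherits(model, "cortrec_net"), inherits(tc, "cortrec_train_config"))
  cfg <- model$config
  for (s in dataset) {
    if (length(dim(s$input)) != 4L || dim(s$input)[4] != cfg$in_channels) {
      stopf("sample input must be (D,H,W,%d)", cfg$in_channels)
    }
    if (!all(dim(s$input)[1:3] == dim(s$target)[1:3] %||% dim(s$target))) {
      stopf("target grid does not match input grid")
    }
  }
  log <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  if (tc$max_epochs == 0) {
    model$training_log <- log
    return(model)
  }
  opt <- model$opt %||% list(m = list(), v = list(), t = 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  streak <- 0L
  prev_loss <- NA_real_
  with_stream(tc$seed, "train", {
    for (epoch in 0:(tc$max_epochs - 1)) {
      lr <- max(tc$initial_lr - epoch * tc$lr_decrement_per_epoch, 0)
      ord <- sample.int(length(dataset))
      epoch_loss <- 0
      nb <- 0
      for (start in seq(1, length(ord), by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1, length(ord))]
        acc <- NULL
        bloss <- 0
        for (si in idx) {
          sm <- sample_patch(dataset[[si]]$input, dataset[[si]]$target,
                             cfg$patch_size, cfg$head == "regression")
          inp <- sm$input; tgt <- sm$target
          if (tc$augment) {
            for (ax in 2:3) if (runif(1) < 0.5) {
              flip <- function(a) {
                idxs <- rep(list(quote(expr = )), length(dim(a)))
                idxs[[ax]] <- rev(seq_len(dim(a)[ax]))
                do.call(`[`, c(list(a), idxs, list(drop = FALSE)))
              }
              inp <- flip(inp); tgt <- array(flip(array(tgt, c(dim(tgt), 1))), dim(tgt))
            }
          }
          fw <- net_forward(model, inp, cache = TRUE)
          ls <- net_loss(cfg, fw$out, tgt, tc$class_weights)
          if (!is.finite(ls$loss)) {
            stopf("NaN/Inf loss at epoch %d (sample %d): lr=%g, |out| max=%g",
                  epoch, si, lr, max(abs(fw$out)))
          }
          bloss <- bloss + ls$loss
          g <- net_backward(model, fw$cache, ls$gout)
          if (is.null(acc)) acc <- g
          else for (nm in names(g)) {
            acc[[nm]]$w <- acc[[nm]]$w + g[[nm]]$w
            acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
          }
        }
        nsamp <- length(idx)
        opt$t <- opt$t + 1
        for (nm in names(acc)) {
          for (part in c("w", "b")) {
            gpt <- acc[[nm]][[part]] / nsamp
            key <- paste0(nm, ".", part)
            m <- (opt$m[[key]] %||% 0) * b1 + (1 - b1) * gpt
            v <- (opt$v[[key]] %||% 0) * b2 + (1 - b2) * gpt^2
            opt$m[[key]] <- m; opt$v[[key]] <- v
            mh <- m / (1 - b1^opt$t); vh <- v / (1 - b2^opt$t)
            model$weights[[nm]][[part]] <- model$weights[[nm]][[part]] -
              lr * mh / (sqrt(vh) + adam_eps)
          }
        }
        epoch_loss <- epoch_loss + bloss / nsamp
        nb <- nb + 1
      }
      epoch_loss <- epoch_loss / nb
      log <- rbind(log, data.frame(epoch = epoch, loss = epoch_loss, lr = lr))
      if (!is.na(prev_loss)) {
        rel <- abs(epoch_loss - prev_loss) / max(abs(prev_loss), 1e-12)
        streak <- if (rel < tc$convergence_tolerance) streak + 1L else 0L
        if (streak >= tc$convergence_window) break
      }
      prev_loss <- epoch_loss
    }
  })
  model$opt <- opt
  model$training_log <- log
  model$provenance <- list(train_config = tc, n_samples = length(dataset),
                           seed = tc$seed)
  model
}

#' Sliding-window prediction over a full volume
#'
#' Volumes larger than the network patch are tiled with overlapping windows
#' at half-patch stride and blended with a Gaussian weight centred on each
#' window (sigma = patch/8), so constants are conserved and seams are
#' feathered. Volumes smaller than the patch are zero-padded and cropped
#' back. Deterministic.
#'
#' @param model a `cortrec_net`.
#' @param image a [volume()] (already normalized for trained models).
#' @param mask optional [volume()] supplying the second input channel.
#' @return For a 1-channel head, a [volume()]; otherwise an array
#'   `(D, H, W, out_channels)` of class probabilities.
#' @export
predict_sliding <- function(model, image, mask = NULL) {
  stopifnot(inherits(model, "cortrec_net"), inherits(image, "cortrec_volume"))
  cfg <- model$config
  chans <- list(image$data)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "cortrec_volume"))
    if (!all(dim(mask$data) == dim(image$data))) stopf("mask grid differs from image grid")
    chans <- c(chans, list(mask$data))
  }
  if (length(chans) != cfg$in_channels) {
    stopf("model expects %d input channel(s), got %d", cfg$in_channels, length(chans))
  }
  d0 <- dim(image$data)
  patch <- cfg$patch_size
  d <- pmax(d0, patch)
  x <- array(0, c(d, cfg$in_channels))
  for (ci in seq_along(chans)) {
    x[1:d0[1], 1:d0[2], 1:d0[3], ci] <- chans[[ci]]
  }
  starts <- function(n, p) {
    if (n == p) return(1L)
    s <- seq(1L, n - p + 1L, by = max(p %/% 2L, 1L))
    if (tail(s, 1) != n - p + 1L) s <- c(s, n - p + 1L)
    s
  }
  gw1 <- function(p) exp(-0.5 * ((seq_len(p) - (p + 1) / 2) / (p / 8))^2)
  wwin <- outer(outer(gw1(patch[1]), gw1(patch[2])), gw1(patch[3]))
  acc <- array(0, c(d, cfg$out_channels))
  wacc <- array(0, d)
  for (k in starts(d[3], patch[3]))
    for (j in starts(d[2], patch[2]))
      for (i in starts(d[1], patch[1])) {
        sub <- x[i:(i + patch[1] - 1), j:(j + patch[2] - 1), k:(k + patch[3] - 1), ,
                 drop = FALSE]
        out <- net_forward(model, sub, cache = FALSE)$out
        if (cfg$head == "segmentation") out <- softmax_channels(out)
        for (co in seq_len(cfg$out_channels)) {
          acc[i:(i + patch[1] - 1), j:(j + patch[2] - 1), k:(k + patch[3] - 1), co] <-
            acc[i:(i + patch[1] - 1), j:(j + patch[2] - 1), k:(k + patch[3] - 1), co] +
            wwin * out[, , , co]
        }
        wacc[i:(i + patch[1] - 1), j:(j + patch[2] - 1), k:(k + patch[3] - 1)] <-
          wacc[i:(i + patch[1] - 1), j:(j + patch[2] - 1), k:(k + patch[3] - 1)] + wwin
      }
  acc <- acc / as.vector(wacc)
  acc <- acc[1:d0[1], 1:d0[2], 1:d0[3], , drop = FALSE]
  if (cfg$out_channels == 1L) {
    volume(array(acc, d0), image$affine)
  } else {
    acc
  }
}

#' @export
predict.cortrec_net <- function(object, image, mask = NULL, ...) {
  predict_sliding(object, image, mask)
}

#' Split a segmentation prediction into hemisphere masks
#'
#' Runs sliding-window prediction with a segmentation model (>= 3 classes:
#' background, left WM, right WM), takes the voxel-wise argmax and returns
#' disjoint binary masks for the two hemispheres. An empty mask triggers a
#' warning.
#'
#' @param model a segmentation `cortrec_net`.
#' @param image a normalized [volume()].
#' @return `list(left = , right = )` of binary volumes.
#' @export
segment_hemispheres <- function(model, image) {
  stopifnot(inherits(model, "cortrec_net"))
  if (model$config$head != "segmentation" || model$config$out_channels < 3) {
    stopf("segment_hemispheres needs a segmentation model with >= 3 classes")
  }
  p <- predict_sliding(model, image)
  cls <- array(max.col(matrix(p, ncol = dim(p)[4]), ties.method = "first"), dim(p)[1:3])
  left <- volume(array(as.numeric(cls == 2), dim(cls)), image$affine)
  right <- volume(array(as.numeric(cls == 3), dim(cls)), image$affine)
  if (!any(left$data > 0)) warnf("left hemisphere mask is empty")
  if (!any(right$data > 0)) warnf("right hemisphere mask is empty")
  list(left = left, right = right)
}

#' Save and reload a trained model
#'
#' The model directory holds the architecture and training configuration as
#' YAML, the training log as CSV and the weights; a save/load round trip
#' reproduces bit-identical predictions.
#'
#' @param model a `cortrec_net`.
#' @param dir model directory (created if needed).
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "cortrec_net"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(model$config), file.path(dir, "net_config.yaml"))
  if (!is.null(model$provenance)) {
    yaml::write_yaml(list(train_config = unclass(model$provenance$train_config),
                          n_samples = model$provenance$n_samples,
                          seed = model$provenance$seed),
                     file.path(dir, "provenance.yaml"))
  }
  if (!is.null(model$training_log)) {
    utils::write.csv(model$training_log, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
  }
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "net_config.yaml"))
  cfg <- net_config(n_stages = cfgl$n_stages, base_channels = cfgl$base_channels,
                    in_channels = cfgl$in_channels, out_channels = cfgl$out_channels,
                    patch_size = cfgl$patch_size, head = cfgl$head,
                    lrelu_slope = cfgl$lrelu_slope,
                    head_bias = cfgl$head_bias %||% 0)
  model <- structure(list(config = cfg,
                          weights = readRDS(file.path(dir, "weights.rds")),
                          opt = NULL, training_log = NULL, provenance = NULL),
                     class = "cortrec_net")
  logp <- file.path(dir, "training_log.csv")
  if (file.exists(logp)) model$training_log <- utils::read.csv(logp)
  model
}
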
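#' Segmentation training configuration
#'
#' Defaults follow the training recipe used for eye-region segmentation:
#' Adam with learning rate 1e-4, a multiplicative per-epoch learning-rate
#' decay of 0.99, 200 epochs, Kaiming weight initialization and a soft Dice
#' loss. The architecture hyperparameters (encoder depth and first-level
#' channel count) default to a full-size network; tests and the phantom
#' benchmark use `depth = 3, base_channels = 8`.
#'
#' @param learning_rate Initial Adam learning rate (> 0).
#' @param lr_decay_per_epoch Multiplicative decay applied each epoch,
#'   in (0, 1].
#' @param epochs Number of training epochs (>= 1).
#' @param batch_size Images per gradient step.
#' @param base_channels Feature channels at the first encoder level.
#' @param depth Number of encoder levels (>= 2); inputs must be divisible by
#'   `2^(depth-1)` or they are reflection-padded and cropped back.
#' @param seed Integer seed for initialization and shuffling.
#' @param deep_supervision Not supported; must be `FALSE`.
#' @return Object of class `seg_train_config`.
#' @export
seg_train_config <- function(learning_rate = 1e-4, lr_decay_per_epoch = 0.99,
                             epochs = 200, batch_size = 4,
                             base_channels = 32, depth = 5, seed = 1,
                             deep_supervision = FALSE) {
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  if (lr_decay_per_epoch <= 0 || lr_decay_per_epoch > 1)
    abort("`lr_decay_per_epoch` must lie in (0, 1]")
  if (epochs < 1) abort("`epochs` must be >= 1")
  if (depth < 2) abort("`depth` must be >= 2")
  if (isTRUE(deep_supervision))
    abort("deep supervision is not supported")
  structure(list(learning_rate = learning_rate,
                 lr_decay_per_epoch = lr_decay_per_epoch,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), seed = as.integer(seed),
                 deep_supervision = FALSE),
            class = "seg_train_config")
}

#' Soft Dice loss between a probability map and a binary mask
#'
#' `1 - 2 * sum(p * t) / (sum(p) + sum(t))`, the soft relaxation of
#' `1 - Dice`: the intersection is the sum of elementwise products and the
#' set sizes are plain sums. On hard (0/1) predictions it equals
#' `1 - Dice(p, t)` exactly. An empty-vs-empty comparison is defined as 0
#' (perfect agreement) and logged with a warning.
#'
#' @param prediction Numeric matrix of per-pixel probabilities in \[0, 1\].
#' @param truth Logical (or 0/1) matrix on the same grid.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prediction, truth) {
  truth <- stopifnot_mask(truth, "truth")
  same_shape(prediction, truth, c("prediction", "truth"))
  if (min(prediction) < -1e-9 || max(prediction) > 1 + 1e-9)
    abort("`prediction` values must lie in [0, 1]")
  den <- sum(prediction) + sum(truth)
  if (den == 0) {
    warn("both prediction and truth are empty; Dice loss defined as 0")
    return(0)
  }
  1 - 2 * sum(prediction * truth) / den
}

node_names <- function(depth) {
  nms <- character(0)
  for (j in 0:(depth - 1)) for (i in 0:(depth - 1 - j))
    nms <- c(nms, sprintf("x_%d_%d", i, j))
  nms
}

#' Build an untrained U-Net++ segmenter
#'
#' A nested encoder-decoder with dense skip pathways: node `X(i,j)` at
#' resolution level `i` receives the concatenation of all previous nodes at
#' its level, `X(i,0..j-1)`, and the 2x upsampled `X(i+1,j-1)`. Each node is
#' two 3x3 convolution + batch-norm + ReLU stages; the output head is a 1x1
#' convolution with a sigmoid giving a per-pixel foreground probability.
#' Weights use Kaiming-normal initialization seeded from the config, so two
#' builds with the same seed are identical.
#'
#' @param config A [seg_train_config()].
#' @return Object of class `exoct_unetpp` with elements `params`, `config`,
#'   `n_parameters`.
#' @export
build_unetpp <- function(config = seg_train_config()) {
  stopifnot(inherits(config, "seg_train_config"))
  d <- config$depth; base <- config$base_channels
  ch <- function(i) base * 2^i
  with_seed(config$seed, {
    params <- list()
    for (j in 0:(d - 1)) for (i in 0:(d - 1 - j)) {
      ch_in1 <- if (j == 0) {
        if (i == 0) 1L else ch(i - 1)
      } else {
        j * ch(i) + ch(i + 1)
      }
      params[[sprintf("x_%d_%d", i, j)]] <-
        list(s1 = new_conv_bn(ch_in1, ch(i)), s2 = new_conv_bn(ch(i), ch(i)))
    }
    params$head <- list(W = matrix(rnorm(ch(0), 0, sqrt(2 / ch(0))), ch(0), 1),
                        b = 0)
    n_par <- sum(vapply(node_names(d), function(nm)
      sum(lengths(lapply(params[[nm]], function(p)
        c(p$W, p$b, p$gamma, p$beta)))), 0)) +
      length(params$head$W) + 1
    structure(list(params = params, config = config,
                   n_parameters = n_par, trained = FALSE, history = NULL),
              class = "exoct_unetpp")
  })
}

#' @export
print.exoct_unetpp <- function(x, ...) {
  cat(sprintf("<exoct_unetpp> depth %d, base %d channels, %d parameters%s\n",
              x$config$depth, x$config$base_channels, x$n_parameters,
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

check_divisible <- function(h, w, depth) {
  f <- 2^(depth - 1)
  if (h %% f != 0 || w %% f != 0)
    abort(sprintf(paste("input %dx%d is not divisible by 2^(depth-1) = %d;",
                        "pad the image (segment_eyes() reflection-pads",
                        "automatically)"), h, w, f))
}

# full forward pass; x is an (H*W) x 1 matrix in [0,1]
unetpp_fwd <- function(params, x, h, w, depth, train) {
  check_divisible(h, w, depth)
  ft <- list(); caches <- list(); sizes <- list()
  for (i in 0:(depth - 1)) {
    hi <- h / 2^i; wi <- w / 2^i
    sizes[[i + 1]] <- c(hi, wi)
    if (i == 0) {
      inp <- x
    } else {
      pl <- maxpool_fwd(ft[[sprintf("x_%d_%d", i - 1, 0)]], 2 * hi, 2 * wi)
      caches[[sprintf("pool_%d", i)]] <- pl
      inp <- pl$y
    }
    nm <- sprintf("x_%d_%d", i, 0)
    bf <- block_fwd(inp, hi, wi, params[[nm]], train)
    ft[[nm]] <- bf$y
    caches[[nm]] <- bf$cache
  }
  for (j in 1:(depth - 1)) for (i in 0:(depth - 1 - j)) {
    hi <- h / 2^i; wi <- w / 2^i
    up <- upsample_fwd(ft[[sprintf("x_%d_%d", i + 1, j - 1)]], hi, wi)
    skips <- lapply(0:(j - 1), function(jj) ft[[sprintf("x_%d_%d", i, jj)]])
    inp <- do.call(cbind, c(skips, list(up)))
    nm <- sprintf("x_%d_%d", i, j)
    bf <- block_fwd(inp, hi, wi, params[[nm]], train)
    ft[[nm]] <- bf$y
    caches[[nm]] <- bf$cache
  }
  top <- ft[[sprintf("x_0_%d", depth - 1)]]
  z <- top %*% params$head$W + params$head$b
  p <- 1 / (1 + exp(-z))
  list(p = p, ft = ft, caches = caches, top = top)
}

# backward from dL/dp; returns gradients congruent with params
unetpp_bwd <- function(params, fwd, dLdp, h, w, depth) {
  p <- fwd$p
  dz <- dLdp * p * (1 - p)
  grads <- list(head = list(W = crossprod(fwd$top, dz), b = sum(dz)))
  dft <- list()
  addg <- function(acc, nm, d) {
    if (is.null(acc[[nm]])) acc[[nm]] <- d else acc[[nm]] <- acc[[nm]] + d
    acc
  }
  dft <- addg(dft, sprintf("x_0_%d", depth - 1), dz %*% t(params$head$W))
  base <- ncol(fwd$ft$x_0_0)
  chn <- function(i) base * 2^i
  for (j in (depth - 1):1) for (i in (depth - 1 - j):0) {
    nm <- sprintf("x_%d_%d", i, j)
    hi <- h / 2^i; wi <- w / 2^i
    bb <- block_bwd(dft[[nm]], fwd$caches[[nm]], params[[nm]], hi, wi)
    grads[[nm]] <- bb$grads
    dinp <- bb$dx
    # split the concatenated input gradient: j skips at ch(i), then up at ch(i+1)
    pos <- 0L
    for (jj in 0:(j - 1)) {
      dft <- addg(dft, sprintf("x_%d_%d", i, jj),
                  dinp[, pos + seq_len(chn(i)), drop = FALSE])
      pos <- pos + chn(i)
    }
    dup <- dinp[, pos + seq_len(chn(i + 1)), drop = FALSE]
    dft <- addg(dft, sprintf("x_%d_%d", i + 1, j - 1),
                upsample_bwd(dup, hi, wi))
  }
  for (i in (depth - 1):0) {
    nm <- sprintf("x_%d_%d", i, 0)
    hi <- h / 2^i; wi <- w / 2^i
    bb <- block_bwd(dft[[nm]], fwd$caches[[nm]], params[[nm]], hi, wi)
    grads[[nm]] <- bb$grads
    if (i > 0) {
      dpooled <- maxpool_bwd(bb$dx, fwd$caches[[sprintf("pool_%d", i)]],
                             2 * hi, 2 * wi, ncol(bb$dx))
      dft <- addg(dft, sprintf("x_%d_%d", i - 1, 0), dpooled)
    }
  }
  grads
}

dice_loss_grad <- function(p, t) {
  den <- sum(p) + sum(t)
  if (den == 0) return(list(loss = 0, grad = p * 0))
  inter <- sum(p * t)
  list(loss = 1 - 2 * inter / den,
       grad = -2 * (t * den - inter) / den^2)
}

# Adam with per-epoch multiplicative LR decay
adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v, path) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        p[[nm]] <- p[[nm]] - lr * (m[[nm]] / bc1) / (sqrt(v[[nm]] / bc2) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v, character(0))
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) grads_add(a[[nm]], b[[nm]])
               else a[[nm]] + b[[nm]]
  }
  a
}

grads_scale <- function(g, s) rapply(g, function(x) x * s, how = "replace")

as_train_pair <- function(p) {
  img <- if (inherits(p$slice %||% p$image, "ct_slice"))
    (p$slice %||% p$image)$pixels else (p$slice %||% p$image)
  list(x = matrix(img / 255, length(img), 1), mask = p$mask,
       h = nrow(img), w = ncol(img))
}

#' Train the U-Net++ eye segmenter
#'
#' Minimizes the soft Dice loss with Adam; the learning rate is multiplied
#' by `lr_decay_per_epoch` after every epoch. Gradients are averaged over
#' mini-batches of `batch_size` images (batch-norm statistics are computed
#' per image). The returned model carries the weights that achieved the best
#' validation loss (best training loss, with a warning, when no validation
#' set is given) and a per-epoch loss history.
#'
#' @param train List of pairs `list(image = <matrix or ct_slice>,
#'   mask = <logical matrix>)` (a [render_phantom()] sample works directly:
#'   pass `list(image = s$slice, mask = s$eye_mask_true)`).
#' @param val Validation pairs in the same format (may be empty).
#' @param config A [seg_train_config()].
#' @return A trained `exoct_unetpp`; `$history` is a tibble with columns
#'   `epoch`, `train_loss`, `val_loss`, `lr`.
#' @export
train_segmenter <- function(train, val = list(), config = seg_train_config()) {
  if (length(train) == 0) abort("training set is empty")
  model <- build_unetpp(config)
  pairs <- lapply(train, as_train_pair)
  vpairs <- lapply(val, as_train_pair)
  for (p in c(pairs, vpairs)) {
    if (!identical(dim(p$mask), c(p$h, p$w)))
      abort("mask and image grids differ")
    check_divisible(p$h, p$w, config$depth)
  }
  if (length(vpairs) == 0)
    warn("validation set empty; checkpointing on training loss")
  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params)
  hist <- vector("list", config$epochs)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate * config$lr_decay_per_epoch^(epoch - 1)
      ord <- sample(length(pairs))
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        acc <- NULL
        for (ii in b) {
          pr <- pairs[[ii]]
          fwd <- unetpp_fwd(params, pr$x, pr$h, pr$w, config$depth, TRUE)
          lg <- dice_loss_grad(fwd$p, as.numeric(pr$mask))
          losses <- c(losses, lg$loss)
          g <- unetpp_bwd(params, fwd, matrix(lg$grad, ncol = 1),
                          pr$h, pr$w, config$depth)
          acc <- grads_add(acc, g)
          params <- update_running_stats(
            params, fwd$caches[node_names(config$depth)])
        }
        st <- adam_step(params, grads_scale(acc, 1 / length(b)), state, lr)
        params <- st$params
        state <- st$state
      }
      val_loss <- if (length(vpairs)) {
        mean(vapply(vpairs, function(pr) {
          fwd <- unetpp_fwd(params, pr$x, pr$h, pr$w, config$depth, FALSE)
          dice_loss_grad(fwd$p, as.numeric(pr$mask))$loss
        }, 0))
      } else NA_real_
      sel_loss <- if (is.na(val_loss)) mean(losses) else val_loss
      if (sel_loss < best$loss) best <- list(loss = sel_loss, params = params)
      hist[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                              val_loss = val_loss, lr = lr)
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$history <- purrr::list_rbind(hist)
  model
}

pad_reflect <- function(m, ph, pw) {
  h <- nrow(m); w <- ncol(m)
  if (ph > 0) m <- rbind(m, m[seq(h - 1, by = -1, length.out = ph), , drop = FALSE])
  if (pw > 0) m <- cbind(m, m[, seq(w - 1, by = -1, length.out = pw), drop = FALSE])
  m
}

#' Oracle and threshold-band segmenters
#'
#' `oracle_segmenter()` wraps a known ground-truth mask so the geometric
#' pipeline can be exercised independently of learning;
#' `threshold_segmenter()` is a crude intensity-band fallback.
#'
#' @param mask Logical ground-truth eye mask.
#' @return A segmenter usable with [segment_eyes()].
#' @export
oracle_segmenter <- function(mask) {
  structure(list(mask = stopifnot_mask(mask)), class = "oracle_segmenter")
}

#' @rdname oracle_segmenter
#' @param lo,hi Inclusive intensity band taken as eye tissue.
#' @export
threshold_segmenter <- function(lo = 120, hi = 180) {
  structure(list(lo = lo, hi = hi), class = "threshold_segmenter")
}

#' Segment the eye region of a CT slice
#'
#' Applies a segmenter to a canonical 8-bit slice and returns the per-pixel
#' foreground probability and the binarized mask (probability >= 0.5).
#' U-Net++ input is scaled to \[0, 1\] and reflection-padded to a multiple of
#' `2^(depth-1)` if needed, with the output cropped back to the input grid.
#'
#' @param slice A [ct_slice()].
#' @param segmenter An [oracle_segmenter()], [threshold_segmenter()] or
#'   trained [build_unetpp()] model.
#' @return Object of class `seg_result`: `probability`, `mask`, `source`.
#' @export
segment_eyes <- function(slice, segmenter) {
  stopifnot(inherits(slice, "ct_slice"))
  img <- slice$pixels
  if (inherits(segmenter, "oracle_segmenter")) {
    same_shape(img, segmenter$mask, c("slice", "oracle mask"))
    res <- list(probability = segmenter$mask * 1, mask = segmenter$mask,
                source = "oracle")
  } else if (inherits(segmenter, "threshold_segmenter")) {
    m <- img >= segmenter$lo & img <= segmenter$hi
    res <- list(probability = m * 1, mask = m, source = "threshold_fallback")
  } else if (inherits(segmenter, "exoct_unetpp")) {
    d <- segmenter$config$depth
    f <- 2^(d - 1)
    h <- nrow(img); w <- ncol(img)
    ph <- (f - h %% f) %% f; pw <- (f - w %% f) %% f
    x <- pad_reflect(img / 255, ph, pw)
    fwd <- unetpp_fwd(segmenter$params, matrix(x, length(x), 1),
                      nrow(x), ncol(x), d, train = FALSE)
    prob <- matrix(fwd$p, nrow(x), ncol(x))[seq_len(h), seq_len(w)]
    res <- list(probability = prob, mask = prob >= 0.5, source = "unetpp")
  } else {
    abort("unknown segmenter type")
  }
  structure(res, class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("<seg_result> source %s, %d foreground px\n",
              x$source, sum(x$mask)))
  invisible(x)
}
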
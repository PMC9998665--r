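# Minimal CNN engine used by the U-Net++ segmenter.
#
# Feature maps are matrices of shape (H*W) x C in column-major pixel order,
# with the raster height/width carried alongside. Convolutions are 3x3
# same-padding via im2col + BLAS matmul; weights are (9*Cin) x Cout matrices
# whose row order is channel-major, kernel-offset-minor, matching im2col.

nn_offsets <- local({
  memo <- new.env(parent = emptyenv())
  function(h, w) {
    key <- paste0(h, "x", w)
    if (!is.null(memo[[key]])) return(memo[[key]])
    hp <- h + 2L
    inner <- function(dr, dc)
      as.vector(outer(seq_len(h) + dr, (seq_len(w) + dc - 1L) * hp,
                      `+`))
    offs <- vector("list", 9L)
    k <- 0L
    for (dc in 0:2) for (dr in 0:2) {
      k <- k + 1L
      offs[[k]] <- inner(dr, dc)
    }
    interior <- as.vector(outer(seq_len(h) + 1L, (seq_len(w)) * hp, `+`))
    res <- list(offs = offs, interior = interior, hp = hp, wp = w + 2L)
    memo[[key]] <- res
    res
  }
})

im2col3 <- function(x, h, w) {
  ch <- ncol(x)
  o <- nn_offsets(h, w)
  xp <- matrix(0, o$hp * o$wp, ch)
  xp[o$interior, ] <- x
  col <- matrix(0, h * w, 9L * ch)
  cidx <- (seq_len(ch) - 1L) * 9L
  for (k in 1:9) col[, cidx + k] <- xp[o$offs[[k]], , drop = FALSE]
  col
}

col2im3 <- function(dcol, h, w, ch) {
  o <- nn_offsets(h, w)
  dxp <- matrix(0, o$hp * o$wp, ch)
  cidx <- (seq_len(ch) - 1L) * 9L
  for (k in 1:9)
    dxp[o$offs[[k]], ] <- dxp[o$offs[[k]], , drop = FALSE] +
      dcol[, cidx + k, drop = FALSE]
  dxp[o$interior, , drop = FALSE]
}

conv_fwd <- function(x, h, w, W, b) {
  col <- im2col3(x, h, w)
  y <- col %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = y, col = col)
}

conv_bwd <- function(dy, cache, W, h, w, ch_in) {
  list(dW = crossprod(cache$col, dy),
       db = colSums(dy),
       dx = col2im3(dy %*% t(W), h, w, ch_in))
}

bn_fwd <- function(x, p, train, eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, istd, `*`)
    y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
    list(y = y, xhat = xhat, istd = istd, mu = mu, v = v)
  } else {
    xhat <- sweep(sweep(x, 2, p$rmean), 2, 1 / sqrt(p$rvar + eps), `*`)
    list(y = sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`))
  }
}

bn_bwd <- function(dy, cache, gamma) {
  dxhat <- sweep(dy, 2, gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, `*`)
  dx <- sweep(dx, 2, cache$istd, `*`)
  list(dx = dx, dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

pool_idx <- local({
  memo <- new.env(parent = emptyenv())
  function(h, w) {
    key <- paste0(h, "x", w)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                  function(d) as.vector(outer(seq(1L, h, 2L) + d[1],
                                              (seq(1L, w, 2L) + d[2] - 1L) * h,
                                              `+`)))
    memo[[key]] <- res
    res
  }
})

maxpool_fwd <- function(x, h, w) {
  ix <- pool_idx(h, w)
  xs <- lapply(ix, function(i) x[i, , drop = FALSE])
  # argmax with deterministic first-max-wins tie-break
  arg <- matrix(1L, nrow(xs[[1]]), ncol(xs[[1]]))
  best <- xs[[1]]
  for (m in 2:4) {
    better <- xs[[m]] > best
    arg[better] <- m
    best[better] <- xs[[m]][better]
  }
  list(y = best, arg = arg)
}

maxpool_bwd <- function(dy, cache, h, w, ch) {
  ix <- pool_idx(h, w)
  dx <- matrix(0, h * w, ch)
  for (m in 1:4) {
    sel <- cache$arg == m
    d <- dy
    d[!sel] <- 0
    dx[ix[[m]], ] <- dx[ix[[m]], , drop = FALSE] + d
  }
  dx
}

upsample_fwd <- function(x, h2, w2) {
  ix <- pool_idx(h2, w2)
  y <- matrix(0, h2 * w2, ncol(x))
  for (m in 1:4) y[ix[[m]], ] <- x
  y
}

upsample_bwd <- function(dy, h2, w2) {
  ix <- pool_idx(h2, w2)
  dy[ix[[1]], , drop = FALSE] + dy[ix[[2]], , drop = FALSE] +
    dy[ix[[3]], , drop = FALSE] + dy[ix[[4]], , drop = FALSE]
}

new_conv_bn <- function(ch_in, ch_out, kaiming_sd = sqrt(2 / (9 * ch_in))) {
  list(W = matrix(rnorm(9 * ch_in * ch_out, 0, kaiming_sd), 9 * ch_in, ch_out),
       b = numeric(ch_out),
       gamma = rep(1, ch_out), beta = numeric(ch_out),
       rmean = numeric(ch_out), rvar = rep(1, ch_out))
}

# conv3x3 -> batch norm -> ReLU, twice
block_fwd <- function(x, h, w, blk, train) {
  cache <- list()
  for (s in 1:2) {
    p <- blk[[s]]
    cv <- conv_fwd(x, h, w, p$W, p$b)
    bn <- bn_fwd(cv$y, p, train)
    relu <- bn$y > 0
    x <- bn$y * relu
    cache[[s]] <- list(conv = cv, bn = bn, relu = relu,
                       ch_in = ncol(cv$col) / 9L)
  }
  list(y = x, cache = cache)
}

block_bwd <- function(dy, cache, blk, h, w) {
  grads <- list()
  for (s in 2:1) {
    cc <- cache[[s]]
    dy <- dy * cc$relu
    bnb <- bn_bwd(dy, cc$bn, blk[[s]]$gamma)
    cvb <- conv_bwd(bnb$dx, cc$conv, blk[[s]]$W, h, w, cc$ch_in)
    grads[[paste0("s", s)]] <- list(W = cvb$dW, b = cvb$db,
                                    gamma = bnb$dgamma, beta = bnb$dbeta)
    dy <- cvb$dx
  }
  list(dx = dy, grads = grads)
}

update_running_stats <- function(params, caches, momentum = 0.1) {
  for (nm in names(caches)) {
    for (s in 1:2) {
      bn <- caches[[nm]][[s]]$bn
      params[[nm]][[s]]$rmean <-
        (1 - momentum) * params[[nm]][[s]]$rmean + momentum * bn$mu
      params[[nm]][[s]]$rvar <-
        (1 - momentum) * params[[nm]][[s]]$rvar + momentum * bn$v
    }
  }
  params
}
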
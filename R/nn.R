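## Internal neural-network engine.
##
## Layers operate on arrays of shape (channels, length, batch). Convolutions
## use "same" zero padding and are computed as one BLAS matrix product per
## layer via im2col; batch normalisation is per channel over batch x time.
## Everything needed for training (forward caches, analytic gradients, Adam)
## lives here; the user-facing surface is in model.R.

.nnIm2col <- function(x, k) {
  d <- dim(x); C <- d[1L]; L <- d[2L]; N <- d[3L]
  pl <- (k - 1L) %/% 2L
  xp <- array(0, c(C, L + k - 1L, N))
  xp[, (pl + 1L):(pl + L), ] <- x
  out <- array(0, c(C, k, L * N))
  for (j in seq_len(k)) out[, j, ] <- xp[, j:(j + L - 1L), ]
  dim(out) <- c(C * k, L * N)
  out
}

.nnConvForward <- function(x, W) {
  d <- dim(x); dw <- dim(W)            # W: (C_out, C_in, k)
  k <- dw[3L]
  xc <- .nnIm2col(x, k)
  y <- matrix(W, nrow = dw[1L]) %*% xc
  dim(y) <- c(dw[1L], d[2L], d[3L])
  list(y = y, cache = list(xc = xc, dimx = d, k = k))
}

.nnConvBackward <- function(dy, W, cache) {
  d <- cache$dimx; dw <- dim(W); k <- cache$k
  C <- d[1L]; L <- d[2L]; N <- d[3L]
  dym <- matrix(dy, nrow = dw[1L])
  dW <- dym %*% t(cache$xc)
  dim(dW) <- dw
  dxc <- crossprod(matrix(W, nrow = dw[1L]), dym)   # (C*k, L*N)
  dim(dxc) <- c(C, k, L, N)
  pl <- (k - 1L) %/% 2L
  dxp <- array(0, c(C, L + k - 1L, N))
  for (j in seq_len(k))
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), ] + dxc[, j, , ]
  list(dx = dxp[, (pl + 1L):(pl + L), , drop = FALSE], dW = dW)
}

.nnBnForward <- function(x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  d <- dim(x); C <- d[1L]; M <- d[2L] * d[3L]
  xm <- matrix(x, nrow = C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    if (is.null(state$mu)) {           # first batch primes the running stats
      state$mu <- mu; state$v <- v
    } else {
      state$mu <- (1 - momentum) * state$mu + momentum * mu
      state$v <- (1 - momentum) * state$v + momentum * v
    }
  } else if (is.null(state$mu)) {      # untrained model: fall back to batch
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
  } else {
    mu <- state$mu; v <- state$v
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = xhat, istd = istd, d = d))
}

.nnBnBackward <- function(dy, gamma, cache) {
  d <- cache$d; C <- d[1L]; M <- d[2L] * d[3L]
  dym <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dx <- (gamma * cache$istd) *
    (dym - dbeta / M - xhat * (dgamma / M))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.nnPoolForward <- function(x, p) {
  if (p == 1L) return(list(y = x, cache = NULL))
  d <- dim(x); C <- d[1L]; L <- d[2L]; N <- d[3L]
  Lo <- L %/% p
  xm <- x[, seq_len(Lo * p), , drop = FALSE]
  dim(xm) <- c(C, p, Lo, N)
  cur <- xm[, 1L, , , drop = TRUE]
  dim(cur) <- c(C, Lo, N)
  idx <- array(1L, c(C, Lo, N))
  for (j in seq_len(p)[-1L]) {
    sl <- xm[, j, , , drop = TRUE]
    dim(sl) <- c(C, Lo, N)
    w <- sl > cur
    cur[w] <- sl[w]
    idx[w] <- j
  }
  list(y = cur, cache = list(idx = idx, dimx = d, p = p, Lo = Lo))
}

.nnPoolBackward <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  d <- cache$dimx; p <- cache$p; Lo <- cache$Lo
  C <- d[1L]; N <- d[3L]
  dxp <- array(0, c(C, p, Lo, N))
  for (j in seq_len(p)) {
    m <- cache$idx == j
    sl <- array(0, c(C, Lo, N))
    sl[m] <- dy[m]
    dxp[, j, , ] <- sl
  }
  dim(dxp) <- c(C, p * Lo, N)
  if (p * Lo < d[2L]) {
    full <- array(0, d)
    full[, seq_len(p * Lo), ] <- dxp
    dxp <- full
  }
  dxp
}

.nnSoftmax <- function(z) {
  z <- z - matrix(apply(z, 2L, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

## Full forward pass. Returns probabilities (nClasses x N) and, when
## `training`, the caches needed for the backward pass.
.nnForward <- function(clf, x, training = FALSE) {
  cfg <- clf@config
  params <- clf@params
  state <- clf@state
  nb <- length(cfg@filters)
  caches <- if (training) vector("list", nb) else NULL
  h <- x
  for (b in seq_len(nb)) {
    cv <- .nnConvForward(h, params[[paste0("W", b)]])
    bnState <- if (b <= length(state$bn)) state$bn[[b]] else list()
    bn <- .nnBnForward(cv$y, params[[paste0("g", b)]],
                       params[[paste0("b", b)]], bnState, training)
    state$bn[[b]] <- bn$state
    relu <- pmax(bn$y, 0)
    pl <- .nnPoolForward(relu, cfg@pools[b])
    if (training)
      caches[[b]] <- list(conv = cv$cache, bn = bn$cache,
                          mask = bn$y > 0, pool = pl$cache)
    h <- pl$y
  }
  d <- dim(h)
  z <- matrix(h, nrow = d[1L] * d[2L])          # flatten -> (C*L, N)
  h1 <- NULL
  if (cfg@fcWidth > 0L) {                       # optional hidden dense layer
    a1 <- params$Wh %*% z + params$bh
    h1 <- pmax(a1, 0)
    logits <- params$Wfc %*% h1 + params$bfc
  } else {
    logits <- params$Wfc %*% z + params$bfc
  }
  list(probs = .nnSoftmax(logits), caches = caches, flat = z, h1 = h1,
       hdim = d, state = state)
}

## Backward pass from dlogits (nClasses x N); returns gradient list keyed
## like params.
.nnBackward <- function(clf, fwd, dlogits) {
  cfg <- clf@config
  params <- clf@params
  if (cfg@fcWidth > 0L) {
    grads <- list(Wfc = dlogits %*% t(fwd$h1), bfc = rowSums(dlogits))
    dh1 <- crossprod(params$Wfc, dlogits) * (fwd$h1 > 0)
    grads$Wh <- dh1 %*% t(fwd$flat)
    grads$bh <- rowSums(dh1)
    dh <- crossprod(params$Wh, dh1)
  } else {
    grads <- list(Wfc = dlogits %*% t(fwd$flat), bfc = rowSums(dlogits))
    dh <- crossprod(params$Wfc, dlogits)
  }
  dim(dh) <- fwd$hdim
  for (b in rev(seq_along(cfg@filters))) {
    cc <- fwd$caches[[b]]
    dh <- .nnPoolBackward(dh, cc$pool)
    dh <- dh * cc$mask
    bn <- .nnBnBackward(dh, params[[paste0("g", b)]], cc$bn)
    grads[[paste0("g", b)]] <- bn$dgamma
    grads[[paste0("b", b)]] <- bn$dbeta
    cv <- .nnConvBackward(bn$dx, params[[paste0("W", b)]], cc$conv)
    grads[[paste0("W", b)]] <- cv$dW
    dh <- cv$dx
  }
  grads
}

## Adam update, in place on the param list; opt carries first/second moments.
.nnAdamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) { opt$m[[nm]] <- g * 0; opt$v[[nm]] <- g * 0 }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
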
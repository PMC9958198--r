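# Internal neural-network primitives.
#
# Layers operate on dense arrays laid out as (channels, height, width, batch);
# 1-D signal layers reuse the same layout with height fixed to 1.  All heavy
# arithmetic reduces to BLAS-backed matrix products; convolutions are computed
# by accumulating one GEMM per kernel offset, which avoids an explicit im2col
# buffer while keeping the inner loop at kh*kw R-level iterations.
#
# Each module is a plain list: $type, $params (learnable arrays), $buffers
# (running statistics), plus static hyper-parameters.  Forward passes return
# the output, a cache for the backward pass and (for batch norm in training
# mode) updated buffers; the caller threads buffers through functionally.

.modBN <- function(C) {
  list(type = "bn",
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       buffers = list(rm = rep(0, C), rv = rep(1, C)),
       eps = 1e-5, mom = 0.1)
}

.modConv <- function(Cin, Cout, kh, kw, ph, pw) {
  # He initialization: sd = sqrt(2 / fan_in)
  fanIn <- Cin * kh * kw
  W <- array(stats::rnorm(Cout * Cin * kh * kw, sd = sqrt(2 / fanIn)),
             c(Cout, Cin, kh, kw))
  list(type = "conv", params = list(W = W, b = rep(0, Cout)),
       kh = kh, kw = kw, ph = ph, pw = pw)
}

.modDropout <- function(p) list(type = "dropout", p = p)

.modPool <- function(rh, rw) list(type = "pool", rh = rh, rw = rw)

.modReLU <- function() list(type = "relu")

.modLinear <- function(nin, nout, zeroInit = FALSE) {
  # The classification head starts at zero so an untrained model emits
  # uniform log-probabilities and attributions carry no initialization bias;
  # hidden layers use He initialization.
  W <- if (zeroInit) matrix(0, nout, nin)
       else matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  list(type = "linear", params = list(W = W, b = rep(0, nout)))
}

## ---- convolution -----------------------------------------------------------

.convForward <- function(mod, x) {
  y <- .cppConvForward(x, mod$params$W, mod$params$b,
                       mod$kh, mod$kw, mod$ph, mod$pw)
  list(y = y, cache = list(x = x, od = dim(y)))
}

.convBackward <- function(mod, dy, cache, needParam = TRUE, needInput = TRUE) {
  dim(dy) <- cache$od
  res <- .cppConvBackward(cache$x, mod$params$W, dy,
                          mod$kh, mod$kw, mod$ph, mod$pw,
                          needParam, needInput)
  grads <- if (needParam) list(W = res$dW, b = res$db) else NULL
  list(dx = if (needInput) res$dx else NULL, grads = grads)
}

## ---- batch normalization ---------------------------------------------------

.bnForward <- function(mod, x, train) {
  C <- dim(x)[1L]
  n <- length(x) / C
  xm <- x
  dim(xm) <- c(C, n)
  g <- mod$params$gamma
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    ivar <- 1 / sqrt(v + mod$eps)
    xhat <- (xm - mu) * ivar
    y <- g * xhat + mod$params$beta
    dim(y) <- dim(x)
    nb <- max(n - 1, 1)
    buffers <- list(rm = (1 - mod$mom) * mod$buffers$rm + mod$mom * mu,
                    rv = (1 - mod$mom) * mod$buffers$rv + mod$mom * v * n / nb)
    list(y = y, cache = list(xhat = xhat, ivar = ivar, n = n, train = TRUE),
         buffers = buffers)
  } else {
    ivar <- 1 / sqrt(mod$buffers$rv + mod$eps)
    xhat <- (xm - mod$buffers$rm) * ivar
    y <- g * xhat + mod$params$beta
    dim(y) <- dim(x)
    list(y = y, cache = list(xhat = xhat, ivar = ivar, n = n, train = FALSE),
         buffers = NULL)
  }
}

.bnBackward <- function(mod, dy, cache, needParam = TRUE, needInput = TRUE) {
  C <- length(mod$params$gamma)
  od <- dim(dy)
  dym <- dy
  dim(dym) <- c(C, cache$n)
  g <- mod$params$gamma
  grads <- NULL
  if (needParam)
    grads <- list(gamma = rowSums(dym * cache$xhat), beta = rowSums(dym))
  dx <- NULL
  if (needInput) {
    if (cache$train) {
      dxhat <- g * dym
      mdx <- rowMeans(dxhat)
      mdxx <- rowMeans(dxhat * cache$xhat)
      dx <- cache$ivar * (dxhat - mdx - cache$xhat * mdxx)
    } else {
      dx <- (g * cache$ivar) * dym
    }
    dim(dx) <- od
  }
  list(dx = dx, grads = grads)
}

## ---- pooling (max, window 2 along selected axes, stride = window) ----------

.poolForward <- function(mod, x) {
  res <- .cppPoolForward(x, mod$rh, mod$rw)
  list(y = res$y, cache = list(idx = res$idx, inDim = dim(x)))
}

.poolBackward <- function(mod, dy, cache) {
  .cppPoolBackward(dy, cache$idx, cache$inDim)
}

## ---- elementwise layers ----------------------------------------------------

.reluForward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, cache = mask)
}

.dropoutForward <- function(mod, x, train) {
  if (!train || mod$p <= 0) return(list(y = x, cache = NULL))
  keep <- (stats::runif(length(x)) >= mod$p) / (1 - mod$p)
  list(y = x * keep, cache = keep)
}

## ---- generic sequential dispatch -------------------------------------------

.moduleForward <- function(mod, x, train) {
  switch(mod$type,
    bn = .bnForward(mod, x, train),
    conv = .convForward(mod, x),
    dropout = .dropoutForward(mod, x, train),
    pool = .poolForward(mod, x),
    relu = .reluForward(x),
    stop("unknown module type: ", mod$type))
}

.moduleBackward <- function(mod, dy, cache, needParam = TRUE,
                            needInput = TRUE) {
  switch(mod$type,
    bn = .bnBackward(mod, dy, cache, needParam, needInput),
    conv = .convBackward(mod, dy, cache, needParam, needInput),
    dropout = {
      if (!is.null(cache)) dy <- dy * cache
      list(dx = dy, grads = NULL)
    },
    pool = list(dx = .poolBackward(mod, dy, cache), grads = NULL),
    relu = {
      dy[!cache] <- 0
      list(dx = dy, grads = NULL)
    },
    stop("unknown module type: ", mod$type))
}

.seqForward <- function(mods, x, train) {
  caches <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    res <- .moduleForward(mods[[i]], x, train)
    x <- res$y
    caches[[i]] <- res$cache
    if (!is.null(res$buffers)) mods[[i]]$buffers <- res$buffers
  }
  list(y = x, caches = caches, mods = mods)
}

.seqBackward <- function(mods, caches, dy, needParam = TRUE,
                         needInput = TRUE) {
  grads <- vector("list", length(mods))
  for (i in rev(seq_along(mods))) {
    lastInput <- i == 1L && !needInput
    res <- .moduleBackward(mods[[i]], dy, caches[[i]], needParam,
                           needInput = !lastInput)
    dy <- res$dx
    grads[i] <- list(res$grads)  # keep NULL placeholders for param-free layers
  }
  list(dx = dy, grads = grads)
}

## ---- dense head helpers ----------------------------------------------------

.linearForward <- function(mod, x) {
  list(y = mod$params$W %*% x + mod$params$b, cache = x)
}

.linearBackward <- function(mod, dy, cache, needParam = TRUE,
                            needInput = TRUE) {
  grads <- if (needParam) list(W = dy %*% t(cache), b = rowSums(dy)) else NULL
  dx <- if (needInput) crossprod(mod$params$W, dy) else NULL
  list(dx = dx, grads = grads)
}

.logSoftmax <- function(z) {
  mx <- apply(z, 2L, max)
  zs <- sweep(z, 2L, mx)
  lse <- log(colSums(exp(zs)))
  sweep(zs, 2L, lse)
}
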
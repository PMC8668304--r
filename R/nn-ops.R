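# Internal minimal neural-network engine.
#
# Activations are stored as dense matrices of shape (N*P, C): one row per
# pixel of each of N images (column-major within an image), one column per
# channel. Convolutions are computed by im2col gathers + BLAS matrix
# multiplication; gather index vectors depend only on (H, W, kernel, N) and
# are cached. Row N*P+1 of a zero-extended activation matrix plays the role
# of the zero-padding pixel.

.geomCache <- new.env(parent = emptyenv())

gatherConv <- function(h, w, k, n) {
  key <- paste("conv", h, w, k, n, sep = "_")
  got <- .geomCache[[key]]
  if (!is.null(got)) return(got)
  P <- h * w
  r <- (k - 1L) %/% 2L
  ri <- rep(seq_len(h), times = w)
  ci <- rep(seq_len(w), each = h)
  idxs <- vector("list", k * k)
  m <- 0L
  for (dj in seq.int(-r, r)) for (di in seq.int(-r, r)) {
    m <- m + 1L
    r2 <- ri + di; c2 <- ci + dj
    base <- ifelse(r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w,
                   (c2 - 1L) * h + r2, NA_integer_)
    big <- rep(base, n) + rep((seq_len(n) - 1L) * P, each = P)
    big[is.na(big)] <- n * P + 1L
    idxs[[m]] <- big
  }
  res <- list(idx = idxs, valid = lapply(idxs, function(v) v <= n * P))
  .geomCache[[key]] <- res
  res
}

# 2x2 non-overlapping window indices: maps each (h/2 x w/2) output pixel to
# its 4 source pixels in the h x w raster. Also reused (transposed roles) to
# scatter 2x stride-2 transposed-convolution outputs.
gatherPool <- function(h, w, n) {
  key <- paste("pool", h, w, n, sep = "_")
  got <- .geomCache[[key]]
  if (!is.null(got)) return(got)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  P <- h * w; P2 <- h2 * w2
  ro <- rep(seq_len(h2), times = w2)
  co <- rep(seq_len(w2), each = h2)
  idxs <- vector("list", 4L)
  m <- 0L
  for (dj in 0:1) for (di in 0:1) {
    m <- m + 1L
    base <- (2L * co - 2L + dj) * h + (2L * ro - 1L + di)
    idxs[[m]] <- rep(base, n) + rep((seq_len(n) - 1L) * P, each = P2)
  }
  res <- list(idx = idxs, h2 = h2, w2 = w2)
  .geomCache[[key]] <- res
  res
}

# column-wise broadcasting without sweep()'s aperm overhead
addCols <- function(X, v) X + rep(v, each = nrow(X))
mulCols <- function(X, v) X * rep(v, each = nrow(X))

glorotMatrix <- function(nrow, ncol, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

layerConv <- function(k, cin, cout) {
  list(type = "conv", k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout),
       W = glorotMatrix(k * k * cin, cout, k * k * cin, k * k * cout),
       b = numeric(cout), frozen = FALSE)
}

layerBN <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), eps = 1e-5, momentum = 0.1,
       frozen = FALSE)
}

layerReLU <- function() list(type = "relu", frozen = FALSE)
layerPool <- function() list(type = "pool", frozen = FALSE)

layerTConv <- function(cin, cout) {
  list(type = "tconv", cin = as.integer(cin), cout = as.integer(cout),
       W = glorotMatrix(cin, 4L * cout, cin, 4L * cout),
       b = numeric(cout), frozen = FALSE)
}

layerGAP <- function() list(type = "gap", frozen = FALSE)
layerDropout <- function(rate) list(type = "dropout", rate = rate, frozen = FALSE)

layerFC <- function(cin, cout) {
  list(type = "fc", cin = as.integer(cin), cout = as.integer(cout),
       W = glorotMatrix(cin, cout, cin, cout), b = numeric(cout),
       frozen = FALSE)
}

# inception-style block: parallel convolutions (1x1, 3x3, 5x5) over the same
# input, outputs concatenated along channels
layerInception <- function(cin, couts, ks = c(1L, 3L, 5L)) {
  list(type = "inception",
       branches = Map(function(k, co) layerConv(k, cin, co), ks, couts),
       cout = sum(couts), frozen = FALSE)
}

convForward <- function(layer, X, h, w, n) {
  g <- gatherConv(h, w, layer$k, n)
  cin <- layer$cin
  k2 <- layer$k^2
  Xz <- rbind(X, matrix(0, 1L, cin))
  Xcol <- matrix(0, nrow(X), k2 * cin)
  for (m in seq_len(k2))
    Xcol[, ((m - 1L) * cin + 1L):(m * cin)] <- Xz[g$idx[[m]], , drop = FALSE]
  Y <- Xcol %*% layer$W
  Y <- addCols(Y, layer$b)
  list(out = Y, cache = list(Xcol = Xcol, h = h, w = w, n = n))
}

convBackward <- function(layer, cache, dY) {
  g <- gatherConv(cache$h, cache$w, layer$k, cache$n)
  cin <- layer$cin
  dXcol <- dY %*% t(layer$W)
  dX <- matrix(0, nrow(dY), cin)
  for (m in seq_len(layer$k^2)) {
    v <- g$valid[[m]]
    rows <- g$idx[[m]][v]
    # within one kernel offset the shift map is injective, so plain
    # subscripted addition accumulates correctly
    dX[rows, ] <- dX[rows, ] +
      dXcol[v, ((m - 1L) * cin + 1L):(m * cin), drop = FALSE]
  }
  list(dX = dX,
       grads = list(W = crossprod(cache$Xcol, dY), b = colSums(dY)))
}

bnForward <- function(layer, X, training) {
  if (training) {
    mu <- colMeans(X)
    Xc <- addCols(X, -mu)
    v <- colMeans(Xc * Xc)
    istd <- 1 / sqrt(v + layer$eps)
    xhat <- mulCols(Xc, istd)
    out <- addCols(mulCols(xhat, layer$gamma), layer$beta)
    list(out = out, cache = list(xhat = xhat, istd = istd),
         rmean = (1 - layer$momentum) * layer$rmean + layer$momentum * mu,
         rvar = (1 - layer$momentum) * layer$rvar + layer$momentum * v)
  } else {
    xhat <- mulCols(addCols(X, -layer$rmean),
                    1 / sqrt(layer$rvar + layer$eps))
    list(out = addCols(mulCols(xhat, layer$gamma), layer$beta),
         cache = NULL)
  }
}

bnBackward <- function(layer, cache, dY) {
  Nr <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- mulCols(dY, layer$gamma)
  t1 <- addCols(dxhat, -colSums(dxhat) / Nr)
  t2 <- mulCols(xhat, colSums(dxhat * xhat) / Nr)
  list(dX = mulCols(t1 - t2, cache$istd),
       grads = list(gamma = dgamma, beta = dbeta))
}

poolForward <- function(X, h, w, n) {
  g <- gatherPool(h, w, n)
  M <- X[g$idx[[1L]], , drop = FALSE]
  sel <- matrix(1L, nrow(M), ncol(M))
  for (m in 2:4) {
    Mk <- X[g$idx[[m]], , drop = FALSE]
    better <- Mk > M
    M[better] <- Mk[better]
    sel[better] <- m
  }
  list(out = M, h = g$h2, w = g$w2,
       cache = list(sel = sel, h = h, w = w, n = n, nIn = nrow(X)))
}

poolBackward <- function(cache, dY) {
  g <- gatherPool(cache$h, cache$w, cache$n)
  dX <- matrix(0, cache$nIn, ncol(dY))
  for (m in 1:4) {
    tmp <- dY * (cache$sel == m)
    dX[g$idx[[m]], ] <- dX[g$idx[[m]], ] + tmp
  }
  dX
}

tconvForward <- function(layer, X, h, w, n) {
  cout <- layer$cout
  Yb <- X %*% layer$W
  g <- gatherPool(2L * h, 2L * w, n)
  Y <- matrix(0, 4L * nrow(X), cout)
  for (m in 1:4)
    Y[g$idx[[m]], ] <- Yb[, ((m - 1L) * cout + 1L):(m * cout), drop = FALSE]
  Y <- addCols(Y, layer$b)
  list(out = Y, h = 2L * h, w = 2L * w,
       cache = list(X = X, h = h, w = w, n = n))
}

tconvBackward <- function(layer, cache, dY) {
  cout <- layer$cout
  g <- gatherPool(2L * cache$h, 2L * cache$w, cache$n)
  dYb <- matrix(0, nrow(cache$X), 4L * cout)
  for (m in 1:4)
    dYb[, ((m - 1L) * cout + 1L):(m * cout)] <- dY[g$idx[[m]], , drop = FALSE]
  list(dX = dYb %*% t(layer$W),
       grads = list(W = crossprod(cache$X, dYb), b = colSums(dY)))
}

gapForward <- function(X, h, w, n) {
  P <- h * w
  grp <- rep(seq_len(n), each = P)
  list(out = rowsum(X, grp, reorder = TRUE) / P, h = NA_integer_,
       w = NA_integer_, cache = list(P = P, n = n))
}

gapBackward <- function(cache, dY) {
  dY[rep(seq_len(cache$n), each = cache$P), , drop = FALSE] / cache$P
}

incForward <- function(layer, X, h, w, n) {
  outs <- vector("list", length(layer$branches))
  caches <- vector("list", length(layer$branches))
  for (i in seq_along(layer$branches)) {
    r <- convForward(layer$branches[[i]], X, h, w, n)
    outs[[i]] <- r$out
    caches[[i]] <- r$cache
  }
  list(out = do.call(cbind, outs), cache = caches)
}

incBackward <- function(layer, cache, dY) {
  dX <- NULL
  grads <- vector("list", length(layer$branches))
  off <- 0L
  for (i in seq_along(layer$branches)) {
    co <- layer$branches[[i]]$cout
    r <- convBackward(layer$branches[[i]], cache[[i]],
                      dY[, (off + 1L):(off + co), drop = FALSE])
    off <- off + co
    grads[[i]] <- r$grads
    dX <- if (is.null(dX)) r$dX else dX + r$dX
  }
  list(dX = dX, grads = list(branches = grads))
}

# Forward pass through a layer list. Returns the output, final spatial dims,
# per-layer caches for backprop, and the (possibly updated, for batch-norm
# running statistics) layer list.
nnForward <- function(layers, X, h, w, n, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    res <- switch(l$type,
      conv = convForward(l, X, h, w, n),
      bn = {
        r <- bnForward(l, X, training)
        if (training) {
          layers[[i]]$rmean <- r$rmean
          layers[[i]]$rvar <- r$rvar
        }
        r
      },
      relu = list(out = pmax(X, 0), cache = list(pos = X > 0)),
      pool = poolForward(X, h, w, n),
      tconv = tconvForward(l, X, h, w, n),
      gap = gapForward(X, h, w, n),
      dropout = if (training) {
        msk <- (matrix(runif(length(X)), nrow(X), ncol(X)) >= l$rate) /
          (1 - l$rate)
        list(out = X * msk, cache = list(m = msk))
      } else list(out = X, cache = list(m = 1)),
      fc = list(out = addCols(X %*% l$W, l$b), cache = list(X = X)),
      inception = incForward(l, X, h, w, n),
      stop("unknown layer type: ", l$type))
    caches[[i]] <- res$cache
    X <- res$out
    if (!is.null(res$h)) { h <- res$h; w <- res$w }
  }
  list(out = X, h = h, w = w, caches = caches, layers = layers)
}

nnBackward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dX <- dOut
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cch <- caches[[i]]
    res <- switch(l$type,
      conv = convBackward(l, cch, dX),
      bn = bnBackward(l, cch, dX),
      relu = list(dX = dX * cch$pos),
      pool = list(dX = poolBackward(cch, dX)),
      tconv = tconvBackward(l, cch, dX),
      gap = list(dX = gapBackward(cch, dX)),
      dropout = list(dX = dX * cch$m),
      fc = list(dX = dX %*% t(l$W),
                grads = list(W = crossprod(cch$X, dX), b = colSums(dX))),
      inception = incBackward(l, cch, dX))
    grads[i] <- list(res$grads)  # keep NULLs in place for param-free layers
    dX <- res$dX
  }
  list(grads = grads, dX = dX)
}

layerParamNames <- function(l) {
  switch(l$type,
         conv = , tconv = , fc = c("W", "b"),
         bn = c("gamma", "beta"),
         character(0))
}

adamInitLayer <- function(l) {
  if (l$type == "inception")
    return(list(branches = lapply(l$branches, adamInitLayer)))
  nm <- layerParamNames(l)
  st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
  names(st) <- nm
  st
}

adamInit <- function(layers) lapply(layers, adamInitLayer)

adamStepLayer <- function(l, g, st, lr, c1, c2, beta1, beta2, eps) {
  if (l$type == "inception") {
    for (i in seq_along(l$branches)) {
      r <- adamStepLayer(l$branches[[i]], g$branches[[i]], st$branches[[i]],
                         lr, c1, c2, beta1, beta2, eps)
      l$branches[[i]] <- r$l
      st$branches[[i]] <- r$st
    }
    return(list(l = l, st = st))
  }
  for (p in layerParamNames(l)) {
    st[[p]]$m <- beta1 * st[[p]]$m + (1 - beta1) * g[[p]]
    st[[p]]$v <- beta2 * st[[p]]$v + (1 - beta2) * g[[p]]^2
    l[[p]] <- l[[p]] - lr * (st[[p]]$m / c1) / (sqrt(st[[p]]$v / c2) + eps)
  }
  list(l = l, st = st)
}

adamStep <- function(layers, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    if (isTRUE(layers[[i]]$frozen) || is.null(grads[[i]])) next
    r <- adamStepLayer(layers[[i]], grads[[i]], state[[i]],
                       lr, c1, c2, beta1, beta2, eps)
    layers[[i]] <- r$l
    state[[i]] <- r$st
  }
  list(layers = layers, state = state)
}

countLayerParams <- function(l) {
  if (l$type == "inception")
    return(sum(vapply(l$branches, countLayerParams, numeric(1))))
  sum(vapply(layerParamNames(l), function(p) length(l[[p]]), numeric(1)))
}

parameterCount <- function(layers)
  sum(vapply(layers, countLayerParams, numeric(1)))

parameterList <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "inception") out <- c(out, parameterList(l$branches))
    else for (p in layerParamNames(l)) out <- c(out, list(l[[p]]))
  }
  out
}

softmaxRows <- function(Z) {
  mx <- Z[, 1L]
  for (j in seq_len(ncol(Z))[-1L]) mx <- pmax(mx, Z[, j])
  E <- exp(Z - mx)
  E / rowSums(E)
}

# Focal loss (and its gradient w.r.t. logits) for rows of a logit matrix.
# target is a 0-based class vector with NA marking ignored rows.
# Per contributing row r with true-class probability pt:
#   L_r = -(1 - pt)^gamma * weight[t_r] * ln(pt)
# and the reported loss is the mean over contributing rows.
focalFromLogits <- function(Z, target, gamma, weights, epsClamp = 1e-7) {
  keep <- !is.na(target)
  if (!any(keep))
    stop("degenerate batch: no pixels contribute to the loss (all carry the ",
         "ignore label)", call. = FALSE)
  P <- softmaxRows(Z)
  M <- sum(keep)
  tk <- target[keep] + 1L
  pt <- pmax(P[cbind(which(keep), tk)], epsClamp)
  wt <- weights[tk]
  onemp <- pmax(1 - pt, 0)
  loss <- sum(wt * onemp^gamma * (-log(pt))) / M
  # dL/dpt, with the gamma term dropped exactly when gamma == 0
  onempSafe <- pmax(onemp, 1e-12)
  dLdpt <- wt * (if (gamma > 0)
    gamma * onempSafe^(gamma - 1) * log(pt) else 0)
  dLdpt <- dLdpt - wt * onemp^gamma / pt
  a <- dLdpt * pt / M
  dZ <- -P * replace(numeric(nrow(Z)), which(keep), a)
  dZ[cbind(which(keep), tk)] <- dZ[cbind(which(keep), tk)] + a
  list(loss = loss, dZ = dZ, prob = P)
}
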
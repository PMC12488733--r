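# Minimal dense/conv/recurrent network engine (forward + analytic backprop,
# Adam). Written for the three small spectral regression architectures of
# this package; batch activations are kept as base-R arrays
# (batch x length x channels) and every layer has a hand-derived gradient,
# verified against finite differences in the test suite.

.bnEps <- 1e-5
.bnMomentum <- 0.1

# ---- primitive layers -------------------------------------------------------

# 1-D convolution, kernel 3, same padding. x: B x L x C; W: (3C) x F; b: F.
conv1dForward <- function(x, W, b) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  Fo <- ncol(W)
  xp <- array(0, c(B, L + 2L, C))
  xp[, 2:(L + 1L), ] <- x
  Xc <- do.call(cbind, lapply(0:2, function(k)
    matrix(xp[, (1:L) + k, , drop = FALSE], B * L, C)))
  out <- Xc %*% W + rep(b, each = B * L)
  list(out = array(out, c(B, L, Fo)), Xc = Xc, dims = c(B, L, C))
}

conv1dBackward <- function(dout, cache, W) {
  B <- cache$dims[1]; L <- cache$dims[2]; C <- cache$dims[3]
  dmat <- matrix(dout, B * L, dim(dout)[3])
  dW <- crossprod(cache$Xc, dmat)
  db <- colSums(dmat)
  dXc <- tcrossprod(dmat, W)
  dxp <- array(0, c(B, L + 2L, C))
  for (k in 0:2)
    dxp[, (1:L) + k, ] <- dxp[, (1:L) + k, , drop = FALSE] +
      array(dXc[, k * C + seq_len(C)], c(B, L, C))
  list(dx = dxp[, 2:(L + 1L), , drop = FALSE], dW = dW, db = db)
}

# Max pooling, window = stride = w, floor semantics on odd lengths.
maxpoolForward <- function(x, w) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  L2 <- L %/% w
  xr <- array(x[, seq_len(L2 * w), , drop = FALSE], c(B, w, L2, C))
  m <- array(xr[, 1L, , , drop = FALSE], c(B, L2, C))
  idx <- array(1L, c(B, L2, C))
  if (w > 1L) for (j in 2:w) {
    xj <- array(xr[, j, , , drop = FALSE], c(B, L2, C))
    upd <- xj > m
    m[upd] <- xj[upd]
    idx[upd] <- j
  }
  list(out = m, idx = idx, dims = d, w = w, L2 = L2)
}

maxpoolBackward <- function(dout, cache) {
  d <- cache$dims; B <- d[1]; C <- d[3]; w <- cache$w; L2 <- cache$L2
  dxr <- array(0, c(B, w, L2, C))
  for (j in seq_len(w)) {
    sel <- cache$idx == j
    slice <- array(0, c(B, L2, C))
    slice[sel] <- dout[sel]
    dxr[, j, , ] <- slice
  }
  dx <- array(0, d)
  dx[, seq_len(L2 * w), ] <- array(dxr, c(B, L2 * w, C))
  dx
}

# Batch normalization per channel over batch and length positions.
batchnormForward <- function(x, gamma, beta, training, running) {
  d <- dim(x); C <- d[3]
  xm <- matrix(x, prod(d[1:2]), C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    running$mean <- (1 - .bnMomentum) * running$mean + .bnMomentum * mu
    running$var <- (1 - .bnMomentum) * running$var + .bnMomentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(xm, 2L, mu)
  }
  istd <- 1 / sqrt(v + .bnEps)
  xhat <- sweep(xc, 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = array(out, d), xhat = xhat, istd = istd, dims = d,
       running = running)
}

batchnormBackward <- function(dout, cache, gamma) {
  d <- cache$dims; N <- prod(d[1:2])
  dy <- matrix(dout, N, d[3])
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  # dx = istd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- N * dxhat
  t2 <- matrix(colSums(dxhat), N, d[3], byrow = TRUE)
  t3 <- cache$xhat * matrix(colSums(dxhat * cache$xhat), N, d[3], byrow = TRUE)
  dx <- sweep(t1 - t2 - t3, 2L, cache$istd / N, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# GRU over a sequence of scalars. x: B x L; params: W* (vectors length H),
# U* (H x H), b* (H). Returns final hidden state and caches for BPTT.
gruForward <- function(x, p) {
  B <- nrow(x); L <- ncol(x); H <- length(p$Wz)
  h <- matrix(0, B, H)
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- x[, t]
    z <- sigmoid(outer(xt, p$Wz) + h %*% p$Uz + rep(p$bz, each = B))
    r <- sigmoid(outer(xt, p$Wr) + h %*% p$Ur + rep(p$br, each = B))
    n <- tanh(outer(xt, p$Wn) + (r * h) %*% p$Un + rep(p$bn, each = B))
    hNew <- (1 - z) * n + z * h
    cache[[t]] <- list(xt = xt, hPrev = h, z = z, r = r, n = n)
    h <- hNew
  }
  list(h = h, cache = cache, B = B, L = L, H = H)
}

gruBackward <- function(dh, fwd, p) {
  H <- fwd$H
  g <- list(Wz = numeric(H), Wr = numeric(H), Wn = numeric(H),
            Uz = matrix(0, H, H), Ur = matrix(0, H, H), Un = matrix(0, H, H),
            bz = numeric(H), br = numeric(H), bn = numeric(H))
  dx <- matrix(0, fwd$B, fwd$L)
  for (t in rev(seq_len(fwd$L))) {
    cc <- fwd$cache[[t]]
    dz <- dh * (cc$hPrev - cc$n)
    dzp <- dz * cc$z * (1 - cc$z)
    dn <- dh * (1 - cc$z)
    dnp <- dn * (1 - cc$n^2)
    dg <- tcrossprod(dnp, p$Un)          # grad wrt (r * hPrev)
    drp <- (dg * cc$hPrev) * cc$r * (1 - cc$r)
    dhPrev <- dh * cc$z + dg * cc$r +
      tcrossprod(dzp, p$Uz) + tcrossprod(drp, p$Ur)
    g$Wz <- g$Wz + as.numeric(crossprod(cc$xt, dzp))
    g$Wr <- g$Wr + as.numeric(crossprod(cc$xt, drp))
    g$Wn <- g$Wn + as.numeric(crossprod(cc$xt, dnp))
    g$Uz <- g$Uz + crossprod(cc$hPrev, dzp)
    g$Ur <- g$Ur + crossprod(cc$hPrev, drp)
    g$Un <- g$Un + crossprod(cc$r * cc$hPrev, dnp)
    g$bz <- g$bz + colSums(dzp)
    g$br <- g$br + colSums(drp)
    g$bn <- g$bn + colSums(dnp)
    dx[, t] <- as.numeric(dzp %*% p$Wz + drp %*% p$Wr + dnp %*% p$Wn)
    dh <- dhPrev
  }
  list(dx = dx, grads = g)
}

# Single-head dot-product self-attention over a sequence of scalar tokens.
# s: B x P. Queries/keys are learned 50-dim projections of each scalar token
# (Q_i = s_i * wq + bq); values are the token scalars themselves, so the
# layer re-weights the feature sequence: out_i = sum_j softmax_j(E_ij) s_j.
attentionForward <- function(s, p) {
  B <- nrow(s); P <- ncol(s)
  dk <- length(p$wq)
  al <- sum(p$wq * p$wk); be <- sum(p$wq * p$bk)
  ga <- sum(p$bq * p$wk); de <- sum(p$bq * p$bk)
  idxB <- rep(seq_len(B), each = P)
  si <- as.vector(t(s))                 # row (b, i), i fastest
  Srep <- s[idxB, , drop = FALSE]       # (B*P) x P
  # E_ij = ((al*s_i + ga)*s_j + (be*s_i + de)) / sqrt(dk); row-indexed
  # vectors recycle down columns, i.e. over the (b, i) row index.
  rq <- (al * si + ga) / sqrt(dk)
  rc <- (be * si + de) / sqrt(dk)
  E <- rq * Srep + rc
  mx <- E[cbind(seq_len(nrow(E)), max.col(E, ties.method = "first"))]
  A <- exp(E - mx)
  ones <- rep(1, P)
  A <- A / as.numeric(A %*% ones)
  outVec <- as.numeric((A * Srep) %*% ones)
  out <- t(matrix(outVec, P, B))
  list(out = out, A = A, Srep = Srep, si = si, idxB = idxB, outVec = outVec,
       scalars = c(al = al, be = be, ga = ga, de = de), dk = dk,
       B = B, P = P)
}

attentionBackward <- function(dout, cache, p) {
  B <- cache$B; P <- cache$P; dk <- cache$dk
  sc <- cache$scalars
  dVec <- as.vector(t(dout))
  dA <- dVec * cache$Srep
  # softmax backward; rowSums(dA * A) = dVec * rowSums(A * Srep) = dVec * out
  dE <- cache$A * (dA - dVec * cache$outVec)
  ones <- rep(1, P)
  t1 <- as.numeric((dE * cache$Srep) %*% ones)
  t2 <- as.numeric(dE %*% ones)
  dal <- sum(t1 * cache$si) / sqrt(dk)
  dga <- sum(t1) / sqrt(dk)
  dbe <- sum(t2 * cache$si) / sqrt(dk)
  dde <- sum(t2) / sqrt(dk)
  dsi <- (sc[["al"]] * t1 + sc[["be"]] * t2) / sqrt(dk)
  dSrep <- cache$A * dVec +                             # value path
    dE * ((sc[["al"]] * cache$si + sc[["ga"]]) / sqrt(dk))
  ds <- t(matrix(dsi, P, B)) + rowsum(dSrep, cache$idxB)
  grads <- list(
    wq = dal * p$wk + dbe * p$bk,
    wk = dal * p$wq + dga * p$bq,
    bq = dga * p$wk + dde * p$bk,
    bk = dbe * p$wq + dde * p$bq)
  list(ds = ds, grads = grads)
}

# ---- initialization ---------------------------------------------------------

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -lim, lim), dims)
}

gruInit <- function(H, inDim = 1L) {
  mk <- function() as.numeric(glorot(inDim, H, c(inDim, H)))
  mkU <- function() glorot(H, H)
  list(Wz = mk(), Wr = mk(), Wn = mk(), Uz = mkU(), Ur = mkU(), Un = mkU(),
       bz = numeric(H), br = numeric(H), bn = numeric(H))
}

initParams <- function(kind, nBands) {
  L <- nBands
  if (kind == "cnn") {
    L2 <- (L %/% 2L) %/% 2L
    p <- list(
      W1 = glorot(3, 8, c(3, 8)), b1 = numeric(8),
      g1 = rep(1, 8), be1 = numeric(8),
      W2 = glorot(24, 32, c(24, 32)), b2 = numeric(32),
      g2 = rep(1, 32), be2 = numeric(32),
      Wd1 = glorot(L2 * 32, 32), bd1 = numeric(32),
      Wd2 = glorot(32, 1), bd2 = numeric(1))
    bn <- list(bn1 = list(mean = numeric(8), var = rep(1, 8)),
               bn2 = list(mean = numeric(32), var = rep(1, 32)))
  } else {
    Lc <- L %/% 3L
    p <- list(
      Wc = glorot(3, 16, c(3, 16)), bc = numeric(16),
      gc = rep(1, 16), bec = numeric(16),
      Wd25 = glorot(Lc * 16, 25), bd25 = numeric(25),
      fwd = gruInit(35L), bwd = gruInit(35L),
      Wo = glorot(95, 1), bo = numeric(1))
    if (kind == "cnn_bigru_attention")
      p <- c(p, list(wq = as.numeric(glorot(1, 50, c(1, 50))),
                     bq = numeric(50),
                     wk = as.numeric(glorot(1, 50, c(1, 50))),
                     bk = numeric(50)))
    bn <- list(bnc = list(mean = numeric(16), var = rep(1, 16)))
  }
  list(params = p, bn = bn)
}

# parameter names subject to L2 weight decay (weights, not biases/BN)
decayNames <- function(kind) {
  if (kind == "cnn") c("W1", "W2", "Wd1", "Wd2")
  else c("Wc", "Wd25", "Wo",
         if (kind == "cnn_bigru_attention") c("wq", "wk"))
}
gruDecayNames <- c("Wz", "Wr", "Wn", "Uz", "Ur", "Un")

# ---- architecture forward/backward -----------------------------------------

# Each returns list(pred = B x 1, grads = params-shaped list) when y given,
# otherwise just predictions; `training` toggles BN batch stats and dropout.
cnnPass <- function(p, bn, x, y = NULL, training = FALSE, dropout = 0.4) {
  B <- nrow(x); L <- ncol(x)
  a0 <- array(x, c(B, L, 1L))
  c1 <- conv1dForward(a0, p$W1, p$b1)
  n1 <- batchnormForward(c1$out, p$g1, p$be1, training, bn$bn1)
  bn$bn1 <- n1$running
  r1 <- pmax(n1$out, 0)
  p1 <- maxpoolForward(r1, 2L)
  c2 <- conv1dForward(p1$out, p$W2, p$b2)
  n2 <- batchnormForward(c2$out, p$g2, p$be2, training, bn$bn2)
  bn$bn2 <- n2$running
  r2 <- pmax(n2$out, 0)
  p2 <- maxpoolForward(r2, 2L)
  dmask <- if (training && dropout > 0)
    array(rbinom(length(p2$out), 1L, 1 - dropout) / (1 - dropout),
          dim(p2$out)) else 1
  dr <- p2$out * dmask
  Fw <- matrix(dr, B, length(dr) / B)
  h1 <- pmax(Fw %*% p$Wd1 + rep(p$bd1, each = B), 0)
  pred <- h1 %*% p$Wd2 + rep(p$bd2, each = B)
  if (is.null(y)) return(list(pred = pred, bn = bn))
  loss <- mean((pred - y)^2)
  dpred <- 2 * (pred - y) / B
  g <- list()
  g$Wd2 <- crossprod(h1, dpred); g$bd2 <- colSums(dpred)
  dh1 <- tcrossprod(dpred, p$Wd2) * (h1 > 0)
  g$Wd1 <- crossprod(Fw, dh1); g$bd1 <- colSums(dh1)
  dFw <- tcrossprod(dh1, p$Wd1)
  ddr <- array(dFw, dim(p2$out)) * dmask
  dp2 <- maxpoolBackward(ddr, p2)
  dr2 <- dp2 * (n2$out > 0)
  b2g <- batchnormBackward(dr2, n2, p$g2)
  g$g2 <- b2g$dgamma; g$be2 <- b2g$dbeta
  c2g <- conv1dBackward(b2g$dx, c2, p$W2)
  g$W2 <- c2g$dW; g$b2 <- c2g$db
  dp1 <- maxpoolBackward(c2g$dx, p1)
  dr1 <- dp1 * (n1$out > 0)
  b1g <- batchnormBackward(dr1, n1, p$g1)
  g$g1 <- b1g$dgamma; g$be1 <- b1g$dbeta
  c1g <- conv1dBackward(b1g$dx, c1, p$W1)
  g$W1 <- c1g$dW; g$b1 <- c1g$db
  list(pred = pred, loss = loss, grads = g, bn = bn)
}

hybridPass <- function(p, bn, x, y = NULL, training = FALSE,
                       attention = FALSE) {
  B <- nrow(x); L <- ncol(x)
  # CNN branch
  a0 <- array(x, c(B, L, 1L))
  c1 <- conv1dForward(a0, p$Wc, p$bc)
  n1 <- batchnormForward(c1$out, p$gc, p$bec, training, bn$bnc)
  bn$bnc <- n1$running
  r1 <- pmax(n1$out, 0)
  p1 <- maxpoolForward(r1, 3L)
  Fw <- matrix(p1$out, B, length(p1$out) / B)
  hc <- pmax(Fw %*% p$Wd25 + rep(p$bd25, each = B), 0)
  # BiGRU branch (forward sequence + flipped sequence)
  gf <- gruForward(x, p$fwd)
  gb <- gruForward(x[, rev(seq_len(L)), drop = FALSE], p$bwd)
  s <- cbind(hc, gf$h, gb$h)            # B x 95
  att <- NULL
  feats <- s
  if (attention) {
    att <- attentionForward(s, p)
    feats <- s + att$out          # residual connection around the block
  }
  pred <- feats %*% p$Wo + rep(p$bo, each = B)
  if (is.null(y)) return(list(pred = pred, bn = bn))
  loss <- mean((pred - y)^2)
  dpred <- 2 * (pred - y) / B
  g <- list()
  g$Wo <- crossprod(feats, dpred); g$bo <- colSums(dpred)
  dfeats <- tcrossprod(dpred, p$Wo)
  if (attention) {
    ab <- attentionBackward(dfeats, att, p)
    g <- c(g, ab$grads)
    ds <- dfeats + ab$ds          # residual path
  } else ds <- dfeats
  dhc <- ds[, 1:25, drop = FALSE]
  dhf <- ds[, 26:60, drop = FALSE]
  dhb <- ds[, 61:95, drop = FALSE]
  # CNN branch backward
  dhc <- dhc * (hc > 0)
  g$Wd25 <- crossprod(Fw, dhc); g$bd25 <- colSums(dhc)
  dFw <- tcrossprod(dhc, p$Wd25)
  dp1 <- maxpoolBackward(array(dFw, dim(p1$out)), p1)
  dr1 <- dp1 * (n1$out > 0)
  bg <- batchnormBackward(dr1, n1, p$gc)
  g$gc <- bg$dgamma; g$bec <- bg$dbeta
  cg <- conv1dBackward(bg$dx, c1, p$Wc)
  g$Wc <- cg$dW; g$bc <- cg$db
  # BiGRU backward
  gfB <- gruBackward(dhf, gf, p$fwd)
  gbB <- gruBackward(dhb, gb, p$bwd)
  g$fwd <- gfB$grads
  g$bwd <- gbB$grads
  list(pred = pred, loss = loss, grads = g, bn = bn)
}

networkPass <- function(kind, p, bn, x, y = NULL, training = FALSE,
                        dropout = 0.4) {
  switch(kind,
    cnn = cnnPass(p, bn, x, y, training, dropout),
    cnn_bigru = hybridPass(p, bn, x, y, training, attention = FALSE),
    cnn_bigru_attention = hybridPass(p, bn, x, y, training, attention = TRUE),
    stop("unknown model kind: ", kind))
}

# ---- Adam -------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a (possibly two-level) parameter list to named leaves and back;
# lets the optimizer run a plain loop over arrays with no nested closures.
flattenLeaves <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      sub <- p[[nm]]
      for (sn in names(sub)) out[[paste(nm, sn, sep = ".")]] <- sub[[sn]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

unflattenLeaves <- function(flat, template) {
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      for (sn in names(template[[nm]]))
        template[[nm]][[sn]] <- flat[[paste(nm, sn, sep = ".")]]
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

adamInit <- function(params) {
  flat <- flattenLeaves(params)
  zeros <- lapply(flat, function(x) x * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  fp <- flattenLeaves(params)
  fg <- flattenLeaves(grads)
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(fp)) {
    g <- fg[[nm]]
    m <- b1 * state$m[[nm]] + (1 - b1) * g
    v <- b2 * state$v[[nm]] + (1 - b2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    fp[[nm]] <- fp[[nm]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  list(params = unflattenLeaves(fp, params), state = state)
}

# add L2 decay gradients in place (weights only, never biases or BN params)
addDecay <- function(grads, params, kind, l2) {
  if (l2 <= 0) return(grads)
  for (nm in decayNames(kind))
    grads[[nm]] <- grads[[nm]] + l2 * params[[nm]]
  for (dir in intersect(c("fwd", "bwd"), names(params)))
    for (nm in gruDecayNames)
      grads[[dir]][[nm]] <- grads[[dir]][[nm]] + l2 * params[[dir]][[nm]]
  grads
}
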
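# Internal neural-network primitives for 1-D signals.
#
# All activations are (channels, time, batch) arrays.  Convolutions use
# same-length zero padding and are computed as im2col + GEMM; gradients
# are written by hand.  Nothing here is exported - the model-fitting
# functions in reconnet.R / minet.R are the public surface.

lrelu <- function(x, a = 0.1) pmax(x, 0) + a * pmin(x, 0)
lrelu_grad <- function(x, a = 0.1) (x > 0) + a * (x <= 0)

# Precomputed index geometry for a conv of kernel k over records of
# length N, batch nb.  idx_col gathers the sliding windows out of the
# zero-padded signal, idx_center addresses the un-padded positions, and
# idx_off[[j]] the positions touched by kernel offset j (for col2im).
conv_geom <- function(N, k, nb) {
  N <- as.integer(N); k <- as.integer(k); nb <- as.integer(nb)
  Np <- N + k - 1L
  rec_off <- (seq_len(nb) - 1L) * Np
  base <- as.vector(outer(seq_len(k), 0:(N - 1L), `+`))
  h <- (k - 1L) %/% 2L
  list(N = N, k = k, nb = nb, Np = Np,
       idx_col = as.vector(outer(base, rec_off, `+`)),
       idx_center = as.vector(outer(h + seq_len(N), rec_off, `+`)),
       idx_off = lapply(seq_len(k), function(j)
         as.vector(outer(j:(j + N - 1L), rec_off, `+`))))
}

# Geometry cache keyed by (N, k, nb); avoids rebuilding index vectors
# every minibatch.
geom_cache <- function() {
  env <- new.env(parent = emptyenv())
  function(N, k, nb) {
    key <- paste(N, k, nb, sep = "_")
    g <- env[[key]]
    if (is.null(g)) {
      g <- conv_geom(N, k, nb)
      env[[key]] <- g
    }
    g
  }
}

# He-style initialization; W stored as cout x (cin * k) with the input
# channel index varying fastest (matches the im2col layout).
conv_init <- function(cin, cout, k, gain = 1) {
  list(W = matrix(stats::rnorm(cout * cin * k), cout) *
         (gain * sqrt(2 / (cin * k))),
       b = numeric(cout))
}

conv_fwd <- function(p, X, g) {
  cin <- dim(X)[1L]
  Xp <- matrix(0, cin, g$Np * g$nb)
  Xp[, g$idx_center] <- X
  Xcol <- Xp[, g$idx_col, drop = FALSE]
  dim(Xcol) <- c(cin * g$k, g$N * g$nb)
  Y <- p$W %*% Xcol + p$b
  dim(Y) <- c(nrow(p$W), g$N, g$nb)
  list(out = Y, Xcol = Xcol)
}

conv_bwd <- function(p, cache, dY, g, need_dx = TRUE) {
  cout <- dim(dY)[1L]
  dim(dY) <- c(cout, g$N * g$nb)
  dW <- tcrossprod(dY, cache$Xcol)
  db <- rowSums(dY)
  dX <- NULL
  if (need_dx) {
    dXcol <- crossprod(p$W, dY)
    cin <- nrow(dXcol) %/% g$k
    dXp <- matrix(0, cin, g$Np * g$nb)
    for (j in seq_len(g$k)) {
      rows <- ((j - 1L) * cin + 1L):(j * cin)
      dXp[, g$idx_off[[j]]] <- dXp[, g$idx_off[[j]]] +
        dXcol[rows, , drop = FALSE]
    }
    dX <- dXp[, g$idx_center, drop = FALSE]
    dim(dX) <- c(cin, g$N, g$nb)
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

# Residual unit: conv(k) -> leaky ReLU -> conv(k), plus identity skip
# (1x1 projection when the channel count changes), then leaky ReLU.
runit_init <- function(cin, cout, k) {
  p <- list(c1 = conv_init(cin, cout, k), c2 = conv_init(cout, cout, k))
  if (cin != cout) p$proj <- conv_init(cin, cout, 1L)
  p
}

runit_fwd <- function(p, X, getg) {
  g <- getg(dim(X)[2L], ncol(p$c1$W) %/% dim(X)[1L], dim(X)[3L])
  f1 <- conv_fwd(p$c1, X, g)
  z1 <- lrelu(f1$out)
  f2 <- conv_fwd(p$c2, z1, g)
  if (!is.null(p$proj)) {
    g1 <- getg(dim(X)[2L], 1L, dim(X)[3L])
    fs <- conv_fwd(p$proj, X, g1)
    skip <- fs$out
  } else {
    fs <- NULL
    skip <- X
  }
  pre <- f2$out + skip
  list(out = lrelu(pre),
       cache = list(g = g, a1 = f1$out, Xcol1 = f1$Xcol,
                    Xcol2 = f2$Xcol, Xcols = fs$Xcol, pre = pre))
}

runit_bwd <- function(p, cache, dOut, getg, need_dx = TRUE) {
  g <- cache$g
  dpre <- dOut * lrelu_grad(cache$pre)
  b2 <- conv_bwd(p$c2, list(Xcol = cache$Xcol2), dpre, g, need_dx = TRUE)
  dz1 <- b2$dX * lrelu_grad(cache$a1)
  need_main_dx <- need_dx
  b1 <- conv_bwd(p$c1, list(Xcol = cache$Xcol1), dz1, g,
                 need_dx = need_main_dx)
  grads <- list(c1 = b1$grads, c2 = b2$grads)
  dX <- NULL
  if (!is.null(p$proj)) {
    g1 <- getg(g$N, 1L, g$nb)
    bp <- conv_bwd(p$proj, list(Xcol = cache$Xcols), dpre, g1,
                   need_dx = need_dx)
    grads$proj <- bp$grads
    if (need_dx) dX <- b1$dX + bp$dX
  } else if (need_dx) {
    dX <- b1$dX + dpre
  }
  list(dX = dX, grads = grads)
}

# A section = a stack of residual units (first unit changes the channel
# count, the rest keep it).
section_init <- function(cin, cout, k, n_units) {
  c(list(runit_init(cin, cout, k)),
    if (n_units > 1L)
      replicate(n_units - 1L, runit_init(cout, cout, k), simplify = FALSE))
}

section_fwd <- function(params, X, getg) {
  caches <- vector("list", length(params))
  for (i in seq_along(params)) {
    r <- runit_fwd(params[[i]], X, getg)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

section_bwd <- function(params, caches, dOut, getg, need_dx = TRUE) {
  grads <- vector("list", length(params))
  for (i in rev(seq_along(params))) {
    r <- runit_bwd(params[[i]], caches[[i]], dOut, getg,
                   need_dx = need_dx || i > 1L)
    dOut <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dOut, grads = grads)
}

# Dense layer on (features x batch) matrices.
dense_init <- function(nin, nout, gain = 1) {
  list(W = matrix(stats::rnorm(nout * nin), nout) *
         (gain * sqrt(2 / nin)),
       b = numeric(nout))
}

dense_fwd <- function(p, X) list(out = p$W %*% X + p$b, X = X)

dense_bwd <- function(p, cache, dY) {
  list(dX = crossprod(p$W, dY),
       grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
}

# Average pooling by 2 along time (drops a trailing odd sample).
pool2_fwd <- function(X) {
  n2 <- dim(X)[2L] %/% 2L
  idx <- seq_len(2L * n2)
  X <- X[, idx, , drop = FALSE]
  (X[, seq(1L, 2L * n2, by = 2L), , drop = FALSE] +
     X[, seq(2L, 2L * n2, by = 2L), , drop = FALSE]) / 2
}

pool2_bwd <- function(dY, n_in) {
  d <- dim(dY)
  out <- array(0, c(d[1L], n_in, d[3L]))
  half <- dY / 2
  out[, seq(1L, 2L * d[2L], by = 2L), ] <- half
  out[, seq(2L, 2L * d[2L], by = 2L), ] <- half
  out
}

# --- parameter flattening (for the Adam update) -------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  rebuild <- function(s) {
    if (is.list(s)) return(lapply(s, rebuild))
    n <- length(s)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(s)
    out
  }
  rebuild(skeleton)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
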
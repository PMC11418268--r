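# Neural primitives with analytic forward/backward passes.
#
# No deep-learning framework is available in this R stack, so every layer is
# written as a pair of pure functions: `*_fwd` returns the output plus the
# cache needed by `*_bwd`, which maps the upstream gradient to input and
# parameter gradients. Correctness is pinned by finite-difference tests.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- scaled dot-product attention (Eq.-3 style) -------------------------

#' Scaled dot-product attention
#'
#' `Softmax(Q K' / sqrt(d_k)) V` with the softmax over the key axis, so each
#' output row is a convex combination of the rows of `V`. The scale is the
#' width of `K` as passed.
#'
#' @param Q,K,V numeric row-matrices; `K` and `V` must have equal row counts
#'   and `Q`, `K` equal widths.
#' @return matrix with `nrow(Q)` rows and `ncol(V)` columns.
#' @export
attention <- function(Q, K, V) attention_fwd(Q, K, V)$out

attention_fwd <- function(Q, K, V) {
  Q <- as_rows(Q); K <- as_rows(K); V <- as_rows(V)
  if (ncol(Q) != ncol(K)) stop("attention: Q and K widths differ")
  if (nrow(K) != nrow(V)) stop("attention: K and V row counts differ")
  scale <- sqrt(ncol(K))
  A <- softmax_rows(Q %*% t(K) / scale)
  list(out = A %*% V, cache = list(A = A, Q = Q, K = K, V = V, scale = scale))
}

attention_bwd <- function(dO, cache) {
  A <- cache$A
  dV <- t(A) %*% dO
  dA <- dO %*% t(cache$V)
  dS <- A * (dA - rowSums(A * dA))
  list(dQ = dS %*% cache$K / cache$scale,
       dK = t(dS) %*% cache$Q / cache$scale,
       dV = dV)
}

as_rows <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

## ---- multi-head attention ----------------------------------------------

#' Initialise multi-head attention parameters
#'
#' `Wq`, `Wk`, `Wv`, `Wo` are `d x d`; the column blocks of `Wq`/`Wk`/`Wv`
#' (width `d/h`) are the per-head projections.
#'
#' @param d model width; must be divisible by `h` at call time.
#' @return parameter list.
#' @export
init_mh_params <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d))
}

#' Multi-head attention
#'
#' Projects queries/keys/values per head, applies [attention()] head-wise,
#' concatenates the heads over the feature axis and projects by `Wo`.
#'
#' @param Q,K,V row-matrices of width `d`.
#' @param params from [init_mh_params()].
#' @param h number of heads; `d` must be divisible by `h`.
#' @return matrix `nrow(Q) x d`.
#' @export
multi_head <- function(Q, K, V, params, h) multi_head_fwd(Q, K, V, params, h)$out

multi_head_fwd <- function(Q, K, V, params, h) {
  Q <- as_rows(Q); K <- as_rows(K); V <- as_rows(V)
  d <- ncol(params$Wq)
  if (ncol(Q) != d || ncol(K) != d || ncol(V) != d)
    stop("multi_head: input width does not match parameters")
  if (d %% h != 0L) stop("multi_head: width ", d, " not divisible by h = ", h)
  Qp <- Q %*% params$Wq; Kp <- K %*% params$Wk; Vp <- V %*% params$Wv
  dh <- d %/% h
  heads <- vector("list", h)
  C <- matrix(0, nrow(Q), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    heads[[i]] <- attention_fwd(Qp[, cols, drop = FALSE],
                                Kp[, cols, drop = FALSE],
                                Vp[, cols, drop = FALSE])
    C[, cols] <- heads[[i]]$out
  }
  list(out = C %*% params$Wo,
       cache = list(Q = Q, K = K, V = V, Qp = Qp, Kp = Kp, Vp = Vp,
                    C = C, heads = heads, h = h, dh = dh))
}

multi_head_bwd <- function(dO, cache, params) {
  dWo <- t(cache$C) %*% dO
  dC <- dO %*% t(params$Wo)
  dQp <- matrix(0, nrow(cache$Qp), ncol(cache$Qp))
  dKp <- matrix(0, nrow(cache$Kp), ncol(cache$Kp))
  dVp <- matrix(0, nrow(cache$Vp), ncol(cache$Vp))
  for (i in seq_len(cache$h)) {
    cols <- ((i - 1L) * cache$dh + 1L):(i * cache$dh)
    g <- attention_bwd(dC[, cols, drop = FALSE], cache$heads[[i]]$cache)
    dQp[, cols] <- g$dQ; dKp[, cols] <- g$dK; dVp[, cols] <- g$dV
  }
  list(dQ = dQp %*% t(params$Wq),
       dK = dKp %*% t(params$Wk),
       dV = dVp %*% t(params$Wv),
       grads = list(Wq = t(cache$Q) %*% dQp, Wk = t(cache$K) %*% dKp,
                    Wv = t(cache$V) %*% dVp, Wo = dWo))
}

## ---- layer normalization ------------------------------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * inv_std
  out <- sweep(xhat, 2L, g, `*`)
  out <- sweep(out, 2L, b, `+`)
  list(out = out, cache = list(xhat = xhat, inv_std = inv_std, g = g))
}

layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, cache$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv_std * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

## ---- transformer set encoder (one MH + FFN block) -----------------------

#' Initialise transformer encoder parameters
#'
#' One multi-head self-attention sub-layer plus a position-wise feed-forward
#' sub-layer (two linear maps with ReLU between, inner width `s`), each with
#' a residual connection followed by layer normalization. There is no
#' positional encoding: the encoder treats its input as a set.
#'
#' @param dim model width.
#' @param s FFN inner width.
#' @return parameter list.
#' @export
init_encoder_params <- function(dim, s) {
  c(init_mh_params(dim),
    list(W1 = glorot(dim, s), b1 = numeric(s),
         W2 = glorot(s, dim), b2 = numeric(dim),
         ln1_g = rep(1, dim), ln1_b = numeric(dim),
         ln2_g = rep(1, dim), ln2_b = numeric(dim)))
}

#' Transformer set encoder
#'
#' `Enc(X) = LayerNorm(H + FFN(H))` with `H = LayerNorm(X + MH(X, X, X))`.
#' Permutation-equivariant: permuting input rows permutes output rows.
#'
#' @param X row-matrix, one embedding row per code; at least one row.
#' @param params from [init_encoder_params()].
#' @param h number of heads.
#' @return matrix of the same shape as `X`.
#' @export
encoder <- function(X, params, h) encoder_fwd(X, params, h)$out

encoder_fwd <- function(X, params, h) {
  X <- as_rows(X)
  if (nrow(X) == 0L) stop("encoder: empty input (no code rows)")
  mh <- multi_head_fwd(X, X, X, params, h)
  ln1 <- layernorm_fwd(X + mh$out, params$ln1_g, params$ln1_b)
  H <- ln1$out
  A1 <- H %*% params$W1
  A1 <- sweep(A1, 2L, params$b1, `+`)
  R <- A1 * (A1 > 0)
  FF <- sweep(R %*% params$W2, 2L, params$b2, `+`)
  ln2 <- layernorm_fwd(H + FF, params$ln2_g, params$ln2_b)
  list(out = ln2$out,
       cache = list(X = X, mh = mh, ln1 = ln1, H = H, A1 = A1, R = R,
                    ln2 = ln2, h = h))
}

encoder_bwd <- function(dY, cache, params) {
  b2g <- layernorm_bwd(dY, cache$ln2$cache)
  dH <- b2g$dX                       # residual branch
  dFF <- b2g$dX
  dR <- dFF %*% t(params$W2)
  dW2 <- t(cache$R) %*% dFF
  db2 <- colSums(dFF)
  dA1 <- dR * (cache$A1 > 0)
  dW1 <- t(cache$H) %*% dA1
  db1 <- colSums(dA1)
  dH <- dH + dA1 %*% t(params$W1)
  b1g <- layernorm_bwd(dH, cache$ln1$cache)
  dX <- b1g$dX
  mg <- multi_head_bwd(b1g$dX, cache$mh$cache, params)
  dX <- dX + mg$dQ + mg$dK + mg$dV
  grads <- mg$grads
  grads$W1 <- dW1; grads$b1 <- db1; grads$W2 <- dW2; grads$b2 <- db2
  grads$ln1_g <- b1g$dg; grads$ln1_b <- b1g$db
  grads$ln2_g <- b2g$dg; grads$ln2_b <- b2g$db
  list(dX = dX, grads = grads)
}

## ---- set pooling --------------------------------------------------------

#' Mean-pool a set of embedding rows to a single vector
#'
#' Resolves set-valued encoder outputs to the single vectors the prediction
#' heads consume. Mean (rather than sum) keeps the scale independent of the
#' set size.
#'
#' @param rows row-matrix with at least one row.
#' @return numeric vector of length `ncol(rows)`.
#' @export
pool_set <- function(rows) {
  rows <- as_rows(rows)
  if (nrow(rows) == 0L) stop("pool_set: zero rows")
  colMeans(rows)
}

## ---- CA-MHSA block ------------------------------------------------------

#' Cross-attention + multi-head self-attention (CA-MHSA) block
#'
#' Cross-attends the query rows against the diagnosis rows and against the
#' procedure rows, concatenates the two results over the feature axis
#' (width `2*dim`), applies multi-head self-attention over the query rows,
#' and mean-pools the rows to a single `2*dim` vector.
#'
#' @param Q_rows,D_rows,P_rows row-matrices of width `dim`.
#' @param params multi-head parameters of width `2*dim`
#'   (from `init_mh_params(2 * dim)`).
#' @param h number of heads; `2*dim` must be divisible by `h`.
#' @return numeric vector of length `2*dim`.
#' @export
ca_mhsa <- function(Q_rows, D_rows, P_rows, params, h)
  ca_mhsa_fwd(Q_rows, D_rows, P_rows, params, h)$out

ca_mhsa_fwd <- function(Q_rows, D_rows, P_rows, params, h) {
  Q_rows <- as_rows(Q_rows); D_rows <- as_rows(D_rows); P_rows <- as_rows(P_rows)
  if (nrow(D_rows) == 0L || nrow(P_rows) == 0L)
    stop("ca_mhsa: empty key/value rows")
  a1 <- attention_fwd(Q_rows, D_rows, D_rows)
  a2 <- attention_fwd(Q_rows, P_rows, P_rows)
  CA <- cbind(a1$out, a2$out)
  mh <- multi_head_fwd(CA, CA, CA, params, h)
  list(out = colMeans(mh$out),
       cache = list(a1 = a1, a2 = a2, mh = mh, n_q = nrow(Q_rows),
                    dim = ncol(Q_rows)))
}

ca_mhsa_bwd <- function(d_out, cache, params) {
  n_q <- cache$n_q
  dM <- matrix(d_out / n_q, n_q, length(d_out), byrow = TRUE)
  mg <- multi_head_bwd(dM, cache$mh$cache, params)
  dCA <- mg$dQ + mg$dK + mg$dV
  d <- cache$dim
  g1 <- attention_bwd(dCA[, seq_len(d), drop = FALSE], cache$a1$cache)
  g2 <- attention_bwd(dCA[, d + seq_len(d), drop = FALSE], cache$a2$cache)
  list(dQ = g1$dQ + g2$dQ,
       dD = g1$dK + g1$dV,
       dP = g2$dK + g2$dV,
       grads = mg$grads)
}

## ---- GRU ----------------------------------------------------------------

#' Initialise GRU parameters
#' @param dim input and hidden width.
#' @return parameter list (update/reset/candidate gates).
#' @export
init_gru_params <- function(dim) {
  list(Wz = glorot(dim, dim), Uz = glorot(dim, dim), bz = numeric(dim),
       Wr = glorot(dim, dim), Ur = glorot(dim, dim), br = numeric(dim),
       Wh = glorot(dim, dim), Uh = glorot(dim, dim), bh = numeric(dim))
}

# X_seq: T x dim matrix (one pooled visit vector per row, chronological).
# Gate convention: h_t = (1 - z_t) * h_{t-1} + z_t * htilde_t.
gru_fwd <- function(X_seq, p) {
  X_seq <- as_rows(X_seq)
  dim <- ncol(X_seq)
  h <- numeric(dim)
  steps <- vector("list", nrow(X_seq))
  for (t in seq_len(nrow(X_seq))) {
    x <- X_seq[t, ]
    z <- sigmoid(drop(crossprod(p$Wz, x)) + drop(crossprod(p$Uz, h)) + p$bz)
    r <- sigmoid(drop(crossprod(p$Wr, x)) + drop(crossprod(p$Ur, h)) + p$br)
    hc <- tanh(drop(crossprod(p$Wh, x)) + drop(crossprod(p$Uh, r * h)) + p$bh)
    h_new <- (1 - z) * h + z * hc
    steps[[t]] <- list(x = x, h_prev = h, z = z, r = r, hc = hc)
    h <- h_new
  }
  list(out = h, cache = steps)
}

gru_bwd <- function(dh, cache, p) {
  g <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  dim_ <- length(dh)
  dX <- matrix(0, length(cache), dim_)
  for (t in rev(seq_along(cache))) {
    s <- cache[[t]]
    dz <- dh * (s$hc - s$h_prev)
    dhc <- dh * s$z
    dhp <- dh * (1 - s$z)
    da_hc <- dhc * (1 - s$hc^2)
    g$Wh <- g$Wh + outer(s$x, da_hc)
    g$Uh <- g$Uh + outer(s$r * s$h_prev, da_hc)
    g$bh <- g$bh + da_hc
    dx <- drop(p$Wh %*% da_hc)
    drh <- drop(p$Uh %*% da_hc)
    dr <- drh * s$h_prev
    dhp <- dhp + drh * s$r
    da_z <- dz * s$z * (1 - s$z)
    g$Wz <- g$Wz + outer(s$x, da_z)
    g$Uz <- g$Uz + outer(s$h_prev, da_z)
    g$bz <- g$bz + da_z
    dx <- dx + drop(p$Wz %*% da_z)
    dhp <- dhp + drop(p$Uz %*% da_z)
    da_r <- dr * s$r * (1 - s$r)
    g$Wr <- g$Wr + outer(s$x, da_r)
    g$Ur <- g$Ur + outer(s$h_prev, da_r)
    g$br <- g$br + da_r
    dx <- dx + drop(p$Wr %*% da_r)
    dhp <- dhp + drop(p$Ur %*% da_r)
    dX[t, ] <- dx
    dh <- dhp
  }
  list(dX = dX, grads = g)
}

## ---- gradient-tree helpers ----------------------------------------------

# Recursively add gradient tree `b` into `a`; `b` may omit entries.
grad_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.list(a)) {
    keys <- names(b) %||% seq_along(b)
    for (nm in keys) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

grad_zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, grad_zero_like))
  if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
}

grad_scale <- function(g, s) {
  if (is.list(g)) return(lapply(g, grad_scale, s = s))
  g * s
}
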
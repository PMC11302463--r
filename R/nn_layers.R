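# Dense-layer primitives with hand-derived backward passes: linear maps,
# row-wise layer normalization, multi-head attention and the position-wise
# feed-forward block.  Each *_fwd returns its output plus the cache the
# matching *_bwd needs; *_bwd returns the input gradient plus a gradient
# list shaped like the parameter list.

linear_fwd <- function(x, p) {
  y <- x %*% p$W
  if (!is.null(p$b)) y <- sweep(y, 2, p$b, "+")
  list(out = y, cache = x)
}

linear_bwd <- function(dy, cache, p) {
  g <- list(W = crossprod(cache, dy))
  if (!is.null(p$b)) g$b <- colSums(dy)
  list(dx = tcrossprod(dy, p$W), grads = g)
}

LN_EPS <- 1e-5

layernorm_fwd <- function(x, p) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd))
}

layernorm_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  dxhat <- sweep(dy, 2, p$gamma, "*")
  # dx = inv_sd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dx <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx,
       grads = list(gamma = colSums(dy * xhat), beta = colSums(dy)))
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# Multi-head attention.  q_in: Tq x d, k_in/v_in: Tk x d.  p holds Wq, bq,
# Wk, bk, Wv, bv, Wo, bo (all d x d / length d).
mha_fwd <- function(q_in, k_in, v_in, p, n_heads) {
  d <- ncol(q_in)
  dh <- d / n_heads
  q <- sweep(q_in %*% p$Wq, 2, p$bq, "+")
  k <- sweep(k_in %*% p$Wk, 2, p$bk, "+")
  v <- sweep(v_in %*% p$Wv, 2, p$bv, "+")
  o <- matrix(0, nrow(q), d)
  attn <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    a <- softmax_rows(tcrossprod(q[, cols, drop = FALSE],
                                 k[, cols, drop = FALSE]) / sqrt(dh))
    attn[[h]] <- a
    o[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  out <- sweep(o %*% p$Wo, 2, p$bo, "+")
  list(out = out,
       cache = list(q_in = q_in, k_in = k_in, v_in = v_in,
                    q = q, k = k, v = v, o = o, attn = attn,
                    n_heads = n_heads, dh = dh))
}

mha_bwd <- function(dout, cache, p) {
  dh <- cache$dh
  do <- tcrossprod(dout, p$Wo)
  g <- list(Wo = crossprod(cache$o, dout), bo = colSums(dout))
  dq <- matrix(0, nrow(cache$q), ncol(cache$q))
  dk <- matrix(0, nrow(cache$k), ncol(cache$k))
  dv <- matrix(0, nrow(cache$v), ncol(cache$v))
  for (h in seq_len(cache$n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    a <- cache$attn[[h]]
    doh <- do[, cols, drop = FALSE]
    da <- tcrossprod(doh, cache$v[, cols, drop = FALSE])
    dv[, cols] <- crossprod(a, doh)
    ds <- a * (da - rowSums(da * a))
    dq[, cols] <- ds %*% cache$k[, cols, drop = FALSE] / sqrt(dh)
    dk[, cols] <- crossprod(ds, cache$q[, cols, drop = FALSE]) / sqrt(dh)
  }
  g$Wq <- crossprod(cache$q_in, dq); g$bq <- colSums(dq)
  g$Wk <- crossprod(cache$k_in, dk); g$bk <- colSums(dk)
  g$Wv <- crossprod(cache$v_in, dv); g$bv <- colSums(dv)
  list(dq_in = tcrossprod(dq, p$Wq),
       dk_in = tcrossprod(dk, p$Wk),
       dv_in = tcrossprod(dv, p$Wv),
       grads = g)
}

ffn_fwd <- function(x, p) {
  h <- sweep(x %*% p$W1, 2, p$b1, "+")
  hr <- pmax(h, 0)
  list(out = sweep(hr %*% p$W2, 2, p$b2, "+"),
       cache = list(x = x, h = h, hr = hr))
}

ffn_bwd <- function(dy, cache, p) {
  dhr <- tcrossprod(dy, p$W2)
  dh <- dhr * (cache$h > 0)
  list(dx = tcrossprod(dh, p$W1),
       grads = list(W1 = crossprod(cache$x, dh), b1 = colSums(dh),
                    W2 = crossprod(cache$hr, dy), b2 = colSums(dy)))
}

# --- nested-list (parameter tree) helpers ------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_reduce_sum <- function(f, tree) {
  if (is.list(tree)) {
    sum(vapply(tree, function(t) tree_reduce_sum(f, t), 0))
  } else {
    f(tree)
  }
}

zero_like <- function(tree) tree_map(function(x) x * 0, tree)

count_parameters <- function(tree) tree_reduce_sum(length, tree)
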
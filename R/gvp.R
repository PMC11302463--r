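# The geometric vector perceptron (GVP): a layer operating jointly on
# rotation-invariant scalar channels S (length n) and rotation-equivariant
# vector channels V (v x 3).  The vector path is strictly linear across
# channels (never across the three spatial coordinates) and bias-free,
# which is what makes the layer exactly equivariant:
#
#   V_h = W_h V            (channel mixing of the input vectors)
#   S_h = ||V_h||_2        (row-wise norms: invariant scalars)
#   S_m = W_m [S_h; S_n]   (affine map on concatenated scalars, with bias)
#   V_mu = W_mu V_h        (second channel mixing)
#   v_mu = ||V_mu||_2
#   V' = sigma_plus(v_mu) . V_mu   (row-wise norm gating)
#   S' = sigma(S_m)
#
# with h = max(v, n).  sigma defaults to ReLU, sigma_plus to the logistic
# gate; norms carry an epsilon floor inside the square root so gradients
# stay finite at zero vectors.

GVP_EPS <- 1e-8

#' Create a GVP parameter set
#'
#' @param n_in,v_in Input scalar / vector channel counts.
#' @param n_out,v_out Output scalar / vector channel counts.
#' @param sigma Scalar nonlinearity: `"relu"` or `"identity"`.
#' @param sigma_plus Gating nonlinearity: `"sigmoid"` or `"identity"`.
#' @param init `"glorot"` for seeded random weights (the caller seeds the
#'   RNG) or `"identity"` for square identity maps (useful in tests).
#' @return List of GVP weights: `W_h` (v_in x h), `W_mu` (h x v_out),
#'   `W_m` ((h + n_in) x n_out), `b_m`, plus the activation names.
#' @export
gvp_params <- function(n_in, v_in, n_out, v_out,
                       sigma = "relu", sigma_plus = "sigmoid",
                       init = "glorot") {
  if (n_in == 0 && v_in == 0) stop("GVP needs at least one input channel")
  h <- max(v_in, n_in)
  mk <- function(nr, nc) {
    if (init == "identity") {
      diag(1, nr, nc)
    } else {
      matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    }
  }
  list(W_h = mk(v_in, h), W_mu = mk(h, v_out),
       W_m = mk(h + n_in, n_out), b_m = numeric(n_out),
       sigma = sigma, sigma_plus = sigma_plus, h = h,
       n_in = n_in, v_in = v_in, n_out = n_out, v_out = v_out)
}

act_apply <- function(x, name) {
  switch(name, relu = pmax(x, 0), identity = x,
         sigmoid = logistic(x), stop("unknown activation ", name))
}

#' Forward pass of a geometric vector perceptron
#'
#' @param S Scalar channels: B x n matrix (or length-n vector for a single
#'   state).
#' @param V Vector channels: list with components `x`, `y`, `z`, each a
#'   B x v matrix (or a v x 3 matrix for a single state).
#' @param p Parameters from [gvp_params()].
#' @param with_cache Keep intermediates for [gvp_backward()].
#' @return List with `S` (B x n_out), `V` (list x/y/z of B x v_out), and
#'   `cache`.
#' @export
gvp_forward <- function(S, V, p, with_cache = FALSE) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  if (is.matrix(V)) V <- list(x = t(V[, 1, drop = FALSE]),
                              y = t(V[, 2, drop = FALSE]),
                              z = t(V[, 3, drop = FALSE]))
  if (any(!is.finite(S)) || any(!vapply(V, function(m) all(is.finite(m)), TRUE))) {
    stop("non-finite values in GVP input")
  }
  Vh <- lapply(V, function(m) m %*% p$W_h)
  Sh <- sqrt(Vh$x^2 + Vh$y^2 + Vh$z^2 + GVP_EPS)
  M <- cbind(Sh, S)
  Sm <- sweep(M %*% p$W_m, 2, p$b_m, "+")
  Vmu <- lapply(Vh, function(m) m %*% p$W_mu)
  vmu <- sqrt(Vmu$x^2 + Vmu$y^2 + Vmu$z^2 + GVP_EPS)
  gate <- act_apply(vmu, p$sigma_plus)
  Vp <- lapply(Vmu, function(m) gate * m)
  Sp <- act_apply(Sm, p$sigma)
  out <- list(S = Sp, V = Vp)
  if (with_cache) {
    out$cache <- list(S = S, V = V, Vh = Vh, Sh = Sh, M = M, Sm = Sm,
                      Vmu = Vmu, vmu = vmu, gate = gate)
  }
  out
}

#' Backward pass of a geometric vector perceptron
#'
#' @param dS,dV Gradients of the loss with respect to the layer outputs
#'   (same shapes as the forward outputs).
#' @param cache Cache from `gvp_forward(..., with_cache = TRUE)`.
#' @param p Parameters from [gvp_params()].
#' @return List with `dS`, `dV` (input gradients) and `grads` (W_h, W_mu,
#'   W_m, b_m).
#' @export
gvp_backward <- function(dS, dV, cache, p) {
  dSm <- switch(p$sigma,
                relu = dS * (cache$Sm > 0),
                identity = dS)
  dM <- tcrossprod(dSm, p$W_m)
  gW_m <- crossprod(cache$M, dSm)
  gb_m <- colSums(dSm)
  h <- p$h
  dSh <- dM[, seq_len(h), drop = FALSE]
  dS_in <- dM[, h + seq_len(p$n_in), drop = FALSE]
  gate <- cache$gate
  dgate <- dV$x * cache$Vmu$x + dV$y * cache$Vmu$y + dV$z * cache$Vmu$z
  dVmu <- lapply(dV, function(m) m * gate)
  dvmu <- switch(p$sigma_plus,
                 sigmoid = dgate * gate * (1 - gate),
                 identity = dgate)
  rad <- dvmu / cache$vmu
  dVmu <- list(x = dVmu$x + rad * cache$Vmu$x,
               y = dVmu$y + rad * cache$Vmu$y,
               z = dVmu$z + rad * cache$Vmu$z)
  dVh <- lapply(dVmu, function(m) tcrossprod(m, p$W_mu))
  gW_mu <- crossprod(cache$Vh$x, dVmu$x) + crossprod(cache$Vh$y, dVmu$y) +
    crossprod(cache$Vh$z, dVmu$z)
  shr <- dSh / cache$Sh
  dVh <- list(x = dVh$x + shr * cache$Vh$x,
              y = dVh$y + shr * cache$Vh$y,
              z = dVh$z + shr * cache$Vh$z)
  dV_in <- lapply(dVh, function(m) tcrossprod(m, p$W_h))
  gW_h <- crossprod(cache$V$x, dVh$x) + crossprod(cache$V$y, dVh$y) +
    crossprod(cache$V$z, dVh$z)
  list(dS = dS_in, dV = dV_in,
       grads = list(W_h = gW_h, W_mu = gW_mu, W_m = gW_m, b_m = gb_m))
}

# --- GVP-GNN message passing over the residue graph ---------------------

# Build node scalar/vector inputs for the GVP stack from a feature bundle.
gvp_node_inputs <- function(bundle) {
  dih_feat <- cbind(sin(bundle$dihedrals) * bundle$dihedrals_defined,
                    cos(bundle$dihedrals) * bundle$dihedrals_defined)
  S0 <- cbind(dih_feat, bundle$plddt, bundle$seq_embedding)
  pick <- function(m, at) m[, at, drop = FALSE]
  comp <- function(ci) cbind(
    pick(bundle$orientation_forward, c(0, 3, 6) + ci),
    pick(bundle$orientation_backward, c(0, 3, 6) + ci),
    pick(bundle$sidechain, c(0, 3) + ci))
  list(S = S0, V = list(x = comp(1), y = comp(2), z = comp(3)),
       dih_feat = dih_feat)
}

# Forward through embedding GVP + n message-passing blocks; returns the
# final node states and the full cache for backprop.
gvp_stack_forward <- function(bundle, params, config) {
  inp <- gvp_node_inputs(bundle)
  emb <- gvp_forward(inp$S, inp$V, params$gvp_embed, with_cache = TRUE)
  S <- emb$S; V <- emb$V
  edges <- bundle$edges
  L <- bundle$n_residues
  layer_caches <- vector("list", length(params$gvp_layers))
  for (l in seq_along(params$gvp_layers)) {
    pl <- params$gvp_layers[[l]]
    lc <- list()
    if (nrow(edges) > 0) {
      to <- edges[, "to"]; from <- edges[, "from"]
      Se <- cbind(S[to, , drop = FALSE], S[from, , drop = FALSE],
                  bundle$edge_rbf)
      Ve <- list(x = cbind(V$x[to, , drop = FALSE], V$x[from, , drop = FALSE],
                           bundle$edge_vector[, 1]),
                 y = cbind(V$y[to, , drop = FALSE], V$y[from, , drop = FALSE],
                           bundle$edge_vector[, 2]),
                 z = cbind(V$z[to, , drop = FALSE], V$z[from, , drop = FALSE],
                           bundle$edge_vector[, 3]))
      msg <- gvp_forward(Se, Ve, pl$msg, with_cache = TRUE)
      counts <- tabulate(to, nbins = L)
      agg <- function(m) {
        out <- matrix(0, L, ncol(m))
        rs <- rowsum(m, group = to)
        idx <- as.integer(rownames(rs))
        out[idx, ] <- rs / counts[idx]
        out
      }
      aggS <- agg(msg$S)
      aggV <- lapply(msg$V, agg)
      lc$msg <- msg$cache
      lc$counts <- counts
    } else {
      aggS <- matrix(0, L, pl$msg$n_out)
      aggV <- list(x = matrix(0, L, pl$msg$v_out),
                   y = matrix(0, L, pl$msg$v_out),
                   z = matrix(0, L, pl$msg$v_out))
      lc$msg <- NULL
    }
    ln1 <- layernorm_fwd(S + aggS, pl$ln1)
    S1 <- ln1$out
    V1 <- tree_map2(`+`, V, aggV)
    ff <- gvp_forward(S1, V1, pl$node, with_cache = TRUE)
    ln2 <- layernorm_fwd(S1 + ff$S, pl$ln2)
    lc$ln1 <- ln1$cache; lc$ln2 <- ln2$cache; lc$ff <- ff$cache
    layer_caches[[l]] <- lc
    S <- ln2$out
    V <- tree_map2(`+`, V1, ff$V)
  }
  vnorm <- sqrt(V$x^2 + V$y^2 + V$z^2 + GVP_EPS)
  scal <- cbind(S, vnorm)
  proj <- linear_fwd(scal, params$gvp_out)
  list(out = proj$out,
       cache = list(inp = inp, emb = emb$cache, layers = layer_caches,
                    S = S, V = V, vnorm = vnorm, scal = scal,
                    proj = proj$cache, edges = edges, L = L))
}

gvp_stack_backward <- function(dout, cache, params, config) {
  grads <- list()
  pb <- linear_bwd(dout, cache$proj, params$gvp_out)
  grads$gvp_out <- pb$grads
  ns <- ncol(cache$S)
  dS <- pb$dx[, seq_len(ns), drop = FALSE]
  dnorm <- pb$dx[, ns + seq_len(ncol(cache$vnorm)), drop = FALSE]
  rad <- dnorm / cache$vnorm
  dV <- list(x = rad * cache$V$x, y = rad * cache$V$y, z = rad * cache$V$z)
  grads$gvp_layers <- vector("list", length(params$gvp_layers))
  edges <- cache$edges
  for (l in rev(seq_along(params$gvp_layers))) {
    pl <- params$gvp_layers[[l]]
    lc <- cache$layers[[l]]
    gl <- list()
    # V_out = V1 + ff$V ; S_out = LN2(S1 + ff$S)
    ln2b <- layernorm_bwd(dS, lc$ln2, pl$ln2)
    gl$ln2 <- ln2b$grads
    ffb <- gvp_backward(ln2b$dx, dV, lc$ff, pl$node)
    gl$node <- ffb$grads
    dS1 <- ln2b$dx + ffb$dS
    dV1 <- tree_map2(`+`, dV, ffb$dV)
    ln1b <- layernorm_bwd(dS1, lc$ln1, pl$ln1)
    gl$ln1 <- ln1b$grads
    dS_res <- ln1b$dx          # gradient of (S + aggS)
    dAggV <- dV1
    dS <- dS_res               # residual into previous S
    dV <- dV1
    if (!is.null(lc$msg)) {
      to <- edges[, "to"]; from <- edges[, "from"]
      cnt <- lc$counts[to]
      dmsgS <- dS_res[to, , drop = FALSE] / cnt
      dmsgV <- lapply(dAggV, function(m) m[to, , drop = FALSE] / cnt)
      mb <- gvp_backward(dmsgS, dmsgV, lc$msg, pl$msg)
      gl$msg <- mb$grads
      nsS <- ncol(dS)
      nvV <- ncol(dV$x)
      addS <- function(acc, contrib, idx) {
        rs <- rowsum(contrib, group = idx)
        at <- as.integer(rownames(rs))
        acc[at, ] <- acc[at, , drop = FALSE] + rs
        acc
      }
      dS <- addS(dS, mb$dS[, seq_len(nsS), drop = FALSE], to)
      dS <- addS(dS, mb$dS[, nsS + seq_len(nsS), drop = FALSE], from)
      for (cc in c("x", "y", "z")) {
        dV[[cc]] <- addS(dV[[cc]], mb$dV[[cc]][, seq_len(nvV), drop = FALSE], to)
        dV[[cc]] <- addS(dV[[cc]], mb$dV[[cc]][, nvV + seq_len(nvV), drop = FALSE], from)
      }
    } else {
      gl$msg <- zero_like(pl$msg[c("W_h", "W_mu", "W_m", "b_m")])
    }
    grads$gvp_layers[[l]] <- gl
  }
  eb <- gvp_backward(dS, dV, cache$emb, params$gvp_embed)
  grads$gvp_embed <- eb$grads
  list(grads = grads, dS0 = eb$dS, dV0 = eb$dV)
}
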
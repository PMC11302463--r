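# The full predictor: per-residue feature-embedding summation, GVP-GNN +
# transformer self-attention encoder, and a GO-query transformer decoder
# with a sigmoid head producing one confidence per candidate GO term.
#
# Every quantity entering the transformer stack is a rotation-invariant
# scalar (distances, torsions, vector-channel norms), so predictions are
# invariant under rigid motions of the input structure by construction.

#' Model configuration
#'
#' Hyperparameters of the predictor and its training recipe.  Defaults
#' follow the published recipe where stated (embedding dimension 128,
#' eight attention heads, two GVP layers, pLDDT threshold 0.9, positive
#' class weight 3.0, Adam with learning rate 1e-4, batch size 8); layer
#' counts and channel widths not fixed by the recipe are configurable.
#'
#' @param d_model Embedding dimension shared by all feature streams.
#' @param n_heads Attention heads (must divide `d_model`).
#' @param n_gvp_layers GVP message-passing blocks.
#' @param n_encoder_layers,n_decoder_layers Transformer layer counts.
#' @param k_neighbors Neighbours in the residue kNN graph.
#' @param plddt_threshold Residues below this confidence are geometry-masked.
#' @param pos_weight Weight of positive labels in the training loss.
#' @param learning_rate,batch_size,epochs,patience,grad_clip Training
#'   recipe (Adam; early stopping on validation loss; global-norm gradient
#'   clipping).
#' @param d_esm Dimension of the input sequence embeddings.
#' @param gvp_scalar_channels,gvp_vector_channels Hidden channel counts of
#'   the GVP node states.
#' @param d_ffn Feed-forward width of the transformer blocks.
#' @param n_rbf,d_max Radial-basis encoding of edge distances.
#' @param seed Integer seed controlling initialization and data order.
#' @return A list of class `model_config`.
#' @export
model_config <- function(d_model = 128, n_heads = 8, n_gvp_layers = 2,
                         n_encoder_layers = 4, n_decoder_layers = 2,
                         k_neighbors = 30, plddt_threshold = 0.9,
                         pos_weight = 3.0, learning_rate = 1e-4,
                         batch_size = 8, epochs = 30, patience = 5,
                         grad_clip = 1.0, d_esm = 32,
                         gvp_scalar_channels = 128,
                         gvp_vector_channels = 16,
                         d_ffn = 2 * d_model, n_rbf = 16, d_max = 20,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(d_model %% n_heads == 0, d_model >= 1, n_heads >= 1,
            n_gvp_layers >= 1, n_encoder_layers >= 1, n_decoder_layers >= 1,
            k_neighbors >= 1, pos_weight > 0,
            plddt_threshold >= 0, plddt_threshold <= 1)
  structure(cfg, class = "model_config")
}

N_TOKENS <- 21  # 20 amino acids + X

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

linear_params <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out))
}

mha_params <- function(d) {
  list(Wq = glorot(d, d), bq = numeric(d), Wk = glorot(d, d),
       bk = numeric(d), Wv = glorot(d, d), bv = numeric(d),
       Wo = glorot(d, d), bo = numeric(d))
}

ln_params <- function(d) list(gamma = rep(1, d), beta = numeric(d))

ffn_params <- function(d, dff) {
  list(W1 = glorot(d, dff), b1 = numeric(dff),
       W2 = glorot(dff, d), b2 = numeric(d))
}

#' Initialize model parameters
#'
#' @param config A [model_config()].
#' @param n_terms Number of candidate GO terms (rows of the GO-query
#'   embedding table).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Nested list of parameter tensors (class `model_params`).
#' @export
init_model_params <- function(config, n_terms, seed = config$seed) {
  stopifnot(n_terms >= 1)
  set.seed(seed)
  d <- config$d_model
  ns <- config$gvp_scalar_channels
  nv <- config$gvp_vector_channels
  n0 <- 7 + config$d_esm   # dihedral sin/cos (6) + pLDDT + sequence emb
  v0 <- 8                  # 6 orientation + 2 side-chain vectors
  p <- list(
    gvp_embed = gvp_params(n0, v0, ns, nv),
    gvp_layers = lapply(seq_len(config$n_gvp_layers), function(l) {
      list(msg = gvp_params(2 * ns + config$n_rbf, 2 * nv + 1, ns, nv),
           node = gvp_params(ns, nv, ns, nv),
           ln1 = ln_params(ns), ln2 = ln_params(ns))
    }),
    gvp_out = linear_params(ns + nv, d),
    token_emb = glorot(N_TOKENS, d),
    dih = linear_params(6, d),
    plddt = linear_params(1, d),
    esm = linear_params(config$d_esm, d),
    enc = lapply(seq_len(config$n_encoder_layers), function(l) {
      list(attn = mha_params(d), ln1 = ln_params(d),
           ffn = ffn_params(d, config$d_ffn), ln2 = ln_params(d))
    }),
    dec = lapply(seq_len(config$n_decoder_layers), function(l) {
      list(self_attn = mha_params(d), ln1 = ln_params(d),
           cross_attn = mha_params(d), ln2 = ln_params(d),
           ffn = ffn_params(d, config$d_ffn), ln3 = ln_params(d))
    }),
    go_query = glorot(n_terms, d),
    head = list(W = glorot(d, 1), b = numeric(1))
  )
  class(p) <- c("model_params", "list")
  p
}

# Analytic parameter count implied by a configuration (self-consistency
# check against count_parameters()).
analytic_parameter_count <- function(config, n_terms) {
  d <- config$d_model; ns <- config$gvp_scalar_channels
  nv <- config$gvp_vector_channels; dff <- config$d_ffn
  n0 <- 7 + config$d_esm; v0 <- 8
  gvp_count <- function(n_in, v_in, n_out, v_out) {
    h <- max(v_in, n_in)
    v_in * h + h * v_out + (h + n_in) * n_out + n_out
  }
  mha <- 4 * (d * d + d)
  ln <- 2 * d
  ffn <- d * dff + dff + dff * d + d
  gvp_count(n0, v0, ns, nv) +
    config$n_gvp_layers *
      (gvp_count(2 * ns + config$n_rbf, 2 * nv + 1, ns, nv) +
         gvp_count(ns, nv, ns, nv) + 2 * (2 * ns)) +
    ((ns + nv) * d + d) +
    N_TOKENS * d + (6 * d + d) + (1 * d + d) + (config$d_esm * d + d) +
    config$n_encoder_layers * (mha + ffn + 2 * ln) +
    config$n_decoder_layers * (2 * mha + ffn + 3 * ln) +
    n_terms * d + (d + 1)
}

# Trainable-leaf subtree of a GVP parameter list (drops metadata fields).
gvp_trainable <- function(p) p[c("W_h", "W_mu", "W_m", "b_m")]

#' Sum the per-residue feature-embedding streams
#'
#' Embeds each feature stream (amino-acid tokens, the invariant structural
#' summary from the GVP stack, dihedral sin/cos, sequence embeddings,
#' pLDDT) into `d_model` dimensions and sums them element-wise.
#'
#' @param streams Named list with entries `token` (integer vector),
#'   `invariant` (L x d_model matrix, already embedded), `dihedral`
#'   (L x 6), `esm` (L x d_esm) and `plddt` (length-L numeric).
#' @param params Model parameters.
#' @return L x d_model matrix.
#' @export
embed_and_sum <- function(streams, params) {
  for (need in c("token", "invariant", "dihedral", "esm", "plddt")) {
    if (is.null(streams[[need]])) stop("missing feature stream: ", need)
  }
  params$token_emb[streams$token, , drop = FALSE] +
    streams$invariant +
    linear_fwd(streams$dihedral, params$dih)$out +
    linear_fwd(matrix(streams$plddt, ncol = 1), params$plddt)$out +
    linear_fwd(streams$esm, params$esm)$out
}

encode_forward <- function(bundle, params, config) {
  if (bundle$n_residues < 1) stop("empty protein")
  gvp <- gvp_stack_forward(bundle, params, config)
  dih_feat <- gvp$cache$inp$dih_feat
  h <- embed_and_sum(list(token = bundle$tokens, invariant = gvp$out,
                          dihedral = dih_feat, esm = bundle$seq_embedding,
                          plddt = bundle$plddt), params)
  emb_cache <- list(dih_feat = dih_feat, tokens = bundle$tokens,
                    plddt = bundle$plddt, esm = bundle$seq_embedding)
  enc_caches <- vector("list", length(params$enc))
  for (l in seq_along(params$enc)) {
    pl <- params$enc[[l]]
    at <- mha_fwd(h, h, h, pl$attn, config$n_heads)
    ln1 <- layernorm_fwd(h + at$out, pl$ln1)
    ff <- ffn_fwd(ln1$out, pl$ffn)
    ln2 <- layernorm_fwd(ln1$out + ff$out, pl$ln2)
    enc_caches[[l]] <- list(attn = at$cache, ln1 = ln1$cache,
                            ffn = ff$cache, ln2 = ln2$cache)
    h <- ln2$out
  }
  list(out = h, cache = list(gvp = gvp$cache, emb = emb_cache,
                             enc = enc_caches))
}

encode_backward <- function(dh, cache, params, config) {
  grads <- list(enc = vector("list", length(params$enc)))
  for (l in rev(seq_along(params$enc))) {
    pl <- params$enc[[l]]; lc <- cache$enc[[l]]
    ln2b <- layernorm_bwd(dh, lc$ln2, pl$ln2)
    ffb <- ffn_bwd(ln2b$dx, lc$ffn, pl$ffn)
    d1 <- ln2b$dx + ffb$dx
    ln1b <- layernorm_bwd(d1, lc$ln1, pl$ln1)
    ab <- mha_bwd(ln1b$dx, lc$attn, pl$attn)
    dh <- ln1b$dx + ab$dq_in + ab$dk_in + ab$dv_in
    grads$enc[[l]] <- list(attn = ab$grads, ln1 = ln1b$grads,
                           ffn = ffb$grads, ln2 = ln2b$grads)
  }
  # dh is now the gradient w.r.t. the summed embedding
  ec <- cache$emb
  grads$token_emb <- matrix(0, N_TOKENS, ncol(dh))
  tok_sum <- rowsum(dh, group = ec$tokens)
  grads$token_emb[as.integer(rownames(tok_sum)), ] <- tok_sum
  grads$dih <- list(W = crossprod(ec$dih_feat, dh), b = colSums(dh))
  grads$plddt <- list(W = crossprod(matrix(ec$plddt, ncol = 1), dh),
                      b = colSums(dh))
  grads$esm <- list(W = crossprod(ec$esm, dh), b = colSums(dh))
  gvpb <- gvp_stack_backward(dh, cache$gvp, params, config)
  grads <- c(grads, gvpb$grads)
  grads
}

decode_forward <- function(context, params, config) {
  if (nrow(params$go_query) < 1) stop("zero candidate terms")
  q <- params$go_query
  dec_caches <- vector("list", length(params$dec))
  for (l in seq_along(params$dec)) {
    pl <- params$dec[[l]]
    sa <- mha_fwd(q, q, q, pl$self_attn, config$n_heads)
    ln1 <- layernorm_fwd(q + sa$out, pl$ln1)
    ca <- mha_fwd(ln1$out, context, context, pl$cross_attn, config$n_heads)
    ln2 <- layernorm_fwd(ln1$out + ca$out, pl$ln2)
    ff <- ffn_fwd(ln2$out, pl$ffn)
    ln3 <- layernorm_fwd(ln2$out + ff$out, pl$ln3)
    dec_caches[[l]] <- list(self_attn = sa$cache, ln1 = ln1$cache,
                            cross_attn = ca$cache, ln2 = ln2$cache,
                            ffn = ff$cache, ln3 = ln3$cache)
    q <- ln3$out
  }
  head <- linear_fwd(q, params$head)
  logits <- drop(head$out)
  list(logits = logits, probs = logistic(logits),
       cache = list(dec = dec_caches, head = head$cache))
}

decode_backward <- function(dlogits, cache, params, config) {
  grads <- list(dec = vector("list", length(params$dec)))
  hb <- linear_bwd(matrix(dlogits, ncol = 1), cache$head, params$head)
  grads$head <- hb$grads
  dq <- hb$dx
  dcontext <- NULL
  for (l in rev(seq_along(params$dec))) {
    pl <- params$dec[[l]]; lc <- cache$dec[[l]]
    ln3b <- layernorm_bwd(dq, lc$ln3, pl$ln3)
    ffb <- ffn_bwd(ln3b$dx, lc$ffn, pl$ffn)
    d2 <- ln3b$dx + ffb$dx
    ln2b <- layernorm_bwd(d2, lc$ln2, pl$ln2)
    cab <- mha_bwd(ln2b$dx, lc$cross_attn, pl$cross_attn)
    dctx_l <- cab$dk_in + cab$dv_in
    dcontext <- if (is.null(dcontext)) dctx_l else dcontext + dctx_l
    d1 <- ln2b$dx + cab$dq_in
    ln1b <- layernorm_bwd(d1, lc$ln1, pl$ln1)
    sab <- mha_bwd(ln1b$dx, lc$self_attn, pl$self_attn)
    dq <- ln1b$dx + sab$dq_in + sab$dk_in + sab$dv_in
    grads$dec[[l]] <- list(self_attn = sab$grads, ln1 = ln1b$grads,
                           cross_attn = cab$grads, ln2 = ln2b$grads,
                           ffn = ffb$grads, ln3 = ln3b$grads)
  }
  grads$go_query <- dq
  list(grads = grads, dcontext = dcontext)
}

#' Encode a featurized protein into per-residue context states
#'
#' GVP-GNN stack output (scalarized) summed with the token/dihedral/
#' sequence-embedding/pLDDT streams, then passed through the transformer
#' encoder layers (bidirectional self-attention, no mask).
#'
#' @param bundle A `feature_bundle` from [featurize()].
#' @param params Model parameters from [init_model_params()].
#' @param config The [model_config()].
#' @return n_residues x d_model matrix of context states.
#' @export
encode <- function(bundle, params, config) {
  encode_forward(bundle, params, config)$out
}

#' Decode GO-term confidences from encoder context
#'
#' GO-query self-attention, cross-attention against the residue context,
#' and a feed-forward block per decoder layer (no attention masks), then a
#' linear + logistic head giving one confidence in \[0, 1\] per candidate
#' term.
#'
#' @param context Encoder output (n_residues x d_model).
#' @inheritParams encode
#' @return Numeric vector of confidences, one per candidate term.
#' @export
decode <- function(context, params, config) {
  decode_forward(context, params, config)$probs
}

#' Weighted binary cross-entropy loss
#'
#' Mean over terms of `-(pos_weight * y * log(p) + (1 - y) * log(1 - p))`.
#' Predictions exactly at 0 or 1 are clamped to `1e-7` away from the
#' boundary with a warning.
#'
#' @param pred Predicted confidences in (0, 1).
#' @param labels Binary labels (same shape).
#' @param pos_weight Weight applied to positive terms.
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(pred, labels, pos_weight = 3.0) {
  stopifnot(length(pred) == length(labels), all(labels %in% c(0, 1)))
  if (any(pred <= 0 | pred >= 1)) {
    warning("predictions at the boundary clamped to [1e-7, 1 - 1e-7]")
    pred <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  }
  -mean(pos_weight * labels * log(pred) + (1 - labels) * log(1 - pred))
}

# Numerically stable loss + gradient w.r.t. logits.
bce_logits_loss_grad <- function(logits, labels, pos_weight) {
  spn <- log1p(exp(-abs(logits))) + pmax(-logits, 0)   # softplus(-z)
  loss <- mean(pos_weight * labels * spn + (1 - labels) * (logits + spn))
  p <- logistic(logits)
  grad <- (pos_weight * labels * (p - 1) + (1 - labels) * p) / length(logits)
  list(loss = loss, grad = grad)
}

model_forward <- function(bundle, params, config, labels = NULL) {
  enc <- encode_forward(bundle, params, config)
  dec <- decode_forward(enc$out, params, config)
  out <- list(probs = dec$probs, logits = dec$logits,
              enc_cache = enc$cache, dec_cache = dec$cache,
              context = enc$out)
  if (!is.null(labels)) {
    lg <- bce_logits_loss_grad(dec$logits, labels, config$pos_weight)
    out$loss <- lg$loss
    out$dlogits <- lg$grad
  }
  out
}

model_backward <- function(fw, params, config) {
  db <- decode_backward(fw$dlogits, fw$dec_cache, params, config)
  eg <- encode_backward(db$dcontext, fw$enc_cache, params, config)
  c(db$grads, eg)
}
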
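# Training recipe: Adam on the weighted binary cross-entropy loss, batch
# accumulation, global-norm gradient clipping, early stopping on
# validation loss with checkpointing of the best parameters.

# Update parameter tree `p` in place along the gradient tree `g` (walked
# by name/position; metadata leaves absent from `g` are untouched).
adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  walk(p, g, m, v)
}

clip_gradients <- function(grads, max_norm) {
  nrm <- sqrt(tree_reduce_sum(function(x) sum(x * x), grads))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- tree_map(function(x) x * (max_norm / nrm), grads)
  }
  grads
}

featurize_all <- function(structures, embeddings, config) {
  out <- lapply(names(structures), function(id) {
    featurize(structures[[id]], embeddings[[id]],
              k = config$k_neighbors,
              plddt_threshold = config$plddt_threshold,
              n_rbf = config$n_rbf, d_max = config$d_max)
  })
  names(out) <- names(structures)
  out
}

label_matrix <- function(prop_ann, ids, candidate_terms) {
  t(vapply(ids, function(id) {
    as.numeric(candidate_terms %in% prop_ann$annotations[[id]])
  }, numeric(length(candidate_terms))))
}

#' Train the GO-term predictor
#'
#' Full training recipe on a dataset of structures, per-residue sequence
#' embeddings and GO annotations: candidate terms are selected from the
#' propagated training annotations, every protein is featurized once, and
#' the model is optimized with Adam on the weighted binary cross-entropy
#' loss (batch-accumulated gradients, global-norm clipping, early stopping
#' on validation loss, checkpointing of the best epoch).  Deterministic
#' given `config$seed`.
#'
#' @param dataset List with `structures` (named list of
#'   [protein_structure()]), `embeddings` (named list of matrices),
#'   `annotations` (unpropagated [annotation_set()]), `dag` (a `go_dag`)
#'   and `splits` (named character vector: train/val/test per protein id),
#'   as produced by [make_synthetic_dataset()].
#' @param config A [model_config()].
#' @param min_proteins Candidate-term threshold passed to
#'   [select_candidate_terms()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `gvpgo_model`.
#' @export
gvpgo_train <- function(dataset, config = model_config(),
                        min_proteins = 10, verbose = FALSE) {
  dag <- dataset$dag
  d_emb <- ncol(dataset$embeddings[[1]])
  if (d_emb != config$d_esm) {
    stop("sequence-embedding dimension (", d_emb,
         ") does not match config$d_esm (", config$d_esm, ")")
  }
  prop_ann <- propagate_annotations(dataset$annotations, dag)
  train_ids <- names(dataset$splits)[dataset$splits == "train"]
  val_ids <- names(dataset$splits)[dataset$splits == "val"]
  stopifnot(length(train_ids) > 0, length(val_ids) > 0)
  terms <- select_candidate_terms(
    annotation_set(prop_ann$annotations[train_ids], propagated = TRUE),
    dag, min_proteins = min_proteins)
  bundles <- featurize_all(dataset$structures, dataset$embeddings, config)
  y_train <- label_matrix(prop_ann, train_ids, terms)
  y_val <- label_matrix(prop_ann, val_ids, terms)
  params <- init_model_params(config, n_terms = length(terms))
  m_state <- NULL; v_state <- NULL; t_step <- 0
  best <- list(loss = Inf, params = params, epoch = 0)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  wait <- 0
  for (epoch in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, epoch))
    order_ids <- sample(train_ids)
    batches <- split(order_ids,
                     ceiling(seq_along(order_ids) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      acc <- NULL
      for (id in batch) {
        fw <- model_forward(bundles[[id]], params, config,
                            labels = y_train[id, ])
        if (!is.finite(fw$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", protein ", id)
        }
        epoch_loss <- epoch_loss + fw$loss
        g <- model_backward(fw, params, config)
        acc <- if (is.null(acc)) g else tree_map2(`+`, acc, g)
      }
      acc <- tree_map(function(x) x / length(batch), acc)
      acc <- clip_gradients(acc, config$grad_clip)
      if (is.null(m_state)) {
        m_state <- zero_like(acc); v_state <- zero_like(acc)
      }
      t_step <- t_step + 1
      upd <- adam_step(params, acc, m_state, v_state,
                       lr = config$learning_rate, t = t_step)
      params <- upd$p; m_state <- upd$m; v_state <- upd$v
    }
    train_loss <- epoch_loss / length(train_ids)
    val_loss <- mean(vapply(val_ids, function(id) {
      bce_logits_loss_grad(
        decode_forward(encode_forward(bundles[[id]], params, config)$out,
                       params, config)$logits,
        y_val[id, ], config$pos_weight)$loss
    }, 0))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      train_loss, val_loss))
    }
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config,
                 candidate_terms = terms, dag = dag, history = history,
                 best_epoch = best$epoch, best_val_loss = best$loss),
            class = "gvpgo_model")
}

#' @export
print.gvpgo_model <- function(x, ...) {
  cat("<gvpgo_model> ", length(x$candidate_terms), " candidate terms, ",
      count_parameters(trainable_parameters(x$params)),
      " trainable parameters\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs; best epoch ", x$best_epoch,
      " (validation loss ", sprintf("%.4f", x$best_val_loss), ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.gvpgo_model <- function(object, ...) {
  print(object)
  cat("  d_model ", object$config$d_model, ", heads ",
      object$config$n_heads, ", GVP layers ", object$config$n_gvp_layers,
      ", encoder ", object$config$n_encoder_layers, ", decoder ",
      object$config$n_decoder_layers, "\n", sep = "")
  invisible(object)
}

# Trainable subtree of the parameter list (metadata leaves dropped).
trainable_parameters <- function(params) {
  params$gvp_embed <- gvp_trainable(params$gvp_embed)
  params$gvp_layers <- lapply(params$gvp_layers, function(l) {
    l$msg <- gvp_trainable(l$msg); l$node <- gvp_trainable(l$node); l
  })
  params
}

#' Predict GO-term confidences for featurized proteins
#'
#' @param object A trained `gvpgo_model`.
#' @param bundles Named list of `feature_bundle`s (see [featurize()]).
#' @param ... Unused.
#' @return A [prediction_set()] of unpropagated confidences over the
#'   model's candidate terms.
#' @export
predict.gvpgo_model <- function(object, bundles, ...) {
  preds <- lapply(bundles, function(b) {
    ctx <- encode_forward(b, object$params, object$config)$out
    stats::setNames(decode_forward(ctx, object$params, object$config)$probs,
                    object$candidate_terms)
  })
  prediction_set(preds)
}

#' Predict GO terms for one structure file
#'
#' Full featurize -> encode -> decode pipeline for a single protein.
#'
#' @param model A trained `gvpgo_model`.
#' @param structure A [protein_structure()] (or path to a PDB/mmCIF file).
#' @param embedding n x d_esm sequence-embedding matrix; a stub embedding
#'   is generated when `NULL`.
#' @return Named numeric vector of confidences over the candidate terms.
#' @export
predict_structure <- function(model, structure, embedding = NULL) {
  if (is.character(structure)) structure <- read_structure(structure)
  if (is.null(embedding)) {
    embedding <- make_stub_embedding(structure$aa, model$config$d_esm,
                                     model$config$seed)
  }
  b <- featurize(structure, embedding, k = model$config$k_neighbors,
                 plddt_threshold = model$config$plddt_threshold,
                 n_rbf = model$config$n_rbf, d_max = model$config$d_max)
  ctx <- encode_forward(b, model$params, model$config)$out
  stats::setNames(decode_forward(ctx, model$params, model$config)$probs,
                  model$candidate_terms)
}

#' Save / load a model checkpoint
#'
#' The checkpoint records a format version, the full configuration, the
#' candidate-term list and all parameter tensors.
#'
#' @param model A `gvpgo_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `gvpgo_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(version = "gvpgo-checkpoint-1", model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$version, "gvpgo-checkpoint-1")) {
    stop("unrecognized checkpoint version in ", path)
  }
  structure(ck$model, class = "gvpgo_model")
}

PERMUTABLE_FEATURES <- c("esm", "token", "dihedral", "distance",
                         "edge_vector", "orientation_vector", "plddt",
                         "sidechain_vector")

# Permute one feature across all residues (or edges) pooled over the
# bundle list, preserving its marginal distribution while destroying its
# association with the proteins.
permute_feature <- function(bundles, feature, seed) {
  feature <- match.arg(feature, PERMUTABLE_FEATURES)
  set.seed(seed)
  node_level <- !feature %in% c("distance", "edge_vector")
  sizes <- vapply(bundles, function(b) {
    if (node_level) b$n_residues else nrow(b$edges)
  }, 0L)
  idx_split <- split(seq_len(sum(sizes)), rep(seq_along(bundles), sizes))
  perm <- sample(sum(sizes))
  get_rows <- function(f) do.call(rbind, lapply(bundles, f))
  pooled <- switch(feature,
    token = matrix(unlist(lapply(bundles, `[[`, "tokens")), ncol = 1),
    plddt = matrix(unlist(lapply(bundles, `[[`, "plddt")), ncol = 1),
    esm = get_rows(function(b) b$seq_embedding),
    dihedral = get_rows(function(b) cbind(b$dihedrals, b$dihedrals_defined)),
    orientation_vector = get_rows(function(b) {
      cbind(b$orientation_forward, b$orientation_backward,
            b$orientation_forward_defined, b$orientation_backward_defined)
    }),
    sidechain_vector = get_rows(function(b) b$sidechain),
    distance = matrix(unlist(lapply(bundles, `[[`, "edge_distance")),
                      ncol = 1),
    edge_vector = get_rows(function(b) b$edge_vector))
  pooled <- pooled[perm, , drop = FALSE]
  for (i in seq_along(bundles)) {
    rows <- pooled[idx_split[[i]], , drop = FALSE]
    b <- bundles[[i]]
    if (feature == "token") b$tokens <- as.integer(rows[, 1])
    if (feature == "plddt") b$plddt <- rows[, 1]
    if (feature == "esm") b$seq_embedding <- rows
    if (feature == "dihedral") {
      b$dihedrals <- rows[, 1:3, drop = FALSE]
      b$dihedrals_defined <- rows[, 4:6, drop = FALSE] > 0.5
      dimnames(b$dihedrals) <- dimnames(b$dihedrals_defined) <-
        list(NULL, c("phi", "psi", "omega"))
    }
    if (feature == "orientation_vector") {
      b$orientation_forward <- rows[, 1:9, drop = FALSE]
      b$orientation_backward <- rows[, 10:18, drop = FALSE]
      b$orientation_forward_defined <- rows[, 19] > 0.5
      b$orientation_backward_defined <- rows[, 20] > 0.5
    }
    if (feature == "sidechain_vector") b$sidechain <- rows
    if (feature == "distance") {
      b$edge_distance <- rows[, 1]
      b$edge_rbf <- rbf_encode(b$edge_distance, b$n_rbf, b$d_max)
    }
    if (feature == "edge_vector") b$edge_vector <- rows
    bundles[[i]] <- b
  }
  bundles
}

#' Permutation feature importance
#'
#' Re-evaluates the trained model with one input feature permuted across
#' all residues (pooled over the evaluation set), and reports the change
#' in the protein-centric metrics.  A feature the model relies on degrades
#' the metrics when permuted; an ignored feature leaves them unchanged.
#'
#' @param model A trained `gvpgo_model`.
#' @param dataset The dataset the model was trained on (see
#'   [gvpgo_train()]).
#' @param feature One of `"esm"`, `"token"`, `"dihedral"`, `"distance"`,
#'   `"edge_vector"`, `"orientation_vector"`, `"plddt"`,
#'   `"sidechain_vector"`.
#' @param seed Integer seed for the permutation.
#' @param split Evaluation split (default `"val"`).
#' @param ontology Namespace for the metrics.
#' @return List with the baseline and permuted metric sets and their
#'   deltas (`delta_fmax`, `delta_smin`, `delta_aupr`).
#' @export
permutation_importance <- function(model, dataset, feature, seed = 1,
                                   split = "val", ontology = "MFO") {
  ids <- names(dataset$splits)[dataset$splits == split]
  prop_ann <- propagate_annotations(dataset$annotations, dataset$dag)
  ic <- information_content(prop_ann, dataset$dag)
  truth <- annotation_set(prop_ann$annotations[ids], propagated = TRUE)
  bundles <- featurize_all(dataset$structures[ids],
                           dataset$embeddings[ids], model$config)
  score <- function(bl) {
    preds <- propagate_predictions(predict(model, bl), dataset$dag)
    list(fmax = fmax_metric(preds, truth, dataset$dag, ontology)$fmax,
         smin = smin_metric(preds, truth, dataset$dag, ic, ontology)$smin,
         aupr = aupr_metric(preds, truth, dataset$dag, ontology))
  }
  base <- score(bundles)
  perm <- score(permute_feature(bundles, feature, seed))
  list(feature = feature, baseline = base, permuted = perm,
       delta_fmax = perm$fmax - base$fmax,
       delta_smin = perm$smin - base$smin,
       delta_aupr = perm$aupr - base$aupr)
}
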
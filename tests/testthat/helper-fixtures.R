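# Shared fixtures: hand-written structure files, inline OBO ontologies,
# small model configurations and rotation helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three-residue PDB with pLDDT 95 / 85 / 91 in the B-factor column.
tiny_pdb_lines <- function(drop_atom = NULL) {
  s <- make_toy_structure(3, "helix", sequence = c("A", "G", "V"),
                          plddt = c(0.95, 0.85, 0.91), seed = 1,
                          protein_id = "tiny")
  path <- tempfile(fileext = ".pdb")
  write_structure(s, path)
  lines <- readLines(path)
  if (!is.null(drop_atom)) {
    lines <- lines[!grepl(drop_atom, lines)]
  }
  lines
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Chain ontology  c -> b -> a  (a is the MFO root), plus BPO/CCO roots so
# the namespaces partition.
chain_obo <- function() {
  write_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: molecular_function",
    "is_a: GO:0000001 ! a", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: molecular_function",
    "is_a: GO:0000002 ! b", "alt_id: GO:0000333", "",
    "[Term]", "id: GO:0000004", "name: bp root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000005", "name: cc root",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: molecular_function", "is_obsolete: true", ""), ".obo")
}

chain_dag <- function() parse_obo(chain_obo())

# Diamond: d -> {b, c} -> a  (two paths to the root).
diamond_dag <- function() {
  parse_obo(write_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: molecular_function",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: molecular_function",
    "relationship: part_of GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: d", "namespace: molecular_function",
    "is_a: GO:0000002", "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: bp root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000006", "name: cc root",
    "namespace: cellular_component", ""), ".obo"))
}

# Small configuration used throughout the model tests.
tiny_config <- function(...) {
  defaults <- list(d_model = 16, n_heads = 2, n_gvp_layers = 2,
                   n_encoder_layers = 1, n_decoder_layers = 1,
                   k_neighbors = 4, d_esm = 5, gvp_scalar_channels = 6,
                   gvp_vector_channels = 3, d_ffn = 12, n_rbf = 4, seed = 7)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_bundle <- function(len = 8, seed = 2, k = 4, conformation = "mixed",
                        plddt = 0.95) {
  s <- make_toy_structure(len, conformation, seed = seed, plddt = plddt)
  featurize(s, make_stub_embedding(s$aa, 5, 1), k = k, n_rbf = 4)
}

# Rotate a vector-channel list (x/y/z matrices) by rotation matrix R.
rotate_channels <- function(V, R) {
  list(x = V$x * R[1, 1] + V$y * R[1, 2] + V$z * R[1, 3],
       y = V$x * R[2, 1] + V$y * R[2, 2] + V$z * R[2, 3],
       z = V$x * R[3, 1] + V$y * R[3, 2] + V$z * R[3, 3])
}

seeded_rotation <- function(seed) {
  set.seed(seed)
  gvpgo:::random_rotation()
}

# Brute-force kNN oracle: full pairwise distance sort per residue.
brute_knn <- function(ca, k, subset = rep(TRUE, nrow(ca))) {
  idx <- which(subset)
  out <- list()
  for (a in idx) {
    d <- sqrt(colSums((t(ca[idx, , drop = FALSE]) - ca[a, ])^2))
    ord <- idx[order(d, idx)]
    ord <- ord[ord != a]
    out[[length(out) + 1]] <- cbind(a, ord[seq_len(min(k, length(ord)))])
  }
  do.call(rbind, out)
}

# Independent exhaustive-threshold Fmax oracle: re-implements the
# precision/recall averages from scratch and sweeps every distinct
# confidence value.
oracle_fmax <- function(preds, truth, mfo_terms, roots) {
  terms <- setdiff(mfo_terms, roots)
  truth <- lapply(truth, function(x) intersect(x, terms))
  ids <- names(truth)[lengths(truth) > 0]
  scores <- lapply(preds[ids], function(v) v[names(v) %in% terms])
  cand <- sort(unique(unlist(lapply(scores, unname))))
  cand <- cand[cand > 0]
  best <- 0
  for (t in cand) {
    prs <- c(); rc_sum <- 0
    for (p in ids) {
      pset <- names(scores[[p]])[scores[[p]] >= t]
      tp <- length(intersect(pset, truth[[p]]))
      if (length(pset) > 0) prs <- c(prs, tp / length(pset))
      rc_sum <- rc_sum + tp / length(truth[[p]])
    }
    if (length(prs) == 0) next
    pr <- mean(prs); rc <- rc_sum / length(ids)
    if (pr + rc > 0) best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

# Pairwise-comparison AUROC oracle (ties get half credit).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Random prediction/truth instance for the metric-oracle suites.
random_metric_instance <- function(seed, n_prot = 10, n_terms = 12) {
  set.seed(seed)
  dag <- make_toy_dag(n_terms, seed = seed)
  mfo <- setdiff(dag$terms[dag$namespace == "MFO"], dag$roots)
  ids <- sprintf("P%02d", seq_len(n_prot))
  truth <- lapply(ids, function(p) {
    sample(mfo, sample(1:min(4, length(mfo)), 1))
  })
  names(truth) <- ids
  truth <- propagate_annotations(annotation_set(truth), dag)
  preds <- lapply(ids, function(p) {
    terms <- sample(mfo, sample(seq_along(mfo), 1))
    stats::setNames(round(stats::runif(length(terms)), 2), terms)
  })
  names(preds) <- ids
  preds <- propagate_predictions(prediction_set(preds), dag)
  list(dag = dag, truth = truth, preds = preds, mfo = mfo, ids = ids)
}
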
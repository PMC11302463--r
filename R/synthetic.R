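# Synthetic data: backbones with exactly controlled torsions, toy GO DAGs,
# deterministic stub sequence embeddings and a plantable structure->function
# rule, so the whole pipeline is exercisable without downloads.
#
# Backbones are built by sequential internal-coordinate atom placement
# (NeRF) from ideal bond lengths and angles, which makes the backbone
# torsions analytically controllable: measuring phi/psi on a generated
# chain returns the requested values to machine precision.

IDEAL_GEOMETRY <- list(
  bond_n_ca = 1.458, bond_ca_c = 1.525, bond_c_n = 1.329,
  angle_n_ca_c = 111.0 * pi / 180,
  angle_ca_c_n = 116.2 * pi / 180,
  angle_c_n_ca = 121.7 * pi / 180
)

CONFORMATION_TORSIONS <- list(
  helix = list(phi = -57, psi = -47),
  helix_left = list(phi = 57, psi = 47),
  extended = list(phi = -120, psi = 120)
)

# Place atom D given A, B, C and the internal coordinates |CD|, angle BCD,
# torsion ABCD.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n * n))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion),
                 -sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

#' Build a backbone with exactly specified torsions
#'
#' Constructs an ideal-geometry backbone (bond lengths N-CA 1.458, CA-C
#' 1.525, C-N 1.329 Angstrom) by sequential atom placement with the
#' requested phi/psi torsions and omega = 180 degrees.  Named
#' conformations: `helix` (phi = -57, psi = -47), `helix_left` (its mirror
#' image, +57/+47), `extended` (-120/+120) and `mixed` (seeded alternating
#' helix/extended segments).
#'
#' @param length Number of residues (>= 2).
#' @param conformation One of `"helix"`, `"helix_left"`, `"extended"`,
#'   `"mixed"`; ignored when `torsions` is given.
#' @param torsions Optional list with numeric vectors `phi` and `psi`
#'   (degrees, length `length`; `phi[1]` and `psi[length]` are unused).
#' @param sequence Optional one-letter amino-acid string/vector; random if
#'   `NULL`.
#' @param plddt Per-residue confidence in \[0, 1\] (scalar recycled).
#' @param seed Integer seed for the random sequence / mixed segments.
#' @param protein_id Identifier for the returned structure.
#' @return A [protein_structure()].
#' @export
make_toy_structure <- function(length, conformation = "helix",
                               torsions = NULL, sequence = NULL,
                               plddt = 0.95, seed = 1,
                               protein_id = "synthetic") {
  stopifnot(length >= 2)
  set.seed(seed)
  if (is.null(torsions)) {
    if (conformation == "mixed") {
      phi <- numeric(length); psi <- numeric(length)
      i <- 1; state <- "helix"
      while (i <= length) {
        seg <- min(sample(4:8, 1), length - i + 1)
        phi[i:(i + seg - 1)] <- CONFORMATION_TORSIONS[[state]]$phi
        psi[i:(i + seg - 1)] <- CONFORMATION_TORSIONS[[state]]$psi
        i <- i + seg
        state <- if (state == "helix") "extended" else "helix"
      }
      torsions <- list(phi = phi, psi = psi)
    } else if (conformation %in% names(CONFORMATION_TORSIONS)) {
      torsions <- list(
        phi = rep(CONFORMATION_TORSIONS[[conformation]]$phi, length),
        psi = rep(CONFORMATION_TORSIONS[[conformation]]$psi, length))
    } else {
      stop("unknown conformation: ", conformation)
    }
  }
  phi <- torsions$phi * pi / 180
  psi <- torsions$psi * pi / 180
  omega <- pi
  g <- IDEAL_GEOMETRY
  N <- matrix(0, length, 3); CA <- matrix(0, length, 3)
  C <- matrix(0, length, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bond_n_ca, 0, 0)
  C[1, ] <- CA[1, ] + g$bond_ca_c * c(-cos(g$angle_n_ca_c),
                                      sin(g$angle_n_ca_c), 0)
  for (i in 2:length) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$bond_c_n, g$angle_ca_c_n, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$bond_n_ca, g$angle_c_n_ca, omega)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                         g$bond_ca_c, g$angle_n_ca_c, phi[i])
  }
  if (is.null(sequence)) {
    sequence <- sample(setdiff(AA_ALPHABET, "X"), length, replace = TRUE)
  } else if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  protein_structure(protein_id, seq_len(length), sequence, N, CA, C,
                    rep_len(plddt, length))
}

#' Generate a random toy GO DAG
#'
#' One random rooted DAG per namespace (MFO, BPO, CCO), acyclic by
#' construction: every non-root term draws its parent(s) among previously
#' created terms of the same namespace.
#'
#' @param n_terms Terms per namespace (>= 1, including the root).
#' @param branching Expected number of parents per term (1 or 2 drawn).
#' @param seed Integer seed.
#' @return A `go_dag`.
#' @export
make_toy_dag <- function(n_terms = 6, branching = 1.3, seed = 1) {
  stopifnot(n_terms >= 1)
  set.seed(seed)
  terms <- character(0); namespace <- character(0); parents <- list()
  for (ns_i in seq_along(c("MFO", "BPO", "CCO"))) {
    ns <- c("MFO", "BPO", "CCO")[ns_i]
    ids <- sprintf("GO:%d%06d", ns_i, seq_len(n_terms))
    for (j in seq_len(n_terms)) {
      par <- if (j == 1) character(0) else {
        np <- if (j > 2 && stats::runif(1) < branching - 1) 2 else 1
        unique(sample(ids[seq_len(j - 1)], min(np, j - 1)))
      }
      terms <- c(terms, ids[j])
      namespace[ids[j]] <- ns
      parents[[ids[j]]] <- par
    }
  }
  name <- stats::setNames(paste("toy term", terms), terms)
  new_go_dag(terms, namespace, name, parents)
}

# The fixed ontology used by the planted structure->function rule.
rule_dag <- function() {
  terms <- c("GO:1000001", "GO:1000002", "GO:1000003", "GO:1000004",
             "GO:2000001", "GO:2000002", "GO:3000001", "GO:3000002")
  namespace <- stats::setNames(
    c("MFO", "MFO", "MFO", "MFO", "BPO", "BPO", "CCO", "CCO"), terms)
  parents <- list(
    "GO:1000001" = character(0),
    "GO:1000002" = "GO:1000001",
    "GO:1000003" = "GO:1000002",   # right-handed helix leaf
    "GO:1000004" = "GO:1000002",   # left-handed helix leaf
    "GO:2000001" = character(0),
    "GO:2000002" = "GO:2000001",   # sequence-motif leaf
    "GO:3000001" = character(0),
    "GO:3000002" = "GO:3000001")
  name <- stats::setNames(c(
    "molecular function root", "helical binding activity",
    "right-handed helix binding", "left-handed helix binding",
    "biological process root", "motif-mediated process",
    "cellular component root", "generic compartment"), terms)
  new_go_dag(terms, namespace, name, parents)
}

#' Deterministic stub sequence embeddings
#'
#' A stand-in for per-residue protein-language-model embeddings: each row
#' is a pseudo-random vector keyed by (residue identity, position, seed),
#' so identical sequences under the same seed give identical matrices and
#' the embedding is informative of residue type by construction.
#'
#' @param sequence One-letter amino-acid string or character vector.
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @return length(sequence) x dim numeric matrix.
#' @export
make_stub_embedding <- function(sequence, dim = 32, seed = 1) {
  stopifnot(dim >= 1)
  if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  tok <- match(sequence, AA_ALPHABET)
  tok[is.na(tok)] <- length(AA_ALPHABET)
  emb <- matrix(0, length(sequence), dim)
  for (i in seq_along(sequence)) {
    set.seed(as.integer((tok[i] * 7919 + i * 104729 +
                           as.numeric(seed) * 31) %% 2147483629))
    emb[i, ] <- stats::rnorm(dim) / sqrt(dim)
  }
  emb
}

#' Specification of a synthetic rule dataset
#'
#' The planted rule labels each protein by its backbone chirality class
#' (right- vs left-handed helix, which have identical pairwise-distance
#' geometry and differ only in torsion sign) and by the presence of the
#' sequence motif `CWC`.  Chirality determines the MFO leaf term, the motif
#' the BPO leaf; every protein carries the generic CCO term.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer range of chain lengths.
#' @param conformations The two chirality classes of the rule.
#' @param motif Planted sequence motif.
#' @param motif_prob Probability a protein carries the motif.
#' @param low_conf_prob Probability a protein has a low-confidence segment.
#' @param low_conf_frac Fraction of residues in that segment.
#' @param label_noise Probability each rule-derived leaf label is flipped.
#' @param d_emb Stub embedding dimension.
#' @param seed Integer seed (mandatory).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 200, length_range = c(20, 32),
                           conformations = c("helix", "helix_left"),
                           motif = "CWC", motif_prob = 0.5,
                           low_conf_prob = 0.3, low_conf_frac = 0.2,
                           label_noise = 0, d_emb = 32, seed = 1) {
  stopifnot(label_noise >= 0, label_noise <= 1, motif_prob >= 0,
            motif_prob <= 1, !missing(seed) || TRUE)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic rule dataset
#'
#' Produces structures, stub embeddings, unpropagated annotations, a
#' sequence-identity table (motif-sharing pairs score high, so identity
#' filtering has signal), and an 80/10/10 train/validation/test split.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dag`, `structures`, `embeddings`, `annotations`,
#'   `identity` (data.frame query/subject/identity), `splits`, `classes`,
#'   `has_motif` and `spec`.
#' @export
make_synthetic_dataset <- function(spec = synthetic_spec()) {
  dag <- rule_dag()
  rule <- list(helix = "GO:1000003", helix_left = "GO:1000004",
               extended = "GO:1000003", mixed = "GO:1000004",
               motif = "GO:2000002", everyone = "GO:3000002")
  if (!all(unlist(rule) %in% dag$terms)) stop("rule references unknown terms")
  set.seed(spec$seed)
  n <- spec$n_proteins
  ids <- sprintf("SYN%04d", seq_len(n))
  classes <- sample(spec$conformations, n, replace = TRUE)
  lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
  has_motif <- stats::runif(n) < spec$motif_prob
  motif_chars <- strsplit(spec$motif, "")[[1]]
  structures <- vector("list", n); names(structures) <- ids
  embeddings <- vector("list", n); names(embeddings) <- ids
  ann <- vector("list", n); names(ann) <- ids
  for (i in seq_len(n)) {
    sqc <- sample(setdiff(AA_ALPHABET, c("X", motif_chars[1])),
                  lens[i], replace = TRUE)
    if (has_motif[i]) {
      pos <- sample(2:(lens[i] - length(motif_chars)), 1)
      sqc[pos:(pos + length(motif_chars) - 1)] <- motif_chars
    }
    plddt <- stats::runif(lens[i], 0.91, 0.99)
    if (stats::runif(1) < spec$low_conf_prob) {
      seg <- max(1, round(spec$low_conf_frac * lens[i]))
      at <- sample(seq_len(lens[i] - seg + 1), 1)
      plddt[at:(at + seg - 1)] <- stats::runif(seg, 0.55, 0.85)
    }
    structures[[i]] <- make_toy_structure(
      lens[i], conformation = classes[i], sequence = sqc, plddt = plddt,
      seed = derive_seed(spec$seed, i), protein_id = ids[i])
    embeddings[[i]] <- make_stub_embedding(sqc, spec$d_emb, spec$seed)
    leaf_class <- rule[[classes[i]]]
    if (stats::runif(1) < spec$label_noise) {
      leaf_class <- setdiff(c("GO:1000003", "GO:1000004"), leaf_class)
    }
    motif_now <- has_motif[i]
    if (stats::runif(1) < spec$label_noise) motif_now <- !motif_now
    ann[[i]] <- c(leaf_class, if (motif_now) rule$motif, rule$everyone)
  }
  # Identity table: motif-sharing pairs look like close homologs.
  qs <- character(0); ss <- character(0); idv <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      base <- stats::runif(1, 0.20, 0.45)
      if (has_motif[i] && has_motif[j]) base <- stats::runif(1, 0.85, 0.98)
      if (base > 0.25) {
        qs <- c(qs, ids[i], ids[j]); ss <- c(ss, ids[j], ids[i])
        idv <- c(idv, base, base)
      }
    }
  }
  split_lab <- sample(rep(c("train", "val", "test"),
                          c(round(0.8 * n), round(0.1 * n),
                            n - round(0.8 * n) - round(0.1 * n))))
  list(dag = dag, structures = structures, embeddings = embeddings,
       annotations = annotation_set(ann),
       identity = data.frame(query = qs, subject = ss, identity = idv),
       splits = stats::setNames(split_lab, ids),
       classes = stats::setNames(classes, ids),
       has_motif = stats::setNames(has_motif, ids),
       spec = spec)
}

#' Write a synthetic dataset to disk in the production formats
#'
#' Structures as PDB, the ontology as OBO, annotations and the identity
#' table as TSV, embeddings and splits as RDS.
#'
#' @param dataset Output of [make_synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in dataset$structures) {
    write_structure(s, file.path(dir, paste0(s$protein_id, ".pdb")))
  }
  write_obo(dataset$dag, file.path(dir, "ontology.obo"))
  write_annotations(dataset$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(dataset$identity, file.path(dir, "identity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  saveRDS(dataset$embeddings, file.path(dir, "embeddings.rds"))
  saveRDS(dataset$splits, file.path(dir, "splits.rds"))
  invisible(dir)
}
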
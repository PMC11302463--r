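# Structure-based featurization.
#
# All features are derived from backbone N/CA/C coordinates: a k-nearest-
# neighbour graph on CA atoms with Euclidean distances and unit edge
# vectors, orientation vectors to the adjacent residues (per backbone atom
# type), the two side-chain direction vectors N->CA and CA->C, the backbone
# torsions phi/psi/omega, canonical per-residue local frames, and the
# pLDDT-based confidence mask.  Scalar features (distances, torsions,
# norms) are invariant under rigid motions; vector features are
# equivariant.

#' Compute the k-nearest-neighbour graph on CA atoms
#'
#' For each residue, edges to its `k` nearest residues by CA-CA Euclidean
#' distance (self excluded, capped at n-1 neighbours).  Ties are broken by
#' residue order.
#'
#' @param structure A [protein_structure()].
#' @param k Number of neighbours per residue.
#' @param subset Optional logical vector; residues with `FALSE` neither send
#'   nor receive edges (used for confidence masking).
#' @return List with `edges` (E x 2 integer matrix, columns target/source:
#'   row `(i, j)` means residue `i` receives an edge from neighbour `j`) and
#'   `dist` (numeric length E).
#' @export
knn_graph <- function(structure, k, subset = NULL) {
  stopifnot(k >= 1)
  ca <- structure$CA
  n <- nrow(ca)
  idx <- seq_len(n)
  if (!is.null(subset)) idx <- idx[subset]
  if (length(idx) <= 1) {
    warning("structure has fewer than two usable residues; empty edge set")
    return(list(edges = matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("to", "from"))),
                dist = numeric(0)))
  }
  d <- as.matrix(stats::dist(ca[idx, , drop = FALSE]))
  kk <- min(k, length(idx) - 1)
  edges <- matrix(integer(0), 0, 2)
  dists <- numeric(0)
  for (a in seq_along(idx)) {
    ord <- order(d[a, ], seq_along(idx))
    ord <- ord[ord != a][seq_len(kk)]
    edges <- rbind(edges, cbind(idx[a], idx[ord]))
    dists <- c(dists, d[a, ord])
  }
  colnames(edges) <- c("to", "from")
  list(edges = edges, dist = dists)
}

#' Unit edge vectors CA(source) -> CA(destination)
#'
#' @param structure A [protein_structure()].
#' @param edges E x 2 matrix as returned by [knn_graph()] (`to` receives
#'   from `from`); the vector points from the source (`from`) CA to the
#'   destination (`to`) CA.
#' @return E x 3 matrix of unit vectors.
#' @export
edge_vectors <- function(structure, edges) {
  if (nrow(edges) == 0) return(matrix(numeric(0), 0, 3))
  if (is.null(colnames(edges))) colnames(edges) <- c("to", "from")
  v <- structure$CA[edges[, "to"], , drop = FALSE] -
    structure$CA[edges[, "from"], , drop = FALSE]
  unit_rows(v, strict = TRUE, what = "edge (coincident CA atoms)")
}

#' Orientation vectors to the adjacent residues
#'
#' For every residue and each backbone atom type (N, CA, C), the unit vector
#' to the same atom of the following residue (forward) and of the preceding
#' residue (backward).  Undefined at the chain termini: zero vectors with
#' the defined-flag `FALSE`.
#'
#' @param structure A [protein_structure()].
#' @return List with `forward`/`backward` (n x 9 matrices; columns grouped
#'   N, CA, C) and `forward_defined`/`backward_defined` logical vectors.
#' @export
orientation_vectors <- function(structure) {
  n <- n_residues(structure)
  if (n < 2) stop("orientation vectors need at least two residues")
  fwd <- matrix(0, n, 9)
  bwd <- matrix(0, n, 9)
  for (j in seq_along(c("N", "CA", "C"))) {
    atom <- c("N", "CA", "C")[j]
    coords <- structure[[atom]]
    dvec <- coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE]
    dvec <- unit_rows(dvec, strict = TRUE, what = "adjacent-residue step")
    cols <- (j - 1) * 3 + 1:3
    fwd[-n, cols] <- dvec
    bwd[-1, cols] <- -dvec
  }
  list(forward = fwd, backward = bwd,
       forward_defined = c(rep(TRUE, n - 1), FALSE),
       backward_defined = c(FALSE, rep(TRUE, n - 1)))
}

#' Side-chain direction vectors
#'
#' Unit vectors N -> CA and CA -> C per residue (the two backbone bonds
#' flanking the side chain).
#'
#' @param structure A [protein_structure()].
#' @return n x 6 matrix: columns 1-3 the N->CA unit vector, 4-6 CA->C.
#' @export
sidechain_vectors <- function(structure) {
  v1 <- unit_rows(structure$CA - structure$N, what = "N-CA bond")
  v2 <- unit_rows(structure$C - structure$CA, what = "CA-C bond")
  cbind(v1, v2)
}

# Signed torsion angle (radians, (-pi, pi]) for four points; NA when the
# configuration is degenerate (collinear atoms).
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1 * n1) < 1e-12 || sum(n2 * n2) < 1e-12) return(NA_real_)
  b2u <- b2 / sqrt(sum(b2 * b2))
  m1 <- c(n1[2] * b2u[3] - n1[3] * b2u[2],
          n1[3] * b2u[1] - n1[1] * b2u[3],
          n1[1] * b2u[2] - n1[2] * b2u[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

#' Backbone dihedral angles
#'
#' Standard phi (C'[i-1], N, CA, C'), psi (N, CA, C', N[i+1]) and omega
#' (CA, C', N[i+1], CA[i+1]) torsions per residue, in radians in (-pi, pi].
#' Undefined entries (chain termini, collinear atoms) are zero-filled with
#' the defined-flag `FALSE`.
#'
#' @param structure A [protein_structure()].
#' @return List with `angles` (n x 3 matrix, columns phi/psi/omega) and
#'   `defined` (n x 3 logical matrix).
#' @export
backbone_dihedrals <- function(structure) {
  n <- n_residues(structure)
  if (n < 2) stop("dihedrals need at least two residues")
  ang <- matrix(0, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  def <- matrix(FALSE, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(n)) {
    if (i > 1) {
      a <- torsion_angle(structure$C[i - 1, ], structure$N[i, ],
                         structure$CA[i, ], structure$C[i, ])
      if (!is.na(a)) { ang[i, "phi"] <- a; def[i, "phi"] <- TRUE }
    }
    if (i < n) {
      a <- torsion_angle(structure$N[i, ], structure$CA[i, ],
                         structure$C[i, ], structure$N[i + 1, ])
      if (!is.na(a)) { ang[i, "psi"] <- a; def[i, "psi"] <- TRUE }
      a <- torsion_angle(structure$CA[i, ], structure$C[i, ],
                         structure$N[i + 1, ], structure$CA[i + 1, ])
      if (!is.na(a)) { ang[i, "omega"] <- a; def[i, "omega"] <- TRUE }
    }
  }
  list(angles = ang, defined = def)
}

#' Canonical per-residue local frames
#'
#' Gram-Schmidt frame from the backbone atoms of each residue: e1 along
#' CA->C, e2 the component of CA->N orthogonal to e1, e3 = e1 x e2; origin
#' at CA.  The returned rotation is proper (det +1).
#'
#' @param structure A [protein_structure()].
#' @return List with `rotations` (n x 3 x 3 array; `rotations[i, , ]` has
#'   the frame axes as columns) and `origins` (n x 3 matrix of CA
#'   coordinates).
#' @export
canonical_frames <- function(structure) {
  n <- n_residues(structure)
  rot <- array(0, c(n, 3, 3))
  for (i in seq_len(n)) {
    e1 <- structure$C[i, ] - structure$CA[i, ]
    u <- structure$N[i, ] - structure$CA[i, ]
    e1n <- sqrt(sum(e1 * e1))
    if (e1n < 1e-10) stop("degenerate backbone at residue ", i)
    e1 <- e1 / e1n
    e2 <- u - sum(u * e1) * e1
    e2n <- sqrt(sum(e2 * e2))
    if (e2n < 1e-8) stop("collinear N, CA, C at residue ", i)
    e2 <- e2 / e2n
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    rot[i, , ] <- cbind(e1, e2, e3)
  }
  list(rotations = rot, origins = structure$CA)
}

#' Gaussian radial basis encoding of distances
#'
#' @param d Numeric vector of distances (Angstrom).
#' @param n_rbf Number of Gaussian basis functions.
#' @param d_max Upper end of the centre range (centres span 0..d_max).
#' @return length(d) x n_rbf matrix.
#' @export
rbf_encode <- function(d, n_rbf = 16, d_max = 20) {
  centers <- seq(0, d_max, length.out = n_rbf)
  width <- (d_max / (n_rbf - 1))
  exp(-((outer(d, centers, "-") / width)^2))
}

# Degenerate-length-tolerant wrappers: a single-residue chain has no
# torsions or chain-neighbour orientations, only zero-filled features.
safe_dihedrals <- function(structure) {
  n <- n_residues(structure)
  if (n >= 2) return(backbone_dihedrals(structure))
  list(angles = matrix(0, n, 3,
                       dimnames = list(NULL, c("phi", "psi", "omega"))),
       defined = matrix(FALSE, n, 3,
                        dimnames = list(NULL, c("phi", "psi", "omega"))))
}

safe_orientation <- function(structure) {
  n <- n_residues(structure)
  if (n >= 2) return(orientation_vectors(structure))
  list(forward = matrix(0, n, 9), backward = matrix(0, n, 9),
       forward_defined = rep(FALSE, n), backward_defined = rep(FALSE, n))
}

#' Featurize a structure for the model
#'
#' Assembles the full feature bundle: kNN graph with distances, RBF distance
#' encodings and unit edge vectors; orientation, side-chain and dihedral
#' features; amino-acid tokens; pLDDT; and the per-residue sequence
#' embedding matrix.  The pLDDT confidence mask is applied via
#' [apply_plddt_mask()].
#'
#' @param structure A [protein_structure()].
#' @param seq_embedding n x d matrix of per-residue sequence embeddings
#'   (e.g. from a protein language model); see [make_stub_embedding()] for a
#'   deterministic stand-in.
#' @param k Neighbours per residue in the kNN graph.
#' @param plddt_threshold Residues with pLDDT below this are geometry-masked.
#' @param n_rbf,d_max Parameters of [rbf_encode()].
#' @return An object of class `feature_bundle`.
#' @export
featurize <- function(structure, seq_embedding, k = 30,
                      plddt_threshold = 0.9, n_rbf = 16, d_max = 20) {
  n <- n_residues(structure)
  seq_embedding <- as.matrix(seq_embedding)
  stopifnot(nrow(seq_embedding) == n)
  dih <- safe_dihedrals(structure)
  ori <- safe_orientation(structure)
  bundle <- structure(list(
    protein_id = structure$protein_id,
    n_residues = n,
    structure = structure,
    edges = NULL, edge_distance = NULL, edge_rbf = NULL, edge_vector = NULL,
    orientation_forward = ori$forward,
    orientation_backward = ori$backward,
    orientation_forward_defined = ori$forward_defined,
    orientation_backward_defined = ori$backward_defined,
    sidechain = sidechain_vectors(structure),
    dihedrals = dih$angles,
    dihedrals_defined = dih$defined,
    tokens = match(structure$aa, AA_ALPHABET),
    plddt = structure$plddt,
    seq_embedding = seq_embedding,
    mask = rep(FALSE, n),
    k = k, n_rbf = n_rbf, d_max = d_max
  ), class = "feature_bundle")
  apply_plddt_mask(bundle, plddt_threshold)
}

#' Apply the pLDDT confidence mask to a feature bundle
#'
#' Residues with pLDDT below `threshold` have their 3D geometry masked:
#' their vector and dihedral features are zeroed with defined-flags
#' `FALSE`, and they are excluded from the kNN graph (they neither send nor
#' receive edges).  Their tokens, pLDDT values and sequence embeddings are
#' retained so the model still sees the residue and its confidence.  The
#' kNN graph is (re)built on the unmasked subset.
#'
#' @param bundle A `feature_bundle`.
#' @param threshold pLDDT threshold in \[0, 1\].
#' @return The updated `feature_bundle`.
#' @export
apply_plddt_mask <- function(bundle, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  mask <- bundle$plddt < threshold
  if (all(mask)) stop("no confident residues: all pLDDT below ", threshold)
  bundle$mask <- mask
  s <- bundle$structure
  n <- bundle$n_residues
  # Rebuild geometric features from scratch on the unmasked subset.
  dih <- safe_dihedrals(s)
  ori <- safe_orientation(s)
  sc <- sidechain_vectors(s)
  if (any(mask)) {
    # A torsion/orientation feature is defined only if every residue whose
    # atoms it touches is confident.
    for (i in which(mask)) {
      lo <- max(1, i - 1); hi <- min(n, i + 1)
      dih$defined[lo:hi, ] <- FALSE
      ori$forward_defined[lo:hi] <- FALSE
      ori$backward_defined[lo:hi] <- FALSE
    }
    dih$angles[!dih$defined] <- 0
    ori$forward[!ori$forward_defined, ] <- 0
    ori$backward[!ori$backward_defined, ] <- 0
    sc[mask, ] <- 0
  }
  g <- if (sum(!mask) > 1) {
    knn_graph(s, bundle$k, subset = !mask)
  } else {
    suppressWarnings(knn_graph(s, bundle$k, subset = !mask))
  }
  bundle$edges <- g$edges
  bundle$edge_distance <- g$dist
  bundle$edge_rbf <- rbf_encode(g$dist, bundle$n_rbf, bundle$d_max)
  bundle$edge_vector <- edge_vectors(s, g$edges)
  bundle$dihedrals <- dih$angles
  bundle$dihedrals_defined <- dih$defined
  bundle$orientation_forward <- ori$forward
  bundle$orientation_backward <- ori$backward
  bundle$orientation_forward_defined <- ori$forward_defined
  bundle$orientation_backward_defined <- ori$backward_defined
  bundle$sidechain <- sc
  bundle
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat("<feature_bundle> ", x$protein_id, ": ", x$n_residues, " residues, ",
      nrow(x$edges), " edges, ", sum(x$mask), " masked\n", sep = "")
  invisible(x)
}
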
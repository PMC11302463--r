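test_that("kNN graph matches nearest-point geometry and caps at n-1", {
  s <- make_toy_structure(3, "extended", seed = 1)
  s$CA <- matrix(c(0, 0, 0, 3.8, 0, 0, 100, 0, 0), 3, byrow = TRUE)
  g <- knn_graph(s, 1)
  e1 <- g$edges[g$edges[, "to"] == 1, ]
  expect_equal(unname(e1["from"]), 2)
  expect_equal(g$dist[g$edges[, "to"] == 1], 3.8)
  s4 <- make_toy_structure(4, "helix", seed = 2)
  g4 <- knn_graph(s4, 5)
  expect_equal(as.integer(table(g4$edges[, "to"])), rep(3L, 4))
})

test_that("kNN graph equals the brute-force all-pairs oracle", {
  for (seed in 1:5) {
    s <- make_toy_structure(sample(8:30, 1), "mixed", seed = seed)
    g <- knn_graph(s, 4)
    oracle <- brute_knn(s$CA, 4)
    expect_equal(unname(g$edges), unname(oracle))
  }
})

test_that("edge vectors are unit, antisymmetric and equivariant", {
  s <- make_toy_structure(10, "helix", seed = 3)
  g <- knn_graph(s, 3)
  ev <- edge_vectors(s, g$edges)
  expect_equal(sqrt(rowSums(ev^2)), rep(1, nrow(ev)), tolerance = 1e-9)
  flipped <- g$edges[, c("from", "to")]
  colnames(flipped) <- c("to", "from")
  expect_equal(edge_vectors(s, flipped), -ev)
  R <- seeded_rotation(11)
  s2 <- gvpgo:::transform_structure(s, R, c(1, 2, 3))
  expect_equal(edge_vectors(s2, g$edges), ev %*% t(R), tolerance = 1e-9)
  s$CA[2, ] <- s$CA[1, ]
  expect_error(edge_vectors(s, rbind(c(2, 1))), "degenerate")
})

test_that("orientation vectors point along the chain with terminus flags", {
  s <- make_toy_structure(4, "helix", seed = 1)
  s$CA <- cbind(seq(0, 11.4, by = 3.8), 0, 0)
  s$N <- s$CA + rep(c(0.5, 0.1, 0), each = 4)
  s$C <- s$CA + rep(c(-0.5, 0.2, 0), each = 4)
  o <- orientation_vectors(s)
  expect_equal(unname(o$forward[1:3, 4:6]),
               matrix(rep(c(1, 0, 0), each = 3), 3))
  expect_equal(unname(o$backward[2:4, 4:6]),
               matrix(rep(c(-1, 0, 0), each = 3), 3))
  expect_false(o$backward_defined[1])
  expect_false(o$forward_defined[4])
  expect_equal(o$backward[1, ], rep(0, 9))
})

test_that("side-chain vectors are the normalized backbone bond directions", {
  s <- protein_structure("p", 1, "A", c(0, 0, 0), c(1.46, 0, 0),
                         c(1.46, 1.52, 0), 0.9)
  sc <- sidechain_vectors(s)
  expect_equal(sc[1, 1:3], c(1, 0, 0))
  expect_equal(sc[1, 4:6], c(0, 1, 0))
  s2 <- make_toy_structure(12, "mixed", seed = 9)
  sc2 <- sidechain_vectors(s2)
  expect_equal(sqrt(rowSums(sc2[, 1:3]^2)), rep(1, 12), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(sc2[, 4:6]^2)), rep(1, 12), tolerance = 1e-9)
})

test_that("backbone torsions recover generator inputs and flip chirality", {
  s <- make_toy_structure(10, "helix", seed = 5)
  d <- backbone_dihedrals(s)
  expect_equal(d$angles[2:10, "phi"], rep(-57 * pi / 180, 9),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(d$angles[1:9, "psi"], rep(-47 * pi / 180, 9),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(abs(d$angles[1:9, "omega"]), rep(pi, 9), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_false(d$defined[1, "phi"])
  expect_false(d$defined[10, "psi"])
  mirror <- s
  for (f in c("N", "CA", "C")) mirror[[f]][, 3] <- -mirror[[f]][, 3]
  dm <- backbone_dihedrals(mirror)
  expect_equal(dm$angles[2:10, "phi"], -d$angles[2:10, "phi"],
               tolerance = 1e-9)
  expect_equal(dm$angles[1:9, "psi"], -d$angles[1:9, "psi"],
               tolerance = 1e-9)
})

test_that("degenerate (collinear) torsions are flagged, not NaN", {
  s <- make_toy_structure(3, "helix", seed = 1)
  line <- cbind(seq_len(9), 0, 0)
  s$N <- line[c(1, 4, 7), ]; s$CA <- line[c(2, 5, 8), ]
  s$C <- line[c(3, 6, 9), ]
  d <- backbone_dihedrals(s)
  expect_false(any(d$defined))
  expect_true(all(is.finite(d$angles)))
})

test_that("canonical frames are proper rotations that compose with R", {
  s <- make_toy_structure(8, "mixed", seed = 6)
  fr <- canonical_frames(s)
  for (i in 1:8) {
    m <- fr$rotations[i, , ]
    expect_equal(t(m) %*% m, diag(3), tolerance = 1e-9)
    expect_equal(det(m), 1, tolerance = 1e-9)
  }
  R <- seeded_rotation(21)
  fr2 <- canonical_frames(gvpgo:::transform_structure(s, R))
  for (i in 1:8) {
    expect_equal(fr2$rotations[i, , ], R %*% fr$rotations[i, , ],
                 tolerance = 1e-9)
  }
  bad <- s
  bad$N[2, ] <- bad$CA[2, ] + (bad$C[2, ] - bad$CA[2, ])
  expect_error(canonical_frames(bad), "collinear")
})

test_that("pLDDT masking hides geometry but keeps sequence information", {
  plddt <- c(0.95, 0.85, 0.91, rep(0.95, 7))
  b <- tiny_bundle(10, seed = 3, k = 3, plddt = plddt)
  expect_equal(b$mask, plddt < 0.9)
  b0 <- apply_plddt_mask(b, 0)
  expect_false(any(b0$mask))
  expect_error(apply_plddt_mask(b, 1), "no confident residues")

  plddt5 <- rep(0.95, 10); plddt5[5] <- 0.5
  b5 <- tiny_bundle(10, seed = 3, k = 3, plddt = plddt5)
  expect_false(any(b5$edges == 5))
  oracle <- brute_knn(b5$structure$CA, 3, subset = plddt5 >= 0.9)
  expect_equal(unname(b5$edges), unname(oracle))
  # sequence-level features retained
  expect_equal(b5$tokens, b$tokens)
  expect_equal(b5$plddt[5], 0.5)
  expect_true(all(b5$seq_embedding[5, ] != 0))
  # geometry zeroed
  expect_equal(b5$sidechain[5, ], rep(0, 6))
  expect_false(any(b5$dihedrals_defined[4:6, ]))
})

test_that("masking fraction matches the analytically expected fraction", {
  set.seed(31)
  plddt <- stats::runif(400, 0.5, 1)
  s <- make_toy_structure(400, "mixed", seed = 8, plddt = plddt)
  b <- featurize(s, make_stub_embedding(s$aa, 4, 1), k = 4,
                 plddt_threshold = 0.9, n_rbf = 4)
  expect_equal(mean(b$mask), mean(plddt < 0.9))
})

test_that("scalar features are invariant and vector features equivariant
           under seeded rigid motions", {
  s <- make_toy_structure(14, "mixed", seed = 10)
  # break the exact distance ties of ideal geometry so the kNN edge set
  # is unambiguous
  set.seed(99)
  for (f in c("N", "CA", "C")) s[[f]] <- s[[f]] + rnorm(42, sd = 0.02)
  emb <- make_stub_embedding(s$aa, 5, 1)
  b <- featurize(s, emb, k = 4, n_rbf = 4)
  for (seed in 1:20) {
    R <- seeded_rotation(seed)
    t <- stats::rnorm(3, sd = 10)
    b2 <- featurize(gvpgo:::transform_structure(s, R, t), emb, k = 4,
                    n_rbf = 4)
    expect_equal(b2$edge_distance, b$edge_distance, tolerance = 1e-6)
    # compare torsions through their sin/cos encoding (wrap-safe at pi)
    expect_equal(sin(b2$dihedrals), sin(b$dihedrals), tolerance = 1e-6)
    expect_equal(cos(b2$dihedrals), cos(b$dihedrals), tolerance = 1e-6)
    expect_equal(b2$edge_vector, b$edge_vector %*% t(R), tolerance = 1e-6)
    expect_equal(b2$sidechain[, 1:3], b$sidechain[, 1:3] %*% t(R),
                 tolerance = 1e-6)
    expect_equal(b2$orientation_forward[, 1:3],
                 b$orientation_forward[, 1:3] %*% t(R), tolerance = 1e-6)
  }
})
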
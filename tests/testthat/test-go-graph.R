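test_that("OBO parsing builds the expected DAG and handles aliases", {
  dag <- chain_dag()
  expect_s3_class(dag, "go_dag")
  expect_equal(sort(dag$terms),
               c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
                 "GO:0000005"))
  expect_equal(dag$parents[["GO:0000003"]], "GO:0000002")
  expect_false("GO:0000009" %in% dag$terms)  # obsolete dropped
  expect_equal(go_ancestors(dag, "GO:0000333"),
               go_ancestors(dag, "GO:0000003"))  # alt_id resolves
  expect_error(go_ancestors(dag, "GO:9999999"), "unknown GO term")
})

test_that("cycles and unknown namespaces are rejected", {
  cyc <- write_tmp(c(
    "[Term]", "id: GO:0000001", "name: a",
    "namespace: molecular_function", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "name: b",
    "namespace: molecular_function", "is_a: GO:0000001", ""), ".obo")
  expect_error(parse_obo(cyc), "cycle")
  badns <- write_tmp(c(
    "[Term]", "id: GO:0000001", "name: a", "namespace: made_up", ""),
    ".obo")
  expect_error(parse_obo(badns), "namespace")
})

test_that("ancestor/descendant closure matches a fixpoint oracle", {
  dag <- chain_dag()
  expect_setequal(go_ancestors(dag, "GO:0000003"),
                  c("GO:0000002", "GO:0000001"))
  expect_equal(go_ancestors(dag, "GO:0000001"), character(0))
  expect_setequal(go_descendants(dag, "GO:0000001"),
                  c("GO:0000002", "GO:0000003"))
  for (seed in 1:5) {
    dag <- make_toy_dag(17, branching = 1.5, seed = seed)
    # brute force: repeated one-step expansion until fixpoint
    for (t in sample(dag$terms, 6)) {
      anc <- dag$parents[[t]]
      repeat {
        grown <- unique(c(anc, unlist(dag$parents[anc], use.names = FALSE)))
        if (setequal(grown, anc)) break
        anc <- grown
      }
      expect_setequal(go_ancestors(dag, t), anc)
    }
  }
})

test_that("annotation propagation is the ancestor closure, idempotently", {
  dag <- chain_dag()
  ann <- annotation_set(list(P1 = "GO:0000003"))
  prop <- propagate_annotations(ann, dag)
  expect_setequal(prop$annotations$P1,
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_true(prop$propagated)
  again <- propagate_annotations(
    annotation_set(prop$annotations, propagated = FALSE), dag)
  expect_equal(lapply(again$annotations, sort),
               lapply(prop$annotations, sort))
  # diamond: the shared root is counted once
  dd <- diamond_dag()
  pd <- propagate_annotations(annotation_set(list(P = "GO:0000004")), dd)
  expect_equal(sort(pd$annotations$P),
               c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  expect_error(propagate_annotations(annotation_set(list(P = "GO:7777777")),
                                     dag), "not in the ontology")
})

test_that("prediction propagation takes the descendant maximum", {
  dag <- chain_dag()
  preds <- prediction_set(list(P = c("GO:0000003" = 0.9,
                                     "GO:0000002" = 0.2)))
  prop <- propagate_predictions(preds, dag)
  expect_equal(prop$predictions$P[["GO:0000002"]], 0.9)
  expect_equal(prop$predictions$P[["GO:0000001"]], 0.9)
  # random DAGs: parent dominance and equality with the brute-force
  # per-term maximum over descendants
  for (seed in 1:10) {
    dag <- make_toy_dag(12, branching = 1.4, seed = seed)
    set.seed(seed)
    scored <- sample(dag$terms, 8)
    preds <- prediction_set(list(P = stats::setNames(runif(8), scored)))
    prop <- propagate_predictions(preds, dag)$predictions$P
    for (t in names(prop)) {
      fam <- c(t, go_descendants(dag, t))
      inp <- preds$predictions$P[intersect(names(preds$predictions$P), fam)]
      expect_equal(prop[[t]], max(inp))
      for (p in dag$parents[[t]]) {
        expect_gte(prop[[p]], prop[[t]])
      }
    }
  }
})

test_that("information content counts propagated protein occurrences", {
  dag <- chain_dag()
  # 3 proteins: P1 {c,b,a}, P2 {b,a}, P3 {b,a} after propagation
  ann <- propagate_annotations(annotation_set(list(
    P1 = "GO:0000003", P2 = "GO:0000002", P3 = "GO:0000002")), dag)
  ic <- information_content(ann, dag)
  total <- 7  # hand count: P1 contributes 3 pairs, P2 and P3 two each
  expect_equal(ic[["GO:0000003"]], -log10(1 / total))
  expect_equal(ic[["GO:0000002"]], -log10(3 / total))
  expect_equal(ic[["GO:0000001"]], -log10(3 / total))
  expect_equal(ic[["GO:0000004"]], Inf)  # never observed
  # degenerate single-term corpus: IC = 0
  one <- annotation_set(list(P = "GO:0000001"), propagated = TRUE)
  expect_equal(information_content(one, dag)[["GO:0000001"]], 0)
  expect_error(information_content(annotation_set(list(), TRUE), dag),
               "empty")
})

test_that("IC is non-negative and anti-monotone along edges", {
  set.seed(4)
  dag <- make_toy_dag(10, seed = 4)
  ids <- sprintf("P%02d", 1:20)
  ann <- propagate_annotations(annotation_set(stats::setNames(
    lapply(ids, function(i) sample(dag$terms, 3)), ids)), dag)
  ic <- information_content(ann, dag)
  expect_true(all(ic[is.finite(ic)] >= 0))
  for (t in dag$terms) {
    for (p in dag$parents[[t]]) {
      if (is.finite(ic[[t]]) && is.finite(ic[[p]])) {
        expect_lte(ic[[p]], ic[[t]] + 1e-12)
      }
    }
  }
})

test_that("candidate terms respect the frequency threshold and skip roots", {
  dag <- chain_dag()
  ids <- sprintf("P%03d", 1:60)
  ann <- annotation_set(c(
    stats::setNames(rep(list("GO:0000003"), 49), ids[1:49]),
    stats::setNames(rep(list("GO:0000002"), 11), ids[50:60])))
  prop <- propagate_annotations(ann, dag)
  sel50 <- select_candidate_terms(prop, dag, min_proteins = 50)
  expect_false("GO:0000003" %in% sel50)  # 49 proteins: below threshold
  expect_true("GO:0000002" %in% sel50)   # 60 proteins
  expect_false("GO:0000001" %in% sel50)  # root excluded
  sel1 <- select_candidate_terms(prop, dag, min_proteins = 1)
  expect_setequal(sel1, c("GO:0000002", "GO:0000003"))
  expect_error(select_candidate_terms(prop, dag, min_proteins = 1000),
               "no candidate terms")
})

test_that("annotation TSV and GAF readers filter evidence codes", {
  path <- write_tmp(c("P1\tGO:0000003\tEXP", "P1\tGO:0000002\tIEA",
                      "P2\tGO:0000002\tIDA"), ".tsv")
  ann <- read_annotations(path)
  expect_equal(ann$annotations$P1, "GO:0000003")  # IEA dropped
  expect_equal(ann$annotations$P2, "GO:0000002")
  gaf <- write_tmp(c(
    "!gaf-version: 2.1",
    paste(c("UniProtKB", "P1", "SYMB", "", "GO:0000003", "PMID:1", "EXP",
            "", "F", "", "", "protein", "taxon:9606", "20200101", "UniProt",
            "", ""), collapse = "\t"),
    paste(c("UniProtKB", "P2", "SYMB", "NOT", "GO:0000002", "PMID:1", "IDA",
            "", "F", "", "", "protein", "taxon:9606", "20200101", "UniProt",
            "", ""), collapse = "\t")), ".gaf")
  expect_warning(g <- read_annotations(gaf), "NOT")
  expect_equal(names(g$annotations), "P1")
})

test_that("prediction TSV round trips at 3-decimal precision", {
  preds <- prediction_set(list(P1 = c("GO:0000003" = 0.8763,
                                      "GO:0000002" = 0.1)))
  path <- tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_equal(back$predictions$P1[["GO:0000003"]], 0.876)
  expect_equal(back$predictions$P1[["GO:0000002"]], 0.1)
})
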
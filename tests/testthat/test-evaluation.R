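# Independent oracles (exhaustive-threshold Fmax, pairwise AUROC) live in
# helper-fixtures.R and are shared with the acceptance suite.

test_that("a perfect predictor scores Fmax 1 at every threshold", {
  dag <- chain_dag()
  truth <- propagate_annotations(annotation_set(list(
    P1 = "GO:0000003", P2 = "GO:0000002")), dag)
  preds <- propagate_predictions(prediction_set(lapply(
    truth$annotations, function(x) stats::setNames(rep(1, length(x)), x))),
    dag)
  fm <- fmax_metric(preds, truth, dag, "MFO")
  expect_equal(fm$fmax, 1)
  f_all <- with(fm$curve, 2 * pr * rc / (pr + rc))
  expect_true(all(f_all == 1))
})

test_that("the two-protein toy instance gives Fmax 2/3 at low thresholds", {
  dag <- chain_dag()
  # roots excluded; B = GO:0000002, C = GO:0000003 (C is_a B)
  truth <- annotation_set(list(P1 = "GO:0000002",
                               P2 = c("GO:0000003", "GO:0000002")),
                          propagated = TRUE)
  truth$annotations$P1 <- "GO:0000002"
  # hand-set propagated predictions: P1 {B:0.8, C:0.3}, P2 {B:0.9, C:0.2}
  preds <- prediction_set(list(
    P1 = c("GO:0000002" = 0.8, "GO:0000003" = 0.3),
    P2 = c("GO:0000002" = 0.9, "GO:0000003" = 0.2)))
  # evaluate with truth P1={B}, P2={C}: restrict truth
  truth2 <- annotation_set(list(P1 = "GO:0000002", P2 = "GO:0000003"),
                           propagated = TRUE)
  fm <- fmax_metric(preds, truth2, dag, "MFO")
  expect_equal(fm$fmax, 2 / 3, tolerance = 1e-12)
  expect_lte(fm$threshold, 0.2)
  at02 <- fm$curve[abs(fm$curve$t - 0.2) < 1e-9, ]
  expect_equal(at02$pr, 0.5)
  expect_equal(at02$rc, 1.0)
})

test_that("Fmax in exact mode equals the exhaustive-threshold oracle", {
  for (seed in 1:50) {
    inst <- random_metric_instance(seed)
    fm <- fmax_metric(inst$preds, inst$truth, inst$dag, "MFO",
                      thresholds = "exact")
    oracle <- oracle_fmax(inst$preds$predictions, inst$truth$annotations,
                          inst$mfo, inst$dag$roots)
    expect_equal(fm$fmax, oracle, tolerance = 1e-9)
  }
})

test_that("Fmax is invariant under strictly monotone score transforms", {
  inst <- random_metric_instance(99)
  f1 <- fmax_metric(inst$preds, inst$truth, inst$dag, "MFO",
                    thresholds = "exact")$fmax
  squashed <- prediction_set(lapply(inst$preds$predictions,
                                    function(v) v^3))
  f2 <- fmax_metric(squashed, inst$truth, inst$dag, "MFO",
                    thresholds = "exact")$fmax
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("empty predictions yield Fmax 0 with a warning", {
  dag <- chain_dag()
  truth <- annotation_set(list(P1 = "GO:0000002"), propagated = TRUE)
  expect_warning(
    fm <- fmax_metric(prediction_set(list(P1 = stats::setNames(
      numeric(0), character(0)))), truth, dag, "MFO"),
    "empty")
  expect_equal(fm$fmax, 0)
})

test_that("Smin is zero for perfect predictions and the truth IC for
           empty ones", {
  dag <- chain_dag()
  ann <- propagate_annotations(annotation_set(list(
    P1 = "GO:0000003", P2 = "GO:0000002", P3 = "GO:0000002")), dag)
  ic <- information_content(ann, dag)
  perfect <- prediction_set(lapply(ann$annotations, function(x) {
    stats::setNames(rep(1, length(x)), x)
  }))
  expect_equal(smin_metric(perfect, ann, dag, ic, "MFO")$smin, 0)
  empty <- prediction_set(lapply(ann$annotations, function(x) {
    stats::setNames(numeric(0), character(0))
  }))
  # all-false-negative limit: ru = mean per-protein truth IC, mi = 0
  truth_ic <- mean(vapply(ann$annotations, function(x) {
    sum(ic[setdiff(x, dag$roots)])
  }, 0))
  expect_equal(smin_metric(empty, ann, dag, ic, "MFO")$smin, truth_ic)
})

test_that("Smin matches manual enumeration on the toy corpus", {
  dag <- chain_dag()
  ann <- propagate_annotations(annotation_set(list(
    P1 = "GO:0000003", P2 = "GO:0000002", P3 = "GO:0000002")), dag)
  ic <- information_content(ann, dag)   # b: -log10(3/7), c: -log10(1/7)
  # P1 predicted {c: 0.6, b: 0.6}; P2 {b: 0.3}; P3 {} (roots excluded)
  preds <- prediction_set(list(
    P1 = c("GO:0000003" = 0.6, "GO:0000002" = 0.6),
    P2 = c("GO:0000002" = 0.3),
    P3 = stats::setNames(numeric(0), character(0))))
  icb <- ic[["GO:0000002"]]; icc <- ic[["GO:0000003"]]
  # t <= 0.3 : P1 perfect, P2 perfect, P3 misses b  -> ru = icb/3, mi = 0
  # 0.3 < t <= 0.6: P2 also misses b -> ru = 2 icb / 3
  # t > 0.6: everything missed -> ru = (icc + 3 icb)/3
  s_hand <- min(icb / 3, 2 * icb / 3, (icc + 3 * icb) / 3)
  sm <- smin_metric(preds, ann, dag, ic, "MFO",
                    thresholds = c(0.3, 0.6, 0.9))
  expect_equal(sm$smin, s_hand, tolerance = 1e-12)
  expect_equal(sm$threshold, 0.3)
})

test_that("Smin errors when a summed term has infinite IC", {
  dag <- chain_dag()
  ann <- propagate_annotations(annotation_set(list(P1 = "GO:0000002")), dag)
  ic <- information_content(ann, dag)
  preds <- prediction_set(list(P1 = c("GO:0000003" = 0.9)))
  expect_error(smin_metric(preds, ann, dag, ic, "MFO"), "infinite")
})

test_that("AUPR is 1 for a perfect predictor and matches a step-wise
           integrator on random instances", {
  dag <- chain_dag()
  truth <- propagate_annotations(annotation_set(list(
    P1 = "GO:0000003", P2 = "GO:0000002")), dag)
  perfect <- prediction_set(lapply(truth$annotations, function(x) {
    stats::setNames(rep(1, length(x)), x)
  }))
  expect_equal(aupr_metric(perfect, truth, dag, "MFO"), 1)
  for (seed in 1:50) {
    inst <- random_metric_instance(seed)
    a <- suppressWarnings(aupr_metric(inst$preds, inst$truth, inst$dag,
                                      "MFO", thresholds = "exact"))
    # independent integrator: explicit loop over consecutive points
    fm <- fmax_metric(inst$preds, inst$truth, inst$dag, "MFO",
                      thresholds = "exact")
    cv <- fm$curve[!is.na(fm$curve$pr), ]
    cv <- cv[order(cv$rc, cv$pr), ]
    rc <- c(0, cv$rc); pr <- c(cv$pr[1], cv$pr)
    area <- 0
    for (j in 2:length(rc)) {
      area <- area + (rc[j] - rc[j - 1]) * (pr[j] + pr[j - 1]) / 2
    }
    expect_equal(a, area, tolerance = 1e-9)
  }
})

test_that("a constant-score predictor gives a degenerate single-point
           precision-recall curve", {
  dag <- chain_dag()
  truth <- annotation_set(list(P1 = "GO:0000002", P2 = "GO:0000003"),
                          propagated = TRUE)
  const <- prediction_set(list(
    P1 = c("GO:0000002" = 0.5, "GO:0000003" = 0.5),
    P2 = c("GO:0000002" = 0.5, "GO:0000003" = 0.5)))
  expect_warning(a <- aupr_metric(const, truth, dag, "MFO",
                                  thresholds = "exact"), "degenerate")
  expect_equal(a, 0.5 * 1.0)  # pr = 0.5, rc = 1 rectangle
})

test_that("term-centric AUROC is 0.5 under constant scores, 1 under
           perfect separation, and matches the pairwise oracle", {
  dag <- chain_dag()
  ids <- sprintf("P%02d", 1:8)
  truth <- annotation_set(stats::setNames(lapply(1:8, function(i) {
    if (i <= 4) c("GO:0000003", "GO:0000002") else "GO:0000002"
  }), ids), propagated = TRUE)
  const <- prediction_set(stats::setNames(rep(list(
    c("GO:0000002" = 0.4, "GO:0000003" = 0.4)), 8), ids))
  au_const <- suppressWarnings(term_auroc(const, truth, dag, "MFO"))
  expect_equal(au_const$per_term[["GO:0000003"]], 0.5)
  perfect <- prediction_set(stats::setNames(lapply(1:8, function(i) {
    c("GO:0000002" = 1, "GO:0000003" = as.numeric(i <= 4))
  }), ids))
  expect_warning(
    au <- term_auroc(perfect, truth, dag, "MFO"), "skipped")
  expect_equal(au$per_term[["GO:0000003"]], 1)
  for (seed in 1:50) {
    inst <- random_metric_instance(seed, n_prot = 20)
    au <- suppressWarnings(term_auroc(inst$preds, inst$truth, inst$dag,
                                      "MFO"))
    labels <- vapply(inst$ids, function(p) {
      as.numeric(names(au$per_term)[1] %in% inst$truth$annotations[[p]])
    }, 0)
    scores <- vapply(inst$ids, function(p) {
      v <- inst$preds$predictions[[p]]
      if (names(au$per_term)[1] %in% names(v)) v[[names(au$per_term)[1]]]
      else 0
    }, 0)
    expect_equal(unname(au$per_term[1]), oracle_auroc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("metrics never mix namespaces", {
  dag <- diamond_dag()
  truth <- annotation_set(list(P1 = c("GO:0000002", "GO:0000006")),
                          propagated = TRUE)
  # a BPO/CCO prediction must not affect MFO metrics
  p1 <- prediction_set(list(P1 = c("GO:0000002" = 0.9)))
  p2 <- prediction_set(list(P1 = c("GO:0000002" = 0.9,
                                   "GO:0000006" = 0.99)))
  expect_equal(fmax_metric(p1, truth, dag, "MFO")$fmax,
               fmax_metric(p2, truth, dag, "MFO")$fmax)
})
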
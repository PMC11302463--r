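# CAFA-style evaluation.  Protein-centric: Fmax (maximum over confidence
# thresholds of the F1 between precision averaged over proteins with at
# least one prediction at the threshold and recall averaged over all
# evaluated proteins), Smin (minimum over thresholds of
# sqrt(ru^2 + mi^2), with remaining uncertainty ru and misinformation mi
# as information-content-weighted false negatives / false positives, both
# averaged over all evaluated proteins) and AUPR.  Term-centric:
# tie-corrected rank AUROC per term, macro-averaged.
#
# Conventions: both predictions and truth must be propagated; namespaces
# are never mixed; namespace roots are excluded; proteins with no truth
# term in the evaluated namespace are excluded from that namespace's n.

DEFAULT_THRESHOLDS <- seq(0.01, 1, by = 0.01)

eval_sets <- function(preds, truth, dag, ontology) {
  ontology <- match.arg(ontology, c("MFO", "BPO", "CCO"))
  if (!truth$propagated) stop("truth annotations must be propagated")
  ns_terms <- setdiff(dag$terms[dag$namespace == ontology], dag$roots)
  ids <- names(truth$annotations)
  truth_ns <- lapply(truth$annotations, function(x) intersect(x, ns_terms))
  ids <- ids[lengths(truth_ns) > 0]
  if (length(ids) == 0) stop("no protein has truth terms in ", ontology)
  scores <- lapply(ids, function(p) {
    v <- preds$predictions[[p]]
    if (is.null(v)) return(stats::setNames(numeric(0), character(0)))
    v[names(v) %in% ns_terms]
  })
  names(scores) <- ids
  list(ids = ids, truth = truth_ns[ids], scores = scores,
       ns_terms = ns_terms)
}

resolve_thresholds <- function(thresholds, scores) {
  if (is.numeric(thresholds)) {
    stopifnot(all(diff(thresholds) > 0))
    return(thresholds)
  }
  if (identical(thresholds, "grid")) return(DEFAULT_THRESHOLDS)
  if (identical(thresholds, "exact")) {
    vals <- sort(unique(unlist(lapply(scores, unname), use.names = FALSE)))
    vals <- vals[vals > 0]
    if (length(vals) == 0) vals <- 1
    return(vals)
  }
  stop("thresholds must be 'grid', 'exact' or an increasing numeric vector")
}

pr_rc_curve <- function(es, thresholds) {
  n <- length(es$ids)
  out <- data.frame(t = thresholds, pr = NA_real_, rc = NA_real_,
                    m = NA_integer_)
  for (j in seq_along(thresholds)) {
    t <- thresholds[j]
    pr_i <- numeric(0)
    rc_sum <- 0
    m <- 0L
    for (i in seq_len(n)) {
      sc <- es$scores[[i]]
      p_set <- names(sc)[sc >= t]
      tp <- sum(p_set %in% es$truth[[i]])
      if (length(p_set) > 0) {
        m <- m + 1L
        pr_i <- c(pr_i, tp / length(p_set))
      }
      rc_sum <- rc_sum + tp / length(es$truth[[i]])
    }
    out$m[j] <- m
    out$pr[j] <- if (m > 0) mean(pr_i) else NA_real_
    out$rc[j] <- rc_sum / n
  }
  out
}

#' Protein-centric Fmax
#'
#' Maximum over confidence thresholds of
#' `2 * pr(t) * rc(t) / (pr(t) + rc(t))`, with precision averaged over the
#' m(t) proteins having at least one prediction at threshold t and recall
#' averaged over all n evaluated proteins.
#'
#' @param preds A propagated [prediction_set()].
#' @param truth A propagated [annotation_set()].
#' @param dag A `go_dag`.
#' @param ontology `"MFO"`, `"BPO"` or `"CCO"` (namespaces never mix).
#' @param thresholds `"grid"` (0.01..1.00 in steps of 0.01), `"exact"`
#'   (every distinct positive confidence), or an increasing numeric
#'   vector.
#' @return List with `fmax`, `threshold` (argmax) and the `curve`
#'   data.frame (t, pr, rc, m).
#' @export
fmax_metric <- function(preds, truth, dag, ontology = "MFO",
                        thresholds = "grid") {
  es <- eval_sets(preds, truth, dag, ontology)
  if (all(lengths(es$scores) == 0)) {
    warning("empty prediction set: Fmax = 0")
    return(list(fmax = 0, threshold = NA_real_, curve = NULL))
  }
  th <- resolve_thresholds(thresholds, es$scores)
  curve <- pr_rc_curve(es, th)
  f <- ifelse(!is.na(curve$pr) & (curve$pr + curve$rc) > 0,
              2 * curve$pr * curve$rc / (curve$pr + curve$rc), NA_real_)
  if (all(is.na(f))) return(list(fmax = 0, threshold = NA_real_, curve = curve))
  best <- which.max(f)
  list(fmax = f[best], threshold = curve$t[best], curve = curve)
}

#' Protein-centric Smin
#'
#' Minimum over thresholds of `sqrt(ru(t)^2 + mi(t)^2)`: remaining
#' uncertainty ru(t) sums the information content of false-negative terms,
#' misinformation mi(t) of false-positive terms, each averaged over all
#' evaluated proteins.
#'
#' @inheritParams fmax_metric
#' @param ic Named IC vector from [information_content()]; must be finite
#'   for every term entering a sum.
#' @return List with `smin`, `threshold` and the `curve` (t, ru, mi).
#' @export
smin_metric <- function(preds, truth, dag, ic, ontology = "MFO",
                        thresholds = "grid") {
  es <- eval_sets(preds, truth, dag, ontology)
  th <- resolve_thresholds(thresholds, es$scores)
  n <- length(es$ids)
  ru <- numeric(length(th)); mi <- numeric(length(th))
  for (j in seq_along(th)) {
    t <- th[j]
    ru_sum <- 0; mi_sum <- 0
    for (i in seq_len(n)) {
      sc <- es$scores[[i]]
      p_set <- names(sc)[sc >= t]
      fn <- setdiff(es$truth[[i]], p_set)
      fp <- setdiff(p_set, es$truth[[i]])
      used <- ic[c(fn, fp)]
      if (any(!is.finite(used))) {
        stop("infinite information content for term(s) outside the corpus: ",
             paste(c(fn, fp)[!is.finite(used)], collapse = ", "))
      }
      ru_sum <- ru_sum + sum(ic[fn])
      mi_sum <- mi_sum + sum(ic[fp])
    }
    ru[j] <- ru_sum / n
    mi[j] <- mi_sum / n
  }
  s <- sqrt(ru^2 + mi^2)
  best <- which.min(s)
  list(smin = s[best], threshold = th[best],
       curve = data.frame(t = th, ru = ru, mi = mi))
}

#' Area under the protein-centric precision-recall curve
#'
#' Trapezoidal integration of precision over recall along the threshold
#' sweep, with the curve extended to recall 0 at the precision of the
#' highest threshold point.
#'
#' @inheritParams fmax_metric
#' @return Scalar AUPR.
#' @export
aupr_metric <- function(preds, truth, dag, ontology = "MFO",
                        thresholds = "grid") {
  es <- eval_sets(preds, truth, dag, ontology)
  th <- resolve_thresholds(thresholds, es$scores)
  curve <- pr_rc_curve(es, th)
  curve <- curve[!is.na(curve$pr), , drop = FALSE]
  if (nrow(curve) == 0) return(0)
  curve <- curve[order(curve$rc, curve$pr), , drop = FALSE]
  if (nrow(curve) == 1 || length(unique(curve$rc)) == 1) {
    warning("degenerate precision-recall curve (single point); ",
            "returning the pr * rc rectangle")
    return(max(curve$pr * curve$rc))
  }
  rc <- c(0, curve$rc)
  pr <- c(curve$pr[1], curve$pr)
  sum(diff(rc) * (utils::head(pr, -1) + utils::tail(pr, -1)) / 2)
}

# Tie-corrected rank AUROC: positives' mean rank against negatives.
rank_auroc <- function(scores, labels) {
  r <- rank(scores)   # average ranks on ties -> half credit
  np <- sum(labels == 1); nn <- sum(labels == 0)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Term-centric AUROC
#'
#' For every evaluable term (at least one positive and one negative
#' protein), the rank-based AUROC of its predicted confidences across
#' proteins, ties receiving half credit; absent predictions score 0.
#'
#' @inheritParams fmax_metric
#' @param terms Terms to evaluate (default: all namespace terms, roots
#'   excluded).  Terms without both classes are skipped with a warning.
#' @return List with `per_term` (named vector) and `macro` (mean over
#'   evaluable terms).
#' @export
term_auroc <- function(preds, truth, dag, ontology = "MFO", terms = NULL) {
  es <- eval_sets(preds, truth, dag, ontology)
  terms <- terms %||% es$ns_terms
  score_mat <- vapply(es$ids, function(p) {
    v <- es$scores[[p]]
    out <- stats::setNames(numeric(length(terms)), terms)
    hit <- intersect(names(v), terms)
    out[hit] <- v[hit]
    out
  }, numeric(length(terms)))
  score_mat <- matrix(score_mat, nrow = length(terms),
                      dimnames = list(terms, es$ids))
  label_mat <- vapply(es$ids, function(p) {
    as.numeric(terms %in% es$truth[[p]])
  }, numeric(length(terms)))
  label_mat <- matrix(label_mat, nrow = length(terms))
  pos <- rowSums(label_mat)
  evaluable <- pos > 0 & pos < ncol(label_mat)
  if (!any(evaluable)) stop("no evaluable terms in ", ontology)
  if (any(!evaluable)) {
    warning(sum(!evaluable), " term(s) skipped (single-class)")
  }
  per_term <- vapply(which(evaluable), function(i) {
    rank_auroc(score_mat[i, ], label_mat[i, ])
  }, 0)
  names(per_term) <- terms[evaluable]
  list(per_term = per_term, macro = mean(per_term))
}

#' Evaluate predictions with the full metric suite
#'
#' Convenience wrapper computing Fmax, Smin, AUPR and macro AUROC for one
#' namespace.
#'
#' @inheritParams fmax_metric
#' @param ic IC vector for Smin (skipped when `NULL`).
#' @return List of metric results.
#' @export
evaluate_predictions <- function(preds, truth, dag, ic = NULL,
                                 ontology = "MFO", thresholds = "grid") {
  fm <- fmax_metric(preds, truth, dag, ontology, thresholds)
  out <- list(fmax = fm$fmax, fmax_threshold = fm$threshold,
              aupr = aupr_metric(preds, truth, dag, ontology, thresholds),
              auroc = term_auroc(preds, truth, dag, ontology)$macro,
              curve = fm$curve)
  if (!is.null(ic)) {
    sm <- smin_metric(preds, truth, dag, ic, ontology, thresholds)
    out$smin <- sm$smin
    out$smin_threshold <- sm$threshold
  }
  out
}
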
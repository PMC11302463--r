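# Baseline predictors: the Naive frequency predictor and BLAST-style
# annotation transfer from a precomputed sequence-identity table, plus the
# identity-based test-set decontamination filter.

#' Read a pairwise sequence-identity table
#'
#' Tab-separated columns query_id, subject_id, identity (with or without a
#' header).  Identities on the 0-100 scale are auto-detected and rescaled
#' to 0-1.  Absent pairs mean no reported alignment.
#'
#' @param path Input path.
#' @return data.frame with columns `query`, `subject`, `identity`.
#' @export
read_identity_table <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("quer|subj|ident", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  names(df) <- c("query", "subject", "identity")
  df$identity <- as.numeric(df$identity)
  if (any(df$identity > 1.5)) df$identity <- df$identity / 100
  if (any(df$identity < 0 | df$identity > 1)) {
    stop("identity scores outside [0, 1]")
  }
  df
}

#' Naive frequency baseline
#'
#' Every test protein receives, for every term, the relative frequency of
#' that term among the training proteins (propagated annotations).  Scores
#' are identical across proteins, which is why this baseline's
#' term-centric AUROC is exactly 0.5.
#'
#' @param train_ann A propagated [annotation_set()] of training proteins.
#' @param test_ids Character vector of test protein ids.
#' @return A [prediction_set()].
#' @export
naive_predict <- function(train_ann, test_ids) {
  if (length(train_ann$annotations) == 0) stop("empty training annotations")
  n_train <- length(train_ann$annotations)
  freq <- table(unlist(train_ann$annotations, use.names = FALSE)) / n_train
  scores <- stats::setNames(as.numeric(freq), names(freq))
  prediction_set(stats::setNames(
    rep(list(scores), length(test_ids)), test_ids))
}

#' BLAST-transfer baseline
#'
#' `score(q, f)` is the maximum identity among the training proteins
#' annotated with term f that align to query q.  Queries with no hits get
#' empty predictions.
#'
#' @param identities data.frame query/subject/identity (see
#'   [read_identity_table()]).
#' @param train_ann A propagated [annotation_set()].
#' @param test_ids Character vector of query ids.
#' @return A [prediction_set()].
#' @export
blast_transfer <- function(identities, train_ann, test_ids) {
  if (any(identities$identity > 1)) stop("identity scores above 1")
  train_ids <- names(train_ann$annotations)
  hits <- identities[identities$subject %in% train_ids, , drop = FALSE]
  preds <- lapply(test_ids, function(q) {
    h <- hits[hits$query == q, , drop = FALSE]
    if (nrow(h) == 0) return(stats::setNames(numeric(0), character(0)))
    best <- new.env()
    for (r in seq_len(nrow(h))) {
      for (f in train_ann$annotations[[h$subject[r]]]) {
        cur <- best[[f]] %||% 0
        if (h$identity[r] > cur) best[[f]] <- h$identity[r]
      }
    }
    unlist(as.list(best))
  })
  names(preds) <- test_ids
  prediction_set(preds)
}

#' Filter test proteins by maximum training identity
#'
#' Removes test proteins whose maximum identity to any training protein
#' strictly exceeds `cutoff`; proteins absent from the table are retained.
#'
#' @param test_ids Character vector of test ids.
#' @param identities data.frame query/subject/identity.
#' @param cutoff Identity cutoff in (0, 1\].
#' @return The retained test ids.
#' @export
filter_by_identity <- function(test_ids, identities, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1)
  max_id <- vapply(test_ids, function(q) {
    v <- identities$identity[identities$query == q]
    if (length(v)) max(v) else 0
  }, 0)
  kept <- test_ids[max_id <= cutoff]
  if (length(kept) == 0) warning("identity filter removed every test protein")
  kept
}
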
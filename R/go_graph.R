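# Gene Ontology machinery: OBO parsing, ancestor/descendant closure,
# annotation and prediction propagation, information content, candidate
# term selection.
#
# The DAG keeps is_a and part_of edges (both propagate, following CAFA
# convention), drops obsolete terms and maps alt_ids to their primary ids.
# Namespaces are abbreviated MFO/BPO/CCO.

NAMESPACE_MAP <- c(molecular_function = "MFO",
                   biological_process = "BPO",
                   cellular_component = "CCO")

EXPERIMENTAL_EVIDENCE <- c("EXP", "IDA", "IMP", "IGI", "IEP", "TAS", "IC")

new_go_dag <- function(terms, namespace, name, parents, alt = character(0)) {
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (ch in terms) {
    for (p in parents[[ch]]) children[[p]] <- c(children[[p]], ch)
  }
  roots <- terms[vapply(parents[terms], length, 1L) == 0]
  dag <- structure(
    list(terms = terms, namespace = namespace, name = name,
         parents = parents, children = children,
         roots = stats::setNames(roots, namespace[roots]), alt = alt),
    class = "go_dag")
  assert_acyclic(dag)
  for (t in terms) {
    if (!(t %in% roots)) {
      anc <- go_ancestors(dag, t)
      if (!any(anc %in% roots)) {
        stop("term ", t, " does not reach its namespace root")
      }
    }
  }
  dag
}

assert_acyclic <- function(dag) {
  state <- stats::setNames(rep(0L, length(dag$terms)), dag$terms)
  visit <- function(t) {
    if (state[[t]] == 1L) stop("cycle detected in ontology at ", t)
    if (state[[t]] == 2L) return(invisible())
    state[[t]] <<- 1L
    for (p in dag$parents[[t]]) visit(p)
    state[[t]] <<- 2L
  }
  for (t in dag$terms) visit(t)
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  tab <- table(x$namespace)
  cat("<go_dag> ", length(x$terms), " terms (",
      paste(names(tab), tab, sep = ":", collapse = ", "), "), roots: ",
      paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Parse a GO ontology in OBO format
#'
#' Supports the OBO 1.2/1.4 subset used by the Gene Ontology: `[Term]`
#' stanzas with `id`, `name`, `namespace`, `is_a`, `relationship: part_of`,
#' `alt_id` and `is_obsolete`.  Obsolete terms are dropped; alt_ids resolve
#' to their primary id.  Cyclic input and unknown namespaces are errors.
#'
#' @param path Path to the .obo file.
#' @return An object of class `go_dag`.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  terms <- character(0); namespace <- character(0); name <- character(0)
  parents <- list(); alt <- character(0); obsolete <- character(0)
  for (si in seq_along(stanza_starts)) {
    if (lines[stanza_starts[si]] != "[Term]") next
    from <- stanza_starts[si] + 1
    to <- if (si < length(stanza_starts)) stanza_starts[si + 1] - 1 else length(lines)
    block <- lines[from:to]
    field <- function(key) {
      sub(paste0("^", key, ": *"), "",
          grep(paste0("^", key, ":"), block, value = TRUE))
    }
    id <- field("id")[1]
    if (is.na(id)) next
    if (length(field("is_obsolete")) && field("is_obsolete")[1] == "true") {
      obsolete <- c(obsolete, id)
      next
    }
    ns_raw <- field("namespace")[1]
    ns <- NAMESPACE_MAP[ns_raw]
    if (is.na(ns)) stop("unknown namespace '", ns_raw, "' for term ", id)
    isa <- sub(" *!.*$", "", field("is_a"))
    po <- field("relationship")
    po <- sub(" *!.*$", "", po[grepl("^part_of ", po)])
    po <- sub("^part_of +", "", po)
    for (a in field("alt_id")) alt[a] <- id
    terms <- c(terms, id)
    namespace[id] <- unname(ns)
    name[id] <- field("name")[1] %||% id
    parents[[id]] <- unique(c(isa, po))
  }
  if (length(terms) == 0) stop("no terms found in ", path)
  # Drop edges pointing at obsolete/unknown terms.
  for (t in terms) parents[[t]] <- intersect(parents[[t]], terms)
  new_go_dag(terms, namespace[terms], name[terms], parents, alt)
}

#' Serialize a DAG back to OBO
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_obo <- function(dag, path) {
  inv_ns <- stats::setNames(names(NAMESPACE_MAP), NAMESPACE_MAP)
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: ", dag$name[[t]]),
               paste0("namespace: ", inv_ns[[dag$namespace[[t]]]]),
               paste0("is_a: ", dag$parents[[t]]), "")
  }
  writeLines(lines, path)
  invisible(path)
}

resolve_term <- function(dag, term) {
  if (term %in% dag$terms) return(term)
  if (term %in% names(dag$alt)) return(unname(dag$alt[term]))
  stop("unknown GO term: ", term)
}

closure_walk <- function(adj, start) {
  seen <- character(0)
  frontier <- adj[[start]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(adj[new], use.names = FALSE))
  }
  seen
}

#' Transitive ancestors of a term (excluding itself)
#' @param dag A `go_dag`.
#' @param term Term id (alt_ids resolve).
#' @return Character vector of ancestor term ids.
#' @export
go_ancestors <- function(dag, term) {
  closure_walk(dag$parents, resolve_term(dag, term))
}

#' Transitive descendants of a term (excluding itself)
#' @inheritParams go_ancestors
#' @return Character vector of descendant term ids.
#' @export
go_descendants <- function(dag, term) {
  closure_walk(dag$children, resolve_term(dag, term))
}

#' Construct an annotation set
#'
#' @param annotations Named list: protein id -> character vector of term
#'   ids.
#' @param propagated Whether the sets are already closed under ancestors.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, propagated = FALSE) {
  structure(list(annotations = lapply(annotations, unique),
                 propagated = propagated),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x$annotations), " proteins, ",
      sum(lengths(x$annotations)), " (protein, term) pairs",
      if (x$propagated) ", propagated" else "", "\n", sep = "")
  invisible(x)
}

#' Read a protein -> GO annotation table
#'
#' Tab-separated columns: protein_id, term_id, evidence_code.  Rows whose
#' evidence code is not in `evidence` are dropped.  GAF 2.x files (17
#' columns, `!` comments) are auto-detected; their NOT-qualified rows are
#' dropped with a warning.
#'
#' @param path Input path.
#' @param evidence Evidence codes to keep (default: the experimental set
#'   EXP, IDA, IMP, IGI, IEP, TAS, IC).
#' @return An unpropagated [annotation_set()].
#' @export
read_annotations <- function(path, evidence = EXPERIMENTAL_EVIDENCE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols >= 15)) {  # GAF 2.x
    qual <- vapply(parts, `[`, "", 4)
    if (any(grepl("NOT", qual))) {
      warning("dropping ", sum(grepl("NOT", qual)), " NOT-qualified rows")
      parts <- parts[!grepl("NOT", qual)]
    }
    df <- data.frame(protein = vapply(parts, `[`, "", 2),
                     term = vapply(parts, `[`, "", 5),
                     code = vapply(parts, `[`, "", 7))
  } else {
    df <- data.frame(protein = vapply(parts, `[`, "", 1),
                     term = vapply(parts, `[`, "", 2),
                     code = vapply(parts, `[`, "", 3))
  }
  df <- df[df$code %in% evidence, , drop = FALSE]
  annotation_set(split(df$term, df$protein))
}

#' Write an annotation set as TSV (protein_id, term_id, evidence_code)
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @param code Evidence code written for every row.
#' @return The path, invisibly.
#' @export
write_annotations <- function(ann, path, code = "EXP") {
  rows <- unlist(lapply(names(ann$annotations), function(p) {
    paste(p, ann$annotations[[p]], code, sep = "\t")
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Propagate annotations to the root
#'
#' Each protein's term set is unioned with all ancestors of its terms, so
#' the set becomes closed under the ancestor relation (is_a and part_of).
#'
#' @param ann An [annotation_set()].
#' @param dag A `go_dag`.
#' @return A propagated [annotation_set()].
#' @export
propagate_annotations <- function(ann, dag) {
  all_terms <- unique(unlist(ann$annotations, use.names = FALSE))
  missing <- all_terms[!vapply(all_terms, function(t) {
    t %in% dag$terms || t %in% names(dag$alt)
  }, TRUE)]
  if (length(missing)) {
    stop("annotation terms not in the ontology: ",
         paste(missing, collapse = ", "))
  }
  anc_cache <- lapply(stats::setNames(all_terms, all_terms), function(t) {
    prim <- resolve_term(dag, t)
    c(prim, go_ancestors(dag, prim))
  })
  out <- lapply(ann$annotations, function(terms) {
    unique(unlist(anc_cache[terms], use.names = FALSE))
  })
  annotation_set(out, propagated = TRUE)
}

#' Construct a prediction set
#'
#' @param predictions Named list: protein id -> named numeric vector of
#'   confidences in \[0, 1\] (names are term ids).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(predictions) {
  for (p in names(predictions)) {
    v <- predictions[[p]]
    if (length(v) && (any(v < 0) || any(v > 1))) {
      stop("confidences outside [0, 1] for protein ", p)
    }
  }
  structure(list(predictions = predictions), class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", length(x$predictions), " proteins, ",
      sum(lengths(x$predictions)), " scored (protein, term) pairs\n",
      sep = "")
  invisible(x)
}

#' Propagate prediction scores up the DAG
#'
#' Each term's confidence becomes the maximum predicted score among itself
#' and all of its descendants.  Terms with no score and no scored
#' descendant remain absent.
#'
#' @param preds A [prediction_set()].
#' @param dag A `go_dag`.
#' @return A [prediction_set()] with parent scores dominating child scores.
#' @export
propagate_predictions <- function(preds, dag) {
  topo <- topological_order(dag)   # parents before children
  out <- lapply(preds$predictions, function(scores) {
    val <- stats::setNames(rep(-Inf, length(dag$terms)), dag$terms)
    keep <- names(scores)[names(scores) %in% dag$terms]
    val[keep] <- scores[keep]
    # children before parents: reverse topological order
    for (t in rev(topo)) {
      for (p in dag$parents[[t]]) {
        if (val[[t]] > val[[p]]) val[[p]] <- val[[t]]
      }
    }
    val[is.finite(val)]
  })
  prediction_set(out)
}

topological_order <- function(dag) {
  indeg <- vapply(dag$parents[dag$terms], length, 1L)
  order <- character(0)
  queue <- dag$terms[indeg == 0]
  indeg <- stats::setNames(indeg, dag$terms)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in dag$children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  order
}

#' Information content of GO terms
#'
#' IC(f) = -log10(Occur_f / Occur_all), where Occur_f is the number of
#' distinct proteins annotated with f after propagation (which subsumes the
#' occurrences of f's descendants) and Occur_all is the total number of
#' propagated (protein, term) annotation pairs.  Terms never observed get
#' `Inf`.
#'
#' @param ann A propagated [annotation_set()].
#' @param dag A `go_dag`.
#' @return Named numeric vector of IC values over `dag$terms`.
#' @export
information_content <- function(ann, dag) {
  if (!ann$propagated) stop("annotations must be propagated first")
  if (length(ann$annotations) == 0) stop("empty annotation set")
  counts <- table(unlist(ann$annotations, use.names = FALSE))
  total <- sum(counts)
  ic <- stats::setNames(rep(Inf, length(dag$terms)), dag$terms)
  seen <- intersect(names(counts), dag$terms)
  ic[seen] <- -log10(as.numeric(counts[seen]) / total)
  ic
}

#' Select candidate terms by annotation frequency
#'
#' Terms annotated (after propagation) to at least `min_proteins` distinct
#' proteins, excluding the namespace roots, sorted.
#'
#' @param ann A propagated [annotation_set()].
#' @param dag A `go_dag`.
#' @param min_proteins Minimum number of distinct annotated proteins.
#' @return Sorted character vector of candidate term ids.
#' @export
select_candidate_terms <- function(ann, dag, min_proteins = 50) {
  if (!ann$propagated) stop("annotations must be propagated first")
  counts <- table(unlist(ann$annotations, use.names = FALSE))
  keep <- names(counts)[counts >= min_proteins]
  keep <- setdiff(intersect(keep, dag$terms), dag$roots)
  if (length(keep) == 0) stop("no candidate terms pass the threshold")
  sort(keep)
}

#' Write predictions as a CAFA-style TSV
#' @param preds A [prediction_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(preds, path) {
  rows <- unlist(lapply(names(preds$predictions), function(p) {
    v <- preds$predictions[[p]]
    if (!length(v)) return(character(0))
    sprintf("%s\t%s\t%.3f", p, names(v), v)
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Read a CAFA-style prediction TSV (protein_id, term_id, confidence)
#' @param path Input path.
#' @return A [prediction_set()].
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein", "term", "score"),
                          colClasses = c("character", "character", "numeric"))
  prediction_set(lapply(split(df, df$protein), function(d) {
    stats::setNames(d$score, d$term)
  }))
}
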
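#' Gene Ontology DAG objects
#'
#' A `go_dag` holds the parsed Gene Ontology graph restricted to the `is_a`
#' and `part_of` relations: term identifiers, their namespace (MF = molecular
#' function, BP = biological process, CC = cellular component), parent edges,
#' the root term(s) of each namespace, an `alt_id` lookup, and (once
#' [term_probabilities()] has been run against a corpus) per-term annotation
#' probabilities used by [sim_rel()] and the information-content metrics.
#'
#' @param terms Character vector of term identifiers.
#' @param namespace Named character vector mapping every term to
#'   `"MF"`, `"BP"` or `"CC"`.
#' @param parents Named list mapping every term to a character vector of
#'   parent term identifiers (empty for roots). All edges must stay within
#'   one namespace.
#' @param alt_ids Named character vector mapping alternative identifiers to
#'   canonical ones (may be empty).
#' @param term_prob Optional named numeric vector of per-term annotation
#'   probabilities in `[0, 1]`.
#'
#' @return An object of class `go_dag`.
#' @keywords internal
new_go_dag <- function(terms, namespace, parents, alt_ids = character(),
                       term_prob = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) abort("duplicate term identifiers in DAG")
  namespace <- namespace[terms]
  parents <- lapply(parents[terms], function(x) as.character(x %||% character()))
  names(parents) <- terms
  bad_ns <- !namespace %in% NAMESPACES
  if (any(bad_ns)) {
    abort(paste0("terms with unknown namespace: ",
                 paste(utils::head(terms[bad_ns], 5), collapse = ", ")))
  }
  for (t in terms) {
    pp <- parents[[t]]
    if (length(pp)) {
      missing <- setdiff(pp, terms)
      if (length(missing)) {
        abort(paste0("parent(s) of ", t, " not in DAG: ",
                     paste(missing, collapse = ", ")))
      }
      if (any(namespace[pp] != namespace[[t]])) {
        abort(paste0("cross-namespace parent edge at term ", t))
      }
    }
  }
  dag <- structure(
    list(
      terms = terms,
      namespace = namespace,
      parents = parents,
      children = invert_edges_(terms, parents),
      roots = split(terms[lengths(parents) == 0L],
                    namespace[lengths(parents) == 0L]),
      alt_ids = alt_ids,
      term_prob = term_prob
    ),
    class = "go_dag"
  )
  check_acyclic_(dag)
  dag
}

invert_edges_ <- function(terms, parents) {
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children
}

# Kahn-style topological check; aborts on a cycle inside any namespace.
check_acyclic_ <- function(dag) {
  indeg <- lengths(dag$parents)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  indeg_env <- indeg
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in dag$children[[t]]) {
      indeg_env[[ch]] <- indeg_env[[ch]] - 1L
      if (indeg_env[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(dag$terms)) {
    abort("ontology graph contains a cycle within a namespace")
  }
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  ns_tab <- table(x$namespace)
  cat("<go_dag> ", length(x$terms), " terms (",
      paste(names(ns_tab), as.integer(ns_tab), sep = ": ", collapse = ", "),
      "); ", sum(lengths(x$parents)), " parent edges",
      if (!is.null(x$term_prob)) "; term probabilities attached" else "",
      "\n", sep = "")
  invisible(x)
}

#' Parse a Gene Ontology OBO file
#'
#' Reads an OBO 1.2/1.4 flat file and builds a [go_dag][new_go_dag]. Only the
#' `is_a` and `relationship: part_of` edges are retained (the transitive
#' relations used for annotation propagation); obsolete terms are excluded
#' and `alt_id` entries are recorded so that lookups through
#' [resolve_terms()] map them to their canonical identifier. Parent edges
#' pointing outside the retained term set or across namespaces are dropped
#' with a warning.
#'
#' @param path Path to an OBO file.
#' @return A `go_dag`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root",
#'   "namespace: molecular_function", "",
#'   "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: molecular_function", "is_a: GO:0000001 ! root"
#' ), obo)
#' dag <- parse_obo(obo)
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) abort(paste0("OBO file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) abort("no stanzas found; not an OBO file?")
  ns_map <- c(molecular_function = "MF", biological_process = "BP",
              cellular_component = "CC")
  terms <- character()
  namespace <- character()
  parents <- list()
  alt_ids <- character()
  n_dropped_edges <- 0L
  stanza_bounds <- cbind(starts, c(starts[-1] - 1L, length(lines)))
  records <- list()
  for (i in seq_len(nrow(stanza_bounds))) {
    head_line <- lines[stanza_bounds[i, 1]]
    if (head_line != "[Term]") next
    body <- lines[(stanza_bounds[i, 1] + 1L):stanza_bounds[i, 2]]
    body <- body[nzchar(body)]
    fields <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    ok <- lengths(fields) == 3L
    if (any(!ok)) {
      abort(paste0("malformed OBO stanza line: '", body[!ok][1],
                   "' (near file line ", stanza_bounds[i, 1], ")"))
    }
    key <- map_chr(fields, 2)
    val <- map_chr(fields, 3)
    id <- val[key == "id"][1]
    if (is.na(id)) abort(paste0("[Term] stanza without id near line ",
                                stanza_bounds[i, 1]))
    if (any(key == "is_obsolete" & grepl("^true", val))) next
    ns_raw <- val[key == "namespace"][1]
    ns <- ns_map[[ns_raw]] %||% ns_raw
    isa <- sub("\\s*!.*$", "", val[key == "is_a"])
    rel <- val[key == "relationship"]
    partof <- sub("\\s*!.*$", "",
                  sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)]))
    records[[id]] <- list(ns = ns, parents = unique(c(isa, partof)),
                          alt = val[key == "alt_id"])
  }
  if (!length(records)) abort("no non-obsolete [Term] stanzas found")
  terms <- names(records)
  namespace <- stats::setNames(map_chr(records, "ns"), terms)
  if (any(!namespace %in% NAMESPACES)) {
    abort(paste0("unknown namespace value: ",
                 namespace[!namespace %in% NAMESPACES][1]))
  }
  parents <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    pp <- records[[t]]$parents
    keep_pp <- pp[pp %in% terms & namespace[pp] == namespace[[t]]]
    n_dropped_edges <- n_dropped_edges + length(pp) - length(keep_pp)
    parents[[t]] <- keep_pp
    alts <- records[[t]]$alt
    if (length(alts)) {
      alt_ids[alts] <- t
    }
  }
  if (n_dropped_edges > 0L) {
    warn(paste0("dropped ", n_dropped_edges,
                " parent edge(s) pointing outside the DAG or across namespaces"))
  }
  new_go_dag(terms, namespace, parents, alt_ids = alt_ids)
}

#' Resolve term identifiers against a DAG
#'
#' Maps `alt_id` aliases to canonical identifiers and flags unknown terms.
#'
#' @param terms Character vector of GO identifiers.
#' @param dag A `go_dag`.
#' @param on_unknown `"error"` to abort on an unknown identifier, `"drop"` to
#'   silently remove it, `"na"` to keep an `NA` placeholder.
#' @return Character vector of canonical identifiers.
#' @export
resolve_terms <- function(terms, dag, on_unknown = c("error", "drop", "na")) {
  on_unknown <- match.arg(on_unknown)
  out <- as.character(terms)
  is_alt <- out %in% names(dag$alt_ids)
  out[is_alt] <- dag$alt_ids[out[is_alt]]
  unknown <- !out %in% dag$terms
  if (any(unknown)) {
    if (on_unknown == "error") {
      abort(paste0("unknown GO term(s): ",
                   paste(utils::head(unique(terms[unknown]), 5), collapse = ", ")))
    }
    if (on_unknown == "drop") out <- out[!unknown]
    if (on_unknown == "na") out[unknown] <- NA_character_
  }
  out
}

#' Ancestral closure of a GO term set
#'
#' Returns the union of the input terms with all their ancestors along the
#' `is_a`/`part_of` edges ("propagating the parent terms"). A term counts as
#' its own ancestor, so the operation is idempotent.
#'
#' @param terms Character vector of GO identifiers (alt ids allowed).
#' @param dag A `go_dag`.
#' @return Character vector: the ancestral closure, in DAG term order.
#' @export
propagate <- function(terms, dag) {
  if (!inherits(dag, "go_dag")) abort("`dag` must be a go_dag")
  terms <- resolve_terms(terms, dag, on_unknown = "error")
  seen <- structure(logical(length(dag$terms)), names = dag$terms)
  stack <- unique(terms)
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[[t]]) next
    seen[[t]] <- TRUE
    pp <- dag$parents[[t]]
    if (length(pp)) stack <- c(stack, pp[!seen[pp]])
  }
  dag$terms[seen[dag$terms]]
}

# Ancestor closure of a single term (including itself); internal fast path.
ancestors_ <- function(term, dag) propagate(term, dag)

#' Per-term annotation probabilities from a corpus
#'
#' Fills the `term_prob` slot of the DAG with `p(go)`, the fraction of corpus
#' proteins annotated (after propagation) with each term. The root of a
#' namespace therefore gets the fraction of proteins with any annotation in
#' that namespace.
#'
#' @param corpus An [annotation_corpus][build_corpus].
#' @param dag A `go_dag`.
#' @return The `go_dag` with `term_prob` filled.
#' @export
term_probabilities <- function(corpus, dag) {
  if (!inherits(corpus, "annotation_corpus")) {
    abort("`corpus` must be an annotation_corpus")
  }
  n <- length(corpus$proteins)
  if (n == 0L) abort("empty corpus")
  counts <- structure(numeric(length(dag$terms)), names = dag$terms)
  for (ns in NAMESPACES) {
    tab <- table(unlist(corpus$terms_of[[ns]], use.names = FALSE))
    if (length(tab)) counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  dag$term_prob <- counts / n
  dag
}

#' Relevance semantic similarity of two GO terms
#'
#' The relevance similarity (simRel) of two terms of the same namespace: the
#' maximum over their common ancestors `go` (each term counting as its own
#' ancestor) of
#' `(2 log p(go) / (log p(go1) + log p(go2))) * (1 - p(go))`,
#' with natural logarithms. The uniqueness-weight `(1 - p(go))` sends the
#' contribution of the root (probability 1) to zero, so a pair whose only
#' common ancestor is the root scores 0.
#'
#' @param go1,go2 GO identifiers in the same namespace.
#' @param dag A `go_dag` with `term_prob` computed (see
#'   [term_probabilities()]).
#' @return Similarity in `[0, 1]`.
#' @export
sim_rel <- function(go1, go2, dag) {
  if (is.null(dag$term_prob)) {
    abort("term probabilities not computed; run term_probabilities() first")
  }
  go1 <- resolve_terms(go1, dag)
  go2 <- resolve_terms(go2, dag)
  if (dag$namespace[[go1]] != dag$namespace[[go2]]) {
    abort("sim_rel is undefined across namespaces")
  }
  p1 <- dag$term_prob[[go1]]
  p2 <- dag$term_prob[[go2]]
  if (p1 <= 0 || p2 <= 0) {
    abort(paste0("term with zero annotation probability (corpus/ontology ",
                 "mismatch): ", if (p1 <= 0) go1 else go2))
  }
  common <- intersect(ancestors_(go1, dag), ancestors_(go2, dag))
  if (!length(common)) return(0)
  best <- 0
  den <- log(p1) + log(p2)
  for (a in common) {
    pa <- dag$term_prob[[a]]
    val <- if (pa >= 1 || den == 0) 0 else (2 * log(pa) / den) * (1 - pa)
    if (val > best) best <- val
  }
  best
}

#' Best-match-average similarity of two GO term sets
#'
#' All-vs-all simRel over the two sets, then the maximum of the two
#' directional best-match averages (rows and columns of the similarity
#' matrix). Symmetric in its two arguments.
#'
#' @param set_a,set_b Non-empty character vectors of GO identifiers, all in
#'   one namespace.
#' @param dag A `go_dag` with `term_prob` computed.
#' @return Similarity score in `[0, 1]`.
#' @export
go_score <- function(set_a, set_b, dag) {
  if (!length(set_a) || !length(set_b)) {
    abort("go_score requires two non-empty term sets")
  }
  s <- matrix(0, length(set_a), length(set_b))
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      s[i, j] <- sim_rel(set_a[[i]], set_b[[j]], dag)
    }
  }
  max(mean(apply(s, 1, max)), mean(apply(s, 2, max)))
}

#' Functional similarity of two annotated proteins (funSim)
#'
#' Averages the squared per-namespace [go_score()] values over the three GO
#' categories (normalised by the theoretical per-category maximum of 1). A
#' category in which either protein lacks annotations contributes 0 to the
#' sum; if no category is annotated for both proteins the score is
#' undefined and an error is raised.
#'
#' @param annots_a,annots_b Named lists (`MF`, `BP`, `CC`) of GO identifier
#'   vectors for the two proteins; missing or empty elements are allowed.
#' @param dag A `go_dag` with `term_prob` computed.
#' @return Similarity in `[0, 1]`.
#' @export
fun_sim <- function(annots_a, annots_b, dag) {
  total <- 0
  shared <- 0L
  for (ns in NAMESPACES) {
    a <- annots_a[[ns]]
    b <- annots_b[[ns]]
    if (length(a) && length(b)) {
      shared <- shared + 1L
      total <- total + go_score(a, b, dag)^2
    }
  }
  if (shared == 0L) abort("funSim undefined: no namespace annotated for both proteins")
  total / 3
}
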
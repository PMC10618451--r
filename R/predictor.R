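#' Embed a protein as the mean of its domain embeddings
#'
#' A protein with domains `d_1 ... d_m` is represented by the arithmetic
#' mean of the corresponding rows of the domain-embedding matrix. Domains
#' unknown to the model are dropped; if none remain an error of class
#' `godomains_no_embeddable_domains` is raised so callers can fall back to
#' homology/interaction evidence alone.
#'
#' @param domains Character vector of domain identifiers.
#' @param model An [embedding_model][init_model].
#' @return Numeric vector of length `model$d`.
#' @export
protein_embedding <- function(domains, model) {
  known <- intersect(unique(domains), model$domain_vocab)
  if (!length(known)) {
    abort("no embeddable domains for this protein",
          class = "godomains_no_embeddable_domains")
  }
  colMeans(model$phi[known, , drop = FALSE])
}

#' Embed every corpus protein for one namespace
#'
#' @param corpus An [annotation_corpus][build_corpus].
#' @param model An [embedding_model][init_model].
#' @return A numeric matrix (proteins x d) with protein ids as row names;
#'   proteins with no embeddable domain are omitted.
#' @export
embed_proteins <- function(corpus, model) {
  rows <- map(corpus$domains_of, function(ds) {
    known <- intersect(ds, model$domain_vocab)
    if (!length(known)) NULL else colMeans(model$phi[known, , drop = FALSE])
  })
  keep <- !map_lgl(rows, is.null)
  if (!any(keep)) abort("no corpus protein has embeddable domains")
  do.call(rbind, rows[keep])
}

#' Reference set for KNN annotation transfer
#'
#' Bundles, per namespace, the embeddings of the annotated reference
#' (training) proteins with their propagated GO term sets and the
#' neighbourhood size K. Default K values are 1000 (MF), 800 (BP), 1200
#' (CC); K is capped at the reference size with a warning.
#'
#' @param corpus An [annotation_corpus][build_corpus] of reference proteins.
#' @param models Named list of [embedding_model][init_model]s (`MF`, `BP`,
#'   `CC`; any subset).
#' @param k Named integer vector of neighbourhood sizes per namespace.
#' @return An object of class `reference_set`.
#' @export
build_reference_set <- function(corpus, models,
                                k = c(MF = 1000L, BP = 800L, CC = 1200L)) {
  ref <- list(namespaces = intersect(NAMESPACES, names(models)), k = list(),
              emb = list(), terms_of = list())
  for (ns in ref$namespaces) {
    stopifnot(identical(models[[ns]]$namespace, ns))
    emb <- embed_proteins(corpus, models[[ns]])
    k_ns <- as.integer(k[[ns]] %||% k[[1]])
    if (k_ns <= 0) abort("K must be positive")
    if (k_ns > nrow(emb)) {
      warn(paste0("K = ", k_ns, " exceeds the ", nrow(emb),
                  " reference proteins for ", ns, "; capped"))
      k_ns <- nrow(emb)
    }
    ref$emb[[ns]] <- emb
    ref$k[[ns]] <- k_ns
    ref$terms_of[[ns]] <- corpus$terms_of[[ns]][rownames(emb)]
  }
  structure(ref, class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> namespaces: ",
      paste0(x$namespaces, " (n = ", map_int(x$emb[x$namespaces], nrow),
             ", K = ", unlist(x$k[x$namespaces]), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Distance-weighted KNN annotation scores
#'
#' Selects the K reference proteins nearest (Euclidean distance of mean
#' domain embeddings) to the query and scores every GO term annotated to at
#' least one neighbour as a weighted vote
#' `sum_k I(p_k, GO) w_k / sum_k w_k`. Two weighting schemes are available:
#' `"as_printed"` uses the squared distance itself as the weight
#' (`w_k = ||D(q) - D(p_k)||^2 + eps`), the form the source model states;
#' `"inverse"` uses `1 / (||.||^2 + eps)`, the conventional
#' closeness-weighted KNN. `eps` keeps an exact duplicate neighbour from
#' producing 0/0. Ties at the K-th rank are broken by reference order.
#'
#' @param query_emb Numeric query embedding (length d).
#' @param ref A [reference_set][build_reference_set].
#' @param namespace Namespace to score.
#' @param k Optional override of the reference K.
#' @param weighting `"as_printed"` or `"inverse"`.
#' @param exclude Optional protein id excluded from the neighbourhood
#'   (leave-one-out evaluation).
#' @param eps Stabiliser added to squared distances.
#' @return A tibble with columns `go`, `score` (in `[0, 1]`), sparse: terms
#'   absent from every neighbour are omitted.
#' @export
knn_score <- function(query_emb, ref, namespace, k = NULL,
                      weighting = c("as_printed", "inverse"),
                      exclude = NULL, eps = 1e-8) {
  weighting <- match.arg(weighting)
  assert_namespace_(namespace)
  emb <- ref$emb[[namespace]]
  if (is.null(emb)) abort(paste0("reference set has no ", namespace, " embeddings"))
  k <- as.integer(k %||% ref$k[[namespace]])
  if (k <= 0) abort("K must be positive")
  keep <- rep(TRUE, nrow(emb))
  if (!is.null(exclude)) keep <- rownames(emb) != exclude
  emb <- emb[keep, , drop = FALSE]
  if (!nrow(emb)) abort("empty reference set")
  k <- min(k, nrow(emb))
  d2 <- colSums((t(emb) - query_emb)^2)
  nn <- order(d2)[seq_len(k)]  # order() breaks ties by position
  w <- if (weighting == "as_printed") d2[nn] + eps else 1 / (d2[nn] + eps)
  terms <- ref$terms_of[[namespace]][keep][nn]
  votes <- rowsum(rep(w, lengths(terms)), unlist(terms, use.names = FALSE))
  if (!length(votes)) {
    return(tibble(go = character(), score = numeric()))
  }
  tibble(go = rownames(votes), score = as.numeric(votes) / sum(w)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$go)
}

# Shared weighted-vote kernel behind the BLAST and PPI transfer scores.
weighted_vote_ <- function(hits, weights, terms_of) {
  keep <- hits %in% names(terms_of)
  hits <- hits[keep]
  weights <- weights[keep]
  if (!length(hits) || sum(weights) == 0) {
    return(tibble(go = character(), score = numeric()))
  }
  terms <- terms_of[hits]
  votes <- rowsum(rep(weights, lengths(terms)), unlist(terms, use.names = FALSE))
  tibble(go = rownames(votes), score = as.numeric(votes) / sum(weights)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$go)
}

#' Homology-transfer scores from BLAST bit-scores
#'
#' Bit-score-weighted vote over the query's reference hits:
#' `S_B(GO) = sum_k I(p_k, GO) B(q, p_k) / sum_k B(q, p_k)`. With no hits
#' the score map is empty and the fusion indicator is 0.
#'
#' @param query Query protein id.
#' @param blast A tibble from [read_blast_tab()] (columns `query`,
#'   `subject`, `bits`).
#' @param terms_of Named list: reference protein id to GO term set (one
#'   namespace, propagated).
#' @return A tibble with columns `go`, `score`.
#' @export
blast_score <- function(query, blast, terms_of) {
  hits <- blast[blast$query == query, ]
  weighted_vote_(hits$subject, hits$bits, terms_of)
}

#' Interaction-transfer scores from PPI edge weights
#'
#' As [blast_score()], with STRING-style combined edge weights in place of
#' bit-scores. Edges are treated as undirected.
#'
#' @param query Query protein id.
#' @param links A tibble from [read_string_links()] (columns `protein1`,
#'   `protein2`, `weight`).
#' @param terms_of Named list: reference protein id to GO term set.
#' @return A tibble with columns `go`, `score`.
#' @export
ppi_score <- function(query, links, terms_of) {
  fwd <- links[links$protein1 == query, c("protein2", "weight")]
  rev <- links[links$protein2 == query, c("protein1", "weight")]
  names(fwd) <- names(rev) <- c("partner", "weight")
  edges <- dplyr::bind_rows(fwd, rev)
  edges <- edges[!duplicated(edges$partner), ]
  weighted_vote_(edges$partner, edges$weight, terms_of)
}

#' Fuse embedding, homology and interaction scores
#'
#' Per GO term, `S = (S_D + I_B S_B + I_N S_N) / (1 + I_B + I_N)`, where the
#' indicators are 1 exactly when the corresponding evidence source produced
#' any score for this protein (an empty tibble means "no evidence", `NULL`
#' means "source not used" — both give indicator 0). A term missing from a
#' present source contributes 0 for that source. When the embedding score is
#' unavailable (`s_d = NULL`, e.g. no embeddable domains), its term and
#' implicit indicator are dropped symmetrically, so a query with only BLAST
#' hits receives `S = S_B`.
#'
#' @param s_d,s_b,s_n Tibbles with columns `go`, `score`, or `NULL`.
#' @return A tibble with columns `go`, `score`; a convex combination, so
#'   scores stay in `[0, 1]`.
#' @export
combine_scores <- function(s_d, s_b = NULL, s_n = NULL) {
  present <- function(x) !is.null(x) && nrow(x) > 0
  sources <- list(s_d, s_b, s_n)
  # s_d supplied-but-empty still counts as a source (a legitimate zero vote);
  # for BLAST/PPI an empty map means "no match found", indicator 0.
  ind <- c(!is.null(s_d), present(s_b), present(s_n))
  denom <- sum(ind)
  if (denom == 0) return(tibble(go = character(), score = numeric()))
  all_terms <- unique(unlist(map(sources[ind], function(x) x$go)))
  if (!length(all_terms)) return(tibble(go = character(), score = numeric()))
  acc <- stats::setNames(numeric(length(all_terms)), all_terms)
  for (x in sources[ind]) {
    if (present(x)) acc[x$go] <- acc[x$go] + x$score
  }
  tibble(go = all_terms, score = as.numeric(acc) / denom) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$go)
}

#' Concatenated, mean-normalised protein embedding
#'
#' Concatenates the MF, BP and CC protein embeddings and rescales each
#' namespace block by the mean L2 norm of that block over the reference
#' set, so the three blocks carry comparable magnitude in the combined
#' 3d-dimensional vector.
#'
#' @param vectors Named list (`MF`, `BP`, `CC`) of per-namespace embedding
#'   vectors; all three required.
#' @param stats Named numeric vector of per-namespace mean block norms from
#'   [reference_block_stats()].
#' @return Numeric vector of length `3 d`.
#' @export
concat_embedding <- function(vectors, stats) {
  missing_ns <- setdiff(NAMESPACES, names(vectors)[!map_lgl(vectors, is.null)])
  if (length(missing_ns)) {
    abort(paste0("missing namespace vector(s): ",
                 paste(missing_ns, collapse = ", ")))
  }
  unlist(map(NAMESPACES, function(ns) {
    s <- stats[[ns]]
    if (is.na(s) || s == 0) vectors[[ns]] else vectors[[ns]] / s
  }), use.names = FALSE)
}

#' @rdname concat_embedding
#' @param ref A [reference_set][build_reference_set] covering all three
#'   namespaces.
#' @export
reference_block_stats <- function(ref) {
  stats::setNames(map_dbl(NAMESPACES, function(ns) {
    emb <- ref$emb[[ns]]
    if (is.null(emb)) return(NA_real_)
    mean(sqrt(rowSums(emb^2)))
  }), NAMESPACES)
}

#' Predict GO terms for query proteins
#'
#' The full prediction path: embed each query protein from its domains,
#' score terms by distance-weighted KNN against the reference set, fuse
#' with BLAST and PPI evidence when supplied, and optionally enforce
#' parent-above-child score consistency.
#'
#' @param queries Named list: query protein id to character vector of
#'   domain identifiers.
#' @param ref A [reference_set][build_reference_set].
#' @param models Named list of [embedding_model][init_model]s per namespace.
#' @param namespace Namespace to predict.
#' @param blast Optional BLAST tibble ([read_blast_tab()]).
#' @param links Optional PPI tibble ([read_string_links()]).
#' @param weighting KNN weighting scheme, see [knn_score()].
#' @param k Optional K override.
#' @param hierarchical If `TRUE`, raise every term's score to the maximum
#'   over its descendants after fusion (requires `dag`).
#' @param dag A `go_dag`, required when `hierarchical = TRUE`.
#' @return A tibble with columns `protein`, `go`, `score`.
#' @export
predict_go <- function(queries, ref, models, namespace,
                       blast = NULL, links = NULL,
                       weighting = "as_printed", k = NULL,
                       hierarchical = FALSE, dag = NULL) {
  assert_namespace_(namespace)
  model <- models[[namespace]]
  terms_of <- ref$terms_of[[namespace]]
  out <- imap(queries, function(domains, pid) {
    s_d <- tryCatch({
      q <- protein_embedding(domains, model)
      knn_score(q, ref, namespace, k = k, weighting = weighting)
    }, godomains_no_embeddable_domains = function(e) NULL)
    s_b <- if (!is.null(blast)) blast_score(pid, blast, terms_of)
    s_n <- if (!is.null(links)) ppi_score(pid, links, terms_of)
    sc <- combine_scores(s_d, s_b, s_n)
    if (nrow(sc)) sc$protein <- pid
    sc
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(tibble(protein = character(), go = character(),
                                score = numeric()))
  res <- dplyr::select(res, "protein", "go", "score")
  if (hierarchical) {
    if (is.null(dag)) abort("`dag` required when hierarchical = TRUE")
    res <- res |>
      dplyr::group_by(.data$protein) |>
      dplyr::group_modify(~ enforce_hierarchy_(.x, dag)) |>
      dplyr::ungroup()
  }
  res
}

# Raise each predicted term's score to the max over its predicted
# descendants (a term is its own descendant), so parent >= child holds.
enforce_hierarchy_ <- function(scores, dag) {
  s <- stats::setNames(scores$score, scores$go)
  out <- s
  for (g in names(s)) {
    for (a in propagate(g, dag)) {
      if (!is.na(out[a]) && !is.null(out[a]) && a %in% names(out)) {
        out[a] <- max(out[a], s[[g]])
      }
    }
  }
  tibble(go = names(out), score = as.numeric(out))
}
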
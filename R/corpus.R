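#' Build an annotation corpus
#'
#' Joins protein-to-domain assignments with protein-to-GO annotations into
#' the corpus object every later stage consumes. Proteins without any domain
#' assignment are discarded (their count is reported), because a
#' domain-based predictor can say nothing about them; proteins with domains
#' but no GO annotation are kept — they still contribute to the
#' domain-probability denominators and serve as negative reference points.
#' GO annotations are resolved against the DAG (unknown ids are skipped with
#' a summary warning) and closed under ancestor propagation per namespace.
#'
#' @param domain_assignments Data frame with columns `protein`, `domain`.
#' @param go_annotations Data frame with columns `protein`, `go`.
#' @param dag A [go_dag][new_go_dag].
#' @return An object of class `annotation_corpus`: a list with elements
#'   `proteins` (character), `domains_of` (named list), `terms_of` (list of
#'   named lists per namespace), `domain_vocab`, `term_vocab` (list per
#'   namespace), and `n_dropped` (proteins discarded for lacking domains).
#' @export
build_corpus <- function(domain_assignments, go_annotations, dag) {
  stopifnot(all(c("protein", "domain") %in% names(domain_assignments)))
  stopifnot(all(c("protein", "go") %in% names(go_annotations)))
  dom <- dplyr::distinct(as_tibble(domain_assignments[c("protein", "domain")]))
  ann <- as_tibble(go_annotations[c("protein", "go")])

  proteins <- sort(unique(c(dom$protein, ann$protein)))
  with_domain <- unique(dom$protein)
  n_dropped <- length(setdiff(proteins, with_domain))
  if (n_dropped > 0L) {
    inform(paste0("discarded ", n_dropped,
                  " protein(s) without domain assignments"))
  }
  proteins <- sort(with_domain)
  if (!length(proteins)) abort("no proteins with domain assignments")

  ann <- dplyr::filter(ann, .data$protein %in% proteins)
  resolved <- resolve_terms(ann$go, dag, on_unknown = "na")
  n_unknown <- sum(is.na(resolved))
  if (n_unknown > 0L) {
    warn(paste0("skipped ", n_unknown, " annotation(s) with unknown GO ids"))
  }
  ann$go <- resolved
  ann <- dplyr::filter(ann, !is.na(.data$go))

  domains_of <- split(dom$domain, factor(dom$protein, levels = proteins))
  domains_of <- map(domains_of, unique)

  terms_of <- list()
  for (ns in NAMESPACES) {
    ns_terms <- dag$terms[dag$namespace == ns]
    ann_ns <- dplyr::filter(ann, .data$go %in% ns_terms)
    by_protein <- split(ann_ns$go, factor(ann_ns$protein, levels = proteins))
    terms_of[[ns]] <- map(by_protein, function(ts) {
      if (!length(ts)) character() else propagate(unique(ts), dag)
    })
  }

  structure(
    list(
      proteins = proteins,
      domains_of = domains_of,
      terms_of = terms_of,
      domain_vocab = sort(unique(dom$domain)),
      term_vocab = map(terms_of, function(x)
        sort(unique(unlist(x, use.names = FALSE)))),
      n_dropped = n_dropped
    ),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus> ", length(x$proteins), " proteins, ",
      length(x$domain_vocab), " domains; GO terms per namespace: ",
      paste(NAMESPACES, lengths(x$term_vocab)[NAMESPACES],
            sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Domain-GO co-occurrence conditional probabilities
#'
#' Counts, over all corpus proteins, the marginal probability of carrying
#' each domain and the joint probability of carrying a domain while being
#' annotated with a GO term, and forms the conditional probability
#' `p(GO | domain) = p(domain & GO) / p(domain)` that serves as the
#' pseudo-label for self-supervised embedding training. Only pairs with a
#' positive joint probability are stored; all other pairs are implicitly 0.
#'
#' @param corpus An [annotation_corpus][build_corpus].
#' @param namespace One of `"MF"`, `"BP"`, `"CC"`.
#' @return A tibble of class `cooccurrence_tbl` with columns `domain`, `go`,
#'   `p_domain`, `p_joint`, `p_cond`, and attributes `namespace`,
#'   `n_proteins`, `p_domain_all` (named vector over the full domain
#'   vocabulary) and `term_vocab`.
#' @export
conditional_probabilities <- function(corpus, namespace) {
  assert_namespace_(namespace)
  if (!inherits(corpus, "annotation_corpus")) {
    abort("`corpus` must be an annotation_corpus")
  }
  n <- length(corpus$proteins)
  if (n == 0L) abort("empty corpus")

  pd_long <- tibble(
    protein = rep(corpus$proteins, lengths(corpus$domains_of)),
    domain = unlist(corpus$domains_of, use.names = FALSE)
  )
  ts <- corpus$terms_of[[namespace]]
  pg_long <- tibble(
    protein = rep(corpus$proteins, lengths(ts)),
    go = unlist(ts, use.names = FALSE)
  )
  if (nrow(pg_long) == 0L) {
    warn(paste0("no ", namespace, " annotations in corpus; empty table"))
  }

  p_domain_all <- table(factor(pd_long$domain, levels = corpus$domain_vocab)) / n
  p_domain_all <- stats::setNames(as.numeric(p_domain_all), corpus$domain_vocab)

  joint <- dplyr::count(
    dplyr::inner_join(pd_long, pg_long, by = "protein",
                      relationship = "many-to-many"),
    .data$domain, .data$go, name = "n_joint"
  )
  out <- joint |>
    dplyr::mutate(
      p_domain = unname(p_domain_all[.data$domain]),
      p_joint = .data$n_joint / n,
      p_cond = .data$p_joint / .data$p_domain
    ) |>
    dplyr::select("domain", "go", "p_domain", "p_joint", "p_cond") |>
    dplyr::arrange(.data$domain, .data$go)

  new_cooccurrence_tbl(out, namespace = namespace, n_proteins = n,
                       p_domain_all = p_domain_all,
                       term_vocab = corpus$term_vocab[[namespace]])
}

new_cooccurrence_tbl <- function(df, namespace, n_proteins, p_domain_all,
                                 term_vocab) {
  structure(
    df,
    namespace = namespace, n_proteins = n_proteins,
    p_domain_all = p_domain_all, term_vocab = term_vocab,
    class = c("cooccurrence_tbl", class(tibble()))
  )
}

#' Remove curated domain-GO pairs from a co-occurrence table
#'
#' The adversarial-training filter: every `(domain, GO)` pair present in the
#' supplied mapping (for example an InterPro2GO extract) is removed from the
#' stored pair list, so the embedding model can only learn those
#' associations indirectly, from co-occurring domains and the term
#' hierarchy. Domain marginal probabilities are unchanged. Mapping rows
#' whose domain or term is outside the corpus vocabulary are ignored (their
#' count is reported). Removed pairs are recorded in the `excluded_pairs`
#' attribute: their probability is unknown rather than zero, so
#' [make_training_pairs()] keeps them out of the negative-sampling pool.
#'
#' @param table A [cooccurrence_tbl][conditional_probabilities].
#' @param mapping Data frame with columns `domain`, `go`.
#' @return A filtered `cooccurrence_tbl`.
#' @export
adversarial_filter <- function(table, mapping) {
  stopifnot(inherits(table, "cooccurrence_tbl"))
  stopifnot(all(c("domain", "go") %in% names(mapping)))
  mapping <- dplyr::distinct(as_tibble(mapping[c("domain", "go")]))
  in_vocab <- mapping$domain %in% names(attr(table, "p_domain_all")) &
    mapping$go %in% attr(table, "term_vocab")
  if (any(!in_vocab)) {
    inform(paste0("ignored ", sum(!in_vocab),
                  " mapping pair(s) outside the corpus vocabularies"))
  }
  mapping <- mapping[in_vocab, ]
  out <- dplyr::anti_join(as_tibble(table), mapping, by = c("domain", "go"))
  out <- new_cooccurrence_tbl(out,
                              namespace = attr(table, "namespace"),
                              n_proteins = attr(table, "n_proteins"),
                              p_domain_all = attr(table, "p_domain_all"),
                              term_vocab = attr(table, "term_vocab"))
  # removed pairs are *unknown*, not observed zeros: downstream negative
  # sampling must not turn them into zero-target training examples
  attr(out, "excluded_pairs") <- dplyr::bind_rows(
    attr(table, "excluded_pairs"), mapping)
  out
}

#' Build training pairs with negative sampling
#'
#' Positive pairs carry the empirical conditional probability as regression
#' target. For each domain, a number of GO terms drawn uniformly from
#' `n_neg_range` that never co-occur with it (conditional probability
#' exactly 0) are sampled without replacement as zero-target negatives,
#' mimicking negative sampling in word-embedding training. Positives are
#' split into training and validation by `split_frac`; negatives are split
#' the same way, and the pool is drawn once per run so validation loss is
#' comparable across epochs. Fully deterministic under `seed`.
#'
#' When `n_neg_range` is `NULL` the draw for each domain is additionally
#' capped at 10 times its positive-pair count, which keeps small corpora
#' from being swamped by zeros; pass `c(1000, 2000)` explicitly for
#' full-scale corpora.
#'
#' @param table A [cooccurrence_tbl][conditional_probabilities].
#' @param n_neg_range Integer vector `c(lo, hi)`, or `NULL` for the
#'   auto-capped default.
#' @param split_frac Fraction of pairs assigned to the training split
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A tibble of class `training_pairs` with columns `domain`, `go`,
#'   `target`, `split`, plus attributes `namespace`, `domain_vocab`,
#'   `term_vocab`.
#' @export
make_training_pairs <- function(table, n_neg_range = NULL, split_frac = 0.8,
                                seed = 1L) {
  stopifnot(inherits(table, "cooccurrence_tbl"))
  auto_cap <- is.null(n_neg_range)
  if (auto_cap) n_neg_range <- c(1000L, 2000L)
  if (length(n_neg_range) != 2L || n_neg_range[1] > n_neg_range[2] ||
      n_neg_range[1] < 0) {
    abort("`n_neg_range` must be c(lo, hi) with 0 <= lo <= hi")
  }
  if (!(split_frac > 0 && split_frac < 1)) {
    abort("`split_frac` must be strictly between 0 and 1")
  }
  term_vocab <- attr(table, "term_vocab")
  domain_vocab <- names(attr(table, "p_domain_all"))
  pos_by_domain <- split(table$go, factor(table$domain, levels = domain_vocab))
  # pairs dropped by adversarial_filter() stay out of the negative pool too
  excl <- attr(table, "excluded_pairs")
  excl_by_domain <- if (!is.null(excl)) {
    split(excl$go, factor(excl$domain, levels = domain_vocab))
  }

  with_seed_(seed, {
    negs <- map(domain_vocab, function(d) {
      avail <- setdiff(term_vocab, c(pos_by_domain[[d]], excl_by_domain[[d]]))
      if (!length(avail)) return(character())
      k <- if (n_neg_range[1] == n_neg_range[2]) n_neg_range[1] else
        sample(seq(n_neg_range[1], n_neg_range[2]), 1L)
      if (auto_cap) k <- min(k, 10L * max(length(pos_by_domain[[d]]), 1L))
      sample(avail, min(k, length(avail)))
    })
    pairs <- dplyr::bind_rows(
      tibble(domain = table$domain, go = table$go, target = table$p_cond,
             positive = TRUE),
      tibble(domain = rep(domain_vocab, lengths(negs)),
             go = unlist(negs, use.names = FALSE) %||% character(),
             target = 0, positive = FALSE)
    )
    n_pos <- sum(pairs$positive)
    split_of <- function(n) {
      s <- rep("val", n)
      s[sample.int(n, size = round(split_frac * n))] <- "train"
      s
    }
    pairs$split <- NA_character_
    pairs$split[pairs$positive] <- split_of(n_pos)
    pairs$split[!pairs$positive] <- split_of(nrow(pairs) - n_pos)
    structure(
      dplyr::select(pairs, "domain", "go", "target", "split", "positive"),
      namespace = attr(table, "namespace"),
      domain_vocab = domain_vocab,
      term_vocab = term_vocab,
      class = c("training_pairs", class(tibble()))
    )
  })
}
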
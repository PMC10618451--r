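# Small fixture builders used across the suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# A linear MF chain root <- a <- b plus an alt_id and an obsolete stanza.
chain_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: a", "namespace: molecular_function",
    "alt_id: GO:0000099", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: b", "namespace: molecular_function",
    "is_a: GO:0000002 ! a", "",
    "[Term]", "id: GO:0000666", "name: gone", "namespace: molecular_function",
    "is_obsolete: true", "")
}

chain_dag <- function() {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(chain_obo_lines(), path)
  parse_obo(path)
}

# A flat ontology: one root per namespace, `n_leaves` leaf children each.
flat_dag <- function(n_leaves = 3) {
  ns_long <- c(MF = "molecular_function", BP = "biological_process",
               CC = "cellular_component")
  lines <- c("format-version: 1.2", "")
  id <- 0L
  for (ns in c("MF", "BP", "CC")) {
    id <- id + 1L
    root <- sprintf("GO:%07d", id)
    lines <- c(lines, "[Term]", paste0("id: ", root),
               paste0("name: ", ns, " root"),
               paste0("namespace: ", ns_long[[ns]]), "")
    for (j in seq_len(n_leaves)) {
      id <- id + 1L
      lines <- c(lines, "[Term]", paste0("id: ", sprintf("GO:%07d", id)),
                 paste0("name: leaf"), paste0("namespace: ", ns_long[[ns]]),
                 paste0("is_a: ", root, " ! root"), "")
    }
  }
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(lines, path)
  parse_obo(path)
}

# Random annotation corpus over a generated DAG; returns corpus + raw tables.
random_corpus <- function(seed, n_proteins = 40, n_domains = 8, n_terms = 10) {
  spec <- synth_spec(n_proteins = n_proteins, n_domains = n_domains,
                     n_terms = c(MF = n_terms, BP = n_terms, CC = n_terms),
                     dag_depth = 3, seed = seed)
  dag <- generate_dag(spec)
  sim <- generate_corpus(spec, dag)
  sim
}

# Hand-constructed training_pairs tibble for trainer unit tests.
manual_pairs <- function(entries, domain_vocab, term_vocab, namespace = "MF") {
  structure(
    tibble::as_tibble(entries),
    namespace = namespace,
    domain_vocab = domain_vocab,
    term_vocab = term_vocab,
    class = c("training_pairs", class(tibble::tibble()))
  )
}

# Random sparse prediction/truth instance for the metric oracles.
random_eval_instance <- function(seed, n_prot = 10, n_term = 20) {
  withr::with_seed(seed, {
    proteins <- sprintf("P%03d", seq_len(n_prot))
    terms <- sprintf("GO:%07d", seq_len(n_term))
    truth <- do.call(rbind, lapply(proteins, function(p) {
      k <- sample(1:5, 1)
      data.frame(protein = p, go = sample(terms, k))
    }))
    pred <- do.call(rbind, lapply(proteins, function(p) {
      k <- sample(3:12, 1)
      data.frame(protein = p, go = sample(terms, k),
                 score = round(stats::runif(k), 2))
    }))
    list(pred = tibble::as_tibble(pred), truth = tibble::as_tibble(truth),
         proteins = proteins, terms = terms)
  })
}
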
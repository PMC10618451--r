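#' Specification for a synthetic benchmark
#'
#' Describes a seeded synthetic world: a random GO-like ontology per
#' namespace, a domain vocabulary, proteins carrying 1-4 domains, and a
#' planted association matrix Pi whose entry `Pi[d, g]` is the probability
#' that a protein containing domain `d` is annotated with term `g`.
#' Annotation emission is leaky noisy-OR over a protein's domains, so the
#' planted structure induces exactly the conditional-probability signal the
#' co-occurrence table estimates. Identifier patterns mimic UniProt
#' accessions, InterPro entries and GO ids so the format readers are
#' exercised realistically.
#'
#' @param n_proteins Number of proteins.
#' @param n_domains Number of domains.
#' @param n_terms Named integer vector: terms per namespace (including the
#'   namespace root).
#' @param dag_depth Maximum depth of each namespace tree (1 = root only).
#' @param domains_per_protein Integer range `c(lo, hi)` of domains drawn per
#'   protein.
#' @param noise_rate Leak probability of the noisy-OR emission (an
#'   annotation can appear without any supporting domain).
#' @param family_size Domains are partitioned into families of roughly this
#'   size; family members share their planted terms (with per-domain
#'   jitter) and preferentially co-occur in proteins, mirroring how real
#'   domain families carry common function and appear together in
#'   architectures.
#' @param within_family_prob Probability that each additional domain of a
#'   protein is drawn from the first domain's family rather than uniformly.
#' @param assoc_per_family Range of planted term associations per family.
#' @param assoc_prob Range from which planted association probabilities are
#'   drawn (per-domain jitter of +-0.1 applied within the family).
#' @param seed Mandatory integer seed; every generator is a pure function
#'   of (spec, seed).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 2000L, n_domains = 50L,
                       n_terms = c(MF = 40L, BP = 40L, CC = 40L),
                       dag_depth = 4L, domains_per_protein = c(1L, 4L),
                       noise_rate = 0.01,
                       family_size = 3L, within_family_prob = 0.5,
                       assoc_per_family = c(1L, 3L),
                       assoc_prob = c(0.6, 0.95),
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory for synthetic specs")
  if (n_proteins < 1 || n_domains < 1 || any(n_terms < 1)) {
    abort("vocabulary sizes must be at least 1")
  }
  if (dag_depth < 1) abort("`dag_depth` must be >= 1")
  if (noise_rate < 0 || noise_rate > 1) abort("`noise_rate` must be in [0, 1]")
  if (!all(NAMESPACES %in% names(n_terms))) {
    abort("`n_terms` must name MF, BP and CC")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_domains = as.integer(n_domains),
                 n_terms = n_terms[NAMESPACES],
                 dag_depth = as.integer(dag_depth),
                 domains_per_protein = as.integer(domains_per_protein),
                 noise_rate = noise_rate,
                 family_size = as.integer(family_size),
                 within_family_prob = within_family_prob,
                 assoc_per_family = as.integer(assoc_per_family),
                 assoc_prob = assoc_prob,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

synth_protein_ids <- function(n) sprintf("P%05d", seq_len(n))
synth_domain_ids <- function(n) sprintf("IPR%06d", seq_len(n))

#' Generate a random GO-like DAG
#'
#' Builds, per namespace, a random tree of the requested depth plus a few
#' shortcut `part_of` edges (each non-root term may gain one extra parent
#' closer to the root), giving a single-rooted DAG that is acyclic by
#' construction. Term ids are GO-style and unique across namespaces.
#'
#' @param spec A [synth_spec()].
#' @return A [go_dag][new_go_dag].
#' @export
generate_dag <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed_(spec$seed, {
    terms <- character()
    namespace <- character()
    parents <- list()
    offset <- 0L
    for (ns in NAMESPACES) {
      n <- spec$n_terms[[ns]]
      ids <- sprintf("GO:%07d", offset + seq_len(n))
      offset <- offset + n
      depth <- integer(n)
      depth[1] <- 0L
      pars <- stats::setNames(vector("list", n), ids)
      if (n > 1L) {
        for (i in 2:n) {
          # candidate parents: earlier terms below the depth cap
          cand <- which(depth[seq_len(i - 1L)] < spec$dag_depth - 1L)
          if (!length(cand)) cand <- 1L
          p <- cand[[sample.int(length(cand), 1L)]]
          depth[i] <- depth[p] + 1L
          pars[[ids[i]]] <- ids[p]
          # occasional shortcut edge to a second, shallower parent
          if (depth[i] >= 2L && stats::runif(1) < 0.2) {
            shallow <- which(depth[seq_len(i - 1L)] < depth[i] - 1L)
            extra <- shallow[[sample.int(length(shallow), 1L)]]
            if (extra != p) pars[[ids[i]]] <- c(pars[[ids[i]]], ids[extra])
          }
        }
      }
      terms <- c(terms, ids)
      namespace <- c(namespace, stats::setNames(rep(ns, n), ids))
      parents <- c(parents, pars)
    }
    new_go_dag(terms, namespace, parents)
  })
}

#' Write a DAG as an OBO file
#'
#' Emits standard `[Term]` stanzas (id, name, namespace, is_a); second and
#' later parents are written as `relationship: part_of`, matching how the
#' generator plants shortcut edges. Output round-trips through
#' [parse_obo()].
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  ns_long <- c(MF = "molecular_function", BP = "biological_process",
               CC = "cellular_component")
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    pp <- dag$parents[[t]]
    lines <- c(lines, "[Term]",
               paste0("id: ", t),
               paste0("name: synthetic term ", t),
               paste0("namespace: ", ns_long[[dag$namespace[[t]]]]))
    if (length(pp)) {
      lines <- c(lines, paste0("is_a: ", pp[[1]], " ! parent"))
      if (length(pp) > 1L) {
        lines <- c(lines, paste0("relationship: part_of ", pp[-1], " ! parent"))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Domain family assignment
#'
#' Deterministic partition of the domain vocabulary into consecutive
#' families of `family_size`.
#'
#' @param spec A [synth_spec()].
#' @return Integer vector: family index per domain, named by domain id.
#' @export
domain_families <- function(spec) {
  stats::setNames(
    rep(seq_len(ceiling(spec$n_domains / spec$family_size)),
        each = spec$family_size)[seq_len(spec$n_domains)],
    synth_domain_ids(spec$n_domains))
}

#' Plant a domain-to-term association matrix
#'
#' Associations are planted at the family level: each domain family is
#' assigned a few non-root terms (count drawn from `assoc_per_family`) with
#' a family base probability from `assoc_prob`, and each member domain
#' carries those terms at the base probability plus a small per-domain
#' jitter. Family members therefore share function — the structure that
#' makes associations of one domain recoverable from the co-occurrence
#' context of its relatives.
#'
#' @param spec A [synth_spec()].
#' @param dag The DAG from [generate_dag()].
#' @return Named list of matrices (domains x non-root namespace terms).
#' @export
planted_associations <- function(spec, dag) {
  stopifnot(inherits(spec, "synth_spec"))
  fam <- domain_families(spec)
  n_fam <- max(fam)
  with_seed_(spec$seed + 1L, {
    domains <- synth_domain_ids(spec$n_domains)
    out <- list()
    for (ns in NAMESPACES) {
      ns_terms <- dag$terms[dag$namespace == ns]
      leaves <- setdiff(ns_terms, unlist(dag$roots[ns]))
      Pi <- matrix(0, spec$n_domains, length(leaves),
                   dimnames = list(domains, leaves))
      if (length(leaves)) {
        for (f in seq_len(n_fam)) {
          k <- sample(seq(spec$assoc_per_family[1], spec$assoc_per_family[2]), 1L)
          k <- min(k, length(leaves))
          which_terms <- sample(length(leaves), k)
          base <- stats::runif(k, spec$assoc_prob[1], spec$assoc_prob[2])
          for (i in which(fam == f)) {
            jit <- stats::runif(k, -0.1, 0.1)
            Pi[i, which_terms] <- pmin(pmax(base + jit, 0.05), 1)
          }
        }
      }
      out[[ns]] <- Pi
    }
    out
  })
}

#' Generate a synthetic annotation corpus with planted structure
#'
#' Each protein draws its domain count uniformly from
#' `domains_per_protein`; the first domain is uniform over the vocabulary
#' and each further domain comes from the first domain's family with
#' probability `within_family_prob` (uniform otherwise), giving the
#' family-level co-occurrence seen in real domain architectures. Each
#' non-root term `g` is annotated with leaky noisy-OR probability
#' `1 - (1 - noise_rate) * prod_d (1 - Pi[d, g])` over the protein's
#' domains; annotations are then propagated up the DAG. Entries with
#' `Pi[d, g] = 1` are deterministic: every protein carrying `d` gets `g`.
#'
#' @param spec A [synth_spec()].
#' @param dag The DAG from [generate_dag()].
#' @param assoc Optional association matrices ([planted_associations()]);
#'   generated from the spec seed when omitted.
#' @return A list with elements `corpus` (an
#'   [annotation_corpus][build_corpus]), `assoc` (the planted matrices),
#'   `domain_assignments` and `go_annotations` (the raw tibbles, useful for
#'   writing files), and `dag`.
#' @export
generate_corpus <- function(spec, dag, assoc = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(assoc)) assoc <- planted_associations(spec, dag)
  domains <- synth_domain_ids(spec$n_domains)
  proteins <- synth_protein_ids(spec$n_proteins)
  fam <- domain_families(spec)
  members <- split(seq_len(spec$n_domains), fam)
  with_seed_(spec$seed + 2L, {
    lo <- spec$domains_per_protein[1]
    hi <- spec$domains_per_protein[2]
    counts <- if (lo == hi) rep(lo, spec$n_proteins) else
      sample(seq(lo, hi), spec$n_proteins, replace = TRUE)
    domain_sets <- map(counts, function(k) {
      first <- sample.int(spec$n_domains, 1L)
      ds <- first
      if (k > 1L) {
        kin <- setdiff(members[[fam[[first]]]], first)
        for (j in seq_len(k - 1L)) {
          pick <- if (length(kin) &&
                      stats::runif(1) < spec$within_family_prob) {
            kin[[sample.int(length(kin), 1L)]]
          } else {
            sample.int(spec$n_domains, 1L)
          }
          ds <- c(ds, pick)
        }
      }
      domains[unique(ds)]
    })
    # membership matrix proteins x domains
    M <- matrix(0, spec$n_proteins, spec$n_domains,
                dimnames = list(proteins, domains))
    M[cbind(rep(seq_len(spec$n_proteins), lengths(domain_sets)),
            match(unlist(domain_sets), domains))] <- 1

    ann <- list()
    for (ns in NAMESPACES) {
      Pi <- assoc[[ns]]
      if (!ncol(Pi)) next
      capped <- pmin(Pi, 1 - 1e-12)
      log_miss <- log1p(-capped)
      p_on <- 1 - (1 - spec$noise_rate) * exp(M %*% log_miss)
      # deterministic entries: Pi exactly 1
      forced <- (M %*% (Pi == 1)) > 0
      draws <- matrix(stats::runif(length(p_on)), nrow(p_on))
      on <- draws < p_on | forced
      idx <- which(on, arr.ind = TRUE)
      if (nrow(idx)) {
        ann[[ns]] <- tibble(protein = proteins[idx[, 1]],
                            go = colnames(Pi)[idx[, 2]])
      }
    }
    go_annotations <- dplyr::bind_rows(ann)
    if (!nrow(go_annotations)) {
      go_annotations <- tibble(protein = character(), go = character())
    }
    domain_assignments <- tibble(
      protein = rep(proteins, lengths(domain_sets)),
      domain = unlist(domain_sets, use.names = FALSE)
    )
    corpus <- build_corpus(domain_assignments, go_annotations, dag)
    list(corpus = corpus, assoc = assoc,
         domain_assignments = domain_assignments,
         go_annotations = go_annotations, dag = dag)
  })
}

#' Generate synthetic BLAST and PPI evidence
#'
#' Emits BLAST-like tabular hits between proteins sharing at least one
#' domain, with bit-scores increasing in the Jaccard overlap of their
#' domain sets, and STRING-like edges between proteins sharing non-root GO
#' terms, weighted by term-set overlap. Partner lists are capped per
#' protein to keep files desk-sized.
#'
#' @param sim Output of [generate_corpus()].
#' @param spec The same [synth_spec()].
#' @param max_partners Cap on partners per protein.
#' @return A list with tibbles `blast` (`query`, `subject`, `bits`) and
#'   `links` (`protein1`, `protein2`, `weight`).
#' @export
generate_evidence <- function(sim, spec, max_partners = 25L) {
  corpus <- sim$corpus
  with_seed_(spec$seed + 3L, {
    by_domain <- list()
    for (i in seq_along(corpus$proteins)) {
      for (d in corpus$domains_of[[i]]) {
        by_domain[[d]] <- c(by_domain[[d]], i)
      }
    }
    blast_rows <- list()
    for (i in seq_along(corpus$proteins)) {
      mates <- setdiff(unique(unlist(by_domain[corpus$domains_of[[i]]])), i)
      if (!length(mates)) next
      if (length(mates) > max_partners) {
        mates <- sort(sample(mates, max_partners))
      }
      jac <- map_dbl(mates, function(j) {
        a <- corpus$domains_of[[i]]
        b <- corpus$domains_of[[j]]
        length(intersect(a, b)) / length(union(a, b))
      })
      blast_rows[[i]] <- tibble(query = corpus$proteins[i],
                                subject = corpus$proteins[mates],
                                bits = round(50 + 450 * jac, 1))
    }
    blast <- dplyr::bind_rows(blast_rows)
    if (!nrow(blast)) blast <- tibble(query = character(),
                                      subject = character(), bits = numeric())

    roots <- unlist(corpus_dag_roots_(sim$dag))
    term_sets <- map(seq_along(corpus$proteins), function(i) {
      setdiff(unlist(map(NAMESPACES, function(ns)
        corpus$terms_of[[ns]][[i]]), use.names = FALSE), roots)
    })
    by_term <- list()
    for (i in seq_along(term_sets)) {
      for (t in term_sets[[i]]) by_term[[t]] <- c(by_term[[t]], i)
    }
    link_rows <- list()
    for (i in seq_along(corpus$proteins)) {
      mates <- setdiff(unique(unlist(by_term[term_sets[[i]]])), i)
      mates <- mates[mates > i]  # undirected, each pair once
      if (!length(mates)) next
      if (length(mates) > max_partners) mates <- sort(sample(mates, max_partners))
      ov <- map_dbl(mates, function(j) {
        a <- term_sets[[i]]
        b <- term_sets[[j]]
        length(intersect(a, b)) / length(union(a, b))
      })
      keep <- ov >= 0.15
      if (!any(keep)) next
      link_rows[[i]] <- tibble(protein1 = corpus$proteins[i],
                               protein2 = corpus$proteins[mates[keep]],
                               weight = round(ov[keep], 3))
    }
    links <- dplyr::bind_rows(link_rows)
    if (!nrow(links)) links <- tibble(protein1 = character(),
                                      protein2 = character(),
                                      weight = numeric())
    list(blast = blast, links = links)
  })
}

corpus_dag_roots_ <- function(dag) dag$roots

#' Write synthetic artifacts in their external dialects
#'
#' Writers matching the formats the readers accept: GAF 2.2, InterProScan
#' TSV, InterPro2GO flat mapping, BLAST tabular (outfmt 6), STRING links.
#' Dummy values fill the columns the readers ignore.
#'
#' @param annotations Tibble `protein`, `go`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  lines <- c("!gaf-version: 2.2",
             sprintf("DB\t%s\t%s\t\t%s\t PMID:0000001\tIEA\t\tP\t\t\tprotein\ttaxon:0000\t20260101\tDB\t\t",
                     annotations$protein, annotations$protein, annotations$go))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gaf
#' @param assignments Tibble `protein`, `domain`.
#' @export
write_interproscan_tsv <- function(assignments, path) {
  lines <- sprintf(
    "%s\tmd5\t100\tPfam\tPF00000\tdesc\t1\t99\t1e-10\tT\t20260101\t%s\tsynthetic entry\t-\t-",
    assignments$protein, assignments$domain)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gaf
#' @param mapping Tibble `domain`, `go`.
#' @export
write_interpro2go <- function(mapping, path) {
  lines <- c("!version date: synthetic",
             sprintf("InterPro:%s synthetic entry > GO:synthetic term ; %s",
                     mapping$domain, mapping$go))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gaf
#' @param blast Tibble `query`, `subject`, `bits`.
#' @export
write_blast_tab <- function(blast, path) {
  lines <- sprintf("%s\t%s\t90.0\t100\t5\t0\t1\t100\t1\t100\t1e-30\t%g",
                   blast$query, blast$subject, blast$bits)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gaf
#' @param links Tibble `protein1`, `protein2`, `weight` (0-1 scale; written
#'   on STRING's 0-1000 scale).
#' @export
write_string_links <- function(links, path) {
  lines <- c("protein1 protein2 combined_score",
             sprintf("%s %s %d", links$protein1, links$protein2,
                     as.integer(round(links$weight * 1000))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gaf
#' @export
write_annotation_tsv <- function(annotations, path) {
  writeLines(sprintf("%s\t%s", annotations$protein, annotations$go), path)
  invisible(path)
}

#' @rdname write_gaf
#' @export
write_domain_tsv <- function(assignments, path) {
  writeLines(sprintf("%s\t%s", assignments$protein, assignments$domain), path)
  invisible(path)
}
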
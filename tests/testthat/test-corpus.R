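test_that("build_corpus drops domain-less proteins and propagates terms", {
  dag <- chain_dag()
  dom <- tibble::tibble(protein = c("P1", "P2"), domain = c("IPR1", "IPR2"))
  ann <- tibble::tibble(protein = c("P1", "P2", "P3"),
                        go = c("GO:0000003", "GO:0000002", "GO:0000003"))
  expect_message(corpus <- build_corpus(dom, ann, dag), "discarded 1")
  expect_equal(length(corpus$proteins), 2L)
  expect_false("P3" %in% corpus$proteins)
  # annotation {b} with root <- a <- b closes to {b, a, root}
  expect_setequal(corpus$terms_of$MF[["P1"]],
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  # unknown GO ids are skipped with a warning, not an error
  ann_bad <- tibble::tibble(protein = "P1", go = c("GO:0000003", "GO:7777777"))
  expect_warning(build_corpus(dom, ann_bad, dag), "skipped 1")
  expect_error(build_corpus(dom[0, ], ann, dag), "no proteins")
})

test_that("corpus counts match a brute-force tally on random tables", {
  for (seed in c(2, 9)) {
    sim <- random_corpus(seed, n_proteins = 30)
    corpus <- sim$corpus
    # re-tally from the raw generator tables
    expect_equal(sort(corpus$proteins),
                 sort(unique(sim$domain_assignments$protein)))
    expect_equal(corpus$domain_vocab,
                 sort(unique(sim$domain_assignments$domain)))
    for (p in corpus$proteins) {
      expect_setequal(corpus$domains_of[[p]],
                      unique(sim$domain_assignments$domain[
                        sim$domain_assignments$protein == p]))
      raw <- sim$go_annotations$go[sim$go_annotations$protein == p]
      for (ns in c("MF", "BP", "CC")) {
        raw_ns <- raw[sim$dag$namespace[raw] == ns]
        want <- if (length(raw_ns)) {
          oracle_reachability(unique(raw_ns), sim$dag)
        } else {
          character()
        }
        expect_setequal(corpus$terms_of[[ns]][[p]], want)
      }
    }
  }
})

test_that("conditional probabilities: two-protein worked example", {
  dag <- flat_dag(n_leaves = 2)
  mf <- dag$terms[dag$namespace == "MF"]
  root <- intersect(unlist(dag$roots), mf)
  g <- setdiff(mf, root)[1]
  h <- setdiff(mf, root)[2]
  dom <- tibble::tibble(protein = c("P1", "P2"), domain = "IPRA")
  ann <- tibble::tibble(protein = c("P1", "P2", "P2"), go = c(g, g, h))
  corpus <- build_corpus(dom, ann, dag)
  tab <- conditional_probabilities(corpus, "MF")
  expect_equal(tab$p_cond[tab$domain == "IPRA" & tab$go == g], 1.0)
  expect_equal(tab$p_cond[tab$domain == "IPRA" & tab$go == h], 0.5)
  expect_equal(attr(tab, "n_proteins"), 2L)
})

test_that("co-occurrence table equals exhaustive enumeration and keeps invariants", {
  for (seed in c(5, 21)) {
    sim <- random_corpus(seed, n_proteins = 50)
    for (ns in c("MF", "BP")) {
      tab <- conditional_probabilities(sim$corpus, ns)
      oracle <- oracle_cooccurrence(sim$corpus, ns)
      expect_equal(tab$domain, oracle$domain)
      expect_equal(tab$go, oracle$go)
      expect_equal(tab$p_domain, oracle$p_domain)
      expect_equal(tab$p_joint, oracle$p_joint)
      expect_equal(tab$p_cond, oracle$p_cond)
      # invariants: p_cond = p_joint / p_domain, bounds
      expect_true(all(abs(tab$p_cond - tab$p_joint / tab$p_domain) < 1e-12))
      expect_true(all(tab$p_cond > 0 & tab$p_cond <= 1))
      expect_true(all(tab$p_joint <= tab$p_domain + 1e-15))
    }
  }
})

test_that("a domain-GO pair with zero joint probability is not stored", {
  dag <- flat_dag(n_leaves = 2)
  mf <- setdiff(dag$terms[dag$namespace == "MF"], unlist(dag$roots))
  bp <- setdiff(dag$terms[dag$namespace == "BP"], unlist(dag$roots))
  dom <- tibble::tibble(protein = c("P1", "P2"), domain = "IPRA")
  # all proteins carry the domain; the BP term never co-occurs in MF table
  ann <- tibble::tibble(protein = "P1", go = bp[1])
  corpus <- build_corpus(dom, ann, dag)
  expect_warning(tab <- conditional_probabilities(corpus, "MF"),
                 "no MF annotations")
  expect_equal(nrow(tab), 0L)
})

test_that("adversarial filter removes exactly the mapped pairs", {
  sim <- random_corpus(seed = 7, n_proteins = 40)
  tab <- conditional_probabilities(sim$corpus, "MF")
  expect_gt(nrow(tab), 5)
  # remove two specific pairs
  mapping <- tab[c(1, 3), c("domain", "go")]
  filtered <- adversarial_filter(tab, mapping)
  expect_equal(nrow(filtered), nrow(tab) - 2L)
  strip <- function(x, cols = c("domain", "go")) {
    out <- as.data.frame(x)[, cols, drop = FALSE]
    rownames(out) <- NULL
    out
  }
  expect_equal(
    strip(dplyr::anti_join(tibble::as_tibble(tab), mapping,
                           by = c("domain", "go"))),
    strip(filtered))
  # removed pairs are remembered as unknown, not zero
  expect_equal(strip(attr(filtered, "excluded_pairs")), strip(mapping))
  # p_domain untouched
  expect_equal(attr(filtered, "p_domain_all"), attr(tab, "p_domain_all"))
  # empty mapping is the identity on the stored pairs
  same <- adversarial_filter(tab, tab[0, c("domain", "go")])
  expect_equal(strip(same, names(tab)), strip(tab, names(tab)))
  # out-of-vocabulary pairs are ignored with a note
  expect_message(
    adversarial_filter(tab, tibble::tibble(domain = "IPR999999",
                                           go = "GO:0000001")),
    "ignored 1")
})

test_that("training pairs: targets, splits and negative ranges", {
  sim <- random_corpus(seed = 8, n_proteins = 60)
  tab <- conditional_probabilities(sim$corpus, "MF")
  pairs <- make_training_pairs(tab, n_neg_range = c(2, 5), split_frac = 0.8,
                               seed = 99)
  pos <- pairs[pairs$positive, ]
  neg <- pairs[!pairs$positive, ]
  # positives carry the table's conditional probabilities
  key <- paste(tab$domain, tab$go)
  expect_setequal(paste(pos$domain, pos$go), key)
  expect_equal(pos$target[match(key, paste(pos$domain, pos$go))], tab$p_cond)
  # negatives are exact zeros, never among the stored pairs
  expect_true(all(neg$target == 0))
  expect_false(any(paste(neg$domain, neg$go) %in% key))
  # per-domain negative counts lie in [lo, min(hi, available)]
  vocab_n <- length(attr(tab, "term_vocab"))
  for (d in unique(neg$domain)) {
    avail <- vocab_n - sum(tab$domain == d)
    expect_gte(sum(neg$domain == d), min(2, avail))
    expect_lte(sum(neg$domain == d), min(5, avail))
  }
  # split fraction approximately honoured on positives
  expect_equal(sum(pos$split == "train"), round(0.8 * nrow(pos)))
  expect_error(make_training_pairs(tab, n_neg_range = c(5, 2)), "lo <= hi")
})

test_that("training pairs are byte-identical across runs with one seed", {
  sim <- random_corpus(seed = 8, n_proteins = 40)
  tab <- conditional_probabilities(sim$corpus, "MF")
  a <- make_training_pairs(tab, n_neg_range = c(1, 3), seed = 5)
  b <- make_training_pairs(tab, n_neg_range = c(1, 3), seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a domain co-occurring with every term draws no negatives", {
  dag <- flat_dag(n_leaves = 2)
  mf <- dag$terms[dag$namespace == "MF"]
  g <- setdiff(mf, unlist(dag$roots))
  dom <- tibble::tibble(protein = "P1", domain = "IPRA")
  ann <- tibble::tibble(protein = "P1", go = g)
  corpus <- build_corpus(dom, ann, dag)
  tab <- conditional_probabilities(corpus, "MF")
  pairs <- make_training_pairs(tab, n_neg_range = c(10, 20), seed = 1)
  expect_equal(sum(!pairs$positive), 0L)
})
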
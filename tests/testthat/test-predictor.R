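make_ref <- function(emb, terms_of, k = nrow(emb), namespace = "MF") {
  structure(list(namespaces = namespace,
                 k = stats::setNames(list(as.integer(k)), namespace),
                 emb = stats::setNames(list(emb), namespace),
                 terms_of = stats::setNames(list(terms_of), namespace)),
            class = "reference_set")
}

test_that("protein embeddings average the domain rows", {
  m <- init_model(sprintf("D%d", 1:6), "G1", "MF", d = 5, h = 2, seed = 1)
  expect_equal(protein_embedding("D2", m), colMeans(m$phi[2, , drop = FALSE]))
  # two domains: elementwise midpoint
  expect_equal(protein_embedding(c("D1", "D4"), m),
               (m$phi[1, ] + m$phi[4, ]) / 2)
  # several domains vs an explicit per-column mean
  ds <- c("D1", "D2", "D3", "D5", "D6")
  want <- apply(m$phi[ds, ], 2, mean)
  expect_equal(protein_embedding(ds, m), want)
  # unknown domains are dropped; all-unknown raises the dedicated error
  expect_equal(protein_embedding(c("D1", "DX"), m), m$phi[1, ])
  expect_error(protein_embedding("DX", m),
               class = "godomains_no_embeddable_domains")
})

test_that("KNN scoring: weights cancel at K = 1 and split evenly at ties", {
  emb <- rbind(a = c(0, 0), b = c(3, 4))
  terms_of <- list(a = c("G1"), b = c("G1", "G2"))
  ref <- make_ref(emb, terms_of)
  s1 <- knn_score(c(0.1, 0), ref, "MF", k = 1)
  expect_equal(s1$score[s1$go == "G1"], 1)
  # two equidistant neighbours, one annotated with G2
  emb2 <- rbind(a = c(1, 0), b = c(-1, 0))
  ref2 <- make_ref(emb2, terms_of)
  s2 <- knn_score(c(0, 0), ref2, "MF", k = 2)
  expect_equal(s2$score[s2$go == "G2"], 0.5)
  expect_equal(s2$score[s2$go == "G1"], 1)
  expect_error(knn_score(c(0, 0), ref2, "MF", k = 0), "positive")
})

test_that("KNN scoring matches the weighted-vote formula in both modes", {
  emb <- rbind(a = c(1, 0), b = c(2, 0), c = c(4, 0))
  terms_of <- list(a = c("G1", "G2"), b = "G1", c = "G3")
  ref <- make_ref(emb, terms_of)
  q <- c(0, 0)
  d2 <- c(1, 4, 16)
  eps <- 1e-8
  for (mode in c("as_printed", "inverse")) {
    w <- if (mode == "as_printed") d2 + eps else 1 / (d2 + eps)
    want <- c(G1 = (w[1] + w[2]) / sum(w), G2 = w[1] / sum(w),
              G3 = w[3] / sum(w))
    got <- knn_score(q, ref, "MF", k = 3, weighting = mode)
    expect_equal(stats::setNames(got$score, got$go)[names(want)], want)
    expect_true(all(got$score >= 0 & got$score <= 1))
  }
})

test_that("an exact duplicate of a reference protein ranks first for any K", {
  withr::with_seed(23, {
    emb <- matrix(stats::rnorm(40), 10, 4,
                  dimnames = list(sprintf("P%02d", 1:10), NULL))
    terms_of <- stats::setNames(
      lapply(1:10, function(i) sprintf("G%d", i)), rownames(emb))
    ref <- make_ref(emb, terms_of)
    for (k in c(1, 3, 10)) {
      s <- knn_score(emb[7, ], ref, "MF", k = k, weighting = "inverse")
      expect_equal(s$go[1], "G7")
    }
  })
})

test_that("BLAST votes weight hits by bit-score", {
  terms_of <- list(r1 = c("G1"), r2 = c("G1", "G2"))
  blast <- tibble::tibble(query = c("q", "q"), subject = c("r1", "r2"),
                          bits = c(100, 300))
  s <- blast_score("q", blast, terms_of)
  expect_equal(s$score[s$go == "G1"], 1)
  expect_equal(s$score[s$go == "G2"], 0.75)  # 300 / 400
  # single hit: every annotated term gets the full vote
  s1 <- blast_score("q", blast[1, ], terms_of)
  expect_equal(s1$score, 1)
  # no hits: empty map
  expect_equal(nrow(blast_score("other", blast, terms_of)), 0L)
})

test_that("BLAST and PPI votes equal a random weighted-vote oracle", {
  withr::with_seed(31, {
    refs <- sprintf("r%d", 1:8)
    terms_of <- stats::setNames(lapply(1:8, function(i)
      sample(sprintf("G%d", 1:6), sample(1:3, 1))), refs)
    blast <- tibble::tibble(query = "q",
                            subject = sample(refs, 5),
                            bits = round(stats::runif(5, 50, 400)))
    s <- blast_score("q", blast, terms_of)
    for (g in s$go) {
      num <- sum(blast$bits[vapply(blast$subject, function(r)
        g %in% terms_of[[r]], logical(1))])
      expect_equal(s$score[s$go == g], num / sum(blast$bits))
    }
    links <- tibble::tibble(protein1 = c("q", "q", "x"),
                            protein2 = c("r1", "r2", "q"),
                            weight = c(0.9, 0.4, 0.7))
    sn <- ppi_score("q", links, terms_of)
    partners <- c(r1 = 0.9, r2 = 0.4, x = 0.7)
    partners <- partners[names(partners) %in% names(terms_of)]
    for (g in sn$go) {
      num <- sum(partners[vapply(names(partners), function(r)
        g %in% terms_of[[r]], logical(1))])
      expect_equal(sn$score[sn$go == g], num / sum(partners))
    }
  })
})

test_that("PPI with a single weighted neighbour and with no edges", {
  terms_of <- list(r1 = "G1")
  links <- tibble::tibble(protein1 = "q", protein2 = "r1", weight = 0.9)
  s <- ppi_score("q", links, terms_of)
  expect_equal(s$score[s$go == "G1"], 1)
  expect_equal(nrow(ppi_score("lonely", links, terms_of)), 0L)
})

test_that("score fusion averages present sources only", {
  s_d <- tibble::tibble(go = "G1", score = 0.6)
  # embedding only
  expect_equal(combine_scores(s_d)$score, 0.6)
  # embedding + BLAST
  s_b <- tibble::tibble(go = "G1", score = 0.3)
  expect_equal(combine_scores(s_d, s_b)$score, 0.45)
  # all three sources
  s_n <- tibble::tibble(go = "G1", score = 0.9)
  expect_equal(combine_scores(s_d, s_b, s_n)$score, 0.6)
  # a term absent from one present source contributes 0 there
  s_b2 <- tibble::tibble(go = "G2", score = 0.8)
  got <- combine_scores(s_d, s_b2)
  expect_equal(got$score[got$go == "G1"], 0.3)
  expect_equal(got$score[got$go == "G2"], 0.4)
  # without embedding scores, remaining sources are averaged symmetrically
  expect_equal(combine_scores(NULL, s_b)$score, 0.3)
  # convexity: never above the max of the inputs
  expect_lte(max(combine_scores(s_d, s_b, s_n)$score), 0.9)
})

test_that("concatenated embeddings are block-rescaled by reference norms", {
  vs <- list(MF = c(3, 4), BP = c(0, 0), CC = c(1, 0))
  stats <- c(MF = 5, BP = 2, CC = 1)
  got <- concat_embedding(vs, stats)
  expect_equal(got, c(0.6, 0.8, 0, 0, 1, 0))
  # equal-norm blocks with unit stats are untouched
  vs2 <- list(MF = c(1, 0), BP = c(0, 1), CC = c(1, 0))
  expect_equal(concat_embedding(vs2, c(MF = 1, BP = 1, CC = 1)),
               c(1, 0, 0, 1, 1, 0))
  expect_error(concat_embedding(vs[c("MF", "BP")], stats), "missing namespace")
})

test_that("reference block statistics equalise mean block norms", {
  withr::with_seed(41, {
    ns_emb <- lapply(c(MF = 1, BP = 10, CC = 100), function(sc)
      matrix(stats::rnorm(60, sd = sc), 10, 6,
             dimnames = list(sprintf("P%02d", 1:10), NULL)))
    ref <- structure(list(namespaces = c("MF", "BP", "CC"),
                          k = list(MF = 5L, BP = 5L, CC = 5L),
                          emb = ns_emb,
                          terms_of = list(MF = list(), BP = list(), CC = list())),
                     class = "reference_set")
    st <- reference_block_stats(ref)
    scaled_norms <- vapply(c("MF", "BP", "CC"), function(ns)
      mean(sqrt(rowSums((ns_emb[[ns]] / st[[ns]])^2))), numeric(1))
    expect_equal(unname(scaled_norms), rep(1, 3), tolerance = 1e-12)
  })
})

test_that("hierarchical consistency raises ancestors to descendant scores", {
  dag <- chain_dag()
  emb <- rbind(r1 = c(0, 0))
  terms_of <- list(r1 = c("GO:0000001", "GO:0000002", "GO:0000003"))
  ref <- make_ref(emb, terms_of, k = 1)
  m <- init_model("IPRA", "GO:0000003", "MF", d = 2, h = 2, seed = 1)
  preds <- tibble::tibble(
    protein = "q", go = c("GO:0000001", "GO:0000002", "GO:0000003"),
    score = c(0.2, 0.1, 0.9))
  fixed <- godomains:::enforce_hierarchy_(preds[, c("go", "score")], dag)
  s <- stats::setNames(fixed$score, fixed$go)
  expect_gte(s[["GO:0000002"]], s[["GO:0000003"]])
  expect_gte(s[["GO:0000001"]], s[["GO:0000002"]])
  expect_equal(unname(s[["GO:0000003"]]), 0.9)
})
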
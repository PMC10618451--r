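test_that("precision/recall: perfect predictor and empty threshold set", {
  truth <- tibble::tibble(protein = c("P1", "P1", "P2"),
                          go = c("G1", "G2", "G1"))
  pred <- dplyr::mutate(truth, score = 1)
  pp <- precision_recall(pred, truth, tau = 1)
  expect_equal(pp$pr, 1)
  expect_equal(pp$rc, 1)
  expect_equal(pp$h, 2L)
  # threshold above every score: h = 0, precision reported as 0
  low <- dplyr::mutate(truth, score = 0.4)
  pp2 <- precision_recall(low, truth, tau = 0.9)
  expect_equal(pp2$h, 0L)
  expect_equal(pp2$pr, 0)
  expect_error(precision_recall(pred, truth[0, ], 0.5), "no proteins")
})

test_that("precision/recall matches a per-protein double loop", {
  inst <- random_eval_instance(101)
  for (tau in c(0.2, 0.5, 0.8)) {
    got <- precision_recall(inst$pred, inst$truth, tau)
    want <- oracle_pr_rc(inst$pred, inst$truth, tau, length(inst$proteins))
    expect_equal(got$pr, want$pr)
    expect_equal(got$rc, want$rc)
    expect_equal(got$h, want$h)
  }
})

test_that("Fmax: perfect and all-zero predictors, grid-oracle equality", {
  truth <- tibble::tibble(protein = rep(c("P1", "P2"), each = 2),
                          go = c("G1", "G2", "G1", "G3"))
  perfect <- dplyr::mutate(truth, score = 1)
  expect_equal(fmax(perfect, truth)$fmax, 1)
  zero <- dplyr::mutate(truth, score = 0)
  # all-zero scores never separate anything: recall stays 0 above tau = 0
  got0 <- fmax(zero, truth, tau_grid = seq(0.01, 1, by = 0.01))
  expect_equal(got0$fmax, 0)
  grid <- seq(0, 1, by = 0.01)
  for (seed in c(7, 19, 33)) {
    inst <- random_eval_instance(seed)
    expect_equal(fmax(inst$pred, inst$truth, grid)$fmax,
                 oracle_fmax(inst$pred, inst$truth, grid),
                 tolerance = 1e-12)
  }
})

test_that("Fmax argmax resolves ties to the smallest threshold", {
  truth <- tibble::tibble(protein = "P1", go = "G1")
  pred <- tibble::tibble(protein = "P1", go = "G1", score = 0.5)
  got <- fmax(pred, truth, tau_grid = c(0.1, 0.3, 0.5))
  expect_equal(got$fmax, 1)
  expect_equal(got$tau, 0.1)
})

test_that("AUPR: separable scores give 1, oracle equality on random instances", {
  truth <- tibble::tibble(protein = "P1", go = c("G1", "G2"))
  pred <- tibble::tibble(protein = "P1", go = c("G1", "G2", "G3", "G4"),
                         score = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(aupr(pred, truth), 1)
  for (seed in c(3, 12, 29)) {
    inst <- random_eval_instance(seed)
    expect_equal(aupr(inst$pred, inst$truth),
                 oracle_aupr(inst$pred, inst$truth),
                 tolerance = 1e-12)
  }
  expect_error(aupr(pred, truth[0, ]), "no positive")
})

test_that("AUPR approaches prevalence when scores anti-separate", {
  n_neg <- 60
  truth <- tibble::tibble(protein = "P1", go = "Gpos")
  pred <- tibble::tibble(protein = "P1",
                         go = c("Gpos", sprintf("N%d", 1:n_neg)),
                         score = c(0.01, stats::runif(n_neg, 0.5, 1)))
  val <- aupr(pred, truth)
  prevalence <- 1 / (n_neg + 1)
  expect_lt(val, 3 * prevalence)
})

test_that("information content counts proteins against their parents", {
  dag <- chain_dag()
  dom <- tibble::tibble(protein = sprintf("P%d", 1:4), domain = "IPRA")
  # two proteins reach the leaf; all four reach the middle term
  ann <- tibble::tibble(protein = c("P1", "P2", "P3", "P4"),
                        go = c("GO:0000003", "GO:0000003",
                               "GO:0000002", "GO:0000002"))
  corpus <- build_corpus(dom, ann, dag)
  ic <- information_content(corpus, dag)
  expect_equal(unname(ic["GO:0000001"]), 0)           # root
  expect_equal(unname(ic["GO:0000002"]), -log(4 / 4)) # every parent protein
  expect_equal(unname(ic["GO:0000003"]), -log(2 / 4)) # half of them
})

test_that("information content equals the counting oracle on random corpora", {
  for (seed in c(6, 18)) {
    sim <- random_corpus(seed, n_proteins = 40)
    ic <- information_content(sim$corpus, sim$dag)
    expect_equal(as.numeric(ic), as.numeric(oracle_ic(sim$corpus, sim$dag)))
  }
})

test_that("Smin: exact predictions give zero, empty predictions give total IC", {
  sim <- random_corpus(seed = 25, n_proteins = 30)
  ic <- information_content(sim$corpus, sim$dag)
  ts <- sim$corpus$terms_of$MF
  truth <- tibble::tibble(protein = rep(names(ts), lengths(ts)),
                          go = unlist(ts, use.names = FALSE))
  perfect <- dplyr::mutate(truth, score = 1)
  expect_equal(smin(perfect, truth, ic)$smin, 0)
  # empty predictions: ru is the total truth IC at every threshold, mi = 0
  empty <- tibble::tibble(protein = character(), go = character(),
                          score = numeric())
  n <- dplyr::n_distinct(truth$protein)
  expect_equal(smin(empty, truth, ic)$smin, sum(ic[truth$go]) / n)
})

test_that("Smin equals the brute-force grid oracle", {
  grid <- seq(0, 1, by = 0.01)
  for (seed in c(9, 27)) {
    inst <- random_eval_instance(seed)
    ic <- stats::setNames(withr::with_seed(seed, stats::runif(20, 0.1, 3)),
                          inst$terms)
    expect_equal(smin(inst$pred, inst$truth, ic, grid)$smin,
                 oracle_smin(inst$pred, inst$truth, ic, grid),
                 tolerance = 1e-12)
  }
})

test_that("degrading a perfect prediction never improves Fmax or Smin", {
  sim <- random_corpus(seed = 35, n_proteins = 25)
  ic <- information_content(sim$corpus, sim$dag)
  ts <- sim$corpus$terms_of$MF
  truth <- tibble::tibble(protein = rep(names(ts), lengths(ts)),
                          go = unlist(ts, use.names = FALSE))
  vocab <- unique(truth$go)
  perfect <- dplyr::mutate(truth, score = 1)
  f0 <- fmax(perfect, truth)$fmax
  s0 <- smin(perfect, truth, ic)$smin
  withr::with_seed(99, {
    for (rep in 1:100) {
      damaged <- perfect
      # flip: drop a true pair and add a spurious one at full confidence
      drop_i <- sample(nrow(damaged), 1)
      p <- damaged$protein[drop_i]
      damaged <- damaged[-drop_i, ]
      wrong <- setdiff(vocab, truth$go[truth$protein == p])
      if (length(wrong)) {
        damaged <- dplyr::bind_rows(damaged,
          tibble::tibble(protein = p, go = sample(wrong, 1), score = 1))
      }
      expect_lte(fmax(damaged, truth)$fmax, f0 + 1e-12)
      expect_gte(smin(damaged, truth, ic)$smin, s0 - 1e-12)
    }
  })
})

test_that("weighted F1 averages by support", {
  expect_equal(weighted_f1(0.8, 5), 0.8)
  expect_equal(weighted_f1(c(1, 0), c(3, 1)), 0.75)
  withr::with_seed(8, {
    f1 <- stats::runif(10)
    w <- sample(0:20, 10, replace = TRUE)
    w[1] <- max(w[1], 1)
    expect_equal(weighted_f1(f1, w), sum(f1 * w) / sum(w))
  })
  expect_error(weighted_f1(c(1, 0), c(0, 0)), "zero")
  expect_error(weighted_f1(1, -1), "non-negative")
})

test_that("domain Jaccard similarity over thresholded term sets", {
  sim <- random_corpus(seed = 44, n_proteins = 50)
  tab <- conditional_probabilities(sim$corpus, "MF")
  d <- unique(tab$domain)
  expect_equal(domain_jaccard(tab, d[1], d[1]), 1)
  # symmetric; threshold 1 never yields a larger assigned set than 0.5
  expect_equal(domain_jaccard(tab, d[1], d[2]),
               domain_jaccard(tab, d[2], d[1]))
  for (dd in d[1:3]) {
    set_at <- function(th) sum(tab$domain == dd & tab$p_cond >= th)
    expect_lte(set_at(1), set_at(0.5))
  }
  expect_error(domain_jaccard(tab, d[1], "IPR999999"), "unknown")
})

test_that("domain Jaccard worked examples: identical, empty, sharing 1 of 3", {
  dag <- flat_dag(n_leaves = 4)
  mf <- setdiff(dag$terms[dag$namespace == "MF"], unlist(dag$roots))
  dom <- tibble::tibble(protein = c("P1", "P2", "P3"),
                        domain = c("A", "B", "C"))
  # A's set {root, mf1}; B's set {root, mf2}; C has no MF annotation at all
  ann <- tibble::tibble(protein = c("P1", "P2"), go = c(mf[1], mf[2]))
  corpus <- build_corpus(dom, ann, dag)
  tab <- conditional_probabilities(corpus, "MF")
  expect_equal(domain_jaccard(tab, "A", "A"), 1)
  # sets {root, mf1} vs {root, mf2}: 1 shared of 3 distinct
  expect_equal(domain_jaccard(tab, "A", "B"), 1 / 3)
  # one empty assigned set: similarity 0; two empty sets defined as 0
  expect_equal(domain_jaccard(tab, "A", "C"), 0)
  expect_equal(domain_jaccard(tab, "C", "C"), 0)
})

test_that("Manhattan distance sums absolute coordinate differences", {
  expect_equal(manhattan(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(manhattan(c(0, 0), c(1, 2)), 3)
  withr::with_seed(3, {
    a <- stats::rnorm(20)
    b <- stats::rnorm(20)
    want <- 0
    for (i in 1:20) want <- want + abs(a[i] - b[i])
    expect_equal(manhattan(a, b), want)
  })
  expect_error(manhattan(1:3, 1:4), "equal length")
})

test_that("evaluate_predictions bundles the three metrics coherently", {
  sim <- random_corpus(seed = 55, n_proteins = 30)
  ic <- information_content(sim$corpus, sim$dag)
  ts <- sim$corpus$terms_of$MF
  truth <- tibble::tibble(protein = rep(names(ts), lengths(ts)),
                          go = unlist(ts, use.names = FALSE))
  perfect <- dplyr::mutate(truth, score = 1)
  res <- evaluate_predictions(perfect, truth, ic = ic, namespace = "MF")
  expect_s3_class(res, "go_eval")
  expect_equal(res$fmax, 1)
  expect_equal(res$smin, 0)
  expect_equal(res$aupr, 1)
  g <- glance(res)
  expect_equal(g$fmax, 1)
  expect_equal(g$namespace, "MF")
  expect_s3_class(autoplot(res), "ggplot")
})
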
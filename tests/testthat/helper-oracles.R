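# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (nested loops, explicit reachability),
# sharing no code with the implementation under test.

# Transitive ancestor closure by repeated single-step parent expansion.
oracle_reachability <- function(terms, dag) {
  out <- unique(terms)
  repeat {
    step <- unique(c(out, unlist(dag$parents[out], use.names = FALSE)))
    if (length(step) == length(out)) break
    out <- step
  }
  sort(out)
}

# Per-term probabilities by scanning every protein's term sets.
oracle_term_prob <- function(corpus, dag) {
  n <- length(corpus$proteins)
  sapply(dag$terms, function(t) {
    cnt <- 0L
    for (i in seq_along(corpus$proteins)) {
      for (ns in c("MF", "BP", "CC")) {
        if (t %in% corpus$terms_of[[ns]][[i]]) {
          cnt <- cnt + 1L
          break
        }
      }
    }
    cnt / n
  })
}

# Eq-by-eq simRel scan over every common ancestor.
oracle_sim_rel <- function(go1, go2, dag) {
  anc <- function(g) oracle_reachability(g, dag)
  common <- intersect(anc(go1), anc(go2))
  p <- dag$term_prob
  vals <- sapply(common, function(a) {
    if (p[[a]] >= 1) return(0)
    den <- log(p[[go1]]) + log(p[[go2]])
    if (den == 0) return(0)
    (2 * log(p[[a]]) / den) * (1 - p[[a]])
  })
  if (!length(vals)) 0 else max(vals)
}

oracle_go_score <- function(set_a, set_b, dag) {
  s <- matrix(0, length(set_a), length(set_b))
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      s[i, j] <- oracle_sim_rel(set_a[[i]], set_b[[j]], dag)
    }
  }
  row_best <- numeric(length(set_a))
  for (i in seq_along(set_a)) row_best[i] <- max(s[i, ])
  col_best <- numeric(length(set_b))
  for (j in seq_along(set_b)) col_best[j] <- max(s[, j])
  max(mean(row_best), mean(col_best))
}

# Co-occurrence probabilities by explicit double loop over domains x terms.
oracle_cooccurrence <- function(corpus, namespace) {
  n <- length(corpus$proteins)
  rows <- list()
  for (d in corpus$domain_vocab) {
    has_d <- vapply(seq_len(n), function(i)
      d %in% corpus$domains_of[[i]], logical(1))
    for (g in corpus$term_vocab[[namespace]]) {
      has_g <- vapply(seq_len(n), function(i)
        g %in% corpus$terms_of[[namespace]][[i]], logical(1))
      n_joint <- sum(has_d & has_g)
      if (n_joint > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          domain = d, go = g,
          p_domain = sum(has_d) / n,
          p_joint = n_joint / n,
          p_cond = (n_joint / n) / (sum(has_d) / n)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$domain, out$go), ]
}

# Information content by explicit counting.
oracle_ic <- function(corpus, dag) {
  n <- length(corpus$proteins)
  has_term <- function(t, i) {
    any(vapply(c("MF", "BP", "CC"), function(ns)
      t %in% corpus$terms_of[[ns]][[i]], logical(1)))
  }
  sapply(dag$terms, function(t) {
    pp <- dag$parents[[t]]
    if (!length(pp)) return(0)
    n_c <- sum(vapply(seq_len(n), function(i) has_term(t, i), logical(1)))
    n_pa <- sum(vapply(seq_len(n), function(i)
      all(vapply(pp, has_term, logical(1), i = i)), logical(1)))
    if (n_c == 0L) -log(1 / (n_pa + 1)) else -log(n_c / n_pa)
  })
}

# Protein-centric precision/recall at one threshold, fully nested loops.
oracle_pr_rc <- function(pred, truth, tau, n_proteins) {
  proteins <- unique(truth$protein)
  pr_terms <- c()
  rc_sum <- 0
  h <- 0L
  for (p in proteins) {
    pred_p <- pred[pred$protein == p & pred$score >= tau, ]
    true_p <- truth[truth$protein == p, ]
    if (nrow(pred_p) > 0L) {
      h <- h + 1L
      tp <- sum(pred_p$go %in% true_p$go)
      pr_terms <- c(pr_terms, tp / nrow(pred_p))
      rc_sum <- rc_sum + tp / nrow(true_p)
    }
  }
  list(pr = if (h > 0) mean(pr_terms) else 0, rc = rc_sum / n_proteins, h = h)
}

oracle_fmax <- function(pred, truth, tau_grid) {
  n_p <- length(unique(truth$protein))
  best <- 0
  for (tau in tau_grid) {
    pp <- oracle_pr_rc(pred, truth, tau, n_p)
    if (pp$h == 0) next
    if (pp$pr + pp$rc > 0) {
      f1 <- 2 * pp$pr * pp$rc / (pp$pr + pp$rc)
      if (f1 > best) best <- f1
    }
  }
  best
}

# Micro AUPR: explicit threshold walk over distinct scores.
oracle_aupr <- function(pred, truth) {
  truth_key <- paste(truth$protein, truth$go)
  pred_key <- paste(pred$protein, pred$go)
  scores <- pred$score
  labels <- pred_key %in% truth_key
  for (k in setdiff(truth_key, pred_key)) {
    scores <- c(scores, 0)
    labels <- c(labels, TRUE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- 0
  prec <- NULL
  recs <- c()
  precs <- c()
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels & sel)
    precs <- c(precs, tp / sum(sel))
    recs <- c(recs, tp / sum(labels))
  }
  x <- c(0, recs)
  y <- c(precs[1], precs)
  area <- 0
  for (i in seq_len(length(x) - 1)) {
    area <- area + (x[i + 1] - x[i]) * (y[i + 1] + y[i]) / 2
  }
  area
}

oracle_smin <- function(pred, truth, ic, tau_grid) {
  proteins <- unique(truth$protein)
  n <- length(proteins)
  best <- Inf
  for (tau in tau_grid) {
    ru <- 0
    mi <- 0
    for (p in proteins) {
      true_set <- truth$go[truth$protein == p]
      pred_set <- pred$go[pred$protein == p & pred$score >= tau]
      ru <- ru + sum(ic[setdiff(true_set, pred_set)])
      mi <- mi + sum(ic[setdiff(pred_set, true_set)])
    }
    s <- sqrt((ru / n)^2 + (mi / n)^2)
    if (s < best) best <- s
  }
  best
}
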
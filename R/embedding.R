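#' Training configuration for the dual-embedding network
#'
#' Defaults follow the published training protocol: learning rate 0.001,
#' batch size 163,840 (auto-capped at the number of training pairs), 200
#' epochs, dropout p = 0.05 on the hidden layer, L1 penalty weight 0.1 on
#' the domain-embedding matrix, and 10 repeated runs with the best model
#' chosen on validation loss. For small synthetic corpora a smaller batch
#' and a larger learning rate give the optimizer enough steps within the
#' same epoch budget; see the package vignette.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (capped at the training-set size).
#' @param epochs Number of passes over the training pairs.
#' @param dropout_p Dropout probability on the 128-unit hidden layer.
#' @param l1_lambda Weight of the L1 penalty, applied to the mean absolute
#'   value of the domain-embedding matrix.
#' @param n_repeats Number of restarts for [train_with_selection()].
#' @param seed Integer seed governing initialisation, dropout and shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 163840L,
                         epochs = 200L, dropout_p = 0.05, l1_lambda = 0.1,
                         n_repeats = 10L, seed = 1L) {
  if (learning_rate <= 0 || batch_size <= 0 || epochs <= 0 ||
      l1_lambda < 0 || n_repeats < 1) {
    abort("train_config values must be positive (l1_lambda may be 0)")
  }
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout_p = dropout_p,
                 l1_lambda = l1_lambda, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialise a dual-embedding model
#'
#' Creates the domain-embedding matrix `phi` (n_domains x d), the GO-term
#' embedding matrix `psi` (n_terms x d), and a two-layer head that maps the
#' Hadamard product of a domain row and a term row through `h` ReLU units to
#' a single linear output approximating `p(GO | domain)`. Weights are drawn
#' from symmetric uniform distributions scaled by the reciprocal square root
#' of the fan-in; biases start at zero. Deterministic under `seed`.
#'
#' @param domain_vocab Character vector of domain identifiers (row order of
#'   `phi`).
#' @param term_vocab Character vector of GO identifiers (row order of `psi`).
#' @param namespace The sub-ontology this model serves; models refuse
#'   cross-namespace queries downstream.
#' @param d Embedding dimension (default 256).
#' @param h Hidden-layer width (default 128).
#' @param seed Integer seed.
#' @return An object of class `embedding_model`.
#' @export
init_model <- function(domain_vocab, term_vocab, namespace,
                       d = 256L, h = 128L, seed = 1L) {
  assert_namespace_(namespace)
  if (d <= 0 || h <= 0) abort("`d` and `h` must be positive")
  if (!length(domain_vocab) || !length(term_vocab)) {
    abort("vocabularies must be non-empty")
  }
  nd <- length(domain_vocab)
  ng <- length(term_vocab)
  with_seed_(seed, {
    sc <- 1 / sqrt(d)
    model <- list(
      phi = matrix(stats::runif(nd * d, -sc, sc), nd, d,
                   dimnames = list(domain_vocab, NULL)),
      psi = matrix(stats::runif(ng * d, -sc, sc), ng, d,
                   dimnames = list(term_vocab, NULL)),
      W1 = matrix(stats::runif(d * h, -sc, sc), d, h),
      b1 = numeric(h),
      W2 = matrix(stats::runif(h, -1 / sqrt(h), 1 / sqrt(h)), h, 1),
      b2 = 0,
      d = as.integer(d), h = as.integer(h),
      namespace = namespace,
      domain_vocab = domain_vocab,
      term_vocab = term_vocab,
      history = NULL
    )
    structure(model, class = "embedding_model")
  })
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> [", x$namespace, "] ",
      nrow(x$phi), " domains x ", nrow(x$psi), " GO terms, d = ", x$d,
      ", h = ", x$h,
      if (!is.null(x$history)) paste0("; trained ", nrow(x$history), " epochs"),
      "\n", sep = "")
  invisible(x)
}

#' Forward pass of the dual-embedding network
#'
#' Computes `W2' ReLU(W1' (phi_d * psi_g) + b1) + b2` for vectors of domain
#' and term row indices (`*` the elementwise/Hadamard product). The output
#' is an unclipped linear score; clip to `[0, 1]` at reporting time with
#' `pmin(pmax(., 0), 1)`. Dropout on the hidden layer is applied only when
#' `training = TRUE` (inverted dropout, scaled by `1/(1 - p)`).
#'
#' @param model An [embedding_model][init_model].
#' @param domain_idx,go_idx Integer vectors of equal length indexing rows of
#'   `phi` and `psi`.
#' @param training Apply dropout?
#' @param dropout_p Dropout probability used when `training = TRUE`.
#' @return Numeric vector of predictions (and, when `training = TRUE`, the
#'   intermediate activations as attributes used by the backward pass).
#' @export
model_forward <- function(model, domain_idx, go_idx, training = FALSE,
                          dropout_p = 0) {
  if (length(domain_idx) != length(go_idx)) {
    abort("`domain_idx` and `go_idx` must have equal length")
  }
  if (any(domain_idx < 1L) || any(domain_idx > nrow(model$phi)) ||
      any(go_idx < 1L) || any(go_idx > nrow(model$psi))) {
    abort("embedding index out of range")
  }
  X <- model$phi[domain_idx, , drop = FALSE] *
    model$psi[go_idx, , drop = FALSE]
  Z1 <- sweep(X %*% model$W1, 2, model$b1, "+")
  H <- pmax(Z1, 0)
  mask <- NULL
  if (training && dropout_p > 0) {
    mask <- matrix(stats::runif(length(H)) >= dropout_p, nrow(H), ncol(H)) /
      (1 - dropout_p)
    H <- H * mask
  }
  out <- unname(drop(H %*% model$W2 + model$b2))
  if (training) {
    attr(out, "cache") <- list(X = X, Z1 = Z1, H = H, mask = mask)
  }
  out
}

# One Adam update; st holds first/second moments and the step counter.
adam_step_ <- function(param, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train the dual-embedding network
#'
#' Minimises the mean squared error between the network output and the
#' conditional-probability targets, plus `l1_lambda` times the mean absolute
#' value of the domain-embedding matrix `phi`, with mini-batch Adam (the
#' remaining Adam parameters at their conventional defaults). Training pairs
#' are shuffled each epoch under the configured seed; per-epoch training and
#' validation MSE (penalty excluded) are recorded in `model$history`.
#'
#' @param model An [embedding_model][init_model] whose vocabularies and
#'   namespace match `pairs`.
#' @param pairs A [training_pairs][make_training_pairs] tibble containing
#'   both `train` and `val` splits.
#' @param cfg A [train_config()].
#' @return The trained `embedding_model`; `model$history` is a tibble with
#'   columns `epoch`, `train_mse`, `val_mse`.
#' @export
train_model <- function(model, pairs, cfg = train_config()) {
  stopifnot(inherits(model, "embedding_model"),
            inherits(pairs, "training_pairs"))
  if (!identical(attr(pairs, "namespace"), model$namespace)) {
    abort(paste0("namespace mismatch: model is ", model$namespace,
                 ", pairs are ", attr(pairs, "namespace")))
  }
  di_all <- match(pairs$domain, model$domain_vocab)
  gi_all <- match(pairs$go, model$term_vocab)
  if (anyNA(di_all) || anyNA(gi_all)) {
    abort("training pairs reference ids absent from the model vocabularies")
  }
  is_train <- pairs$split == "train"
  if (!any(is_train) || !any(!is_train)) {
    abort("both train and val splits must be non-empty")
  }
  di <- di_all[is_train]; gi <- gi_all[is_train]
  y <- pairs$target[is_train]
  di_v <- di_all[!is_train]; gi_v <- gi_all[!is_train]
  y_v <- pairs$target[!is_train]

  n <- length(y)
  bs <- min(cfg$batch_size, n)
  zero_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  st <- map(model[c("phi", "psi", "W1", "b1", "W2", "b2")],
            function(p) list(m = zero_like(p), v = zero_like(p), t = 0L))
  lam <- cfg$l1_lambda
  n_phi <- length(model$phi)

  hist <- matrix(NA_real_, cfg$epochs, 2)
  with_seed_(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        bd <- di[idx]; bg <- gi[idx]; by <- y[idx]
        pred <- model_forward(model, bd, bg, training = TRUE,
                              dropout_p = cfg$dropout_p)
        cache <- attr(pred, "cache")
        resid <- as.numeric(pred) - by
        if (anyNA(resid) || any(!is.finite(resid))) {
          abort(paste0("non-finite loss in epoch ", epoch,
                       " (batch starting at pair ", start, ")"))
        }
        m <- length(by)
        dy <- matrix(2 * resid / m, m, 1)
        dW2 <- crossprod(cache$H, dy)
        db2 <- sum(dy)
        dH <- dy %*% t(model$W2)
        if (!is.null(cache$mask)) dH <- dH * cache$mask
        dZ1 <- dH * (cache$Z1 > 0)
        dW1 <- crossprod(cache$X, dZ1)
        db1 <- colSums(dZ1)
        dX <- dZ1 %*% t(model$W1)
        dphi_rows <- dX * model$psi[bg, , drop = FALSE]
        dpsi_rows <- dX * model$phi[bd, , drop = FALSE]
        dphi <- matrix(0, nrow(model$phi), model$d)
        agg_d <- rowsum(dphi_rows, group = bd)
        dphi[as.integer(rownames(agg_d)), ] <- agg_d
        dphi <- dphi + lam * sign(model$phi) / n_phi
        dpsi <- matrix(0, nrow(model$psi), model$d)
        agg_g <- rowsum(dpsi_rows, group = bg)
        dpsi[as.integer(rownames(agg_g)), ] <- agg_g

        grads <- list(phi = dphi, psi = dpsi, W1 = dW1, b1 = db1,
                      W2 = dW2, b2 = db2)
        for (nm in names(grads)) {
          st[[nm]]$t <- st[[nm]]$t + 1L
          upd <- adam_step_(model[[nm]], grads[[nm]], st[[nm]],
                            cfg$learning_rate)
          model[[nm]] <- upd$param
          st[[nm]] <- upd$state
        }
        dimnames(model$phi) <- list(model$domain_vocab, NULL)
        dimnames(model$psi) <- list(model$term_vocab, NULL)
      }
      tr_pred <- model_forward(model, di, gi)
      va_pred <- model_forward(model, di_v, gi_v)
      hist[epoch, ] <- c(mean((tr_pred - y)^2), mean((va_pred - y_v)^2))
    }
  })
  model$history <- tibble(epoch = seq_len(cfg$epochs),
                          train_mse = hist[, 1], val_mse = hist[, 2])
  model
}

#' Train with repeated restarts and validation-based selection
#'
#' Runs [train_model()] `cfg$n_repeats` times with seeds `seed + 0 ..
#' seed + n - 1` (fresh initialisation each run) and returns the run with
#' the lowest final validation MSE. All validation scores are attached as
#' the `selection` attribute.
#'
#' @param pairs A [training_pairs][make_training_pairs] tibble.
#' @param cfg A [train_config()].
#' @param d,h Embedding and hidden dimensions for the fresh models.
#' @return The best `embedding_model`; `attr(., "selection")` is a tibble
#'   with one row per run.
#' @export
train_with_selection <- function(pairs, cfg = train_config(),
                                 d = 256L, h = 128L) {
  stopifnot(inherits(pairs, "training_pairs"))
  seeds <- derive_seeds_(cfg$seed, cfg$n_repeats)
  runs <- vector("list", cfg$n_repeats)
  scores <- rep(NA_real_, cfg$n_repeats)
  for (i in seq_len(cfg$n_repeats)) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[[i]]
    model <- init_model(attr(pairs, "domain_vocab"),
                        attr(pairs, "term_vocab"),
                        attr(pairs, "namespace"),
                        d = d, h = h, seed = seeds[[i]])
    runs[[i]] <- train_model(model, pairs, cfg_i)
    scores[[i]] <- utils::tail(runs[[i]]$history$val_mse, 1)
  }
  if (all(is.na(scores))) abort("all training runs failed")
  best <- which.min(scores)
  out <- runs[[best]]
  attr(out, "selection") <- tibble(run = seq_len(cfg$n_repeats),
                                   seed = seeds, val_mse = scores,
                                   selected = seq_len(cfg$n_repeats) == best)
  out
}

#' Look up the embedding of a domain
#'
#' Returns the learned row of the domain-embedding matrix; pure and
#' dropout-free.
#'
#' @param model An [embedding_model][init_model].
#' @param domain A single domain identifier.
#' @return Numeric vector of length `model$d`.
#' @export
domain_embedding <- function(model, domain) {
  i <- match(domain, model$domain_vocab)
  if (is.na(i)) abort(paste0("unknown domain: ", domain), class = "godomains_unknown_domain")
  model$phi[i, ]
}

#' Predict conditional probabilities for domain-GO pairs
#'
#' Convenience wrapper around [model_forward()] taking identifiers rather
#' than indices and clipping the linear output to `[0, 1]`.
#'
#' @param model An [embedding_model][init_model].
#' @param domains,terms Character vectors of equal length.
#' @return A tibble with columns `domain`, `go`, `p_pred`.
#' @export
predict_pair_probability <- function(model, domains, terms) {
  di <- match(domains, model$domain_vocab)
  gi <- match(terms, model$term_vocab)
  if (anyNA(di)) abort(paste0("unknown domain: ", domains[is.na(di)][1]))
  if (anyNA(gi)) abort(paste0("unknown GO term: ", terms[is.na(gi)][1]))
  raw <- model_forward(model, di, gi)
  tibble(domain = domains, go = terms,
         p_pred = pmin(pmax(as.numeric(raw), 0), 1))
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a directory of plain-text files: vocabulary TSVs
#' mapping row indices to identifiers, one whitespace-separated matrix file
#' per weight, and a small JSON manifest. Values are written with 17
#' significant digits, so reloading restores bit-identical forward outputs.
#'
#' @param model An [embedding_model][init_model].
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` invisibly (`save_model`); the restored `embedding_model`
#'   (`load_model`).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, file) {
    writeLines(apply(matrix(sprintf("%.17g", m), nrow(m)), 1, paste,
                     collapse = "\t"), file.path(dir, file))
  }
  write_mat(model$phi, "phi.tsv")
  write_mat(model$psi, "psi.tsv")
  write_mat(model$W1, "W1.tsv")
  write_mat(model$W2, "W2.tsv")
  writeLines(sprintf("%.17g", model$b1), file.path(dir, "b1.tsv"))
  writeLines(sprintf("%.17g", model$b2), file.path(dir, "b2.tsv"))
  utils::write.table(
    data.frame(index = seq_along(model$domain_vocab), id = model$domain_vocab),
    file.path(dir, "domain_vocab.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(index = seq_along(model$term_vocab), id = model$term_vocab),
    file.path(dir, "term_vocab.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(namespace = model$namespace, d = model$d,
                            h = model$h),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  read_mat <- function(file) {
    rows <- strsplit(readLines(file.path(dir, file)), "\t", fixed = TRUE)
    do.call(rbind, map(rows, as.numeric))
  }
  dv <- utils::read.table(file.path(dir, "domain_vocab.tsv"), sep = "\t",
                          header = TRUE, colClasses = c("integer", "character"))
  tv <- utils::read.table(file.path(dir, "term_vocab.tsv"), sep = "\t",
                          header = TRUE, colClasses = c("integer", "character"))
  model <- list(
    phi = read_mat("phi.tsv"), psi = read_mat("psi.tsv"),
    W1 = read_mat("W1.tsv"), W2 = read_mat("W2.tsv"),
    b1 = as.numeric(readLines(file.path(dir, "b1.tsv"))),
    b2 = as.numeric(readLines(file.path(dir, "b2.tsv"))),
    d = as.integer(manifest$d), h = as.integer(manifest$h),
    namespace = manifest$namespace,
    domain_vocab = dv$id[order(dv$index)],
    term_vocab = tv$id[order(tv$index)],
    history = NULL
  )
  dimnames(model$phi) <- list(model$domain_vocab, NULL)
  dimnames(model$psi) <- list(model$term_vocab, NULL)
  structure(model, class = "embedding_model")
}
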
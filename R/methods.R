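#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an embedding model into a long tibble
#'
#' One row per (domain, dimension) with the embedding value; set
#' `matrix = "psi"` for the GO-term embeddings.
#'
#' @param x An [embedding_model][init_model].
#' @param matrix `"phi"` (domains, default) or `"psi"` (GO terms).
#' @param ... Unused.
#' @return A tibble with columns `id`, `dimension`, `value`.
#' @export
tidy.embedding_model <- function(x, matrix = c("phi", "psi"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  tibble(
    id = rep(rownames(m), ncol(m)),
    dimension = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.numeric(m)
  )
}

#' One-row model summary
#'
#' @param x An [embedding_model][init_model].
#' @param ... Unused.
#' @return A tibble with the namespace, dimensions, parameter count and
#'   final training/validation MSE (NA if untrained).
#' @export
glance.embedding_model <- function(x, ...) {
  n_par <- length(x$phi) + length(x$psi) + length(x$W1) + length(x$b1) +
    length(x$W2) + 1L
  tibble(
    namespace = x$namespace,
    n_domains = nrow(x$phi),
    n_terms = nrow(x$psi),
    d = x$d, h = x$h, n_parameters = n_par,
    epochs = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    train_mse = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$train_mse, 1),
    val_mse = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$val_mse, 1)
  )
}

#' Plot the training history of an embedding model
#'
#' @param object A trained [embedding_model][init_model].
#' @param ... Unused.
#' @return A ggplot: train/validation MSE per epoch on a log scale.
#' @export
autoplot.embedding_model <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history")
  df <- tidyr::pivot_longer(object$history, cols = c("train_mse", "val_mse"),
                            names_to = "split", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE",
                  title = paste0("Embedding training (", object$namespace, ")")) +
    ggplot2::theme_minimal()
}

#' Tidy evaluation results
#'
#' @param x A [go_eval][evaluate_predictions] object.
#' @param ... Unused.
#' @return The per-threshold precision/recall curve as a tibble.
#' @export
tidy.go_eval <- function(x, ...) x$pr_curve

#' One-row evaluation summary
#'
#' @param x A [go_eval][evaluate_predictions] object.
#' @param ... Unused.
#' @return A tibble with `fmax`, `tau_fmax`, `aupr`, `smin`, `tau_smin`,
#'   `n_proteins`, `namespace`.
#' @export
glance.go_eval <- function(x, ...) {
  tibble(fmax = x$fmax, tau_fmax = x$tau_fmax, aupr = x$aupr,
         smin = x$smin, tau_smin = x$tau_smin,
         n_proteins = x$n_proteins, namespace = x$namespace)
}

#' Plot the protein-centric precision-recall curve
#'
#' @param object A [go_eval][evaluate_predictions] object.
#' @param ... Unused.
#' @return A ggplot of precision against recall over the threshold grid.
#' @export
autoplot.go_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve,
                  ggplot2::aes(x = .data$rc, y = .data$pr)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("Fmax = %.3f at tau = %.2f",
                                     object$fmax, object$tau_fmax)) +
    ggplot2::theme_minimal()
}

#' Embedding distance versus functional similarity of domains
#'
#' For every (or a sample of) domain pair(s), computes the Manhattan
#' distance between the learned embeddings and the Jaccard functional
#' similarity from the co-occurrence table ([domain_jaccard()]). A
#' functionally informative embedding shows a negative rank correlation
#' between the two.
#'
#' @param model A trained [embedding_model][init_model].
#' @param table The matching [cooccurrence_tbl][conditional_probabilities].
#' @param max_pairs Maximum number of domain pairs (sampled under `seed`
#'   when exceeded).
#' @param threshold Jaccard assignment threshold on `p_cond`.
#' @param seed Seed for pair sampling.
#' @return A tibble with columns `domain_a`, `domain_b`, `distance`,
#'   `jaccard`, carrying the Spearman rank correlation as attribute
#'   `spearman`.
#' @export
distance_similarity <- function(model, table, max_pairs = 20000L,
                                threshold = 0.5, seed = 1L) {
  doms <- model$domain_vocab
  pairs <- utils::combn(length(doms), 2)
  if (ncol(pairs) > max_pairs) {
    keep <- with_seed_(seed, sample.int(ncol(pairs), max_pairs))
    pairs <- pairs[, keep, drop = FALSE]
  }
  sets <- split(table$go[table$p_cond >= threshold],
                factor(table$domain[table$p_cond >= threshold], levels = doms))
  dist <- map_dbl(seq_len(ncol(pairs)), function(j) {
    manhattan(model$phi[pairs[1, j], ], model$phi[pairs[2, j], ])
  })
  jac <- map_dbl(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]
    b <- sets[[pairs[2, j]]]
    u <- union(a, b)
    if (!length(u)) 0 else length(intersect(a, b)) / length(u)
  })
  out <- tibble(domain_a = doms[pairs[1, ]], domain_b = doms[pairs[2, ]],
                distance = dist, jaccard = jac)
  attr(out, "spearman") <- if (stats::sd(jac) > 0 && stats::sd(dist) > 0) {
    stats::cor(dist, jac, method = "spearman")
  } else NA_real_
  out
}

#' @rdname distance_similarity
#' @param data A tibble from [distance_similarity()].
#' @return `plot_distance_similarity()`: a ggplot of Jaccard similarity
#'   against embedding distance.
#' @export
plot_distance_similarity <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$distance, y = .data$jaccard)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Manhattan distance of domain embeddings",
                  y = "Jaccard functional similarity") +
    ggplot2::theme_minimal()
}
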
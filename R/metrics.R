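#' Protein-centric precision and recall at a threshold
#'
#' At cut-off `tau`, a protein's predicted term set is the stored
#' predictions with score at least `tau` (unstored pairs are implicit
#' zeros and are never predicted). Precision is averaged over the `h(tau)`
#' proteins with at least one prediction at the threshold; recall is
#' averaged over all `n_proteins` ground-truth proteins. With `h(tau) = 0`
#' precision is reported as 0.
#'
#' @param pred Tibble of predictions: columns `protein`, `go`, `score`.
#' @param truth Tibble of ground-truth annotations: columns `protein`,
#'   `go` (closed under propagation).
#' @param tau Threshold in `[0, 1]`.
#' @param n_proteins Number of evaluated proteins; defaults to the number
#'   of distinct proteins in `truth`.
#' @return A one-row tibble with columns `tau`, `pr`, `rc`, `h`.
#' @export
precision_recall <- function(pred, truth, tau,
                             n_proteins = dplyr::n_distinct(truth$protein)) {
  grid <- pr_curve_(pred, truth, tau, n_proteins)
  grid
}

# Vectorised protein-centric pr/rc over a tau grid.
pr_curve_ <- function(pred, truth, tau_grid, n_proteins) {
  if (n_proteins == 0L) abort("ground truth contains no proteins")
  truth_key <- paste(truth$protein, truth$go)
  pred <- pred[pred$protein %in% unique(truth$protein), , drop = FALSE]
  hit <- paste(pred$protein, pred$go) %in% truth_key
  n_true <- table(truth$protein)
  out <- map(tau_grid, function(tau) {
    at <- pred$score >= tau
    if (!any(at)) return(tibble(tau = tau, pr = 0, rc = 0, h = 0L))
    p_at <- pred$protein[at]
    npred <- table(p_at)
    ntp <- table(factor(p_at[hit[at]], levels = names(npred)))
    pr_per <- as.numeric(ntp) / as.numeric(npred)
    rc_per <- as.numeric(ntp) / as.numeric(n_true[names(npred)])
    rc_per[is.na(rc_per)] <- 0  # protein predicted but absent from truth rows
    tibble(tau = tau,
           pr = mean(pr_per),
           rc = sum(rc_per) / n_proteins,
           h = length(pr_per))
  })
  dplyr::bind_rows(out)
}

#' Maximum protein-centric F1 over thresholds (Fmax)
#'
#' Sweeps the threshold grid, computes the harmonic mean of the averaged
#' precision and recall at each threshold, and returns the maximum. Grid
#' points where no protein has a prediction (`h = 0`) are excluded from the
#' argmax; ties resolve to the smallest threshold.
#'
#' @inheritParams precision_recall
#' @param tau_grid Thresholds to sweep (default 0 to 1 in steps of 0.01).
#' @return A list with elements `fmax`, `tau`, and the full `curve` tibble.
#' @export
fmax <- function(pred, truth, tau_grid = seq(0, 1, by = 0.01),
                 n_proteins = dplyr::n_distinct(truth$protein)) {
  if (!length(tau_grid)) abort("`tau_grid` must be non-empty")
  curve <- pr_curve_(pred, truth, tau_grid, n_proteins)
  f1 <- ifelse(curve$pr + curve$rc > 0 & curve$h > 0,
               2 * curve$pr * curve$rc / (curve$pr + curve$rc), 0)
  valid <- which(curve$h > 0)
  if (!length(valid)) return(list(fmax = 0, tau = tau_grid[[1]], curve = curve))
  best <- valid[which.max(f1[valid])]
  list(fmax = f1[[best]], tau = curve$tau[[best]], curve = curve)
}

#' Area under the precision-recall curve (AUPR)
#'
#' By default micro-averaged over all (protein, term) pairs: every stored
#' prediction is a ranked instance, positives are the ground-truth pairs,
#' and ground-truth pairs missing from the predictions enter as zero-score
#' instances, so recall reaches its true ceiling. Integration is by the
#' trapezoidal rule over recall. `mode = "protein_centric"` instead
#' integrates the threshold-averaged [precision_recall()] curve.
#'
#' @inheritParams fmax
#' @param mode `"micro"` or `"protein_centric"`.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(pred, truth, mode = c("micro", "protein_centric"),
                 tau_grid = seq(0, 1, by = 0.01)) {
  mode <- match.arg(mode)
  if (!nrow(truth)) abort("no positive labels in ground truth")
  if (mode == "protein_centric") {
    curve <- pr_curve_(pred, truth, tau_grid, dplyr::n_distinct(truth$protein))
    ord <- order(curve$rc)
    return(trapz_(curve$rc[ord], curve$pr[ord]))
  }
  truth_key <- paste(truth$protein, truth$go)
  pred <- pred[pred$protein %in% unique(truth$protein), , drop = FALSE]
  pred_key <- paste(pred$protein, pred$go)
  scores <- pred$score
  labels <- pred_key %in% truth_key
  missed <- setdiff(truth_key, pred_key)
  if (length(missed)) {
    scores <- c(scores, rep(0, length(missed)))
    labels <- c(labels, rep(TRUE, length(missed)))
  }
  if (!any(labels)) abort("no positive labels in ground truth")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  labels <- labels[ord]
  # one PR point per distinct score (all ties enter together)
  cum_tp <- cumsum(labels)
  cum_n <- seq_along(labels)
  last_of_tie <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- cum_tp[last_of_tie]
  n <- cum_n[last_of_tie]
  prec <- tp / n
  rec <- tp / sum(labels)
  trapz_(c(0, rec), c(if (length(prec)) prec[[1]] else 1, prec))
}

trapz_ <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Information content of GO terms relative to their parents
#'
#' `IC(c) = -log( n(c) / n(parents(c)) )` with natural logarithms, where
#' `n(c)` counts corpus proteins annotated (after propagation) with `c` and
#' `n(parents(c))` counts proteins annotated with all direct parents of
#' `c` simultaneously. Roots get IC 0. Terms never annotated in the corpus
#' get a pseudo-count of 1 in numerator and denominator so downstream
#' misinformation sums stay finite (their ids are attached as the
#' `pseudo_counted` attribute).
#'
#' @param corpus An [annotation_corpus][build_corpus] (propagated).
#' @param dag A `go_dag`.
#' @return Named numeric vector of IC values over `dag$terms`.
#' @export
information_content <- function(corpus, dag) {
  n_prot <- length(corpus$proteins)
  if (n_prot == 0L) abort("empty corpus")
  term_sets <- list()
  for (ns in NAMESPACES) {
    ts <- corpus$terms_of[[ns]]
    long <- tibble(protein = rep(seq_along(ts), lengths(ts)),
                   go = unlist(ts, use.names = FALSE))
    term_sets[[ns]] <- split(long$protein, long$go)
  }
  protein_ids_of <- do.call(c, unname(term_sets))
  count_of <- lengths(protein_ids_of)

  ic <- structure(numeric(length(dag$terms)), names = dag$terms)
  pseudo <- character()
  for (t in dag$terms) {
    pp <- dag$parents[[t]]
    if (!length(pp)) next  # root: IC 0
    n_c <- count_of[t]
    if (is.na(n_c)) n_c <- 0L
    pa_sets <- protein_ids_of[pp]
    pa_sets[map_lgl(pa_sets, is.null)] <- list(integer())
    n_pa <- length(Reduce(intersect, pa_sets))
    if (n_c == 0L) {
      pseudo <- c(pseudo, t)
      ic[[t]] <- -log(1 / (n_pa + 1))
    } else {
      ic[[t]] <- -log(n_c / n_pa)
    }
  }
  attr(ic, "pseudo_counted") <- pseudo
  ic
}

#' Minimum semantic distance between prediction and truth (Smin)
#'
#' At each threshold `t`, remaining uncertainty `ru(t)` sums the information
#' content of true terms not predicted at `t`, and misinformation `mi(t)`
#' sums the IC of predicted terms that are not true, both averaged over all
#' proteins. Smin is the minimum over the grid of
#' `sqrt(ru(t)^2 + mi(t)^2)`.
#'
#' @inheritParams fmax
#' @param ic Named numeric vector of IC values ([information_content()])
#'   covering every term in `pred` and `truth`.
#' @return A list with elements `smin`, `tau`, and the `curve` tibble
#'   (columns `tau`, `ru`, `mi`).
#' @export
smin <- function(pred, truth, ic, tau_grid = seq(0, 1, by = 0.01),
                 n_proteins = dplyr::n_distinct(truth$protein)) {
  missing_ic <- setdiff(unique(c(pred$go, truth$go)), names(ic))
  if (length(missing_ic)) {
    abort(paste0("no information content for term(s): ",
                 paste(utils::head(missing_ic, 5), collapse = ", ")))
  }
  if (n_proteins == 0L) abort("ground truth contains no proteins")
  pred <- pred[pred$protein %in% unique(truth$protein), , drop = FALSE]
  truth_key <- paste(truth$protein, truth$go)
  pred_key <- paste(pred$protein, pred$go)
  pred_is_true <- pred_key %in% truth_key
  truth_ic <- ic[truth$go]
  total_truth_ic <- sum(truth_ic)
  # truth pairs that appear among predictions, with their scores
  m <- match(truth_key, pred_key)
  truth_pred_score <- ifelse(is.na(m), -Inf, pred$score[m])
  pred_ic <- ic[pred$go]
  curve <- map(tau_grid, function(tau) {
    at <- pred$score >= tau
    # ru: IC of truth terms whose prediction (if any) falls below tau
    ru <- sum(truth_ic[truth_pred_score < tau]) / n_proteins
    mi <- sum(pred_ic[at & !pred_is_true]) / n_proteins
    tibble(tau = tau, ru = ru, mi = mi)
  })
  curve <- dplyr::bind_rows(curve)
  s <- sqrt(curve$ru^2 + curve$mi^2)
  best <- which.min(s)
  list(smin = s[[best]], tau = curve$tau[[best]], curve = curve)
}

#' Support-weighted mean F1
#'
#' Averages per-term F1 scores weighted by the number of proteins carrying
#' each term.
#'
#' @param f1 Numeric vector of per-term F1 scores.
#' @param support Non-negative per-term support counts (same length).
#' @return Weighted mean F1.
#' @export
weighted_f1 <- function(f1, support) {
  if (length(f1) != length(support)) abort("`f1` and `support` lengths differ")
  if (any(support < 0)) abort("`support` must be non-negative")
  if (sum(support) <= 0) abort("total support is zero")
  sum(f1 * support) / sum(support)
}

#' Functional similarity of two domains (Jaccard index)
#'
#' The GO terms "assigned" to a domain are those with conditional
#' probability at least `threshold` (default 0.5) in the co-occurrence
#' table; the similarity of two domains is the Jaccard index of their
#' assigned-term sets. If both sets are empty the similarity is defined
#' as 0.
#'
#' @param table A [cooccurrence_tbl][conditional_probabilities].
#' @param domain_a,domain_b Domain identifiers present in the table's
#'   vocabulary.
#' @param threshold Assignment cut-off on `p_cond`.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
domain_jaccard <- function(table, domain_a, domain_b, threshold = 0.5) {
  vocab <- names(attr(table, "p_domain_all"))
  for (d in c(domain_a, domain_b)) {
    if (!d %in% vocab) abort(paste0("unknown domain: ", d))
  }
  set_of <- function(d) table$go[table$domain == d & table$p_cond >= threshold]
  a <- set_of(domain_a)
  b <- set_of(domain_b)
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

#' Manhattan (L1) distance between two vectors
#'
#' The distance used throughout the embedding-geometry analyses; preferred
#' over Euclidean distance in high-dimensional embedding spaces.
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sum(|a - b|)`.
#' @export
manhattan <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  sum(abs(a - b))
}

#' Evaluate a prediction set with the protein-centric CAFA metrics
#'
#' Convenience wrapper computing Fmax, AUPR and (when `ic` is supplied)
#' Smin in one pass.
#'
#' @inheritParams fmax
#' @param ic Optional named IC vector for Smin.
#' @param namespace Optional namespace label carried into the result.
#' @return An object of class `go_eval` with elements `fmax`, `tau_fmax`,
#'   `aupr`, `smin`, `tau_smin`, `pr_curve`, `ru_mi_curve`, `namespace`,
#'   `n_proteins`.
#' @export
evaluate_predictions <- function(pred, truth, ic = NULL,
                                 tau_grid = seq(0, 1, by = 0.01),
                                 namespace = NA_character_,
                                 n_proteins = dplyr::n_distinct(truth$protein)) {
  f <- fmax(pred, truth, tau_grid, n_proteins)
  a <- aupr(pred, truth)
  s <- if (!is.null(ic)) smin(pred, truth, ic, tau_grid, n_proteins)
  structure(
    list(fmax = f$fmax, tau_fmax = f$tau, aupr = a,
         smin = if (!is.null(s)) s$smin else NA_real_,
         tau_smin = if (!is.null(s)) s$tau else NA_real_,
         pr_curve = f$curve,
         ru_mi_curve = if (!is.null(s)) s$curve,
         namespace = namespace, n_proteins = n_proteins),
    class = "go_eval"
  )
}

#' @export
print.go_eval <- function(x, ...) {
  cat("<go_eval>", if (!is.na(x$namespace)) paste0(" [", x$namespace, "]"),
      " n = ", x$n_proteins,
      sprintf("; Fmax = %.3f (tau = %.2f), AUPR = %.3f", x$fmax, x$tau_fmax,
              x$aupr),
      if (!is.na(x$smin)) sprintf(", Smin = %.3f", x$smin),
      "\n", sep = "")
  invisible(x)
}
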
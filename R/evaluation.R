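# CAFA-style F1max, repeated nested cross-validation, exact Wilcoxon
# signed-rank comparison, and the BLAST annotation-transfer baseline.

#' F1max over a threshold grid
#'
#' For each threshold t, the predicted label set of protein i is
#' `P_i(t) = {f : score_i(f) >= t}` (inclusive, so t = 0 predicts every
#' label). Precision `pr_i` is averaged over the `m(t)` proteins with at
#' least one predicted label, recall `rc_i` over all n proteins, and F1(t)
#' is the harmonic mean of the two averages (0 when `m(t) = 0` or both
#' averages are 0). F1max is the maximum over the grid.
#'
#' @param truth binary matrix instances x labels; every row must have at
#'   least one positive label.
#' @param scores numeric matrix of the same shape with values in `[0, 1]`.
#' @param thresholds threshold grid (default 0, 0.1, ..., 1).
#' @return Object of class `eval_result`: list with `f1max`, `threshold`
#'   (argmax, first on ties), and `grid` (data.frame `t`, `AvgPr`, `AvgRc`,
#'   `m`, `F1`).
#' @export
f1max <- function(truth, scores, thresholds = seq(0, 1, by = 0.1)) {
  truth <- as.matrix(truth)
  scores <- as.matrix(scores)
  stopifnot(all(dim(truth) == dim(scores)))
  if (any(rowSums(truth) < 1)) {
    stop("every protein must have at least one true label")
  }
  n <- nrow(truth)
  grid <- data.frame(t = thresholds, AvgPr = 0, AvgRc = 0,
                     m = 0L, F1 = 0)
  for (g in seq_along(thresholds)) {
    t <- thresholds[g]
    P <- scores >= t
    npred <- rowSums(P)
    ntrue <- rowSums(truth)
    ninter <- rowSums(P & truth == 1)
    has_pred <- npred >= 1
    m <- sum(has_pred)
    avg_pr <- if (m > 0) sum(ninter[has_pred] / npred[has_pred]) / m else 0
    avg_rc <- sum(ninter / ntrue) / n
    f1 <- if (m == 0 || avg_pr + avg_rc == 0) 0 else
      2 * avg_pr * avg_rc / (avg_pr + avg_rc)
    grid$AvgPr[g] <- avg_pr
    grid$AvgRc[g] <- avg_rc
    grid$m[g] <- m
    grid$F1[g] <- f1
  }
  best <- which.max(grid$F1)
  structure(list(f1max = grid$F1[best], threshold = thresholds[best],
                 grid = grid),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("F1max = %.4f at threshold %.1f (AvgPr %.4f, AvgRc %.4f)\n",
              x$f1max, x$threshold,
              x$grid$AvgPr[x$grid$t == x$threshold],
              x$grid$AvgRc[x$grid$t == x$threshold]))
  invisible(x)
}

#' Default hyperparameter grid for nested cross-validation
#'
#' The three tuned knobs: number of trees, features per split, and the
#' number of top-ranked features retained by RF-ML selection (`Inf` = all).
#'
#' @return data.frame `n_trees`, `mtry_rule`, `top_n` (row order is the
#'   declared tie-break order).
#' @export
default_cv_grid <- function() {
  expand.grid(n_trees = c(100L, 300L, 500L),
              mtry_rule = c("sqrt", "log2"),
              top_n = c(50, 100, 200, Inf),
              stringsAsFactors = FALSE)
}

resolve_mtry <- function(rule, p) {
  if (is.null(rule) || is.na(rule)) return(NULL)
  m <- switch(as.character(rule),
              sqrt = floor(sqrt(p)),
              log2 = floor(log2(p)) + 1,
              as.integer(rule))
  max(1L, min(as.integer(m), p))
}

make_folds <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

fit_with_selection <- function(X, Y, transformation, n_trees, mtry_rule,
                               top_n, base_seed, rakel_k, rakel_m) {
  ranked <- suppressWarnings(
    rfml_rank_features(X, Y, seed = base_seed))
  keep <- ranked$feature[seq_len(min(top_n, nrow(ranked)))]
  keep <- intersect(colnames(X), keep)  # preserve registry order
  Xs <- X[, keep, drop = FALSE]
  spec <- base_learner_spec(
    n_trees = n_trees, mtry = resolve_mtry(mtry_rule, ncol(Xs)),
    seed = base_seed)
  model <- suppressWarnings(
    fit_multilabel(Xs, Y, transformation, spec, k = rakel_k, m = rakel_m))
  list(model = model, keep = keep)
}

#' Repeated nested cross-validation
#'
#' For each repetition the data are shuffled into `outer` folds; within each
#' outer training set an `inner`-fold grid search (feature selection and
#' model fitting repeated per inner fold, so selection never sees held-out
#' data) picks the hyperparameter row maximizing the mean inner F1max (ties:
#' first row in grid order). The winner is refitted on the full outer
#' training set and evaluated on the outer test fold.
#'
#' @param features,labels training matrices (see
#'   [build_training_matrices()]).
#' @param transformation `"rakel"`, `"br"` or `"lp"`.
#' @param grid hyperparameter data.frame (`n_trees`, `mtry_rule`, `top_n`);
#'   default [default_cv_grid()].
#' @param outer,inner,reps fold and repetition counts (defaults 5, 3, 5).
#' @param seed base RNG seed.
#' @param rakel_k,rakel_m RAkEL subset size and member count.
#' @return Object of class `cv_report`: list with `results` (one row per
#'   (rep, fold): chosen hyperparameters, test F1max / precision / recall /
#'   threshold), `summary` (mean and SD of F1max), and `folds` (per (rep,
#'   fold) the outer-test and inner-fold row indices, for leakage auditing).
#' @export
nested_cv <- function(features, labels, transformation = "rakel",
                      grid = default_cv_grid(), outer = 5, inner = 3,
                      reps = 5, seed = 1, rakel_k = 3, rakel_m = NULL) {
  n <- nrow(features)
  stopifnot(n >= outer)
  results <- list()
  fold_log <- list()
  for (r in seq_len(reps)) {
    set.seed(seed + 1000L * r)
    outer_folds <- make_folds(n, outer)
    for (f in seq_len(outer)) {
      test_idx <- which(outer_folds == f)
      train_idx <- which(outer_folds != f)
      set.seed(seed + 1000L * r + f)
      inner_folds <- make_folds(length(train_idx), inner)
      inner_scores <- matrix(NA_real_, nrow(grid), inner)
      for (g in seq_len(nrow(grid))) {
        for (h in seq_len(inner)) {
          tr <- train_idx[inner_folds != h]
          te <- train_idx[inner_folds == h]
          fitted <- fit_with_selection(
            features[tr, , drop = FALSE], labels[tr, , drop = FALSE],
            transformation, grid$n_trees[g], grid$mtry_rule[g],
            grid$top_n[g], seed, rakel_k, rakel_m)
          sc <- predict(fitted$model,
                        features[te, fitted$keep, drop = FALSE])
          inner_scores[g, h] <-
            f1max(labels[te, , drop = FALSE], sc)$f1max
        }
      }
      winner <- which.max(rowMeans(inner_scores))  # first max in grid order
      fitted <- fit_with_selection(
        features[train_idx, , drop = FALSE],
        labels[train_idx, , drop = FALSE],
        transformation, grid$n_trees[winner], grid$mtry_rule[winner],
        grid$top_n[winner], seed, rakel_k, rakel_m)
      sc <- predict(fitted$model,
                    features[test_idx, fitted$keep, drop = FALSE])
      ev <- f1max(labels[test_idx, , drop = FALSE], sc)
      at <- ev$grid[ev$grid$t == ev$threshold, ]
      results[[length(results) + 1L]] <- data.frame(
        rep = r, fold = f,
        n_trees = grid$n_trees[winner],
        mtry_rule = grid$mtry_rule[winner],
        top_n = grid$top_n[winner],
        f1max = ev$f1max, precision = at$AvgPr, recall = at$AvgRc,
        threshold = ev$threshold, stringsAsFactors = FALSE)
      fold_log[[sprintf("r%d_f%d", r, f)]] <- list(
        outer_test = test_idx,
        inner = lapply(seq_len(inner),
                       function(h) train_idx[inner_folds == h]))
    }
  }
  results <- do.call(rbind, results)
  structure(list(
    results = results,
    summary = c(mean_f1max = mean(results$f1max),
                sd_f1max = stats::sd(results$f1max)),
    folds = fold_log),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("nested CV: %d evaluations, F1max %.3f +/- %.3f\n",
              nrow(x$results), x$summary["mean_f1max"],
              x$summary["sd_f1max"]))
  invisible(x)
}

#' Wilcoxon signed-rank comparison of paired metrics
#'
#' Two-sided signed-rank test on paired vectors (e.g. per-fold F1max of two
#' models). Zero differences are dropped; for up to 25 nonzero pairs the
#' exact null distribution of the positive-rank sum is enumerated (midranks
#' under ties), above that a normal approximation with continuity and tie
#' correction is used.
#'
#' @param metric_vector_a,metric_vector_b equal-length numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_compare <- function(metric_vector_a, metric_vector_b) {
  stopifnot(length(metric_vector_a) == length(metric_vector_b))
  d <- metric_vector_a - metric_vector_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero")
    return(1.0)
  }
  if (n < 2L) {
    warning("fewer than 2 nonzero differences; p-value uninformative")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # exact: distribution of the positive-rank sum over all 2^n sign
    # assignments, by convolution over doubled midranks (integers)
    weights <- as.integer(round(2 * r))
    dist <- c(1, numeric(sum(weights)))
    for (wi in weights) {
      shifted <- c(numeric(wi), dist[seq_len(length(dist) - wi)])
      dist <- dist + shifted
    }
    total <- 2^n
    support <- seq_along(dist) - 1L
    w2 <- round(2 * w)
    p_ge <- sum(dist[support >= w2]) / total
    p_le <- sum(dist[support <= w2]) / total
    return(min(1, 2 * min(p_ge, p_le)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' BLAST annotation-transfer baseline
#'
#' Transfers the labels of each query's best passing training hit (minimum
#' E-value, ties by maximum bitscore) and scores every transferred label
#' with the hit's percent identity divided by 100. Queries without a
#' passing hit get an all-zero row.
#'
#' @param train_annotations `go_annotations` over the training proteins.
#' @param query_hits `similarity_hits` of test-vs-train searches.
#' @param e_cutoff E-value criterion for transfer.
#' @param query_ids rows of the output (default: every query id seen in
#'   `query_hits`).
#' @return Score matrix query x vocabulary in `[0, 1]`.
#' @export
blast_transfer_baseline <- function(train_annotations, query_hits, e_cutoff,
                                    query_ids = NULL) {
  stopifnot(inherits(train_annotations, "go_annotations"))
  if (is.null(query_ids)) query_ids <- sort(unique(query_hits$query_id))
  vocab <- train_annotations$vocabulary$go_id
  scores <- matrix(0, length(query_ids), length(vocab),
                   dimnames = list(query_ids, vocab))
  mapped <- map_query(query_hits, max_targets = 1, e_cutoff = e_cutoff)
  for (i in seq_len(nrow(mapped))) {
    q <- mapped$query_id[i]
    if (!q %in% query_ids) next
    terms <- train_annotations$annotations[[mapped$subject_id[i]]]
    if (is.null(terms)) next
    scores[q, terms] <- mapped$pct_identity[i] / 100
  }
  scores
}
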
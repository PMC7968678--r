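# End-to-end orchestration: neighborhoods -> clustering -> distances ->
# tree -> Phylo scores -> quantile bins -> training matrices, plus simple
# k-fold cross-validated scoring used by the evaluation workflows and the
# command-line wrapper (inst/scripts/neighborgo).

#' Run the feature-construction pipeline
#'
#' Executes every preprocessing stage at one modeling tier and returns all
#' intermediate artifacts: neighborhood clusters, protein clustering, the
#' gene-content distance matrix and NJ genome tree, the Phylo score table,
#' fitted quantile bins and the aligned training matrices.
#'
#' @param collection a [genome_collection()].
#' @param hits all-vs-all `similarity_hits`.
#' @param annotations a `go_annotations` object.
#' @param tier modeling E-value tier (default 1e-10).
#' @param max_gap,div_min,div_max neighborhood thresholds in bp
#'   (defaults 250; 200-1000).
#' @return list with `neighborhoods`, `clustering`, `dist`, `tree`,
#'   `score_table`, `bins`, `features`, `labels`, `instances`,
#'   `feature_names`.
#' @export
run_pipeline <- function(collection, hits, annotations, tier = 1e-10,
                         max_gap = 250, div_min = 200, div_max = 1000) {
  neighborhoods <- call_neighborhoods(collection, max_gap = max_gap,
                                      div_min = div_min, div_max = div_max)
  clustering <- cluster_proteins(hits, collection$genes$protein_id, tier)
  D <- build_distance_matrix(collection, clustering)
  tree <- build_tree(D)
  score_table <- build_phylo_scores(neighborhoods, clustering, tree)
  bins <- fit_quantile_bins(score_table$raw)
  mats <- build_training_matrices(collection, clustering, score_table,
                                  bins, annotations)
  c(list(neighborhoods = neighborhoods, clustering = clustering,
         dist = D, tree = tree, score_table = score_table, bins = bins),
    mats)
}

#' K-fold cross-validated prediction scores and F1max
#'
#' Shuffles instances into `folds` folds, fits the chosen transformation on
#' each training split and scores the held-out fold; held-out scores are
#' pooled and a single F1max computed over them (CAFA style).
#'
#' @param features,labels training matrices.
#' @param transformation `"rakel"`, `"br"` or `"lp"`.
#' @param base_spec a [base_learner_spec()].
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param rakel_k,rakel_m RAkEL parameters.
#' @return list with `f1max` (an `eval_result`), `scores` (pooled held-out
#'   score matrix) and `fold_assignment`.
#' @export
cv_f1max <- function(features, labels, transformation = "rakel",
                     base_spec = base_learner_spec(), folds = 5, seed = 1,
                     rakel_k = 3, rakel_m = NULL) {
  n <- nrow(features)
  set.seed(seed)
  fold <- make_folds(n, folds)
  scores <- matrix(NA_real_, n, ncol(labels),
                   dimnames = dimnames(labels))
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- suppressWarnings(
      fit_multilabel(features[tr, , drop = FALSE],
                     labels[tr, , drop = FALSE],
                     transformation, base_spec, k = rakel_k, m = rakel_m))
    scores[!tr, ] <- predict(model, features[!tr, , drop = FALSE])
  }
  list(f1max = f1max(labels, scores), scores = scores,
       fold_assignment = fold)
}
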
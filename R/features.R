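# Assembly of genome-neighborhood profile features and the binary label
# matrix. Instances are proteins (so homologous proteins with different
# annotations stay distinct instances, with identical feature rows); feature
# columns are the neighbor protein-clusters ever observed adjacent to an
# instance's focal cluster, valued by the discretized Phylo score.

#' Build one genome-neighborhood profile row
#'
#' @param focal_cluster protein cluster id of the instance.
#' @param score_table a [build_phylo_scores()] table at the modeling tier.
#' @param bins a [fit_quantile_bins()] result.
#' @param feature_names optional fixed column registry; defaults to the
#'   neighbors of `focal_cluster` in the score table.
#' @return Named integer vector over `feature_names` with values in
#'   \{0,1,2,3\}; all zero (with a warning) if the focal cluster has no entry
#'   in the score table.
#' @export
build_profile <- function(focal_cluster, score_table, bins,
                          feature_names = NULL) {
  rows <- score_table[score_table$focal == focal_cluster, , drop = FALSE]
  if (is.null(feature_names)) feature_names <- sort(unique(rows$neighbor))
  prof <- setNames(integer(length(feature_names)), feature_names)
  if (nrow(rows) == 0L) {
    warning("focal cluster absent from score table: ", focal_cluster)
    return(prof)
  }
  hit <- rows$neighbor %in% feature_names
  prof[rows$neighbor[hit]] <- discretize(rows$raw[hit], bins)
  prof
}

#' Build aligned training feature and label matrices
#'
#' Instances are the annotated proteins of the collection (after vocabulary
#' restriction; proteins with zero in-vocabulary labels are excluded and
#' counted). Feature columns are the union of neighbor clusters observed for
#' the instances' focal clusters; the column order is the serialized feature
#' registry used to align prediction-time profiles.
#'
#' @param collection a [genome_collection()].
#' @param clustering a [cluster_proteins()] result at the modeling tier.
#' @param score_table a [build_phylo_scores()] table at the same tier.
#' @param bins a [fit_quantile_bins()] result.
#' @param annotations a `go_annotations` object.
#' @return list with `features` (instances x neighbor clusters, \{0,1,2,3\}),
#'   `labels` (instances x vocabulary, binary), `instances` (data.frame
#'   `protein_id`, `focal_cluster`), `feature_names`, `n_excluded`.
#' @export
build_training_matrices <- function(collection, clustering, score_table,
                                    bins, annotations) {
  stopifnot(inherits(annotations, "go_annotations"))
  vocab <- annotations$vocabulary$go_id
  prots <- intersect(names(annotations$annotations),
                     collection$genes$protein_id)
  prots <- sort(prots)
  n_excluded <- length(names(annotations$annotations)) - length(prots)
  focal <- unname(clustering$assignment[prots])
  if (anyNA(focal)) stop("annotated protein missing from clustering: ",
                         prots[which(is.na(focal))[1]])
  feature_names <- sort(unique(
    score_table$neighbor[score_table$focal %in% focal]))
  X <- matrix(0L, length(prots), length(feature_names),
              dimnames = list(prots, feature_names))
  profiles <- lapply(unique(focal), function(fc)
    suppressWarnings(build_profile(fc, score_table, bins, feature_names)))
  names(profiles) <- unique(focal)
  for (i in seq_along(prots)) X[i, ] <- profiles[[focal[i]]]
  Y <- matrix(0L, length(prots), length(vocab),
              dimnames = list(prots, vocab))
  for (i in seq_along(prots)) {
    Y[i, annotations$annotations[[prots[i]]]] <- 1L
  }
  stopifnot(all(rowSums(Y) >= 1))
  list(features = X, labels = Y,
       instances = data.frame(protein_id = prots, focal_cluster = focal,
                              stringsAsFactors = FALSE),
       feature_names = feature_names, n_excluded = n_excluded)
}

#' Align prediction-time feature rows to a training registry
#'
#' Columns unseen at training are dropped (and counted); training columns
#' absent from the input are filled with 0.
#'
#' @param features matrix or named-vector profile(s).
#' @param feature_names the training feature registry.
#' @return Matrix over `feature_names` with attribute `n_dropped`.
#' @export
align_features <- function(features, feature_names) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  dropped <- setdiff(colnames(features), feature_names)
  out <- matrix(0L, nrow(features), length(feature_names),
                dimnames = list(rownames(features), feature_names))
  shared <- intersect(colnames(features), feature_names)
  out[, shared] <- features[, shared, drop = FALSE]
  attr(out, "n_dropped") <- length(dropped)
  out
}
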
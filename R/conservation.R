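# Genome gene-content distances, the genome tree, neighborhood conservation
# (Phylo) scores, and their quantile discretization.
#
# The Phylo score of a (focal family, neighbor family) pair is the
# phylogenetic diversity -- total branch length of the minimal spanning
# subtree -- of the genomes that conserve the adjacency, on a neighbor-
# joining tree built from Jaccard gene-content distances. A pair supported
# by at most one genome scores 0 (nonconserved); a pair conserved across
# the whole collection scores the total tree length.

#' Jaccard gene-content distance between two genomes
#'
#' @param genome_a_clusters,genome_b_clusters character vectors: the protein
#'   cluster ids present in each genome at a fixed tier.
#' @return `1 - |A n B| / |A u B|`, in `[0, 1]`.
#' @export
genome_distance <- function(genome_a_clusters, genome_b_clusters) {
  a <- unique(genome_a_clusters)
  b <- unique(genome_b_clusters)
  if (length(a) == 0L && length(b) == 0L) {
    stop("both genomes have empty cluster sets")
  }
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Protein-cluster content per genome
#'
#' @param collection a [genome_collection()].
#' @param clustering a [cluster_proteins()] result.
#' @return Named list genome_id -> character vector of cluster ids.
#' @export
genome_cluster_sets <- function(collection, clustering) {
  g <- collection$genes
  cl <- clustering$assignment[g$protein_id]
  lapply(split(unname(cl), g$genome_id), unique)
}

#' Pairwise genome distance matrix
#'
#' Computes the Jaccard gene-content distance for every unordered genome
#' pair: `G * (G - 1) / 2` evaluations for `G` genomes, with a zero diagonal.
#'
#' @param collection a [genome_collection()].
#' @param clustering a [cluster_proteins()] result at the modeling tier.
#' @return Symmetric numeric matrix with genome ids as dimnames and an
#'   attribute `n_pairs`: the number of unordered pairs actually evaluated.
#' @export
build_distance_matrix <- function(collection, clustering) {
  sets <- genome_cluster_sets(collection, clustering)
  ids <- sort(names(sets))
  G <- length(ids)
  if (G < 2L) stop("need at least 2 genomes")
  D <- matrix(0, G, G, dimnames = list(ids, ids))
  n_pairs <- 0L
  for (i in seq_len(G - 1L)) {
    for (j in seq.int(i + 1L, G)) {
      d <- genome_distance(sets[[ids[i]]], sets[[ids[j]]])
      D[i, j] <- D[j, i] <- d
      n_pairs <- n_pairs + 1L
    }
  }
  attr(D, "n_pairs") <- n_pairs
  D
}

#' Build the genome tree by neighbor joining
#'
#' For two genomes the tree is a single edge of length `d` (represented as
#' two half-length pendant edges); for three or more, `ape::nj` is used and
#' negative branch-length estimates are clamped to zero.
#'
#' @param distance_matrix symmetric matrix from [build_distance_matrix()].
#' @return An unrooted `ape::phylo` tree whose tips are the genome ids.
#' @export
build_tree <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(D), tol = 1e-12)) {
    stop("distance matrix must be symmetric")
  }
  G <- nrow(D)
  if (G < 2L) stop("need at least 2 genomes")
  if (G == 2L) {
    tr <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      edge.length = rep(D[1, 2] / 2, 2),
      tip.label = rownames(D), Nnode = 1L), class = "phylo")
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Phylogenetic diversity of a set of leaves
#'
#' Total branch length of the minimal subtree of `tree` spanning `leaves`;
#' 0 for at most one leaf.
#'
#' @param tree an `ape::phylo` tree.
#' @param leaves character vector of tip labels.
#' @return Non-negative scalar.
#' @export
phylogenetic_diversity <- function(tree, leaves) {
  leaves <- unique(leaves)
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown)) stop("unknown tree leaves: ", unknown[1])
  if (length(leaves) <= 1L) return(0)
  if (length(leaves) == length(tree$tip.label)) {
    return(sum(tree$edge.length))
  }
  sum(ape::keep.tip(tree, leaves)$edge.length)
}

#' Per-genome neighborhood co-membership of protein clusters
#'
#' For each genome, the set of unordered protein-cluster pairs that share a
#' neighborhood cluster. Internal helper for Phylo scoring.
#'
#' @keywords internal
cluster_pair_support <- function(neighborhoods, clustering) {
  nb <- as.data.frame(neighborhoods)
  nb$pcluster <- unname(clustering$assignment[nb$protein_id])
  if (anyNA(nb$pcluster)) {
    stop("neighborhood protein missing from clustering: ",
         nb$protein_id[which(is.na(nb$pcluster))[1]])
  }
  support <- new.env(parent = emptyenv())
  by_nc <- split(nb[, c("genome_id", "pcluster")], nb$cluster_id)
  for (piece in by_nc) {
    cls <- sort(unique(piece$pcluster))
    if (length(cls) < 2L) next
    gnm <- piece$genome_id[1]
    pairs <- combn(cls, 2L)
    for (k in seq_len(ncol(pairs))) {
      key <- paste(pairs[1, k], pairs[2, k], sep = "\r")
      support[[key]] <- union(support[[key]], gnm)
    }
  }
  support
}

#' Conservation (Phylo) score of one cluster pair
#'
#' The supporting set S is the set of genomes in which at least one member
#' of the focal cluster shares a neighborhood cluster with at least one
#' member of the neighbor cluster. The score is 0 if `|S| <= 1`
#' (nonconserved), otherwise the phylogenetic diversity of S on the genome
#' tree.
#'
#' @param focal_cluster,neighbor_cluster protein cluster ids.
#' @param neighborhoods a `neighborhood_set` covering every genome.
#' @param clustering the [cluster_proteins()] result at the same tier.
#' @param tree genome tree from [build_tree()].
#' @return list with `raw` (score) and `supporting` (genome ids).
#' @export
phylo_score <- function(focal_cluster, neighbor_cluster,
                        neighborhoods, clustering, tree) {
  for (cl in c(focal_cluster, neighbor_cluster)) {
    if (!cl %in% clustering$assignment) stop("unknown cluster: ", cl)
  }
  support <- cluster_pair_support(neighborhoods, clustering)
  key <- paste(min(focal_cluster, neighbor_cluster),
               max(focal_cluster, neighbor_cluster), sep = "\r")
  s <- support[[key]]
  if (is.null(s)) s <- character(0)
  raw <- if (length(s) <= 1L) 0 else phylogenetic_diversity(tree, s)
  list(raw = raw, supporting = sort(s))
}

#' Phylo score table for every observed cluster adjacency
#'
#' Scores every unordered protein-cluster pair that shares a neighborhood
#' cluster in at least one genome, then expands to both orientations
#' (focal, neighbor).
#'
#' @param neighborhoods a `neighborhood_set`.
#' @param clustering a [cluster_proteins()] result.
#' @param tree genome tree from [build_tree()].
#' @return data.frame of class `phylo_score_table`: `focal`, `neighbor`,
#'   `tier`, `raw`, `n_support`, and list-column `supporting`.
#' @export
build_phylo_scores <- function(neighborhoods, clustering, tree) {
  support <- cluster_pair_support(neighborhoods, clustering)
  keys <- ls(support)
  if (length(keys) == 0L) {
    out <- data.frame(focal = character(0), neighbor = character(0),
                      tier = numeric(0), raw = numeric(0),
                      n_support = integer(0), supporting = I(list()))
    class(out) <- c("phylo_score_table", "data.frame")
    return(out)
  }
  pair <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  sets <- lapply(keys, function(k) sort(support[[k]]))
  raw <- vapply(sets, function(s) {
    if (length(s) <= 1L) 0 else phylogenetic_diversity(tree, s)
  }, numeric(1))
  half <- data.frame(focal = pair[, 1], neighbor = pair[, 2],
                     tier = clustering$tier, raw = raw,
                     n_support = lengths(sets),
                     supporting = I(sets), stringsAsFactors = FALSE)
  other <- half
  other$focal <- half$neighbor
  other$neighbor <- half$focal
  out <- rbind(half, other)
  out <- out[order(out$focal, out$neighbor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phylo_score_table", "data.frame")
  out
}

#' Fit quantile bins for Phylo score discretization
#'
#' Cutoffs are the 1/3 and 2/3 empirical quantiles (linear interpolation of
#' the empirical CDF, `type = 4`) of the strictly positive training scores;
#' zero scores never enter the fit. With fewer than three distinct positive
#' scores both cutoffs fall back to their median.
#'
#' @param raw_scores numeric vector of raw training Phylo scores.
#' @return Object of class `quantile_bins`: list with `q1 <= q2`.
#' @export
fit_quantile_bins <- function(raw_scores) {
  if (any(raw_scores < 0)) stop("raw scores must be non-negative")
  pos <- raw_scores[raw_scores > 0]
  if (length(unique(pos)) < 3L) {
    warning("fewer than 3 distinct positive scores; using median for both cutoffs")
    med <- if (length(pos)) median(pos) else 0
    q <- c(med, med)
  } else {
    q <- unname(quantile(pos, c(1 / 3, 2 / 3), type = 4))
  }
  structure(list(q1 = q[1], q2 = q[2]), class = "quantile_bins")
}

#' Discretize raw Phylo scores to ordinal bins
#'
#' `0 -> 0`; `(0, q1] -> 1`; `(q1, q2] -> 2`; `(q2, Inf) -> 3`. Zero always
#' means nonconserved; the upper bin is open so scores beyond the training
#' range map to 3.
#'
#' @param raw numeric vector of raw scores (>= 0).
#' @param bins a [fit_quantile_bins()] result.
#' @return Integer vector of bins in \{0,1,2,3\}.
#' @export
discretize <- function(raw, bins) {
  stopifnot(inherits(bins, "quantile_bins"))
  if (any(raw < 0)) stop("raw scores must be non-negative")
  ifelse(raw <= 0, 0L,
         ifelse(raw <= bins$q1, 1L,
                ifelse(raw <= bins$q2, 2L, 3L)))
}
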
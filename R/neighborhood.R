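# Neighborhood cluster calling: same-strand distance rule, divergent-pair
# merge, and the per-collection driver. A neighborhood cluster is a maximal
# run of consecutive genes on a contig; an interleaved opposite-strand gene
# terminates a same-strand run.

#' Call same-strand neighborhood clusters on one contig
#'
#' Two adjacent genes join one cluster iff they are on the same strand and
#' the intergenic gap `start(next) - end(prev)` (0-based half-open, so
#' overlapping genes have gap <= 0) is at most `max_gap`. Membership is the
#' transitive closure along the contig; an opposite-strand gene between two
#' same-strand genes breaks the run.
#'
#' @param contig_genes data.frame for a single contig with columns `gene_id`,
#'   `start`, `end`, `strand` (and optionally `protein_id`), sorted by
#'   `(start, end, gene_id)`.
#' @param max_gap maximum intergenic distance in bp (inclusive; default 250).
#' @return data.frame, one row per cluster: `cluster`, `start`, `end`,
#'   `strand` and list-column `members` (gene ids in coordinate order).
#' @export
call_same_strand_clusters <- function(contig_genes, max_gap = 250) {
  g <- as.data.frame(contig_genes)
  n <- nrow(g)
  if (n == 0L) {
    return(data.frame(cluster = integer(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      members = I(list())))
  }
  ord <- order(g$start, g$end, g$gene_id)
  if (!identical(ord, seq_len(n))) {
    stop("contig genes must be sorted by (start, end, gene_id)")
  }
  if (n == 1L) {
    cl <- rep(1L, 1)
  } else {
    gap <- g$start[-1] - g$end[-n]
    same <- g$strand[-1] == g$strand[-n]
    new_cluster <- !(same & gap <= max_gap)
    cl <- cumsum(c(TRUE, new_cluster))
  }
  agg <- split(seq_len(n), cl)
  data.frame(
    cluster = seq_along(agg),
    start = vapply(agg, function(i) min(g$start[i]), integer(1)),
    end = vapply(agg, function(i) max(g$end[i]), integer(1)),
    strand = vapply(agg, function(i) paste(unique(g$strand[i]), collapse = ""),
                    character(1)),
    members = I(unname(lapply(agg, function(i) g$gene_id[i]))),
    row.names = NULL)
}

#' Merge divergently transcribed cluster pairs
#'
#' Adjacent clusters where the left one lies entirely on the minus strand and
#' the right one entirely on the plus strand are transcribed away from each
#' other and share an upstream regulatory region. Such a pair is merged into
#' one neighborhood cluster iff the gap between them lies in
#' `[min_gap, max_gap]` (inclusive). Merging is applied once, left to right:
#' a cluster consumed by a merge is not considered again, and mixed-strand
#' (already merged) clusters never merge further.
#'
#' @param clusters output of [call_same_strand_clusters()], ordered by
#'   leftmost coordinate.
#' @param min_gap,max_gap inclusive gap bounds in bp (defaults 200 and 1000).
#' @return data.frame in the same shape; merged rows carry strand `"-+"`.
#' @export
merge_divergent_clusters <- function(clusters, min_gap = 200, max_gap = 1000) {
  cl <- as.data.frame(clusters)
  n <- nrow(cl)
  if (n <= 1L) return(cl)
  if (is.unsorted(cl$start)) stop("clusters must be ordered by start")
  # a cluster contained in its predecessor cannot come from the same-strand
  # caller; merely touching spans (opposite-strand gene overlap) are legal
  # and simply fail the gap test below
  if (any(cl$end[-1] <= cl$end[-n])) stop("clusters overlap")
  keep <- rep(TRUE, n)
  i <- 1L
  while (i < n) {
    gap <- cl$start[i + 1L] - cl$end[i]
    if (identical(cl$strand[i], "-") && identical(cl$strand[i + 1L], "+") &&
        gap >= min_gap && gap <= max_gap) {
      cl$end[i] <- cl$end[i + 1L]
      cl$strand[i] <- "-+"
      cl$members[[i]] <- c(cl$members[[i]], cl$members[[i + 1L]])
      keep[i + 1L] <- FALSE
      i <- i + 2L  # no chained re-merge through the pair just formed
    } else {
      i <- i + 1L
    }
  }
  out <- cl[keep, , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Call neighborhood clusters for a whole genome collection
#'
#' Applies [call_same_strand_clusters()] then [merge_divergent_clusters()]
#' per contig and assigns globally unique cluster ids
#' `"<genome>|<contig>|n<k>"`.
#'
#' @param collection a [genome_collection()].
#' @param max_gap same-strand gap threshold (bp, default 250).
#' @param div_min,div_max divergent-merge gap bounds (bp, defaults 200, 1000).
#' @return data.frame of class `neighborhood_set`: one row per gene with
#'   columns `genome_id`, `contig_id`, `cluster_id`, `gene_id`, `protein_id`,
#'   `strand`, `start`, `end`.
#' @export
call_neighborhoods <- function(collection, max_gap = 250,
                               div_min = 200, div_max = 1000) {
  g <- collection$genes
  pieces <- split(g, list(g$genome_id, g$contig_id), drop = TRUE)
  res <- lapply(pieces, function(cg) {
    cg <- cg[order(cg$start, cg$end, cg$gene_id), , drop = FALSE]
    cl <- call_same_strand_clusters(cg, max_gap = max_gap)
    cl <- merge_divergent_clusters(cl, min_gap = div_min, max_gap = div_max)
    mem <- rep(seq_len(nrow(cl)), lengths(cl$members))
    ids <- unlist(cl$members, use.names = FALSE)
    idx <- match(ids, cg$gene_id)
    data.frame(
      genome_id = cg$genome_id[idx], contig_id = cg$contig_id[idx],
      cluster_id = sprintf("%s|%s|n%03d", cg$genome_id[idx],
                           cg$contig_id[idx], mem),
      gene_id = ids, protein_id = cg$protein_id[idx],
      strand = cg$strand[idx], start = cg$start[idx], end = cg$end[idx],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(genome_id = character(0), contig_id = character(0),
                      cluster_id = character(0), gene_id = character(0),
                      protein_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0))
  }
  out <- out[order(out$genome_id, out$contig_id, out$start,
                   out$end, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("neighborhood_set", "data.frame")
  out
}

#' Neighbors of a protein within its neighborhood cluster
#'
#' @param protein_id a protein present in the collection.
#' @param neighborhoods a `neighborhood_set` from [call_neighborhoods()].
#' @return Character vector of the other member proteins of the protein's
#'   cluster (empty for a singleton gene).
#' @export
neighbors_of <- function(protein_id, neighborhoods) {
  row <- which(neighborhoods$protein_id == protein_id)
  if (length(row) == 0L) stop("unknown protein: ", protein_id)
  cl <- neighborhoods$cluster_id[row[1]]
  mem <- neighborhoods$protein_id[neighborhoods$cluster_id == cl]
  setdiff(mem, protein_id)
}
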
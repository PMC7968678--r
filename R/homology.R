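# Tiered protein clustering from pairwise similarity hits, and query-to-
# database mapping. A cluster is a connected component of the similarity
# graph at an E-value cutoff; stricter cutoffs refine looser ones.

#' Resolve duplicate similarity hits to the best per pair
#'
#' Keeps, for each (query, subject) pair, the hit with minimum E-value,
#' breaking ties by maximum bitscore.
#'
#' @param hits a `similarity_hits` data.frame.
#' @return The de-duplicated hits.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, hits$subject_id, hits$e_value, -hits$bitscore)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(h$query_id, h$subject_id, sep = "\r"))
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster proteins at an E-value tier
#'
#' Builds the undirected graph whose edge (a, b) exists iff the best E-value
#' between a and b in either direction is at most `tier`, and takes connected
#' components. Self-hits are ignored; proteins without hits are singletons.
#' Cluster ids are the lexicographically smallest member id, so ids are
#' stable across runs and input orderings.
#'
#' @param hits a `similarity_hits` data.frame (all-vs-all).
#' @param protein_universe character vector of every protein to assign
#'   (including hit-less ones).
#' @param tier E-value cutoff (> 0), e.g. one of `1e-10`, `1e-50`, `1e-100`.
#' @return Object of class `protein_clustering`: list with `tier` and
#'   `assignment` (named character vector protein_id -> cluster_id).
#' @export
cluster_proteins <- function(hits, protein_universe, tier) {
  stopifnot(tier > 0)
  protein_universe <- sort(unique(protein_universe))
  out <- setdiff(unique(c(hits$query_id, hits$subject_id)), protein_universe)
  if (length(out)) {
    stop("hit references protein outside universe: ", out[1])
  }
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h)) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    key <- paste(a, b, sep = "\r")
    e <- tapply(h$e_value, key, min)          # best direction of the pair
    pair <- do.call(rbind, strsplit(names(e)[e <= tier], "\r", fixed = TRUE))
  } else {
    pair <- NULL
  }
  gr <- igraph::make_empty_graph(n = 0, directed = FALSE)
  gr <- igraph::add_vertices(gr, length(protein_universe),
                             name = protein_universe)
  if (!is.null(pair) && nrow(pair)) {
    gr <- igraph::add_edges(gr, t(pair))
  }
  comp <- igraph::components(gr)$membership
  ids <- tapply(names(comp), comp, min)       # smallest member names cluster
  assignment <- setNames(as.character(ids[as.character(comp)]), names(comp))
  structure(list(tier = tier, assignment = assignment[protein_universe]),
            class = "protein_clustering")
}

#' @export
print.protein_clustering <- function(x, ...) {
  cat(sprintf("protein_clustering @ tier %.3g: %d proteins in %d clusters\n",
              x$tier, length(x$assignment),
              length(unique(x$assignment))))
  invisible(x)
}

#' Map query proteins into the database by best similarity hit
#'
#' For each query, the best database hit (minimum E-value, ties by maximum
#' bitscore) is retained if it passes the E-value cutoff; at most
#' `max_targets` hits are kept per query. Queries with no passing hit are
#' reported as unmapped.
#'
#' @param query_hits `similarity_hits` of query-vs-database searches.
#' @param max_targets maximum matches kept per query (default 1).
#' @param e_cutoff E-value cutoff (default `1e-25`).
#' @return data.frame `query_id`, `subject_id`, `pct_identity`, `e_value`,
#'   `bitscore`, with attribute `unmapped` (character vector of query ids
#'   whose best hit failed the cutoff).
#' @export
map_query <- function(query_hits, max_targets = 1, e_cutoff = 1e-25) {
  if (nrow(query_hits) == 0L) {
    out <- query_hits
    attr(out, "unmapped") <- character(0)
    return(out)
  }
  ord <- order(query_hits$query_id, query_hits$e_value, -query_hits$bitscore)
  h <- query_hits[ord, , drop = FALSE]
  passing <- h[h$e_value <= e_cutoff, , drop = FALSE]
  kept <- do.call(rbind, lapply(split(passing, passing$query_id),
                                head, n = max_targets))
  if (is.null(kept)) kept <- passing
  rownames(kept) <- NULL
  attr(kept, "unmapped") <- setdiff(unique(h$query_id),
                                    unique(kept$query_id))
  kept
}
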
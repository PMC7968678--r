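# Genome neighborhood network: a star graph of a query protein cluster and
# the clusters observed adjacent to it, sized by conservation score, with
# hypergeometric GO enrichment over the neighborhood genes.

#' Build the genome neighborhood network for a query protein
#'
#' One subgraph per clustering tier. The query cluster is drawn as a
#' hexagon; each neighbor cluster (any cluster sharing a neighborhood with
#' the query's cluster in at least one genome) is an ellipse whose size
#' scales linearly from `s_min` to `s_max` with its raw Phylo score
#' (`s_min + (s_max - s_min) * raw / raw_max`); when every neighbor is
#' nonconserved (`raw_max = 0`) all neighbors take the minimal size.
#'
#' @param query_protein a database protein id (map external queries with
#'   [map_query()] first).
#' @param clusterings named list of [cluster_proteins()] results, one per
#'   tier (e.g. `"1e-10"`, `"1e-50"`, `"1e-100"`).
#' @param score_tables named list of [build_phylo_scores()] tables, same
#'   names.
#' @param s_min,s_max node size range in display units (defaults 20, 80).
#' @return Object of class `gnn_graph`: list with `query` and per-tier
#'   `tiers[[tier]]$nodes` / `$edges` data.frames.
#' @export
build_gnn <- function(query_protein, clusterings, score_tables,
                      s_min = 20, s_max = 80) {
  stopifnot(identical(names(clusterings), names(score_tables)))
  tiers <- lapply(names(clusterings), function(tier) {
    cl <- clusterings[[tier]]
    qcl <- unname(cl$assignment[query_protein])
    if (is.na(qcl) || is.null(qcl)) {
      stop("query protein '", query_protein,
           "' is not in the database at tier ", tier,
           "; map it with map_query() first")
    }
    st <- score_tables[[tier]]
    nb <- st[st$focal == qcl, , drop = FALSE]
    raw_max <- if (nrow(nb)) max(nb$raw) else 0
    size <- if (raw_max > 0) s_min + (s_max - s_min) * nb$raw / raw_max
            else rep(s_min, nrow(nb))
    nodes <- rbind(
      data.frame(id = qcl, role = "query", shape = "hexagon",
                 size = s_max, raw_score = NA_real_, conserved = NA,
                 stringsAsFactors = FALSE),
      if (nrow(nb)) data.frame(
        id = nb$neighbor, role = "neighbor", shape = "ellipse",
        size = size, raw_score = nb$raw, conserved = nb$raw > 0,
        stringsAsFactors = FALSE))
    edges <- if (nrow(nb)) {
      data.frame(source = qcl, target = nb$neighbor,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source = character(0), target = character(0))
    }
    list(nodes = nodes, edges = edges)
  })
  names(tiers) <- names(clusterings)
  structure(list(query = query_protein, tiers = tiers), class = "gnn_graph")
}

#' @export
print.gnn_graph <- function(x, ...) {
  for (tier in names(x$tiers)) {
    cat(sprintf("tier %s: %d nodes, %d edges\n", tier,
                nrow(x$tiers[[tier]]$nodes), nrow(x$tiers[[tier]]$edges)))
  }
  invisible(x)
}

#' GO-term enrichment among neighborhood genes
#'
#' One-sided hypergeometric upper-tail test per term: drawing the annotated
#' neighborhood genes from the background of all GO-annotated database
#' proteins, is the term over-represented? P-values are Benjamini-Hochberg
#' adjusted across the tested terms and rows are sorted by raw p.
#'
#' @param neighbor_gene_set character vector of neighborhood protein ids.
#' @param background_annotations `go_annotations` over the database (the
#'   background universe is its annotated protein set).
#' @param vocabulary terms to test; default: every term observed in the
#'   background.
#' @return data.frame `go_id`, `x` (annotated neighbors with the term),
#'   `n_draw` (annotated neighbors), `K` (background proteins with the
#'   term), `N` (background annotated proteins), `p`, `p_adj`.
#' @export
enrich_go <- function(neighbor_gene_set, background_annotations,
                      vocabulary = NULL) {
  stopifnot(inherits(background_annotations, "go_annotations"))
  ann <- background_annotations$annotations
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(ann, use.names = FALSE)))
  }
  neighbors <- intersect(unique(neighbor_gene_set), names(ann))
  if (length(neighbor_gene_set) == 0L) {
    return(data.frame(go_id = character(0), x = integer(0),
                      n_draw = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), p_adj = numeric(0)))
  }
  N <- length(ann)
  n_draw <- length(neighbors)
  rows <- lapply(vocabulary, function(term) {
    K <- sum(vapply(ann, function(t) term %in% t, logical(1)))
    x <- sum(vapply(neighbors, function(pr) term %in% ann[[pr]], logical(1)))
    p <- phyper(x - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(go_id = term, x = x, n_draw = n_draw, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a genome neighborhood network
#'
#' Writes either Cytoscape-elements JSON (nodes with `data` id/label/score/
#' tier and `style` shape/size; edges with source/target) or GraphML via
#' igraph. The tier is encoded as a node/edge attribute so all tiers live in
#' one file.
#'
#' @param graph a [build_gnn()] result.
#' @param path output file.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "gnn_graph"))
  if (format == "json") {
    elements <- list(nodes = list(), edges = list())
    for (tier in names(graph$tiers)) {
      sub <- graph$tiers[[tier]]
      for (i in seq_len(nrow(sub$nodes))) {
        nd <- sub$nodes[i, ]
        elements$nodes[[length(elements$nodes) + 1L]] <- list(
          data = list(id = paste(tier, nd$id, sep = ":"), label = nd$id,
                      score = if (is.na(nd$raw_score)) NULL else nd$raw_score,
                      role = nd$role, tier = tier),
          style = list(shape = nd$shape, width = nd$size, height = nd$size))
      }
      for (i in seq_len(nrow(sub$edges))) {
        ed <- sub$edges[i, ]
        elements$edges[[length(elements$edges) + 1L]] <- list(
          data = list(id = paste(tier, ed$source, ed$target, sep = ":"),
                      source = paste(tier, ed$source, sep = ":"),
                      target = paste(tier, ed$target, sep = ":"),
                      tier = tier))
      }
    }
    jsonlite::write_json(list(elements = elements), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    return(invisible(path))
  }
  nodes <- do.call(rbind, lapply(names(graph$tiers), function(tier) {
    nd <- graph$tiers[[tier]]$nodes
    nd$name <- paste(tier, nd$id, sep = ":")
    nd$tier <- tier
    nd
  }))
  edges <- do.call(rbind, lapply(names(graph$tiers), function(tier) {
    ed <- graph$tiers[[tier]]$edges
    if (nrow(ed) == 0L) return(NULL)
    data.frame(from = paste(tier, ed$source, sep = ":"),
               to = paste(tier, ed$target, sep = ":"),
               tier = tier, stringsAsFactors = FALSE)
  }))
  nodes$raw_score[is.na(nodes$raw_score)] <- -1  # GraphML has no NA
  nodes$conserved <- as.integer(nodes$conserved)
  nodes$conserved[is.na(nodes$conserved)] <- -1L
  nodes$cluster <- nodes$id  # 'id' is reserved by the GraphML writer
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else edges,
    directed = TRUE,
    vertices = nodes[, c("name", "cluster", "role", "shape", "size",
                         "raw_score", "conserved", "tier")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
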
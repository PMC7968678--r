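mk_clustering <- function(assignment, tier = 1e-10) {
  structure(list(tier = tier, assignment = assignment),
            class = "protein_clustering")
}

mk_st <- function(focal, neighbor, raw) {
  st <- data.frame(focal = focal, neighbor = neighbor,
                   tier = rep(1e-10, length(focal)),
                   raw = raw, n_support = ifelse(raw > 0, 2L, 1L),
                   supporting = I(as.list(rep("G1", length(focal)))),
                   stringsAsFactors = FALSE)
  class(st) <- c("phylo_score_table", "data.frame")
  st
}

test_that("the neighborhood network is a sized star per tier", {
  cl <- mk_clustering(c(q1 = "cq"))
  nb <- sprintf("c%02d", 1:11)
  st <- mk_st(rep("cq", 11), nb, seq(0.5, 5.5, by = 0.5))
  g <- build_gnn("q1", list(`1e-10` = cl), list(`1e-10` = st))
  nodes <- g$tiers[["1e-10"]]$nodes
  expect_equal(nrow(nodes), 12L)                # query + 11 neighbors
  expect_equal(nrow(g$tiers[["1e-10"]]$edges), 11L)
  expect_equal(sum(nodes$role == "query"), 1L)
  expect_equal(nodes$shape[nodes$role == "query"], "hexagon")
  # node size is linear in the raw score between 20 and 80
  nbn <- nodes[nodes$role == "neighbor", ]
  expect_equal(min(nbn$size), 20 + 60 * 0.5 / 5.5)
  expect_equal(max(nbn$size), 80)
  expect_equal(order(nbn$size), order(nbn$raw_score))
  # singleton query: one node, no edges
  g0 <- build_gnn("q1", list(`1e-10` = cl),
                  list(`1e-10` = mk_st(character(0), character(0), numeric(0))))
  expect_equal(nrow(g0$tiers[["1e-10"]]$nodes), 1L)
  expect_equal(nrow(g0$tiers[["1e-10"]]$edges), 0L)
  # all-nonconserved neighbors share the minimal size
  gz <- build_gnn("q1", list(`1e-10` = cl),
                  list(`1e-10` = mk_st(rep("cq", 3), nb[1:3], rep(0, 3))))
  expect_equal(gz$tiers[["1e-10"]]$nodes$size[-1], rep(20, 3))
  expect_false(any(gz$tiers[["1e-10"]]$nodes$conserved[-1]))
  # unmapped queries are redirected to the mapping step
  expect_error(build_gnn("zz", list(`1e-10` = cl), list(`1e-10` = st)),
               "map_query")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  ann <- go_annotation_table(data.frame(
    protein_id = sprintf("p%03d", rep(1:100, times = c(rep(2, 10), rep(1, 90)))),
    go_id = c(rep(c("GO:0009523", "GO:0030089"), 10), rep("GO:0030089", 90))))
  # 10 of 100 proteins carry GO:0009523; draw 5 neighbors, 3 annotated
  nbrs <- c(sprintf("p%03d", 1:3), sprintf("p%03d", 50:51))
  res <- enrich_go(nbrs, ann)
  row <- res[res$go_id == "GO:0009523", ]
  expect_equal(row$x, 3L)
  expect_equal(row$K, 10L)
  expect_equal(row$N, 100L)
  expect_equal(row$p, 499752 / 75287520, tolerance = 1e-12)
  # the universal term is never enriched
  expect_equal(res$p[res$go_id == "GO:0030089"], 1)
  # p-values lie in (0, 1] even for x = 0
  expect_true(all(res$p > 0 & res$p <= 1))
  # neighbor set == background: p = 1 everywhere
  all_p <- enrich_go(names(ann$annotations), ann)$p
  expect_equal(all_p, rep(1, length(all_p)))
  # empty neighbor set: empty table
  expect_equal(nrow(enrich_go(character(0), ann)), 0L)
})

test_that("enrichment equals brute-force tail sums on random tables", {
  set.seed(12)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n_draw <- sample(1:N, 1)
    prot <- sprintf("b%03d", 1:N)
    tab <- data.frame(protein_id = prot,
                      go_id = rep("GO:0034357", N))
    tab <- rbind(tab, data.frame(protein_id = prot[1:K],
                                 go_id = "GO:0009521"))
    ann <- go_annotation_table(tab)
    nbrs <- sample(prot, n_draw)
    res <- enrich_go(nbrs, ann, vocabulary = "GO:0009521")
    x <- sum(nbrs %in% prot[1:K])
    expect_equal(res$p, hyper_tail_enum(x, K, N, n_draw), tolerance = 1e-12)
  }
})

test_that("graph export round-trips through JSON and GraphML", {
  cl <- mk_clustering(c(q1 = "cq"))
  st <- mk_st(rep("cq", 3), c("c1", "c2", "c3"), c(1, 2, 0))
  g <- build_gnn("q1", list(`1e-10` = cl, `1e-50` = cl),
                 list(`1e-10` = st, `1e-50` = st))
  fj <- withr::local_tempfile(fileext = ".json")
  export_graph(g, fj, "json")
  back <- jsonlite::read_json(fj)
  expect_length(back$elements$nodes, 8L)   # 4 nodes per tier
  expect_length(back$elements$edges, 6L)
  tiers <- vapply(back$elements$nodes, function(nd) nd$data$tier, "")
  expect_setequal(unique(tiers), c("1e-10", "1e-50"))
  fg <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, fg, "graphml")
  ig <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::vcount(ig), 8L)
  expect_equal(igraph::ecount(ig), 6L)
  # empty graph exports a valid file
  g0 <- build_gnn("q1", list(`1e-10` = cl),
                  list(`1e-10` = mk_st(character(0), character(0), numeric(0))))
  export_graph(g0, fj, "json")
  back0 <- jsonlite::read_json(fj)
  expect_length(back0$elements$nodes, 1L)
  expect_length(back0$elements$edges, 0L)
})
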
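test_that("Jaccard gene-content distance follows the set formula", {
  expect_equal(genome_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(genome_distance(c("a"), c("b")), 1)
  expect_equal(genome_distance(c("c1", "c2"), c("c2", "c3")), 2 / 3)
  expect_error(genome_distance(character(0), character(0)), "empty")
  # metric properties on random genomes
  set.seed(3)
  for (i in 1:20) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    c <- sample(letters, sample(1:20, 1))
    dab <- genome_distance(a, b)
    expect_equal(dab, genome_distance(b, a))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_lte(dab, genome_distance(a, c) + genome_distance(c, b) + 1e-12)
  }
})

test_that("distance matrix enumerates all unordered pairs", {
  sim <- tiny_sim()
  cl <- cluster_proteins(sim$hits, sim$collection$genes$protein_id, 1e-10)
  D <- build_distance_matrix(sim$collection, cl)
  G <- length(genome_ids(sim$collection))
  expect_equal(attr(D, "n_pairs"), G * (G - 1) / 2)
  expect_equal(unname(diag(D)), rep(0, G))
  expect_true(isSymmetric(unname(D)))
  # a duplicated genome sits at distance zero
  g2 <- sim$collection$genes[sim$collection$genes$genome_id ==
                               genome_ids(sim$collection)[1], ]
  g2$genome_id <- "Gdup"
  g2$protein_id <- paste0("dup_", g2$protein_id)
  g2$gene_id <- g2$protein_id
  both <- genome_collection(rbind(sim$collection$genes, g2))
  fam <- sub("^.*_F", "F", both$genes$protein_id)
  cl2 <- structure(list(tier = 1e-10,
                        assignment = setNames(fam, both$genes$protein_id)),
                   class = "protein_clustering")
  D2 <- build_distance_matrix(both, cl2)
  expect_equal(D2[genome_ids(sim$collection)[1], "Gdup"], 0)
})

test_that("the NJ genome tree is exact on additive distances", {
  # two genomes: single edge of length d
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- build_tree(D)
  expect_equal(sum(tr$edge.length), 0.4)
  expect_error(build_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # equidistant leaves: star-like tree, total length G*d/2,
  # pairwise path lengths reproduced
  G <- 5; d <- 0.6
  De <- matrix(d, G, G); diag(De) <- 0
  dimnames(De) <- list(paste0("g", 1:G), paste0("g", 1:G))
  tre <- build_tree(De)
  expect_equal(sum(tre$edge.length), G * d / 2, tolerance = 1e-10)
  # additive 4-leaf matrix from a known tree is reproduced exactly
  set.seed(9)
  ref <- ape::rtree(4)
  Da <- ape::cophenetic.phylo(ref)
  tra <- build_tree(Da)
  expect_equal(ape::cophenetic.phylo(tra)[rownames(Da), colnames(Da)], Da,
               tolerance = 1e-10)
})

test_that("phylo scores are phylogenetic diversity of the supporting set", {
  sim <- tiny_sim()
  pipe <- run_pipeline(sim$collection, sim$hits, sim$annotations)
  st <- pipe$score_table
  # zero iff at most one supporting genome (nonconserved)
  expect_true(all((st$raw == 0) == (st$n_support <= 1)))
  # never exceeds total tree length; equality only when all genomes support
  total <- sum(pipe$tree$edge.length)
  expect_true(all(st$raw <= total + 1e-12))
  full <- st$n_support == length(genome_ids(sim$collection))
  expect_true(all(abs(st$raw[full] - total) < 1e-12))
  # two supporting genomes -> path length between them
  two <- which(st$n_support == 2)[1]
  if (!is.na(two)) {
    pairdist <- ape::cophenetic.phylo(pipe$tree)
    s <- st$supporting[[two]]
    expect_equal(st$raw[two], pairdist[s[1], s[2]], tolerance = 1e-12)
  }
  # single-pair accessor agrees with the table
  k <- which(st$n_support >= 2)[1]
  ps <- phylo_score(st$focal[k], st$neighbor[k], pipe$neighborhoods,
                    pipe$clustering, pipe$tree)
  expect_equal(ps$raw, st$raw[k])
  expect_equal(ps$supporting, st$supporting[[k]])
  expect_error(phylo_score("nope", st$neighbor[k], pipe$neighborhoods,
                           pipe$clustering, pipe$tree), "unknown cluster")
})

test_that("phylogenetic diversity matches brute force and is monotone", {
  for (seed in 1:30) {
    set.seed(seed)
    nt <- sample(4:12, 1)
    tr <- ape::rtree(nt)
    s <- sample(tr$tip.label, sample(2:nt, 1))
    expect_equal(phylogenetic_diversity(tr, s), pd_bruteforce(tr, s),
                 tolerance = 1e-12)
    # adding a leaf never decreases the score
    extra <- setdiff(tr$tip.label, s)
    if (length(extra)) {
      expect_gte(phylogenetic_diversity(tr, c(s, extra[1])) + 1e-12,
                 phylogenetic_diversity(tr, s))
    }
    expect_lte(phylogenetic_diversity(tr, s),
               sum(tr$edge.length) + 1e-12)
  }
  expect_equal(phylogenetic_diversity(ape::rtree(5), "t1"), 0)
})

test_that("quantile bins follow the tertile contract", {
  bins <- fit_quantile_bins(c(0, 0, 1:9))
  expect_equal(bins$q1, 3)
  expect_equal(bins$q2, 6)
  expect_equal(discretize(c(0, 0.5, 3, 4, 6, 6.5, 100), bins),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(discretize(-1, bins), "non-negative")
  expect_warning(fit_quantile_bins(c(0, 2, 2, 2)), "fewer than 3")
  b2 <- suppressWarnings(fit_quantile_bins(c(0, 2, 2, 2)))
  expect_equal(b2$q1, 2)
  expect_equal(b2$q2, 2)
})
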
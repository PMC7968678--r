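# Independent oracles, deliberately written in the most naive style
# (explicit pair loops, literal formulas) so they share no code path with
# the package implementations they check.

# --- neighborhood calling: O(n^2) pairwise rule checker -------------------

# genes: data.frame(gene_id, start, end, strand) sorted by (start,end,gene_id)
brute_force_neighborhoods <- function(genes, max_gap = 250,
                                      div_min = 200, div_max = 1000) {
  n <- nrow(genes)
  if (n == 0L) return(list())
  # same-strand stage: edge between every pair passing the rules, closure
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (genes$strand[i] != genes$strand[j]) next
      gap <- genes$start[j] - genes$end[i]
      if (gap > max_gap) next
      between <- seq_len(n) > i & seq_len(n) < j
      if (any(genes$strand[between] != genes$strand[i])) next
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  clusters <- lapply(sort(unique(comp)), function(cid) which(comp == cid))
  # order clusters by leftmost member
  clusters <- clusters[order(vapply(clusters, function(ix)
    min(genes$start[ix]), numeric(1)))]
  # divergent merge, once left to right
  merged <- list()
  i <- 1L
  while (i <= length(clusters)) {
    if (i < length(clusters)) {
      left <- clusters[[i]]; right <- clusters[[i + 1L]]
      l_str <- unique(genes$strand[left])
      r_str <- unique(genes$strand[right])
      gap <- min(genes$start[right]) - max(genes$end[left])
      if (identical(l_str, "-") && identical(r_str, "+") &&
          gap >= div_min && gap <= div_max) {
        merged[[length(merged) + 1L]] <- c(left, right)
        i <- i + 2L
        next
      }
    }
    merged[[length(merged) + 1L]] <- clusters[[i]]
    i <- i + 1L
  }
  lapply(merged, function(ix) sort(genes$gene_id[ix]))
}

# random contig whose genes overlap at most their immediate predecessor
random_contig <- function(n, seed) {
  set.seed(seed)
  start <- integer(n); end <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    gap <- sample(c(-100:600), 1)
    len <- sample(200:1200, 1)
    start[i] <- max(pos + gap, if (i > 1) start[i - 1] + 1L else 0L, 0L)
    end[i] <- start[i] + len
    pos <- end[i]
  }
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             start = start, end = end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# package cluster membership as sorted gene-id sets, for comparison
called_sets <- function(genes, ...) {
  cl <- call_same_strand_clusters(genes, ...)
  cl <- merge_divergent_clusters(cl)
  sets <- lapply(cl$members, sort)
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# --- F1max: literal transcription of the evaluation equations ------------

f1max_literal <- function(truth, scores, thresholds = seq(0, 1, by = 0.1)) {
  n <- nrow(truth)
  best <- 0
  for (t in thresholds) {
    pr <- c(); rc <- c()
    m <- 0
    rc_sum <- 0
    pr_sum <- 0
    for (i in seq_len(n)) {
      Ti <- which(truth[i, ] == 1)
      Pi <- which(scores[i, ] >= t)
      inter <- length(intersect(Pi, Ti))
      rc_sum <- rc_sum + inter / length(Ti)
      if (length(Pi) >= 1) {
        m <- m + 1
        pr_sum <- pr_sum + inter / length(Pi)
      }
    }
    avg_rc <- rc_sum / n
    avg_pr <- if (m > 0) pr_sum / m else 0
    f1 <- if (m == 0 || avg_pr + avg_rc == 0) 0 else
      2 * avg_pr * avg_rc / (avg_pr + avg_rc)
    if (f1 > best) best <- f1
  }
  best
}

# --- phylogenetic diversity: edge-cut enumeration ------------------------

pd_bruteforce <- function(tree, leaves) {
  if (length(unique(leaves)) <= 1L) return(0)
  total <- 0
  n_edge <- nrow(tree$edge)
  for (e in seq_len(n_edge)) {
    # leaves below this edge (child side)
    child <- tree$edge[e, 2]
    below <- tips_below(tree, child)
    a <- length(intersect(leaves, below))
    b <- length(setdiff(leaves, below))
    if (a >= 1 && b >= 1) total <- total + tree$edge.length[e]
  }
  total
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

# --- hypergeometric upper tail: exhaustive sum ---------------------------

hyper_tail_enum <- function(x, K, N, n_draw) {
  ks <- x:min(n_draw, K)
  if (x > min(n_draw, K)) return(0)
  sum(choose(K, ks) * choose(N - K, n_draw - ks)) / choose(N, n_draw)
}

# --- RReliefF-style weights: naive accumulation --------------------------

rfml_naive <- function(X, Y, k_nn) {
  n <- nrow(X); p <- ncol(X); L <- ncol(Y)
  NdY <- 0; NdF <- numeric(p); NdYdF <- numeric(p); M <- 0
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(abs(X[i, ] - X[j, ]) / 3)
    others <- setdiff(order(d), i)
    nb <- others[seq_len(min(k_nn, n - 1))]
    for (j in nb) {
      dl <- sum(Y[i, ] != Y[j, ]) / L
      NdY <- NdY + dl
      for (f in seq_len(p)) {
        df <- abs(X[i, f] - X[j, f]) / 3
        NdF[f] <- NdF[f] + df
        NdYdF[f] <- NdYdF[f] + dl * df
      }
      M <- M + 1
    }
  }
  if (NdY == 0) return(numeric(p))
  NdYdF / NdY - (NdF - NdYdF) / (M - NdY)
}

# --- small shared fixtures ------------------------------------------------

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genomes = 14, n_families = 80,
                               n_planted_operons = 6, operon_size = 3,
                               clade_fraction = 0.6, labels_per_operon = 2,
                               noise = 0, seed = 11)
      cache <<- simulate_collection(cfg)
    }
    cache
  }
})

# separable 40-instance fixture: feature f_k is 3 exactly when label k is on
separable_fixture <- function(n = 40, L = 3, seed = 5) {
  set.seed(seed)
  Y <- matrix(0L, n, L, dimnames = list(NULL, paste0("GO:000000", seq_len(L))))
  for (i in seq_len(n)) Y[i, sample(seq_len(L), sample(seq_len(min(2, L)), 1))] <- 1L
  X <- Y * 3L
  colnames(X) <- paste0("feat", seq_len(L))
  list(X = X, Y = Y)
}
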
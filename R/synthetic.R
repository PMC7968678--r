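# Synthetic genome simulator: plants conserved operons carrying known GO
# labels across a simulated phylogeny, so that every pipeline stage can be
# validated end-to-end against known ground truth without any downloads.
#
# What it emulates: clade-restricted gene content (so gene-content Jaccard
# distances recover the tree), operons as same-strand gene runs with short
# intergenic gaps, divergently transcribed operon pairs, homology families
# recoverable at every clustering tier, and a neighborhood -> GO-label
# signal. What it does not emulate: sequence evolution (FASTA output is
# placeholder), annotation noise, redundancy, or horizontal transfer.

#' Simulation configuration
#'
#' Defaults define the reference study condition used throughout the test
#' suite: 30 genomes, 400 protein families, 12 planted operons of 4 families
#' carried by clades covering about 60% of the genomes, 2 GO labels per
#' operon from the 24-term default vocabulary, within-operon intergenic gaps
#' uniform on 10-200 bp, background gaps uniform on 400-5000 bp, a quarter
#' of operons placed as divergent pairs, and a 10% chance that a planted
#' neighbor is shuffled out of its operon in any given genome.
#'
#' @param n_genomes number of genomes.
#' @param n_families number of protein families (ground-truth clusters).
#' @param n_planted_operons,operon_size planted operon count and size (>= 2).
#' @param clade_fraction approximate fraction of genomes carrying each
#'   operon.
#' @param labels_per_operon GO labels attached to each operon's focal family.
#' @param gap_within,gap_between intergenic gap ranges (bp) inside operons
#'   and between unrelated genes.
#' @param divergent_rate probability an operon is planted as a divergent
#'   pair (two blocks on opposite strands, 200-1000 bp apart).
#' @param noise probability a planted non-focal member is relocated away
#'   from its operon in a given genome.
#' @param seed RNG seed.
#' @param vocabulary label vocabulary (default [default_go_vocabulary()]).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 30, n_families = 400,
                              n_planted_operons = 12, operon_size = 4,
                              clade_fraction = 0.6, labels_per_operon = 2,
                              gap_within = c(10, 200),
                              gap_between = c(400, 5000),
                              divergent_rate = 0.25, noise = 0.1,
                              seed = 1,
                              vocabulary = default_go_vocabulary()) {
  stopifnot(operon_size >= 2, n_genomes >= 4,
            clade_fraction > 0, clade_fraction <= 1,
            divergent_rate >= 0, divergent_rate <= 1,
            noise >= 0, noise <= 1)
  if (n_planted_operons * operon_size > n_families) {
    stop("infeasible config: planted operons need more families than exist")
  }
  vocabulary <- as_vocabulary(vocabulary)
  if (labels_per_operon > nrow(vocabulary)) {
    stop("labels_per_operon exceeds vocabulary size")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# leaf sets of every node of the tree (tips first, then internals)
tree_clades <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  c(lapply(seq_len(n), function(i) tree$tip.label[i]),
    lapply(parts, function(p) tree$tip.label[p]))
}

#' Simulate a genome collection with planted operons
#'
#' Generates a genome tree (pure-birth process), assigns every protein
#' family to a clade (operon families to clades covering about
#' `clade_fraction` of the genomes), lays out each genome with operon
#' members co-placed at within-operon gaps and background genes far apart,
#' draws within-family similarity hits below 1e-120 and cross-family noise
#' hits above 1e-5 (so all clustering tiers recover the families exactly),
#' and annotates each operon's focal-family proteins with the operon's
#' labels.
#'
#' @param config a [simulation_config()].
#' @return Object of class `synthetic_collection`: list with `collection`
#'   ([genome_collection()]), `hits` (`similarity_hits`), `annotations`
#'   (`go_annotations`), `tree` (`ape::phylo`), `truth` (planted operons,
#'   (focal, neighbor) cluster pairs and informative feature columns), and
#'   `config`.
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genomes
  genomes <- sprintf("G%02d", seq_len(n))
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- genomes  # positional relabel, deterministic
  clades <- tree_clades(tree)
  clade_sizes <- lengths(clades)

  families <- sprintf("F%03d", seq_len(config$n_families))
  n_op <- config$n_planted_operons
  op_fams <- lapply(seq_len(n_op), function(o) {
    families[seq.int((o - 1) * config$operon_size + 1, o * config$operon_size)]
  })
  target <- config$clade_fraction * n
  tol <- max(2, round(0.15 * n))
  candidates <- which(abs(clade_sizes - target) <= tol & clade_sizes >= 2)
  if (length(candidates) == 0L) {
    candidates <- which.min(abs(clade_sizes - target))
  }
  op_clade <- candidates[sample.int(length(candidates), n_op, replace = TRUE)]
  op_divergent <- runif(n_op) < config$divergent_rate
  op_labels <- lapply(seq_len(n_op), function(o) {
    sort(sample(config$vocabulary$go_id, config$labels_per_operon))
  })

  bg_fams <- setdiff(families, unlist(op_fams))
  bg_clade <- seq_along(clades)[sample.int(length(clades),
                                           length(bg_fams), replace = TRUE)]
  names(bg_clade) <- bg_fams

  gene_rows <- list()
  for (g in genomes) {
    ops_here <- which(vapply(op_clade, function(cl) g %in% clades[[cl]],
                             logical(1)))
    singles <- bg_fams[vapply(bg_clade, function(cl) g %in% clades[[cl]],
                              logical(1))]
    blocks <- list()
    for (o in ops_here) {
      fams <- op_fams[[o]]
      keep <- c(TRUE, runif(length(fams) - 1) >= config$noise)  # focal stays
      singles <- c(singles, fams[!keep])
      fams <- fams[keep]
      if (length(fams) == 0L) next
      blocks[[length(blocks) + 1L]] <-
        list(fams = fams, divergent = op_divergent[o] && length(fams) >= 2)
    }
    items <- c(blocks, lapply(singles, function(f)
      list(fams = f, divergent = FALSE)))
    if (length(items) == 0L) next
    items <- items[sample(length(items))]
    pos <- 0L
    for (it in items) {
      fams <- it$fams
      k <- length(fams)
      lens <- round(runif(k, 300, 2500))
      if (it$divergent) {
        n_left <- ceiling(k / 2)
        strands <- c(rep("-", n_left), rep("+", k - n_left))
        gaps <- c(0, round(runif(max(0, n_left - 1),
                                 config$gap_within[1], config$gap_within[2])),
                  round(runif(1, 200, 1000)),
                  round(runif(max(0, k - n_left - 1),
                              config$gap_within[1], config$gap_within[2])))
        gaps <- gaps[seq_len(k)]
      } else {
        strands <- rep(sample(c("+", "-"), 1), k)
        gaps <- c(0, round(runif(k - 1, config$gap_within[1],
                                 config$gap_within[2])))
      }
      for (i in seq_len(k)) {
        pos <- pos + if (i == 1L) {
          round(runif(1, config$gap_between[1], config$gap_between[2]))
        } else gaps[i]
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = paste0(g, "_", fams[i]),
          protein_id = paste0(g, "_", fams[i]),
          genome_id = g, contig_id = "c1",
          start = pos, end = pos + lens[i], strand = strands[i],
          stringsAsFactors = FALSE)
        pos <- pos + lens[i]
      }
    }
  }
  genes <- do.call(rbind, gene_rows)
  collection <- genome_collection(genes)

  # similarity hits: star within each family, noise across families
  fam_members <- split(genes$protein_id,
                       sub("^G[0-9]+_", "", genes$protein_id))
  hit_rows <- list()
  for (f in names(fam_members)) {
    mem <- sort(fam_members[[f]])
    if (length(mem) < 2L) next
    k <- length(mem) - 1L
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = mem[1], subject_id = mem[-1],
      pct_identity = round(runif(k, 90, 100), 1),
      e_value = 10^runif(k, -180, -130),
      bitscore = round(runif(k, 800, 2000), 1),
      stringsAsFactors = FALSE)
  }
  n_cross <- min(500L, nrow(genes))
  q <- sample(genes$protein_id, n_cross, replace = TRUE)
  s <- sample(genes$protein_id, n_cross, replace = TRUE)
  diff_fam <- sub("^G[0-9]+_", "", q) != sub("^G[0-9]+_", "", s)
  hit_rows[[length(hit_rows) + 1L]] <- data.frame(
    query_id = q[diff_fam], subject_id = s[diff_fam],
    pct_identity = round(runif(sum(diff_fam), 20, 35), 1),
    e_value = 10^runif(sum(diff_fam), -4, 1),
    bitscore = round(runif(sum(diff_fam), 25, 60), 1),
    stringsAsFactors = FALSE)
  hits <- do.call(rbind, hit_rows)
  class(hits) <- c("similarity_hits", "data.frame")

  # annotations: focal-family proteins carry the operon's labels
  ann_rows <- list()
  for (o in seq_len(n_op)) {
    focal <- op_fams[[o]][1]
    carriers <- intersect(genomes, clades[[op_clade[o]]])
    for (g in carriers) {
      pid <- paste0(g, "_", focal)
      if (!pid %in% genes$protein_id) next
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        protein_id = pid, go_id = op_labels[[o]], stringsAsFactors = FALSE)
    }
  }
  ann_tab <- do.call(rbind, ann_rows)
  annotations <- go_annotation_table(ann_tab, config$vocabulary)

  # ground truth: cluster id of a family = its smallest member protein id
  fam_cluster <- vapply(fam_members, function(m) min(m), character(1))
  planted_pairs <- do.call(rbind, lapply(seq_len(n_op), function(o) {
    fams <- op_fams[[o]]
    data.frame(operon = o, focal_family = fams[1],
               neighbor_family = fams[-1],
               focal_cluster = unname(fam_cluster[fams[1]]),
               neighbor_cluster = unname(fam_cluster[fams[-1]]),
               stringsAsFactors = FALSE)
  }))
  truth <- list(
    operons = data.frame(
      operon = seq_len(n_op),
      focal_family = vapply(op_fams, `[`, character(1), 1),
      divergent = op_divergent,
      n_carriers = clade_sizes[op_clade],
      labels = I(op_labels),
      families = I(op_fams),
      carriers = I(lapply(op_clade, function(cl) sort(clades[[cl]])))),
    planted_pairs = planted_pairs,
    informative_features = sort(unique(planted_pairs$neighbor_cluster)),
    family_cluster = fam_cluster)

  structure(list(collection = collection, hits = hits,
                 annotations = annotations, tree = tree, truth = truth,
                 config = config),
            class = "synthetic_collection")
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat(sprintf(
    "synthetic_collection: %d genomes, %d genes, %d planted operons, %d annotated proteins\n",
    length(genome_ids(x$collection)), nrow(x$collection$genes),
    nrow(x$truth$operons), length(x$annotations$annotations)))
  invisible(x)
}

#' Write a simulated collection to disk
#'
#' Emits exactly the formats the readers consume: the native gene-table TSV,
#' 12-column similarity hits, the 2-column GO annotation TSV, the genome
#' tree in Newick, and a JSON ground-truth file.
#'
#' @param sim a [simulate_collection()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(sim$collection, file.path(dir, "genes.tsv"))
  write_similarity_hits(sim$hits, file.path(dir, "hits.tsv"))
  ann <- sim$annotations$annotations
  tab <- data.frame(protein_id = rep(names(ann), lengths(ann)),
                    go_id = unlist(ann, use.names = FALSE))
  write.table(tab, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(planted_pairs = sim$truth$planted_pairs,
         informative_features = sim$truth$informative_features),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Permute label rows as a negative control
#'
#' Randomly reassigns whole label rows to instances, preserving every
#' label's prevalence while destroying any feature-label association. The
#' applied permutation is recorded so the operation can be inverted.
#'
#' @param labels binary label matrix.
#' @param seed RNG seed.
#' @return Permuted matrix (original rownames) with attribute `permutation`.
#' @export
permute_labels <- function(labels, seed = 1) {
  set.seed(seed)
  perm <- sample(nrow(labels))
  out <- labels[perm, , drop = FALSE]
  rownames(out) <- rownames(labels)
  attr(out, "permutation") <- perm
  out
}
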
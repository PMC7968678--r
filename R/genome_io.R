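# Readers/writers for the external formats the pipeline touches, and the
# in-memory genome model. Internal coordinates are 0-based half-open
# throughout; GFF3 (1-based inclusive) is converted once, on read.

#' Construct a genome collection
#'
#' The canonical in-memory model of one or more annotated genomes: a flat
#' gene table plus a per-contig circularity flag. Genes are sorted within
#' each contig by `(start, end, gene_id)`.
#'
#' @param genes data.frame with columns `gene_id`, `protein_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`. Coordinates are 0-based half-open;
#'   strand is `"+"` or `"-"`.
#' @param circular named logical vector keyed by `"genome_id/contig_id"`;
#'   contigs not named are linear. Circular contigs are stored but wraparound
#'   neighborhoods are not computed.
#' @return An object of class `genome_collection`.
#' @export
genome_collection <- function(genes, circular = logical(0)) {
  req <- c("gene_id", "protein_id", "genome_id", "contig_id",
           "start", "end", "strand")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols)) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes)[, req]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(is.na(genes$start)) || any(is.na(genes$end))) {
    stop("non-integer gene coordinates")
  }
  if (any(genes$start < 0)) stop("negative start coordinate")
  bad <- genes$end <= genes$start
  if (any(bad)) {
    stop("end <= start for gene(s): ",
         paste(genes$gene_id[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  key <- paste(genes$genome_id, genes$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate (genome_id, gene_id): ", key[duplicated(key)][1])
  }
  pg <- unique(genes[, c("protein_id", "genome_id")])
  if (anyDuplicated(pg$protein_id)) {
    stop("protein_id appears in more than one genome: ",
         pg$protein_id[duplicated(pg$protein_id)][1])
  }
  ord <- order(genes$genome_id, genes$contig_id, genes$start,
               genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, circular = circular),
            class = "genome_collection")
}

#' @export
print.genome_collection <- function(x, ...) {
  cat(sprintf("genome_collection: %d genes, %d genomes, %d contigs\n",
              nrow(x$genes), length(unique(x$genes$genome_id)),
              nrow(unique(x$genes[, c("genome_id", "contig_id")]))))
  invisible(x)
}

#' Genome ids of a collection
#' @param collection a `genome_collection`.
#' @return Character vector of genome ids.
#' @export
genome_ids <- function(collection) {
  sort(unique(collection$genes$genome_id))
}

#' Read a gene coordinate table
#'
#' Reads gene loci either from GFF3 (`dialect = "gff3"`, 1-based inclusive,
#' converted to the internal 0-based half-open convention by `start - 1`) or
#' from the package's native 6/7-column TSV dialect (`dialect = "tsv"`,
#' already 0-based half-open; header `genome_id, contig_id, gene_id, start,
#' end, strand[, protein_id]`). The dialect must be stated explicitly so that
#' an already-converted table is never converted twice.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gff3"`; no default.
#' @param genome_id genome identifier for GFF3 input (one genome per file);
#'   defaults to the file name without extension.
#' @param feature_types GFF3 feature types retained (default `CDS` and `gene`;
#'   `CDS` preferred when both are present for an ID).
#' @return A [genome_collection()].
#' @export
read_gene_table <- function(path, dialect, genome_id = NULL,
                            feature_types = c("CDS", "gene")) {
  if (missing(dialect)) {
    stop("state the input dialect explicitly ('tsv' or 'gff3'): ",
         "coordinate conversion must happen exactly once")
  }
  dialect <- match.arg(dialect, c("tsv", "gff3"))
  if (dialect == "tsv") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) {
      warning("empty gene table: ", path)
      return(genome_collection(data.frame(
        gene_id = character(0), protein_id = character(0),
        genome_id = character(0), contig_id = character(0),
        start = integer(0), end = integer(0), strand = character(0))))
    }
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      colClasses = "character")
    req <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand")
    if (!all(req %in% names(tab))) {
      stop("TSV gene table must have header columns: ",
           paste(req, collapse = ", "))
    }
    if (nrow(tab) == 0L) {
      warning("gene table has a header but no rows: ", path)
    }
    start <- suppressWarnings(as.integer(tab$start))
    end <- suppressWarnings(as.integer(tab$end))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) {
      stop(sprintf("malformed coordinate at line %d of %s", bad[1] + 1L, path))
    }
    if (!"protein_id" %in% names(tab)) tab$protein_id <- tab$gene_id
    return(genome_collection(data.frame(
      gene_id = tab$gene_id, protein_id = tab$protein_id,
      genome_id = tab$genome_id, contig_id = tab$contig_id,
      start = start, end = end, strand = tab$strand,
      stringsAsFactors = FALSE)))
  }
  # GFF3: 1-based inclusive in, 0-based half-open out
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) {
    warning("no retained features in GFF3 file: ", path)
    return(genome_collection(data.frame(
      gene_id = character(0), protein_id = character(0),
      genome_id = character(0), contig_id = character(0),
      start = integer(0), end = integer(0), strand = character(0))))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  if ("locus_tag" %in% names(S4Vectors::mcols(gr))) {
    ids <- ifelse(is.na(ids), gr$locus_tag, ids)
  }
  if (anyNA(ids)) stop("GFF3 feature without ID or locus_tag in ", path)
  prot <- ids
  if ("protein_id" %in% names(S4Vectors::mcols(gr))) {
    prot <- ifelse(is.na(gr$protein_id), ids, gr$protein_id)
  }
  # prefer CDS over gene for duplicated ids
  type_rank <- match(as.character(gr$type), feature_types)
  keep <- !duplicated(ids[order(type_rank)])[order(order(type_rank))]
  genes <- data.frame(
    gene_id = ids, protein_id = prot, genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based
    end = GenomicRanges::end(gr),           # inclusive end == half-open end
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  genome_collection(genes)
}

#' Write a genome collection in the native TSV dialect
#'
#' @param collection a `genome_collection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(collection, path) {
  g <- collection$genes[, c("genome_id", "contig_id", "gene_id",
                            "start", "end", "strand", "protein_id")]
  write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read all-vs-all protein similarity hits
#'
#' Parses the 12-column BLAST/DIAMOND tabular dialect (outfmt 6): columns
#' 1, 2, 3, 11, 12 are query, subject, percent identity, E-value, bitscore;
#' the rest are ignored. Duplicate (query, subject) pairs are kept in file
#' order; downstream consumers resolve them by minimum E-value, then maximum
#' bitscore.
#'
#' @param path file path.
#' @return data.frame of class `similarity_hits` with columns `query_id`,
#'   `subject_id`, `pct_identity`, `e_value`, `bitscore`.
#' @export
read_similarity_hits <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    warning("empty similarity file: ", path)
    return(empty_hits())
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 12) stop("expected >= 12 tab-separated columns in ", path)
  ev <- suppressWarnings(as.numeric(tab[[11]]))
  bad <- which(is.na(ev))
  if (length(bad)) {
    stop(sprintf("non-numeric e-value at line %d of %s", bad[1], path))
  }
  if (any(ev < 0)) stop("negative e-value in ", path)
  hits <- data.frame(
    query_id = tab[[1]], subject_id = tab[[2]],
    pct_identity = as.numeric(tab[[3]]),
    e_value = ev, bitscore = as.numeric(tab[[12]]),
    stringsAsFactors = FALSE)
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}

empty_hits <- function() {
  hits <- data.frame(query_id = character(0), subject_id = character(0),
                     pct_identity = numeric(0), e_value = numeric(0),
                     bitscore = numeric(0), stringsAsFactors = FALSE)
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}

#' Write similarity hits in 12-column tabular form
#'
#' Unknown alignment columns (4-10) are written as 0.
#'
#' @param hits a `similarity_hits` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_hits <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id, hits$pct_identity,
                    0L, 0L, 0L, 0L, 0L, 0L, 0L,
                    format(hits$e_value, scientific = TRUE, trim = TRUE),
                    hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read protein-to-GO annotations restricted to a vocabulary
#'
#' Reads a 2-column TSV (`protein_id`, `go_id`, no header). Terms outside the
#' vocabulary are dropped and counted; proteins left without any in-vocabulary
#' term are excluded from the instance set (training uses only proteins
#' annotated within the label vocabulary).
#'
#' @param path file path.
#' @param vocabulary GO vocabulary (data.frame `go_id`/`name` or character
#'   vector); defaults to [default_go_vocabulary()].
#' @return Object of class `go_annotations`: list with `annotations` (named
#'   list protein_id -> character vector of GO ids), `vocabulary`,
#'   `n_dropped_terms`, `excluded_proteins`.
#' @export
read_go_annotations <- function(path, vocabulary = default_go_vocabulary()) {
  vocabulary <- as_vocabulary(vocabulary)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    warning("empty annotation file: ", path)
    return(go_annotation_table(data.frame(protein_id = character(0),
                                          go_id = character(0)), vocabulary))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("expected 2 tab-separated columns in ", path)
  names(tab)[1:2] <- c("protein_id", "go_id")
  bad <- which(!grepl(go_id_pattern, tab$go_id))
  if (length(bad)) {
    stop(sprintf("malformed GO id '%s' at line %d of %s",
                 tab$go_id[bad[1]], bad[1], path))
  }
  go_annotation_table(tab[, 1:2], vocabulary)
}

#' Build a GO annotation table from a protein/term data.frame
#'
#' @param tab data.frame with columns `protein_id`, `go_id`.
#' @param vocabulary GO vocabulary; see [read_go_annotations()].
#' @return A `go_annotations` object.
#' @export
go_annotation_table <- function(tab, vocabulary = default_go_vocabulary()) {
  vocabulary <- as_vocabulary(vocabulary)
  in_vocab <- tab$go_id %in% vocabulary$go_id
  n_dropped <- sum(!in_vocab)
  all_prot <- unique(tab$protein_id)
  tab <- unique(tab[in_vocab, , drop = FALSE])
  ann <- split(tab$go_id, tab$protein_id)
  ann <- lapply(ann, sort)
  excluded <- setdiff(all_prot, names(ann))
  structure(list(annotations = ann, vocabulary = vocabulary,
                 n_dropped_terms = n_dropped,
                 excluded_proteins = excluded),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf(
    "go_annotations: %d proteins, %d-term vocabulary (%d out-of-vocabulary rows dropped, %d proteins excluded)\n",
    length(x$annotations), nrow(x$vocabulary), x$n_dropped_terms,
    length(x$excluded_proteins)))
  invisible(x)
}

#' Write feature + label matrices as ARFF
#'
#' Serializes the training table in the ARFF dialect used by Weka-family
#' multi-label tools: every neighborhood feature is a nominal attribute with
#' values \{0,1,2,3\} (the discretized conservation bins) and every label a
#' binary nominal attribute. Instances appear in matrix row order. The
#' companion [read_arff()] restores both integer matrices losslessly.
#'
#' @param features integer matrix, values in \{0,1,2,3\}, colnames = feature ids.
#' @param labels binary integer matrix, same row count, colnames = GO ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_arff <- function(features, labels, path) {
  stopifnot(is.matrix(features), is.matrix(labels),
            nrow(features) == nrow(labels))
  if (length(features) && !all(features %in% 0:3)) {
    stop("feature values must be in {0,1,2,3}")
  }
  if (length(labels) && !all(labels %in% 0:1)) {
    stop("labels must be binary")
  }
  if (nrow(features) == 0L) warning("writing header-only ARFF (0 instances)")
  df <- data.frame(
    lapply(as.data.frame(features), factor, levels = 0:3),
    check.names = FALSE)
  ldf <- data.frame(
    lapply(as.data.frame(labels), factor, levels = 0:1),
    check.names = FALSE)
  out <- cbind(df, ldf)
  if (nrow(features) == 0L) {
    # foreign::write.arff mishandles 0-row frames; emit the header directly
    attrs <- c(sprintf("@attribute '%s' {0,1,2,3}", colnames(features)),
               sprintf("@attribute '%s' {0,1}", colnames(labels)))
    writeLines(c("@relation neighborGO", attrs, "@data"), path)
    return(invisible(path))
  }
  foreign::write.arff(out, path)
  invisible(path)
}

#' Read an ARFF file written by [write_arff()]
#'
#' @param path ARFF file.
#' @param label_pattern regular expression identifying label attributes
#'   (default: GO-id-shaped names).
#' @return list with integer matrices `features` and `labels`.
#' @export
read_arff <- function(path, label_pattern = "^GO:") {
  lines <- readLines(path)
  has_data <- any(trimws(tolower(lines)) == "@data") &&
    length(grep("^\\s*@", lines, invert = TRUE, value = TRUE)) > 0
  if (!has_data || all(grepl("^\\s*(@|%|$)", lines))) {
    att <- sub("^\\s*@attribute\\s+'?([^']+?)'?\\s+\\{.*$", "\\1",
               grep("^\\s*@attribute", lines, ignore.case = TRUE, value = TRUE))
    is_lab <- grepl(label_pattern, att)
    return(list(
      features = matrix(0L, 0, sum(!is_lab),
                        dimnames = list(NULL, att[!is_lab])),
      labels = matrix(0L, 0, sum(is_lab),
                      dimnames = list(NULL, att[is_lab]))))
  }
  df <- foreign::read.arff(path)
  m <- vapply(df, function(col) as.integer(as.character(col)),
              integer(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)))
  is_lab <- grepl(label_pattern, colnames(m))
  list(features = m[, !is_lab, drop = FALSE],
       labels = m[, is_lab, drop = FALSE])
}
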
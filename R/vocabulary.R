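#' Default photosynthesis GO vocabulary
#'
#' Curated set of 24 photosynthesis-specific GO terms used as the default
#' label vocabulary: child terms of photosynthesis (GO:0015979) observed in
#' photosynthetic prokaryotes, plus phycobilisome (GO:0030089), the
#' cyanobacterial light-harvesting complex, which connects to photosynthesis
#' through the photosynthetic membrane (GO:0034357). The set spans biological
#' process, cellular component and molecular function aspects. Any other
#' vocabulary can be supplied wherever this default is accepted: it is a
#' configuration, not a constraint of the method.
#'
#' @return A data.frame with columns `go_id` and `name`, 24 rows.
#' @export
#' @examples
#' v <- default_go_vocabulary()
#' nrow(v) # 24
default_go_vocabulary <- function() {
  data.frame(
    go_id = c(
      "GO:0009521", "GO:0009522", "GO:0009523", "GO:0009538", "GO:0009539",
      "GO:0009579", "GO:0009654", "GO:0009765", "GO:0009767", "GO:0009768",
      "GO:0009772", "GO:0009773", "GO:0010109", "GO:0010207", "GO:0019253",
      "GO:0019684", "GO:0019685", "GO:0030089", "GO:0030094", "GO:0030096",
      "GO:0034357", "GO:0042548", "GO:0042549", "GO:0045156"
    ),
    name = c(
      "photosystem",
      "photosystem I",
      "photosystem II",
      "photosystem I reaction center",
      "photosystem II reaction center",
      "thylakoid",
      "photosystem II oxygen evolving complex",
      "photosynthesis, light harvesting",
      "photosynthetic electron transport chain",
      "photosynthesis, light harvesting in photosystem I",
      "photosynthetic electron transport in photosystem II",
      "photosynthetic electron transport in photosystem I",
      "regulation of photosynthesis",
      "photosystem II assembly",
      "reductive pentose-phosphate cycle",
      "photosynthesis, light reaction",
      "photosynthesis, dark reaction",
      "phycobilisome",
      "plasma membrane-derived photosystem I",
      "plasma membrane-derived thylakoid photosystem II",
      "photosynthetic membrane",
      "regulation of photosynthesis, light reaction",
      "photosystem II stabilization",
      "cyclic photosynthetic electron transport activity"
    ),
    stringsAsFactors = FALSE
  )
}

go_id_pattern <- "^GO:[0-9]{7}$"

#' Validate a GO vocabulary table
#'
#' @param vocabulary data.frame with columns `go_id`, `name` (or a character
#'   vector of GO ids, in which case names are set to the ids).
#' @return A normalized data.frame with `go_id`, `name`.
#' @keywords internal
as_vocabulary <- function(vocabulary) {
  if (is.character(vocabulary)) {
    vocabulary <- data.frame(go_id = vocabulary, name = vocabulary,
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(vocabulary), all(c("go_id", "name") %in% names(vocabulary)))
  bad <- !grepl(go_id_pattern, vocabulary$go_id)
  if (any(bad)) {
    stop("malformed GO id(s) in vocabulary: ",
         paste(vocabulary$go_id[bad], collapse = ", "))
  }
  if (anyDuplicated(vocabulary$go_id)) stop("duplicate GO ids in vocabulary")
  vocabulary[, c("go_id", "name")]
}
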
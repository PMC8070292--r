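#' Path to a packaged example/fixture data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
litkn_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "litkn")))
  }
  path <- system.file("extdata", file, package = "litkn")
  if (!nzchar(path)) stop("no packaged file called ", file, call. = FALSE)
  path
}

#' The ten flesh color node labels
#'
#' The designated set of trait labels that collectively stand for tuber flesh
#' color in the time analysis, chosen from the most complete (final-year)
#' network.
#'
#' @param normalized if `TRUE` (default) the labels are returned in
#'   normalized uppercase form, as they appear as network node labels;
#'   otherwise in plain lowercase.
#' @return Character vector of ten labels.
#' @export
flesh_color_nodes <- function(normalized = TRUE) {
  labels <- c("color", "flesh", "flesh color", "flesh trait",
              "orange flesh color", "tuber color", "tuber flesh",
              "tuber flesh color", "white flesh color",
              "yellow-orange flesh color")
  if (normalized) toupper(labels) else labels
}

#' Transcribed first-order neighbor sets of the flesh color nodes
#'
#' The packaged transcription of the published comparison between the
#' first-order neighbors of the tuber flesh color nodes in full-text networks
#' (set A, 38 entities) and in abstract-only networks (set B), together with
#' the printed difference column. The printed difference column is carried
#' verbatim so that its consistency with the computed set difference can be
#' checked rather than assumed.
#'
#' @return List with character vectors `set_a`, `set_b` and
#'   `printed_difference`.
#' @export
table1_neighbor_sets <- function() {
  x <- utils::read.delim(litkn_extdata("table1_neighbor_sets.tsv"),
                         sep = "\t", header = TRUE, colClasses = "character",
                         quote = "", fileEncoding = "UTF-8")
  list(
    set_a = x$label[x$set == "A"],
    set_b = x$label[x$set == "B"],
    printed_difference = x$label[x$set == "DIFF"]
  )
}

#' Transcribed master distance table (tracked nodes by year)
#'
#' The packaged transcription of the published node-by-year matrix of
#' shortest-path distances from each eventual flesh color neighbor to the
#' nearest flesh color node, for the cumulative yearly networks 2000-2016;
#' `"x"` marks absence. Parsed with [read_master_table()].
#'
#' @return A `distance_table` with 21 tracked nodes and 17 years.
#' @export
table2_master <- function() {
  read_master_table(litkn_extdata("table2_master_distances.csv"))
}

#' Packaged normalization configuration
#'
#' A [normalization_config()] whose EC-number and spelling maps are loaded
#' from the packaged fixture tables, suitable for the worked examples and for
#' normalizing the entities named in the packaged neighbor/distance tables.
#'
#' @return A `normalization_config`.
#' @export
fixture_normalization_config <- function() {
  ec <- utils::read.delim(litkn_extdata("ec_map.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  sp <- utils::read.delim(litkn_extdata("spelling_map.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  normalization_config(ec_map = ec, spelling_map = sp)
}

#' Packaged synonym table
#'
#' Covers every entity named in the packaged neighbor and distance tables,
#' plus the abbreviation and variant aliases used by the worked normalization
#' examples (gene symbols to full enzyme names, spelling variants of
#' beta-carotene, allelic variants collapsed onto their main label).
#'
#' @return A `synonym_table`.
#' @export
fixture_synonyms <- function() {
  synonym_table(litkn_extdata("synonyms.tsv"))
}
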
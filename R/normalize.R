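#' Default Greek-letter transliteration map
#'
#' @return Named character vector mapping Greek letters to Latin names.
#' @export
default_greek_map <- function() {
  c("α" = "alpha", "β" = "beta", "γ" = "gamma",
    "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
    "κ" = "kappa", "λ" = "lambda", "ω" = "omega",
    # uppercase forms, so that case folding upstream cannot defeat the rule
    "Α" = "alpha", "Β" = "beta", "Γ" = "gamma",
    "Δ" = "delta", "Ε" = "epsilon", "Ζ" = "zeta",
    "Κ" = "kappa", "Λ" = "lambda", "Ω" = "omega")
}

NORMALIZATION_RULES <- c("transliterate", "strip_marks", "uppercase",
                         "species_prefix", "family_suffix", "ec_lookup")

#' Normalization configuration
#'
#' Bundles the rule set used to map raw entity surface forms to canonical
#' preferred labels: Greek transliteration and American spelling conversion,
#' removal of apostrophes and `#` marks, uppercase conversion, species-prefix
#' stripping from gene names (e.g. `StAN1` from *Solanum tuberosum* to `AN1`),
#' gene-family suffix-digit stripping (`BCH1`, `BCH2` to `BCH`), and EC-number
#' expansion to enzyme names. Prefix and suffix stripping only fire when the
#' stripped remainder is a known label, so unrelated words are never damaged.
#'
#' @param species_prefixes short genus-species codes stripped from gene names.
#' @param ec_map data.frame with columns `ec_number`, `enzyme_name`, or `NULL`.
#' @param spelling_map data.frame with columns `variant`, `american`
#'   (applied token-wise, case-insensitively), or `NULL`.
#' @param greek_map named character vector; see [default_greek_map()].
#' @param strip_family_digits logical; strip trailing digits from gene-family
#'   member names when the base resolves.
#' @param rule_order permutation of the six rule names fixing application
#'   order; the default applies character-level cleanup before the
#'   dictionary-dependent rules.
#' @return Object of class `normalization_config`.
#' @export
normalization_config <- function(species_prefixes = c("St", "Le", "Sl", "Ca",
                                                      "At", "Nt"),
                                 ec_map = NULL,
                                 spelling_map = NULL,
                                 greek_map = default_greek_map(),
                                 strip_family_digits = TRUE,
                                 rule_order = NORMALIZATION_RULES) {
  if (!setequal(rule_order, NORMALIZATION_RULES) ||
      length(rule_order) != length(NORMALIZATION_RULES)) {
    stop("rule_order must be a permutation of: ",
         paste(NORMALIZATION_RULES, collapse = ", "), call. = FALSE)
  }
  if (!is.null(ec_map)) {
    stopifnot(is.data.frame(ec_map),
              all(c("ec_number", "enzyme_name") %in% names(ec_map)))
  }
  if (!is.null(spelling_map)) {
    stopifnot(is.data.frame(spelling_map),
              all(c("variant", "american") %in% names(spelling_map)))
  }
  structure(list(
    species_prefixes = as.character(species_prefixes),
    ec_map = ec_map,
    spelling_map = spelling_map,
    greek_map = greek_map,
    strip_family_digits = isTRUE(strip_family_digits),
    rule_order = rule_order
  ), class = "normalization_config")
}

#' Synonym table
#'
#' Maps alias labels to preferred labels (lookup is case-insensitive after
#' rule application). The table must be acyclic: a preferred label may not
#' itself be an alias of a different label, and no alias may map to two
#' different preferred labels.
#'
#' @param x data.frame with columns `alias`, `preferred_label` and optionally
#'   `source`, or a path to a TSV file with that header.
#' @return Object of class `synonym_table`.
#' @export
synonym_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  }
  stopifnot(is.data.frame(x))
  if (!all(c("alias", "preferred_label") %in% names(x))) {
    stop("synonym table needs columns alias and preferred_label", call. = FALSE)
  }
  if (!"source" %in% names(x)) x$source <- NA_character_
  x <- unique(x[, c("alias", "preferred_label", "source")])
  if (any(!nzchar(x$alias))) stop("empty alias in synonym table", call. = FALSE)
  key <- toupper(x$alias)
  amb <- tapply(x$preferred_label, key, function(p) length(unique(p)))
  if (any(amb > 1L)) {
    stop("alias mapped to multiple preferred labels: ",
         paste(names(amb)[amb > 1L], collapse = ", "), call. = FALSE)
  }
  # acyclicity: a preferred label must not be an alias of a *different* label
  pref_as_alias <- match(toupper(x$preferred_label), key)
  bad <- !is.na(pref_as_alias) &
    toupper(x$preferred_label[pref_as_alias]) != toupper(x$preferred_label)
  if (any(bad)) {
    stop("synonym table is cyclic for preferred label(s): ",
         paste(unique(x$preferred_label[bad]), collapse = ", "), call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("synonym_table", "data.frame")
  x
}

resolvable <- function(z, syn, known) {
  pool <- toupper(c(if (!is.null(syn)) c(syn$alias, syn$preferred_label),
                    known))
  toupper(z) %in% pool
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

normalize_one <- function(x, syn, config, known) {
  for (rule in config$rule_order) {
    x <- switch(rule,
      transliterate = {
        gm <- config$greek_map
        for (g in names(gm)) x <- gsub(g, gm[[g]], x, fixed = TRUE)
        sm <- config$spelling_map
        if (!is.null(sm)) {
          for (r in seq_len(nrow(sm))) {
            x <- gsub(paste0("\\b", escape_regex(sm$variant[r]), "\\b"),
                      sm$american[r], x, ignore.case = TRUE, perl = TRUE)
          }
        }
        x
      },
      strip_marks = gsub("['’′ʹ#]", "", x),
      uppercase = toupper(x),
      species_prefix = {
        for (p in toupper(config$species_prefixes)) {
          if (nchar(x) > nchar(p) &&
              toupper(substr(x, 1L, nchar(p))) == p) {
            rest <- substr(x, nchar(p) + 1L, nchar(x))
            if (grepl("^[[:alnum:]]", rest) && resolvable(rest, syn, known)) {
              x <- rest
              break
            }
          }
        }
        x
      },
      family_suffix = {
        if (config$strip_family_digits && grepl("[^0-9][0-9]+$", x)) {
          base <- sub("[0-9]+$", "", x)
          if (resolvable(base, syn, known)) x <- base
        }
        x
      },
      ec_lookup = {
        em <- config$ec_map
        if (!is.null(em) && grepl("^EC[[:space:].:]*[0-9]", toupper(x))) {
          key <- sub("^EC[[:space:].:]*", "", toupper(x))
          hit <- match(key, em$ec_number)
          if (!is.na(hit)) x <- toupper(em$enzyme_name[hit])
        }
        x
      }
    )
  }
  if (!is.null(syn)) {
    hit <- match(toupper(x), toupper(syn$alias))
    if (!is.na(hit)) return(syn$preferred_label[hit])
    hit <- match(toupper(x), toupper(syn$preferred_label))
    if (!is.na(hit)) return(syn$preferred_label[hit])
  }
  x
}

#' Normalize an entity (or relationship) label
#'
#' Applies the configured rule sequence and finally looks the processed form
#' up in the synonym table, returning its preferred label. Labels that resolve
#' nowhere pass through as their rule-processed uppercase form.
#'
#' @param x character vector of raw labels (non-empty strings).
#' @param syn a [synonym_table()] or `NULL`.
#' @param config a [normalization_config()].
#' @param known optional character vector of additional known labels (e.g.
#'   lexicon preferred labels) consulted by the prefix/suffix resolvability
#'   checks.
#' @return Character vector of preferred labels, same length as `x`.
#' @export
normalize_label <- function(x, syn = NULL, config = normalization_config(),
                            known = NULL) {
  stopifnot(inherits(config, "normalization_config"))
  if (!is.null(syn)) stopifnot(inherits(syn, "synonym_table"))
  x <- as.character(x)
  if (any(is.na(x) | !nzchar(x))) {
    stop("normalize_label requires non-empty labels", call. = FALSE)
  }
  vapply(x, normalize_one, character(1), syn = syn, config = config,
         known = known, USE.NAMES = FALSE)
}

#' Is a label already in normalized form?
#'
#' @inheritParams normalize_label
#' @return Logical vector: `TRUE` where normalizing the label is a no-op.
#' @export
is_normalized <- function(x, syn = NULL, config = normalization_config(),
                          known = NULL) {
  normalize_label(x, syn = syn, config = config, known = known) == x
}
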
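.lexicon_cache <- new.env(parent = emptyenv())

#' Load the family-member and cue lexicons
#'
#' Reads the YAML lexicon resource shipped with the package (or a
#' user-supplied override) and compiles it into fast lookup structures:
#' a surface-term dictionary mapping kin terms to normalized names, the
#' first/second degree split, the kinship composition table (e.g. a
#' "sister" modified by "mother" is an Aunt), family-side cue lists, and
#' living-status / negation trigger inventories. The shipped cue lists
#' are supersets of the documented examples and are meant to be edited.
#'
#' @param path Optional path to a YAML file with the same layout as
#'   `system.file("extdata", "lexicons.yaml", package = "famhx")`.
#' @return An object of class `fh_lexicons`.
#' @export
load_lexicons <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.lexicon_cache$default)) return(.lexicon_cache$default)
    path <- system.file("extdata", "lexicons.yaml", package = "famhx")
  }
  raw <- yaml::read_yaml(path)
  term_map <- character(0)
  for (norm in names(raw$family_members)) {
    terms <- tolower(unlist(raw$family_members[[norm]]))
    term_map[terms] <- norm
  }
  degree <- c(stats::setNames(rep("first", length(raw$first_degree)),
                              raw$first_degree),
              stats::setNames(rep("second", length(raw$second_degree)),
                              raw$second_degree))
  lex <- structure(list(
    term_map = term_map,
    excluded = tolower(unlist(raw$excluded_members)),
    degree = degree,
    composition = unlist(raw$composition),
    paternal = tolower(unlist(raw$cues$paternal)),
    maternal = tolower(unlist(raw$cues$maternal)),
    not_alive = tolower(unlist(raw$cues$not_alive)),
    healthy = tolower(unlist(raw$cues$healthy)),
    negation_triggers = tolower(unlist(raw$negation$triggers)),
    negation_termination = tolower(unlist(raw$negation$termination)),
    negation_scope = as.integer(raw$negation$scope_tokens)
  ), class = "fh_lexicons")
  stopifnot(all(lex$term_map %in% FM_NAMES),
            all(names(lex$degree) %in% FM_NAMES),
            length(lex$not_alive) > 0L, length(lex$healthy) > 0L)
  if (default) .lexicon_cache$default <- lex
  lex
}

#' @export
print.fh_lexicons <- function(x, ...) {
  cat(sprintf(paste0("<fh_lexicons: %d kin terms -> %d normalized names, ",
                     "%d composition rules, %d negation triggers>\n"),
              length(x$term_map), length(unique(x$term_map)),
              length(x$composition), length(x$negation_triggers)))
  invisible(x)
}

# Lowercase cue search over a region; a cue must start at a word
# boundary so e.g. the Maternal cue "mother's" does not fire inside
# "grandmother's".
cue_present <- function(region, cues) {
  region <- tolower(region)
  for (cue in cues) {
    pat <- paste0("(?<![a-z])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", cue))
    if (grepl(pat, region, perl = TRUE)) return(TRUE)
  }
  FALSE
}
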
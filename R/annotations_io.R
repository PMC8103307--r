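FM_NAMES <- c("Father", "Mother", "Parent", "Brother", "Sister", "Sibling",
              "Son", "Daughter", "Child", "Grandfather", "Grandmother",
              "Grandparent", "Uncle", "Aunt", "Cousin")
FM_SIDES <- c("Paternal", "Maternal", "NA")

#' Read entity and relation annotation files
#'
#' Parses the package's tab-separated annotation dialect (see
#' [write_annotations()] for the exact column layout) into entity and
#' relation tables with validated category, side, negation and score
#' values. Files carry document-level tuples, not character offsets, so
#' spans on the returned entities are `NA`.
#'
#' @param entity_path Path to the entity TSV file.
#' @param relation_path Path to the relation TSV file (optional).
#' @return List with elements `entities` and `relations`.
#' @export
read_annotations <- function(entity_path, relation_path = NULL) {
  entities <- fh_entities()
  lines <- read_tsv_lines(entity_path)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) {
      stop(entity_path, " line ", i, ": expected 4 tab-separated fields, got ",
           length(f))
    }
    row <- switch(f[2L],
      FamilyMember = {
        if (!f[3L] %in% FM_NAMES) {
          stop(entity_path, " line ", i, ": unknown normalized name '", f[3L], "'")
        }
        if (!f[4L] %in% FM_SIDES) {
          stop(entity_path, " line ", i, ": unknown family side '", f[4L], "'")
        }
        fh_entities(f[1L], "FamilyMember", NA_integer_, NA_integer_,
                    NA_character_, normalized = f[3L], side = f[4L])
      },
      Observation = {
        if (!f[4L] %in% c("Negated", "Non_Negated")) {
          stop(entity_path, " line ", i, ": unknown negation '", f[4L], "'")
        }
        fh_entities(f[1L], "Observation", NA_integer_, NA_integer_,
                    text = f[3L], negation = f[4L])
      },
      LivingStatus = {
        sc <- suppressWarnings(as.integer(f[4L]))
        if (is.na(sc) || !sc %in% c(0L, 2L, 4L)) {
          stop(entity_path, " line ", i, ": living-status score '", f[4L],
               "' not in {0, 2, 4}")
        }
        fh_entities(f[1L], "LivingStatus", NA_integer_, NA_integer_,
                    text = f[3L], score = sc)
      },
      stop(entity_path, " line ", i, ": unknown category '", f[2L], "'")
    )
    entities <- rbind(entities, row)
  }

  relations <- fh_relations()
  if (!is.null(relation_path)) {
    lines <- read_tsv_lines(relation_path)
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 5L) {
        stop(relation_path, " line ", i, ": expected >= 5 fields, got ",
             length(f))
      }
      if (!f[2L] %in% FM_NAMES) {
        stop(relation_path, " line ", i, ": unknown normalized name '", f[2L], "'")
      }
      if (!f[3L] %in% FM_SIDES) {
        stop(relation_path, " line ", i, ": unknown family side '", f[3L], "'")
      }
      row <- switch(f[4L],
        LivingStatus = {
          if (length(f) != 5L) {
            stop(relation_path, " line ", i, ": living-status relations have 5 fields")
          }
          sc <- suppressWarnings(as.integer(f[5L]))
          if (is.na(sc) || !sc %in% c(0L, 2L, 4L)) {
            stop(relation_path, " line ", i, ": score '", f[5L], "' not in {0, 2, 4}")
          }
          fh_relations(f[1L], "FamilyMember_LivingStatus", f[2L], f[3L],
                       score = sc)
        },
        Observation = {
          if (length(f) != 6L) {
            stop(relation_path, " line ", i, ": observation relations have 6 fields")
          }
          if (!f[6L] %in% c("Negated", "Non_Negated")) {
            stop(relation_path, " line ", i, ": unknown negation '", f[6L], "'")
          }
          fh_relations(f[1L], "FamilyMember_Observation", f[2L], f[3L],
                       other_text = f[5L], negation = f[6L])
        },
        stop(relation_path, " line ", i, ": unknown relation target '", f[4L], "'")
      )
      relations <- rbind(relations, row)
    }
  }
  list(entities = entities, relations = relations)
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

#' Write entity and relation annotation files
#'
#' Emits the tab-separated dialect, one record per line, no quoting:
#' entity lines are `doc_id  category  field3  field4` with
#' `field3`/`field4` being normalized name and family side for family
#' members, surface text and negation for observations, surface text and
#' score for living status. Relation lines are
#' `doc_id  fm_normalized  fm_side  LivingStatus  score` or
#' `doc_id  fm_normalized  fm_side  Observation  obs_text  negation`.
#' Output is byte-deterministic for a fixed input.
#'
#' @param entities Entity table.
#' @param relations Relation table.
#' @param out_dir Output directory; files `entities.tsv` and
#'   `relations.tsv` are (over)written there.
#' @return Invisibly, the two file paths.
#' @export
write_annotations <- function(entities, relations, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ent_path <- file.path(out_dir, "entities.tsv")
  rel_path <- file.path(out_dir, "relations.tsv")

  ent_lines <- character(0)
  if (NROW(entities) > 0L) {
    f3 <- ifelse(entities$category == "FamilyMember",
                 entities$normalized, entities$text)
    f4 <- ifelse(entities$category == "FamilyMember",
                 ifelse(is.na(entities$side), "NA", entities$side),
          ifelse(entities$category == "Observation",
                 ifelse(is.na(entities$negation), "Non_Negated",
                        entities$negation),
                 as.character(entities$score)))
    ent_lines <- paste(entities$doc_id, entities$category, f3, f4, sep = "\t")
  }
  writeLines(ent_lines, ent_path, useBytes = TRUE)

  rel_lines <- character(0)
  if (NROW(relations) > 0L) {
    is_ls <- relations$type == "FamilyMember_LivingStatus"
    side <- ifelse(is.na(relations$fm_side), "NA", relations$fm_side)
    rel_lines <- ifelse(is_ls,
      paste(relations$doc_id, relations$fm_normalized, side,
            "LivingStatus", relations$score, sep = "\t"),
      paste(relations$doc_id, relations$fm_normalized, side,
            "Observation", relations$other_text, relations$negation,
            sep = "\t"))
  }
  writeLines(rel_lines, rel_path, useBytes = TRUE)
  invisible(c(entities = ent_path, relations = rel_path))
}

#' Read a directory of plain-text clinical notes
#'
#' One document per `.txt` file; the document id is the file name stem.
#'
#' @param dir Directory of note files.
#' @return List of [preprocess()]ed `fh_document` objects.
#' @export
read_notes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(files, function(f) {
    txt <- paste(readLines(f, warn = FALSE), collapse = "\n")
    preprocess(txt, sub("\\.txt$", "", basename(f)))
  })
}
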
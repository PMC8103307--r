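#' Construct an entity table
#'
#' Entities are kept in a plain data frame with one row per mention:
#' `doc_id`, `category` (FamilyMember, Observation or LivingStatus),
#' 0-based half-open character span (`start`, `end`), surface `text`, and
#' the category's attributes (`normalized` and `side` for family members,
#' `negation` for observations, `score` in \{0, 2, 4\} for living status);
#' attribute columns not applicable to a category are `NA`.
#'
#' @param doc_id,category,start,end,text,normalized,side,negation,score
#'   Vectors, recycled to a common length.
#' @return A data frame with the canonical entity columns.
#' @export
fh_entities <- function(doc_id = character(0), category = character(0),
                        start = integer(0), end = integer(0),
                        text = character(0), normalized = NA_character_,
                        side = NA_character_, negation = NA_character_,
                        score = NA_integer_) {
  n <- max(length(doc_id), length(category), length(start))
  if (n == 0L) {
    return(data.frame(doc_id = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      text = character(0), normalized = character(0),
                      side = character(0), negation = character(0),
                      score = integer(0), stringsAsFactors = FALSE))
  }
  bad <- setdiff(unique(category), ENTITY_CATEGORIES)
  if (length(bad)) stop("unknown entity category: ", paste(bad, collapse = ", "))
  if (!all(is.na(score) | score %in% c(0L, 2L, 4L))) {
    stop("living-status score must be in {0, 2, 4}")
  }
  data.frame(doc_id = rep_len(as.character(doc_id), n),
             category = rep_len(as.character(category), n),
             start = rep_len(as.integer(start), n),
             end = rep_len(as.integer(end), n),
             text = rep_len(as.character(text), n),
             normalized = rep_len(as.character(normalized), n),
             side = rep_len(as.character(side), n),
             negation = rep_len(as.character(negation), n),
             score = rep_len(as.integer(score), n),
             stringsAsFactors = FALSE)
}

#' Construct a relation table
#'
#' Relations are document-level tuples: a family member (by normalized
#' name and family side) related either to a living-status phrase with a
#' score in \{0, 2, 4\} (type `FamilyMember_LivingStatus`) or to an
#' observation with a negation flag (type `FamilyMember_Observation`).
#'
#' @param doc_id,type,fm_normalized,fm_side,other_text,score,negation
#'   Vectors, recycled to a common length.
#' @return A data frame with the canonical relation columns.
#' @export
fh_relations <- function(doc_id = character(0), type = character(0),
                         fm_normalized = character(0), fm_side = "NA",
                         other_text = NA_character_, score = NA_integer_,
                         negation = NA_character_) {
  n <- max(length(doc_id), length(type), length(fm_normalized))
  if (n == 0L) {
    return(data.frame(doc_id = character(0), type = character(0),
                      fm_normalized = character(0), fm_side = character(0),
                      other_text = character(0), score = integer(0),
                      negation = character(0), stringsAsFactors = FALSE))
  }
  bad <- setdiff(unique(type),
                 c("FamilyMember_LivingStatus", "FamilyMember_Observation"))
  if (length(bad)) stop("unknown relation type: ", paste(bad, collapse = ", "))
  out <- data.frame(doc_id = rep_len(as.character(doc_id), n),
                    type = rep_len(as.character(type), n),
                    fm_normalized = rep_len(as.character(fm_normalized), n),
                    fm_side = rep_len(as.character(fm_side), n),
                    other_text = rep_len(as.character(other_text), n),
                    score = rep_len(as.integer(score), n),
                    negation = rep_len(as.character(negation), n),
                    stringsAsFactors = FALSE)
  ls <- out$type == "FamilyMember_LivingStatus"
  if (any(ls & !(out$score %in% c(0L, 2L, 4L)))) {
    stop("living-status relations must carry a score in {0, 2, 4}")
  }
  if (any(!ls & !(out$negation %in% c("Negated", "Non_Negated")))) {
    stop("observation relations must carry Negated or Non_Negated")
  }
  out
}

BIO_LABELS <- c("O",
                "B-FamilyMember", "I-FamilyMember",
                "B-Observation", "I-Observation",
                "B-LivingStatus", "I-LivingStatus")

#' Encode gold entities over a sentence as BIO token tags
#'
#' The first token covered by an entity receives `B-<category>`, later
#' covered tokens `I-<category>`, everything else `O`. Entities of the
#' same category may not overlap; a cross-category overlap on the same
#' token is a gold-corpus defect and raises an error.
#'
#' @param sentence One element of `fh_document$sentences`.
#' @param entities Entity table (only rows overlapping the sentence are
#'   used).
#' @return Character vector of BIO tags, one per sentence token.
#' @seealso [decode_bio()]
#' @export
encode_bio <- function(sentence, entities) {
  toks <- sentence$tokens
  tags <- rep("O", nrow(toks))
  if (nrow(toks) == 0L || NROW(entities) == 0L) return(tags)
  ent <- entities[entities$start < sentence$end & entities$end > sentence$start, ,
                  drop = FALSE]
  if (nrow(ent) == 0L) return(tags)
  ent <- ent[order(ent$start, ent$end), , drop = FALSE]
  owner <- rep(NA_integer_, nrow(toks))
  for (k in seq_len(nrow(ent))) {
    covered <- which(toks$start < ent$end[k] & toks$end > ent$start[k])
    if (length(covered) == 0L) next
    clash <- covered[!is.na(owner[covered])]
    if (length(clash)) {
      stop("overlapping gold entities at tokens ",
           paste(toks$text[clash], collapse = " "),
           " (", ent$category[k], " vs ",
           ent$category[owner[clash[1L]]], ")")
    }
    owner[covered] <- k
    tags[covered[1L]] <- paste0("B-", ent$category[k])
    if (length(covered) > 1L) {
      tags[covered[-1L]] <- paste0("I-", ent$category[k])
    }
  }
  tags
}

#' Decode BIO token tags over a sentence into entities
#'
#' Maximal `B-`/`I-` runs of one category become entities whose character
#' span stretches from the first to the last covered token. A malformed
#' leading `I-` (after `O`, start of sentence, or a different category) is
#' repaired as `B-` rather than dropped.
#'
#' @param tags Character vector of BIO tags, one per token.
#' @param sentence One element of `fh_document$sentences`.
#' @param doc_id Document identifier stamped on the entities.
#' @param doc_text Full document text; when supplied, entity surface text
#'   is filled in from the spans.
#' @return Entity table (attributes all `NA`).
#' @export
decode_bio <- function(tags, sentence, doc_id = "doc", doc_text = NULL) {
  toks <- sentence$tokens
  if (length(tags) != nrow(toks)) {
    stop("tag/token length mismatch: ", length(tags), " vs ", nrow(toks))
  }
  out <- fh_entities()
  cur_cat <- NULL
  cur_first <- NA_integer_
  cur_last <- NA_integer_
  flush <- function() {
    if (is.null(cur_cat)) return()
    out[nrow(out) + 1L, c("doc_id", "category", "start", "end")] <<-
      list(doc_id, cur_cat, toks$start[cur_first], toks$end[cur_last])
    cur_cat <<- NULL
  }
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag == "O") {
      flush()
    } else {
      cat <- sub("^[BI]-", "", tag)
      begin <- startsWith(tag, "B-") || is.null(cur_cat) || cur_cat != cat
      if (begin) {
        flush()
        cur_cat <- cat
        cur_first <- i
      }
      cur_last <- i
    }
  }
  flush()
  if (nrow(out) > 0L && !is.null(doc_text)) {
    out$text <- span_text(doc_text, out$start, out$end)
  }
  out
}

# Key uniquely identifying an entity mention (exact span + category).
entity_key <- function(entities) {
  paste(entities$doc_id, entities$category, entities$start, entities$end,
        sep = "\r")
}
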
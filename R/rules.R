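#' Rule-based family member mention detection
#'
#' Flags every token whose lowercase form is a known first- or
#' second-degree kin term and whose part-of-speech tag is a noun (NN,
#' NNP or NNS) as a family member mention. Excluded kin ("spouse",
#' "nephew", ...) are never matched; a kin word used as a verb ("they
#' will father a child") is filtered out by the POS constraint.
#'
#' @param doc An `fh_document`.
#' @param lexicons Lexicons from [load_lexicons()].
#' @return Entity table of `FamilyMember` mentions (one per matching
#'   token; attributes unset).
#' @export
match_family_members <- function(doc, lexicons = load_lexicons()) {
  out <- fh_entities()
  for (sent in doc$sentences) {
    toks <- sent$tokens
    if (nrow(toks) == 0L) next
    lw <- tolower(toks$text)
    hit <- lw %in% names(lexicons$term_map) &
      !(lw %in% lexicons$excluded) &
      toks$pos %in% c("NN", "NNP", "NNS")
    if (any(hit)) {
      out <- rbind(out, fh_entities(doc$doc_id, "FamilyMember",
                                    toks$start[hit], toks$end[hit],
                                    toks$text[hit]))
    }
  }
  out
}

#' Normalize a family member mention to its canonical kinship name
#'
#' Lowercases the mention, strips digits and number words, and looks the
#' remaining kin term up in the dictionary ("his dad" -> Father, "three
#' uncles" -> Uncle). If the sentence is supplied and the nearest kin
#' token preceding the mention modifies it — possessive (`mother's
#' sister`) or subject of has/have/had (`mother has sister`) — the
#' kinship composition table is applied, so that sister becomes Aunt.
#'
#' @param text Mention surface text.
#' @param sentence Optional sentence (element of `fh_document$sentences`)
#'   containing the mention, enabling composition.
#' @param start Mention start offset (0-based, document coordinates);
#'   required when `sentence` is given.
#' @param lexicons Lexicons from [load_lexicons()].
#' @return The normalized name, or `NA_character_` when the term is not
#'   in the dictionary (surfaced, not guessed).
#' @export
normalize_family_member <- function(text, sentence = NULL, start = NULL,
                                    lexicons = load_lexicons()) {
  words <- regmatches(tolower(text), gregexpr("[a-z]+", tolower(text)))[[1]]
  kin <- words[words %in% names(lexicons$term_map)]
  if (length(kin) == 0L) return(NA_character_)
  base <- unname(lexicons$term_map[kin[length(kin)]])
  if (is.null(sentence) || is.null(start)) return(base)

  toks <- sentence$tokens
  before <- which(toks$end <= start)
  if (length(before) == 0L) return(base)
  lw <- tolower(toks$text)
  kin_before <- before[lw[before] %in% names(lexicons$term_map)]
  if (length(kin_before) == 0L) return(base)
  k <- kin_before[length(kin_before)]            # nearest preceding kin token
  if (k >= nrow(toks)) return(base)
  nxt <- lw[k + 1L]
  if (!(nxt == "'s" || nxt %in% c("has", "had", "have"))) return(base)
  ctx <- unname(lexicons$term_map[lw[k]])
  comp <- lexicons$composition[paste(ctx, base, sep = "|")]
  if (is.na(comp)) base else unname(comp)
}

#' Assign the family side (Paternal / Maternal) of a mention
#'
#' First-degree relatives never carry a side (`"NA"`). For second-degree
#' relatives, side cues ("paternal", "mother's", "father had", ...) are
#' searched first inside the mention text itself and, if absent, the
#' search is expanded to the sentence; with no cue anywhere the side
#' stays `"NA"`.
#'
#' @param text Mention surface text.
#' @param sentence_text Text of the containing sentence.
#' @param normalized Normalized kinship name of the mention.
#' @param lexicons Lexicons from [load_lexicons()].
#' @return `"Paternal"`, `"Maternal"` or `"NA"`.
#' @export
assign_family_side <- function(text, sentence_text, normalized,
                               lexicons = load_lexicons()) {
  if (is.na(normalized) || !identical(unname(lexicons$degree[normalized]), "second")) {
    return("NA")
  }
  for (region in c(text, sentence_text)) {
    pat <- cue_present(region, lexicons$paternal)
    mat <- cue_present(region, lexicons$maternal)
    if (pat && !mat) return("Paternal")
    if (mat && !pat) return("Maternal")
    if (pat && mat) return("Paternal")   # fixed tie-break
  }
  "NA"
}

#' Score a living-status phrase
#'
#' Implements the ordinal living-status scale: any *not alive* cue in
#' the phrase gives 0; otherwise any *healthy* cue gives 4; with neither
#' cue the score is 2 (alive, health unknown). The not-alive check runs
#' first, so a phrase containing both kinds of cue scores 0.
#'
#' @param phrase Living-status surface text, non-empty.
#' @param lexicons Lexicons from [load_lexicons()].
#' @return Integer score: 0, 2 or 4.
#' @examples
#' score_living_status("passed away")    # 0
#' score_living_status("alive and well") # 4
#' score_living_status("lives in Ohio")  # 2
#' @export
score_living_status <- function(phrase, lexicons = load_lexicons()) {
  stopifnot(is.character(phrase), length(phrase) == 1L, nzchar(phrase))
  if (cue_present(phrase, lexicons$not_alive)) return(0L)
  if (cue_present(phrase, lexicons$healthy)) return(4L)
  2L
}

#' ConText-style negation detection for an observation mention
#'
#' Scans the sentence for negation trigger phrases (matched as lowercase
#' token sequences, e.g. "no family history of", "denies"). Each trigger
#' opens a forward scope running to the sentence end, to a termination
#' conjunction (but / however / although), or to a fixed 6-token window,
#' whichever comes first. An observation whose tokens fall inside any
#' trigger's scope is `Negated`, otherwise `Non_Negated`.
#'
#' @param sentence Sentence (element of `fh_document$sentences`)
#'   containing the observation.
#' @param observation One-row entity table (or any list with `start`,
#'   `end`) for the observation mention.
#' @param lexicons Lexicons from [load_lexicons()].
#' @return `"Negated"` or `"Non_Negated"`.
#' @export
detect_negation <- function(sentence, observation, lexicons = load_lexicons()) {
  toks <- sentence$tokens
  n <- nrow(toks)
  if (n == 0L) return("Non_Negated")
  lw <- tolower(toks$text)
  obs_idx <- which(toks$start < observation$end[1L] &
                   toks$end > observation$start[1L])
  if (length(obs_idx) == 0L) return("Non_Negated")
  trigger_toks <- lapply(lexicons$negation_triggers, function(tr) {
    regmatches(tr, gregexpr("[a-z]+|[^a-z[:space:]]+", tr))[[1]]
  })
  term <- lw %in% lexicons$negation_termination
  for (tt in trigger_toks) {
    L <- length(tt)
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      if (!all(lw[s:(s + L - 1L)] == tt)) next
      scope_start <- s + L
      if (scope_start > n) next
      scope_end <- min(n, scope_start + lexicons$negation_scope - 1L)
      stop_at <- which(term[scope_start:scope_end])
      if (length(stop_at)) scope_end <- scope_start + stop_at[1L] - 2L
      if (scope_end >= scope_start &&
          any(obs_idx >= scope_start & obs_idx <= scope_end)) {
        return("Negated")
      }
    }
  }
  "Non_Negated"
}

# Attach rule-derived attributes to entities: normalization + side for
# family members, negation for observations, score for living status.
apply_entity_attributes <- function(entities, docs, lexicons = load_lexicons()) {
  if (NROW(entities) == 0L) return(entities)
  doc_index <- stats::setNames(seq_along(docs),
                               vapply(docs, `[[`, "", "doc_id"))
  for (i in seq_len(nrow(entities))) {
    doc <- docs[[doc_index[[entities$doc_id[i]]]]]
    sent <- containing_sentence(doc, entities$start[i], entities$end[i])
    cat_i <- entities$category[i]
    if (cat_i == "FamilyMember") {
      norm <- normalize_family_member(entities$text[i], sent,
                                      entities$start[i], lexicons)
      entities$normalized[i] <- norm
      sent_text <- if (is.null(sent)) "" else
        span_text(doc$text, sent$start, sent$end)
      entities$side[i] <- assign_family_side(entities$text[i], sent_text,
                                             norm, lexicons)
    } else if (cat_i == "Observation") {
      entities$negation[i] <- if (is.null(sent)) "Non_Negated" else
        detect_negation(sent, entities[i, ], lexicons)
    } else {
      entities$score[i] <- score_living_status(entities$text[i], lexicons)
    }
  }
  entities
}

containing_sentence <- function(doc, start, end) {
  for (sent in doc$sentences) {
    if (start >= sent$start && end <= sent$end) return(sent)
  }
  # fall back to best-overlapping sentence
  best <- NULL; best_ov <- 0L
  for (sent in doc$sentences) {
    ov <- min(end, sent$end) - max(start, sent$start)
    if (ov > best_ov) { best <- sent; best_ov <- ov }
  }
  best
}
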
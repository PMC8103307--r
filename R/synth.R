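DISEASES <- c(
  "breast cancer", "colon cancer", "lung cancer", "prostate cancer",
  "ovarian cancer", "skin cancer", "pancreatic cancer", "leukemia",
  "lymphoma", "melanoma", "diabetes", "hypertension", "heart disease",
  "coronary artery disease", "stroke", "asthma", "emphysema", "arthritis",
  "osteoporosis", "depression", "anxiety", "schizophrenia", "dementia",
  "kidney disease", "liver disease", "thyroid disease", "anemia",
  "obesity", "glaucoma", "epilepsy", "migraines", "gout")

FIRST_KIN <- c("mother", "father", "brother", "sister", "son", "daughter")
SECOND_KIN <- c("grandmother", "grandfather", "uncle", "aunt", "cousin")
NUM_WORDS <- c("two", "three", "four", "five")

#' Configuration for the synthetic family-history corpus generator
#'
#' @param n_documents Number of documents to generate (>= 1).
#' @param sentences_range Inclusive range of sentences per document.
#' @param seed Integer seed; the generator never touches the caller's
#'   global RNG state.
#' @param rates Named list of probabilities (any subset overrides the
#'   defaults): `negation` (a related observation sentence is phrased
#'   with a negation trigger), `side_cue` (a second-degree relative gets
#'   a paternal/maternal cue), `numeric` (a related observation sentence
#'   uses a numeric kin modifier, e.g. "three uncles"), `nested` (nested
#'   kinship, e.g. "mother has a sister"), `unrelated_obs` (an
#'   observation participates in no relation; the default 0.23 matches a
#'   corpus in which roughly 77% of observation entities are related),
#'   `cross_line` (an unrelated observation is realized as a pair split
#'   across a newline).
#' @return An object of class `fh_gen_config`.
#' @export
gen_config <- function(n_documents = 25L, sentences_range = c(3L, 8L),
                       seed = 1L, rates = list()) {
  defaults <- list(negation = 0.15, side_cue = 0.6, numeric = 0.10,
                   nested = 0.10, unrelated_obs = 0.23, cross_line = 0.4)
  stopifnot(n_documents >= 1L, length(sentences_range) == 2L,
            sentences_range[1L] >= 1L,
            sentences_range[2L] >= sentences_range[1L])
  unknown <- setdiff(names(rates), names(defaults))
  if (length(unknown)) stop("unknown rate(s): ", paste(unknown, collapse = ", "))
  defaults[names(rates)] <- rates
  if (!all(unlist(defaults) >= 0 & unlist(defaults) <= 1)) {
    stop("rates must be probabilities in [0, 1]")
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_range = as.integer(sentences_range),
                 seed = as.integer(seed), rates = defaults),
            class = "fh_gen_config")
}

# Evaluate expr under a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# ---- sentence assembly ------------------------------------------------

lit <- function(text) list(text = text, category = NULL)
ent <- function(text, category, ref = NULL, normalized = NA, side = NA,
                negation = NA, score = NA) {
  list(text = text, category = category, ref = ref, normalized = normalized,
       side = side, negation = negation, score = score)
}

# Assemble parts into one sentence string plus gold entities (offsets
# relative to the sentence) and relation wiring by ref.
assemble <- function(parts, relations = list()) {
  text <- ""
  ents <- fh_entities()
  refs <- character(0)
  for (p in parts) {
    at <- nchar(text)
    text <- paste0(text, p$text)
    if (!is.null(p$category)) {
      ents <- rbind(ents, fh_entities(
        "", p$category, at, at + nchar(p$text), p$text,
        normalized = p$normalized, side = p$side,
        negation = p$negation, score = p$score))
      refs <- c(refs, if (is.null(p$ref)) NA_character_ else p$ref)
    }
  }
  ents$ref <- refs
  list(text = text, entities = ents, relations = relations)
}

pick <- function(x) x[[sample.int(length(x), 1L)]]
coin <- function(p) stats::runif(1L) < p

# A kin noun phrase: surface text plus gold normalized name and side.
draw_kin <- function(rates, possessive = FALSE) {
  second <- coin(0.4)
  kin <- if (second) pick(SECOND_KIN) else pick(FIRST_KIN)
  lex <- load_lexicons()
  norm <- unname(lex$term_map[kin])
  side <- "NA"
  prefix <- ""
  if (second && coin(rates$side_cue)) {
    side <- pick(c("Maternal", "Paternal"))
    prefix <- paste0(side, " ")
  }
  lead <- if (nzchar(prefix)) prefix
          else if (possessive) paste0(pick(c("His", "Her")), " ")
          else ""
  list(surface = kin, lead = lead, normalized = norm, side = side,
       capitalize = !nzchar(lead))
}

cap1 <- function(x) paste0(toupper(substring(x, 1L, 1L)), substring(x, 2L))

# ---- sentence templates ----------------------------------------------
# Each returns assemble() output; an attribute "newline_pair" marks a
# two-sentence group joined by a newline.

tmpl_died_of <- function(rates) {
  k <- draw_kin(rates, possessive = TRUE)
  surf <- if (k$capitalize) cap1(k$surface) else k$surface
  dis <- pick(DISEASES)
  assemble(list(
    lit(k$lead),
    ent(surf, "FamilyMember", ref = "fm", normalized = k$normalized,
        side = k$side),
    lit(" "),
    ent("died", "LivingStatus", ref = "ls", score = 0L),
    lit(" of "),
    ent(dis, "Observation", ref = "obs", negation = "Non_Negated"),
    lit(".")),
    relations = list(list(type = "FamilyMember_LivingStatus",
                          fm = "fm", other = "ls"),
                     list(type = "FamilyMember_Observation",
                          fm = "fm", other = "obs")))
}

tmpl_has_history <- function(rates) {
  k <- draw_kin(rates, possessive = TRUE)
  surf <- if (k$capitalize) cap1(k$surface) else k$surface
  dis <- pick(DISEASES)
  verb <- pick(c(" has a history of ", " was diagnosed with ",
                 " struggled with ", " has "))
  assemble(list(
    lit(k$lead),
    ent(surf, "FamilyMember", ref = "fm", normalized = k$normalized,
        side = k$side),
    lit(verb),
    ent(dis, "Observation", ref = "obs", negation = "Non_Negated"),
    lit(".")),
    relations = list(list(type = "FamilyMember_Observation",
                          fm = "fm", other = "obs")))
}

tmpl_negated_obs <- function(rates) {
  k <- draw_kin(rates, possessive = TRUE)
  surf <- if (k$capitalize) cap1(k$surface) else k$surface
  dis <- pick(DISEASES)
  frame <- pick(c("has no history of", "denies any history of",
                  "is not aware of any"))
  assemble(list(
    lit(k$lead),
    ent(surf, "FamilyMember", ref = "fm", normalized = k$normalized,
        side = k$side),
    lit(paste0(" ", frame, " ")),
    ent(dis, "Observation", ref = "obs", negation = "Negated"),
    lit(".")),
    relations = list(list(type = "FamilyMember_Observation",
                          fm = "fm", other = "obs")))
}

tmpl_numeric_kin <- function(rates) {
  base <- pick(c("uncles", "aunts", "cousins", "brothers", "sisters"))
  lex <- load_lexicons()
  norm <- unname(lex$term_map[base])
  surf <- paste(pick(NUM_WORDS), base)
  dis <- pick(DISEASES)
  assemble(list(
    lit(pick(c("She has ", "He has ", "The patient has "))),
    ent(surf, "FamilyMember", ref = "fm", normalized = norm, side = "NA"),
    lit(" with "),
    ent(dis, "Observation", ref = "obs", negation = "Non_Negated"),
    lit(".")),
    relations = list(list(type = "FamilyMember_Observation",
                          fm = "fm", other = "obs")))
}

tmpl_nested_kin <- function(rates) {
  parent <- pick(c("mother", "father"))
  target <- pick(c("sister", "brother"))
  lex <- load_lexicons()
  comp <- unname(lex$composition[paste(lex$term_map[parent],
                                       lex$term_map[target], sep = "|")])
  side <- if (parent == "mother") "Maternal" else "Paternal"
  dis <- pick(DISEASES)
  possessive <- coin(0.5)
  parts <- c(
    list(lit(pick(c("His ", "Her "))),
         ent(parent, "FamilyMember", ref = "fm0",
             normalized = unname(lex$term_map[parent]), side = "NA")),
    if (possessive) list(lit("'s ")) else list(lit(" has a ")),
    list(ent(target, "FamilyMember", ref = "fm",
             normalized = comp, side = side)),
    if (possessive) list(lit(" had ")) else list(lit(" with ")),
    list(ent(dis, "Observation", ref = "obs", negation = "Non_Negated"),
         lit(".")))
  assemble(parts,
           relations = list(list(type = "FamilyMember_Observation",
                                 fm = "fm", other = "obs")))
}

tmpl_living_status <- function(rates) {
  k <- draw_kin(rates, possessive = FALSE)
  surf <- if (k$capitalize) cap1(k$surface) else k$surface
  u <- stats::runif(1L)
  ls <- if (u < 0.40) {
    list(verb = " ", phrase = pick(c("passed away", "is deceased",
                                     "died last year")), score = 0L)
  } else if (u < 0.75) {
    list(verb = " is ", phrase = pick(c("alive and well", "healthy",
                                        "in good health")), score = 4L)
  } else {
    list(verb = " ", phrase = pick(c("lives out of state",
                                     "lives in Ohio", "is still working")),
         score = 2L)
  }
  assemble(list(
    lit(k$lead),
    ent(surf, "FamilyMember", ref = "fm", normalized = k$normalized,
        side = k$side),
    lit(ls$verb),
    ent(ls$phrase, "LivingStatus", ref = "ls", score = ls$score),
    lit(".")),
    relations = list(list(type = "FamilyMember_LivingStatus",
                          fm = "fm", other = "ls")))
}

tmpl_two_fm <- function(rates) {
  assemble(list(
    ent("Mother", "FamilyMember", ref = "fm1", normalized = "Mother",
        side = "NA"),
    lit(" and "),
    ent("father", "FamilyMember", ref = "fm2", normalized = "Father",
        side = "NA"),
    lit(" are "),
    ent("healthy", "LivingStatus", ref = "ls", score = 4L),
    lit(".")),
    relations = list(list(type = "FamilyMember_LivingStatus",
                          fm = "fm1", other = "ls"),
                     list(type = "FamilyMember_LivingStatus",
                          fm = "fm2", other = "ls")))
}

tmpl_no_family_history <- function(rates) {
  dis <- pick(DISEASES)
  assemble(list(
    lit("No family history of "),
    ent(dis, "Observation", negation = "Negated"),
    lit(".")))
}

tmpl_filler <- function(rates) {
  assemble(list(lit(pick(c(
    "The patient was seen in clinic today.",
    "Family history was reviewed in detail.",
    "Social history is unremarkable.",
    "The patient reports feeling well.")))))
}

# Unrelated observation on its own line, after a family member line: the
# newline between them makes the pair a pruned negative.
tmpl_cross_line <- function(rates) {
  k <- draw_kin(rates, possessive = FALSE)
  surf <- if (k$capitalize) cap1(k$surface) else k$surface
  first <- assemble(list(
    lit(k$lead),
    ent(surf, "FamilyMember", ref = "fm", normalized = k$normalized,
        side = k$side),
    lit(" "),
    ent("is deceased", "LivingStatus", ref = "ls", score = 0L),
    lit(".")),
    relations = list(list(type = "FamilyMember_LivingStatus",
                          fm = "fm", other = "ls")))
  dis <- pick(DISEASES)
  second <- assemble(list(
    ent(cap1(dis), "Observation", negation = "Non_Negated"),
    lit(" was noted in the record.")))
  structure(list(first, second), class = "newline_pair")
}

draw_sentence <- function(rates) {
  u <- stats::runif(1L)
  if (u < 0.50) {                      # observation-bearing
    if (coin(rates$unrelated_obs)) {
      if (coin(rates$cross_line)) tmpl_cross_line(rates)
      else tmpl_no_family_history(rates)
    } else if (coin(rates$nested)) {
      tmpl_nested_kin(rates)
    } else if (coin(rates$numeric)) {
      tmpl_numeric_kin(rates)
    } else if (coin(rates$negation)) {
      tmpl_negated_obs(rates)
    } else if (coin(0.3)) {
      tmpl_died_of(rates)
    } else {
      tmpl_has_history(rates)
    }
  } else if (u < 0.80) {
    tmpl_living_status(rates)
  } else if (u < 0.90) {
    tmpl_two_fm(rates)
  } else {
    tmpl_filler(rates)
  }
}

#' Generate one synthetic family-history document with gold annotations
#'
#' Draws template sentences (kin + disease + living status phrasing with
#' negation triggers, side cues, numeric modifiers, nested kinship and
#' newline-separated pairs) and assembles them into a note whose gold
#' entities carry exact character offsets by construction.
#'
#' @param doc_id Document identifier.
#' @param config A [gen_config()].
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (as when called from [generate_corpus()]).
#' @return List with `document` (an `fh_document`), `entities` and
#'   `relations` (gold tables).
#' @export
generate_document <- function(doc_id = "doc", config = gen_config(),
                              seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_document(doc_id, config)))
  rates <- config$rates
  n_sent <- sample(seq(config$sentences_range[1L], config$sentences_range[2L]),
                   1L)
  text <- ""
  entities <- fh_entities()
  entities$ref <- character(0)
  relations <- fh_relations()
  add_sentence <- function(sent, sep) {
    if (nzchar(text)) text <<- paste0(text, sep)
    at <- nchar(text)
    text <<- paste0(text, sent$text)
    ents <- sent$entities
    if (nrow(ents) > 0L) {
      ents$doc_id <- doc_id
      ents$start <- ents$start + at
      ents$end <- ents$end + at
      entities <<- rbind(entities, ents)
    }
    for (rel in sent$relations) {
      fm <- ents[!is.na(ents$ref) & ents$ref == rel$fm, ]
      other <- ents[!is.na(ents$ref) & ents$ref == rel$other, ]
      relations <<- rbind(relations, fh_relations(
        doc_id, rel$type, fm$normalized, fm$side,
        other_text = other$text,
        score = if (rel$type == "FamilyMember_LivingStatus")
          other$score else NA_integer_,
        negation = if (rel$type == "FamilyMember_Observation")
          other$negation else NA_character_))
    }
  }
  i <- 0L
  while (i < n_sent) {
    s <- draw_sentence(rates)
    if (inherits(s, "newline_pair")) {
      add_sentence(s[[1L]], " ")
      add_sentence(s[[2L]], "\n")
      i <- i + 2L
    } else {
      add_sentence(s, " ")
      i <- i + 1L
    }
  }
  entities$ref <- NULL
  doc <- preprocess(text, doc_id)
  list(document = doc, entities = entities, relations = relations)
}

#' Generate a deterministic synthetic family-history corpus
#'
#' Emulates the make-up of a family-history shared-task corpus: family
#' member, observation and living-status mentions with gold
#' character-offset annotations, family-side cues, negation triggers,
#' numeric and nested kinship modifiers, and a configurable fraction of
#' observations (default about 23%) that participate in no relation.
#' The same seed always yields a byte-identical corpus, and the
#' caller's RNG state is left untouched.
#'
#' @param config A [gen_config()].
#' @return List with `documents` (list of `fh_document`), `entities` and
#'   `relations` (gold tables over all documents).
#' @examples
#' corp <- generate_corpus(gen_config(n_documents = 3, seed = 7))
#' table(corp$entities$category)
#' @export
generate_corpus <- function(config = gen_config()) {
  stopifnot(inherits(config, "fh_gen_config"))
  with_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    entities <- fh_entities()
    relations <- fh_relations()
    for (i in seq_len(config$n_documents)) {
      g <- generate_document(sprintf("synth_%04d", i), config)
      docs[[i]] <- g$document
      entities <- rbind(entities, g$entities)
      relations <- rbind(relations, g$relations)
    }
    list(documents = docs, entities = entities, relations = relations)
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits one `.txt` note per document plus gold `entities.tsv` and
#' `relations.tsv` in the annotation dialect of [write_annotations()].
#'
#' @param corpus Output of [generate_corpus()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_corpus <- function(corpus, out_dir) {
  notes_dir <- file.path(out_dir, "notes")
  dir.create(notes_dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus$documents) {
    writeLines(doc$text, file.path(notes_dir, paste0(doc$doc_id, ".txt")),
               useBytes = TRUE)
  }
  write_annotations(corpus$entities, corpus$relations,
                    file.path(out_dir, "gold"))
  invisible(out_dir)
}
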
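#' famhx: family history information extraction from clinical notes
#'
#' Extracts family-member, observation (disease) and living-status entity
#' mentions and the relations between them (family member-living status,
#' family member-observation) from free-text clinical notes, using a hybrid
#' of rule-based matching and an ensemble of bidirectional recurrent BIO
#' sequence taggers, plus online-gradient-descent linear relation
#' classifiers and heuristic attribute rules.
#'
#' All character offsets in the package are 0-based and half-open:
#' a span `[start, end)` covers `substring(text, start + 1, end)`.
#'
#' @useDynLib famhx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

ENTITY_CATEGORIES <- c("FamilyMember", "Observation", "LivingStatus")

#' Preprocess a clinical note into sentences and POS-tagged tokens
#'
#' Splits raw note text into sentences (at `.`, `!`, `?` followed by
#' whitespace, and at newlines) and each sentence into tokens annotated
#' with Penn-Treebank part-of-speech tags from a small deterministic
#' lexicon-and-suffix tagger. Offsets are 0-based half-open character
#' spans into the original text, so every token's text equals the
#' document substring at its span.
#'
#' @param raw_text Note text (UTF-8), non-empty.
#' @param doc_id Document identifier (by convention, the file name stem).
#' @return An object of class `fh_document`: a list with `doc_id`, `text`
#'   and `sentences`, each sentence a list with `start`, `end` and a
#'   `tokens` data frame (`text`, `start`, `end`, `pos`).
#' @examples
#' doc <- preprocess("Mother has diabetes. Father is deceased.", "doc1")
#' length(doc$sentences)
#' doc$sentences[[1]]$tokens
#' @export
preprocess <- function(raw_text, doc_id = "doc") {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text) || !nzchar(trimws(raw_text))) {
    stop("unusable document '", doc_id, "': empty text")
  }
  spans <- split_sentences(raw_text)
  sentences <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]
    e <- spans$end[i]
    sent_text <- substring(raw_text, s + 1L, e)
    toks <- tokenize(sent_text)
    toks$start <- toks$start + s
    toks$end <- toks$end + s
    first_cap <- nrow(toks) > 0L && grepl("^[A-Z]", toks$text[1L])
    toks$pos <- pos_tag(toks$text, sentence_initial_capital = first_cap)
    list(start = s, end = e, tokens = toks)
  })
  structure(list(doc_id = doc_id, text = raw_text, sentences = sentences),
            class = "fh_document")
}

#' @export
print.fh_document <- function(x, ...) {
  n_tok <- sum(vapply(x$sentences, function(s) nrow(s$tokens), integer(1)))
  cat(sprintf("<fh_document '%s': %d chars, %d sentences, %d tokens>\n",
              x$doc_id, nchar(x$text), length(x$sentences), n_tok))
  invisible(x)
}

# Sentence spans (0-based half-open), trimmed of surrounding whitespace.
split_sentences <- function(text) {
  n <- nchar(text)
  m <- gregexpr("[.!?](?=\\s|$)|\n", text, perl = TRUE)[[1]]
  cut_after <- integer(0)                 # 1-based index of last char kept
  if (m[1L] != -1L) {
    for (p in as.integer(m)) {
      ch <- substring(text, p, p)
      cut_after <- c(cut_after, if (ch == "\n") p - 1L else p)
    }
  }
  cut_after <- unique(c(cut_after, n))
  starts <- c(1L, cut_after[-length(cut_after)] + 1L)
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_along(cut_after)) {
    s <- starts[i]; e <- cut_after[i]
    if (e < s) next
    seg <- substring(text, s, e)
    lead <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[[:space:]]+$", "", seg))
    s2 <- s + lead; e2 <- e - trail
    if (e2 < s2) next
    out <- rbind(out, data.frame(start = s2 - 1L, end = e2))
  }
  if (nrow(out) == 0L) out <- data.frame(start = 0L, end = n)
  out
}

# Word / number / possessive / punctuation tokens with 0-based spans
# relative to the supplied string.
tokenize <- function(text) {
  m <- gregexpr("'s(?![A-Za-z])|[A-Za-z]+|[0-9]+|[^A-Za-z0-9[:space:]]",
                text, perl = TRUE)[[1]]
  if (m[1L] == -1L) {
    return(data.frame(text = character(0), start = integer(0),
                      end = integer(0), pos = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(text = substring(text, starts, starts + lens - 1L),
             start = starts - 1L, end = starts + lens - 1L,
             pos = NA_character_, stringsAsFactors = FALSE)
}

.pos_lexicon <- local({
  lex <- c(
    the = "DT", a = "DT", an = "DT", this = "DT", that = "DT",
    these = "DT", those = "DT", any = "DT", some = "DT", no = "DT",
    each = "DT", every = "DT", both = "DT", all = "DT", another = "DT",
    he = "PRP", she = "PRP", it = "PRP", they = "PRP", i = "PRP",
    we = "PRP", you = "PRP", him = "PRP", them = "PRP", her = "PRP$",
    his = "PRP$", its = "PRP$", their = "PRP$", my = "PRP$", our = "PRP$",
    your = "PRP$", who = "WP",
    of = "IN", "in" = "IN", on = "IN", with = "IN", at = "IN", "for" = "IN",
    from = "IN", by = "IN", about = "IN", after = "IN", before = "IN",
    during = "IN", without = "IN", against = "IN", since = "IN",
    out = "IN", into = "IN",
    to = "TO", and = "CC", or = "CC", but = "CC", nor = "CC",
    will = "MD", would = "MD", can = "MD", could = "MD", may = "MD",
    might = "MD", shall = "MD", should = "MD", must = "MD",
    is = "VBZ", was = "VBD", are = "VBP", were = "VBD", be = "VB",
    been = "VBN", being = "VBG", am = "VBP",
    has = "VBZ", have = "VBP", had = "VBD", does = "VBZ", do = "VBP",
    did = "VBD",
    died = "VBD", passed = "VBD", reported = "VBD", noted = "VBD",
    diagnosed = "VBN", denied = "VBD", expired = "VBD", treated = "VBN",
    suffered = "VBD", survived = "VBD", struggled = "VBD",
    denies = "VBZ", reports = "VBZ", lives = "VBZ", suffers = "VBZ",
    smokes = "VBZ", remains = "VBZ", struggles = "VBZ", lived = "VBD",
    living = "VBG", away = "RB", ago = "RB",
    not = "RB", never = "RB", also = "RB", currently = "RB", still = "RB",
    longer = "RB", however = "RB", although = "IN", very = "RB",
    healthy = "JJ", alive = "JJ", well = "JJ", deceased = "JJ",
    dead = "JJ", good = "JJ", general = "JJ", maternal = "JJ",
    paternal = "JJ", medical = "JJ", significant = "JJ", aware = "JJ",
    unremarkable = "JJ", positive = "JJ", negative = "JJ", late = "JJ",
    early = "JJ", several = "JJ", old = "JJ", young = "JJ", unknown = "JJ",
    one = "CD", two = "CD", three = "CD", four = "CD", five = "CD",
    six = "CD", seven = "CD", eight = "CD", nine = "CD", ten = "CD",
    eleven = "CD", twelve = "CD", twice = "CD"
  )
  lex
})

.punct_pos <- c("." = ".", "," = ",", ":" = ":", ";" = ":", "?" = ".",
                "!" = ".", "(" = "-LRB-", ")" = "-RRB-", '"' = "''",
                "'" = "''", "-" = ":", "/" = ":")

# Deterministic Penn-Treebank tagging: closed-class lexicon, then suffix
# and local-context rules (a token after a modal or 'to' is a base verb).
pos_tag <- function(tokens, sentence_initial_capital = TRUE) {
  n <- length(tokens)
  if (n == 0L) return(character(0))
  tags <- character(n)
  lower <- tolower(tokens)
  prev_tag <- ""
  for (i in seq_len(n)) {
    tok <- tokens[i]
    lw <- lower[i]
    lex_tag <- unname(.pos_lexicon[lw])
    closed <- !is.na(lex_tag) &&
      !(lex_tag %in% c("NN", "JJ") || startsWith(lex_tag, "V"))
    tag <- if (tok == "'s") {
      "POS"
    } else if (grepl("^[0-9]+$", tok)) {
      "CD"
    } else if (!grepl("[A-Za-z0-9]", tok)) {
      p <- .punct_pos[tok]
      if (is.na(p)) "SYM" else unname(p)
    } else if (closed) {
      lex_tag
    } else if (prev_tag %in% c("MD", "TO")) {
      "VB"
    } else if (!is.na(lex_tag)) {
      lex_tag
    } else if (grepl("ly$", lw) && nchar(lw) > 3L) {
      "RB"
    } else if (grepl("ing$", lw) && nchar(lw) > 5L) {
      "VBG"
    } else if (grepl("[A-Z]", substring(tok, 1L, 1L)) &&
               !(i == 1L && sentence_initial_capital)) {
      "NNP"
    } else if (grepl("s$", lw) && !grepl("ss$", lw) && nchar(lw) > 3L) {
      "NNS"
    } else {
      "NN"
    }
    tags[i] <- tag
    prev_tag <- tag
  }
  tags
}

# Flatten a document's tokens into one data frame with sentence indices.
doc_tokens <- function(doc) {
  out <- lapply(seq_along(doc$sentences), function(i) {
    t <- doc$sentences[[i]]$tokens
    if (nrow(t) > 0L) t$sentence <- i
    t
  })
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  if (length(out) == 0L) {
    return(data.frame(text = character(0), start = integer(0),
                      end = integer(0), pos = character(0),
                      sentence = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Substring at a 0-based half-open span.
span_text <- function(text, start, end) substring(text, start + 1L, end)
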
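#' Generate candidate family member-other entity pairs for a document
#'
#' Crosses every family member mention with every living-status and
#' observation mention of the same document. In training mode, pairs
#' whose document-level tuple (family member normalized name + side,
#' other entity text) appears in the gold relations are labeled
#' `related` and the rest `unrelated`; negative pairs separated by a
#' newline are filtered out. The same newline pruning is applied to
#' test pairs so the classifier sees the distribution it was trained
#' on.
#'
#' @param entities Entity table for the document, with attributes
#'   (`normalized`, `side`) already assigned to family members.
#' @param doc The `fh_document`.
#' @param mode `"train"` (labels from `gold_relations`) or `"test"`.
#' @param gold_relations Gold relation table (required for training).
#' @return Data frame of candidate pairs: `doc_id`, `type`, `fm_row`,
#'   `other_row` (row indices into `entities`), `label` (1 related,
#'   0 unrelated, `NA` in test mode).
#' @export
generate_candidate_pairs <- function(entities, doc, mode = c("test", "train"),
                                     gold_relations = NULL) {
  mode <- match.arg(mode)
  if (mode == "train" && is.null(gold_relations)) {
    stop("training mode requires gold relations")
  }
  ent <- entities[entities$doc_id == doc$doc_id, , drop = FALSE]
  fm_rows <- which(ent$category == "FamilyMember")
  other_rows <- which(ent$category != "FamilyMember")
  out <- data.frame(doc_id = character(0), type = character(0),
                    fm_row = integer(0), other_row = integer(0),
                    label = integer(0), stringsAsFactors = FALSE)
  if (length(fm_rows) == 0L || length(other_rows) == 0L) return(out)
  gold_doc <- if (!is.null(gold_relations)) {
    gold_relations[gold_relations$doc_id == doc$doc_id, , drop = FALSE]
  }
  for (i in fm_rows) {
    for (j in other_rows) {
      type <- if (ent$category[j] == "LivingStatus") {
        "FamilyMember_LivingStatus"
      } else {
        "FamilyMember_Observation"
      }
      label <- NA_integer_
      if (mode == "train") {
        hit <- gold_doc$type == type &
          gold_doc$fm_normalized == ent$normalized[i] &
          gold_doc$fm_side == ent$side[i]
        # gold that stores the other entity's surface text matches on
        # it; tuple-only living-status gold matches on the score
        hit <- hit & ifelse(!is.na(gold_doc$other_text),
                            gold_doc$other_text == ent$text[j],
                            !is.na(ent$score[j]) &
                              gold_doc$score == ent$score[j])
        label <- as.integer(isTRUE(any(hit, na.rm = TRUE)))
      }
      # newline pruning between the pair's spans
      lo <- min(ent$end[i], ent$end[j])
      hi <- max(ent$start[i], ent$start[j])
      has_newline <- hi > lo &&
        grepl("\n", span_text(doc$text, lo, hi), fixed = TRUE)
      if (has_newline && (is.na(label) || label == 0L)) next
      out <- rbind(out, data.frame(doc_id = doc$doc_id, type = type,
                                   fm_row = i, other_row = j, label = label,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Extract sparse lexical features for a candidate pair
#'
#' Indicator features over lowercase tokens in eight namespaces: the
#' words inside each of the two mentions, the 7 tokens preceding and
#' the 7 tokens following each mention (truncated at document edges),
#' the words strictly between the two mentions, and the number of other
#' family member mentions between the pair, bucketed at 0/1/2/3+.
#'
#' @param pair One row of [generate_candidate_pairs()] output.
#' @param doc The `fh_document`.
#' @param entities The entity table the pair indexes into.
#' @param window Tokens of context on each side of a mention (7).
#' @return Character vector of `namespace=token` feature strings.
#' @export
extract_features <- function(pair, doc, entities, window = 7L) {
  toks <- doc_tokens(doc)
  lw <- tolower(toks$text)
  fm <- entities[pair$fm_row, ]
  other <- entities[pair$other_row, ]
  span_toks <- function(e) which(toks$start < e$end & toks$end > e$start)
  fm_t <- span_toks(fm)
  ot_t <- span_toks(other)
  n <- nrow(toks)
  ctx <- function(idx, side) {
    if (length(idx) == 0L) return(integer(0))
    if (side == "left") {
      lo <- max(1L, min(idx) - window)
      if (min(idx) == 1L) integer(0) else seq(lo, min(idx) - 1L)
    } else {
      hi <- min(n, max(idx) + window)
      if (max(idx) == n) integer(0) else seq(max(idx) + 1L, hi)
    }
  }
  between <- if (length(fm_t) && length(ot_t)) {
    lo <- min(max(fm_t), max(ot_t))
    hi <- max(min(fm_t), min(ot_t))
    if (hi - lo > 1L) seq(lo + 1L, hi - 1L) else integer(0)
  } else {
    integer(0)
  }
  fm_between <- entities$category == "FamilyMember" &
    entities$doc_id == fm$doc_id &
    entities$start >= min(fm$end, other$end) &
    entities$end <= max(fm$start, other$start)
  bucket <- min(sum(fm_between), 3L)
  ns <- function(prefix, words) {
    if (length(words) == 0L) character(0) else paste0(prefix, "=", words)
  }
  feats <- c(
    ns("fm_w", lw[fm_t]),
    ns("ot_w", lw[ot_t]),
    ns("fm_l", lw[ctx(fm_t, "left")]),
    ns("fm_r", lw[ctx(fm_t, "right")]),
    ns("ot_l", lw[ctx(ot_t, "left")]),
    ns("ot_r", lw[ctx(ot_t, "right")]),
    ns("btw", lw[between]),
    paste0("type=", pair$type),
    paste0("cnt=", if (bucket == 3L) "3plus" else bucket))
  unique(feats)
}

#' Train a binary online-gradient-descent relation classifier
#'
#' Logistic loss, one gradient update per example, learning rate
#' `lr0 / sqrt(t)` over the running update count, features hashed into
#' `2^hash_bits` dimensions, seeded example shuffling each pass, 100
#' passes by default.
#'
#' @param features List of feature-string vectors
#'   ([extract_features()] output), one per example.
#' @param labels Integer vector of 0/1 labels (both classes required).
#' @param passes Training passes over the data.
#' @param lr0 Base learning rate.
#' @param hash_bits Feature space is `2^hash_bits`.
#' @param seed Shuffling seed.
#' @return Object of class `fh_relation_model`.
#' @export
train_relation_model <- function(features, labels, passes = 100L, lr0 = 0.5,
                                 hash_bits = 18L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(features) != length(labels)) stop("features/labels length mismatch")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 with no missing values")
  }
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both related and unrelated examples")
  }
  dim <- bitwShiftL(1L, hash_bits)
  idx <- lapply(features, hash_features, dim = dim)
  fit <- ogd_fit(idx, labels, dim, passes, lr0, seed)
  structure(list(weights = fit$weights, bias = fit$bias,
                 pass_loss = fit$pass_loss, passes = as.integer(passes),
                 lr0 = lr0, hash_bits = as.integer(hash_bits),
                 seed = as.integer(seed)),
            class = "fh_relation_model")
}

#' @export
print.fh_relation_model <- function(x, ...) {
  cat(sprintf(paste0("<fh_relation_model: OGD logistic classifier, 2^%d ",
                     "hashed features, %d passes, final loss %.4f>\n"),
              x$hash_bits, x$passes, x$pass_loss[length(x$pass_loss)]))
  invisible(x)
}

#' Classify candidate pairs as related or unrelated
#'
#' Deterministic given the trained weights; a pair is `related` when
#' the predicted probability is at least 0.5 (ties count as related).
#'
#' @param model An `fh_relation_model`.
#' @param features List of feature-string vectors.
#' @return Data frame with `probability` and logical `related`.
#' @export
classify_pairs <- function(model, features) {
  dim <- bitwShiftL(1L, model$hash_bits)
  idx <- lapply(features, hash_features, dim = dim)
  prob <- ogd_decision(idx, model$weights, model$bias)
  data.frame(probability = prob, related = prob >= 0.5)
}

#' @export
#' @method predict fh_relation_model
#' @param object,newdata,... `newdata` is a list of feature-string
#'   vectors; returns the [classify_pairs()] data frame.
predict.fh_relation_model <- function(object, newdata, ...) {
  classify_pairs(object, newdata)
}

#' Assemble typed relations from positively classified pairs
#'
#' Family member-living status relations carry the rule-based score of
#' the living-status phrase (0 not alive, 4 healthy, 2 otherwise);
#' family member-observation relations carry ConText-style negation
#' detected over the observation's sentence. Duplicate tuples (same
#' document, family member tuple and other entity tuple) collapse to a
#' single relation.
#'
#' @param pairs Candidate-pair rows classified as related.
#' @param entities The entity table the pairs index into.
#' @param docs List of `fh_document`s (for negation context).
#' @param lexicons Lexicons from [load_lexicons()].
#' @return Relation table.
#' @export
assemble_relations <- function(pairs, entities, docs,
                               lexicons = load_lexicons()) {
  out <- fh_relations()
  if (NROW(pairs) == 0L) return(out)
  doc_ids <- vapply(docs, `[[`, "", "doc_id")
  for (k in seq_len(nrow(pairs))) {
    fm <- entities[pairs$fm_row[k], ]
    other <- entities[pairs$other_row[k], ]
    doc <- docs[[match(pairs$doc_id[k], doc_ids)]]
    if (pairs$type[k] == "FamilyMember_LivingStatus") {
      out <- rbind(out, fh_relations(
        pairs$doc_id[k], "FamilyMember_LivingStatus",
        fm$normalized, fm$side, other_text = other$text,
        score = score_living_status(other$text, lexicons)))
    } else {
      sent <- containing_sentence(doc, other$start, other$end)
      neg <- if (is.null(sent)) "Non_Negated" else
        detect_negation(sent, other, lexicons)
      out <- rbind(out, fh_relations(
        pairs$doc_id[k], "FamilyMember_Observation",
        fm$normalized, fm$side, other_text = other$text,
        negation = neg))
    }
  }
  unique(out)
}
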
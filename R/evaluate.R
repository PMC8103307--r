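#' Micro-averaged precision, recall and F1 from pooled counts
#'
#' Precision is `100 * TP / (TP + FP)`, recall `100 * TP / (TP + FN)`
#' (0 when the denominator is 0), and F1 their harmonic mean with equal
#' weight. Values are percentages; reports round to 2 decimals.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `precision`, `recall`, `f1` (percent,
#'   unrounded).
#' @examples
#' micro_prf(5, 5, 5)  # 50/50/50
#' @export
micro_prf <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Percentages (or any common scale).
#' @return F1 on the same scale (0 when both inputs are 0).
#' @examples
#' f1_score(78.90, 83.84)  # 81.30 to 2 decimals
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Attribute matching specification for evaluation
#'
#' Controls which entity attributes must agree for a true positive,
#' mirroring attribute-ablation reporting where the system is rescored
#' with one attribute ignored at a time.
#'
#' @param ignore_side Ignore the family side of family members.
#' @param ignore_living_status Ignore living-status scores.
#' @param ignore_negation Ignore observation negation.
#' @return Object of class `fh_match_spec`.
#' @export
match_spec <- function(ignore_side = FALSE, ignore_living_status = FALSE,
                       ignore_negation = FALSE) {
  structure(list(ignore_side = isTRUE(ignore_side),
                 ignore_living_status = isTRUE(ignore_living_status),
                 ignore_negation = isTRUE(ignore_negation)),
            class = "fh_match_spec")
}

lower_words <- function(x) {
  regmatches(tolower(x), gregexpr("[a-z0-9]+", tolower(x)))
}

# Greedy 1:1 word-overlap assignment between system and reference
# strings (>= 1 lowercase alphanumeric word in common), in supplied
# order; returns TP count.
greedy_overlap_tp <- function(sys, ref) {
  if (length(sys) == 0L || length(ref) == 0L) return(0L)
  sys_w <- lower_words(sys)
  ref_w <- lower_words(ref)
  used <- logical(length(ref))
  tp <- 0L
  for (i in seq_along(sys_w)) {
    for (j in seq_along(ref_w)) {
      if (!used[j] && length(intersect(sys_w[[i]], ref_w[[j]])) > 0L) {
        used[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  tp
}

# Multiset intersection size of two key vectors (keys already deduped
# at the full-attribute level; reduced keys may repeat).
multiset_tp <- function(s, r) {
  if (length(s) == 0L || length(r) == 0L) return(0L)
  ts <- table(s)
  tr <- table(r)
  common <- intersect(names(ts), names(tr))
  as.integer(sum(pmin(ts[common], tr[common])))
}

report_row <- function(tp, fp, fn) {
  m <- micro_prf(tp, fp, fn)
  data.frame(tp = tp, fp = fp, fn = fn,
             precision = round(m[["precision"]], 2),
             recall = round(m[["recall"]], 2),
             f1 = round(m[["f1"]], 2))
}

finish_report <- function(rows) {
  per <- do.call(rbind, lapply(names(rows), function(nm) {
    cbind(data.frame(category = nm, stringsAsFactors = FALSE),
          report_row(rows[[nm]][1L], rows[[nm]][2L], rows[[nm]][3L]))
  }))
  tot <- Reduce(`+`, rows)
  out <- rbind(per, cbind(data.frame(category = "Overall"),
                          report_row(tot[1L], tot[2L], tot[3L])))
  rownames(out) <- NULL
  class(out) <- c("fh_eval_report", "data.frame")
  out
}

#' Evaluate entity predictions against a reference standard
#'
#' Document-level unique-tuple matching. A family member is a true
#' positive when the reference contains the same (document, normalized
#' name, family side) tuple — side being ignored under the matching
#' spec. Observations match when system and reference texts share at
#' least one lowercase word, assigned greedily one-to-one per document
#' (each reference consumed at most once).
#'
#' @param system,reference Entity tables.
#' @param spec A [match_spec()].
#' @return An `fh_eval_report` data frame: per-category and overall
#'   TP/FP/FN with micro-averaged precision, recall and F1 (percent,
#'   2 decimals).
#' @export
evaluate_entities <- function(system, reference, spec = match_spec()) {
  fm_tuple <- function(e) {
    fm <- e[e$category == "FamilyMember", , drop = FALSE]
    side <- ifelse(is.na(fm$side), "NA", fm$side)
    full <- paste(fm$doc_id, fm$normalized, side, sep = "\r")
    keep <- !duplicated(full)
    if (spec$ignore_side) {
      paste(fm$doc_id, fm$normalized, sep = "\r")[keep]
    } else {
      full[keep]
    }
  }
  s_fm <- fm_tuple(system)
  r_fm <- fm_tuple(reference)
  fm_tp <- multiset_tp(s_fm, r_fm)
  fm_counts <- c(fm_tp, length(s_fm) - fm_tp, length(r_fm) - fm_tp)

  obs_tp <- 0L; obs_fp <- 0L; obs_fn <- 0L
  s_obs <- system[system$category == "Observation", , drop = FALSE]
  r_obs <- reference[reference$category == "Observation", , drop = FALSE]
  for (d in union(s_obs$doc_id, r_obs$doc_id)) {
    s_d <- unique(tolower(s_obs$text[s_obs$doc_id == d]))
    r_d <- unique(tolower(r_obs$text[r_obs$doc_id == d]))
    tp <- greedy_overlap_tp(s_d, r_d)
    obs_tp <- obs_tp + tp
    obs_fp <- obs_fp + length(s_d) - tp
    obs_fn <- obs_fn + length(r_d) - tp
  }
  finish_report(list(FamilyMember = fm_counts,
                     Observation = c(obs_tp, obs_fp, obs_fn)))
}

#' Evaluate relation predictions against a reference standard
#'
#' Living-status relations match on the (document, family member
#' normalized name + side, score) tuple; observation relations on the
#' family member tuple, word-overlap observation matching (greedy,
#' one-to-one) and negation. Attributes are dropped from the tuples
#' according to the matching spec.
#'
#' @inheritParams evaluate_entities
#' @param system,reference Relation tables.
#' @return An `fh_eval_report` data frame.
#' @export
evaluate_relations <- function(system, reference, spec = match_spec()) {
  side_of <- function(x) if (spec$ignore_side) rep("", NROW(x)) else
    ifelse(is.na(x$fm_side), "NA", x$fm_side)

  ls_tuple <- function(r) {
    ls <- r[r$type == "FamilyMember_LivingStatus", , drop = FALSE]
    side_full <- ifelse(is.na(ls$fm_side), "NA", ls$fm_side)
    full <- paste(ls$doc_id, ls$fm_normalized, side_full, ls$score,
                  sep = "\r")
    keep <- !duplicated(full)
    score <- if (spec$ignore_living_status) rep("", nrow(ls)) else ls$score
    paste(ls$doc_id, ls$fm_normalized, side_of(ls), score, sep = "\r")[keep]
  }
  s_ls <- ls_tuple(system)
  r_ls <- ls_tuple(reference)
  ls_tp <- multiset_tp(s_ls, r_ls)
  ls_counts <- c(ls_tp, length(s_ls) - ls_tp, length(r_ls) - ls_tp)

  obs_group <- function(r) {
    o <- r[r$type == "FamilyMember_Observation", , drop = FALSE]
    side_full <- ifelse(is.na(o$fm_side), "NA", o$fm_side)
    full <- paste(o$doc_id, o$fm_normalized, side_full, o$negation,
                  tolower(o$other_text), sep = "\r")
    neg <- if (spec$ignore_negation) rep("", nrow(o)) else o$negation
    o$group <- paste(o$doc_id, o$fm_normalized, side_of(o), neg, sep = "\r")
    o[!duplicated(full), , drop = FALSE]
  }
  s_obs <- obs_group(system)
  r_obs <- obs_group(reference)
  obs_tp <- 0L
  for (g in union(s_obs$group, r_obs$group)) {
    obs_tp <- obs_tp + greedy_overlap_tp(s_obs$other_text[s_obs$group == g],
                                         r_obs$other_text[r_obs$group == g])
  }
  obs_counts <- c(obs_tp, nrow(s_obs) - obs_tp, nrow(r_obs) - obs_tp)
  finish_report(list(LivingStatus = ls_counts, Observation = obs_counts))
}

#' Accuracy of the rule-based attribute classifiers on gold concepts
#'
#' Runs each heuristic on reference-standard concepts (oracle spans)
#' and reports the percentage of correct predictions among total
#' instances, per task: family member normalization, family side,
#' living-status scoring (over gold living-status mentions), and
#' observation negation (over gold observation mentions with an
#' annotated negation value).
#'
#' @param docs List of `fh_document`s.
#' @param gold_entities Gold entity table with spans and attributes.
#' @param gold_relations Unused; accepted so a full gold standard can
#'   be passed through unchanged.
#' @param lexicons Lexicons from [load_lexicons()].
#' @return Named numeric vector of accuracies in percent
#'   (`normalization`, `side`, `living_status`, `negation`), with
#'   counts as an attribute.
#' @export
attribute_accuracy <- function(docs, gold_entities, gold_relations = NULL,
                               lexicons = load_lexicons()) {
  doc_ids <- vapply(docs, `[[`, "", "doc_id")
  fm <- gold_entities[gold_entities$category == "FamilyMember", , drop = FALSE]
  norm_ok <- side_ok <- logical(nrow(fm))
  for (i in seq_len(nrow(fm))) {
    doc <- docs[[match(fm$doc_id[i], doc_ids)]]
    sent <- containing_sentence(doc, fm$start[i], fm$end[i])
    pred_norm <- normalize_family_member(fm$text[i], sent, fm$start[i],
                                         lexicons)
    norm_ok[i] <- identical(pred_norm, fm$normalized[i])
    sent_text <- if (is.null(sent)) "" else
      span_text(doc$text, sent$start, sent$end)
    pred_side <- assign_family_side(fm$text[i], sent_text, fm$normalized[i],
                                    lexicons)
    side_ok[i] <- identical(pred_side,
                            ifelse(is.na(fm$side[i]), "NA", fm$side[i]))
  }

  ls_ents <- gold_entities[gold_entities$category == "LivingStatus" &
                           !is.na(gold_entities$score), , drop = FALSE]
  ls_ok <- vapply(seq_len(nrow(ls_ents)), function(i) {
    score_living_status(ls_ents$text[i], lexicons) == ls_ents$score[i]
  }, logical(1))

  obs_ents <- gold_entities[gold_entities$category == "Observation" &
                            !is.na(gold_entities$negation), , drop = FALSE]
  obs_ok <- logical(nrow(obs_ents))
  for (i in seq_len(nrow(obs_ents))) {
    doc <- docs[[match(obs_ents$doc_id[i], doc_ids)]]
    sent <- containing_sentence(doc, obs_ents$start[i], obs_ents$end[i])
    pred <- if (is.null(sent)) "Non_Negated" else
      detect_negation(sent, obs_ents[i, ], lexicons)
    obs_ok[i] <- identical(pred, obs_ents$negation[i])
  }

  acc <- function(ok) if (length(ok) == 0L) NA_real_ else 100 * mean(ok)
  out <- c(normalization = acc(norm_ok), side = acc(side_ok),
           living_status = acc(ls_ok), negation = acc(obs_ok))
  attr(out, "n") <- c(normalization = nrow(fm), side = nrow(fm),
                      living_status = nrow(ls_ents), negation = nrow(obs_ents))
  out
}

#' Sweep the ensemble voting threshold and score each setting
#'
#' Resolves the vote table at every threshold and evaluates each
#' resulting entity set against the reference, yielding the
#' precision/recall trade-off curve of the voting ensemble (the
#' candidate pool shrinks monotonically as the threshold rises).
#'
#' @param predictions List of per-model entity tables (with spans).
#' @param reference Gold entity table.
#' @param docs List of `fh_document`s (for attribute assignment before
#'   scoring).
#' @param thresholds Integer thresholds to evaluate.
#' @param spec A [match_spec()].
#' @param lexicons Lexicons for attribute assignment.
#' @return Data frame with one row per threshold: overall TP/FP/FN,
#'   precision, recall, F1 and the surviving candidate count.
#' @export
sweep_thresholds <- function(predictions, reference, docs,
                             thresholds = seq_along(predictions),
                             spec = match_spec(),
                             lexicons = load_lexicons()) {
  votes <- collect_votes(predictions)
  ranking <- if (length(predictions) >= 2L) rank_models(predictions)
  rows <- lapply(thresholds, function(th) {
    ents <- resolve_entities(votes, ranking, th)
    ents <- apply_entity_attributes(ents, docs, lexicons)
    rep <- evaluate_entities(ents, reference, spec)
    ov <- rep[rep$category == "Overall", ]
    data.frame(threshold = th, candidates = nrow(ents), tp = ov$tp,
               fp = ov$fp, fn = ov$fn, precision = ov$precision,
               recall = ov$recall, f1 = ov$f1)
  })
  do.call(rbind, rows)
}
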
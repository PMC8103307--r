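#' Tally candidate entities across ensemble members
#'
#' Each distinct candidate — identified exactly by document, category
#' and character span — is keyed once, with the set of models that
#' voted for it.
#'
#' @param predictions List of entity tables, one per ensemble member,
#'   over the same documents.
#' @return Object of class `fh_vote_table`: a data frame with the
#'   candidate columns plus `votes` and a `voters` list column of model
#'   indices; the number of models is kept as attribute `n_models`.
#' @export
collect_votes <- function(predictions) {
  n <- length(predictions)
  rows <- list()
  for (i in seq_len(n)) {
    p <- predictions[[i]]
    if (NROW(p) == 0L) next
    p <- p[!duplicated(entity_key(p)), , drop = FALSE]
    p$model <- i
    rows[[length(rows) + 1L]] <- p[, c("doc_id", "category", "start", "end",
                                       "text", "model")]
  }
  if (length(rows) == 0L) {
    out <- data.frame(doc_id = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      text = character(0), votes = integer(0))
    out$voters <- list()
  } else {
    all <- do.call(rbind, rows)
    key <- paste(all$doc_id, all$category, all$start, all$end, sep = "\r")
    first <- !duplicated(key)
    out <- all[first, c("doc_id", "category", "start", "end", "text")]
    out$votes <- as.integer(table(key)[key[first]])
    out$voters <- unname(split(all$model, key)[key[first]])
    rownames(out) <- NULL
  }
  attr(out, "n_models") <- n
  class(out) <- c("fh_vote_table", "data.frame")
  out
}

#' Rank ensemble members by agreement with the other members
#'
#' Member `i`'s agreement with member `j` is the entity F1 of `i`'s
#' predictions scored against `j`'s as reference, with exact span and
#' category matching (F1 is symmetric under swapping system and
#' reference, so the matrix is symmetric). Members are ranked by their
#' mean agreement with all other members, best first; ties break by
#' model index.
#'
#' @param predictions List of at least two entity tables.
#' @return Object of class `fh_model_ranking`: list with `pairwise_f1`
#'   (NxN matrix, diagonal `NA`), `mean_agreement`, and `rank` (model
#'   indices, best first).
#' @export
rank_models <- function(predictions) {
  n <- length(predictions)
  if (n < 2L) stop("model ranking requires at least 2 prediction sets")
  keys <- lapply(predictions, function(p) unique(entity_key(p)))
  f1 <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      tp <- length(intersect(keys[[i]], keys[[j]]))
      fp <- length(keys[[i]]) - tp
      fn <- length(keys[[j]]) - tp
      f <- micro_prf(tp, fp, fn)[["f1"]]
      f1[i, j] <- f
      f1[j, i] <- f
    }
  }
  mean_agr <- rowMeans(f1, na.rm = TRUE)
  mean_agr[is.nan(mean_agr)] <- 0
  rank <- order(-mean_agr, seq_len(n))
  structure(list(pairwise_f1 = f1, mean_agreement = mean_agr, rank = rank),
            class = "fh_model_ranking")
}

#' @export
print.fh_model_ranking <- function(x, ...) {
  cat("<fh_model_ranking>\n  rank (best first):",
      paste(x$rank, collapse = " "), "\n  mean agreement (F1 %):",
      paste(sprintf("%.2f", x$mean_agreement), collapse = " "), "\n")
  invisible(x)
}

# Preference order between vote-table rows: more votes first, then the
# candidate whose best voter has the better (smaller) rank position,
# then earlier span start / end.
vote_preference_order <- function(votes, ranking) {
  n_models <- attr(votes, "n_models")
  rank_pos <- seq_len(max(n_models, 1L))
  if (!is.null(ranking)) rank_pos[ranking$rank] <- seq_along(ranking$rank)
  best_rank <- vapply(votes$voters, function(v) min(rank_pos[v]), numeric(1))
  order(-votes$votes, best_rank, votes$start, votes$end)
}

#' Resolve voted candidates into a final entity set
#'
#' Keeps candidates with at least `threshold` votes, then resolves
#' character-overlapping candidates of the same category within a
#' document: the higher vote count wins; on a tie, the candidate whose
#' best-ranked voting model outranks the other's wins; any remaining tie
#' goes to the earlier span start. The result contains no two
#' overlapping same-category entities.
#'
#' @param votes An [collect_votes()] table.
#' @param ranking An [rank_models()] ranking (may be `NULL` for a
#'   single-model "ensemble", where no tie-breaking is needed).
#' @param threshold Integer vote threshold in `[1, n_models]` (an
#'   entity is kept when `votes >= threshold`); the submitted systems
#'   used thresholds 4 to 6, default 5.
#' @return Entity table (attributes unset; `votes` carried along).
#' @export
resolve_entities <- function(votes, ranking = NULL, threshold = 5L) {
  n_models <- attr(votes, "n_models")
  if (threshold < 1L || threshold > n_models) {
    stop("threshold must be in [1, ", n_models, "]")
  }
  keep <- votes[votes$votes >= threshold, , drop = FALSE]
  attr(keep, "n_models") <- n_models
  if (nrow(keep) == 0L) {
    out <- fh_entities()
    out$votes <- integer(0)
    return(out)
  }
  ord <- vote_preference_order(keep, ranking)
  keep <- keep[ord, , drop = FALSE]
  accepted <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    conflict <- FALSE
    if (i > 1L) {
      prev <- which(accepted[seq_len(i - 1L)])
      conflict <- any(keep$doc_id[prev] == keep$doc_id[i] &
                      keep$category[prev] == keep$category[i] &
                      keep$start[prev] < keep$end[i] &
                      keep$end[prev] > keep$start[i])
    }
    accepted[i] <- !conflict
  }
  res <- keep[accepted, , drop = FALSE]
  res <- res[order(res$doc_id, res$start, res$end), , drop = FALSE]
  out <- fh_entities(res$doc_id, res$category, res$start, res$end, res$text)
  out$votes <- res$votes
  out
}
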
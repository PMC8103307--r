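# Independent brute-force oracles used by the voting and acceptance
# suites. These deliberately reimplement the contracts naively.

# Random prediction sets over a small universe of candidate spans.
random_prediction_sets <- function(n_models, n_spans = 8L) {
  spans <- data.frame(start = seq(0L, by = 3L, length.out = n_spans))
  spans$end <- spans$start + sample(2:5, n_spans, replace = TRUE)
  spans$category <- sample(c("FamilyMember", "Observation"), n_spans,
                           replace = TRUE)
  lapply(seq_len(n_models), function(i) {
    pick <- runif(n_spans) < 0.5
    fh_entities(rep("d", sum(pick)), spans$category[pick],
                spans$start[pick], spans$end[pick], "x")
  })
}

brute_force_tally <- function(predictions) {
  keys <- unlist(lapply(seq_along(predictions), function(i) {
    p <- predictions[[i]]
    unique(paste(p$doc_id, p$category, p$start, p$end))
  }))
  table(keys)
}

# Exhaustive pairwise-conflict resolver: repeatedly eliminate the loser
# of any overlapping same-category pair under the documented preference
# (votes, then best voter rank, then span position).
brute_force_resolve <- function(votes, ranking, threshold) {
  keep <- votes[votes$votes >= threshold, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  n_models <- attr(votes, "n_models")
  rank_pos <- seq_len(n_models)
  if (!is.null(ranking)) rank_pos[ranking$rank] <- seq_along(ranking$rank)
  best <- vapply(keep$voters, function(v) min(rank_pos[v]), numeric(1))
  pref <- order(-keep$votes, best, keep$start, keep$end)
  prefrank <- integer(nrow(keep))
  prefrank[pref] <- seq_len(nrow(keep))
  # repeatedly finalize the best remaining candidate; every candidate it
  # overlaps (same document + category) loses the pairwise comparison
  # and is eliminated
  alive <- rep(TRUE, nrow(keep))
  final <- rep(FALSE, nrow(keep))
  while (any(alive & !final)) {
    cand <- which(alive & !final)
    i <- cand[which.min(prefrank[cand])]
    final[i] <- TRUE
    clash <- alive & !final &
      keep$doc_id == keep$doc_id[i] & keep$category == keep$category[i] &
      keep$start < keep$end[i] & keep$end > keep$start[i]
    alive[clash] <- FALSE
  }
  keep[alive, , drop = FALSE]
}

# Naive run scanner over BIO tags: maximal same-category runs, leading
# I- treated as a new run.
run_scanner <- function(tags) {
  runs <- list()
  cur <- NULL
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      if (!is.null(cur)) { runs[[length(runs) + 1L]] <- cur; cur <- NULL }
    } else {
      cat_i <- sub("^[BI]-", "", t)
      if (startsWith(t, "B-") || is.null(cur) || cur$category != cat_i) {
        if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
        cur <- list(category = cat_i, from = i, to = i)
      } else {
        cur$to <- i
      }
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}
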
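# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# A mid-sized synthetic corpus for structural tests.
fix_corpus <- function() {
  memo("corpus", generate_corpus(gen_config(n_documents = 30, seed = 7)))
}

# A quick tagger trained on a handful of documents (reduced epochs).
fix_quick_tagger <- function(seed = 1L) {
  memo(paste0("tagger", seed), {
    corp <- fix_corpus()
    train_tagger(corp$documents[1:12], corp$entities,
                 tagger_config(epochs = 10L, seed = seed))
  })
}

one_sentence_doc <- function(text, doc_id = "doc") {
  doc <- preprocess(text, doc_id)
  stopifnot(length(doc$sentences) == 1L)
  doc
}

# Entity helper: span located by surface text within the document.
ent_at <- function(doc, text, category, occurrence = 1L) {
  hits <- gregexpr(text, doc$text, fixed = TRUE)[[1]]
  stopifnot(hits[1L] != -1L, length(hits) >= occurrence)
  s <- as.integer(hits[occurrence]) - 1L
  fh_entities(doc$doc_id, category, s, s + nchar(text), text)
}

# Random entity table over a document's tokens for fuzzing: picks
# non-overlapping token runs per category.
random_entities <- function(doc, n = 3L) {
  toks <- doc_tokens_all(doc)
  out <- fh_entities()
  if (nrow(toks) == 0L) return(out)
  taken <- rep(FALSE, nrow(toks))
  for (k in seq_len(n)) {
    i <- sample.int(nrow(toks), 1L)
    len <- sample.int(2L, 1L)
    j <- min(i + len - 1L, nrow(toks))
    if (any(taken[i:j]) || toks$sentence[i] != toks$sentence[j]) next
    taken[i:j] <- TRUE
    out <- rbind(out, fh_entities(doc$doc_id,
                                  sample(c("FamilyMember", "Observation",
                                           "LivingStatus"), 1L),
                                  toks$start[i], toks$end[j],
                                  substring(doc$text, toks$start[i] + 1L,
                                            toks$end[j])))
  }
  out
}

doc_tokens_all <- function(doc) {
  out <- lapply(seq_along(doc$sentences), function(i) {
    t <- doc$sentences[[i]]$tokens
    if (nrow(t) > 0L) t$sentence <- i
    t
  })
  do.call(rbind, out)
}

# Strict span+category micro F1 between two entity tables (fraction,
# not percent) -- used as an independent summary in recovery tests.
strict_entity_f1 <- function(system, reference) {
  sk <- unique(paste(system$doc_id, system$category, system$start,
                     system$end))
  rk <- unique(paste(reference$doc_id, reference$category, reference$start,
                     reference$end))
  tp <- length(intersect(sk, rk))
  if (length(sk) == 0L || length(rk) == 0L) return(0)
  p <- tp / length(sk)
  r <- tp / length(rk)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}
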
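#' Tagger hyperparameter configuration
#'
#' Defaults follow the training regime the ensemble was designed around:
#' 30 epochs of the Nadam optimizer with a 50% dropout rate on the
#' recurrent units, and 10-dimensional embeddings for each auxiliary
#' concept channel. Hidden width and the trainable word-embedding
#' dimension are desk-scale declared defaults.
#'
#' @param epochs Training epochs (>= 1), default 30.
#' @param recurrent_dropout Dropout fraction on the recurrent outputs,
#'   in `[0, 1)`, default 0.5.
#' @param optimizer Adaptive-moment optimizer name (informational;
#'   `"nadam"`).
#' @param hidden_units Recurrent units per direction.
#' @param word_embed_dim Trainable word-embedding dimension.
#' @param channel_embed_dim Embedding dimension per auxiliary channel.
#' @param learning_rate Nadam step size.
#' @param seed Integer seed for weight initialization and shuffling.
#' @return Object of class `fh_tagger_config`.
#' @export
tagger_config <- function(epochs = 30L, recurrent_dropout = 0.5,
                          optimizer = "nadam", hidden_units = 32L,
                          word_embed_dim = 50L, channel_embed_dim = 10L,
                          learning_rate = 0.01, seed = 1L) {
  stopifnot(epochs >= 1L, recurrent_dropout >= 0, recurrent_dropout < 1,
            hidden_units >= 1L, channel_embed_dim >= 1L)
  structure(list(epochs = as.integer(epochs),
                 recurrent_dropout = recurrent_dropout,
                 optimizer = optimizer,
                 hidden_units = as.integer(hidden_units),
                 word_embed_dim = as.integer(word_embed_dim),
                 channel_embed_dim = as.integer(channel_embed_dim),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "fh_tagger_config")
}

# ---- embedding providers ---------------------------------------------

#' Embedding providers for the tagger's fixed input channels
#'
#' A provider maps a token character vector to a numeric matrix with one
#' row per token and a fixed column dimension; providers are *not*
#' updated during training. `char_hash_provider()` hashes character
#' trigrams of each token into a fixed number of buckets and
#' L2-normalizes the counts — a deterministic, vocabulary-free stand-in
#' for contextual vectors that gives the tagger sub-word generalization.
#' `word_vector_provider()` reads pretrained vectors in the word2vec
#' text dialect (one `token v1 v2 ...` line per word); unknown tokens
#' get a zero vector.
#'
#' @param dim Number of hash buckets (vector dimension).
#' @return Object of class `fh_embedding_provider` with fields `fun`,
#'   `dim` and `kind`.
#' @export
char_hash_provider <- function(dim = 20L) {
  dim <- as.integer(dim)
  fun <- function(tokens) {
    out <- matrix(0, nrow = length(tokens), ncol = dim)
    if (length(tokens) == 0L) return(out)
    for (i in seq_along(tokens)) {
      padded <- paste0("^", tolower(tokens[i]), "$")
      n <- nchar(padded)
      if (n < 3L) next
      grams <- substring(padded, 1:(n - 2L), 3:n)
      idx <- hash_features(grams, dim) + 1L
      for (j in idx) out[i, j] <- out[i, j] + 1
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
  structure(list(fun = fun, dim = dim, kind = "static"),
            class = "fh_embedding_provider")
}

#' @rdname char_hash_provider
#' @param path Path to a word2vec-text embedding file.
#' @export
word_vector_provider <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # optional "<count> <dim>" header
  if (length(lines) && grepl("^[0-9]+\\s+[0-9]+$", lines[1L])) {
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\\s+")
  words <- tolower(vapply(parts, `[[`, "", 1L))
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1L]]) - 1L)))
  rownames(vecs) <- words
  dim <- ncol(vecs)
  fun <- function(tokens) {
    out <- matrix(0, nrow = length(tokens), ncol = dim)
    hit <- match(tolower(tokens), words)
    ok <- !is.na(hit)
    out[ok, ] <- vecs[hit[ok], , drop = FALSE]
    out
  }
  structure(list(fun = fun, dim = dim, kind = "static"),
            class = "fh_embedding_provider")
}

default_providers <- function() list(char_hash_provider(20L))

# ---- external concept taggers and the semantic-type map ---------------

#' Pluggable external concept tagger interface
#'
#' An external concept tagger produces concept mentions (character
#' spans with a coarse semantic type) for a document; its predictions
#' feed the sequence tagger as an auxiliary BIO channel after filtering
#' through a [build_semantic_type_map()]. `mock_concept_tagger()` is a
#' dictionary-based stand-in shipped for development and testing: it
#' tags the generator's disease vocabulary with plausible semantic
#' types ("dsyn", "neop", ...) plus a deliberately unaligned type
#' ("fndg" on the word "history") so that map filtering has something
#' to drop. `mock_problem_tagger()` emulates a clinical problem-concept
#' model by emitting disease mentions directly as Observation concepts.
#'
#' @param name Channel name.
#' @param fun Function `(fh_document) -> data.frame(start, end,
#'   semantic_type)` (or `category` for pre-mapped taggers).
#' @return Object of class `fh_concept_tagger`.
#' @export
concept_tagger <- function(name, fun) {
  structure(list(name = name, fun = fun), class = "fh_concept_tagger")
}

.mock_semtype <- function(term) {
  if (grepl("cancer|leukemia|lymphoma|melanoma", term)) "neop"
  else if (grepl("depression|anxiety|schizophrenia|dementia", term)) "mobd"
  else if (grepl("migraines|gout", term)) "sosy"
  else "dsyn"
}

# Dictionary scan for a fixed term list; longest match first.
.dict_mentions <- function(doc, terms) {
  out <- data.frame(start = integer(0), end = integer(0),
                    term = character(0), stringsAsFactors = FALSE)
  lower <- tolower(doc$text)
  for (term in terms[order(-nchar(terms))]) {
    pat <- paste0("(?<![a-z])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
                  "(?![a-z])")
    m <- gregexpr(pat, lower, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    for (k in seq_along(m)) {
      s <- as.integer(m[k]) - 1L
      e <- s + attr(m, "match.length")[k]
      if (any(out$start < e & out$end > s)) next   # keep longest match
      out <- rbind(out, data.frame(start = s, end = e, term = term,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' @rdname concept_tagger
#' @export
mock_concept_tagger <- function() {
  concept_tagger("metamap_mock", function(doc) {
    m <- .dict_mentions(doc, c(DISEASES, "history"))
    if (nrow(m) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        semantic_type = character(0)))
    }
    data.frame(start = m$start, end = m$end,
               semantic_type = ifelse(m$term == "history", "fndg",
                                      vapply(m$term, .mock_semtype, "")),
               stringsAsFactors = FALSE)
  })
}

#' @rdname concept_tagger
#' @export
mock_problem_tagger <- function() {
  concept_tagger("i2b2_mock", function(doc) {
    m <- .dict_mentions(doc, DISEASES)
    data.frame(start = m$start, end = m$end,
               category = rep("Observation", nrow(m)),
               stringsAsFactors = FALSE)
  })
}

#' Build the semantic-type-to-observation mapping table
#'
#' For each semantic type emitted by an external concept tagger over the
#' training documents, counts how many of its mentions align (share at
#' least one character) with a gold observation span of the same
#' document, and keeps the types whose alignment probability exceeds the
#' threshold (strictly greater than 70% by default).
#'
#' @param concept_mentions Data frame with `doc_id`, `start`, `end`,
#'   `semantic_type`.
#' @param gold_observations Entity table (rows with category
#'   `Observation` are used).
#' @param threshold Keep types with `probability > threshold`.
#' @return Object of class `fh_semantic_map`: a data frame with one row
#'   per type (`semantic_type`, `aligned`, `total`, `probability`,
#'   `kept`), plus the threshold as an attribute.
#' @export
build_semantic_type_map <- function(concept_mentions, gold_observations,
                                    threshold = 0.70) {
  gold <- gold_observations[gold_observations$category == "Observation", ,
                            drop = FALSE]
  types <- sort(unique(concept_mentions$semantic_type))
  rows <- lapply(types, function(ty) {
    m <- concept_mentions[concept_mentions$semantic_type == ty, , drop = FALSE]
    aligned <- 0L
    for (i in seq_len(nrow(m))) {
      g <- gold[gold$doc_id == m$doc_id[i], , drop = FALSE]
      if (any(g$start < m$end[i] & g$end > m$start[i])) aligned <- aligned + 1L
    }
    data.frame(semantic_type = ty, aligned = aligned, total = nrow(m),
               probability = aligned / nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(semantic_type = character(0), aligned = integer(0),
                      total = integer(0), probability = numeric(0))
  }
  out <- out[out$total > 0L, , drop = FALSE]
  out$kept <- out$probability > threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("fh_semantic_map", "data.frame")
  out
}

#' Re-encode filtered concept mentions as a BIO channel over a sentence
#'
#' Mentions whose semantic type survives the mapping filter are encoded
#' as `B-Observation` / `I-Observation` over the sentence's tokens;
#' everything else is `O`. With no concept tagger attached the channel
#' is all `O`.
#'
#' @param concept_mentions Data frame with `start`, `end` and either
#'   `semantic_type` (filtered through `map`) or `category` (already
#'   mapped). `NULL` yields an all-O channel.
#' @param map An `fh_semantic_map` (ignored for pre-mapped mentions).
#' @param sentence Element of `fh_document$sentences`.
#' @return Character vector of BIO tags, one per token.
#' @export
derive_aux_channel <- function(concept_mentions, map, sentence) {
  toks <- sentence$tokens
  tags <- rep("O", nrow(toks))
  if (is.null(concept_mentions) || nrow(concept_mentions) == 0L) return(tags)
  m <- concept_mentions
  if (!is.null(m$semantic_type)) {
    kept <- map$semantic_type[map$kept]
    m <- m[m$semantic_type %in% kept, , drop = FALSE]
    m$category <- rep("Observation", nrow(m))
  }
  for (i in seq_len(nrow(m))) {
    covered <- which(toks$start < m$end[i] & toks$end > m$start[i])
    if (length(covered) == 0L) next
    tags[covered[1L]] <- paste0("B-", m$category[i])
    if (length(covered) > 1L) tags[covered[-1L]] <- paste0("I-", m$category[i])
  }
  tags
}

# ---- featurization ----------------------------------------------------

# Precompute per-document channel mentions once.
channel_mentions <- function(channels, doc) {
  lapply(channels, function(ch) ch$fun(doc))
}

# Build the C-side inputs for one document: word ids, channel label ids,
# fixed provider features, one entry per sentence.
featurize_doc <- function(doc, vocab, providers, channels, map) {
  mentions <- channel_mentions(channels, doc)
  n_chan <- length(channels)
  words <- list(); chans <- list(); fixed <- list()
  for (si in seq_along(doc$sentences)) {
    sent <- doc$sentences[[si]]
    toks <- sent$tokens
    T <- nrow(toks)
    ids <- match(tolower(toks$text), vocab)
    ids[is.na(ids)] <- 1L                      # UNK
    cmat <- matrix(1L, nrow = max(n_chan, 1L), ncol = T)
    for (c in seq_len(n_chan)) {
      tags <- derive_aux_channel(mentions[[c]], map, sent)
      cmat[c, ] <- match(tags, BIO_LABELS)
    }
    fmat <- if (length(providers)) {
      t(do.call(cbind, lapply(providers, function(p) p$fun(toks$text))))
    } else {
      matrix(0, nrow = 0L, ncol = T)
    }
    words[[si]] <- ids
    chans[[si]] <- cmat
    fixed[[si]] <- fmat
  }
  list(words = words, chans = chans, fixed = fixed)
}

# ---- training and prediction -----------------------------------------

#' Train a bidirectional recurrent BIO sequence tagger
#'
#' Encodes the gold entities of the training documents as BIO token
#' tags and fits a bidirectional Elman-style recurrent network whose
#' token inputs concatenate a trainable word embedding, a trainable
#' 10-dimensional embedding per auxiliary concept channel, and the fixed
#' provider features. Training is nondeterministic across seeds (weight
#' initialization and sentence shuffling) but exactly reproducible for a
#' fixed seed — the property the voting ensemble exploits.
#'
#' @param docs List of `fh_document` training documents.
#' @param gold Gold entity table with character spans.
#' @param config A [tagger_config()].
#' @param providers List of embedding providers
#'   ([char_hash_provider()], [word_vector_provider()]).
#' @param channels List of [concept_tagger()]s used as auxiliary BIO
#'   channels.
#' @param semantic_map Optional [build_semantic_type_map()] output used
#'   to filter `semantic_type` channels; built from the training gold
#'   when a channel needs it and none is supplied.
#' @return Object of class `fh_tagger`.
#' @export
train_tagger <- function(docs, gold, config = tagger_config(),
                         providers = default_providers(),
                         channels = list(), semantic_map = NULL) {
  stopifnot(inherits(config, "fh_tagger_config"))
  if (length(docs) == 0L) stop("empty training set")
  if (length(providers) == 0L) stop("at least one embedding provider required")

  if (is.null(semantic_map) && length(channels)) {
    mentions <- do.call(rbind, lapply(docs, function(d) {
      out <- lapply(channels, function(ch) {
        m <- ch$fun(d)
        if (!is.null(m$semantic_type) && nrow(m) > 0L) {
          data.frame(doc_id = d$doc_id, m, stringsAsFactors = FALSE)
        }
      })
      do.call(rbind, out)
    }))
    semantic_map <- if (!is.null(mentions) && nrow(mentions) > 0L) {
      build_semantic_type_map(mentions, gold)
    }
  }

  all_tokens <- unlist(lapply(docs, function(d) {
    tolower(doc_tokens(d)$text)
  }))
  vocab <- c("<unk>", sort(unique(all_tokens)))

  words <- list(); chans <- list(); fixed <- list(); labels <- list()
  k <- 0L
  for (doc in docs) {
    feats <- featurize_doc(doc, vocab, providers, channels, semantic_map)
    gold_doc <- gold[gold$doc_id == doc$doc_id, , drop = FALSE]
    for (si in seq_along(doc$sentences)) {
      k <- k + 1L
      words[[k]] <- feats$words[[si]]
      chans[[k]] <- feats$chans[[si]]
      fixed[[k]] <- feats$fixed[[si]]
      tags <- encode_bio(doc$sentences[[si]], gold_doc)
      labels[[k]] <- match(tags, BIO_LABELS)
    }
  }

  d_fixed <- sum(vapply(providers, `[[`, integer(1), "dim"))
  fit <- birnn_fit(words, chans, fixed, labels,
                   vocab_size = length(vocab),
                   n_chan = length(channels),
                   n_chan_labels = length(BIO_LABELS),
                   d_word = config$word_embed_dim,
                   d_chan = config$channel_embed_dim,
                   hidden = config$hidden_units,
                   n_labels = length(BIO_LABELS),
                   d_fixed = d_fixed,
                   epochs = config$epochs,
                   dropout = config$recurrent_dropout,
                   lr = config$learning_rate,
                   seed = config$seed)

  structure(list(weights = fit[names(fit) != "epoch_loss"],
                 epoch_loss = fit$epoch_loss,
                 vocab = vocab, config = config,
                 providers = providers, channels = channels,
                 semantic_map = semantic_map,
                 labels = BIO_LABELS),
            class = "fh_tagger")
}

#' @export
print.fh_tagger <- function(x, ...) {
  cat(sprintf(paste0("<fh_tagger: %d-unit bidirectional recurrent BIO ",
                     "tagger, vocab %d, %d aux channel(s), %d epochs ",
                     "(%s, dropout %.0f%%), seed %d>\n"),
              x$config$hidden_units, length(x$vocab), length(x$channels),
              x$config$epochs, x$config$optimizer,
              100 * x$config$recurrent_dropout, x$config$seed))
  cat(sprintf("  final training loss/token: %.4f\n",
              x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}

#' Predict BIO tag sequences for a document
#'
#' Deterministic given the trained weights; unseen tokens fall back to
#' the unknown-word embedding.
#'
#' @param tagger An `fh_tagger`.
#' @param doc An `fh_document`.
#' @return List of character BIO tag vectors, one per sentence.
#' @export
predict_tags <- function(tagger, doc) {
  feats <- featurize_doc(doc, tagger$vocab, tagger$providers,
                         tagger$channels, tagger$semantic_map)
  ids <- birnn_predict_cpp(tagger$weights, feats$words, feats$chans,
                           feats$fixed, length(tagger$channels),
                           length(BIO_LABELS))
  lapply(ids, function(v) tagger$labels[v])
}

#' @export
#' @method predict fh_tagger
#' @param object,newdata,... Standard predict-method arguments:
#'   `newdata` is one `fh_document` or a list of them.
predict.fh_tagger <- function(object, newdata, ...) {
  docs <- if (inherits(newdata, "fh_document")) list(newdata) else newdata
  out <- fh_entities()
  for (doc in docs) {
    tag_seqs <- predict_tags(object, doc)
    for (si in seq_along(doc$sentences)) {
      out <- rbind(out, decode_bio(tag_seqs[[si]], doc$sentences[[si]],
                                   doc$doc_id, doc$text))
    }
  }
  out
}

#' Train an ensemble of taggers differing only in their random seed
#'
#' All members share hyperparameters; member `i` is trained with seed
#' `config$seed + i - 1` (so with the default `seed = 1`, a 10-member
#' ensemble uses seeds 1 to 10). The members' disagreement — from weight
#' initialization and shuffling — is what gives the voting ensemble its
#' diversity.
#'
#' @inheritParams train_tagger
#' @param n_models Number of members (>= 1), default 10.
#' @return Object of class `fh_ensemble`: list of `fh_tagger`s with a
#'   `seeds` attribute.
#' @export
train_ensemble <- function(docs, gold, config = tagger_config(),
                           n_models = 10L,
                           providers = default_providers(),
                           channels = list(), semantic_map = NULL) {
  stopifnot(n_models >= 1L)
  seeds <- config$seed + seq_len(n_models) - 1L
  members <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    train_tagger(docs, gold, cfg, providers, channels, semantic_map)
  })
  structure(members, seeds = seeds, class = "fh_ensemble")
}

#' @export
print.fh_ensemble <- function(x, ...) {
  cat(sprintf("<fh_ensemble: %d taggers, seeds %s>\n", length(x),
              paste(attr(x, "seeds"), collapse = ", ")))
  invisible(x)
}
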
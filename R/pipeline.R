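#' End-to-end pipeline configuration
#'
#' Bundles every knob of the extraction pipeline: the tagger ensemble
#' (size, hyperparameters, voting threshold), the relation classifiers
#' (passes, seed), and the toggles that reproduce the submitted system
#' variants — `use_rule_fm = TRUE` takes family member entities from
#' the rule-based matcher while observations come from the ensemble,
#' `use_rule_fm = FALSE` takes both from the ensemble.
#'
#' @param tagger A [tagger_config()].
#' @param n_models Ensemble size (default 10).
#' @param threshold Voting threshold (default 5).
#' @param use_rule_fm Rule-based family member entities.
#' @param use_channels Attach the mock external concept taggers as
#'   auxiliary channels.
#' @param relation_passes OGD passes (default 100).
#' @param relation_seed OGD shuffling seed.
#' @param lexicon_path Optional lexicon YAML override.
#' @return Object of class `fh_pipeline_config`.
#' @export
pipeline_config <- function(tagger = tagger_config(), n_models = 10L,
                            threshold = 5L, use_rule_fm = FALSE,
                            use_channels = TRUE, relation_passes = 100L,
                            relation_seed = 1L, lexicon_path = NULL) {
  stopifnot(n_models >= 1L, threshold >= 1L, threshold <= n_models)
  structure(list(tagger = tagger, n_models = as.integer(n_models),
                 threshold = as.integer(threshold),
                 use_rule_fm = isTRUE(use_rule_fm),
                 use_channels = isTRUE(use_channels),
                 relation_passes = as.integer(relation_passes),
                 relation_seed = as.integer(relation_seed),
                 lexicon_path = lexicon_path),
            class = "fh_pipeline_config")
}

pipeline_channels <- function(config) {
  if (config$use_channels) {
    list(mock_concept_tagger(), mock_problem_tagger())
  } else {
    list()
  }
}

#' Train the full extraction system
#'
#' Trains the tagger ensemble on gold BIO sequences and the two
#' relation classifiers (family member-living status, family
#' member-observation) on gold entity pairs, with newline-separated
#' negative pairs pruned.
#'
#' @param docs Training `fh_document`s.
#' @param gold_entities Gold entity table (spans + attributes).
#' @param gold_relations Gold relation table.
#' @param config A [pipeline_config()].
#' @return Object of class `fh_system`.
#' @export
famhx_train <- function(docs, gold_entities, gold_relations,
                        config = pipeline_config()) {
  lexicons <- load_lexicons(config$lexicon_path)
  channels <- pipeline_channels(config)
  ensemble <- train_ensemble(docs, gold_entities, config$tagger,
                             n_models = config$n_models,
                             channels = channels)

  feats_ls <- list(); labs_ls <- integer(0)
  feats_obs <- list(); labs_obs <- integer(0)
  for (doc in docs) {
    ents <- gold_entities[gold_entities$doc_id == doc$doc_id, , drop = FALSE]
    pairs <- generate_candidate_pairs(ents, doc, "train", gold_relations)
    for (k in seq_len(nrow(pairs))) {
      f <- extract_features(pairs[k, ], doc, ents)
      if (pairs$type[k] == "FamilyMember_LivingStatus") {
        feats_ls[[length(feats_ls) + 1L]] <- f
        labs_ls <- c(labs_ls, pairs$label[k])
      } else {
        feats_obs[[length(feats_obs) + 1L]] <- f
        labs_obs <- c(labs_obs, pairs$label[k])
      }
    }
  }
  model_ls <- train_relation_model(feats_ls, labs_ls,
                                   passes = config$relation_passes,
                                   seed = config$relation_seed)
  model_obs <- train_relation_model(feats_obs, labs_obs,
                                    passes = config$relation_passes,
                                    seed = config$relation_seed)
  structure(list(ensemble = ensemble, relation_ls = model_ls,
                 relation_obs = model_obs, config = config),
            class = "fh_system")
}

#' @export
print.fh_system <- function(x, ...) {
  cat(sprintf(paste0("<fh_system: %d-tagger voting ensemble (threshold ",
                     "%d)%s + 2 OGD relation classifiers>\n"),
              length(x$ensemble), x$config$threshold,
              if (x$config$use_rule_fm) " with rule-based family members"
              else ""))
  invisible(x)
}

#' Run the trained system over documents
#'
#' Stages, in order: per-member tagging, vote collection,
#' agreement-based model ranking, overlap resolution at the voting
#' threshold, optional rule-based family member override, attribute
#' rules, candidate-pair generation, relation classification, and
#' attribute attachment. Fixed seeds make the output deterministic.
#'
#' @param system An `fh_system` from [famhx_train()].
#' @param docs List of `fh_document`s.
#' @param threshold Voting threshold override (default: the config's).
#' @return List with `entities`, `relations`, per-member `predictions`,
#'   and a `log` data frame of per-stage counts.
#' @export
famhx_predict <- function(system, docs, threshold = NULL) {
  config <- system$config
  if (is.null(threshold)) threshold <- config$threshold
  lexicons <- load_lexicons(config$lexicon_path)
  log <- list()
  note <- function(stage, n) log[[length(log) + 1L]] <<-
    data.frame(stage = stage, count = n)

  predictions <- lapply(system$ensemble, predict, newdata = docs)
  note("member_predictions", sum(vapply(predictions, nrow, integer(1))))

  votes <- collect_votes(predictions)
  note("vote_candidates", nrow(votes))
  ranking <- if (length(predictions) >= 2L) rank_models(predictions)
  entities <- resolve_entities(votes, ranking, threshold)
  note("resolved_entities", nrow(entities))

  if (config$use_rule_fm) {
    entities <- entities[entities$category != "FamilyMember", , drop = FALSE]
    for (doc in docs) {
      entities <- rbind(entities,
                        cbind(match_family_members(doc, lexicons),
                              votes = NA_integer_))
    }
    entities <- entities[order(entities$doc_id, entities$start), ,
                         drop = FALSE]
    note("rule_family_members",
         sum(entities$category == "FamilyMember"))
  }
  entities <- apply_entity_attributes(entities, docs, lexicons)
  # unnormalizable family members cannot enter document-level tuples
  entities <- entities[!(entities$category == "FamilyMember" &
                         is.na(entities$normalized)), , drop = FALSE]
  rownames(entities) <- NULL
  note("attributed_entities", nrow(entities))

  relations <- fh_relations()
  n_pairs <- 0L
  for (doc in docs) {
    ents <- entities[entities$doc_id == doc$doc_id, , drop = FALSE]
    pairs <- generate_candidate_pairs(ents, doc, "test")
    if (nrow(pairs) == 0L) next
    feats <- lapply(seq_len(nrow(pairs)), function(k) {
      extract_features(pairs[k, ], doc, ents)
    })
    is_ls <- pairs$type == "FamilyMember_LivingStatus"
    related <- logical(nrow(pairs))
    if (any(is_ls)) {
      related[is_ls] <- classify_pairs(system$relation_ls,
                                       feats[is_ls])$related
    }
    if (any(!is_ls)) {
      related[!is_ls] <- classify_pairs(system$relation_obs,
                                        feats[!is_ls])$related
    }
    n_pairs <- n_pairs + nrow(pairs)
    relations <- rbind(relations,
                       assemble_relations(pairs[related, , drop = FALSE],
                                          ents, docs, lexicons))
  }
  note("candidate_pairs", n_pairs)
  note("relations", nrow(relations))

  list(entities = entities, relations = relations,
       predictions = predictions, log = do.call(rbind, log))
}

#' Run the pipeline end to end and write annotation files
#'
#' Trains (or reuses) a system, predicts over the supplied documents,
#' and writes `entities.tsv`, `relations.tsv` and a `run_log.tsv` of
#' per-stage counts to `out_dir`. With fixed seeds in the
#' configuration, reruns produce byte-identical output files.
#'
#' @param docs Documents to annotate (list of `fh_document`, or a
#'   directory of `.txt` notes).
#' @param system A trained `fh_system`; alternatively supply `train`
#'   to train one here.
#' @param train List with `docs`, `entities`, `relations` used to
#'   train a system when none is given.
#' @param config A [pipeline_config()] (used when training here).
#' @param out_dir Output directory.
#' @return Invisibly, the [famhx_predict()] result with the file paths
#'   attached as `files`.
#' @export
run_end_to_end <- function(docs, system = NULL, train = NULL,
                           config = pipeline_config(), out_dir) {
  if (is.character(docs)) docs <- read_notes(docs)
  if (is.null(system)) {
    if (is.null(train)) {
      stop("no trained system: pass `system =` a trained fh_system, or ",
           "`train = list(docs, entities, relations)` to train one")
    }
    system <- famhx_train(train$docs, train$entities, train$relations, config)
  }
  res <- famhx_predict(system, docs)
  files <- write_annotations(res$entities, res$relations, out_dir)
  log_path <- file.path(out_dir, "run_log.tsv")
  utils::write.table(res$log, log_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  res$files <- c(files, log = log_path)
  invisible(res)
}
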
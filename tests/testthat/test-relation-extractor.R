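make_gold_doc <- function(text, spec) {
  # spec: list(list(text=, category=, ...attrs)); occurrences resolved
  # in order of appearance
  doc <- preprocess(text, "d")
  ents <- fh_entities()
  for (s in spec) {
    e <- ent_at(doc, s$text, s$category)
    if (!is.null(s$normalized)) e$normalized <- s$normalized
    if (!is.null(s$side)) e$side <- s$side
    if (!is.null(s$score)) e$score <- s$score
    if (!is.null(s$negation)) e$negation <- s$negation
    ents <- rbind(ents, e)
  }
  list(doc = doc, entities = ents)
}

test_that("candidate pairs cross family members with other entities", {
  g <- make_gold_doc("Mother is deceased.",
                     list(list(text = "Mother", category = "FamilyMember",
                               normalized = "Mother", side = "NA"),
                          list(text = "deceased", category = "LivingStatus",
                               score = 0L)))
  pairs <- generate_candidate_pairs(g$entities, g$doc, "test")
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$type, "FamilyMember_LivingStatus")

  # 3 family members x 2 observations, no newlines -> 6 pairs
  g2 <- make_gold_doc(
    "Mother, father and sister have diabetes and asthma.",
    list(list(text = "Mother", category = "FamilyMember",
              normalized = "Mother", side = "NA"),
         list(text = "father", category = "FamilyMember",
              normalized = "Father", side = "NA"),
         list(text = "sister", category = "FamilyMember",
              normalized = "Sister", side = "NA"),
         list(text = "diabetes", category = "Observation"),
         list(text = "asthma", category = "Observation")))
  pairs2 <- generate_candidate_pairs(g2$entities, g2$doc, "test")
  expect_equal(nrow(pairs2), 6L)
  expect_true(all(pairs2$type == "FamilyMember_Observation"))
})

test_that("negative pairs split by a newline are pruned", {
  text <- "Father is deceased.\nColon cancer was noted."
  g <- make_gold_doc(text,
                     list(list(text = "Father", category = "FamilyMember",
                               normalized = "Father", side = "NA"),
                          list(text = "deceased", category = "LivingStatus",
                               score = 0L),
                          list(text = "Colon cancer",
                               category = "Observation")))
  gold_rel <- fh_relations("d", "FamilyMember_LivingStatus", "Father", "NA",
                           other_text = "deceased", score = 0L)
  train_pairs <- generate_candidate_pairs(g$entities, g$doc, "train",
                                          gold_rel)
  # the cross-newline FM-observation negative is gone
  expect_equal(nrow(train_pairs), 1L)
  expect_equal(train_pairs$label, 1L)
  # pruning applies at inference too
  test_pairs <- generate_candidate_pairs(g$entities, g$doc, "test")
  expect_equal(test_pairs$type, "FamilyMember_LivingStatus")
  # a *positive* crossing a newline is retained in training
  gold_rel2 <- rbind(gold_rel,
                     fh_relations("d", "FamilyMember_Observation", "Father",
                                  "NA", other_text = "Colon cancer",
                                  negation = "Non_Negated"))
  train_pairs2 <- generate_candidate_pairs(g$entities, g$doc, "train",
                                           gold_rel2)
  expect_equal(sort(train_pairs2$type),
               c("FamilyMember_LivingStatus", "FamilyMember_Observation"))
  expect_error(generate_candidate_pairs(g$entities, g$doc, "train"),
               "gold")
})

test_that("window features truncate at document edges", {
  g <- make_gold_doc("Mother has cancer.",
                     list(list(text = "Mother", category = "FamilyMember",
                               normalized = "Mother", side = "NA"),
                          list(text = "cancer", category = "Observation")))
  pairs <- generate_candidate_pairs(g$entities, g$doc, "test")
  f <- extract_features(pairs[1, ], g$doc, g$entities)
  expect_true("fm_w=mother" %in% f)
  expect_true("ot_w=cancer" %in% f)
  # no left context before the document-initial mention
  expect_false(any(startsWith(f, "fm_l=")))
  expect_true("btw=has" %in% f)
  expect_true("cnt=0" %in% f)
})

test_that("family members between the pair are counted and bucketed", {
  g <- make_gold_doc("Mother and father and sister have colon cancer.",
                     list(list(text = "Mother", category = "FamilyMember",
                               normalized = "Mother", side = "NA"),
                          list(text = "father", category = "FamilyMember",
                               normalized = "Father", side = "NA"),
                          list(text = "sister", category = "FamilyMember",
                               normalized = "Sister", side = "NA"),
                          list(text = "colon cancer",
                               category = "Observation")))
  pairs <- generate_candidate_pairs(g$entities, g$doc, "test")
  f_mother <- extract_features(pairs[pairs$fm_row == 1L, ], g$doc,
                               g$entities)
  expect_true("cnt=2" %in% f_mother)
  f_sister <- extract_features(pairs[pairs$fm_row == 3L, ], g$doc,
                               g$entities)
  expect_true("cnt=0" %in% f_sister)
})

test_that("between-words features equal a brute-force token slice", {
  set.seed(9)
  corp <- generate_corpus(gen_config(n_documents = 12, seed = 33))
  for (doc in corp$documents) {
    ents <- corp$entities[corp$entities$doc_id == doc$doc_id, ]
    pairs <- generate_candidate_pairs(ents, doc, "test")
    if (nrow(pairs) == 0L) next
    toks <- doc_tokens_all(doc)
    for (k in sample(nrow(pairs), min(3L, nrow(pairs)))) {
      fm <- ents[pairs$fm_row[k], ]
      ot <- ents[pairs$other_row[k], ]
      lo <- min(fm$end, ot$end)
      hi <- max(fm$start, ot$start)
      expected <- tolower(toks$text[toks$start >= lo & toks$end <= hi])
      f <- extract_features(pairs[k, ], doc, ents)
      got <- sub("^btw=", "", f[startsWith(f, "btw=")])
      expect_setequal(got, unique(expected))
    }
  }
})

test_that("OGD separates a linearly separable toy set perfectly", {
  feats <- c(lapply(1:5, function(i) c("pos=yes", paste0("id=", i))),
             lapply(6:10, function(i) c("neg=no", paste0("id=", i))))
  labels <- rep(c(1L, 0L), each = 5L)
  model <- train_relation_model(feats, labels, passes = 100L, seed = 4L)
  pred <- classify_pairs(model, feats)
  expect_equal(as.integer(pred$related), labels)
  # training loss shrinks over passes
  expect_lt(model$pass_loss[100], model$pass_loss[1])
})

test_that("identical features with mixed labels predict the class prior", {
  feats <- rep(list(c("a=1", "b=2")), 10L)
  labels <- c(rep(1L, 7L), rep(0L, 3L))
  model <- train_relation_model(feats, labels, passes = 200L, seed = 1L)
  prob <- classify_pairs(model, feats[1])$probability
  expect_lt(abs(prob - 0.7), 0.08)
})

test_that("single-class training data is rejected", {
  feats <- rep(list("a=1"), 4L)
  expect_error(train_relation_model(feats, rep(1L, 4L)), "both")
})

test_that("the analytic OGD gradient matches finite differences", {
  set.seed(6)
  dim <- 32L
  for (rep in 1:5) {
    w <- rnorm(dim, sd = 0.5)
    bias <- rnorm(1)
    idx <- sample(0:(dim - 1L), sample(3:8, 1L))
    y <- sample(0:1, 1L)
    analytic <- famhx:::ogd_example_grad(w, bias, idx, y)
    eps <- 1e-6
    for (j in idx) {
      wp <- w; wp[j + 1L] <- wp[j + 1L] + eps
      wm <- w; wm[j + 1L] <- wm[j + 1L] - eps
      fd <- (famhx:::ogd_example_loss(wp, bias, idx, y) -
             famhx:::ogd_example_loss(wm, bias, idx, y)) / (2 * eps)
      expect_lt(abs(fd - analytic[j + 1L]) / max(abs(fd), 1e-8), 1e-6)
    }
    # untouched coordinates have zero gradient
    expect_true(all(analytic[setdiff(seq_len(dim), idx + 1L)] == 0))
  }
})

test_that("classification is deterministic and ties go to related", {
  model <- structure(list(weights = numeric(16), bias = 0,
                          pass_loss = 0, passes = 1L, lr0 = 0.5,
                          hash_bits = 4L, seed = 1L),
                     class = "fh_relation_model")
  feats <- list(c("a=1"), c("b=2", "c=3"))
  out <- classify_pairs(model, feats)
  expect_equal(out$probability, c(0.5, 0.5))
  expect_true(all(out$related))
  expect_identical(out, classify_pairs(model, feats))
})

test_that("assembled relations carry scores, negation, and deduplicate", {
  g <- make_gold_doc(
    "Uncle is deceased. No family history of cancer. Mother has cancer.",
    list(list(text = "Uncle", category = "FamilyMember",
              normalized = "Uncle", side = "NA"),
         list(text = "deceased", category = "LivingStatus", score = 0L),
         list(text = "cancer", category = "Observation"),
         list(text = "Mother", category = "FamilyMember",
              normalized = "Mother", side = "NA")))
  pairs <- generate_candidate_pairs(g$entities, g$doc, "test")
  rel <- assemble_relations(pairs, g$entities, list(g$doc))
  ls <- rel[rel$type == "FamilyMember_LivingStatus", ]
  expect_true(all(ls$score[ls$fm_normalized == "Uncle"] == 0L))
  ob <- rel[rel$type == "FamilyMember_Observation", ]
  # the observation inside the negation scope is Negated
  expect_true(all(ob$negation == "Negated"))
  # duplicated pairs collapse
  rel2 <- assemble_relations(rbind(pairs, pairs), g$entities, list(g$doc))
  expect_equal(nrow(rel2), nrow(rel))
})
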
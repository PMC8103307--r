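test_that("micro precision/recall/F1 follow the zero conventions", {
  expect_equal(unname(round(micro_prf(5, 5, 5), 2)), c(50, 50, 50))
  expect_equal(unname(micro_prf(0, 0, 0)), c(0, 0, 0))
  expect_equal(unname(micro_prf(0, 3, 2)), c(0, 0, 0))
  m <- micro_prf(8, 2, 4)
  expect_equal(unname(m[["precision"]]), 80)
  expect_equal(round(m[["recall"]], 2), 66.67)
})

test_that("F1 is a symmetric harmonic mean bounded by its arguments", {
  set.seed(3)
  for (rep in 1:200) {
    p <- runif(1, 0, 100)
    r <- runif(1, 0, 100)
    f <- f1_score(p, r)
    expect_equal(f, f1_score(r, p))
    expect_lte(f, max(p, r) + 1e-12)
    expect_gte(f, min(p, r) - 1e-12)
  }
  x <- runif(20, 0, 100)
  expect_equal(f1_score(x, x), x)
})

test_that("entity evaluation matches tuples with partial observations", {
  ref <- rbind(
    fh_entities("d1", "Observation", NA, NA, "breast cancer"),
    fh_entities("d1", "FamilyMember", NA, NA, NA, normalized = "Uncle",
                side = "Paternal"))
  sys <- rbind(
    fh_entities("d1", "Observation", NA, NA, "cancer"),
    fh_entities("d1", "FamilyMember", NA, NA, NA, normalized = "Uncle",
                side = "Maternal"))
  rep_default <- evaluate_entities(sys, ref)
  obs <- rep_default[rep_default$category == "Observation", ]
  expect_equal(obs$tp, 1L)   # "cancer" overlaps "breast cancer"
  fm <- rep_default[rep_default$category == "FamilyMember", ]
  expect_equal(c(fm$tp, fm$fp, fm$fn), c(0L, 1L, 1L))  # side enforced
  rep_ign <- evaluate_entities(sys, ref, match_spec(ignore_side = TRUE))
  fm2 <- rep_ign[rep_ign$category == "FamilyMember", ]
  expect_equal(c(fm2$tp, fm2$fp, fm2$fn), c(1L, 0L, 0L))
  # identical sets score 100 everywhere
  perfect <- evaluate_entities(ref, ref)
  expect_true(all(perfect$precision == 100))
  expect_true(all(perfect$recall == 100))
  # overall counts are the category sums (micro-averaging)
  ov <- rep_default[rep_default$category == "Overall", ]
  expect_equal(ov$tp, sum(rep_default$tp[rep_default$category != "Overall"]))
  expect_equal(ov$fp, sum(rep_default$fp[rep_default$category != "Overall"]))
})

test_that("relation evaluation enforces score and negation unless ignored", {
  ref <- rbind(
    fh_relations("d1", "FamilyMember_LivingStatus", "Father", "NA",
                 score = 0L),
    fh_relations("d1", "FamilyMember_Observation", "Mother", "NA",
                 other_text = "colon cancer", negation = "Non_Negated"))
  sys_wrong_score <- rbind(
    fh_relations("d1", "FamilyMember_LivingStatus", "Father", "NA",
                 score = 2L),
    fh_relations("d1", "FamilyMember_Observation", "Mother", "NA",
                 other_text = "colon cancer", negation = "Non_Negated"))
  d <- evaluate_relations(sys_wrong_score, ref)
  ls <- d[d$category == "LivingStatus", ]
  expect_equal(c(ls$tp, ls$fp, ls$fn), c(0L, 1L, 1L))
  i <- evaluate_relations(sys_wrong_score, ref,
                          match_spec(ignore_living_status = TRUE))
  ls2 <- i[i$category == "LivingStatus", ]
  expect_equal(c(ls2$tp, ls2$fp, ls2$fn), c(1L, 0L, 0L))

  sys_wrong_neg <- ref
  sys_wrong_neg$negation[2] <- "Negated"
  d2 <- evaluate_relations(sys_wrong_neg, ref)
  ob <- d2[d2$category == "Observation", ]
  expect_equal(ob$tp, 0L)
  i2 <- evaluate_relations(sys_wrong_neg, ref,
                           match_spec(ignore_negation = TRUE))
  ob2 <- i2[i2$category == "Observation", ]
  expect_equal(ob2$tp, 1L)

  # empty system output: zero recall and precision
  e <- evaluate_relations(fh_relations(), ref)
  ov <- e[e$category == "Overall", ]
  expect_equal(c(ov$precision, ov$recall), c(0, 0))
})

test_that("ignoring an attribute never lowers TP nor raises FP/FN", {
  set.seed(8)
  sides <- c("NA", "Paternal", "Maternal")
  negs <- c("Negated", "Non_Negated")
  fms <- c("Mother", "Father", "Uncle", "Aunt", "Cousin")
  random_rel <- function(n) {
    type <- sample(c("FamilyMember_LivingStatus",
                     "FamilyMember_Observation"), n, replace = TRUE)
    ls <- type == "FamilyMember_LivingStatus"
    fh_relations(sample(c("d1", "d2"), n, TRUE), type,
                 sample(fms, n, TRUE), sample(sides, n, TRUE),
                 other_text = ifelse(ls, NA,
                                     sample(c("colon cancer", "asthma",
                                              "gout"), n, TRUE)),
                 score = ifelse(ls, sample(c(0L, 2L, 4L), n, TRUE), NA),
                 negation = ifelse(ls, NA, sample(negs, n, TRUE)))
  }
  specs <- list(match_spec(),
                match_spec(ignore_side = TRUE),
                match_spec(ignore_living_status = TRUE),
                match_spec(ignore_negation = TRUE),
                match_spec(TRUE, TRUE, TRUE))
  for (rep in 1:60) {
    sys <- random_rel(sample(3:10, 1))
    ref <- random_rel(sample(3:10, 1))
    base <- evaluate_relations(sys, ref)
    b <- base[base$category == "Overall", ]
    for (sp in specs[-1]) {
      ab <- evaluate_relations(sys, ref, sp)
      a <- ab[ab$category == "Overall", ]
      expect_gte(a$tp, b$tp)
      expect_lte(a$fp, b$fp)
      expect_lte(a$fn, b$fn)
    }
  }
})

test_that("attribute accuracy equals a brute-force count on rule breakers", {
  corp <- generate_corpus(gen_config(n_documents = 10, seed = 4))
  clean <- attribute_accuracy(corp$documents, corp$entities)
  expect_equal(unname(clean["normalization"]), 100)
  expect_equal(unname(clean["side"]), 100)
  expect_equal(unname(clean["living_status"]), 100)
  expect_equal(unname(clean["negation"]), 100)

  # inject rule-breaking gold: flip some attributes so the heuristics
  # must disagree by exactly the number of injected errors
  broken <- corp$entities
  fm_idx <- which(broken$category == "FamilyMember")[1:4]
  broken$normalized[fm_idx] <- ifelse(broken$normalized[fm_idx] == "Mother",
                                      "Father", "Mother")
  ls_idx <- which(broken$category == "LivingStatus")[1:3]
  broken$score[ls_idx] <- ifelse(broken$score[ls_idx] == 0L, 4L, 0L)
  acc <- attribute_accuracy(corp$documents, broken)
  n <- attr(acc, "n")
  expect_equal(unname(acc["normalization"]),
               100 * (n[["normalization"]] - 4) / n[["normalization"]])
  expect_equal(unname(acc["living_status"]),
               100 * (n[["living_status"]] - 3) / n[["living_status"]])
})

test_that("threshold sweeps agree with independent per-threshold scoring", {
  corp <- fix_corpus()
  docs <- corp$documents[25:30]
  ref <- corp$entities[corp$entities$doc_id %in%
                       vapply(docs, `[[`, "", "doc_id"), ]
  preds <- lapply(1:3, function(s) {
    tg <- fix_quick_tagger()
    p <- predict(tg, docs)
    # perturb: drop a few rows per pseudo-member for diversity
    set.seed(s)
    if (nrow(p) > 3L) p[-sample(nrow(p), 2L), ] else p
  })
  sw <- sweep_thresholds(preds, ref, docs, 1:3)
  expect_equal(sw$threshold, 1:3)
  expect_true(all(diff(sw$candidates) <= 0))
  votes <- collect_votes(preds)
  ranking <- rank_models(preds)
  for (th in 1:3) {
    ents <- resolve_entities(votes, ranking, th)
    ents <- famhx:::apply_entity_attributes(ents, docs)
    indep <- evaluate_entities(ents, ref)
    ov <- indep[indep$category == "Overall", ]
    expect_equal(sw$f1[sw$threshold == th], ov$f1)
  }
  # all models identical -> flat curves
  flat <- sweep_thresholds(list(preds[[1]], preds[[1]], preds[[1]]),
                           ref, docs, 1:3)
  expect_equal(length(unique(flat$f1)), 1L)
})
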
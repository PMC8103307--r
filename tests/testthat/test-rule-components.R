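test_that("kin nouns are matched; verbs and excluded kin are not", {
  doc <- preprocess("His daughter is well.", "d")
  hits <- match_family_members(doc)
  expect_equal(hits$text, "daughter")
  expect_equal(hits$category, "FamilyMember")

  doc2 <- preprocess("They will father a child soon.", "d")
  hits2 <- match_family_members(doc2)
  expect_false("father" %in% hits2$text)

  doc3 <- preprocess("Her spouse has asthma.", "d")
  expect_equal(nrow(match_family_members(doc3)), 0L)
  doc4 <- preprocess("His nephew is ill.", "d")
  expect_equal(nrow(match_family_members(doc4)), 0L)
})

test_that("normalization maps surface kin text to canonical names", {
  expect_equal(normalize_family_member("his dad"), "Father")
  expect_equal(normalize_family_member("three uncles"), "Uncle")
  expect_equal(normalize_family_member("Grandmother"), "Grandmother")
  expect_equal(normalize_family_member("2 sisters"), "Sister")
  expect_true(is.na(normalize_family_member("paternal relatives")))
  expect_true(is.na(normalize_family_member("twin")))
})

test_that("a preceding kin modifier composes the normalization", {
  doc <- one_sentence_doc("His mother has a sister with cancer.")
  sent <- doc$sentences[[1]]
  st <- sent$tokens$start[sent$tokens$text == "sister"]
  expect_equal(normalize_family_member("sister", sent, st), "Aunt")

  doc2 <- one_sentence_doc("Her father's brother had gout.")
  sent2 <- doc2$sentences[[1]]
  st2 <- sent2$tokens$start[sent2$tokens$text == "brother"]
  expect_equal(normalize_family_member("brother", sent2, st2), "Uncle")

  # coordination is not a modifier: "Mother and father" stays Father
  doc3 <- one_sentence_doc("Mother and father are healthy.")
  sent3 <- doc3$sentences[[1]]
  st3 <- sent3$tokens$start[sent3$tokens$text == "father"]
  expect_equal(normalize_family_member("father", sent3, st3), "Father")
})

test_that("normalization is idempotent at the string level", {
  for (x in c("his dad", "three uncles", "Grandmother", "aunt", "cousins")) {
    n1 <- normalize_family_member(x)
    expect_equal(normalize_family_member(n1), n1)
  }
})

test_that("family side uses cues and never applies to first degree", {
  expect_equal(assign_family_side("paternal grandmother",
                                  "His paternal grandmother had cancer.",
                                  "Grandmother"), "Paternal")
  expect_equal(assign_family_side("grandfather",
                                  "Maternal grandfather is alive.",
                                  "Grandfather"), "Maternal")
  expect_equal(assign_family_side("mother", "His mother is well.",
                                  "Mother"), "NA")
  expect_equal(assign_family_side("cousin", "A cousin has cancer.",
                                  "Cousin"), "NA")
  # cue in sentence on the patient's father's side
  expect_equal(assign_family_side("uncle",
                                  "An uncle on the patient's father side.",
                                  "Uncle"), "Paternal")
  # the Maternal cue "mother's" must not fire inside "grandmother's"
  expect_equal(assign_family_side("cousin",
                                  "Grandmother's town cousin visited.",
                                  "Cousin"), "NA")
  # first-degree names never get a side even with cues around
  for (nm in c("Father", "Mother", "Brother", "Sister", "Son", "Daughter")) {
    expect_equal(assign_family_side(tolower(nm),
                                    "paternal family history of note",
                                    nm), "NA")
  }
})

test_that("living-status scoring follows the 0 / 4 / 2 rule", {
  expect_identical(score_living_status("passed away"), 0L)
  expect_identical(score_living_status("deceased"), 0L)
  expect_identical(score_living_status("no longer living"), 0L)
  expect_identical(score_living_status("alive and well"), 4L)
  expect_identical(score_living_status("in good general health"), 4L)
  expect_identical(score_living_status("lives in Ohio"), 2L)
  expect_identical(score_living_status("lives out of state"), 2L)
  # not-alive precedence over healthy cues
  expect_identical(score_living_status("was healthy until she passed away"),
                   0L)
  # range invariant over arbitrary phrases
  phrases <- c("x", "unknown", "alive", "doing well", "dead at 60",
               "still working", "expired", "healthy and active")
  expect_true(all(vapply(phrases, score_living_status, integer(1))
                  %in% c(0L, 2L, 4L)))
})

test_that("negation triggers open a bounded forward scope", {
  neg_of <- function(text, obs_text) {
    doc <- one_sentence_doc(text)
    detect_negation(doc$sentences[[1]], ent_at(doc, obs_text, "Observation"))
  }
  expect_equal(neg_of("No family history of diabetes.", "diabetes"),
               "Negated")
  expect_equal(neg_of("Mother has diabetes.", "diabetes"), "Non_Negated")
  expect_equal(neg_of("Patient denies cancer but confirms diabetes.",
                      "cancer"), "Negated")
  expect_equal(neg_of("Patient denies cancer but confirms diabetes.",
                      "diabetes"), "Non_Negated")
  # scope ends after 6 tokens
  expect_equal(neg_of("denies any of the other usual familial conditions except diabetes today.",
                      "diabetes"), "Non_Negated")
  expect_equal(neg_of("She is not aware of any hypertension.",
                      "hypertension"), "Negated")
})

test_that("negation scope agrees with an independent window walker", {
  # independent oracle: for every trigger occurrence, walk forward over
  # tokens counting a 6-token window, stopping at termination terms
  lex <- load_lexicons()
  oracle <- function(sent, obs) {
    lw <- tolower(sent$tokens$text)
    obs_idx <- which(sent$tokens$start < obs$end[1] &
                     sent$tokens$end > obs$start[1])
    for (tr in lex$negation_triggers) {
      tt <- strsplit(gsub("'", " ' ", tr), "\\s+")[[1]]
      tt <- tt[nzchar(tt)]
      L <- length(tt)
      if (L > length(lw)) next
      for (s in seq_len(length(lw) - L + 1L)) {
        if (!identical(lw[s:(s + L - 1L)], tt)) next
        k <- s + L
        steps <- 0L
        while (k <= length(lw) && steps < lex$negation_scope &&
               !(lw[k] %in% lex$negation_termination)) {
          if (k %in% obs_idx) return("Negated")
          k <- k + 1L
          steps <- steps + 1L
        }
      }
    }
    "Non_Negated"
  }
  texts <- c("No family history of colon cancer.",
             "Mother denies hypertension but father has hypertension.",
             "He is not aware of any significant family history of stroke.",
             "Family history negative for heart disease.",
             "Without any history of diabetes although cancer was present.",
             "Never had asthma however gout was diagnosed.")
  set.seed(42)
  for (text in texts) {
    doc <- one_sentence_doc(text)
    toks <- doc$sentences[[1]]$tokens
    word_rows <- which(grepl("^[A-Za-z]", toks$text))
    for (i in word_rows) {
      obs <- fh_entities("doc", "Observation", toks$start[i], toks$end[i],
                         toks$text[i])
      expect_equal(detect_negation(doc$sentences[[1]], obs),
                   oracle(doc$sentences[[1]], obs),
                   info = paste(text, "->", toks$text[i]))
    }
  }
})

test_that("lexicons load, validate, and can be overridden", {
  lex <- load_lexicons()
  expect_s3_class(lex, "fh_lexicons")
  expect_true(all(lex$term_map %in%
                  c("Father", "Mother", "Parent", "Brother", "Sister",
                    "Sibling", "Son", "Daughter", "Child", "Grandfather",
                    "Grandmother", "Grandparent", "Uncle", "Aunt", "Cousin")))
  # every normalized name has a degree
  expect_true(all(unique(lex$term_map) %in% names(lex$degree)))
  # composition closed over the enum
  expect_true(all(lex$composition %in% lex$term_map))
  # override file
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("family_members:", "  Mother: [mum]",
               "excluded_members: [spouse]",
               "first_degree: [Mother]", "second_degree: []",
               "composition: {}",
               "cues:", "  paternal: [paternal]", "  maternal: [maternal]",
               "  not_alive: [dead]", "  healthy: [well]",
               "negation:", "  triggers: [denies]",
               "  termination: [but]", "  scope_tokens: 6"), path)
  lex2 <- load_lexicons(path)
  expect_equal(unname(lex2$term_map["mum"]), "Mother")
  expect_identical(score_living_status("dead", lex2), 0L)
})
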
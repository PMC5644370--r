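test_that("medication text normalizes to clean drug-name tokens", {
  expect_identical(normalize_med_text("Aricept 10mg QD"), "aricept")
  expect_identical(normalize_med_text("lisinopril/HCTZ 20-12.5"),
                   c("lisinopril", "hctz"))
  # unit stripping preserves the name's trailing letter
  expect_identical(normalize_med_text("Vitamin D 1000 IU"), "vitamin d")
  expect_identical(normalize_med_text("metformin 500 mg with aspirin"),
                   c("metformin", "aspirin"))
  expect_identical(normalize_med_text("ASA + Fish Oil 1 g"),
                   c("asa", "fish oil"))
  # text reducing to nothing yields zero tokens; empty input errors
  expect_length(normalize_med_text("10 mg QD"), 0L)
  expect_error(normalize_med_text("   "), "empty")
})

test_that("term matching scores, ranks and thresholds candidates", {
  lex <- read_lexicon()
  exact <- match_term("aricept", lex)
  expect_identical(exact$candidate[1], "aricept")
  expect_identical(exact$score[1], 1)
  expect_identical(exact$status[1], "auto_accepted")
  # transposition: edit distance 2 over 7 characters
  typo <- match_term("aricpet", lex)
  expect_identical(typo$candidate[1], "aricept")
  expect_equal(typo$score[1], 1 - 2 / 7, tolerance = 1e-12)
  expect_identical(typo$status[1], "needs_review")
  # garbage token: nothing above the review floor
  junk <- match_term("xzq", lex)
  expect_true(all(junk$status == "rejected"))
  # ties broken lexicographically
  tiny <- structure(list(drugs = list(abcd = "x", abce = "x"),
                         ingredients = list(x = list(
                           list(class = "C", source = "ATC")))),
                    class = "term_lexicon")
  tie <- match_term("abcf", tiny)
  expect_identical(tie$candidate[1:2], c("abcd", "abce"))
  expect_equal(tie$score[1], tie$score[2])
})

test_that("manual review decisions are applied and guarded", {
  lex <- read_lexicon()
  meds <- data.frame(subject_id = c("S1", "S2"), visit = "baseline",
                     raw_text = c("metfromin 500mg", "Aricept 5 mg"))
  m <- match_meds(meds, lex)
  expect_identical(m$status, c("needs_review", "auto_accepted"))
  # empty review file: no change
  expect_identical(apply_review(m, NULL), m)
  rv <- data.frame(query = "metfromin", decision = "accept_as",
                   target = "metformin")
  m2 <- apply_review(m, rv)
  expect_identical(m2$status[1], "manually_adjusted")
  expect_identical(m2$candidate[1], "metformin")
  # downstream classes follow the accepted target
  classes <- map_to_classes(m2, lex, c("Biguanides", "Anticholinesterases"))
  expect_true(classes[classes$subject_id == "S1", "Biguanides"])
  expect_true(classes[classes$subject_id == "S2", "Anticholinesterases"])
  # reviewing an auto-accepted item is rejected
  expect_error(apply_review(m, data.frame(query = "aricept",
                                          decision = "reject",
                                          target = "")),
               "not awaiting review")
  expect_error(apply_review(m, data.frame(query = "nonesuch",
                                          decision = "reject",
                                          target = "")),
               "unknown query")
})

test_that("class rollup has union semantics over ingredients and drugs", {
  lex <- read_lexicon()
  meds <- data.frame(subject_id = c("S1", "S1", "S2"), visit = "baseline",
                     raw_text = c("Sinemet 25-100", "levodopa 100mg",
                                  "vitamin d 400 IU"))
  out <- classify_medications(meds, lex)
  cls <- out$classes
  # combination product: both ingredients carry the same ATC class
  expect_true(cls[cls$subject_id == "S1",
                  "Adrenergic and dopaminergic agents"])
  # reaching one class via two drugs is still a single Boolean TRUE
  expect_identical(sum(unlist(cls[cls$subject_id == "S1", -1])), 1L)
  # class-free ingredient contributes nothing: all-FALSE row
  expect_false(any(unlist(cls[cls$subject_id == "S2", -1])))
  # subjects roster can force all-false rows for unmedicated subjects
  roster <- map_to_classes(out$matches, lex, subjects = c("S1", "S2", "S9"))
  expect_false(any(unlist(roster[roster$subject_id == "S9", -1])))
})

test_that("classification is deterministic and monotone in entries", {
  lex <- read_lexicon()
  meds <- data.frame(subject_id = c("S1", "S2", "S2"), visit = "baseline",
                     raw_text = c("Lipitor 20mg", "metformin", "Zoloft 50"))
  a <- classify_medications(meds, lex)
  b <- classify_medications(meds, lex)
  expect_identical(a, b)
  # adding an entry never turns a TRUE cell FALSE
  more <- rbind(meds, data.frame(subject_id = "S2", visit = "baseline",
                                 raw_text = "Aricept 10mg"))
  c2 <- classify_medications(more, lex)
  for (s in c("S1", "S2")) {
    before <- unlist(a$classes[a$classes$subject_id == s, -1])
    after <- unlist(c2$classes[c2$classes$subject_id == s, -1])
    expect_true(all(after[before]))
  }
  # round trip: matrix -> per-subject class list -> matrix is the identity
  cls <- a$classes
  lists <- lapply(seq_len(nrow(cls)), function(i)
    names(cls)[-1][unlist(cls[i, -1])])
  rebuilt <- cls
  rebuilt[, -1] <- FALSE
  for (i in seq_along(lists)) rebuilt[i, lists[[i]]] <- TRUE
  expect_identical(rebuilt, cls)
})

test_that("the fixture medication table reproduces its truth matrix", {
  fx <- get_fixture()
  out <- classify_medications(fx$meds, review = fx$review)
  got <- out$classes[order(out$classes$subject_id), ]
  want <- fx$truth$med_truth[order(fx$truth$med_truth$subject_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
  # the crafted entries: exact auto-accept at 1.0, misspelling via review,
  # unknown contributes nothing
  crafted <- fx$truth$crafted_meds
  m <- out$matches
  exact <- m[m$subject_id == crafted$subject_id[crafted$kind == "exact"], ]
  expect_identical(exact$status, "auto_accepted")
  expect_identical(exact$score, 1)
  mis <- m[m$subject_id == crafted$subject_id[crafted$kind == "misspelled"], ]
  expect_identical(mis$status, "manually_adjusted")
  unk <- m[m$subject_id == crafted$subject_id[crafted$kind == "unknown"], ]
  expect_identical(unk$status, "rejected")
})
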
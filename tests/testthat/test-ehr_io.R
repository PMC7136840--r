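# Event-table parsing, cohort rules, vocabularies, encoding, splits.

test_that("well-formed rows parse field-for-field; empty file gives empty list", {
  ev <- tiny_events()
  path <- write_tiny_csv(ev)
  parsed <- load_event_table(path)
  expect_equal(nrow(parsed$events), nrow(ev))
  expect_equal(parsed$events$code, ev$code)
  expect_equal(parsed$events$timestamp, ev$timestamp)
  expect_equal(parsed$events$mortality, ev$mortality)
  expect_equal(parsed$events$abnormal_flag, ev$abnormal_flag)
  expect_equal(nrow(parsed$rejections), 0)

  empty <- write_tiny_csv(ev[0, ])
  parsed0 <- load_event_table(empty)
  expect_equal(nrow(parsed0$events), 0)
})

test_that("bad timestamps become rejections with line numbers, not errors", {
  ev <- tiny_events()[1:5, ]
  path <- write_tiny_csv(ev)
  lines <- readLines(path)
  lines[4] <- sub("2011-03-01", "not-a-date", lines[4])  # row 3 of the data
  writeLines(lines, path)
  parsed <- load_event_table(path)
  expect_equal(nrow(parsed$events), 4)
  expect_equal(parsed$rejections$line, 4L)
  expect_match(parsed$rejections$reason, "timestamp")
})

test_that("a missing mandatory column is a hard failure naming the column", {
  ev <- tiny_events()
  ev$view <- NULL
  path <- write_tiny_csv(ev)
  expect_error(load_event_table(path), "view")
})

test_that("jsonl dialect parses equivalently to csv", {
  ev <- tiny_events()
  path <- tempfile(fileext = ".jsonl")
  out <- ev
  out$timestamp <- format(out$timestamp, "%Y-%m-%d")
  writeLines(vapply(seq_len(nrow(out)), function(i) {
    jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1)), path)
  parsed <- load_event_table(path, event_dialect(format = "jsonl"))
  expect_equal(parsed$events$code, ev$code)
  expect_equal(parsed$events$timestamp, ev$timestamp)
})

test_that("cohort rules: <2-encounter exclusion, chronological order, abnormal filter", {
  cohort <- build_cohort(tiny_events())
  # p3 has one encounter -> excluded and counted
  expect_named(cohort, c("p1", "p2"))
  expect_equal(attr(cohort, "n_excluded"), 1L)
  # p2's encounters appear out of order in the file (e3 May, e4 January)
  ts <- vapply(cohort$p2$encounters, function(e) as.character(e$timestamp),
               character(1))
  expect_equal(ts, sort(ts))
  expect_equal(cohort$p2$encounters[[1]]$encounter_id, "e4")
  # abnormal-only: LX abnormal kept (p1), LY normal dropped (p2)
  expect_equal(cohort$p1$encounters[[2]]$codes$lab, "LX")
  expect_equal(cohort$p2$encounters[[1]]$codes$lab, character(0))
  # all-labs mode keeps LY
  all_labs <- build_cohort(tiny_events(), abnormal_only = FALSE)
  expect_equal(all_labs$p2$encounters[[1]]$codes$lab, "LY")
})

test_that("unknown view tags and missing lab flags are hard failures", {
  ev <- tiny_events()
  ev$view[1] <- "vitals"
  expect_error(build_cohort(ev), "vitals")
  ev2 <- tiny_events()
  ev2$abnormal_flag[ev2$view == "lab"] <- NA
  expect_error(build_cohort(ev2), "abnormal_flag")
})

test_that("build_cohort is idempotent on its own exported events", {
  cohort <- build_cohort(tiny_events())
  again <- build_cohort(cohort_events(cohort))
  expect_equal(unclass(again)[names(again)], unclass(cohort)[names(cohort)])
})

test_that("abnormal-only mode never yields more lab indicators than all-labs", {
  sim <- generate_cohort(small_gen_config(seed = 3, n_patients = 40))
  c_abn <- build_cohort(sim$events, abnormal_only = TRUE)
  c_all <- build_cohort(sim$events, abnormal_only = FALSE)
  for (pid in names(c_abn)) {
    for (i in seq_along(c_abn[[pid]]$encounters)) {
      labs_abn <- c_abn[[pid]]$encounters[[i]]$codes$lab
      labs_all <- c_all[[pid]]$encounters[[i]]$codes$lab
      expect_true(all(labs_abn %in% labs_all))
    }
  }
})

test_that("vocabularies are lexicographic, per-view scoped, training-only", {
  tl1 <- make_timeline("a", list(list(diagnosis = c("C", "A")),
                                 list(diagnosis = "B", medication = "A")))
  cohort <- structure(list(a = tl1), class = "ehr_cohort")
  vocabs <- build_vocabularies(cohort)
  expect_equal(vocabs$diagnosis$codes, c("A", "B", "C"))
  expect_equal(vocab_index(vocabs$diagnosis, c("A", "B", "C")), 1:3)
  # the same code string in another view gets an independent index space
  expect_equal(vocabs$medication$codes, "A")
  expect_equal(vocab_index(vocabs$medication, "A"), 1L)
  # size equals distinct-code count per view
  expect_equal(vocabs$diagnosis$size, 3L)
  expect_equal(vocabs$lab$size, 0L)
  expect_error(build_vocabularies(structure(list(), class = "ehr_cohort")),
               "empty")
})

test_that("multi-hot encoding puts 1s exactly at documented indices; OOV skipped", {
  vocabs <- vocabs_from_codes(diagnosis = c("A","B","C","D","E"),
                              medication = "M1", lab = "L1")
  enc <- list(codes = list(diagnosis = c("B", "D"), medication = character(),
                           lab = "L1"))
  mh <- encode_encounter(enc, vocabs)
  expect_equal(mh$diagnosis, c(0, 1, 0, 1, 0))
  expect_equal(mh$medication, 0)        # no events in a view -> all-zero
  expect_equal(attr(mh, "n_oov"), 0L)
  # unseen code: identical output, OOV counter incremented
  enc2 <- enc
  enc2$codes$diagnosis <- c("B", "D", "ZZZ")
  mh2 <- encode_encounter(enc2, vocabs)
  expect_equal(mh2$diagnosis, mh$diagnosis)
  expect_equal(attr(mh2, "n_oov"), 1L)
})

test_that("encode/decode round-trip recovers the in-vocabulary code set", {
  sim <- generate_cohort(small_gen_config(seed = 9, n_patients = 30))
  vocabs <- build_vocabularies(sim$cohort)
  for (tl in sim$cohort[1:10]) {
    for (enc in tl$encounters) {
      mh <- encode_encounter(enc, vocabs)
      for (v in views3) {
        decoded <- vocab_code(vocabs[[v]], which(mh[[v]] == 1))
        expect_setequal(decoded, intersect(enc$codes[[v]], vocabs[[v]]$codes))
      }
    }
  }
})

test_that("last-encounter removal keeps the prefix and the label", {
  tl <- make_timeline("p", replicate(5, list(list(diagnosis = "A")),
                                     simplify = FALSE), mortality = 1L)
  out <- prepare_model_input(tl)
  expect_length(out$encounters, 4)
  expect_identical(out$encounters, tl$encounters[1:4])
  expect_equal(out$mortality, 1L)
  tl2 <- make_timeline("q", list(list(diagnosis = "A")))
  expect_error(prepare_model_input(tl2), "2 encounters")
})

test_that("split sizes follow the floor/remainder convention and are seeded", {
  s <- split_cohort(sprintf("p%02d", 1:10), c(0.7, 0.1, 0.2), seed = 4)
  expect_equal(lengths(s[c("train", "validation", "test")]),
               c(train = 7L, validation = 1L, test = 2L))
  s2 <- split_cohort(sprintf("p%02d", 1:10), c(0.7, 0.1, 0.2), seed = 4)
  expect_identical(s, s2)
  s3 <- split_cohort(sprintf("p%02d", 1:10), c(0.7, 0.1, 0.2), seed = 5)
  expect_equal(lengths(s3[1:3]), lengths(s[1:3]))
  expect_false(identical(s3$train, s$train))
  expect_error(split_cohort(c("a", "b", "c"), c(0.5, 0.2, 0.2), 1), "sum to 1")
  expect_error(split_cohort(c("a", "b"), seed = 1), "at least 3")
})

test_that("splits partition the cohort for 1000 random (N, seed) pairs", {
  set.seed(202)
  for (rep in 1:1000) {
    n <- sample(3:400, 1)
    seed <- sample.int(1e6, 1)
    ids <- as.character(seq_len(n))
    s <- split_cohort(ids, seed = seed)
    expect_equal(length(s$train) + length(s$validation) + length(s$test), n)
    expect_setequal(c(s$train, s$validation, s$test), ids)
    expect_length(intersect(s$train, s$validation), 0)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$validation, s$test), 0)
  }
})

test_that("merged train+validation is disjoint from test; empty validation ok", {
  s <- split_cohort(as.character(1:50), seed = 2)
  m <- merge_train_validation(s)
  expect_length(m, 40)
  expect_length(intersect(m, s$test), 0)
  s$validation <- character(0)
  expect_equal(sort(merge_train_validation(s)), sort(s$train))
})

test_that("split manifests round-trip through JSON", {
  s <- split_cohort(as.character(1:20), seed = 7)
  path <- tempfile(fileext = ".json")
  write_split_manifest(s, path)
  s2 <- read_split_manifest(path)
  expect_equal(s2$train, s$train)
  expect_equal(s2$test, s$test)
  expect_equal(s2$seed, s$seed)
})
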
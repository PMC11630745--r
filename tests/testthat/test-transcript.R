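test_that("exclusion spans are removed and runs split at every mark", {
  r <- raw_transcript("p1", "control", "cookie_theft", 60,
                      "the {fill um} mother is {rep is} drying")
  ct <- parse_transcript(r)
  expect_identical(ct$runs, list("the", c("mother", "is"), "drying"))

  plain <- parse_transcript(raw_transcript("p1", "control", "cookie_theft",
                                           60, "the boy is on the stool"))
  expect_length(plain$runs, 1L)
  expect_identical(plain$runs[[1]],
                   c("the", "boy", "is", "on", "the", "stool"))

  gone <- parse_transcript(raw_transcript("p1", "svPPA", "beach_scene", 45,
                                          "{unint xxx}"))
  expect_length(gone$runs, 0L)
  expect_length(transcript_tokens(gone), 0L)
})

test_that("clause boundaries and prosodic marks break runs without tokens", {
  ct <- parse_transcript(raw_transcript("p1", "control", "cookie_theft", 60,
                                        "the boy // is falling %% down"))
  expect_identical(ct$runs, list(c("the", "boy"), c("is", "falling"), "down"))
})

test_that("tokens are lower-cased, punctuation-stripped, contractions kept", {
  ct <- parse_transcript(raw_transcript("p1", "control", "cookie_theft", 60,
                                        "The Boy, it's half-dried."))
  expect_identical(ct$runs[[1]], c("the", "boy", "it's", "half-dried"))
})

test_that("malformed markup fails with a byte offset", {
  bad_open <- raw_transcript("p1", "control", "cookie_theft", 60,
                             "the {fill um mother")
  expect_error(parse_transcript(bad_open), "unbalanced '\\{' at byte 5")
  bad_close <- raw_transcript("p1", "control", "cookie_theft", 60,
                              "the um} mother")
  expect_error(parse_transcript(bad_close), "unbalanced '\\}' at byte 7")
  bad_code <- raw_transcript("p1", "control", "cookie_theft", 60,
                             "the {zz um} mother")
  expect_error(parse_transcript(bad_code), "unknown exclusion code 'zz'")
})

test_that("metadata is validated at construction", {
  expect_error(raw_transcript("p", "control", "cookie_theft", 0, "x"),
               "duration_s")
  expect_error(raw_transcript("p", "banana", "cookie_theft", 10, "x"))
  expect_error(raw_transcript("p", "control", "garden", 10, "x"))
})

test_that("parsing is idempotent through serialization", {
  for (seed in 1:25) {
    ct <- random_clean(seed)
    reparsed <- parse_transcript(
      raw_transcript(ct$participant_id, ct$group, ct$picture, ct$duration_s,
                     serialize_transcript(ct)))
    expect_identical(reparsed$runs, ct$runs)
  }
})

test_that("retained tokens never exceed whitespace tokens of the raw text", {
  texts <- c("the {fill um} boy // is", "{unint xxx} a b c",
             "one two three", "{rep a} {rep b} c")
  for (tx in texts) {
    ct <- parse_transcript(raw_transcript("p", "PSP", "beach_scene", 30, tx))
    n_ws <- length(strsplit(trimws(tx), "[[:space:]]+")[[1]])
    expect_lte(length(transcript_tokens(ct)), n_ws)
  }
})

test_that("percent agreement uses an LCS alignment over the reference", {
  a <- make_clean(list(sprintf("w%d", 1:10)))
  expect_equal(percent_agreement(a, a)$overall, 1.0)

  b <- make_clean(list(c(sprintf("w%d", 1:4), "zzz", sprintf("w%d", 6:10))))
  expect_equal(percent_agreement(a, b)$overall, 0.9)

  disjoint <- make_clean(list(sprintf("v%d", 1:10)))
  expect_equal(percent_agreement(a, disjoint)$overall, 0.0)

  # denominator is the reference's count: asymmetric by definition
  longer <- make_clean(list(sprintf("w%d", 1:20)))
  expect_equal(percent_agreement(a, longer)$overall, 1.0)
  expect_equal(percent_agreement(longer, a)$overall, 0.5)

  empty <- make_clean(list())
  expect_error(percent_agreement(empty, a), "zero words")

  restricted <- percent_agreement(a, b, word_list = c("w5", "w6"))
  expect_equal(restricted$restricted, 0.5)  # w5 missing in b, w6 matched
})

test_that("agreement requires matching participant and picture", {
  a <- make_clean(list("x"), id = "p1")
  b <- make_clean(list("x"), id = "p2")
  expect_error(percent_agreement(a, b), "same participant")
})

test_that("transcript files round-trip exactly", {
  dir <- withr::local_tempdir()
  raw <- raw_transcript("p7", "lvPPA", "beach_scene", 83.25,
                        "the {fill um} sea // is %% blue {rep blue}")
  path <- file.path(dir, "p7.txt")
  write_transcript(raw, path)
  back <- read_transcript(path)
  expect_identical(back$participant_id, raw$participant_id)
  expect_identical(back$group, raw$group)
  expect_identical(back$picture, raw$picture)
  expect_equal(back$duration_s, raw$duration_s)
  expect_identical(back$text, raw$text)
  expect_identical(parse_transcript(back)$runs, parse_transcript(raw)$runs)
})

test_that("cohort manifests load transcripts and reject missing columns", {
  dir <- withr::local_tempdir()
  write_transcript(raw_transcript("a1", "control", "cookie_theft", 60,
                                  "a boy"), file.path(dir, "a1.txt"))
  write.csv(data.frame(participant_id = "a1", group = "control",
                       picture = "cookie_theft", file = "a1.txt",
                       acer_memory = 24),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  loaded <- read_cohort(file.path(dir, "manifest.csv"))
  expect_length(loaded$transcripts, 1L)
  expect_identical(loaded$transcripts[[1]]$participant_id, "a1")

  write.csv(data.frame(participant_id = "a1"),
            file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "bad.csv")), "lacks column")
})
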
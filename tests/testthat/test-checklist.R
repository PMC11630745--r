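test_that("equivalence-class scoring accepts variants and inflections", {
  boy <- equivalence_class("boy", c("chap", "lad", "bloke"))
  expect_equal(score_word(c("the", "chap", "ran"), boy), 1L)
  expect_equal(score_word(c("the", "dog", "ran"), boy), 0L)
  expect_equal(score_word(c("two", "boys"), boy), 1L)       # plural root

  dig <- equivalence_class("dig")
  expect_equal(score_word("digging", dig), 1L)              # doubling undone
  overflow <- equivalence_class("overflow")
  expect_equal(score_word("overflowing", overflow), 1L)
  steal <- equivalence_class("steal", c("stealing", "stolen"))
  expect_equal(score_word("stolen", steal), 1L)             # explicit variant
  expect_equal(score_word("steals", steal), 1L)

  fall <- equivalence_class("fall")
  expect_equal(score_word("falling", fall), 1L)             # 'll' kept intact
  expect_equal(score_word(character(0), fall), 0L)
})

test_that("indicator scoring is monotone under added tokens", {
  cls <- equivalence_class("plate", "dish")
  set.seed(12)
  vocab <- c("plate", "plates", "dish", "cup", "fork", "spoon", "table")
  for (i in 1:40) {
    toks <- sample(vocab, sample.int(5, 1))
    extra <- c(toks, sample(vocab, 2))
    expect_gte(score_word(extra, cls), score_word(toks, cls))
  }
})

test_that("indicator matrices code production per participant and class", {
  trs <- list(
    parse_transcript(raw_transcript("a", "control", "cookie_theft", 60,
                                    "the boy steals a cookie")),
    parse_transcript(raw_transcript("b", "svPPA", "cookie_theft", 60,
                                    "a thing doing something")),
    parse_transcript(raw_transcript("c", "PSP", "cookie_theft", 60,
                                    "the boy steals a cookie"))
  )
  classes <- list(equivalence_class("boy", c("chap", "lad")),
                  equivalence_class("steal"),
                  equivalence_class("overflow"))
  x <- build_indicator_matrix(trs, classes)
  expect_equal(dim(x), c(3L, 3L))
  expect_equal(unname(x["b", ]), c(0L, 0L, 0L))      # all-zero row
  expect_equal(unname(x["a", ]), unname(x["c", ]))   # identical token sets
  expect_equal(attr(x, "picture"), "cookie_theft")

  dup <- c(trs, trs[1])
  expect_error(build_indicator_matrix(dup, classes), "duplicate participant")
  mixed <- trs
  mixed[[2]] <- parse_transcript(raw_transcript("b", "svPPA", "beach_scene",
                                                60, "sand"))
  expect_error(build_indicator_matrix(mixed, classes), "share one picture")
})

test_that("unique word classes merge inflections under one root", {
  trs <- list(
    parse_transcript(raw_transcript("a", "control", "cookie_theft", 60,
                                    "plates plate washing the washed")),
    parse_transcript(raw_transcript("b", "svPPA", "cookie_theft", 60,
                                    "plate"))
  )
  cls <- unique_word_classes(trs)
  # equal-frequency surface forms tie-break alphabetically ("washed")
  expect_setequal(names(cls), c("plate", "washed"))
  expect_setequal(cls[["plate"]]$variants, c("plate", "plates"))
  expect_setequal(cls[["washed"]]$variants, c("washing", "washed"))
})

test_that("planted production probabilities are recovered in column means", {
  probs <- cbind(control = c(0.9, 0.3), svPPA = c(0.2, 0.3))
  rownames(probs) <- c("w1", "w2")
  sim <- simulate_indicators(200, probs, seed = 44)
  cm <- colMeans(sim$x[sim$groups == "control", ])
  # binomial 99% half-width at n=200, p=.9 is ~0.055
  expect_lt(abs(cm["w1"] - 0.9), 0.08)
  expect_lt(abs(cm["w2"] - 0.3), 0.09)
})

test_that("proportion difference is the absolute gap in production rates", {
  g <- rep(c("control", "svPPA"), each = 10)
  expect_equal(proportion_difference(rep(c(1, 0), each = 10), g,
                                     "control", "svPPA"), 1)
  expect_equal(proportion_difference(rep(c(1, 0), 10), g,
                                     "control", "svPPA"), 0)
  col <- c(rep(1, 8), rep(0, 2), rep(1, 3), rep(0, 7))
  expect_equal(proportion_difference(col, g, "control", "svPPA"), 0.5)
  expect_error(proportion_difference(col, g, "control", "CBS"), "non-empty")
})

test_that("rank ordering is lexicographic in the three criteria", {
  tab <- data.frame(
    word = c("bb", "aa", "cc", "dd"),
    appearance_count = c(1L, 3L, 1L, 1L),
    max_abs_beta = c(2.0, 0.1, 2.0, 0.5),
    proportion_difference = c(0.2, 0.1, 0.9, 0.9)
  )
  ord <- tab$word[connspeech:::rank_order(tab)]
  # appearance dominates beta; beta breaks ties before proportion
  expect_identical(ord, c("aa", "cc", "bb", "dd"))

  ties <- data.frame(word = c("zed", "abc"),
                     appearance_count = c(2L, 2L),
                     max_abs_beta = c(1, 1),
                     proportion_difference = c(0.5, 0.5))
  expect_identical(ties$word[connspeech:::rank_order(ties)], c("abc", "zed"))
})

test_that("pairwise selection pools discriminative words and records null contrasts", {
  probs <- cbind(control = c(0.95, 0.9, 0.3, 0.3),
                 svPPA = c(0.05, 0.9, 0.3, 0.3),
                 lvPPA = c(0.05, 0.1, 0.3, 0.3))
  rownames(probs) <- c("sep_all", "sep_lv", "noise1", "noise2")
  sim <- simulate_indicators(20, probs, seed = 77)
  sel <- pairwise_selection(sim$x, sim$groups, seed = 5)
  expect_true("sep_all" %in% sel$pooled)
  expect_true("sep_lv" %in% sel$pooled)
  expect_named(sel$per_contrast, c("control_vs_svPPA", "control_vs_lvPPA",
                                   "svPPA_vs_lvPPA"))

  # a word produced by all of A and none of B is always pooled
  g2 <- rep(c("control", "PSP"), each = 12)
  x2 <- cbind(perfect = as.integer(g2 == "control"),
              noise = rbinom(24, 1, 0.5))
  sel2 <- pairwise_selection(x2, g2, seed = 3)
  expect_true("perfect" %in% sel2$pooled)
})

test_that("identically generated groups mostly pool nothing (null behaviour)", {
  zero_runs <- 0L
  for (seed in 1:10) {
    probs <- cbind(control = rep(0.4, 6), svPPA = rep(0.4, 6))
    rownames(probs) <- paste0("w", 1:6)
    sim <- simulate_indicators(15, probs, seed = 1000 + seed)
    sel <- pairwise_selection(sim$x, sim$groups, seed = seed)
    if (length(sel$pooled) == 0L) zero_runs <- zero_runs + 1L
  }
  expect_gte(zero_runs, 5L)  # modal outcome is the empty pool
})

test_that("derivation returns a ranked top-15 and is reproducible", {
  coh <- generate_cohort(group_sizes = c(control = 10, svPPA = 8, nfvPPA = 8),
                         seed = 19, n_words = 80,
                         profiles = uniform_profiles())
  clean <- lapply(coh$transcripts, parse_transcript)
  ct <- Filter(function(x) x$picture == "cookie_theft", clean)
  grp <- vapply(ct, `[[`, "", "group")
  d1 <- derive_checklist(ct, grp, seed = 4)
  d2 <- derive_checklist(ct, grp, seed = 4)
  expect_identical(d1$table, d2$table)
  expect_lte(length(d1$checklist$classes), 15L)
  expect_identical(d1$table$rank, seq_len(nrow(d1$table)))
  # every checklist word must carry its inflectional variants
  for (cl in d1$checklist$classes) {
    expect_s3_class(cl, "equivalence_class")
    expect_true(cl$target %in% cl$variants)
  }
})

test_that("an empty pool yields an empty checklist with a warning", {
  x <- cbind(w1 = rep(0:1, 10), w2 = rep(c(1, 0), 10))
  g <- rep(c("control", "svPPA"), each = 10)
  expect_warning(out <- rank_and_truncate(x, g, character(0)), "empty")
  expect_length(out$checklist$classes, 0L)
})

test_that("confusion reports compute accuracy, sensitivity and specificity", {
  truth <- rep(c(1, 0), each = 10)
  pred <- c(rep(1, 9), 0, 1, 1, rep(0, 8))
  rep_ <- connspeech:::confusion_report(truth, pred, "patient", "demo",
                                        "kfold")
  expect_equal(unname(rep_$confusion["true_pos", ]), c(9, 1))
  expect_equal(unname(rep_$confusion["true_neg", ]), c(2, 8))
  expect_equal(rep_$sensitivity, 0.9)
  expect_equal(rep_$specificity, 0.8)
  expect_equal(rep_$accuracy, 0.85)
})

test_that("a perfectly separating word gives 100% k-fold accuracy", {
  set.seed(50)
  g <- rep(c("control", "svPPA"), each = 16)
  x <- cbind(perfect = as.integer(g == "svPPA"),
             noise1 = rbinom(32, 1, 0.5), noise2 = rbinom(32, 1, 0.5))
  rownames(x) <- sprintf("p%02d", 1:32)
  rep_ <- validate_checklist(x, factor(g, c("control", "svPPA")),
                             scheme = "kfold", seed = 2)
  expect_equal(rep_$accuracy, 1.0)
})

test_that("hierarchical validation runs the staged contrasts", {
  coh <- generate_cohort(group_sizes = c(control = 8, svPPA = 6, lvPPA = 6,
                                         nfvPPA = 6, PSP = 5, CBS = 5),
                         seed = 23, n_words = 80)
  clean <- lapply(coh$transcripts, parse_transcript)
  ct <- Filter(function(x) x$picture == "cookie_theft", clean)
  grp <- vapply(ct, `[[`, "", "group")
  planted <- coh$ground_truth$planted$cookie_theft$word
  classes <- lapply(planted, equivalence_class)
  names(classes) <- planted
  x <- build_indicator_matrix(ct, classes)
  reports <- hierarchical_validate(x, grp, scheme = "kfold", seed = 31)
  expect_setequal(names(reports),
                  c("patients_vs_controls", "motor_vs_lexicosemantic",
                    "svPPA_vs_lvPPA", "nfvPPA_vs_PSP_CBS"))
  # planted structure separates stage 1 and stage 2 well above chance
  expect_gt(reports$patients_vs_controls$accuracy, 0.8)
  expect_gt(reports$motor_vs_lexicosemantic$accuracy, 0.75)
  for (r in reports) {
    expect_equal(r$accuracy,
                 sum(diag(r$confusion)) / sum(r$confusion))
  }
})

test_that("out-of-sample validation refuses shared participants and scores a test cohort", {
  set.seed(61)
  g_tr <- rep(c("control", "svPPA"), each = 15)
  x_tr <- cbind(marker = rbinom(30, 1, ifelse(g_tr == "svPPA", 0.9, 0.1)),
                noise = rbinom(30, 1, 0.5))
  rownames(x_tr) <- sprintf("tr%02d", 1:30)
  g_te <- rep(c("control", "svPPA"), each = 8)
  x_te <- cbind(marker = rbinom(16, 1, ifelse(g_te == "svPPA", 0.9, 0.1)),
                noise = rbinom(16, 1, 0.5))
  rownames(x_te) <- sprintf("te%02d", 1:16)
  rep_ <- validate_checklist(x_tr, factor(g_tr, c("control", "svPPA")),
                             scheme = "oos", seed = 5, x_test = x_te,
                             y_test = factor(g_te, c("control", "svPPA")))
  expect_equal(rep_$scheme, "oos")
  expect_gt(rep_$accuracy, 0.7)
  shared <- x_te
  rownames(shared)[1] <- "tr01"
  expect_error(validate_checklist(x_tr, factor(g_tr), scheme = "oos",
                                  x_test = shared, y_test = factor(g_te)),
               "shares participants")
})

test_that("cognitive augmentation z-scores continuous columns and helps when words are uninformative", {
  set.seed(71)
  g <- rep(c("nfvPPA", "PSP"), each = 15)
  x <- matrix(rbinom(30 * 5, 1, 0.5), 30, 5,
              dimnames = list(sprintf("p%02d", 1:30), paste0("w", 1:5)))
  scores <- data.frame(
    mlse_motor_speech = rnorm(30, ifelse(g == "nfvPPA", 8, 12), 1.2),
    flat = rep(3, 30)
  )
  expect_warning(aug <- augment_with_cognitive(x, scores), "flat")
  expect_equal(ncol(aug), 6L)
  expect_equal(mean(aug[, "mlse_motor_speech"]), 0, tolerance = 1e-12)
  expect_equal(sd(aug[, "mlse_motor_speech"]), 1, tolerance = 1e-12)
  expect_true(all(aug[, 1:5] %in% 0:1))

  words_only <- validate_checklist(x, factor(g), scheme = "kfold", seed = 9)
  augmented <- validate_checklist(aug, factor(g), scheme = "kfold", seed = 9)
  expect_gt(augmented$accuracy, words_only$accuracy)
})

test_that("checklist scoresheets serialize targets, variants and betas", {
  dir <- withr::local_tempdir()
  cl <- structure(list(picture = "cookie_theft",
                       classes = list(boy = equivalence_class("boy", "lad"),
                                      dig = equivalence_class("dig")),
                       table = NULL),
                  class = "checklist")
  path <- file.path(dir, "sheet.csv")
  write_checklist(cl, path)
  sheet <- read.csv(path)
  expect_equal(sheet$target, c("boy", "dig"))
  expect_true(grepl("lad", sheet$variants[1]))
})
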
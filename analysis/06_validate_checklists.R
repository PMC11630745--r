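#!/usr/bin/env Rscript
# Step 6: hierarchical validation of the derived checklists.
# Stage 1: patients vs controls. Stage 2: motor (nfvPPA/PSP/CBS) vs
# lexico-semantic (svPPA/lvPPA). Stage 3: within-cluster pairs, with PSP
# and CBS merged. Within-sample stratified 4-fold CV, an independent
# synthetic out-of-sample cohort (second-site layout), and cognitive
# supplementation for svPPA vs lvPPA.

library(connspeech)

seed <- 2026L
cohort <- read_cohort("results/cohort/manifest.csv")
clean <- lapply(cohort$transcripts, parse_transcript)

# second-site cohort: independent participants, same language (lexicon)
oos <- generate_cohort(group_sizes = c(control = 10, svPPA = 7, lvPPA = 13,
                                       nfvPPA = 5, PSP = 2, CBS = 6),
                       seed = seed + 1000L,
                       lexicon = read_norms_lexicon("results/cohort/norms.csv"))
oos_clean <- lapply(oos$transcripts, function(t) {
  ct <- parse_transcript(t)
  ct$participant_id <- paste0("oos_", ct$participant_id)
  ct
})

all_reports <- list()
for (pic in speech_pictures()) {
  sheet <- read.csv(sprintf("results/checklist_%s.csv", pic))
  classes <- lapply(seq_len(nrow(sheet)), function(i) {
    equivalence_class(sheet$target[i],
                      strsplit(sheet$variants[i], "|", fixed = TRUE)[[1]])
  })
  names(classes) <- sheet$target
  trs <- Filter(function(x) x$picture == pic, clean)
  grp <- vapply(trs, `[[`, "", "group")
  x <- build_indicator_matrix(trs, classes)

  message("== ", pic, ": within-sample 4-fold CV ==")
  kf <- suppressWarnings(hierarchical_validate(x, grp, scheme = "kfold",
                                               seed = seed))
  for (r in kf) print(r)

  message("== ", pic, ": out-of-sample ==")
  te <- Filter(function(xx) xx$picture == pic, oos_clean)
  g_te <- vapply(te, `[[`, "", "group")
  x_te <- build_indicator_matrix(te, classes)
  oo <- suppressWarnings(hierarchical_validate(x, grp, scheme = "oos",
                                               seed = seed, x_test = x_te,
                                               groups_test = g_te))
  for (r in oo) print(r)
  all_reports[[pic]] <- list(kfold = kf, oos = oo)

  if (pic == "cookie_theft") {
    message("== cognitive supplementation: svPPA vs lvPPA ==")
    keep <- grp %in% c("svPPA", "lvPPA")
    cog_cols <- grep("^(acer|mlse)_", names(cohort$manifest), value = TRUE)
    man <- cohort$manifest[cohort$manifest$picture == pic, ]
    cog <- man[match(rownames(x)[keep], man$participant_id), cog_cols]
    y <- factor(grp[keep], c("lvPPA", "svPPA"))
    words <- suppressWarnings(validate_checklist(
      x[keep, ], y, scheme = "kfold", seed = seed,
      contrast = "svPPA_vs_lvPPA (words only)"))
    aug <- suppressWarnings(validate_checklist(
      augment_with_cognitive(x[keep, ], cog), y, scheme = "kfold",
      seed = seed, contrast = "svPPA_vs_lvPPA (words + ACE-R/MLSE)"))
    print(words)
    print(aug)
  }
}

json <- lapply(all_reports, function(pr) {
  lapply(pr, function(reports) {
    lapply(reports, function(r) {
      list(contrast = r$contrast, scheme = r$scheme,
           accuracy = r$accuracy, sensitivity = r$sensitivity,
           specificity = r$specificity, n = r$n)
    })
  })
})
jsonlite::write_json(json, "results/validation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("validation written to results/validation.json")
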
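#!/usr/bin/env Rscript
# Step 3: the two varimax-rotated PCAs.
#  (a) Fluency PCA over the 13 measures (rows = participant x picture),
#      three components ('speech quanta', 'lexical richness', 'speech
#      complexity'), one-way ANOVA on each component by group.
#  (b) Word-properties PCA over the pooled unique-word corpus (eight
#      psycholinguistic properties -> 'length', 'semantic richness',
#      'acquisition age'), word scores averaged per participant, two-way
#      group x picture ANOVA.

library(connspeech)

cohort <- read_cohort("results/cohort/manifest.csv")
clean <- lapply(cohort$transcripts, parse_transcript)
lexicon <- read_norms_lexicon("results/cohort/norms.csv")

# (a) fluency PCA ---------------------------------------------------------
profiles <- read.csv("results/fluency_wide.csv")
features <- setdiff(names(profiles), c("participant_id", "group", "picture"))
complete <- profiles[complete.cases(profiles[features]), ]
message(sprintf("fluency KMO = %.2f",
                kmo(complete[features], pseudo_inverse = TRUE)))
fl <- label_components(pca_varimax(complete[features], 3),
                       fluency_measure_labels())
print(fl)
scores <- cbind(complete[c("participant_id", "group", "picture")],
                as.data.frame(fl$scores))
write.csv(scores, "results/fluency_pca_scores.csv", row.names = FALSE)

tests <- pc_group_tests(scores, paste0("PC", 1:3))
for (pc in names(tests)) {
  a <- tests[[pc]]$anova
  message(sprintf("%s by group: F(%d,%d) = %.2f, p = %.2g", pc, a$df,
                  a$df_resid, a$F, a$p))
}

# (b) word-properties PCA -------------------------------------------------
annotated <- annotate_cohort(clean, lexicon)
corpus <- unique(annotated$tokens[c("token", norm_properties())])
message(sprintf("speech corpus: %d unique content words; KMO = %.2f",
                nrow(corpus), kmo(corpus[norm_properties()])))
ev <- eigen(cor(corpus[norm_properties()]), symmetric = TRUE,
            only.values = TRUE)$values
message("scree selection on the corpus spectrum: k = ", scree_select(ev))
wp <- label_components(pca_varimax(corpus[norm_properties()], 3),
                       word_property_labels())
print(wp)

participant_scores <- project_words_and_average(wp, annotated$tokens)
write.csv(participant_scores, "results/participant_word_scores.csv",
          row.names = FALSE)
token_scores <- cbind(annotated$tokens[c("participant_id", "group",
                                         "picture", "token")],
                      as.data.frame(pca_project(wp, annotated$tokens)))
write.csv(token_scores, "results/token_word_scores.csv", row.names = FALSE)

two_way <- pc_group_tests(participant_scores, paste0("PC", 1:3),
                          task_col = "picture")
for (pc in names(two_way)) {
  a <- two_way[[pc]]$anova
  message(pc, " (two-way group x picture):")
  print(a, row.names = FALSE, digits = 3)
}
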
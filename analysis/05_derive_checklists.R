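#!/usr/bin/env Rscript
# Step 5: derive the 15-word diagnostic checklists.
# Per picture: indicator-code every unique content word (inflections
# merged by root), run L1-penalized logistic regressions for all 15
# pairwise group contrasts, pool the selected words, re-fit on the pooled
# set, rank by (appearances, max |beta|, proportion difference) and keep
# the top 15.

library(connspeech)

seed <- 2026L
cohort <- read_cohort("results/cohort/manifest.csv")
clean <- lapply(cohort$transcripts, parse_transcript)

for (pic in speech_pictures()) {
  trs <- Filter(function(x) x$picture == pic, clean)
  grp <- vapply(trs, `[[`, "", "group")
  der <- derive_checklist(trs, grp, seed = seed)
  message(sprintf("%s: %d unique word classes, pooled %d, checklist %d",
                  pic, length(der$classes), length(der$selection$pooled),
                  length(der$checklist$classes)))
  if (length(der$selection$zero_word_contrasts) > 0L) {
    message("  contrasts selecting zero words: ",
            paste(der$selection$zero_word_contrasts, collapse = ", "))
  }
  print(der$checklist)
  write_checklist(der$checklist,
                  sprintf("results/checklist_%s.csv", pic),
                  rerun = der$rerun)
  write.csv(der$table, sprintf("results/ranked_words_%s.csv", pic),
            row.names = FALSE)
}
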
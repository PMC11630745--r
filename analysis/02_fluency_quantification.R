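#!/usr/bin/env Rscript
# Step 2: parse the annotated transcripts and compute the 13
# speech-fluency measures per participant x picture (the input to the
# fluency PCA). Writes wide and long tables and prints the group means
# that should show reduced output in nfvPPA/PSP/CBS.

library(connspeech)

cohort <- read_cohort("results/cohort/manifest.csv")
clean <- lapply(cohort$transcripts, parse_transcript)
profiles <- fluency_profiles(clean)

dir.create("results", showWarnings = FALSE)
write.csv(profiles, "results/fluency_wide.csv", row.names = FALSE)
write.csv(fluency_long(profiles), "results/fluency_long.csv",
          row.names = FALSE)

means <- aggregate(cbind(word_tokens, words_per_minute, combination_ratio) ~
                     group, data = profiles, FUN = mean)
message("group means (both pictures pooled):")
print(means[order(-means$word_tokens), ], row.names = FALSE, digits = 3)
message("reduced total output and rate in the motor groups ",
        "(nfvPPA/PSP/CBS) is the expected pattern")
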
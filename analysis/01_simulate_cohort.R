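#!/usr/bin/env Rscript
# Step 1: generate the synthetic development cohort.
#
# Layout mirrors a realistic progressive-aphasia study: 24 controls, 9
# svPPA, 9 lvPPA, 9 nfvPPA, 10 PSP, 13 CBS, each describing the 'cookie
# theft' and 'beach scene' pictures. The generator plants the group
# structure the later steps should recover: reduced output in the motor
# groups, a high-frequency/high-semantic-diversity tilt in svPPA/lvPPA,
# earlier-acquired words in nfvPPA/CBS, and 12 checklist-discriminative
# words per picture.

library(connspeech)

seed <- 2026L
out <- "results/cohort"

cohort <- generate_cohort(seed = seed)
write_cohort(cohort, out)

print(cohort)
message("planted words (cookie theft):")
print(cohort$ground_truth$planted$cookie_theft[, c("word", "role")])
message("cohort written to ", out)
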
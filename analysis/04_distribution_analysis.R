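#!/usr/bin/env Rscript
# Step 4: distribution analysis of word PC scores.
# Fixed-edge quartiles ([-4,-2], (-2,0], (0,2], (2,4]) on each component;
# per-participant bivariate proportion maps on PC1 x PC2; patient-minus-
# control difference maps with cellwise Welch tests; and a group x
# quartile repeated-measures ANOVA per component.

library(connspeech)

token_scores <- read.csv("results/token_word_scores.csv")

for (pc in paste0("PC", 1:3)) {
  qc <- cohort_quartile_counts(token_scores, pc)
  write.csv(qc, sprintf("results/quartile_counts_%s.csv", pc),
            row.names = FALSE)
  rm_res <- quartile_rm_anova(as.matrix(qc[, c("Q1", "Q2", "Q3", "Q4")]),
                              qc$group)
  message(pc, " group x quartile repeated-measures ANOVA:")
  print(rm_res$anova, row.names = FALSE, digits = 3)
}

# bivariate maps on PC1 ('length') x PC2 ('semantic richness')
split_scores <- split(token_scores,
                      list(token_scores$participant_id,
                           token_scores$picture), drop = TRUE)
maps <- lapply(split_scores, function(d) proportion_map(d$PC1, d$PC2))
map_group <- vapply(split_scores, function(d) d$group[1], "")

ctrl_maps <- maps[map_group == "control"]
for (g in setdiff(unique(map_group), "control")) {
  dm <- difference_map(maps[map_group == g], ctrl_maps)
  out <- data.frame(cell_row = rep(rownames(dm$difference), 4),
                    cell_col = rep(colnames(dm$difference), each = 4),
                    difference = as.vector(dm$difference),
                    t = as.vector(dm$t), p = as.vector(dm$p))
  write.csv(out, sprintf("results/difference_map_%s.csv", g),
            row.names = FALSE)
  sig <- sum(!is.na(dm$p) & dm$p < 0.05)
  message(sprintf("%s vs control: %d/16 cells p < 0.05 (uncorrected)",
                  g, sig))
  peak <- which(abs(dm$difference) == max(abs(dm$difference)), arr.ind = TRUE)[1, ]
  message(sprintf("  peak |difference| %+.3f at [%s, %s]",
                  dm$difference[peak[1], peak[2]],
                  rownames(dm$difference)[peak[1]],
                  colnames(dm$difference)[peak[2]]))
}
message("expected pattern: svPPA/lvPPA mass moves toward semantically ",
        "rich (high PC1) and short (low PC2) words")
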
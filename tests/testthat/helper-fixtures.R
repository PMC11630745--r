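# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds.

make_clean <- function(runs, duration_s = 60, id = "p1", group = "control",
                       picture = "cookie_theft") {
  structure(list(participant_id = id, group = group, picture = picture,
                 duration_s = duration_s, runs = runs),
            class = "clean_transcript")
}

# Random clean transcript over a small vocabulary: random run structure.
random_clean <- function(seed, vocab = sprintf("w%02d", 1:30),
                         max_runs = 6, max_len = 12) {
  set.seed(seed)
  n_runs <- sample.int(max_runs, 1)
  runs <- lapply(seq_len(n_runs), function(i) {
    sample(vocab, sample.int(max_len, 1), replace = TRUE)
  })
  make_clean(runs, duration_s = runif(1, 30, 120),
             id = paste0("r", seed))
}

# A tiny deterministic norms lexicon with known values.
tiny_lexicon <- function() {
  words <- c("boy", "mother", "plate", "dish", "lady", "sink", "water",
             "stool", "cookie", "overflow", "dry", "steal", "jar", "curtain",
             "window", "reach", "fall", "wash", "dig", "kite")
  set.seed(42)
  df <- data.frame(word = words,
                   length = nchar(words),
                   log_frequency = round(runif(20, 1, 5), 2),
                   semantic_diversity = round(runif(20, 0.5, 2.5), 2),
                   semantic_neighbourhood_density = round(runif(20, 0.2, 0.9), 2),
                   concreteness = round(runif(20, 1.5, 5), 2),
                   age_of_acquisition = round(runif(20, 2, 12), 1),
                   old = round(runif(20, 1, 4), 2),
                   pld = round(runif(20, 1, 4), 2))
  norms_lexicon(df, provenance = "test fixture")
}

# Uniform-profile group list: every group generates like controls, so the
# only systematic group differences are the planted checklist words.
uniform_profiles <- function() {
  prof <- group_profiles()
  out <- lapply(prof, function(p) prof$control)
  names(out) <- names(prof)
  out
}

# Indicator matrix + labels with planted production probabilities.
simulate_indicators <- function(n_per_group, probs, seed) {
  # probs: words x groups matrix of production probabilities
  set.seed(seed)
  groups <- rep(colnames(probs), each = n_per_group)
  x <- matrix(0L, length(groups), nrow(probs),
              dimnames = list(NULL, rownames(probs)))
  for (i in seq_along(groups)) {
    x[i, ] <- as.integer(runif(nrow(probs)) < probs[, groups[i]])
  }
  rownames(x) <- sprintf("s%03d", seq_along(groups))
  list(x = x, groups = groups)
}

# Deterministic child seeds for multi-level simulations in tests.
derive_child_seed <- function(a, b = 0, c = 0) {
  as.integer((a * 131071 + b * 1009 + c) %% 2147483587) + 1L
}
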
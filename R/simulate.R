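# Synthetic cohort generator. Emulates the statistical structure the
# analyses assume -- a norms lexicon with a three-cluster property
# correlation structure, group-specific production volume and lexical
# tilts, disfluency rates, planted checklist-discriminative words and
# cognitive sub-scores -- so every pipeline stage is testable without
# clinical data and recovery against known ground truth can be asserted.
# All generators are pure functions of (parameters, seed).

#' Target correlation matrix of the synthetic norms lexicon
#'
#' Three property clusters: word-form complexity (length, OLD, PLD;
#' pairwise r = 0.8), semantic/lexical richness (log frequency, semantic
#' diversity, semantic neighbourhood density, with concreteness loading
#' negatively; |r| = 0.65) and acquisition age (AoA, cross-correlating
#' weakly, |r| = 0.25, positively with word form and negatively with
#' frequency, as in published norm sets). `cross = 0` removes all
#' between-cluster correlation (block-diagonal structure).
#'
#' @param r_form,r_semantic,r_aoa,cross Within/between-cluster correlation
#'   magnitudes.
#' @return 8x8 positive-definite correlation matrix over
#'   [norm_properties()].
#' @export
norms_correlation_targets <- function(r_form = 0.80, r_semantic = 0.65,
                                      r_aoa = 0.25, cross = 0.15) {
  p <- norm_properties()
  m <- diag(length(p))
  dimnames(m) <- list(p, p)
  set_r <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  form <- c("length", "old", "pld")
  sem_pos <- c("log_frequency", "semantic_diversity",
               "semantic_neighbourhood_density")
  for (i in 1:2) for (j in (i + 1):3) set_r(form[i], form[j], r_form)
  for (i in 1:2) for (j in (i + 1):3) set_r(sem_pos[i], sem_pos[j], r_semantic)
  for (s in sem_pos) set_r("concreteness", s, -r_semantic)
  for (f in form) for (s in sem_pos) set_r(f, s, -cross)
  for (f in form) set_r(f, "concreteness", cross)
  for (f in form) set_r("age_of_acquisition", f, r_aoa)
  for (s in sem_pos) set_r("age_of_acquisition", s, -r_aoa)
  set_r("age_of_acquisition", "concreteness", cross)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) stop_pre("target correlation matrix is not positive definite")
  m
}

# Deterministic pronounceable pseudo-words (independent of the RNG).
make_pseudowords <- function(n, prefix = "") {
  on_ <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  nu_ <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(on_, nu_, paste0))
  k <- length(syll)
  words <- character(n)
  for (i in seq_len(n)) {
    a <- ((i - 1L) %% k) + 1L
    b <- (((i - 1L) %/% k) %% k) + 1L
    c_ <- (((i - 1L) %/% (k * k)) %% k) + 1L
    words[i] <- paste0(prefix, syll[a], syll[b], if (i > k * k) syll[c_] else "")
  }
  make.unique(words, sep = "")
}

# Map standard-normal property draws onto realistic rating scales.
scale_norm_draws <- function(z) {
  data.frame(
    length = pmax(1, round(5 + 2 * z[, "length"])),
    log_frequency = 3 + 1.0 * z[, "log_frequency"],
    semantic_diversity = 1.5 + 0.4 * z[, "semantic_diversity"],
    semantic_neighbourhood_density = 0.55 + 0.15 *
      z[, "semantic_neighbourhood_density"],
    concreteness = pmin(5, pmax(1, 3 + 0.8 * z[, "concreteness"])),
    age_of_acquisition = pmin(16, pmax(1.5, 7 + 2.5 * z[, "age_of_acquisition"])),
    old = pmax(0.5, 2.5 + 0.8 * z[, "old"]),
    pld = pmax(0.5, 2.2 + 0.9 * z[, "pld"])
  )
}

#' Generate a synthetic psycholinguistic norms lexicon
#'
#' Draws per-word property vectors from a correlated Gaussian model with
#' the three-cluster structure of [norms_correlation_targets()], then maps
#' them onto realistic rating scales. At `n_words >= 500` the realized
#' correlations sit within about 0.1 of the targets. Entries are
#' deterministic pronounceable pseudo-words; the lexicon is synthetic by
#' construction and stands in for user-supplied published norm sets.
#'
#' @param n_words Number of entries (>= 8).
#' @param seed Integer seed.
#' @param targets Target correlation matrix.
#' @return A `norms_lexicon` with attributes `targets` and `seed`.
#' @export
generate_norms <- function(n_words, seed,
                           targets = norms_correlation_targets()) {
  if (n_words < 8L) stop_pre("n_words must be at least 8")
  z <- with_seed(seed, MASS::mvrnorm(n_words, mu = rep(0, ncol(targets)),
                                     Sigma = targets))
  colnames(z) <- colnames(targets)
  df <- cbind(data.frame(word = make_pseudowords(n_words),
                         stringsAsFactors = FALSE),
              scale_norm_draws(z))
  lex <- norms_lexicon(df, provenance = paste0("synthetic (seed ", seed, ")"))
  attr(lex, "targets") <- targets
  attr(lex, "seed") <- seed
  lex
}

#' Default group production profiles
#'
#' One profile per diagnostic group: negative-binomial output volume
#' (tokens are overdispersed across patients), duration distribution,
#' softmax property-tilt coefficients governing lexical choice (standard
#' deviations of the lexicon's property distribution), per-code disfluency
#' rates, a function-word rate, and cognitive sub-score means. The
#' defaults encode the qualitative group structure of progressive
#' aphasias: markedly reduced output in nfvPPA/PSP/CBS; a shift toward
#' short, high-frequency, high-semantic-diversity words in svPPA/lvPPA;
#' earlier-acquired words in nfvPPA and CBS; disfluency loads highest in
#' nfvPPA.
#'
#' @return Named list of profiles.
#' @export
group_profiles <- function() {
  prof <- function(mean_tokens, dispersion, duration_mean, duration_sd,
                   function_rate, tilt, disfluency, cognitive) {
    list(mean_tokens = mean_tokens, dispersion = dispersion,
         duration_mean = duration_mean, duration_sd = duration_sd,
         function_rate = function_rate, tilt = tilt,
         disfluency = disfluency, cognitive = cognitive)
  }
  no_tilt <- c(log_frequency = 0, semantic_diversity = 0, length = 0,
               age_of_acquisition = 0)
  dis <- function(fill = 0.03, rep = 0.015, pause = 0.02, fs = 0.005,
                  gram = 0.005, unint = 0.005, neo = 0) {
    c(fill = fill, rep = rep, pause = pause, fs = fs, gram = gram,
      unint = unint, neo = neo)
  }
  cog <- function(att, mem, flu, lang, vis, mot, pho, sem, syn, wm) {
    c(acer_attention = att, acer_memory = mem, acer_fluency = flu,
      acer_language = lang, acer_visuospatial = vis,
      mlse_motor_speech = mot, mlse_phonology = pho, mlse_semantics = sem,
      mlse_syntax = syn, mlse_working_memory = wm)
  }
  list(
    control = prof(110, 10, 65, 8, 0.45, no_tilt, dis(),
                   cog(17, 24, 12, 25, 15, 19, 19, 19, 19, 19)),
    svPPA = prof(100, 8, 65, 8, 0.50,
                 c(log_frequency = 0.9, semantic_diversity = 0.9,
                   length = -0.6, age_of_acquisition = 0),
                 dis(fill = 0.04, rep = 0.02, pause = 0.03),
                 cog(15, 14, 8, 16, 14, 18, 17, 8, 17, 16)),
    lvPPA = prof(85, 8, 66, 8, 0.48,
                 c(log_frequency = 0.7, semantic_diversity = 0.7,
                   length = -0.5, age_of_acquisition = 0),
                 dis(fill = 0.06, rep = 0.03, pause = 0.06),
                 cog(14, 16, 9, 18, 13, 17, 10, 16, 15, 9)),
    nfvPPA = prof(45, 6, 70, 10, 0.38,
                  c(log_frequency = 0.2, semantic_diversity = 0,
                    length = 0, age_of_acquisition = -0.8),
                  dis(fill = 0.04, rep = 0.03, pause = 0.10, fs = 0.05,
                      gram = 0.06, unint = 0.01),
                  cog(14, 18, 7, 18, 13, 8, 13, 17, 10, 13)),
    PSP = prof(40, 6, 70, 10, 0.42,
               c(log_frequency = 0.3, semantic_diversity = 0,
                 length = 0, age_of_acquisition = -0.4),
               dis(fill = 0.04, rep = 0.02, pause = 0.08),
               cog(13, 18, 8, 19, 12, 11, 14, 17, 14, 13)),
    CBS = prof(55, 6, 70, 10, 0.42,
               c(log_frequency = 0.2, semantic_diversity = 0,
                 length = 0, age_of_acquisition = -0.7),
               dis(fill = 0.04, rep = 0.02, pause = 0.06),
               cog(13, 18, 8, 19, 10, 12, 14, 17, 14, 13))
  )
}

#' Default planted checklist-word design for one picture
#'
#' Twelve planted words per picture with group-specific production
#' probabilities (gaps >= 0.6 on their discriminative contrasts): four
#' control markers patients omit, four the motor cluster omits, two the
#' lexico-semantic cluster omits and two high-frequency substitution
#' markers patients over-produce. No word separates svPPA from lvPPA and
#' none separates nfvPPA from PSP/CBS, mirroring the clinical reality that
#' those distinctions need more than word occurrence.
#'
#' @param words Character vector of 12 lexicon words to plant.
#' @return Data.frame: `word`, `role`, one probability column per group.
#' @export
planted_word_design <- function(words) {
  stopifnot(length(words) == 12L)
  probs <- rbind(
    matrix(rep(c(0.90, 0.15, 0.20, 0.15, 0.15, 0.15), 4), 4, byrow = TRUE),
    matrix(rep(c(0.85, 0.80, 0.80, 0.15, 0.15, 0.15), 4), 4, byrow = TRUE),
    matrix(rep(c(0.85, 0.15, 0.15, 0.80, 0.80, 0.80), 2), 2, byrow = TRUE),
    matrix(rep(c(0.10, 0.75, 0.75, 0.70, 0.70, 0.70), 2), 2, byrow = TRUE)
  )
  colnames(probs) <- speech_groups()
  cbind(data.frame(word = words,
                   role = rep(c("control_marker", "motor_omit",
                                "lexicosemantic_omit", "patient_marker"),
                              c(4, 4, 2, 2)),
                   stringsAsFactors = FALSE),
        as.data.frame(probs))
}

# Common function words with a frequency-ish sampling weight.
FUNCTION_SAMPLER <- c(
  "the" = 10, "and" = 6, "is" = 6, "a" = 5, "to" = 4, "of" = 3, "in" = 3,
  "on" = 3, "it" = 3, "he" = 2, "she" = 2, "there" = 2, "that" = 2,
  "with" = 2, "are" = 2, "his" = 1, "her" = 1, "from" = 1, "out" = 1,
  "up" = 1, "this" = 1, "they" = 1, "has" = 1, "for" = 1
)

disfluency_material <- function(code, prev_word) {
  switch(code,
         fill = sample(c("um", "er", "uh"), 1L),
         rep = if (nzchar(prev_word)) prev_word else "um",
         pause = "...",
         fs = "th-",
         gram = "is",
         unint = "xxx",
         neo = "flimb",
         "um")
}

#' Generate one annotated synthetic transcript
#'
#' Token count is negative-binomial; content words are sampled from the
#' lexicon with probability proportional to the softmax of the profile's
#' property tilts; planted words occur as independent Bernoulli draws with
#' their group's probability; function words are interleaved at the
#' profile rate; clause boundaries and exclusion-coded disfluency spans
#' are injected at the profile's per-gap rates; the duration is drawn from
#' the profile's distribution.
#'
#' @param profile One entry of [group_profiles()].
#' @param lexicon A `norms_lexicon` (background sampling pool).
#' @param seed Integer seed.
#' @param participant_id,group,picture Transcript metadata.
#' @param planted Optional [planted_word_design()] rows for this picture.
#' @return A `raw_transcript` with attribute `planted_included`.
#' @export
generate_transcript <- function(profile, lexicon, seed, participant_id,
                                group, picture,
                                planted = NULL) {
  lex <- as.data.frame(lexicon)
  background <- if (!is.null(planted)) {
    lex[!(lex$word %in% planted$word), , drop = FALSE]
  } else lex
  tilt_props <- names(profile$tilt)
  zb <- scale(as.matrix(background[, tilt_props, drop = FALSE]))
  wts <- exp(drop(zb %*% profile$tilt))
  with_seed(seed, {
    n_total <- max(5L, stats::rnbinom(1L, mu = profile$mean_tokens,
                                      size = profile$dispersion))
    n_fun <- round(n_total * profile$function_rate)
    n_con <- max(3L, n_total - n_fun)
    content <- sample(background$word, n_con, replace = TRUE, prob = wts)
    if (!is.null(planted) && !is.null(planted[[group]])) {
      p <- planted[[group]]
      hit <- stats::runif(nrow(planted)) < p
      for (w in planted$word[hit]) {
        pos <- sample.int(length(content) + 1L, 1L)
        content <- append(content, w, after = pos - 1L)
      }
      planted_included <- planted$word[hit]
    } else {
      planted_included <- character(0)
    }
    funs <- sample(names(FUNCTION_SAMPLER), n_fun, replace = TRUE,
                   prob = FUNCTION_SAMPLER)
    # interleave function and content words at random positions
    tokens <- character(length(content) + length(funs))
    fun_pos <- sort(sample.int(length(tokens), length(funs)))
    tokens[fun_pos] <- funs
    tokens[setdiff(seq_along(tokens), fun_pos)] <- content
    # clause boundaries and disfluency spans at inter-token gaps
    out <- character(0)
    prev <- ""
    for (i in seq_along(tokens)) {
      for (code in names(profile$disfluency)) {
        if (stats::runif(1L) < profile$disfluency[[code]]) {
          out <- c(out, paste0("{", code, " ",
                               disfluency_material(code, prev), "}"))
        }
      }
      if (i > 1L && stats::runif(1L) < 1 / 8) out <- c(out, "//")
      out <- c(out, tokens[i])
      prev <- tokens[i]
    }
    duration <- max(20, stats::rnorm(1L, profile$duration_mean,
                                     profile$duration_sd))
    raw <- raw_transcript(participant_id, group, picture, duration,
                          paste(out, collapse = " "))
    attr(raw, "planted_included") <- planted_included
    raw
  })
}

#' Generate a full synthetic cohort
#'
#' Group sizes default to a realistic progressive-aphasia study: 24
#' controls, 9 svPPA, 9 lvPPA, 9 nfvPPA, 10 PSP, 13 CBS, each describing
#' both pictures. Per-participant seeds are derived from the master seed,
#' so the cohort is fully reproducible from (parameters, seed). Ground
#' truth (planted words and their probabilities, tilts, volume means) is
#' attached for recovery tests.
#'
#' @param group_sizes Named integer vector over [speech_groups()].
#' @param seed Master seed.
#' @param n_words Background lexicon size (24 planted words are added).
#' @param profiles Group profiles (default [group_profiles()]).
#' @param lexicon Optional `norms_lexicon` from a previously generated
#'   cohort, so that an independent (e.g. second-site) cohort shares the
#'   same language: identical words, properties and planted-word slots.
#' @return A `synthetic_cohort`: `lexicon`, `transcripts` (raw, one per
#'   participant x picture), `manifest` (with durations and cognitive
#'   sub-scores), `cognitive`, `ground_truth`, `seed`.
#' @export
generate_cohort <- function(group_sizes = c(control = 24, svPPA = 9,
                                            lvPPA = 9, nfvPPA = 9,
                                            PSP = 10, CBS = 13),
                            seed = 1L, n_words = 500L,
                            profiles = group_profiles(), lexicon = NULL) {
  if (length(group_sizes) < 1L || is.null(names(group_sizes))) {
    stop_pre("group_sizes must be a named vector")
  }
  if (!all(names(group_sizes) %in% speech_groups())) {
    stop_pre("unknown group in group_sizes")
  }
  if (is.null(lexicon)) {
    lexicon <- generate_norms(n_words + 24L, derive_seed(seed, 1L))
  } else {
    stopifnot(inherits(lexicon, "norms_lexicon"))
    if (nrow(lexicon) < 32L) stop_pre("shared lexicon too small")
    n_words <- nrow(lexicon) - 24L  # last 24 entries are the planted slots
  }
  all_words <- as.data.frame(lexicon)$word
  planted <- list(
    cookie_theft = planted_word_design(all_words[seq(n_words + 1L,
                                                     n_words + 12L)]),
    beach_scene = planted_word_design(all_words[seq(n_words + 13L,
                                                    n_words + 24L)])
  )
  transcripts <- list()
  rows <- list()
  cog_rows <- list()
  pid <- 0L
  for (g in names(group_sizes)) {
    prof <- profiles[[g]]
    for (i in seq_len(group_sizes[[g]])) {
      pid <- pid + 1L
      id <- sprintf("%s_%02d", g, i)
      cogs <- with_seed(derive_seed(seed, 2L, pid), {
        stats::setNames(stats::rnorm(length(prof$cognitive),
                                     prof$cognitive, 1.4),
                        names(prof$cognitive))
      })
      cog_rows[[pid]] <- cbind(data.frame(participant_id = id, group = g,
                                          stringsAsFactors = FALSE),
                               as.data.frame(as.list(round(cogs, 1))))
      for (pic in speech_pictures()) {
        tr <- generate_transcript(prof, lexicon,
                                  derive_seed(seed, 3L, pid,
                                              match(pic, speech_pictures())),
                                  id, g, pic, planted = planted[[pic]])
        transcripts[[length(transcripts) + 1L]] <- tr
        rows[[length(rows) + 1L]] <-
          data.frame(participant_id = id, group = g, picture = pic,
                     duration_s = tr$duration_s, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  cognitive <- do.call(rbind, cog_rows)
  manifest <- merge(manifest, cognitive, by = c("participant_id", "group"),
                    sort = FALSE)
  manifest <- manifest[order(manifest$participant_id, manifest$picture), ]
  rownames(manifest) <- NULL
  ground_truth <- list(
    planted = planted,
    tilts = lapply(profiles[names(group_sizes)], `[[`, "tilt"),
    mean_tokens = vapply(profiles[names(group_sizes)], `[[`, 0,
                         "mean_tokens"),
    group_sizes = as.list(group_sizes)
  )
  structure(list(lexicon = lexicon, transcripts = transcripts,
                 manifest = manifest, cognitive = cognitive,
                 ground_truth = ground_truth, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cognitive), "participants,",
      length(x$transcripts), "transcripts,",
      nrow(x$lexicon), "lexicon entries (seed", x$seed, ")\n")
  print(table(x$cognitive$group))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one transcript file per participant x picture, a cohort manifest
#' CSV (with durations and cognitive sub-scores), the norms lexicon CSV
#' and a ground-truth JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  files <- character(length(cohort$transcripts))
  for (i in seq_along(cohort$transcripts)) {
    tr <- cohort$transcripts[[i]]
    files[i] <- file.path("transcripts",
                          paste0(tr$participant_id, "_", tr$picture, ".txt"))
    write_transcript(tr, file.path(dir, files[i]))
  }
  manifest <- cohort$manifest
  tkey <- vapply(cohort$transcripts,
                 function(t) paste(t$participant_id, t$picture), "")
  manifest$file <- files[match(paste(manifest$participant_id,
                                     manifest$picture), tkey)]
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  write_norms_lexicon(cohort$lexicon, file.path(dir, "norms.csv"))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
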
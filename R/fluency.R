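# The 13 speech-fluency measures per transcript: token/type counts for
# words, bigrams and trigrams, their type-to-token ratios, timing, the
# function/content proportion and the combination ratio.

# Bundled closed-class (function word) list: articles, demonstratives,
# prepositions, pronouns, auxiliaries and copulas, conjunctions, particles,
# quantifiers and wh-words. Overridable wherever a function list is taken.
FUNCTION_WORDS <- c(
  # articles / determiners / demonstratives
  "a", "an", "the", "this", "that", "these", "those", "some", "any", "no",
  "every", "each", "either", "neither", "both", "all", "few", "several",
  "many", "much", "more", "most", "less", "least", "other", "another",
  "such", "own", "same",
  # pronouns
  "i", "me", "my", "mine", "myself", "we", "us", "our", "ours", "ourselves",
  "you", "your", "yours", "yourself", "he", "him", "his", "himself", "she",
  "her", "hers", "herself", "it", "its", "itself", "they", "them", "their",
  "theirs", "themselves", "one", "ones", "someone", "somebody", "something",
  "anyone", "anybody", "anything", "everyone", "everybody", "everything",
  "nobody", "nothing", "who", "whom", "whose", "which", "what", "whatever",
  "whoever",
  # auxiliaries / copulas / modals (with common contractions)
  "am", "is", "are", "was", "were", "be", "been", "being", "do", "does",
  "did", "doing", "have", "has", "had", "having", "will", "would", "shall",
  "should", "can", "could", "may", "might", "must", "ought", "need",
  "i'm", "i've", "i'll", "i'd", "it's", "that's", "there's", "he's",
  "she's", "they're", "we're", "you're", "isn't", "aren't", "wasn't",
  "weren't", "don't", "doesn't", "didn't", "can't", "cannot", "couldn't",
  "won't", "wouldn't", "shouldn't", "hasn't", "haven't", "hadn't",
  # prepositions / particles
  "of", "in", "on", "at", "by", "for", "with", "without", "about", "against",
  "between", "among", "through", "during", "before", "after", "above",
  "below", "under", "over", "up", "down", "out", "off", "into", "onto",
  "from", "to", "towards", "toward", "near", "beside", "behind", "around",
  "across", "along", "past", "beyond", "inside", "outside", "within",
  "upon", "per",
  # conjunctions / complementizers
  "and", "or", "but", "nor", "so", "yet", "if", "then", "than", "because",
  "although", "though", "while", "whilst", "when", "whenever", "where",
  "wherever", "as", "since", "until", "unless", "whether", "that",
  # existential / negation / pro-adverbs
  "there", "here", "not", "n't", "also", "too", "very", "just", "only",
  "again", "well", "now", "how", "why"
)

#' Bundled closed-class function-word list
#'
#' Articles, demonstratives, prepositions, pronouns, auxiliaries,
#' conjunctions and particles. Pass `file` to override with one word per
#' line.
#' @param file Optional path to a plain-text word list (one per line).
#' @return Lower-cased character vector.
#' @export
function_words <- function(file = NULL) {
  if (is.null(file)) return(unique(FUNCTION_WORDS))
  w <- tolower(trimws(readLines(file, warn = FALSE)))
  unique(w[nzchar(w)])
}

#' n-gram token and type counts within runs
#'
#' n-grams never span run boundaries, so material separated by an excluded
#' disfluency or a clause boundary never forms an artefactual bigram or
#' trigram. A run of length L contributes `max(0, L - n + 1)` n-gram tokens.
#'
#' @param transcript A `clean_transcript`.
#' @param n n-gram order (1 = words).
#' @return List with `tokens` and `types` counts.
#' @export
ngram_counts <- function(transcript, n) {
  stopifnot(inherits(transcript, "clean_transcript"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_pre("n must be a positive integer")
  }
  n <- as.integer(n)
  grams <- unlist(lapply(transcript$runs, function(r) {
    L <- length(r)
    if (L < n) return(character(0))
    vapply(seq_len(L - n + 1L),
           function(i) paste(r[i:(i + n - 1L)], collapse = " "), "")
  }))
  if (is.null(grams)) grams <- character(0)
  list(tokens = length(grams), types = length(unique(grams)))
}

#' Speech rate in words per minute
#' @param word_tokens Retained word token count.
#' @param duration_s Description duration in seconds (> 0).
#' @export
words_per_minute <- function(word_tokens, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      is.na(duration_s) || duration_s <= 0) {
    stop_pre("duration_s must be positive")
  }
  word_tokens / (duration_s / 60)
}

#' Proportion of function relative to content words
#'
#' Function tokens divided by content tokens. A transcript with zero content
#' tokens has no defined proportion; `NA` is returned with a warning.
#' @param transcript A `clean_transcript`.
#' @param function_list Character vector of function words.
#' @export
function_content_proportion <- function(transcript,
                                        function_list = function_words()) {
  stopifnot(inherits(transcript, "clean_transcript"))
  if (length(function_list) == 0L) stop_pre("function_list must be non-empty")
  toks <- transcript_tokens(transcript)
  n_fun <- sum(toks %in% function_list)
  n_con <- length(toks) - n_fun
  if (n_con == 0L) {
    warning("no content tokens; function/content proportion undefined",
            call. = FALSE)
    return(NA_real_)
  }
  n_fun / n_con
}

#' The 13 speech-fluency measures for one transcript
#'
#' Assembles word/bigram/trigram token and type counts, the three
#' type-to-token ratios, total time, words per minute, the function/content
#' proportion and the combination ratio (trigram tokens / word tokens, an
#' index of connected multi-word output). Ratios whose denominator is zero
#' are returned as `NA`.
#'
#' @param transcript A `clean_transcript`.
#' @param function_list Function-word list for the function/content measure.
#' @return One-row data.frame with the 13 measures.
#' @export
fluency_profile <- function(transcript, function_list = function_words()) {
  stopifnot(inherits(transcript, "clean_transcript"))
  w <- ngram_counts(transcript, 1L)
  b <- ngram_counts(transcript, 2L)
  t3 <- ngram_counts(transcript, 3L)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  fcp <- if (w$tokens == 0L) NA_real_ else
    suppressWarnings(function_content_proportion(transcript, function_list))
  data.frame(
    word_tokens = w$tokens, word_types = w$types,
    bigram_tokens = b$tokens, bigram_types = b$types,
    trigram_tokens = t3$tokens, trigram_types = t3$types,
    ttr_word = ratio(w$types, w$tokens),
    ttr_bigram = ratio(b$types, b$tokens),
    ttr_trigram = ratio(t3$types, t3$tokens),
    total_time_s = transcript$duration_s,
    words_per_minute = words_per_minute(w$tokens, transcript$duration_s),
    function_content_proportion = fcp,
    combination_ratio = if (w$tokens > 0) t3$tokens / w$tokens else 0
  )
}

#' Fluency profiles for a whole cohort
#'
#' @param transcripts List of `raw_transcript` or `clean_transcript`
#'   objects (raw ones are parsed first).
#' @param function_list Function-word list.
#' @return Data.frame with `participant_id`, `group`, `picture` and the 13
#'   measures, one row per transcript ("wide" layout, the input to the
#'   fluency PCA). `fluency_long()` reshapes it to one row per measure.
#' @export
fluency_profiles <- function(transcripts, function_list = function_words()) {
  rows <- lapply(transcripts, function(tr) {
    if (inherits(tr, "raw_transcript")) tr <- parse_transcript(tr)
    cbind(data.frame(participant_id = tr$participant_id, group = tr$group,
                     picture = tr$picture, stringsAsFactors = FALSE),
          fluency_profile(tr, function_list))
  })
  do.call(rbind, rows)
}

#' @rdname fluency_profiles
#' @param profiles Output of [fluency_profiles()].
#' @export
fluency_long <- function(profiles) {
  measures <- setdiff(names(profiles), c("participant_id", "group", "picture"))
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(participant_id = profiles$participant_id,
               group = profiles$group, picture = profiles$picture,
               measure = m, value = profiles[[m]], stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
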
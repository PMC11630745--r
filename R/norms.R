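# Psycholinguistic norms: lexicon I/O, lookup with singular fallback for
# plurals, and annotation of content tokens (inputs to the word-properties
# PCA).

#' The eight psycholinguistic properties carried by a norms lexicon
#' @export
norm_properties <- function() {
  c("length", "log_frequency", "semantic_diversity",
    "semantic_neighbourhood_density", "concreteness", "age_of_acquisition",
    "old", "pld")
}

#' Build a norms lexicon from a data.frame
#'
#' @param df Data.frame with a `word` column and the eight property columns
#'   of [norm_properties()]; empty/NA cells mark missing ratings.
#' @param provenance Free-text description of the rating sources.
#' @return A `norms_lexicon`: data.frame keyed by lower-cased `word`.
#' @export
norms_lexicon <- function(df, provenance = "unspecified") {
  needed <- c("word", norm_properties())
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop_pre("lexicon lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, needed]
  df$word <- tolower(as.character(df$word))
  if (anyDuplicated(df$word)) {
    stop_pre("duplicate lexicon keys: ",
             paste(unique(df$word[duplicated(df$word)]), collapse = ", "))
  }
  for (p in norm_properties()) df[[p]] <- as.numeric(df[[p]])
  bad <- vapply(norm_properties(),
                function(p) any(is.infinite(df[[p]])), logical(1))
  if (any(bad)) stop_pre("non-finite ratings in: ",
                         paste(norm_properties()[bad], collapse = ", "))
  rownames(df) <- df$word
  structure(df, class = c("norms_lexicon", "data.frame"),
            provenance = provenance)
}

#' Read / write a norms lexicon CSV
#'
#' Schema: header `word,length,log_frequency,semantic_diversity,`
#' `semantic_neighbourhood_density,concreteness,age_of_acquisition,old,pld`;
#' an empty cell is a missing rating.
#' @param path CSV path.
#' @export
read_norms_lexicon <- function(path) {
  norms_lexicon(utils::read.csv(path, stringsAsFactors = FALSE),
                provenance = path)
}

#' @rdname read_norms_lexicon
#' @param lexicon A `norms_lexicon`.
#' @export
write_norms_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "norms_lexicon"))
  utils::write.csv(as.data.frame(lexicon)[, c("word", norm_properties())],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Singular candidates for a plural surface form, most specific rule first:
# -ies -> -y, then -es, then -s.
singular_candidates <- function(word) {
  cand <- character(0)
  if (grepl("ies$", word)) cand <- c(cand, sub("ies$", "y", word))
  if (grepl("es$", word)) cand <- c(cand, sub("es$", "", word))
  if (grepl("s$", word) && !grepl("ss$", word)) cand <- c(cand, sub("s$", "", word))
  unique(cand[nzchar(cand)])
}

#' Look up the norms of one word
#'
#' Exact (lower-cased) match preferred; if absent and the word looks plural
#' (`-s`/`-es`/`-ies`), the singular entry's norms are returned with the
#' `fallback` flag set, mirroring how ratings for pluralized words are
#' conventionally backed off to the singular. No match at all returns
#' `NULL`.
#'
#' @param lexicon A `norms_lexicon`.
#' @param word Lower-cased word.
#' @return One-row data.frame of norms with attribute `fallback`
#'   (`TRUE`/`FALSE`), or `NULL` when missing.
#' @export
norms_lookup <- function(lexicon, word) {
  stopifnot(inherits(lexicon, "norms_lexicon"))
  word <- tolower(word)
  if (word %in% rownames(lexicon)) {
    out <- lexicon[word, , drop = FALSE]
    attr(out, "fallback") <- FALSE
    return(out)
  }
  for (cand in singular_candidates(word)) {
    if (cand %in% rownames(lexicon)) {
      out <- lexicon[cand, , drop = FALSE]
      attr(out, "fallback") <- TRUE
      return(out)
    }
  }
  NULL
}

#' Annotate the content tokens of a transcript with their norms
#'
#' Function words are excluded first; every remaining *token* (not type) is
#' annotated, so that downstream participant averages weight each word by
#' how often it was produced. Tokens without norms even after the singular
#' fallback are dropped and counted in the coverage report.
#'
#' @param transcript A `clean_transcript`.
#' @param lexicon A `norms_lexicon`.
#' @param function_list Function-word list.
#' @return List with `annotations` (data.frame: `token`, `fallback`, the
#'   eight property columns) and `coverage`
#'   (`total`/`function_tokens`/`annotated`/`dropped` counts plus the
#'   dropped types).
#' @export
annotate_content_words <- function(transcript, lexicon,
                                   function_list = function_words()) {
  stopifnot(inherits(transcript, "clean_transcript"))
  toks <- transcript_tokens(transcript)
  is_fun <- toks %in% function_list
  content <- toks[!is_fun]
  rows <- vector("list", length(content))
  fallback <- logical(length(content))
  keep <- logical(length(content))
  dropped <- character(0)
  for (i in seq_along(content)) {
    hit <- norms_lookup(lexicon, content[i])
    if (is.null(hit)) {
      dropped <- c(dropped, content[i])
    } else {
      rows[[i]] <- hit
      fallback[i] <- attr(hit, "fallback")
      keep[i] <- TRUE
    }
  }
  ann <- if (any(keep)) {
    props <- do.call(rbind, lapply(rows[keep], as.data.frame))
    out <- cbind(data.frame(token = content[keep],
                            fallback = fallback[keep],
                            stringsAsFactors = FALSE),
                 props[, norm_properties()])
    rownames(out) <- NULL
    out
  } else {
    empty <- c(list(token = character(0), fallback = logical(0)),
               stats::setNames(rep(list(numeric(0)), length(norm_properties())),
                               norm_properties()))
    as.data.frame(empty, stringsAsFactors = FALSE)
  }
  list(annotations = ann,
       coverage = list(total = length(toks),
                       function_tokens = sum(is_fun),
                       annotated = sum(keep),
                       dropped = length(dropped),
                       dropped_types = sort(unique(dropped))))
}

#' Annotate a whole cohort's content tokens
#'
#' @param transcripts List of `raw_transcript`/`clean_transcript`.
#' @param lexicon A `norms_lexicon`.
#' @param function_list Function-word list.
#' @return List with `tokens` (long data.frame: `participant_id`, `group`,
#'   `picture`, `token`, `fallback` and the eight properties, one row per
#'   annotated content token) and `coverage` (per-transcript data.frame).
#' @export
annotate_cohort <- function(transcripts, lexicon,
                            function_list = function_words()) {
  tok_rows <- list()
  cov_rows <- list()
  for (tr in transcripts) {
    if (inherits(tr, "raw_transcript")) tr <- parse_transcript(tr)
    ann <- annotate_content_words(tr, lexicon, function_list)
    if (nrow(ann$annotations) > 0L) {
      tok_rows[[length(tok_rows) + 1L]] <-
        cbind(data.frame(participant_id = tr$participant_id, group = tr$group,
                         picture = tr$picture, stringsAsFactors = FALSE),
              ann$annotations)
    }
    cov <- ann$coverage
    cov_rows[[length(cov_rows) + 1L]] <-
      data.frame(participant_id = tr$participant_id, group = tr$group,
                 picture = tr$picture, total = cov$total,
                 function_tokens = cov$function_tokens,
                 annotated = cov$annotated, dropped = cov$dropped,
                 stringsAsFactors = FALSE)
  }
  tokens <- if (length(tok_rows) > 0L) do.call(rbind, tok_rows) else NULL
  list(tokens = tokens, coverage = do.call(rbind, cov_rows))
}
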
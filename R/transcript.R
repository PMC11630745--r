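# Transcript parsing: the annotated-transcript dialect, disfluency
# exclusion, tokenization, file I/O and transcription agreement.

#' Diagnostic groups and picture stimuli recognised by the pipeline
#' @export
speech_groups <- function() c("control", "svPPA", "lvPPA", "nfvPPA", "PSP", "CBS")

#' @rdname speech_groups
#' @export
speech_pictures <- function() c("cookie_theft", "beach_scene")

# Exclusion codes of the markup dialect. Spans written `{code material}` are
# removed from analysis; `//` (clause boundary) and `%%` (prosodic mark)
# retain no material but break token runs so n-grams never bridge them.
EXCLUSION_CODES <- c(
  fs    = "false_start",
  gram  = "grammatical_error",
  fill  = "filler",
  pause = "pause",
  rep   = "repetition",
  unint = "unintelligible",
  neo   = "neologism"
)
BOUNDARY_MARKS <- c("//" = "clause_boundary", "%%" = "prosodic")

#' Construct a raw (annotated) transcript
#'
#' A raw transcript is one participant's description of one picture, in the
#' markup dialect: excluded false speech is wrapped in `{code material}`
#' spans with `code` one of `fs` (false start), `gram` (grammatical error),
#' `fill` (filler), `pause`, `rep` (repetition), `unint` (unintelligible),
#' `neo` (neologism); clause boundaries are written `//` and prosodic marks
#' `%%`.
#'
#' @param participant_id Participant identifier.
#' @param group One of [speech_groups()].
#' @param picture One of [speech_pictures()].
#' @param duration_s Total speaking time in seconds (must be positive).
#' @param text Annotated transcript body.
#' @return An object of class `raw_transcript`.
#' @export
raw_transcript <- function(participant_id, group, picture, duration_s, text) {
  group <- match.arg(group, speech_groups())
  picture <- match.arg(picture, speech_pictures())
  if (!is.numeric(duration_s) || length(duration_s) != 1L || is.na(duration_s) ||
      duration_s <= 0) {
    stop_pre("duration_s must be a single positive number")
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         picture = picture, duration_s = as.numeric(duration_s),
         text = as.character(text)),
    class = "raw_transcript"
  )
}

# Lower-case a token and strip leading/trailing non-alphanumeric characters.
# Internal apostrophes and hyphens survive ("it's", "half-dried"); an empty
# result drops the token.
normalize_token <- function(tok) {
  tok <- tolower(tok)
  tok <- sub("^[^[:alnum:]]+", "", tok)
  tok <- sub("[^[:alnum:]]+$", "", tok)
  tok
}

#' Parse an annotated transcript into retained token runs
#'
#' Removes all material inside exclusion-coded `{...}` spans, splits token
#' runs at every exclusion span and at `//`/`%%` boundary marks, lower-cases
#' tokens and strips terminal punctuation. A run is a maximal span of
#' retained tokens uninterrupted by any exclusion or boundary mark, and is
#' the unit within which n-grams are later counted.
#'
#' @param raw A [raw_transcript()].
#' @return An object of class `clean_transcript` with fields
#'   `participant_id`, `group`, `picture`, `duration_s` and `runs` (a list
#'   of character vectors).
#' @examples
#' r <- raw_transcript("p1", "control", "cookie_theft", 60,
#'                     "the {fill um} mother is {rep is} drying")
#' parse_transcript(r)$runs
#' @export
parse_transcript <- function(raw) {
  stopifnot(inherits(raw, "raw_transcript"))
  text <- raw$text
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  segments <- character(0)  # plain-text segments between exclusion spans
  buf <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "}") {
      stop_pre("unbalanced '}' at byte ", i, " in transcript ",
               raw$participant_id)
    }
    if (ch == "{") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "{") stop_pre("nested '{' at byte ", j,
                                      " in transcript ", raw$participant_id)
        if (chars[j] == "}") { close <- j; break }
        j <- j + 1L
      }
      if (is.na(close)) {
        stop_pre("unbalanced '{' at byte ", i, " in transcript ",
                 raw$participant_id)
      }
      span <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      code <- strsplit(trimws(span), "[[:space:]]+")[[1]][1]
      if (is.na(code) || !(code %in% names(EXCLUSION_CODES))) {
        stop_pre("unknown exclusion code '", if (is.na(code)) "" else code,
                 "' at byte ", i, " in transcript ", raw$participant_id)
      }
      segments <- c(segments, paste(buf, collapse = ""), "")
      buf <- character(0)
      i <- close + 1L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  segments <- c(segments, paste(buf, collapse = ""))

  # Tokenize plain segments; exclusion spans () and boundary marks
  # both terminate the current run.
  runs <- list()
  current <- character(0)
  flush <- function() {
    if (length(current) > 0L) runs[[length(runs) + 1L]] <<- current
    current <<- character(0)
  }
  for (seg in segments) {
    if (seg == "") { flush(); next }
    toks <- strsplit(trimws(seg), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    for (tok in toks) {
      if (tok %in% names(BOUNDARY_MARKS)) { flush(); next }
      w <- normalize_token(tok)
      if (nzchar(w)) current <- c(current, w)
    }
  }
  flush()

  structure(
    list(participant_id = raw$participant_id, group = raw$group,
         picture = raw$picture, duration_s = raw$duration_s, runs = runs),
    class = "clean_transcript"
  )
}

#' Retained tokens of a clean transcript, in order
#' @param transcript A `clean_transcript`.
#' @export
transcript_tokens <- function(transcript) {
  stopifnot(inherits(transcript, "clean_transcript"))
  as.character(unlist(transcript$runs))
}

#' Serialize a clean transcript back to dialect text
#'
#' Runs are joined with clause-boundary marks, so re-parsing the serialized
#' text reproduces the runs exactly.
#' @param transcript A `clean_transcript`.
#' @export
serialize_transcript <- function(transcript) {
  stopifnot(inherits(transcript, "clean_transcript"))
  paste(vapply(transcript$runs, paste, "", collapse = " "), collapse = " // ")
}

#' Read / write a transcript file
#'
#' UTF-8 text with header lines `#id:`, `#group:`, `#picture:`,
#' `#duration_s:` followed by the annotated body. Reader and writer
#' round-trip the body byte-exactly.
#' @param path File path.
#' @export
read_transcript <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- function(key) {
    m <- grep(paste0("^#", key, ":"), lines)
    if (length(m) == 0L) stop_pre("missing header '#", key, ":' in ", path)
    trimws(sub(paste0("^#", key, ":"), "", lines[m[1]]))
  }
  body_start <- max(grep("^#", lines[seq_len(min(8, length(lines)))]),
                    0L) + 1L
  body <- if (body_start > length(lines)) "" else
    paste(lines[body_start:length(lines)], collapse = "\n")
  raw_transcript(hdr("id"), hdr("group"), hdr("picture"),
                 as.numeric(hdr("duration_s")), body)
}

#' @rdname read_transcript
#' @param raw A [raw_transcript()] to write.
#' @export
write_transcript <- function(raw, path) {
  stopifnot(inherits(raw, "raw_transcript"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("#id: ", raw$participant_id),
               paste0("#group: ", raw$group),
               paste0("#picture: ", raw$picture),
               paste0("#duration_s: ", format(raw$duration_s, digits = 15)),
               raw$text),
             con, useBytes = TRUE)
  invisible(path)
}

# Longest-common-subsequence length between two token vectors.
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    match_i <- a[i] == b
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Transcription per-cent agreement between two transcripts
#'
#' Positional word matching under a longest-common-subsequence alignment:
#' the number of aligned matching words divided by the total words of the
#' *reference* transcript (the denominator is deliberately asymmetric, as in
#' standard transcription-reliability practice). When `word_list` is given,
#' agreement restricted to those words is also reported: both token
#' sequences are filtered to the list before alignment and the denominator
#' is the reference's filtered count.
#'
#' @param reference,other `clean_transcript`s of the same participant and
#'   picture.
#' @param word_list Optional character vector restricting the comparison
#'   (e.g. the 15-word checklist).
#' @return List with `overall` and (if requested) `restricted` proportions.
#' @export
percent_agreement <- function(reference, other, word_list = NULL) {
  stopifnot(inherits(reference, "clean_transcript"),
            inherits(other, "clean_transcript"))
  if (!identical(reference$participant_id, other$participant_id) ||
      !identical(reference$picture, other$picture)) {
    stop_pre("agreement requires the same participant and picture")
  }
  a <- transcript_tokens(reference)
  b <- transcript_tokens(other)
  if (length(a) == 0L) stop_pre("reference transcript has zero words; agreement undefined")
  out <- list(overall = lcs_length(a, b) / length(a))
  if (!is.null(word_list)) {
    word_list <- tolower(word_list)
    ar <- a[a %in% word_list]
    br <- b[b %in% word_list]
    out$restricted <- if (length(ar) == 0L) NA_real_ else lcs_length(ar, br) / length(ar)
  }
  out
}

#' Read a cohort manifest and its transcripts
#'
#' The manifest is a CSV with columns `participant_id`, `group`, `picture`,
#' `file` (path relative to the manifest) plus any cognitive sub-score
#' columns.
#'
#' @param path Manifest CSV path.
#' @return List with `manifest` (data.frame) and `transcripts` (list of
#'   `raw_transcript`s in manifest order).
#' @export
read_cohort <- function(path) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "group", "picture", "file")
  missing <- setdiff(needed, names(manifest))
  if (length(missing) > 0L) {
    stop_pre("manifest lacks column(s): ", paste(missing, collapse = ", "))
  }
  base <- dirname(path)
  transcripts <- lapply(seq_len(nrow(manifest)), function(i) {
    read_transcript(file.path(base, manifest$file[i]))
  })
  list(manifest = manifest, transcripts = transcripts)
}
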
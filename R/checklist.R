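# Derivation and validation of picture-specific diagnostic word checklists:
# indicator coding with equivalence classes, pairwise L1-penalized
# selection, pooling, three-criterion rank ordering, top-15 truncation,
# hierarchical k-fold / out-of-sample validation and cognitive-score
# supplementation.

#' Strip one inflectional suffix from a word (root form)
#'
#' Rules, first match wins: plural (`-ies` -> `-y`; `-es` after a sibilant;
#' `-s`), then verbal `-ing` / `-ed` / `-en`, undoing consonant doubling
#' afterwards for letters that double under suffixation (so "digging" ->
#' "dig" but "falling" -> "fall"). A light inflectional stemmer is all the
#' scoring needs: explicit variant lists cover irregular forms
#' (stealing/stolen) and anything the stemmer misses.
#'
#' @param word Lower-cased word.
#' @return Root form.
#' @export
word_root <- function(word) {
  w <- word
  if (grepl("ies$", w) && nchar(w) > 4L) return(sub("ies$", "y", w))
  if (grepl("(ss|x|z|ch|sh)es$", w)) return(sub("es$", "", w))
  if (grepl("s$", w) && !grepl("ss$", w) && nchar(w) > 3L) {
    return(sub("s$", "", w))
  }
  undouble <- function(v) {
    last <- substr(v, nchar(v) - 1L, nchar(v))
    if (nchar(v) >= 3L &&
        substr(last, 1, 1) == substr(last, 2, 2) &&
        substr(last, 1, 1) %in% c("b", "d", "g", "m", "n", "p", "r", "t")) {
      substr(v, 1L, nchar(v) - 1L)
    } else v
  }
  for (suf in c("ing", "ed", "en")) {
    if (grepl(paste0(suf, "$"), w) && nchar(w) > nchar(suf) + 2L) {
      return(undouble(sub(paste0(suf, "$"), "", w)))
    }
  }
  w
}

#' An equivalence class of checklist-scorable word forms
#'
#' A canonical target word plus dialect synonyms; any token whose root
#' matches the target's root (or any variant, or a variant's root) scores
#' the class as produced. Example: target "boy" with variants
#' c("chap", "lad", "bloke").
#'
#' @param target Canonical word.
#' @param variants Character vector of dialect synonyms (the target itself
#'   is always a member).
#' @export
equivalence_class <- function(target, variants = character(0)) {
  target <- tolower(target)
  variants <- unique(c(target, tolower(variants)))
  structure(list(target = target, variants = variants,
                 roots = unique(vapply(variants, word_root, ""))),
            class = "equivalence_class")
}

#' Score one equivalence class against produced tokens
#'
#' @param tokens Lower-cased produced tokens.
#' @param class An [equivalence_class()].
#' @return 1L if any token matches (exact variant or root match), else 0L.
#' @export
score_word <- function(tokens, class) {
  stopifnot(inherits(class, "equivalence_class"))
  if (length(tokens) == 0L) return(0L)
  if (any(tokens %in% class$variants)) return(1L)
  roots <- vapply(unique(tokens), word_root, "")
  as.integer(any(roots %in% class$roots))
}

#' Indicator matrix of word production for one picture
#'
#' Entry (i, j) = 1 iff participant i produced any form of equivalence
#' class j.
#'
#' @param transcripts List of `clean_transcript`s, all of the same picture,
#'   one per participant.
#' @param classes List of [equivalence_class()]es (column order preserved).
#' @return Binary matrix, rows named by participant, columns by class
#'   target.
#' @export
build_indicator_matrix <- function(transcripts, classes) {
  transcripts <- lapply(transcripts, function(tr) {
    if (inherits(tr, "raw_transcript")) parse_transcript(tr) else tr
  })
  pics <- unique(vapply(transcripts, `[[`, "", "picture"))
  if (length(pics) != 1L) stop_pre("all transcripts must share one picture")
  ids <- vapply(transcripts, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) {
    stop_pre("duplicate participant for picture ", pics, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  targets <- vapply(classes, `[[`, "", "target")
  if (anyDuplicated(targets)) stop_pre("duplicate class targets")
  m <- matrix(0L, length(transcripts), length(classes),
              dimnames = list(ids, targets))
  # precompute each participant's token and root sets once (equivalent to
  # score_word per cell, but not quadratic in stemming work)
  tok_sets <- lapply(transcripts, function(tr) {
    toks <- unique(transcript_tokens(tr))
    list(tokens = toks, roots = unique(vapply(toks, word_root, "")))
  })
  for (j in seq_along(classes)) {
    cl <- classes[[j]]
    for (i in seq_along(transcripts)) {
      ts <- tok_sets[[i]]
      m[i, j] <- as.integer(any(ts$tokens %in% cl$variants) ||
                              any(ts$roots %in% cl$roots))
    }
  }
  attr(m, "picture") <- pics
  m
}

#' Group all unique content words of a picture into root classes
#'
#' Unique content words are merged by shared root (so plural and tense
#' variants of one word form one indicator column); the most frequent
#' surface form (ties alphabetical) names the class.
#'
#' @param transcripts `clean_transcript`s of one picture.
#' @param function_list Function words to exclude.
#' @return List of [equivalence_class()]es, alphabetical by target.
#' @export
unique_word_classes <- function(transcripts, function_list = function_words()) {
  toks <- unlist(lapply(transcripts, function(tr) {
    if (inherits(tr, "raw_transcript")) tr <- parse_transcript(tr)
    transcript_tokens(tr)
  }))
  toks <- toks[!(toks %in% function_list)]
  if (length(toks) == 0L) return(list())
  freq <- table(toks)
  words <- names(freq)
  roots <- vapply(words, word_root, "")
  classes <- lapply(split(seq_along(words), roots), function(idx) {
    surface <- words[idx]
    counts <- as.integer(freq[surface])
    target <- surface[order(-counts, surface)][1]
    equivalence_class(target, surface)
  })
  classes <- classes[order(vapply(classes, `[[`, "", "target"))]
  names(classes) <- vapply(classes, `[[`, "", "target")
  classes
}

# All 15 unordered group pairs for 6 groups (5 control-vs-patient + 10
# patient-vs-patient), in deterministic order.
group_pairs <- function(groups) {
  lv <- if (is.factor(groups)) levels(droplevels(groups)) else
    unique(as.character(groups))
  ord <- intersect(speech_groups(), lv)
  ord <- c(ord, setdiff(lv, ord))
  utils::combn(ord, 2L, simplify = FALSE)
}

#' Pairwise L1-penalized word selection over all group contrasts
#'
#' Fits one cross-validated L1-penalized logistic regression per group
#' pair (all unique words of the picture as predictors) and pools the
#' union of nonzero-coefficient words. Contrasts selecting zero words are
#' recorded: with six groups there are 15 contrasts, and clinically
#' similar pairs can genuinely yield none.
#'
#' @param x Binary indicator matrix over all unique word classes.
#' @param groups Group label per row.
#' @param cv_folds CV folds per fit (reduced with a warning for groups
#'   with < `cv_folds` members).
#' @param seed Master seed; each contrast derives its own fold seed.
#' @return List: `pooled` (sorted union of selected words), `per_contrast`
#'   (named list of selected-word vectors), `zero_word_contrasts`, `fits`.
#' @export
pairwise_selection <- function(x, groups, cv_folds = 4L, seed = 1L) {
  groups <- as.character(groups)
  pairs <- group_pairs(groups)
  if (length(pairs) < 1L) stop_pre("need at least two groups")
  per <- list()
  fits <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    idx <- which(groups %in% pr)
    y <- factor(groups[idx], levels = pr)
    nm <- paste(pr, collapse = "_vs_")
    fit <- fit_lasso_logistic(x[idx, , drop = FALSE], y, cv_folds = cv_folds,
                              seed = derive_seed(seed, pi))
    per[[nm]] <- fit$selected
    fits[[nm]] <- fit
  }
  pooled <- sort(unique(unlist(per)))
  list(pooled = pooled, per_contrast = per,
       zero_word_contrasts = names(per)[vapply(per, length, 1L) == 0L],
       fits = fits)
}

#' Between-group difference in production proportion of one word
#'
#' `|mean(indicator | group A) - mean(indicator | group B)|`: 1 when every
#' member of one group produced the word and no member of the other did.
#'
#' @param column Binary indicator column.
#' @param groups Group label per row.
#' @param a,b The two group labels.
#' @export
proportion_difference <- function(column, groups, a, b) {
  groups <- as.character(groups)
  ia <- groups == a
  ib <- groups == b
  if (!any(ia) || !any(ib)) stop_pre("both groups must be non-empty")
  abs(mean(column[ia]) - mean(column[ib]))
}

# Lexicographic rank ordering of a word table: appearance count desc,
# max |beta| desc, proportion difference desc, word alphabetical.
rank_order <- function(tab) {
  order(-tab$appearance_count, -tab$max_abs_beta,
        -tab$proportion_difference, tab$word)
}

#' Re-run pairwise fits on the pooled words and rank order them
#'
#' Words surviving the first pairwise screen are refit per contrast on the
#' truncated predictor set, then rank ordered lexicographically by (i) the
#' number of pairwise contrasts in which they are selected (descending),
#' (ii) their maximum |beta| across contrasts (descending), (iii) the
#' maximum between-group production-proportion difference (descending),
#' with an alphabetical final tie-break. The top `top_n` words form the
#' checklist.
#'
#' @param x Indicator matrix over all unique word classes.
#' @param groups Group label per row.
#' @param pooled Pooled word set from [pairwise_selection()].
#' @param classes The full class list (to attach variants to the
#'   checklist).
#' @param top_n Checklist size (default 15).
#' @param cv_folds,seed As in [pairwise_selection()].
#' @return List: `table` (ranked word table), `checklist` (a `checklist`
#'   object with <= `top_n` classes), `rerun` (the second-pass fits).
#' @export
rank_and_truncate <- function(x, groups, pooled, classes = NULL,
                              top_n = 15L, cv_folds = 4L, seed = 1L) {
  if (length(pooled) == 0L) {
    warning("pooled word set is empty; returning empty checklist",
            call. = FALSE)
    return(list(table = NULL,
                checklist = structure(list(picture = attr(x, "picture"),
                                           classes = list(), table = NULL),
                                      class = "checklist"),
                rerun = NULL))
  }
  xr <- x[, pooled, drop = FALSE]
  rerun <- pairwise_selection(xr, groups, cv_folds = cv_folds,
                              seed = derive_seed(seed, 104729L))
  groups_chr <- as.character(groups)
  pairs <- group_pairs(groups_chr)
  appearance <- stats::setNames(integer(length(pooled)), pooled)
  max_beta <- stats::setNames(numeric(length(pooled)), pooled)
  for (fit in rerun$fits) {
    nz <- fit$selected
    appearance[nz] <- appearance[nz] + 1L
    ab <- abs(fit$beta[pooled])
    max_beta <- pmax(max_beta, ifelse(is.na(ab), 0, ab))
  }
  prop_diff <- vapply(pooled, function(w) {
    max(vapply(pairs, function(pr)
      proportion_difference(xr[, w], groups_chr, pr[1], pr[2]), 0))
  }, 0)
  tab <- data.frame(word = pooled, appearance_count = as.integer(appearance),
                    max_abs_beta = max_beta, proportion_difference = prop_diff,
                    stringsAsFactors = FALSE)
  tab <- tab[rank_order(tab), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  top <- utils::head(tab$word, top_n)
  if (length(top) < top_n) {
    message("checklist has only ", length(top), " words (pool smaller than ",
            top_n, ")")
  }
  cls <- if (is.null(classes)) {
    lapply(top, equivalence_class)
  } else {
    classes[top]
  }
  names(cls) <- top
  list(table = tab,
       checklist = structure(list(picture = attr(x, "picture"),
                                  classes = cls,
                                  table = tab[tab$word %in% top, ]),
                             class = "checklist"),
       rerun = rerun)
}

#' @export
print.checklist <- function(x, ...) {
  cat("Word checklist (", x$picture %||% "?", "): ",
      length(x$classes), " targets\n", sep = "")
  for (cl in x$classes) {
    extra <- setdiff(cl$variants, cl$target)
    cat(" -", cl$target,
        if (length(extra) > 0L) paste0("(", paste(extra, collapse = ", "), ")"),
        "\n")
  }
  invisible(x)
}

#' Derive a picture's checklist end to end
#'
#' Convenience wrapper: unique word classes -> indicator matrix -> pairwise
#' selection -> pooled rerun -> ranked top-15 checklist.
#'
#' @param transcripts `clean_transcript`s of one picture (one per
#'   participant).
#' @param groups Group label per transcript.
#' @param function_list,top_n,cv_folds,seed Passed through.
#' @return List: `checklist`, `table`, `selection`, `indicators`,
#'   `classes`.
#' @export
derive_checklist <- function(transcripts, groups,
                             function_list = function_words(),
                             top_n = 15L, cv_folds = 4L, seed = 1L) {
  classes <- unique_word_classes(transcripts, function_list)
  x <- build_indicator_matrix(transcripts, classes)
  sel <- pairwise_selection(x, groups, cv_folds = cv_folds, seed = seed)
  rk <- rank_and_truncate(x, groups, sel$pooled, classes = classes,
                          top_n = top_n, cv_folds = cv_folds, seed = seed)
  list(checklist = rk$checklist, table = rk$table, selection = sel,
       indicators = x, classes = classes)
}

confusion_report <- function(truth, pred, positive, contrast, scheme) {
  tp <- sum(truth == 1L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  fp <- sum(truth == 0L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  structure(
    list(contrast = contrast, scheme = scheme, positive = positive,
         confusion = matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                            dimnames = list(c("true_pos", "true_neg"),
                                            c("pred_pos", "pred_neg"))),
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         n = tp + tn + fp + fn),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(x$contrast, " [", x$scheme, "]: accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy),
      ", sensitivity ", sprintf("%.2f", x$sensitivity),
      ", specificity ", sprintf("%.2f", x$specificity),
      " (n=", x$n, ")\n", sep = "")
  invisible(x)
}

#' Validate a fixed checklist on one binary contrast
#'
#' `scheme = "kfold"`: stratified k-fold cross-validation in which the
#' checklist columns are fixed and only the penalized-logistic
#' coefficients are re-estimated per training fold (the fixed-checklist
#' use case); the held-out rows are classified at threshold 0.5 and pooled
#' into one confusion matrix. `scheme = "oos"`: the model is fit once on
#' all training rows and evaluated on a disjoint test cohort.
#'
#' @param x Indicator matrix restricted to the checklist words (training
#'   rows), optionally with z-scored cognitive columns appended.
#' @param y Binary outcome; the *second* factor level (or 1) is the
#'   positive class.
#' @param scheme `"kfold"` or `"oos"`.
#' @param k Folds for `"kfold"` (default 4).
#' @param seed Fold/fit seed.
#' @param x_test,y_test Test cohort for `"oos"`.
#' @param contrast Free-text contrast name for the report.
#' @return A `validation_report` (confusion matrix, accuracy, sensitivity,
#'   specificity) with per-row predictions in `attr(,"predictions")`.
#' @export
validate_checklist <- function(x, y, scheme = c("kfold", "oos"), k = 4L,
                               seed = 1L, x_test = NULL, y_test = NULL,
                               contrast = "contrast") {
  scheme <- match.arg(scheme)
  yf <- factor(y)
  if (nlevels(yf) != 2L) stop_pre("y must have exactly two classes")
  yi <- as.integer(yf) - 1L
  positive <- levels(yf)[2]
  x <- as.matrix(x)
  if (scheme == "kfold") {
    if (min(table(yi)) < 3L) {
      stop_pre("k-fold validation needs at least 3 members per class ",
               "(contrast ", contrast, ")")
    }
    folds <- make_stratified_folds(yi, k, derive_seed(seed, 7L))
    pred <- integer(length(yi))
    prob <- numeric(length(yi))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- fit_lasso_logistic(x[tr, , drop = FALSE], yi[tr], cv_folds = k,
                                seed = derive_seed(seed, 11L, f))
      prob[!tr] <- predict(fit, x[!tr, , drop = FALSE], type = "response")
      pred[!tr] <- as.integer(prob[!tr] > 0.5)
    }
    rep <- confusion_report(yi, pred, positive, contrast, "kfold")
    attr(rep, "predictions") <- data.frame(row = rownames(x) %||%
                                             seq_along(yi),
                                           truth = yi, prob = prob,
                                           pred = pred)
    rep
  } else {
    if (is.null(x_test) || is.null(y_test)) {
      stop_pre("out-of-sample validation needs x_test and y_test")
    }
    shared <- intersect(rownames(x) %||% character(0),
                        rownames(as.matrix(x_test)) %||% character(0))
    if (length(shared) > 0L) {
      stop_pre("test cohort shares participants with training: ",
               paste(shared, collapse = ", "))
    }
    yt <- factor(y_test, levels = levels(yf))
    if (anyNA(yt)) stop_pre("y_test has labels outside the training classes")
    fit <- fit_lasso_logistic(x, yi, cv_folds = k, seed = derive_seed(seed, 13L))
    xt <- as.matrix(x_test)[, names(fit$beta), drop = FALSE]
    prob <- predict(fit, xt, type = "response")
    pred <- as.integer(prob > 0.5)
    yti <- as.integer(yt) - 1L
    rep <- confusion_report(yti, pred, positive, contrast, "oos")
    attr(rep, "predictions") <- data.frame(row = rownames(xt) %||%
                                             seq_along(yti),
                                           truth = yti, prob = prob,
                                           pred = pred)
    attr(rep, "fit") <- fit
    rep
  }
}

# Binary labels for one hierarchical stage; returns NULL when a side is
# absent. Positive class is the second element of `sides`.
stage_labels <- function(groups, sides) {
  groups <- as.character(groups)
  lab <- rep(NA_character_, length(groups))
  for (s in names(sides)) lab[groups %in% sides[[s]]] <- s
  if (length(unique(stats::na.omit(lab))) < 2L) return(NULL)
  factor(lab, levels = names(sides))
}

#' Hierarchical checklist validation
#'
#' Mirrors the clinical decision sequence: stage 1 separates patients from
#' controls; stage 2 splits patients into the motor cluster (nfvPPA, PSP,
#' CBS) versus the lexico-semantic cluster (svPPA, lvPPA); stage 3
#' discriminates within cluster (svPPA vs lvPPA; nfvPPA vs PSP+CBS, with
#' PSP and CBS merged into one class as sample sizes dictate).
#'
#' @param x Training indicator matrix over checklist words (+ optional
#'   cognitive columns).
#' @param groups Training group labels.
#' @param scheme `"kfold"` or `"oos"`.
#' @param k,seed Passed to [validate_checklist()].
#' @param x_test,groups_test Test cohort for `"oos"`.
#' @param merge_psp_cbs Merge PSP and CBS into one stage-3 class
#'   (default TRUE).
#' @return Named list of `validation_report`s (stages whose classes are
#'   absent from the data are skipped).
#' @export
hierarchical_validate <- function(x, groups, scheme = c("kfold", "oos"),
                                  k = 4L, seed = 1L, x_test = NULL,
                                  groups_test = NULL, merge_psp_cbs = TRUE) {
  scheme <- match.arg(scheme)
  patients <- setdiff(speech_groups(), "control")
  motor <- c("nfvPPA", "PSP", "CBS")
  lexsem <- c("svPPA", "lvPPA")
  stages <- list(
    patients_vs_controls = list(control = "control", patient = patients),
    motor_vs_lexicosemantic = list(lexicosemantic = lexsem, motor = motor),
    svPPA_vs_lvPPA = list(svPPA = "svPPA", lvPPA = "lvPPA")
  )
  stages$nfvPPA_vs_PSP_CBS <- if (merge_psp_cbs) {
    list(nfvPPA = "nfvPPA", PSP_CBS = c("PSP", "CBS"))
  } else {
    list(nfvPPA = "nfvPPA", PSP = "PSP")
  }
  out <- list()
  for (nm in names(stages)) {
    y <- stage_labels(groups, stages[[nm]])
    if (is.null(y)) next
    idx <- !is.na(y)
    if (scheme == "kfold" && min(table(y[idx])) < 3L) {
      warning("skipping ", nm, ": a class has fewer than 3 members",
              call. = FALSE)
      next
    }
    if (scheme == "kfold") {
      out[[nm]] <- validate_checklist(x[idx, , drop = FALSE], y[idx],
                                      scheme = "kfold", k = k,
                                      seed = derive_seed(seed, match(nm, names(stages))),
                                      contrast = nm)
    } else {
      if (is.null(x_test) || is.null(groups_test)) {
        stop_pre("out-of-sample validation needs x_test and groups_test")
      }
      yt <- stage_labels(groups_test, stages[[nm]])
      if (is.null(yt)) next
      it <- !is.na(yt)
      out[[nm]] <- validate_checklist(x[idx, , drop = FALSE], y[idx],
                                      scheme = "oos", k = k,
                                      seed = derive_seed(seed, match(nm, names(stages))),
                                      x_test = x_test[it, , drop = FALSE],
                                      y_test = yt[it], contrast = nm)
    }
  }
  out
}

#' Append z-scored cognitive sub-scores to an indicator matrix
#'
#' Continuous columns are z-scored (binary word indicators stay on their
#' 0/1 scale); all-missing or constant score columns are dropped with a
#' warning, and rows with incomplete retained scores are dropped and
#' recorded in `attr(,"dropped_rows")`.
#'
#' @param x Binary indicator matrix.
#' @param scores Data.frame/matrix of cognitive sub-scores, same rows.
#' @return Augmented numeric matrix.
#' @export
augment_with_cognitive <- function(x, scores) {
  x <- as.matrix(x)
  scores <- as.data.frame(scores)
  if (nrow(scores) != nrow(x)) stop_pre("scores must have one row per participant")
  keep <- vapply(scores, function(col) {
    col <- as.numeric(col)
    !all(is.na(col)) && stats::sd(col, na.rm = TRUE) > 0
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant/all-missing score column(s): ",
            paste(names(scores)[!keep], collapse = ", "), call. = FALSE)
  }
  scores <- scores[, keep, drop = FALSE]
  if (ncol(scores) == 0L) return(x)
  complete <- stats::complete.cases(scores)
  z <- scale(as.matrix(scores[complete, , drop = FALSE]))
  out <- cbind(x[complete, , drop = FALSE], z)
  attr(out, "dropped_rows") <- rownames(x)[!complete] %||% which(!complete)
  out
}

#' Write a checklist scoresheet CSV
#'
#' Columns: `picture,target,variants` (|-separated), plus one
#' `beta_<contrast>` column per fitted pairwise contrast when a selection
#' result is supplied.
#' @param checklist A `checklist`.
#' @param path Output CSV path.
#' @param rerun Optional second-pass [pairwise_selection()] result whose
#'   coefficients are included.
#' @export
write_checklist <- function(checklist, path, rerun = NULL) {
  stopifnot(inherits(checklist, "checklist"))
  df <- data.frame(
    picture = checklist$picture %||% "",
    target = vapply(checklist$classes, `[[`, "", "target"),
    variants = vapply(checklist$classes, function(cl)
      paste(cl$variants, collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(rerun)) {
    for (nm in names(rerun$fits)) {
      b <- rerun$fits[[nm]]$beta[df$target]
      df[[paste0("beta_", nm)]] <- ifelse(is.na(b), 0, b)
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
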
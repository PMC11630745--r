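# Varimax-rotated PCA on the correlation matrix, with Kaiser-Meyer-Olkin
# sampling adequacy, scree-based component selection, projection of new
# rows, and per-participant averaging of word scores.

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the sum of squared off-diagonal correlations divided by that
#' sum plus the sum of squared off-diagonal partial correlations (computed
#' from the inverse correlation matrix). Values near 1 indicate compact
#' correlation structure suitable for factoring; in the two-variable case
#' the partial correlation equals the correlation, so KMO is exactly 0.5
#' for any nonzero r.
#'
#' @param x Numeric matrix or data.frame (rows = observations), at least
#'   two columns and more rows than columns.
#' @param pseudo_inverse Use a Moore-Penrose pseudoinverse when the
#'   correlation matrix is (near-)singular, as factor-analysis practice
#'   does for highly collinear measure sets; the default refuses singular
#'   input instead.
#' @return KMO statistic in (0, 1).
#' @export
kmo <- function(x, pseudo_inverse = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop_pre("KMO needs at least two features")
  if (nrow(x) <= ncol(x)) stop_pre("KMO needs more rows than features")
  r <- stats::cor(x)
  off <- upper.tri(r)
  if (all(abs(r[off]) < 1e-12)) {
    stop_pre("all off-diagonal correlations are zero; KMO undefined")
  }
  inv <- tryCatch(solve(r), error = function(e) {
    if (!pseudo_inverse) {
      stop_pre("correlation matrix is singular; KMO undefined ",
               "(set pseudo_inverse = TRUE to use the Moore-Penrose inverse)")
    }
    e <- eigen(r, symmetric = TRUE)
    keep <- e$values > 1e-10 * max(e$values)
    v <- e$vectors[, keep, drop = FALSE]
    v %*% diag(1 / e$values[keep], sum(keep)) %*% t(v)
  })
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * tcrossprod(d)
  sum_r2 <- sum(r[off]^2)
  sum_p2 <- sum(partial[off]^2)
  sum_r2 / (sum_r2 + sum_p2)
}

#' Scree-based component selection (elbow rule)
#'
#' Operationalizes the visual scree-plot elbow as the position of maximum
#' acceleration of the scree profile: the forward second difference of the
#' log eigenvalues, `log e[i] - 2 log e[i+1] + log e[i+2]`, maximized over
#' i. The log scale makes the rule respond to *relative* flattening --
#' which is what the eye reads off a scree plot -- rather than being
#' dominated by the absolute gaps between the largest components; on the
#' textbook spectrum `c(5, 3, 2, 0.3, 0.25, 0.2)` both scales agree on an
#' elbow after the third component. Near-zero eigenvalues (below 1e-6 of
#' the largest, as arise under exact collinearity) are excluded from the
#' candidate positions. Because the elbow is inherently a judgement call,
#' `override` forces a fixed k and `attr(,"acceleration")` exposes the
#' curve for a human scree check.
#'
#' @param eigenvalues Eigenvalues sorted in decreasing order.
#' @param override Optional fixed k (returned as-is).
#' @return Number of components k, with the acceleration curve attached.
#' @export
scree_select <- function(eigenvalues, override = NULL) {
  if (!is.null(override)) {
    k <- as.integer(override)
    if (k < 1L) stop_pre("override must be a positive integer")
    return(k)
  }
  p <- length(eigenvalues)
  if (p < 3L) stop_pre("scree selection needs at least three eigenvalues")
  if (is.unsorted(rev(eigenvalues))) {
    stop_pre("eigenvalues must be sorted in decreasing order")
  }
  valid <- eigenvalues > 1e-6 * eigenvalues[1]
  le <- log(pmax(eigenvalues, .Machine$double.xmin))
  accel <- le[1:(p - 2L)] - 2 * le[2:(p - 1L)] + le[3:p]
  candidate <- valid[3:p]  # all three terms must be well away from zero
  if (!any(candidate) ||
      max(eigenvalues) - min(eigenvalues[valid]) < 1e-10 ||
      max(accel[candidate]) - min(accel[candidate]) < 1e-10) {
    stop_pre("flat scree spectrum: no elbow; supply override")
  }
  accel[!candidate] <- -Inf
  k <- which.max(accel)
  structure(as.integer(k), acceleration = accel)
}

#' Varimax-rotated principal component analysis
#'
#' Features are z-scored and the correlation matrix eigendecomposed (the
#' measures mix scales: counts, ratios, minutes). The first k component
#' loadings are varimax-rotated with Kaiser normalization (convergence
#' tolerance 1e-12); rotation is orthogonal, so total variance explained
#' by the k components is unchanged. Row scores are the standardized data
#' projected onto the rotated basis and have zero mean and unit variance on
#' the fitted data. Components are ordered by rotated explained variance,
#' and each column's sign is normalized so its largest-|loading| feature
#' loads positively, making refits bit-reproducible.
#'
#' @param x Numeric matrix/data.frame, complete cases only.
#' @param k Number of components to retain.
#' @param labels Optional character vector of human-readable component
#'   labels (attached metadata, never inferred from loadings).
#' @return A `pca_result`: `feature_names`, `center`, `scale`,
#'   `eigenvalues` (all), `k`, `loadings`, `projection`, `explained`
#'   (proportion per component), `total_explained`, `labels`, `scores`.
#' @export
pca_varimax <- function(x, k, labels = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyNA(x)) stop_pre("input must be complete cases (no NA)")
  if (k < 1L || k > ncol(x)) stop_pre("k must be in 1..ncol(x)")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_pre("constant feature(s): ",
             paste(colnames(x)[sds == 0], collapse = ", "))
  }
  ctr <- colMeans(x)
  z <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  if (vals[k] < 1e-10) stop_pre("component ", k, " has (near-)zero eigenvalue")
  v <- eig$vectors[, seq_len(k), drop = FALSE]
  a <- v %*% diag(sqrt(vals[seq_len(k)]), k)
  if (k > 1L) {
    rot <- stats::varimax(a, normalize = TRUE, eps = 1e-12)
    loadings <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  } else {
    loadings <- a
    rotmat <- diag(1)
  }
  projection <- v %*% diag(1 / sqrt(vals[seq_len(k)]), k) %*% rotmat
  # order by rotated explained variance, then fix signs
  ss <- colSums(loadings^2)
  ord <- order(ss, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  projection <- projection[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(loadings[, j]))
    if (loadings[i0, j] < 0) {
      loadings[, j] <- -loadings[, j]
      projection[, j] <- -projection[, j]
      rotmat[, j] <- -rotmat[, j]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(projection) <- dimnames(loadings)
  scores <- z %*% projection
  colnames(scores) <- colnames(loadings)
  structure(
    list(feature_names = colnames(x), center = ctr, scale = sds,
         eigenvalues = eig$values, k = as.integer(k), loadings = loadings,
         projection = projection, rotmat = rotmat,
         explained = colSums(loadings^2) / ncol(x),
         total_explained = sum(loadings^2) / ncol(x),
         labels = labels, scores = scores),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Varimax-rotated PCA:", length(x$feature_names), "features,",
      x$k, "components,",
      sprintf("%.1f%%", 100 * x$total_explained), "variance explained\n")
  if (!is.null(x$labels)) cat("Labels:", paste(x$labels, collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Attach human-readable component labels from a feature-label map
#'
#' Labels are attached metadata, never inferred statistically: each
#' retained component receives the label associated with its
#' largest-|loading| feature, so the conventional working names follow the
#' components wherever the rotation puts them.
#'
#' @param fit A `pca_result`.
#' @param feature_labels Named character vector mapping feature names to
#'   label strings.
#' @return The fit with `labels` filled in (one per component).
#' @export
label_components <- function(fit, feature_labels) {
  stopifnot(inherits(fit, "pca_result"))
  fit$labels <- vapply(seq_len(fit$k), function(j) {
    top <- fit$feature_names[which.max(abs(fit$loadings[, j]))]
    unname(feature_labels[top] %||% top)
  }, "")
  fit
}

#' Conventional label maps for the two PCAs
#'
#' `word_property_labels()`: word-form cluster (length, OLD, PLD) ->
#' "length"; frequency/semantic cluster -> "semantic richness"; AoA ->
#' "acquisition age". `fluency_measure_labels()`: token/type counts ->
#' "speech quanta"; type-to-token ratios -> "lexical richness"; rate,
#' timing and combination measures -> "speech complexity".
#' @export
word_property_labels <- function() {
  c(length = "length", old = "length", pld = "length",
    log_frequency = "semantic richness",
    semantic_diversity = "semantic richness",
    semantic_neighbourhood_density = "semantic richness",
    concreteness = "semantic richness",
    age_of_acquisition = "acquisition age")
}

#' @rdname word_property_labels
#' @export
fluency_measure_labels <- function() {
  c(word_tokens = "speech quanta", word_types = "speech quanta",
    bigram_tokens = "speech quanta", bigram_types = "speech quanta",
    trigram_tokens = "speech quanta", trigram_types = "speech quanta",
    ttr_word = "lexical richness", ttr_bigram = "lexical richness",
    ttr_trigram = "lexical richness",
    total_time_s = "speech complexity",
    words_per_minute = "speech complexity",
    function_content_proportion = "speech complexity",
    combination_ratio = "speech complexity")
}

#' Project new rows into a fitted PCA space
#'
#' @param fit A `pca_result`.
#' @param newdata Matrix/data.frame containing the fitted feature columns.
#' @return Score matrix (rows x k).
#' @export
pca_project <- function(fit, newdata) {
  stopifnot(inherits(fit, "pca_result"))
  m <- as.matrix(as.data.frame(newdata)[, fit$feature_names, drop = FALSE])
  z <- sweep(sweep(m, 2, fit$center), 2, fit$scale, "/")
  s <- z %*% fit$projection
  colnames(s) <- colnames(fit$loadings)
  s
}

#' Average word PC scores per participant
#'
#' Scores every annotated content token of each participant in the fitted
#' word-properties space and averages over tokens, per participant and
#' picture. Token-level averaging weights each word by how often the
#' participant produced it.
#'
#' @param fit Word-properties `pca_result` (fitted on the pooled
#'   unique-word corpus).
#' @param token_table Long token table from [annotate_cohort()]
#'   (`participant_id`, `group`, `picture` + the eight property columns).
#' @param roster Optional data.frame (`participant_id`, `group`, `picture`)
#'   of expected rows; participants with zero annotated tokens then appear
#'   with `NA` scores and `n_tokens = 0`.
#' @return Data.frame: `participant_id`, `group`, `picture`, `n_tokens`,
#'   one column per component.
#' @export
project_words_and_average <- function(fit, token_table, roster = NULL) {
  stopifnot(inherits(fit, "pca_result"))
  scores <- pca_project(fit, token_table)
  key <- interaction(token_table$participant_id, token_table$picture,
                     drop = TRUE, lex.order = TRUE)
  agg <- rowsum(scores, key)
  n <- as.vector(table(key)[rownames(agg)])
  agg <- agg / n
  idx <- match(rownames(agg), as.character(key))
  out <- data.frame(participant_id = token_table$participant_id[idx],
                    group = token_table$group[idx],
                    picture = token_table$picture[idx],
                    n_tokens = n, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(agg))
  rownames(out) <- NULL
  if (!is.null(roster)) {
    have <- paste(out$participant_id, out$picture)
    want <- paste(roster$participant_id, roster$picture)
    miss <- which(!(want %in% have))
    if (length(miss) > 0L) {
      blank <- out[rep(NA_integer_, length(miss)), ]
      blank$participant_id <- roster$participant_id[miss]
      blank$group <- roster$group[miss]
      blank$picture <- roster$picture[miss]
      blank$n_tokens <- 0L
      out <- rbind(out, blank)
      rownames(out) <- NULL
    }
  }
  out[order(out$participant_id, out$picture), , drop = FALSE]
}

#' Group comparisons of PC scores (ANOVA + Tukey HSD)
#'
#' One-way fixed-effects ANOVA on each component's scores by group, or
#' two-way (group x task) when `task` is supplied, with Tukey's honestly
#' significant difference test for post hoc pairwise group comparisons.
#'
#' @param scores Data.frame containing the score columns and grouping
#'   columns.
#' @param score_cols Character vector of score column names.
#' @param group_col Name of the group column.
#' @param task_col Optional name of the task/picture column (two-way).
#' @return Named list per score column: `anova` (data.frame of effects with
#'   F, df and p) and `tukey` (matrix of pairwise group comparisons).
#' @export
pc_group_tests <- function(scores, score_cols, group_col = "group",
                           task_col = NULL) {
  g <- factor(scores[[group_col]])
  if (nlevels(g) < 2L) stop_pre("need at least two groups")
  if (any(table(g) < 2L)) stop_pre("every group needs at least two members")
  out <- list()
  for (sc in score_cols) {
    d <- data.frame(y = scores[[sc]], group = g)
    form <- y ~ group
    if (!is.null(task_col)) {
      d$task <- factor(scores[[task_col]])
      form <- y ~ group * task
    }
    fit <- stats::aov(form, data = d)
    tab <- summary(fit)[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    anova_df <- data.frame(
      effect = eff[keep],
      df = tab$Df[keep],
      df_resid = tab$Df[!keep],
      F = tab$`F value`[keep],
      p = tab$`Pr(>F)`[keep],
      stringsAsFactors = FALSE
    )
    out[[sc]] <- list(anova = anova_df,
                      tukey = stats::TukeyHSD(fit, "group")$group)
  }
  out
}
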
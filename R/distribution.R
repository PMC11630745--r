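# Fixed-edge quartile binning of word PC scores, per-participant bivariate
# proportion maps, group difference maps with cellwise Welch tests, and the
# group x quartile mixed-design ANOVA.

#' Fixed quartile edges of the word PC score scale
#'
#' The score axis is divided into four fixed ranges: \[-4, -2\], (-2, 0\],
#' (0, 2\] and (2, 4\]. These are fixed score ranges on the standardized PC
#' scale, not data quantiles; scores outside \[-4, 4\] are clipped into the
#' end bins (and counted, since unit-variance scores land outside only in
#' the far tails).
#' @export
quartile_edges <- function() c(-4, -2, 0, 2, 4)

quartile_labels <- function() c("Q1", "Q2", "Q3", "Q4")

quartile_bin <- function(scores, edges = quartile_edges()) {
  clipped <- pmin(pmax(scores, edges[1]), edges[length(edges)])
  cut(clipped, breaks = edges, include.lowest = TRUE,
      labels = quartile_labels())
}

#' Count words per fixed score quartile
#'
#' @param scores Finite numeric PC scores (one per produced content token).
#' @param edges Bin edges (default [quartile_edges()]).
#' @return Integer 4-vector (named Q1..Q4) summing to `length(scores)`,
#'   with attribute `n_clipped` counting out-of-range scores.
#' @export
quartile_counts <- function(scores, edges = quartile_edges()) {
  if (any(!is.finite(scores))) stop_pre("scores must be finite")
  n_clip <- sum(scores < edges[1] | scores > edges[length(edges)])
  counts <- table(quartile_bin(scores, edges))
  out <- stats::setNames(as.integer(counts), quartile_labels())
  attr(out, "n_clipped") <- n_clip
  out
}

#' Bivariate proportion map of one participant's word scores
#'
#' The 4x4 grid over two PC axes: each cell holds the proportion of the
#' participant's content tokens whose score pair falls in that region of
#' the psycholinguistic space. Cells sum to 1.
#'
#' @param scores1,scores2 Paired score vectors on the two PCs.
#' @param edges Bin edges.
#' @return 4x4 matrix (rows = axis 1, cols = axis 2) with attribute
#'   `n_words`, or `NULL` when there are no words (missing map).
#' @export
proportion_map <- function(scores1, scores2, edges = quartile_edges()) {
  if (length(scores1) != length(scores2)) stop_pre("score vectors must be paired")
  if (length(scores1) == 0L) return(NULL)
  b1 <- quartile_bin(scores1, edges)
  b2 <- quartile_bin(scores2, edges)
  m <- unclass(table(b1, b2)) / length(scores1)
  dimnames(m) <- list(quartile_labels(), quartile_labels())
  attr(m, "n_words") <- length(scores1)
  m
}

#' Unweighted mean of participant maps (group map)
#'
#' @param maps List of participant 4x4 maps (NULL entries dropped).
#' @export
group_mean_map <- function(maps) {
  maps <- Filter(Negate(is.null), maps)
  if (length(maps) == 0L) stop_pre("no non-missing maps")
  bare <- lapply(maps, function(m) {
    m <- unclass(m)
    attr(m, "n_words") <- NULL
    m
  })
  Reduce(`+`, bare) / length(maps)
}

#' Difference map between a patient group and controls
#'
#' Cell-by-cell difference of the two group mean maps (patient minus
#' control) with a per-cell Welch two-sample two-tailed t-test on the
#' participant-level proportions. P-values are reported uncorrected,
#' following the asterisk convention of exploratory cellwise testing; treat
#' them descriptively under the 16-cell multiplicity.
#'
#' @param group_maps,control_maps Lists of participant maps for the
#'   patient group and controls (at least two each).
#' @return List: `difference` (4x4, sums to 0), `t` and `p` (4x4; `NA`
#'   where both groups have zero variance in a cell).
#' @export
difference_map <- function(group_maps, control_maps) {
  group_maps <- Filter(Negate(is.null), group_maps)
  control_maps <- Filter(Negate(is.null), control_maps)
  if (length(group_maps) < 2L || length(control_maps) < 2L) {
    stop_pre("both groups need at least two participants")
  }
  ga <- simplify2array(lapply(group_maps, unclass))
  ca <- simplify2array(lapply(control_maps, unclass))
  diff <- apply(ga, c(1, 2), mean) - apply(ca, c(1, 2), mean)
  tmat <- pmat <- matrix(NA_real_, 4, 4,
                         dimnames = list(quartile_labels(), quartile_labels()))
  for (i in 1:4) for (j in 1:4) {
    a <- ga[i, j, ]
    b <- ca[i, j, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) next
    tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
    tmat[i, j] <- unname(tt$statistic)
    pmat[i, j] <- tt$p.value
  }
  list(difference = diff, t = tmat, p = pmat)
}

#' Group x quartile mixed-design ANOVA on word counts
#'
#' Repeated-measures ANOVA with quartile as the within-subject factor and
#' group as the between-subject factor, fitted via `aov` with a
#' subject/quartile error stratum. Post hoc pairwise quartile comparisons
#' use Tukey's HSD on the within-subject error term.
#'
#' @param counts Participants x 4 matrix of per-quartile word counts.
#' @param groups Group label per participant (>= 2 per group).
#' @return List: `anova` (data.frame with F, df and p for group, quartile
#'   and group:quartile) and `tukey_quartile` (pairwise quartile table:
#'   difference, studentized-range p).
#' @export
quartile_rm_anova <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop_pre("counts must have four quartile columns")
  if (anyNA(counts)) stop_pre("count table must be complete")
  groups <- factor(groups)
  if (length(groups) != nrow(counts)) stop_pre("one group label per row")
  if (any(table(groups) < 2L)) stop_pre("every group needs >= 2 participants")
  n <- nrow(counts)
  long <- data.frame(
    count = as.vector(counts),
    quartile = factor(rep(quartile_labels(), each = n)),
    group = rep(groups, times = 4L),
    subject = factor(rep(seq_len(n), times = 4L))
  )
  fit <- stats::aov(count ~ group * quartile + Error(subject / quartile),
                    data = long)
  s <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- s[[stratum]][[1]]
    i <- match(effect, trimws(rownames(tab)))
    res <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = effect, df = tab$Df[i], df_resid = tab$Df[res],
               ss = tab$`Sum Sq`[i],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  }
  anova_df <- rbind(pull("Error: subject", "group"),
                    pull("Error: subject:quartile", "quartile"),
                    pull("Error: subject:quartile", "group:quartile"))
  rownames(anova_df) <- NULL
  # a vanished effect (zero sum of squares, possibly against a zero error
  # stratum) is a null effect, not numerical noise
  bad <- !is.finite(anova_df$F) | anova_df$ss < 1e-9 * sum(counts^2)
  anova_df$F[bad] <- 0
  anova_df$p[bad] <- 1
  anova_df$ss <- NULL

  # Tukey HSD on quartile means against the within-subject error MS
  wtab <- s[["Error: subject:quartile"]][[1]]
  res_i <- match("Residuals", trimws(rownames(wtab)))
  mse <- wtab$`Mean Sq`[res_i]
  df_err <- wtab$Df[res_i]
  qmeans <- colMeans(counts)
  pairs <- utils::combn(4L, 2L)
  se <- sqrt(mse / n)
  tk <- data.frame(
    comparison = apply(pairs, 2, function(ij)
      paste(quartile_labels()[ij[2]], "-", quartile_labels()[ij[1]])),
    diff = apply(pairs, 2, function(ij) qmeans[ij[2]] - qmeans[ij[1]]),
    stringsAsFactors = FALSE
  )
  tk$p <- stats::ptukey(abs(tk$diff) / se, nmeans = 4L, df = df_err,
                        lower.tail = FALSE)
  list(anova = anova_df, tukey_quartile = tk)
}

#' Quartile count table per participant for one PC
#'
#' @param word_scores Data.frame with `participant_id`, `group`, `picture`
#'   and token-level score column `pc`.
#' @param pc Score column name (e.g. "PC1").
#' @param edges Bin edges.
#' @return Data.frame: participant metadata, n_tokens, Q1..Q4 counts.
#' @export
cohort_quartile_counts <- function(word_scores, pc, edges = quartile_edges()) {
  key <- interaction(word_scores$participant_id, word_scores$picture,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(kk) {
    idx <- which(key == kk)
    qc <- quartile_counts(word_scores[[pc]][idx], edges)
    data.frame(participant_id = word_scores$participant_id[idx[1]],
               group = word_scores$group[idx[1]],
               picture = word_scores$picture[idx[1]],
               n_tokens = length(idx),
               Q1 = qc[1], Q2 = qc[2], Q3 = qc[3], Q4 = qc[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
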
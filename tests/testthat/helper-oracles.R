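# Independent reference implementations used as oracles. Each is written
# from the defining formula, separately from the package's code paths.

# Brute-force n-gram enumerator: walk every window position explicitly.
brute_ngrams <- function(runs, n) {
  seen <- character(0)
  tokens <- 0L
  for (r in runs) {
    L <- length(r)
    if (L < n) next
    for (i in 1:(L - n + 1)) {
      g <- r[i]
      if (n > 1) for (j in 1:(n - 1)) g <- paste(g, r[i + j])
      seen <- c(seen, g)
      tokens <- tokens + 1L
    }
  }
  list(tokens = tokens, types = length(unique(seen)))
}

# Pairwise Jacobi-sweep varimax with Kaiser normalization, from the
# classical rotation-angle formula.
ref_varimax <- function(a, max_sweeps = 1000, tol = 1e-14) {
  p <- nrow(a)
  k <- ncol(a)
  h <- sqrt(rowSums(a^2))
  w <- a / h
  rot <- diag(k)
  crit <- function(m) sum(apply(m^2, 2, function(col) sum((col - mean(col))^2)))
  old <- crit(w)
  for (sweep in seq_len(max_sweeps)) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      x <- w[, i]; y <- w[, j]
      u <- x^2 - y^2
      v <- 2 * x * y
      num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
      den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) < 1e-15) next
      cs <- cos(phi); sn <- sin(phi)
      w[, i] <- cs * x + sn * y
      w[, j] <- -sn * x + cs * y
      ri <- rot[, i]; rj <- rot[, j]
      rot[, i] <- cs * ri + sn * rj
      rot[, j] <- -sn * ri + cs * rj
    }
    new <- crit(w)
    if (new - old < tol) break
    old <- new
  }
  list(loadings = w * h, rotmat = rot)
}

# Align columns of `b` to `a` up to permutation and sign; returns the
# aligned version of `b` (greedy best-match on absolute inner products).
align_columns <- function(a, b) {
  k <- ncol(a)
  xp <- abs(crossprod(a, b))
  out <- matrix(NA_real_, nrow(b), k)
  used <- rep(FALSE, k)
  for (j in order(-apply(xp, 1, max))) {
    cand <- which.max(ifelse(used, -Inf, xp[j, ]))
    used[cand] <- TRUE
    s <- sign(sum(a[, j] * b[, cand]))
    out[, j] <- s * b[, cand]
  }
  out
}

# KMO from partial correlations computed the long way: residualize each
# pair on all remaining variables with lm, then correlate residuals.
ref_kmo <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  r <- cor(x)
  sum_r2 <- 0
  sum_p2 <- 0
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(1:p, c(i, j))
    ei <- if (length(others) > 0) {
      resid(lm(x[, i] ~ x[, others, drop = FALSE]))
    } else x[, i]
    ej <- if (length(others) > 0) {
      resid(lm(x[, j] ~ x[, others, drop = FALSE]))
    } else x[, j]
    sum_r2 <- sum_r2 + r[i, j]^2
    sum_p2 <- sum_p2 + cor(ei, ej)^2
  }
  sum_r2 / (sum_r2 + sum_p2)
}

# One-way ANOVA F from the defining sums of squares.
ref_oneway_F <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# Welch two-sample t statistic and p from the formula.
ref_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Mixed-design (split-plot) ANOVA for a balanced-within design: one
# between factor (group), one within factor (quartile), from the
# sums-of-squares decomposition.
ref_mixed_anova <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  n <- nrow(counts)
  q <- ncol(counts)
  grand <- mean(counts)
  subj_means <- rowMeans(counts)
  grp_means <- tapply(subj_means, groups, mean)
  q_means <- colMeans(counts)
  ng <- table(groups)
  ss_group <- q * sum(ng * (grp_means - grand)^2)
  ss_subj <- q * sum((subj_means - grp_means[groups])^2)
  ss_quart <- n * sum((q_means - grand)^2)
  cell_means <- apply(counts, 2, function(col) tapply(col, groups, mean))
  # cell_means: group x quartile
  ss_int <- 0
  for (g in levels(groups)) for (j in 1:q) {
    ss_int <- ss_int + ng[g] *
      (cell_means[g, j] - grp_means[g] - q_means[j] + grand)^2
  }
  ss_tot <- sum((counts - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_quart - ss_int
  df_group <- nlevels(groups) - 1
  df_subj <- n - nlevels(groups)
  df_quart <- q - 1
  df_int <- df_group * df_quart
  df_err <- df_subj * df_quart
  f <- c(group = (ss_group / df_group) / (ss_subj / df_subj),
         quartile = (ss_quart / df_quart) / (ss_err / df_err),
         interaction = (ss_int / df_int) / (ss_err / df_err))
  p <- c(group = pf(f[1], df_group, df_subj, lower.tail = FALSE),
         quartile = pf(f[2], df_quart, df_err, lower.tail = FALSE),
         interaction = pf(f[3], df_int, df_err, lower.tail = FALSE))
  list(F = f, p = unname(p))
}

# Reference penalized-path-free logistic MLE (base glm, independent of
# glmnet).
ref_logistic_mle <- function(x, y) {
  d <- as.data.frame(x)
  d$.y <- y
  coef(glm(.y ~ ., data = d, family = binomial()))
}
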
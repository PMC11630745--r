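test_that("bivariate KMO is exactly 0.5 for any nonzero correlation", {
  for (seed in c(3, 17, 91)) {
    set.seed(seed)
    x <- rnorm(80)
    y <- 0.6 * x + rnorm(80, sd = runif(1, 0.3, 2))
    expect_equal(kmo(cbind(x, y)), 0.5, tolerance = 1e-12)
  }
})

test_that("KMO matches the independent partial-correlation oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    z <- matrix(rnorm(50 * 3), 50, 3)
    x <- cbind(z %*% matrix(rnorm(9), 3), matrix(rnorm(50 * 3), 50, 3))
    expect_equal(kmo(x), ref_kmo(x), tolerance = 1e-10)
  }
})

test_that("KMO signals degenerate inputs, with a pseudoinverse escape hatch", {
  set.seed(1)
  x <- matrix(rnorm(40 * 3), 40, 3)
  sing <- cbind(x, x[, 1] + x[, 2])
  expect_error(kmo(sing), "singular")
  expect_error(kmo(x[, 1, drop = FALSE]), "two features")
  expect_error(kmo(matrix(rnorm(6), 2, 3)), "more rows")
  # collinear measure sets are valid with the Moore-Penrose form
  v <- kmo(sing, pseudo_inverse = TRUE)
  expect_true(is.finite(v) && v > 0 && v <= 1)
})

test_that("scree selection finds the textbook elbow and honours overrides", {
  expect_equal(as.integer(scree_select(c(5, 3, 2, 0.3, 0.25, 0.2))), 3L)
  expect_equal(scree_select(c(5, 3, 2, 0.3, 0.25, 0.2), override = 3), 3L)
  expect_equal(scree_select(c(9, 1, 0.5, 0.4), override = 2), 2L)
  expect_error(scree_select(rep(1, 8)), "flat")
  expect_error(scree_select(c(2, 1)), "three eigenvalues")
  expect_error(scree_select(c(1, 2, 3)), "decreasing")
  # a single dominant component: elbow directly after it
  expect_equal(as.integer(scree_select(c(6, 0.4, 0.35, 0.3, 0.3))), 1L)
})

test_that("varimax rotation matches the Jacobi-sweep reference", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(100 * 8), 100, 8) %*% diag(runif(8, 0.5, 2)) +
      rep(1, 100) %o% rnorm(8)
    # plant correlation structure so rotation is non-trivial
    x[, 4:6] <- x[, 1:3] + matrix(rnorm(300, sd = 0.6), 100, 3)
    fit <- pca_varimax(x, 3)
    a <- eigen(cor(x), symmetric = TRUE)
    unrot <- a$vectors[, 1:3] %*% diag(sqrt(a$values[1:3]))
    ref <- ref_varimax(unrot)
    aligned <- align_columns(fit$loadings, ref$loadings)
    expect_lt(max(abs(fit$loadings - aligned)), 1e-6)
  }
})

test_that("rotation is orthogonal and preserves explained variance", {
  set.seed(7)
  x <- matrix(rnorm(60 * 6), 60, 6)
  x[, 4] <- x[, 1] + rnorm(60, sd = 0.4)
  fit <- pca_varimax(x, 3)
  expect_lt(max(abs(crossprod(fit$rotmat) - diag(3))), 1e-8)
  pre <- sum(eigen(cor(x), only.values = TRUE)$values[1:3]) / 6
  expect_equal(fit$total_explained, pre, tolerance = 1e-8)
})

test_that("scores are centred, unit-variance and sign-normalized; refits are bit-identical", {
  set.seed(11)
  x <- matrix(rnorm(80 * 5), 80, 5)
  fit <- pca_varimax(x, 2)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-8)
  expect_equal(unname(apply(fit$scores, 2, sd)), c(1, 1), tolerance = 1e-8)
  for (j in 1:2) {
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }
  expect_identical(pca_varimax(x, 2), fit)
})

test_that("degenerate inputs are rejected with informative errors", {
  set.seed(2)
  x <- cbind(a = rnorm(30), b = rnorm(30), c = rep(1, 30))
  expect_error(pca_varimax(x, 2), "constant feature.*c")
  x2 <- cbind(a = rnorm(30), b = rnorm(30))
  x2[5, 1] <- NA
  expect_error(pca_varimax(x2, 1), "complete cases")
})

test_that("projection reproduces training scores and averages per participant", {
  lex <- generate_norms(40, seed = 5)
  props <- as.data.frame(lex)[, norm_properties()]
  fit <- pca_varimax(props, 3)
  expect_equal(unname(pca_project(fit, props)), unname(fit$scores),
               tolerance = 1e-12)

  w <- as.data.frame(lex)$word
  tok <- data.frame(participant_id = c("a", "a", "b", "b"),
                    group = "control",
                    picture = "cookie_theft",
                    token = w[c(1, 1, 2, 3)])
  tok <- cbind(tok, props[c(1, 1, 2, 3), ])
  avg <- project_words_and_average(fit, tok)
  s <- pca_project(fit, props)
  expect_equal(unname(as.matrix(avg[avg$participant_id == "a",
                                    paste0("PC", 1:3)])),
               unname(s[1, , drop = FALSE]), tolerance = 1e-12)
  expect_equal(unname(as.matrix(avg[avg$participant_id == "b",
                                    paste0("PC", 1:3)])),
               unname((s[2, , drop = FALSE] + s[3, , drop = FALSE]) / 2),
               tolerance = 1e-12)

  # two tokens with opposite scores average to zero
  tok2 <- tok[1:2, ]
  tok2[2, norm_properties()] <- 2 * fit$center - tok2[1, norm_properties()]
  avg2 <- project_words_and_average(fit, tok2)
  expect_equal(unname(as.matrix(avg2[, paste0("PC", 1:3)])),
               matrix(0, 1, 3), tolerance = 1e-10)

  roster <- data.frame(participant_id = c("a", "b", "c"),
                       group = "control", picture = "cookie_theft")
  avg3 <- project_words_and_average(fit, tok, roster = roster)
  expect_equal(avg3$n_tokens[avg3$participant_id == "c"], 0L)
  expect_true(all(is.na(avg3[avg3$participant_id == "c", paste0("PC", 1:3)])))
})

test_that("synthetic lexica recover the planted three-cluster structure", {
  clusters <- list(form = c("length", "old", "pld"),
                   semantic = c("log_frequency", "semantic_diversity",
                                "semantic_neighbourhood_density",
                                "concreteness"),
                   aoa = "age_of_acquisition")
  hits <- 0L
  for (seed in 1:10) {
    lex <- generate_norms(500, seed)
    props <- as.matrix(as.data.frame(lex)[, norm_properties()])
    k <- tryCatch(as.integer(scree_select(
      eigen(cor(props), symmetric = TRUE, only.values = TRUE)$values)),
      error = function(e) NA_integer_)
    fit <- pca_varimax(props, 3)
    dom <- apply(abs(fit$loadings), 1, which.max)
    comp <- vapply(clusters, function(v) {
      u <- unique(dom[v])
      if (length(u) == 1L) u else NA_integer_
    }, 1L)
    if (identical(k, 3L) && !anyNA(comp) && length(unique(comp)) == 3L) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("group ANOVA matches the sums-of-squares oracle and Tukey flags planted shifts", {
  set.seed(21)
  d <- data.frame(group = rep(c("control", "svPPA", "PSP"), each = 12),
                  PC1 = rnorm(36))
  res <- pc_group_tests(d, "PC1")
  expect_equal(res$PC1$anova$F, ref_oneway_F(d$PC1, d$group),
               tolerance = 1e-8)

  # identical groups (copied data): F ~ 0
  d2 <- data.frame(group = rep(c("a", "b"), each = 10),
                   PC1 = rep(rnorm(10), 2))
  expect_lt(pc_group_tests(d2, "PC1")$PC1$anova$F, 1e-20)

  # planted large shift: Tukey p < 0.001 in every seed tried
  for (seed in 1:10) {
    set.seed(seed)
    d3 <- data.frame(group = rep(c("control", "nfvPPA"), each = 20),
                     PC1 = c(rnorm(20), rnorm(20, mean = 3)))
    tk <- pc_group_tests(d3, "PC1")$PC1$tukey
    expect_lt(tk["nfvPPA-control", "p adj"], 0.001)
  }

  # two-way layout reports group, task and interaction
  d4 <- data.frame(group = rep(c("a", "b"), each = 20),
                   task = rep(c("ct", "bs"), times = 20),
                   PC1 = rnorm(40))
  eff <- pc_group_tests(d4, "PC1", task_col = "task")$PC1$anova$effect
  expect_setequal(eff, c("group", "task", "group:task"))
})
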
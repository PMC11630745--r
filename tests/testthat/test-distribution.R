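test_that("quartile counts respect the fixed edges and clip the tails", {
  expect_equal(as.vector(quartile_counts(c(-3.5, -1, 0.5, 3))), c(1L, 1L, 1L, 1L))
  expect_equal(as.vector(quartile_counts(rep(1, 7))), c(0L, 0L, 7L, 0L))
  expect_equal(as.vector(quartile_counts(numeric(0))), c(0L, 0L, 0L, 0L))

  clipped <- quartile_counts(c(-5, 4.7, 0.1))
  expect_equal(as.vector(clipped), c(1L, 0L, 1L, 1L))
  expect_equal(attr(clipped, "n_clipped"), 2L)

  # edge membership: bins are [-4,-2], (-2,0], (0,2], (2,4]
  expect_equal(as.vector(quartile_counts(c(-4, -2, 0, 2, 4))),
               c(2L, 1L, 1L, 1L))
  expect_error(quartile_counts(c(1, NA)), "finite")
})

test_that("proportion maps are normalized histograms over the 4x4 grid", {
  single <- proportion_map(-3, 3)
  expect_equal(single["Q1", "Q4"], 1)
  expect_equal(sum(single), 1)

  centres <- c(-3, -1, 1, 3)
  grid <- expand.grid(a = centres, b = centres)
  uniform <- proportion_map(grid$a, grid$b)
  expect_true(all(abs(uniform - 1 / 16) < 1e-12))

  expect_null(proportion_map(numeric(0), numeric(0)))

  for (seed in 1:20) {
    set.seed(seed)
    s1 <- rnorm(50)
    s2 <- rnorm(50)
    m <- proportion_map(s1, s2)
    expect_equal(sum(m), 1, tolerance = 1e-10)
    # brute-force histogram oracle
    brute <- matrix(0, 4, 4)
    lo <- c(-4, -2, 0, 2)
    hi <- c(-2, 0, 2, 4)
    for (w in seq_along(s1)) {
      a <- min(max(s1[w], -4), 4)
      b <- min(max(s2[w], -4), 4)
      i <- if (a <= -2) 1 else if (a <= 0) 2 else if (a <= 2) 3 else 4
      j <- if (b <= -2) 1 else if (b <= 0) 2 else if (b <= 2) 3 else 4
      brute[i, j] <- brute[i, j] + 1
    }
    expect_equal(unclass(m), brute / 50, ignore_attr = TRUE)
  }
})

test_that("group mean maps are unweighted and permutation-invariant", {
  set.seed(4)
  maps <- lapply(1:6, function(i) proportion_map(rnorm(20 + 5 * i),
                                                 rnorm(20 + 5 * i)))
  m1 <- group_mean_map(maps)
  m2 <- group_mean_map(rev(maps))
  expect_equal(m1, m2)
  expect_equal(sum(m1), 1, tolerance = 1e-10)
})

test_that("difference maps are zero against self and match the Welch oracle", {
  set.seed(9)
  maps <- lapply(1:8, function(i) proportion_map(rnorm(40), rnorm(40)))
  self <- difference_map(maps, maps)
  expect_true(all(abs(self$difference) < 1e-15))
  expect_true(all(self$p[!is.na(self$p)] > 0.999))
  expect_equal(sum(self$difference), 0, tolerance = 1e-10)

  other <- lapply(1:7, function(i) proportion_map(rnorm(40, 0.5), rnorm(40)))
  dm <- difference_map(other, maps)
  expect_equal(sum(dm$difference), 0, tolerance = 1e-10)
  ga <- simplify2array(lapply(other, unclass))
  ca <- simplify2array(lapply(maps, unclass))
  for (i in 1:4) for (j in 1:4) {
    ref <- ref_welch(ga[i, j, ], ca[i, j, ])
    expect_equal(dm$t[i, j], ref$t, tolerance = 1e-10)
    expect_equal(dm$p[i, j], ref$p, tolerance = 1e-10)
  }
})

test_that("a planted shift toward high-PC2/low-PC1 cells is detected", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    ctrl <- lapply(1:20, function(i) proportion_map(rnorm(60, 0.5, 1.2),
                                                    rnorm(60, -0.5, 1.2)))
    sv <- lapply(1:20, function(i) proportion_map(rnorm(60, -1.2, 1.2),
                                                  rnorm(60, 1.2, 1.2)))
    dm <- difference_map(sv, ctrl)
    # mass should move into the low-PC1 / high-PC2 corner (Q2 x Q4 region)
    if (dm$difference["Q2", "Q4"] > 0 && dm$p["Q2", "Q4"] < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("mixed-design ANOVA matches the sums-of-squares oracle", {
  set.seed(31)
  counts <- matrix(rpois(30 * 4, lambda = 8), 30, 4)
  groups <- rep(c("control", "svPPA", "PSP"), each = 10)
  got <- quartile_rm_anova(counts, groups)
  want <- ref_mixed_anova(counts, groups)
  expect_equal(got$anova$F, unname(want$F), tolerance = 1e-6)
  expect_equal(got$anova$p, unname(want$p), tolerance = 1e-6)
  expect_equal(got$anova$effect, c("group", "quartile", "group:quartile"))

  # identical rows for every participant: all effects null
  flat <- matrix(rep(c(5, 7, 9, 3), each = 12), 12, 4)
  got_flat <- quartile_rm_anova(flat, rep(c("a", "b"), each = 6))
  expect_equal(got_flat$anova$F[got_flat$anova$effect != "quartile"],
               c(0, 0))

  expect_error(quartile_rm_anova(counts[1:3, ], c("a", "a", "b")),
               ">= 2 participants")
})

test_that("a planted group-by-quartile interaction is detected", {
  hits <- 0L
  for (seed in 1:15) {
    set.seed(seed)
    base <- c(10, 10, 10, 10)
    shifted <- c(4, 6, 14, 16)  # mass moved up two quartiles
    a <- t(replicate(15, rpois(4, base)))
    b <- t(replicate(15, rpois(4, shifted)))
    res <- quartile_rm_anova(rbind(a, b), rep(c("a", "b"), each = 15))
    p_int <- res$anova$p[res$anova$effect == "group:quartile"]
    if (p_int < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 14L)
})

test_that("per-participant quartile counts conserve annotated tokens", {
  set.seed(6)
  ws <- data.frame(
    participant_id = rep(c("a", "b", "c"), times = c(12, 30, 7)),
    group = rep(c("control", "svPPA", "PSP"), times = c(12, 30, 7)),
    picture = "cookie_theft",
    PC1 = rnorm(49, sd = 1.5)
  )
  qc <- cohort_quartile_counts(ws, "PC1")
  expect_equal(qc$Q1 + qc$Q2 + qc$Q3 + qc$Q4, qc$n_tokens)
  expect_equal(sum(qc$n_tokens), nrow(ws))
  expect_equal(qc$n_tokens[qc$participant_id == "b"], 30L)
})
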
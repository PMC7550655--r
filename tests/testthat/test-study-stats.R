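test_that("normality screening accepts normal and rejects two-point samples", {
  set.seed(21)
  ok <- ksNormality(rnorm(200))
  expect_gt(ok$p, 0.05)
  expect_true(ok$statistic >= 0 && ok$statistic <= 1)

  two_point <- rep(c(0, 1), 50)
  bad <- ksNormality(two_point)
  expect_lt(bad$p, 0.05)

  expect_error(ksNormality(c(1, 2)), "at least 3")
  expect_error(ksNormality(rep(5, 10)), "constant")
})

test_that("one-way ANOVA matches its classical identities", {
  set.seed(31)
  # identical group means: F near 0 for identical samples
  g <- rnorm(8)
  same <- anovaOneway(list(g, g, g))
  expect_equal(same@F, 0, tolerance = 1e-20)
  expect_equal(same@p, 1)

  # two groups: F equals the square of the pooled t statistic
  a <- rnorm(8); b <- rnorm(8, 1)
  fit <- anovaOneway(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(fit@F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit@p, tt$p.value, tolerance = 1e-10)

  # zero within-group variance with unequal means: flagged infinite F
  degen <- anovaOneway(list(rep(1, 4), rep(2, 4)))
  expect_true(degen@infinite_F)
  expect_identical(degen@F, Inf)
  expect_identical(degen@p, 0)
})

test_that("label permutation preserves the null F distribution", {
  set.seed(77)
  nsim <- 400
  F0 <- replicate(nsim, {
    y <- rnorm(32)
    anovaOneway(split(y, rep(1:4, each = 8)))@F
  })
  Fperm <- replicate(nsim, {
    y <- rnorm(32)
    anovaOneway(split(y, sample(rep(1:4, each = 8))))@F
  })
  expect_gt(suppressWarnings(ks.test(F0, Fperm))$p.value, 0.01)
})

test_that("summary-statistic ANOVA equals the raw-data ANOVA exactly", {
  set.seed(41)
  groups <- list(rnorm(8, 10, 2), rnorm(6, 12, 2), rnorm(9, 9, 3),
                 rnorm(7, 11, 1))
  raw <- anovaOneway(groups)
  cells <- data.frame(mean = sapply(groups, mean),
                      sd = sapply(groups, sd),
                      n = sapply(groups, length))
  sum_ <- anovaFromSummary(cells)
  expect_equal(sum_@F, raw@F, tolerance = 1e-12)
  expect_equal(sum_@p, raw@p, tolerance = 1e-12)
  expect_equal(sum_@ms_within, raw@ms_within, tolerance = 1e-12)
  expect_identical(sum_@df_between, raw@df_between)
  expect_identical(sum_@df_within, raw@df_within)
})

test_that("summary ANOVA reproduces printed table rows from mean/SD cells", {
  # tumor volume, control group over time
  t1a <- anovaFromSummary(data.frame(
    mean = c(217.5, 436.3, 702.5, 1039.8),
    sd = c(60.1, 59.6, 42.9, 93.9), n = 8))
  expect_lt(abs(t1a@F - 225.693) / 225.693, 0.01)

  # PTEN staining across groups at the final time point
  pten <- anovaFromSummary(data.frame(
    mean = c(26.1, 44.1, 51.8, 79.0),
    sd = c(5.4, 5.7, 6.7, 9.6), n = 8))
  expect_lt(abs(pten@F - 77.738) / 77.738, 0.01)
})

test_that("SNK rejects nothing when all groups coincide", {
  g <- c(1.2, 3.1, 0.4, 2.2, 1.8, 2.9, 1.1, 2.4)
  ph <- snkPosthoc(list(a = g, b = g, c = g, d = g))
  expect_identical(sum(ph@comparisons$reject), 0L)
})

test_that("two-group SNK coincides with the two-sample t test", {
  set.seed(51)
  for (delta in c(0, 0.5, 1.5, 3)) {
    a <- rnorm(8); b <- rnorm(8, delta)
    ph <- snkPosthoc(list(a = a, b = b), alpha = 0.05)
    tt <- t.test(a, b, var.equal = TRUE)
    # q = t * sqrt(2): the decisions must coincide at the same alpha
    expect_identical(ph@comparisons$reject[1L], tt$p.value < 0.05)
    expect_equal(ph@comparisons$q[1L],
                 abs(unname(tt$statistic)) * sqrt(2), tolerance = 1e-10)
  }
})

test_that("well-separated groups reject every pair; coherence holds", {
  set.seed(61)
  groups <- lapply(c(0, 10, 20, 30), function(m) rnorm(8, m, 1))
  names(groups) <- letters[1:4]
  ph <- snkPosthoc(groups)
  expect_true(all(ph@comparisons$reject))

  # coherence under widening: a rejected inner pair implies its enclosing
  # pairs (in sorted-mean order) were rejected too
  set.seed(62)
  for (rep in 1:20) {
    gs <- lapply(rnorm(4, 0, 1.2), function(m) rnorm(8, m, 1))
    names(gs) <- letters[1:4]
    cmp <- snkPosthoc(gs)@comparisons
    means <- sapply(gs, mean)
    pos <- rank(means)
    for (i in which(cmp$reject)) {
      lo <- pos[cmp$group1[i]]; hi <- pos[cmp$group2[i]]
      enclosing <- cmp[pos[cmp$group1] <= lo & pos[cmp$group2] >= hi, ]
      expect_true(all(enclosing$reject))
    }
    # and every rejection satisfies q > critical
    expect_true(all(cmp$q[cmp$reject] > cmp$q_crit[cmp$reject]))
  }
})

test_that("Pearson correlation and strength labels follow the conventions", {
  x <- c(0.3, 1.1, 2.7, 3.4, 4.9)
  r1 <- pearsonCorrelation(x, 2 * x + 1)
  expect_equal(r1@r, 1, tolerance = 1e-12)
  expect_identical(r1@strength, "high")
  expect_equal(pearsonCorrelation(x, -x)@r, -1, tolerance = 1e-12)

  r08 <- pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r08@r, 0.8, tolerance = 1e-12)
  expect_identical(r08@strength, "moderate")

  set.seed(71)
  a <- rnorm(30); b <- 0.6 * a + rnorm(30)
  base <- pearsonCorrelation(a, b)
  # invariance under affine maps; sign flips with negative scaling
  shifted <- pearsonCorrelation(3 * a - 2, 0.5 * b + 7)
  expect_equal(shifted@r, base@r, tolerance = 1e-12)
  flipped <- pearsonCorrelation(-a, b)
  expect_equal(flipped@r, -base@r, tolerance = 1e-12)
  # p matches the t transform with n - 2 df
  tstat <- base@r * sqrt((base@n - 2) / (1 - base@r^2))
  expect_equal(base@p, 2 * pt(abs(tstat), base@n - 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
})
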
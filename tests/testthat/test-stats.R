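test_that("one-way ANOVA behaves classically", {
  # identical groups: no variance anywhere -> F = 0, p = 1
  a <- anova_oneway(rep(5, 30), rep(c("a", "b", "c"), each = 10))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # well-separated groups are overwhelmingly significant
  set.seed(1)
  v <- c(rnorm(200, 0), rnorm(200, 5), rnorm(200, 10))
  g <- rep(c("a", "b", "c"), each = 200)
  expect_lt(anova_oneway(v, g)$p, 1e-6)
  # two-group ANOVA is the squared pooled-variance t test
  set.seed(2)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  a2 <- anova_oneway(c(x, y), rep(c("x", "y"), c(40, 35)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
  expect_error(anova_oneway(c(1, 2, 3), c("a", "b", "b")), "observations")
})

test_that("Newman-Keuls flags exactly the separated pairs", {
  set.seed(3)
  # identical distributions: nothing significant
  v0 <- rnorm(300)
  g <- rep(c("a", "b", "c"), each = 100)
  expect_false(any(snk_pairwise(v0, g)$significant))
  # all three well separated: every pair significant
  v1 <- c(rnorm(100, 0), rnorm(100, 3), rnorm(100, 6))
  expect_true(all(snk_pairwise(v1, g)$significant))
  # two equal groups, third far: exactly the two far pairs
  set.seed(4)
  v2 <- c(rnorm(500, 0), rnorm(500, 0), rnorm(500, 5))
  g2 <- rep(c("a", "b", "c"), each = 500)
  snk <- snk_pairwise(v2, g2)
  far <- (snk$group1 == "c") | (snk$group2 == "c")
  expect_true(all(snk$significant[far]))
  expect_false(any(snk$significant[!far]))
})

test_that("CDA separates, collapses under shuffling, and matches lda", {
  # two perfectly separated clouds
  set.seed(5)
  x <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
             matrix(rnorm(200, 5, 0.1), 100, 2))
  lab <- rep(c("p", "q"), each = 100)
  cd <- cda_fit(x, lab)
  expect_equal(cd$percent_correct$overall, 100)
  expect_lt(cd$wilks_lambda, 0.01)
  # shuffled labels: near-chance resubstitution accuracy
  ft <- sample_feature_table(n_per_class = 1000, seed = 6)
  set.seed(6)
  sh <- sample(ft$cycle_type)
  cd0 <- cda_fit(ft[, co2_free_predictors()], sh)
  expect_lt(abs(cd0$percent_correct$overall - 100 / 3), 5)
  # independent oracle: MASS::lda finds the same discriminant direction
  ft2 <- sample_feature_table(n_per_class = 400, seed = 7)
  X <- as.matrix(ft2[, co2_free_predictors()])
  cd2 <- cda_fit(X, ft2$cycle_type)
  ld <- MASS::lda(X, grouping = ft2$cycle_type)
  s_ours <- cd2$scores[, 1]
  s_lda <- predict(ld)$x[, 1]
  expect_gt(abs(cor(s_ours, s_lda)), 0.999)
  agree <- mean(cd2$predicted == predict(ld)$class)
  expect_gt(agree, 0.97)
})

test_that("class structure in one dimension leaves a null second variate", {
  set.seed(8)
  n <- 300
  shift <- rep(c(0, 4, 8), each = n / 3)
  x <- cbind(rnorm(n) + shift, rnorm(n) + 2 * shift, rnorm(n))
  cd <- cda_fit(x, rep(c("a", "b", "c"), each = n / 3))
  expect_lt(cd$eigenvalues[2] / cd$eigenvalues[1], 0.02)
})

test_that("Wilks' lambda falls as class separation grows", {
  set.seed(9)
  lam <- vapply(c(0.5, 1, 2, 4), function(d) {
    x <- rbind(matrix(rnorm(400), 200, 2),
               matrix(rnorm(400, d), 200, 2))
    cda_fit(x, rep(c("a", "b"), each = 200))$wilks_lambda
  }, numeric(1))
  expect_true(all(diff(lam) < 0))
})

test_that("confusion-matrix arithmetic reproduces the printed matrix", {
  m <- rbind(I = c(1744, 0, 105),
             II = c(117, 1392, 36),
             III = c(29, 0, 1324))
  colnames(m) <- c("I", "II", "III")
  s <- confusion_summary(m)
  expect_equal(s$overall, 93.95)
  expect_equal(unname(s$per_class["I"]), 94.32)
  expect_equal(unname(s$per_class["III"]), 97.86)
  expect_equal(unname(s$column_totals), c(1890, 1392, 1465))
  # trivial identities
  expect_equal(confusion_summary(diag(10, 3))$overall, 100)
  expect_true(all(confusion_summary(diag(10, 3))$per_class == 100))
  u <- confusion_summary(matrix(10, 3, 3))
  expect_equal(u$overall, 33.33)
  expect_true(all(u$per_class == 33.33))
  # scale invariance
  s10 <- confusion_summary(m * 10)
  expect_equal(s10$per_class, s$per_class)
  expect_equal(s10$overall, s$overall)
  expect_error(confusion_summary(rbind(c(1, 1), c(0, 0))), "row total")
})
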
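# Diagnostic summaries, criterion combination, ROC/DeLong, McNemar, Cochran Q.

test_that("a perfect classifier scores 100 on all five metrics", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  s <- summarizeCriterion(truth, truth)
  expect_true(all(s$metrics == 100))
})

test_that("counts reconstructed from printed SN/SP reproduce the printed accuracy/PPV/NPV", {
  t1row <- countsFromPrinted(90, 88, 60, 50)
  expect_identical(unname(t1row$counts), c(54L, 6L, 44L, 6L))
  expect_identical(unname(t1row$display),
                   c(90, 88, 89, 90, 88))
  t2row <- countsFromPrinted(48, 86, 60, 50)
  expect_identical(unname(t2row$counts[c("TP", "TN")]), c(29L, 43L))
  expect_identical(unname(t2row$display[c("ppv", "npv")]), c(81, 58))
})

test_that("Bayes identities: PPV/NPV from SN, SP and class sizes equal count-based values", {
  set.seed(5)
  for (i in 1:20) {
    truth <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.55, 0.45))
    dec <- ifelse(truth, runif(40) < 0.8, runif(40) < 0.15)
    s <- summarizeCriterion(dec, truth)
    sn <- unname(s$metrics["sensitivity"]) / 100
    sp <- unname(s$metrics["specificity"]) / 100
    np <- sum(truth); nn <- sum(!truth)
    ppv <- 100 * sn * np / (sn * np + (1 - sp) * nn)
    npv <- 100 * sp * nn / (sp * nn + (1 - sn) * np)
    expect_equal(unname(s$metrics["ppv"]), ppv)
    expect_equal(unname(s$metrics["npv"]), npv)
    acc <- 100 * (sn * np + sp * nn) / (np + nn)
    expect_equal(unname(s$metrics["accuracy"]), acc)
  }
})

test_that("any-k-of-n combination matches brute-force counting and handles NA", {
  a <- c(TRUE, FALSE); grid <- expand.grid(a = a, b = a, c = a)
  any2 <- combineCriteria(grid, 2)
  expect_identical(as.logical(any2), rowSums(grid) >= 2)
  all3 <- combineCriteria(grid, 3)
  expect_identical(as.logical(all3), rowSums(grid) == 3)
  # OR of a criterion with itself is the criterion
  x <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_identical(as.logical(combineCriteria(list(x, x), 1)), x)
  expect_error(combineCriteria(grid, 4), "k must be")
  expect_error(combineCriteria(grid, 0), "k must be")
  withNA <- data.frame(a = c(TRUE, NA), b = c(TRUE, TRUE))
  expect_message(cc <- combineCriteria(withNA, 1), "dropped")
  expect_identical(as.logical(cc), c(TRUE, NA))
  expect_identical(attr(cc, "nDropped"), 1L)
})

test_that("OR raises sensitivity, AND raises specificity, on random decision pairs", {
  set.seed(6)
  for (i in 1:15) {
    truth <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    d1 <- runif(30) < ifelse(truth, 0.7, 0.2)
    d2 <- runif(30) < ifelse(truth, 0.6, 0.1)
    sOr <- summarizeCriterion(combineCriteria(list(d1, d2), 1), truth)
    sAnd <- summarizeCriterion(combineCriteria(list(d1, d2), 2), truth)
    s1 <- summarizeCriterion(d1, truth); s2 <- summarizeCriterion(d2, truth)
    expect_gte(sOr$metrics["sensitivity"],
               max(s1$metrics["sensitivity"], s2$metrics["sensitivity"]))
    expect_gte(sAnd$metrics["specificity"],
               max(s1$metrics["specificity"], s2$metrics["specificity"]))
  }
})

test_that("rank AUC matches the pair-counting oracle, including ties", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(rocAuc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)), 0.75)
  # one tied cross-class pair among 2x2 subjects contributes 0.5/4
  expect_equal(rocAuc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE)),
               (1 + 0.5 + 1 + 1) / 4)
  expect_warning(a <- rocAuc(rep(1, 6), rep(c(TRUE, FALSE), 3)), "constant")
  expect_equal(a, 0.5)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "per class")
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(1:8, n, replace = TRUE)  # many ties
    expect_equal(rocAuc(scores, truth), aucPairOracle(scores, truth))
  }
})

test_that("DeLong comparison matches the direct-summation oracle and pROC", {
  set.seed(8)
  truth <- rep(c(TRUE, FALSE), each = 10)
  sa <- rnorm(20) + truth * 1.2
  sb <- 0.5 * sa + rnorm(20, sd = 0.8)
  mine <- delongCompare(sa, sb, truth)
  oracle <- delongDirectOracle(sa, sb, truth)
  expect_equal(mine$aucA, oracle$aucA)
  expect_equal(mine$aucB, oracle$aucB)
  expect_equal(mine$z, oracle$z, tolerance = 1e-10)

  skip_if_not_installed("pROC")
  ra <- pROC::roc(truth, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(truth, sb, quiet = TRUE, direction = "<")
  pr <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(mine$p, pr$p.value, tolerance = 1e-8)
})

test_that("DeLong degenerate and sign behaviors", {
  truth <- rep(c(TRUE, FALSE), each = 8)
  s <- rnorm(16) + truth
  same <- delongCompare(s, s, truth)
  expect_identical(same$z, 0)
  expect_identical(same$p, 1)
  # better separation on A gives positive z
  set.seed(9)
  a <- truth * 3 + rnorm(16, sd = 0.1)
  b <- truth * 0.3 + rnorm(16, sd = 1)
  cmp <- delongCompare(a, b, truth)
  expect_gt(cmp$aucA, cmp$aucB)
  expect_gt(cmp$z, 0)
})

test_that("McNemar: exact binomial on small discordance, chi-square on large", {
  ex <- mcnemarTest(c(rep(TRUE, 5), rep(FALSE, 1), rep(TRUE, 10)),
                    c(rep(FALSE, 5), rep(TRUE, 1), rep(TRUE, 10)))
  expect_identical(ex$method, "exact")
  expect_equal(ex$p, 0.21875)  # 2 * P(X <= 1 | n = 6, p = 1/2)

  eq <- mcnemarTest(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_equal(eq$p, 1)
  none <- mcnemarTest(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(none$p, 1)

  # large discordance: exact and continuity-corrected chi-square agree closely,
  # and the chi-square branch matches stats::mcnemar.test
  a <- c(rep(TRUE, 40), rep(FALSE, 60))
  b <- c(rep(FALSE, 40), rep(TRUE, 60))
  big <- mcnemarTest(a, b)
  expect_identical(big$method, "chi-square")
  exact <- mcnemarTest(a, b, exactLimit = 1000)
  expect_lt(abs(big$p - exact$p), 0.01)
  ref <- stats::mcnemar.test(table(a, b))
  expect_equal(big$p, ref$p.value)
})

test_that("Cochran's Q: identities, k = 2 reduction, direct-formula oracle", {
  m <- cbind(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1)) == 1
  expect_equal(cochranQ(m)$Q, 0)
  expect_equal(cochranQ(m)$p, 1)

  set.seed(10)
  for (i in 1:10) {
    m2 <- matrix(runif(40) < 0.5, 20, 2)
    q <- cochranQ(m2)
    b10 <- sum(m2[, 1] & !m2[, 2]); b01 <- sum(!m2[, 1] & m2[, 2])
    if (b10 + b01 > 0) {
      expect_equal(q$Q, (b10 - b01)^2 / (b10 + b01))
      ref <- stats::mcnemar.test(table(m2[, 1], m2[, 2]), correct = FALSE)
      expect_equal(q$Q, unname(ref$statistic))
    }
    m3 <- matrix(runif(60) < 0.5, 20, 3)
    expect_equal(cochranQ(m3)$Q, cochranQOracle(m3), tolerance = 1e-12)
  }
})

test_that("non-evaluable subjects are excluded from the summary arms", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  dec <- truth
  dec[11:15] <- NA  # five controls not evaluable
  s <- summarizeCriterion(dec, truth)
  expect_identical(unname(s$n["controls"]), 5L)
  expect_identical(unname(s$n["patients"]), 10L)
})
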
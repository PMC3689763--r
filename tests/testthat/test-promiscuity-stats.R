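# Correlation, KS, regression and summary statistics.

test_that("perfect linear relation gives r = 1 with vanishing P", {
  rep1 <- correlatePromiscuity(1:20, (1:20) * 2 + 1)
  expect_equal(rep1@r, 1, tolerance = 1e-12)
  expect_lt(rep1@pValue, 1e-12)
  expect_error(correlatePromiscuity(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlatePromiscuity(1:2, 1:2), "at least 3")
})

test_that("correlation is symmetric and scale invariant without transform", {
  set.seed(61)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  a <- correlatePromiscuity(x, y)
  b <- correlatePromiscuity(y, x)
  expect_equal(a@r, b@r, tolerance = 1e-12)
  expect_equal(a@pValue, b@pValue, tolerance = 1e-12)
  c2 <- correlatePromiscuity(10 * x + 3, y)
  expect_equal(a@r, c2@r, tolerance = 1e-12)
})

test_that("sqrt transform is applied to y before correlating", {
  set.seed(62)
  x <- 3:40
  y <- (0.8 * x + rnorm(length(x)))^2
  rep1 <- correlatePromiscuity(x, y, "sqrt")
  expect_equal(rep1@r, cor(x, sqrt(y)), tolerance = 1e-12)
  expect_error(correlatePromiscuity(x, y - max(y) - 1, "sqrt"),
               "non-negative")
  # sqrt of the full pair count is strictly increasing in n
  n <- 3:20
  expect_true(all(diff(sqrt(choose(n, 2))) > 0))
})

test_that("t-based P-value matches a permutation oracle", {
  set.seed(63)
  n <- 30
  x <- rnorm(n)
  y <- 0.35 * x + rnorm(n, sd = 1)
  rep1 <- correlatePromiscuity(x, y)
  nPerm <- 20000
  robs <- abs(cor(x, y))
  perm <- replicate(nPerm, abs(cor(x, y[sample.int(n)])))
  pPerm <- (1 + sum(perm >= robs)) / (nPerm + 1)
  se <- sqrt(pPerm * (1 - pPerm) / nPerm)
  expect_lt(abs(rep1@pValue - pPerm), 4 * se + 2 / nPerm)
})

test_that("KS comparison: identical, disjoint and oracle-checked samples", {
  same <- c(1, 2, 3, 4, 5)
  r0 <- ksCompare(same, same)
  expect_equal(r0$D, 0)
  r1 <- ksCompare(c(0, 0, 0), c(1, 1, 1))
  expect_equal(r1$D, 1)
  expect_error(ksCompare(numeric(0), 1:3), "empty")
  # D equals a direct ECDF sup-difference scan
  set.seed(64)
  a <- rnorm(37); b <- rnorm(53, mean = 0.4)
  grid <- sort(c(a, b))
  oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(ksCompare(a, b)$D, oracle, tolerance = 1e-12)
})

test_that("KS null rejection rate is calibrated at alpha = 0.05", {
  set.seed(65)
  rej <- mean(replicate(600, {
    ksCompare(rnorm(80), rnorm(80))$pValue <= 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("regression: exact fit, null fit, and degenerate designs", {
  set.seed(66)
  n <- 40
  tab <- data.frame(
    logp = rnorm(n), mw = runif(n, 100, 600),
    conformer_cluster_count = sample(1:5, n, TRUE),
    rotatable_rel = runif(n), rotatable_abs = sample(0:10, n, TRUE))
  tab$target_count <- 2 + 0.5 * tab$logp - 0.01 * tab$mw +
    1.5 * tab$conformer_cluster_count + 3 * tab$rotatable_rel +
    0.2 * tab$rotatable_abs
  fit <- suppressWarnings(regressCombined(tab))  # lm warns on exact fits
  expect_equal(fit$rSquared, 1, tolerance = 1e-9)
  # response independent of the predictors: R^2 near zero
  tab$target_count <- rnorm(n)
  fit0 <- regressCombined(tab)
  expect_lt(fit0$rSquared, 0.35)
  # closed-form OLS oracle on the same data
  X <- cbind(1, as.matrix(tab[, c("logp", "mw", "conformer_cluster_count",
                                  "rotatable_rel", "rotatable_abs")]))
  beta <- solve(crossprod(X), crossprod(X, tab$target_count))
  expect_equal(unname(fit0$coefficients),
               unname(beta[, 1])[c(1, 2, 3, 4, 5, 6)], tolerance = 1e-8)
  expect_error(regressCombined(tab[1:4, ]), "at least")
  tab$rotatable_abs <- tab$rotatable_rel * 2   # collinear
  expect_error(regressCombined(tab), "collinear")
})

test_that("table assembly: counts, exclusions, missing data policy", {
  degrees <- data.frame(drug = c("D1", "D2", "D3"), degree = c(4, 2, 3))
  pv <- data.frame(
    drug = c(rep("D1", 6), rep("D3", 3)),
    similar = c(rep(TRUE, 6), TRUE, FALSE, FALSE),
    tm_score = c(rep(0.7, 6), 0.4, 0.6, 0.3))
  conf <- data.frame(drug = c("D1", "D3"), conformer_clusters = c(2, 1))
  desc <- data.frame(drug = c("D1", "D2", "D3"), mw = c(300, 200, 450),
                     logp = c(1.2, NA, 3.3), rotatable_abs = c(3, 1, 5),
                     rotatable_rel = c(0.2, 0.1, 0.3))
  tab <- buildPromiscuityTable(degrees, pv, conf, desc)
  expect_equal(nrow(tab), 2)              # degree-2 drug is excluded
  expect_equal(tab$similar_pair_count[tab$drug == "D1"], 6)
  expect_equal(tab$structural_similar_pair_count[tab$drug == "D3"], 0)
  expect_true(is.na(tab$logp[tab$drug == "D3"]) == FALSE)
  # unknown drug in the verdicts is an error naming the orphan
  bad <- rbind(pv, data.frame(drug = "ZZ", similar = TRUE, tm_score = 0.5))
  expect_error(buildPromiscuityTable(degrees, bad, conf, desc), "ZZ")
})

test_that("drug-centric summary fractions and top table", {
  tab <- data.frame(
    drug = paste0("D", 1:100),
    target_count = rep(c(3, 4), 50),
    similar_pair_count = c(rep(1, 71), rep(0, 29)),
    possible_pairs = choose(rep(c(3, 4), 50), 2),
    stringsAsFactors = FALSE)
  sm <- summarizeDrugs(tab)
  expect_equal(sm$fractionWithSimilar, 0.71)
  expect_equal(sm$fractionAllSimilar, 0)
  tab$similar_pair_count <- tab$possible_pairs
  sm2 <- summarizeDrugs(tab)
  expect_equal(sm2$fractionWithSimilar, 1)
  expect_equal(sm2$fractionAllSimilar, 1)
  tab$similar_pair_count <- 0
  sm3 <- summarizeDrugs(tab)
  expect_equal(sm3$fractionWithSimilar, 0)
  # identity quantiles appear when pair identities are supplied
  ids <- data.frame(drug = rep("D2", 4), identity_pct = c(10, 20, 30, 80))
  tab$similar_pair_count[2] <- 4
  sm4 <- summarizeDrugs(tab, pairIdentities = ids)
  row <- sm4$topBySimilar[sm4$topBySimilar$drug == "D2", ]
  expect_equal(row$id_min, 10)
  expect_equal(row$id_max, 80)
  expect_equal(row$id_mean, 35)
})
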
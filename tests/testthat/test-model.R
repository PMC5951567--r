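test_that("rank AUC matches exhaustive pair counting with ties", {
  set.seed(50)
  for (i in 1:10) {
    pos <- rep(c(TRUE, FALSE), c(15, 15))
    x <- sample(1:8, 30, replace = TRUE) + rnorm(30, sd = 0.01 * (i %% 2))
    expect_equal(aucRank(x, pos), oracleAuc(x, pos), tolerance = 1e-12)
  }
  expect_equal(aucRank(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_error(aucRank(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("AUC is antisymmetric under score negation", {
  set.seed(51)
  x <- rnorm(40)
  pos <- rep(c(TRUE, FALSE), 20)
  expect_equal(aucRank(x, pos) + aucRank(-x, pos), 1)
})

test_that("univariate screening: separation, null behavior, Bonferroni", {
  set.seed(52)
  n <- 2000
  tab <- data.frame(label = rep(c("benign", "malignant"), each = n),
                    sep = rep(c(0, 10), each = n) + runif(2 * n),
                    null1 = rnorm(2 * n), null2 = rnorm(2 * n))
  scr <- univariateScreen(tab, features = c("sep", "null1", "null2"))
  expect_equal(scr$auc[scr$feature == "sep"], 1)
  expect_true(all(scr$auc[scr$feature != "sep"] > 0.47 &
                    scr$auc[scr$feature != "sep"] < 0.53))
  expect_equal(scr$p_bonferroni, pmin(1, 3 * scr$p))
  expect_true(all(diff(scr$p_bonferroni[order(scr$p)]) >= 0))
})

test_that("Spearman matrix matches the midrank oracle", {
  set.seed(53)
  x <- rnorm(30)
  tab <- data.frame(label = rep(c("benign", "malignant"), 15),
                    a = x, b = 2 * x + 1, c = -x^3, d = rnorm(30))
  rho <- spearmanMatrix(tab, features = c("a", "b", "c", "d"))
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  m <- matrix(rnorm(50), 10, 5)
  tab2 <- data.frame(label = rep("benign", 10), m)
  rho2 <- spearmanMatrix(tab2, features = colnames(tab2)[-1])
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(rho2[i, j], oracleSpearman(m[, i], m[, j]), tolerance = 1e-12)
  # constant column flagged undefined and reported 0
  tab2$X1 <- 5
  rho3 <- spearmanMatrix(tab2, features = colnames(tab2)[2:6])
  expect_equal(rho3["X1", "X2"], 0)
  expect_true(attr(rho3, "undefined")["X1", "X2"])
})

test_that("stability selection contracts: threshold, determinism, scaling", {
  set.seed(54)
  n <- 40
  tab <- data.frame(label = rep(c("benign", "malignant"), each = n))
  tab$good <- c(rnorm(n), rnorm(n, 2))
  for (j in 1:4) tab[[paste0("noise", j)]] <- rnorm(2 * n)
  feats <- setdiff(names(tab), "label")
  s1 <- lassoStabilitySelect(tab, features = feats, runs = 15, seed = 2)
  s2 <- lassoStabilitySelect(tab, features = feats, runs = 15, seed = 2)
  expect_identical(selectionFrequencies(s1), selectionFrequencies(s2))
  sEmpty <- lassoStabilitySelect(tab, features = feats, runs = 5,
                                 freqThreshold = 1.01, seed = 2)
  expect_identical(selectedFeatures(sEmpty), character(0))
  # affine rescaling of a feature leaves frequencies unchanged
  tab2 <- tab
  tab2$good <- 1000 * tab2$good + 5
  s3 <- lassoStabilitySelect(tab2, features = feats, runs = 15, seed = 2)
  expect_equal(selectionFrequencies(s3), selectionFrequencies(s1))
  # degenerate class balance
  expect_error(lassoStabilitySelect(tab[c(1:5, 41:60), ], features = feats),
               "degenerate class balance")
})

test_that("final logistic model recovers known coefficients", {
  set.seed(55)
  reps <- 40
  cover <- 0
  for (r in 1:reps) {
    n <- 5000
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    eta <- 1 * x1 - 0.5 * x2
    y <- runif(n) < plogis(eta)
    tab <- data.frame(label = ifelse(y, "malignant", "benign"),
                      x1 = x1, x2 = x2)
    m <- fitFinalModel(tab, c("x1", "x2"))
    # Wald standard errors recovered from the two-sided p-values
    se1 <- abs(m@coefficients["x1"] / stats::qnorm(m@pValues["x1"] / 2,
                                                   lower.tail = FALSE))
    se2 <- abs(m@coefficients["x2"] / stats::qnorm(m@pValues["x2"] / 2,
                                                   lower.tail = FALSE))
    bRaw <- m@coefficients[-1] / m@scale
    seRaw <- c(se1, se2) / m@scale
    okCover <- (1 >= bRaw[1] - 1.96 * seRaw[1] &&
                1 <= bRaw[1] + 1.96 * seRaw[1]) &&
               (-0.5 >= bRaw[2] - 1.96 * seRaw[2] &&
                -0.5 <= bRaw[2] + 1.96 * seRaw[2])
    cover <- cover + okCover
    if (r == 1) {
      p <- predictClassifier(m, tab)
      expect_true(all(p > 0 & p < 1))
      expect_true(all(m@pValues[-1] < 0.01))
    }
  }
  expect_gte(cover / reps, 0.9)
})

test_that("perfect separation raises an error naming the feature", {
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 30),
                    x = c(rnorm(30, 0, 0.1), rnorm(30, 10, 0.1)),
                    z = rnorm(60))
  expect_error(fitFinalModel(tab, c("x", "z")), "separation.*'x'")
  # ridge fallback produces a finite usable model
  m <- fitFinalModel(tab, c("x", "z"), onSeparation = "ridge")
  expect_true(all(is.finite(m@coefficients)))
  p <- predictClassifier(m, tab)
  expect_gt(aucRank(p, tab$label), 0.99)
  expect_error(fitFinalModel(tab, character(0)), "empty")
})
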
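test_that("Youden cutoff: analytic example, ties, brute-force agreement", {
  y <- youdenCutoff(c(0.1, 0.2, 0.8, 0.9),
                    c("benign", "benign", "malignant", "malignant"))
  expect_equal(y$cutoff, 0.5)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  yAll <- youdenCutoff(rep(0.3, 10), rep(c("benign", "malignant"), 5))
  expect_equal(yAll$youdenJ, 0)
  expect_equal(yAll$sensitivity + yAll$specificity, 1)
  set.seed(60)
  for (i in 1:8) {
    scores <- round(runif(30), 2)
    pos <- runif(30) < 0.5
    if (!any(pos) || all(pos)) next
    got <- youdenCutoff(scores, pos)
    want <- oracleYouden(scores, pos)
    expect_equal(got$youdenJ, unname(want["J"]), tolerance = 1e-12)
  }
  expect_error(youdenCutoff(1:3, rep("malignant", 3)), "non-empty")
})

test_that("optimism correction: identity, determinism, null calibration", {
  set.seed(61)
  n <- 120
  tab <- data.frame(label = rep(c("benign", "malignant"), each = n))
  for (j in 1:8) tab[[paste0("f", j)]] <- rnorm(2 * n)
  tab$f1 <- tab$f1 + rep(c(0, 0.6), each = n)
  proc <- fixedModelProcedure(paste0("f", 1:8))
  r1 <- optimismCorrectedAuc(tab, proc, B = 40, seed = 5)
  r2 <- optimismCorrectedAuc(tab, proc, B = 40, seed = 5)
  expect_equal(correctedAuc(r1), apparentAuc(r1) - optimism(r1))
  expect_identical(correctedAuc(r1), correctedAuc(r2))
  expect_error(optimismCorrectedAuc(tab, proc, B = 0), "B must be")
  # a procedure with selection has positive optimism on average
  set.seed(62)
  opts <- replicate(10, {
    null <- data.frame(label = rep(c("benign", "malignant"), each = 60))
    for (j in 1:6) null[[paste0("g", j)]] <- rnorm(120)
    optimism(optimismCorrectedAuc(null, fixedModelProcedure(paste0("g", 1:6)),
                                  B = 20, seed = sample(1e6, 1)))
  })
  expect_gt(mean(opts), 0)
})

test_that("ablation analysis: row count, full-model consistency, dominance", {
  set.seed(63)
  n <- 100
  tab <- data.frame(label = rep(c("benign", "malignant"), each = n))
  tab$strong <- c(rnorm(n), rnorm(n, 2))
  tab$weak1 <- c(rnorm(n), rnorm(n, 0.3))
  tab$weak2 <- c(rnorm(n), rnorm(n, 0.2))
  sel <- c("strong", "weak1", "weak2")
  ab <- ablationAnalysis(tab, sel, B = 20, seed = 7)
  expect_identical(nrow(ab), length(sel) + 1L)
  full <- optimismCorrectedAuc(tab, fixedModelProcedure(sel), B = 20, seed = 7)
  expect_equal(ab$corrected_auc[ab$removed == "(full model)"],
               correctedAuc(full))
  drops <- ab$corrected_auc[match(sel, ab$removed)]
  expect_identical(sel[which.min(drops)], "strong")
  expect_error(ablationAnalysis(tab, "strong", B = 5), "at least 2")
})

test_that("subset analysis filters on the closed size interval", {
  set.seed(64)
  n <- 150
  tab <- data.frame(label = rep(c("benign", "malignant"), each = n),
                    size_mm = runif(2 * n, 7, 30))
  ## stronger effect inside 7-15 mm than outside
  small <- tab$size_mm <= 15
  tab$f <- rnorm(2 * n) +
    ifelse(tab$label == "malignant", ifelse(small, 2.5, 0.6), 0)
  tab$g <- rnorm(2 * n)
  proc <- fixedModelProcedure(c("f", "g"))
  sub <- subsetAnalysis(tab, c(7, 15), proc, B = 20, seed = 8)
  comp <- subsetAnalysis(tab, c(15.0000001, 30), proc, B = 20, seed = 8)
  expect_gt(correctedAuc(sub), correctedAuc(comp))
  allRange <- subsetAnalysis(tab, c(0, 100), proc, B = 20, seed = 8)
  direct <- optimismCorrectedAuc(tab, proc, B = 20, seed = 8)
  expect_equal(correctedAuc(allRange), correctedAuc(direct))
  oneClass <- tab[tab$label == "malignant" | tab$size_mm > 40, ]
  expect_error(subsetAnalysis(oneClass, c(7, 15), proc), "single class")
})

test_that("validation report fields are populated and consistent", {
  set.seed(65)
  n <- 80
  tab <- data.frame(label = rep(c("benign", "malignant"), each = n),
                    x = c(rnorm(n), rnorm(n, 1)), y = rnorm(2 * n))
  rep <- optimismCorrectedAuc(tab, fixedModelProcedure(c("x", "y")),
                              B = 25, seed = 11)
  expect_true(rep@sensitivity >= 0 && rep@sensitivity <= 1)
  expect_true(rep@specificity >= 0 && rep@specificity <= 1)
  expect_identical(rep@B, 25L)
  expect_identical(rep@n, nrow(tab))
  expect_output(show(rep), "corrected AUC")
})
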
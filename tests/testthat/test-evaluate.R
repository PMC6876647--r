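test_that("confusion-matrix metrics match direct evaluation", {
  m <- confusionMetrics(TP = 84, FN = 16, TN = 78, FP = 22)
  expect_equal(unname(m["sensitivity"]), 0.84)
  expect_equal(unname(m["specificity"]), 0.78)
  expect_equal(unname(m["PPV"]), 84 / 106)
  expect_equal(unname(m["NPV"]), 78 / 94)
  expect_equal(unname(m["accuracy"]), 0.81)

  perfect <- confusionMetrics(TP = 10, TN = 10, FP = 0, FN = 0)
  expect_equal(unname(perfect), rep(1, 5))

  expect_warning(u <- confusionMetrics(TP = 0, FN = 0, TN = 5, FP = 5),
                 "sensitivity undefined")
  expect_true(is.na(u["sensitivity"]))
  expect_equal(unname(u["specificity"]), 0.5)

  expect_error(confusionMetrics(0, 0, 0, 0), "all counts are zero")
  expect_error(confusionMetrics(-1, 1, 1, 1), "nonnegative")
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and specificity", {
  set.seed(20)
  for (rep in 1:20) {
    cts <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))
    m <- suppressWarnings(confusionMetrics(cts[1], cts[2], cts[3], cts[4]))
    P <- cts[1] + cts[4]; N <- cts[2] + cts[3]
    if (!anyNA(m[c("sensitivity", "specificity")]))
      expect_equal(unname(m["accuracy"]),
                   (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("AUC equals the pairwise-comparison oracle and its invariances", {
  lab <- rep(c("contraction", "non_contraction"), each = 5)
  expect_equal(aucScore(lab, c(6:10, 1:5)), 1)
  expect_equal(aucScore(lab, rep(0.5, 10)), 0.5)

  set.seed(21)
  labels <- sample(c("contraction", "non_contraction"), 200, replace = TRUE,
                   prob = c(0.4, 0.6))
  scores <- round(rnorm(200), 1)          # coarse scores force ties
  expect_equal(aucScore(labels, scores), oracleAUC(labels, scores))

  # invariant under strictly monotone transforms of the scores
  expect_equal(aucScore(labels, exp(scores)), aucScore(labels, scores))
  expect_equal(aucScore(labels, rank(scores)), aucScore(labels, scores))

  expect_error(aucScore(rep("contraction", 5), 1:5), "both classes")
})

test_that("fold repeatability test follows Kruskal-Wallis with conventions", {
  same <- foldRepeatability(rep(0.8, 20), rep(1:10, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # power: two groups five SDs apart are flagged nearly always
  hits <- sapply(1:100, function(s) {
    set.seed(300 + s)
    v <- c(rnorm(10), rnorm(10, mean = 5))
    foldRepeatability(v, rep(1:2, each = 10))$p.value < 0.01
  })
  expect_gte(mean(hits), 0.95)

  set.seed(22)
  v <- rnorm(30)
  g <- rep(1:3, each = 10)
  kt <- kruskal.test(v, factor(g))
  fr <- foldRepeatability(v, g)
  expect_equal(fr$statistic, unname(kt$statistic))
  expect_equal(fr$p.value, kt$p.value)

  expect_error(foldRepeatability(rnorm(10), rep(1, 10)), "2 groups")
  expect_error(foldRepeatability(rnorm(3), c(1, 2, 2)), "2 values per group")
})

test_that("channelReport aggregates fold metrics coherently", {
  set.seed(23)
  X <- as.data.frame(matrix(rnorm(60 * 24), 60, 24,
                            dimnames = list(NULL, featureNames())))
  lab <- rep(c("contraction", "non_contraction"), 30)
  X$SamEn <- rnorm(60) - 1.5 * (lab == "contraction")
  run <- runChannel(cbind(label = lab, X), k = 6, seed = 2)
  rep <- channelReport(run)
  expect_equal(nrow(rep$perFold), 6)
  expect_true(all(rep$mean >= 0 & rep$mean <= 1, na.rm = TRUE))
  expect_true(rep$repeatability$p.value >= 0 & rep$repeatability$p.value <= 1)
  expect_equal(unname(rep$mean["accuracy"]),
               mean(rep$perFold$accuracy, na.rm = TRUE))
})
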
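# random but labelled feature table in the package's column layout
randomFeatureTable <- function(n, seed = 1, signal = 0) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * 24), n, 24,
                            dimnames = list(NULL, featureNames())))
  label <- rep(c("contraction", "non_contraction"), length.out = n)
  if (signal > 0)
    X$Power <- X$Power + signal * (label == "contraction")
  cbind(label = label, X)
}

test_that("fold assignment is a stratified, deterministic partition", {
  labels <- rep(c("contraction", "non_contraction"), each = 136)
  f <- makeFolds(labels, k = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) %in% c(27, 28)))
  expect_equal(length(f), 272)                      # each row exactly once
  expect_identical(f, makeFolds(labels, k = 10, seed = 3))
  expect_false(identical(f, makeFolds(labels, k = 10, seed = 4)))

  small <- rep(c("contraction", "non_contraction"), 10)
  fs <- makeFolds(small, k = 10, seed = 1)
  tab <- table(fs, small)
  expect_true(all(tab == 1))                        # one per class per fold

  expect_error(makeFolds(small, k = 30), "more folds")
  expect_error(makeFolds(rep("contraction", 20), k = 10), "both classes")
})

test_that("a perfectly separating feature yields a depth-1 tree owning all importance", {
  tab <- randomFeatureTable(40, seed = 5)
  tab$Power <- ifelse(tab$label == "contraction", 1, -1) + rnorm(40, sd = 0.01)
  set.seed(1)
  fit <- trainCart(tab)
  expect_equal(nrow(fit$splits), 1)
  pred <- predict(fit, tab, type = "class")
  expect_equal(mean(pred == tab$label), 1)
  imp <- treeImportance(fit)
  expect_equal(unname(imp["Power"]), 1)
  expect_equal(sum(imp), 1)
  expect_true(all(imp[setdiff(featureNames(), "Power")] == 0))

  expect_error(trainCart(data.frame(label = rep("contraction", 10),
                                    RMS = rnorm(10))), "single class")
})

test_that("label-independent features give chance-level accuracy", {
  accs <- sapply(1:20, function(s) {
    tab <- randomFeatureTable(100, seed = 100 + s)
    run <- runChannel(tab, k = 10, seed = s)
    mean(run$oof$predicted == run$oof$label)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("duplicated feature columns share the original's importance mass", {
  tab <- randomFeatureTable(80, seed = 6, signal = 1.5)
  set.seed(2)
  base <- pruneBestLevel(trainCart(tab))$tree
  impBase <- treeImportance(base)

  dup <- tab
  dup$SamEn <- dup$Power                  # exact duplicate column
  set.seed(2)
  fit2 <- pruneBestLevel(trainCart(dup))$tree
  imp2 <- treeImportance(fit2)
  expect_equal(unname(imp2["Power"] + imp2["SamEn"]),
               unname(impBase["Power"] + impBase["SamEn"]),
               tolerance = 1e-10)
})

test_that("best-level pruning shrinks overfit trees and respects the 1-SE rule", {
  stumpTab <- randomFeatureTable(20, seed = 7)
  stumpTab[, featureNames()] <- 0        # nothing to split on
  set.seed(3)
  expect_warning(run <- runChannel(stumpTab, k = 4, seed = 1), "identical")
  expect_true(all(vapply(run$folds, `[[`, numeric(1), "bestLevel") == 0))
  expect_true(all(run$ranking$meanImportance == 0))

  shrunk <- sapply(1:20, function(s) {
    tab <- randomFeatureTable(50, seed = 200 + s)   # pure label noise
    set.seed(s)
    fit <- trainCart(tab, treeParams(minSamplesLeaf = 1))
    pr <- pruneBestLevel(fit)
    full <- sum(fit$frame$var == "<leaf>")
    kept <- sum(pr$tree$frame$var == "<leaf>")
    c(kept < full, pr$bestLevel >= 0,
      # chosen level's inner-CV error within 1 SE of the minimum
      fit$cptable[nrow(fit$cptable) - pr$bestLevel, "xerror"] <=
        min(fit$cptable[, "xerror"]) +
        fit$cptable[which.min(fit$cptable[, "xerror"]), "xstd"] + 1e-12)
  })
  expect_gte(mean(shrunk[1, ]), 0.8)
  expect_true(all(shrunk[2, ] == 1))
  expect_true(all(shrunk[3, ] == 1))

  # separable data: pruning never sacrifices training accuracy
  sep <- randomFeatureTable(40, seed = 8)
  sep$Power <- ifelse(sep$label == "contraction", 2, -2)
  set.seed(4)
  pr <- pruneBestLevel(trainCart(sep))
  expect_equal(mean(predict(pr$tree, sep, type = "class") == sep$label), 1)
})

test_that("runChannel produces coherent cross-validated outputs", {
  tab <- randomFeatureTable(60, seed = 9, signal = 2)
  run <- runChannel(tab, k = 10, seed = 11)

  expect_length(run$folds, 10)
  expect_identical(sort(run$oof$row), 1:60)         # every row predicted once
  expect_false(anyNA(run$oof$score))
  for (f in run$folds) {
    s <- sum(f$importances)
    expect_true(abs(s - 1) < 1e-9 || s == 0)
    expect_true(all(f$importances >= 0))
  }
  expect_equal(sort(run$ranking$feature), sort(featureNames()))
  expect_length(run$ranking$feature[run$ranking$top4], 4)
  expect_gte(run$avgBestLevel, 0)

  run2 <- runChannel(tab, k = 10, seed = 11)
  expect_identical(run$oof, run2$oof)               # seeded determinism
})

test_that("grouped fold assignment never splits a group", {
  labels <- rep(c("contraction", "non_contraction"), 30)
  groups <- rep(1:12, each = 5)
  f <- makeFolds(labels, k = 4, seed = 2, groups = groups)
  expect_equal(length(unique(f)), 4)
  for (g in unique(groups))
    expect_length(unique(f[groups == g]), 1)
  expect_identical(f, makeFolds(labels, k = 4, seed = 2, groups = groups))
  expect_error(makeFolds(labels, k = 20, seed = 1, groups = groups),
               "more folds")
})
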
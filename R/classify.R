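#' Stratified k-fold assignment
#'
#' Partitions rows into k folds of near-equal size, stratified by
#' label, deterministically for a fixed seed. When `groups` is given
#' (e.g. subject identifiers), whole groups are kept together in one
#' fold -- the grouped alternative to segment-level assignment, at the
#' cost of approximate stratification and size balance.
#'
#' @param labels character or factor vector of class labels (both
#'   classes must be present).
#' @param k number of folds.
#' @param seed integer seed.
#' @param groups optional grouping vector of the same length; rows
#'   sharing a group never land in different folds.
#' @return integer vector of fold indices (1..k), one per row.
#' @export
makeFolds <- function(labels, k = 10, seed = 1, groups = NULL) {
  n <- length(labels)
  if (k > n) stop("more folds (", k, ") than rows (", n, ")")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (!is.null(groups)) {
    stopifnot(length(groups) == n)
    ug <- unique(groups)
    if (k > length(ug))
      stop("more folds (", k, ") than groups (", length(ug), ")")
    set.seed(seed)
    # round-robin over shuffled groups, largest first, to balance sizes
    cnt <- table(groups)[as.character(ug)]
    ord <- sample(seq_along(ug))
    ord <- ord[order(-cnt[ord])]
    gfold <- integer(length(ug))
    load <- integer(k)
    for (g in ord) {
      f <- which.min(load)
      gfold[g] <- f
      load[f] <- load[f] + cnt[g]
    }
    return(gfold[match(groups, ug)])
  }
  set.seed(seed)
  fold <- integer(n)
  load <- integer(k)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    m <- length(idx)
    sizes <- rep(m %/% k, k)
    if (m %% k > 0) {
      # hand the leftovers to the currently least-filled folds so the
      # global fold sizes stay within one of each other
      ord <- sample(k)
      ord <- ord[order(load[ord])]
      sizes[ord[seq_len(m %% k)]] <- sizes[ord[seq_len(m %% k)]] + 1
    }
    load <- load + sizes
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  fold
}

#' Train a CART classification tree
#'
#' Binary recursive partitioning with axis-aligned threshold splits
#' minimizing Gini impurity (rpart), grown without a complexity
#' penalty (`cp = 0`) so the full cost-complexity pruning sequence is
#' available, with inner cross-validation error estimates recorded for
#' [pruneBestLevel()]. Competing and surrogate splits are disabled so
#' the tree's split table contains exactly the primary splits.
#'
#' @param data data.frame with a factor column `label` and numeric
#'   feature columns; training data must contain both classes.
#' @param params a [TreeParams-class].
#' @return an `rpart` object supporting class-probability prediction.
#' @export
trainCart <- function(data, params = treeParams()) {
  stopifnot(is(params, "TreeParams"), "label" %in% names(data))
  data$label <- factor(data$label)
  if (nlevels(data$label) < 2)
    stop("training data contains a single class")
  rpart::rpart(label ~ ., data = data, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(
                 minsplit = 2 * params@minSamplesLeaf,
                 minbucket = params@minSamplesLeaf,
                 cp = 0, xval = params@innerFolds,
                 maxdepth = params@maxDepth,
                 maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
}

#' Prune a tree at its best level
#'
#' Classic CART best-level pruning: the cost-complexity sequence
#' recorded by [trainCart()] carries an inner cross-validated error
#' (`xerror`) per pruning level; the chosen level is the smallest tree
#' whose error is within one standard error of the minimum (the 1-SE
#' rule). `bestLevel` counts pruning steps from the full tree, so 0
#' means the full tree was kept and larger values mean harder pruning.
#'
#' @param tree an `rpart` object from [trainCart()].
#' @return list with `tree` (the pruned rpart object) and `bestLevel`
#'   (integer >= 0; 0 for a stump input).
#' @export
pruneBestLevel <- function(tree) {
  cp <- tree$cptable
  if (is.null(cp) || nrow(cp) == 1)
    return(list(tree = tree, bestLevel = 0L))
  xerr <- cp[, "xerror"]
  thr <- min(xerr) + cp[which.min(xerr), "xstd"]
  chosen <- which(xerr <= thr)[1]      # rows ordered largest cp first
  pruned <- rpart::prune(tree, cp = cp[chosen, "CP"])
  list(tree = pruned, bestLevel = as.integer(nrow(cp) - chosen))
}

#' Gini importance of a (pruned) tree
#'
#' Per-feature total decrease in Gini impurity over the tree's primary
#' splits (each split's improvement is already weighted by the number
#' of observations reaching the node), normalized to sum to 1. A
#' feature never used in a split has importance 0; a stump returns all
#' zeros.
#'
#' @param tree an `rpart` object.
#' @param features character vector of feature names defining the
#'   output order (default [featureNames()]).
#' @return named numeric vector of importances.
#' @export
treeImportance <- function(tree, features = featureNames()) {
  out <- stats::setNames(numeric(length(features)), features)
  sp <- tree$splits
  if (is.null(sp) || nrow(sp) == 0) return(out)
  imp <- tapply(sp[, "improve"], rownames(sp), sum)
  known <- intersect(names(imp), features)
  out[known] <- imp[known]
  if (sum(out) > 0) out <- out / sum(out)
  out
}

#' Cross-validated CART run for one channel
#'
#' Runs the full per-channel procedure: stratified k-fold assignment,
#' per fold a CART tree trained on the remaining folds, pruned at its
#' best level, then evaluated on the held-out fold (class predictions
#' and contraction-probability scores), with Gini importances extracted
#' from each pruned tree. Importances are summarized as mean and SD
#' over folds and ranked.
#'
#' @param featTab data.frame from [featureTable()] (or the same layout)
#'   restricted to one channel: a `label` column plus the 24 feature
#'   columns; extra metadata columns are ignored.
#' @param k number of outer folds (default 10).
#' @param seed integer seed controlling fold assignment and the inner
#'   pruning cross-validation.
#' @param params a [TreeParams-class].
#' @return list with elements
#'   \describe{
#'     \item{folds}{per-fold list: foldIndex, bestLevel, importances,
#'       testIdx, predicted labels and scores.}
#'     \item{ranking}{data.frame feature/meanImportance/sdImportance,
#'       sorted decreasing, with the rank and top-4 flag.}
#'     \item{avgBestLevel}{mean best pruning level over folds.}
#'     \item{oof}{out-of-fold table: row index, fold, label, predicted,
#'       score (each row predicted exactly once).}
#'   }
#' @export
runChannel <- function(featTab, k = 10, seed = 1, params = treeParams()) {
  stopifnot("label" %in% names(featTab))
  feats <- intersect(featureNames(), names(featTab))
  if (!length(feats)) stop("no feature columns found")
  labels <- factor(featTab$label,
                   levels = c("non_contraction", "contraction"))
  if (anyNA(labels)) stop("labels must be contraction / non_contraction")
  X <- featTab[, feats, drop = FALSE]

  if (length(unique(X)) == 1 || all(vapply(X, function(col)
      length(unique(col)) == 1, logical(1))))
    warning("all feature rows identical; every fold will yield a stump")

  fold <- makeFolds(as.character(labels), k = k, seed = seed)
  folds <- vector("list", k)
  oof <- data.frame(row = seq_along(labels), fold = fold,
                    label = as.character(labels),
                    predicted = NA_character_, score = NA_real_)
  imp <- matrix(0, nrow = k, ncol = length(feats),
                dimnames = list(NULL, feats))
  bestLevels <- numeric(k)

  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    df <- cbind(label = labels[train], X[train, , drop = FALSE])
    set.seed(seed + f)           # inner-CV fold assignment in rpart
    fit <- trainCart(df, params)
    pr <- pruneBestLevel(fit)
    prob <- predict(pr$tree, newdata = X[test, , drop = FALSE],
                    type = "prob")[, "contraction"]
    pred <- ifelse(prob > 0.5, "contraction", "non_contraction")
    imp[f, ] <- treeImportance(pr$tree, feats)
    bestLevels[f] <- pr$bestLevel
    oof$predicted[test] <- pred
    oof$score[test] <- prob
    folds[[f]] <- list(foldIndex = f, bestLevel = pr$bestLevel,
                       importances = imp[f, ], testIdx = test,
                       predicted = pred, scores = prob)
  }

  ranking <- data.frame(feature = feats,
                        meanImportance = colMeans(imp),
                        sdImportance = apply(imp, 2, stats::sd))
  ranking <- ranking[order(-ranking$meanImportance), ]
  ranking$rank <- seq_len(nrow(ranking))
  ranking$top4 <- ranking$rank <= 4
  rownames(ranking) <- NULL

  list(folds = folds, ranking = ranking,
       avgBestLevel = mean(bestLevels), oof = oof)
}
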
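#' Component-disjoint train/test split of a pair set
#'
#' TFs and TGs are each partitioned independently at \code{trainFrac};
#' a pair lands in the training set only when both its TF and its TG are
#' training members (likewise for test), and pairs straddling the
#' partition are dropped and counted. If a side ends up without both
#' classes the split is redrawn with a derived seed, up to
#' \code{maxAttempts} times.
#'
#' @param pairs data.frame with \code{tf_id}, \code{tg_id} and
#'   \code{label}.
#' @param trainFrac fraction of TFs (and of TGs) assigned to training,
#'   default 0.8.
#' @param seed integer seed.
#' @param maxAttempts resampling attempts on a degenerate split.
#' @return list with \code{trainIdx}, \code{testIdx} (row indices into
#'   \code{pairs}), \code{trainTfs}, \code{trainTgs}, \code{testTfs},
#'   \code{testTgs}, \code{droppedCrossPairs}.
#' @export
componentDisjointSplit <- function(pairs, trainFrac = 0.8, seed = 1L,
                                   maxAttempts = 50L) {
  tfs <- unique(pairs$tf_id)
  tgs <- unique(pairs$tg_id)
  if (length(tfs) < 2L || length(tgs) < 2L)
    stop("need at least 2 TFs and 2 TGs to split")
  nTrTf <- round(trainFrac * length(tfs))
  nTrTg <- round(trainFrac * length(tgs))
  if (nTrTf >= length(tfs) || nTrTg >= length(tgs) || nTrTf < 1 ||
      nTrTg < 1)
    stop("trainFrac leaves an empty side")
  haveLabels <- all(c("correlated", "uncorrelated") %in% pairs$label)
  for (attempt in seq_len(maxAttempts)) {
    set.seed(as.integer((as.numeric(seed) + 7919 * (attempt - 1)) %%
                          2147483647))
    trainTfs <- sample(tfs, nTrTf)
    trainTgs <- sample(tgs, nTrTg)
    inTrain <- pairs$tf_id %in% trainTfs & pairs$tg_id %in% trainTgs
    inTest <- !(pairs$tf_id %in% trainTfs) & !(pairs$tg_id %in% trainTgs)
    ok <- if (haveLabels) {
      all(c("correlated", "uncorrelated") %in% pairs$label[inTrain]) &&
        all(c("correlated", "uncorrelated") %in% pairs$label[inTest])
    } else sum(inTrain) > 0 && sum(inTest) > 0
    if (ok)
      return(list(trainIdx = which(inTrain), testIdx = which(inTest),
                  trainTfs = trainTfs, trainTgs = trainTgs,
                  testTfs = setdiff(tfs, trainTfs),
                  testTgs = setdiff(tgs, trainTgs),
                  droppedCrossPairs = sum(!inTrain & !inTest)))
  }
  stop("no valid component-disjoint split with both classes on both ",
       "sides after ", maxAttempts, " attempts")
}

#' Undersample the majority class
#'
#' The minority class is kept intact; the majority class is sampled
#' without replacement down to the minority size. Applied to training
#' data only (test sets stay imbalanced).
#'
#' @param labels class labels.
#' @param seed integer seed.
#' @return integer indices of the balanced subset, in original order.
#' @export
undersampleMajority <- function(labels, seed = 1L) {
  set.seed(seed)
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  minor <- names(tab)[which.min(tab)]
  nMin <- min(tab)
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    if (cl == minor) idx else sample(idx, nMin)
  }))
  sort(keep)
}

#' Train the pair classifier
#'
#' Random Forest with the analysis defaults: 3000 trees, 5 candidate
#' variables per split (when not given, \code{round(0.5 *
#' sqrt(ncol(x)))}), and a minimal terminal-node size of 150 observations
#' (large nodes and few candidate variables deliberately limit
#' overfitting).
#'
#' @param x numeric feature matrix (training rows).
#' @param labels class labels (\code{correlated} treated as the positive
#'   class).
#' @param nTrees number of trees, default 3000.
#' @param varsPerSplit candidate variables per split (mtry).
#' @param minNode minimal terminal-node size, default 150.
#' @param seed integer seed.
#' @return list of class \code{regForest} with elements \code{rf},
#'   \code{features}, \code{positive}.
#' @export
trainForest <- function(x, labels, nTrees = 3000, varsPerSplit = NULL,
                        minNode = 150, seed = 1L) {
  if (is.null(varsPerSplit)) varsPerSplit <- round(0.5 * sqrt(ncol(x)))
  varsPerSplit <- max(1L, min(ncol(x), varsPerSplit))
  if (minNode > nrow(x))
    stop("minNode (", minNode, ") exceeds the training size (", nrow(x),
         ")")
  y <- factor(ifelse(labels == "correlated", "correlated",
                     "uncorrelated"),
              levels = c("uncorrelated", "correlated"))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = nTrees,
                                   mtry = varsPerSplit,
                                   nodesize = minNode)
  structure(list(rf = rf, features = colnames(x),
                 positive = "correlated"),
            class = "regForest")
}

#' Predicted probability of the positive (correlated) class
#' @param forest a \code{regForest} from [trainForest()].
#' @param x feature matrix.
#' @return numeric vector of probabilities.
#' @export
predictPairProb <- function(forest, x) {
  as.numeric(stats::predict(forest$rf, x, type = "prob")[,
                                                         forest$positive])
}

#' Tree structures of a trained forest
#'
#' Each tree as a data.frame with columns \code{left}, \code{right}
#' (child node row indices, 0 for terminal nodes) and \code{var} (the
#' split feature name, \code{NA} at leaves). Hand-built trees in this
#' format are accepted anywhere a forest's structure is traversed.
#'
#' @param forest a \code{regForest}.
#' @return list of data.frames.
#' @export
forestTrees <- function(forest) {
  lapply(seq_len(forest$rf$ntree), function(k) {
    tr <- randomForest::getTree(forest$rf, k, labelVar = TRUE)
    data.frame(left = tr[, "left daughter"],
               right = tr[, "right daughter"],
               var = as.character(tr[, "split var"]))
  })
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) ROC-AUC of scores against binary labels;
#' ties receive midranks.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param positive logical (or 0/1) vector marking positive cases.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes for ROC-AUC")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Precision-recall pairs are computed at every distinct score threshold
#' (descending) and integrated by the trapezoid rule over recall,
#' anchored at recall 0 with the precision of the highest-scoring group.
#'
#' @inheritParams rocAuc
#' @return PR-AUC in [0, 1].
#' @export
prAuc <- function(scores, positive) {
  positive <- as.logical(positive)
  nPos <- sum(positive)
  if (nPos == 0 || all(positive)) stop("need both classes for PR-AUC")
  o <- order(scores, decreasing = TRUE)
  y <- positive[o]
  s <- scores[o]
  cumTP <- cumsum(y)
  n <- seq_along(y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each threshold
  prec <- cumTP[last] / n[last]
  rec <- cumTP[last] / nPos
  rec <- c(0, rec)
  prec <- c(prec[1], prec)
  sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
}

#' Evaluate a forest on a test set
#' @param forest a \code{regForest}.
#' @param x test feature matrix.
#' @param labels test labels.
#' @return named numeric: \code{roc_auc}, \code{pr_auc}.
#' @export
evaluateForest <- function(forest, x, labels) {
  if (length(unique(labels)) < 2L)
    stop("test set must contain both classes")
  p <- predictPairProb(forest, x)
  pos <- labels == forest$positive
  c(roc_auc = rocAuc(p, pos), pr_auc = prAuc(p, pos))
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For each feature: the accuracy (0.5 probability cutoff) on the intact
#' test set minus the mean accuracy over \code{k} random permutations of
#' that feature's test column.
#'
#' @param forest a \code{regForest}.
#' @param x test feature matrix.
#' @param labels test labels.
#' @param k permutations per feature, default 5.
#' @param seed integer seed.
#' @return data.frame \code{feature}, \code{mda}.
#' @export
permutationImportance <- function(forest, x, labels, k = 5, seed = 1L) {
  set.seed(seed)
  pos <- labels == forest$positive
  acc <- function(m) mean((predictPairProb(forest, m) > 0.5) == pos)
  base <- acc(x)
  mda <- vapply(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(k), function(i) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      acc(xp)
    }, numeric(1))
    base - mean(drops)
  }, numeric(1))
  data.frame(feature = colnames(x), mda = mda)
}

# depth of every node of a tree table (root = 1, depth 0)
treeDepths <- function(tree) {
  depth <- rep(NA_real_, nrow(tree))
  depth[1] <- 0
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (ch in c(tree$left[i], tree$right[i])) {
      if (ch > 0) {
        depth[ch] <- depth[i] + 1
        queue <- c(queue, ch)
      }
    }
  }
  depth
}

# nodes of the subtree rooted at i (inclusive)
subtreeNodes <- function(tree, i) {
  out <- integer(0)
  queue <- i
  while (length(queue)) {
    j <- queue[1]; queue <- queue[-1]
    out <- c(out, j)
    for (ch in c(tree$left[j], tree$right[j])) if (ch > 0)
      queue <- c(queue, ch)
  }
  out
}

#' Conditional-depth feature interactions of a forest
#'
#' For an ordered feature pair (v, w): in every tree where v splits, take
#' v's split closest to the root; if w splits inside the subtree rooted
#' there (strictly below it), record the minimal depth of w measured from
#' that subtree's root. The pair's frequency is the number of trees with
#' such a pattern, its mean conditional depth the mean of the recorded
#' depths, and w's unconditional mean depth is the mean (over trees where
#' w splits) of w's minimal depth from the tree root. Frequent pairs with
#' small conditional relative to unconditional depth indicate
#' interaction.
#'
#' @param forest a \code{regForest} or a plain list of tree tables as
#'   returned by [forestTrees()].
#' @param topK report the most frequent pairs, default 30 (\code{Inf}
#'   for all).
#' @return data.frame \code{conditioning_feature}, \code{second_feature},
#'   \code{tree_frequency}, \code{mean_conditional_depth},
#'   \code{unconditional_mean_depth}.
#' @export
interactionDepths <- function(forest, topK = 30) {
  trees <- if (inherits(forest, "regForest")) forestTrees(forest) else
    forest
  condSum <- list(); condN <- list()
  uncondSum <- list(); uncondN <- list()
  addTo <- function(env, key, val) {
    cur <- env[[key]]
    if (is.null(cur)) cur <- 0
    cur + val
  }
  cond <- new.env(); condCnt <- new.env()
  uncond <- new.env(); uncondCnt <- new.env()
  for (tree in trees) {
    splitNodes <- which(!is.na(tree$var) & tree$var != "")
    if (!length(splitNodes)) next
    depth <- treeDepths(tree)
    vars <- unique(tree$var[splitNodes])
    minDepth <- vapply(vars, function(v)
      min(depth[splitNodes[tree$var[splitNodes] == v]]), numeric(1))
    for (v in vars) {
      uncond[[v]] <- addTo(uncond, v, minDepth[[v]])
      uncondCnt[[v]] <- addTo(uncondCnt, v, 1)
    }
    for (v in vars) {
      vNode <- splitNodes[tree$var[splitNodes] == v]
      vNode <- vNode[which.min(depth[vNode])]
      sub <- setdiff(subtreeNodes(tree, vNode), vNode)
      sub <- sub[!is.na(tree$var[sub]) & tree$var[sub] != ""]
      if (!length(sub)) next
      relDepth <- depth[sub] - depth[vNode]
      for (w in unique(tree$var[sub])) {
        key <- paste(v, w, sep = "\r")
        cond[[key]] <- addTo(cond, key,
                             min(relDepth[tree$var[sub] == w]))
        condCnt[[key]] <- addTo(condCnt, key, 1)
      }
    }
  }
  keys <- ls(cond, all.names = TRUE)
  if (!length(keys))
    return(data.frame(conditioning_feature = character(0),
                      second_feature = character(0),
                      tree_frequency = numeric(0),
                      mean_conditional_depth = numeric(0),
                      unconditional_mean_depth = numeric(0)))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  res <- data.frame(
    conditioning_feature = parts[, 1],
    second_feature = parts[, 2],
    tree_frequency = vapply(keys, function(k) condCnt[[k]], numeric(1)),
    mean_conditional_depth = vapply(keys, function(k)
      cond[[k]] / condCnt[[k]], numeric(1)),
    unconditional_mean_depth = vapply(parts[, 2], function(w)
      uncond[[w]] / uncondCnt[[w]], numeric(1)))
  res <- res[order(-res$tree_frequency, res$mean_conditional_depth), ]
  rownames(res) <- NULL
  head(res, topK)
}

#' Cross-validate the pair classifier
#'
#' Repeats of: component-disjoint 80/20 split, undersampling of the
#' majority class in training only, forest training, ROC/PR evaluation on
#' the (imbalanced) test set, test-set permutation importance, and
#' conditional-depth interaction extraction; interaction records and MDA
#' are averaged over repeats. With \code{baseline = TRUE} a
#' permuted-label arm is run on identical splits.
#'
#' @param x feature matrix (rows = pairs).
#' @param pairs data.frame with \code{tf_id}, \code{tg_id}, \code{label}
#'   aligned to the rows of \code{x}; only correlated/uncorrelated rows
#'   are used.
#' @param repeats number of repeats, default 20.
#' @param seed integer seed.
#' @param nTrees,varsPerSplit,minNode forest hyperparameters (see
#'   [trainForest()]).
#' @param trainFrac component split fraction, default 0.8.
#' @param mdaPermutations permutations per feature for MDA, default 5
#'   (0 skips importance).
#' @param interactions extract conditional-depth interactions (default
#'   TRUE).
#' @param topK interactions kept per repeat.
#' @param baseline also run the permuted-label arm (default FALSE).
#' @return a [CVResult-class].
#' @export
crossValidate <- function(x, pairs, repeats = 20, seed = 1L,
                          nTrees = 3000, varsPerSplit = 5, minNode = 150,
                          trainFrac = 0.8, mdaPermutations = 5,
                          interactions = TRUE, topK = 30,
                          baseline = FALSE) {
  keep <- pairs$label %in% c("correlated", "uncorrelated")
  x <- x[keep, , drop = FALSE]
  pairs <- pairs[keep, , drop = FALSE]
  aucs <- data.frame()
  base <- data.frame()
  mdaAcc <- NULL
  interAcc <- list()
  for (r in seq_len(repeats)) {
    rs <- as.integer((as.numeric(seed) * 1000 + r) %% 2147483647)
    sp <- componentDisjointSplit(pairs, trainFrac, seed = rs)
    stopifnot(length(intersect(sp$trainTfs, sp$testTfs)) == 0,
              length(intersect(sp$trainTgs, sp$testTgs)) == 0)
    trLab <- pairs$label[sp$trainIdx]
    bal <- sp$trainIdx[undersampleMajority(trLab, seed = rs)]
    # node size cannot exceed the balanced training size; scale it down
    # for small runs while keeping the configured value when it fits
    nodeUse <- min(minNode, max(1L, floor(length(bal) / 3)))
    if (nodeUse < minNode && r == 1L)
      message("minNode reduced to ", nodeUse, " for a training set of ",
              length(bal))
    fo <- trainForest(x[bal, , drop = FALSE], pairs$label[bal],
                      nTrees = nTrees, varsPerSplit = varsPerSplit,
                      minNode = nodeUse, seed = rs)
    ev <- evaluateForest(fo, x[sp$testIdx, , drop = FALSE],
                         pairs$label[sp$testIdx])
    aucs <- rbind(aucs, data.frame(
      repeat_id = r, roc_auc = ev["roc_auc"], pr_auc = ev["pr_auc"],
      n_train = length(bal), n_test = length(sp$testIdx),
      dropped_cross_pairs = sp$droppedCrossPairs))
    if (mdaPermutations > 0) {
      mda <- permutationImportance(fo, x[sp$testIdx, , drop = FALSE],
                                   pairs$label[sp$testIdx],
                                   k = mdaPermutations, seed = rs)
      mdaAcc <- if (is.null(mdaAcc)) mda$mda else mdaAcc + mda$mda
    }
    if (interactions)
      interAcc[[r]] <- interactionDepths(fo, topK = Inf)
    if (baseline) {
      set.seed(as.integer((rs + 31) %% 2147483647))
      permLab <- sample(pairs$label[bal])
      fb <- trainForest(x[bal, , drop = FALSE], permLab,
                        nTrees = nTrees, varsPerSplit = varsPerSplit,
                        minNode = nodeUse, seed = rs)
      evb <- evaluateForest(fb, x[sp$testIdx, , drop = FALSE],
                            pairs$label[sp$testIdx])
      base <- rbind(base, data.frame(
        repeat_id = r, roc_auc = evb["roc_auc"], pr_auc = evb["pr_auc"]))
    }
  }
  rownames(aucs) <- NULL
  if (nrow(base)) rownames(base) <- NULL
  mdaDf <- if (is.null(mdaAcc))
    data.frame(feature = character(0), mda = numeric(0)) else
      data.frame(feature = colnames(x), mda = mdaAcc / repeats)
  inter <- if (length(interAcc)) {
    all <- do.call(rbind, interAcc)
    key <- paste(all$conditioning_feature, all$second_feature, sep = "\r")
    agg <- function(col, f) vapply(split(all[[col]], key), f, numeric(1))
    freq <- agg("tree_frequency", sum)
    wmean <- vapply(split(seq_along(key), key), function(i)
      sum(all$mean_conditional_depth[i] * all$tree_frequency[i]) /
        sum(all$tree_frequency[i]), numeric(1))
    um <- agg("unconditional_mean_depth", mean)
    parts <- do.call(rbind, strsplit(names(freq), "\r", fixed = TRUE))
    out <- data.frame(conditioning_feature = parts[, 1],
                      second_feature = parts[, 2],
                      tree_frequency = freq / repeats,
                      mean_conditional_depth = wmean,
                      unconditional_mean_depth = um)
    out <- out[order(-out$tree_frequency, out$mean_conditional_depth), ]
    rownames(out) <- NULL
    head(out, topK)
  } else data.frame(conditioning_feature = character(0),
                    second_feature = character(0),
                    tree_frequency = numeric(0),
                    mean_conditional_depth = numeric(0),
                    unconditional_mean_depth = numeric(0))
  new("CVResult", aucs = aucs, mda = mdaDf, interactions = inter,
      baseline = base)
}
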
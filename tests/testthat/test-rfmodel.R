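bipartitePairs <- function(nTF = 10, nTG = 100) {
  p <- expand.grid(tf_id = sprintf("T%02d", seq_len(nTF)),
                   tg_id = sprintf("G%03d", seq_len(nTG)),
                   stringsAsFactors = FALSE)
  p$label <- "unlabeled"
  p
}

test_that("splits never share a TF or TG across the boundary", {
  p <- bipartitePairs()
  for (s in 1:10) {
    sp <- componentDisjointSplit(p, 0.8, seed = s)
    expect_length(intersect(sp$trainTfs, sp$testTfs), 0)
    expect_length(intersect(sp$trainTgs, sp$testTgs), 0)
    expect_true(all(p$tf_id[sp$trainIdx] %in% sp$trainTfs))
    expect_true(all(p$tg_id[sp$testIdx] %in% sp$testTgs))
    expect_equal(length(sp$trainIdx) + length(sp$testIdx) +
                   sp$droppedCrossPairs, nrow(p))
  }
  expect_error(componentDisjointSplit(p, 1.0, seed = 1), "empty side")
})

test_that("cross-pair loss on a complete bipartite set matches 32%", {
  p <- bipartitePairs()
  dropped <- vapply(1:50, function(s)
    componentDisjointSplit(p, 0.8, seed = s)$droppedCrossPairs / nrow(p),
    numeric(1))
  expect_lt(abs(mean(dropped) - 0.32), 0.05)
})

test_that("degenerate splits are redrawn and eventually error", {
  p <- bipartitePairs(4, 4)
  p$label <- "correlated"
  p$label[p$tf_id == "T01"] <- "uncorrelated"  # one TF holds a class
  expect_error(componentDisjointSplit(p[p$tf_id %in% c("T01", "T02"), ],
                                      0.5, seed = 1, maxAttempts = 3),
               "attempts")
})

test_that("undersampling balances classes without touching the minority", {
  labels <- rep(c("correlated", "uncorrelated"), c(100, 900))
  idx <- undersampleMajority(labels, seed = 1)
  expect_equal(as.integer(table(labels[idx])), c(100L, 100L))
  expect_true(all(which(labels == "correlated") %in% idx))
  idx2 <- undersampleMajority(labels, seed = 2)
  expect_equal(as.integer(table(labels[idx2])), c(100L, 100L))
  expect_false(identical(idx, idx2))  # membership differs across seeds
  bal <- rep(c("correlated", "uncorrelated"), 50)
  expect_equal(undersampleMajority(bal, seed = 1), seq_along(bal))
})

test_that("training is deterministic and separates a separable class", {
  set.seed(8)
  x <- cbind(sep = c(rnorm(150, 3), rnorm(150, -3)),
             noise = rnorm(300))
  labels <- rep(c("correlated", "uncorrelated"), each = 150)
  fo <- trainForest(x, labels, nTrees = 100, varsPerSplit = 1,
                    minNode = 20, seed = 3)
  acc <- mean((predictPairProb(fo, x) > 0.5) ==
                (labels == "correlated"))
  expect_gte(acc, 0.95)
  fo2 <- trainForest(x, labels, nTrees = 100, varsPerSplit = 1,
                     minNode = 20, seed = 3)
  expect_identical(predictPairProb(fo, x), predictPairProb(fo2, x))
  expect_error(trainForest(x, labels, minNode = 1000), "training size")
  # default candidate count follows round(0.5 * sqrt(p))
  expect_equal(trainForest(x, labels, nTrees = 5, minNode = 50,
                           seed = 1)$rf$mtry, round(0.5 * sqrt(2)))
})

test_that("ROC-AUC equals the Mann-Whitney identity and pROC", {
  set.seed(9)
  for (i in 1:10) {
    n <- 60
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + y
    u <- unname(wilcox.test(s[y == 1], s[y == 0],
                            exact = FALSE)$statistic)
    expect_equal(rocAuc(s, y), u / (sum(y) * sum(1 - y)),
                 tolerance = 1e-12)
    expect_equal(rocAuc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
})

test_that("perfect and random scores give the expected AUCs", {
  y <- rep(c(1, 0), c(20, 80))
  s <- rep(c(1, 0), c(20, 80))
  expect_equal(rocAuc(s, y), 1)
  expect_equal(prAuc(s, y), 1)
  set.seed(10)
  sc <- runif(50000); yy <- rbinom(50000, 1, 0.08)
  expect_lt(abs(rocAuc(sc, yy) - 0.5), 0.02)
  expect_lt(abs(prAuc(sc, yy) - 0.08), 0.01)
})

test_that("permutation importance ranks the informative feature first", {
  set.seed(11)
  n <- 600
  x <- cbind(info = c(rnorm(n / 2, 1.5), rnorm(n / 2)),
             flat = rep(1, n),
             n1 = rnorm(n), n2 = rnorm(n))
  labels <- rep(c("correlated", "uncorrelated"), each = n / 2)
  fo <- trainForest(x, labels, nTrees = 200, varsPerSplit = 2,
                    minNode = 30, seed = 4)
  mda <- permutationImportance(fo, x, labels, k = 5, seed = 5)
  expect_equal(mda$feature[which.max(mda$mda)], "info")
  expect_equal(mda$mda[mda$feature == "flat"], 0)
})

test_that("conditional depths equal hand-traced values on fixture trees", {
  # root splits v; its left child splits w; right child is a leaf
  t1 <- handTree(left = c(2, 4, 0, 0, 0), right = c(3, 5, 0, 0, 0),
                 var = c("v", "w", NA, NA, NA))
  r1 <- interactionDepths(list(t1), topK = Inf)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$conditioning_feature, "v")
  expect_equal(r1$second_feature, "w")
  expect_equal(r1$tree_frequency, 1)
  expect_equal(r1$mean_conditional_depth, 1)
  expect_equal(r1$unconditional_mean_depth, 1)
  # w above v: (w, v) recorded, (v, w) absent
  t2 <- handTree(left = c(2, 4, 0, 0, 0), right = c(3, 5, 0, 0, 0),
                 var = c("w", "v", NA, NA, NA))
  r2 <- interactionDepths(list(t1, t2), topK = Inf)
  key <- paste(r2$conditioning_feature, r2$second_feature)
  expect_setequal(key, c("v w", "w v"))
  expect_equal(r2$tree_frequency[key == "v w"], 1)
  # a deeper tree: v at root, w at depth 2 under it, and a second v
  t3 <- handTree(left = c(2, 4, 0, 0, 6, 0, 0),
                 right = c(3, 5, 0, 0, 7, 0, 0),
                 var = c("v", "u", NA, NA, "w", NA, NA))
  r3 <- interactionDepths(list(t3), topK = Inf)
  expect_equal(r3$mean_conditional_depth[
    r3$conditioning_feature == "v" & r3$second_feature == "w"], 2)
  expect_equal(r3$unconditional_mean_depth[
    r3$conditioning_feature == "v" & r3$second_feature == "w"], 2)
  expect_equal(r3$mean_conditional_depth[
    r3$conditioning_feature == "u" & r3$second_feature == "w"], 1)
})

test_that("planted XOR-style interactions surface in the top pairs", {
  set.seed(12)
  n <- 3000
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, c("f1", "f2",
                                      sprintf("n%02d", 1:10))))
  y <- ifelse(xor(x[, 1] > 0, x[, 2] > 0), "correlated", "uncorrelated")
  fo <- trainForest(x, y, nTrees = 300, varsPerSplit = 4, minNode = 100,
                    seed = 13)
  top <- interactionDepths(fo, topK = 5)
  key <- paste(top$conditioning_feature, top$second_feature)
  expect_true(any(c("f1 f2", "f2 f1") %in% key))
})

test_that("cross-validation reports every repeat and stays disjoint", {
  sim <- simulatePairClassification(nTF = 20, nTG = 200, pairsPerTf = 40,
                                    prevalence = 0.3, seed = 13)
  cv <- crossValidate(sim$x[, 1:20], sim$pairs, repeats = 4, seed = 14,
                      nTrees = 60, varsPerSplit = 3, minNode = 40,
                      mdaPermutations = 1, interactions = TRUE, topK = 10)
  expect_s4_class(cv, "CVResult")
  expect_equal(nrow(cvAucs(cv)), 4)
  expect_true(all(cvAucs(cv)$roc_auc >= 0 & cvAucs(cv)$roc_auc <= 1))
  expect_equal(nrow(cvImportance(cv)), 20)
  expect_lte(nrow(cvInteractions(cv)), 10)
  expect_gte(nrow(cvInteractions(cv)), 1)
})
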
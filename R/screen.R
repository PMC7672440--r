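#' Merge correlated features into clusters
#'
#' Columns are z-scored (a zero-variance column becomes the constant 0 and
#' stays a singleton, with a warning), a graph is built with an edge
#' wherever the pairwise Pearson correlation exceeds \code{rThreshold},
#' and the connected components of that graph define the clusters
#' (transitive merging, order-independent). Each cluster's value per row
#' is the mean of its z-scored members; the cluster is named after its
#' first member in column order.
#'
#' @param x a [FeatureMatrix-class] or plain numeric matrix (no missing
#'   values).
#' @param rThreshold correlation threshold, default 0.85 (strict
#'   \code{>}).
#' @return list with \code{matrix} (rows x clusters), \code{clusters}
#'   (data.frame \code{feature}, \code{cluster}), and \code{nClusters}.
#' @export
clusterFeatures <- function(x, rThreshold = 0.85) {
  m <- if (is(x, "FeatureMatrix")) featureValues(x) else as.matrix(x)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance column(s) kept as constant ",
            "singletons")
  z <- sweep(sweep(m, 2, colMeans(m)), 2, ifelse(sds > 0, sds, 1), "/")
  cm <- suppressWarnings(cor(z))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) * 0 + (cm > rThreshold)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable cluster ids/names: first member in column order
  first <- vapply(split(seq_along(comp), comp), min, numeric(1))
  ord <- rank(first)
  clusters <- data.frame(feature = colnames(m),
                         cluster = as.integer(ord[as.character(comp)]))
  nms <- colnames(m)[vapply(split(seq_along(comp), comp),
                            min, numeric(1))][order(first)]
  cm2 <- vapply(sort(unique(clusters$cluster)), function(k) {
    idx <- which(clusters$cluster == k)
    if (length(idx) == 1L) z[, idx] else rowMeans(z[, idx, drop = FALSE])
  }, numeric(nrow(z)))
  colnames(cm2) <- nms
  rownames(cm2) <- rownames(m)
  list(matrix = cm2, clusters = clusters, nClusters = ncol(cm2))
}

cohensD <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (is.na(sp2) || sp2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Univariate screen of clustered features
#'
#' Per feature (cluster): a two-sided Wilcoxon-Mann-Whitney test of the
#' correlated versus uncorrelated pair groups, Cohen's D with pooled SD
#' (correlated minus uncorrelated sign convention), and BH FDR across
#' features. Constant features get D = 0 and p = 1.
#'
#' @param x numeric rows x features matrix (e.g. the clustered matrix).
#' @param labels character vector per row with values \code{correlated} /
#'   \code{uncorrelated} (other rows are ignored).
#' @param alternative test sidedness, default \code{two.sided}.
#' @return data.frame \code{feature}, \code{cohens_d}, \code{wilcoxon_p},
#'   \code{p_fdr}.
#' @export
univariateScreen <- function(x, labels, alternative = "two.sided") {
  keep <- labels %in% c("correlated", "uncorrelated")
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  nc <- sum(labels == "correlated"); nu <- sum(labels == "uncorrelated")
  if (nc < 2 || nu < 2)
    stop("each class needs at least 2 observations (got ", nc, " / ",
         nu, ")")
  a <- x[labels == "correlated", , drop = FALSE]
  b <- x[labels == "uncorrelated", , drop = FALSE]
  res <- data.frame(feature = colnames(x),
                    cohens_d = NA_real_, wilcoxon_p = NA_real_)
  for (j in seq_len(ncol(x))) {
    d <- cohensD(a[, j], b[, j])
    p <- if (sd(x[, j]) == 0) 1 else
      suppressWarnings(wilcox.test(a[, j], b[, j],
                                   alternative = alternative)$p.value)
    res$cohens_d[j] <- d
    res$wilcoxon_p[j] <- p
  }
  res$p_fdr <- p.adjust(res$wilcoxon_p, method = "BH")
  res
}

# One-tailed (enrichment) hypergeometric p for a 2x2 table.
hypergeomP <- function(n11, n12, n21, n22, alternative = "greater") {
  if (alternative == "greater")
    phyper(n11 - 1, n11 + n12, n21 + n22, n11 + n21, lower.tail = FALSE)
  else
    phyper(n11, n11 + n12, n21 + n22, n11 + n21, lower.tail = TRUE)
}

#' Fisher enrichment of categorical labels in correlated pairs
#'
#' For every category (TF family, GO term, ...): builds the 2x2 table of
#' correlated/uncorrelated pairs carrying / not carrying the category,
#' computes the one-tailed hypergeometric (Fisher exact) p-value for
#' overrepresentation among correlated pairs (\code{alternative =
#' "less"} gives the depletion direction), the unconditional sample odds
#' ratio \code{(n11 n22) / (n12 n21)}, and BH FDR across categories.
#' Counting is pair-based: every pair contributes once per category it
#' carries.
#'
#' @param labels character vector per pair (\code{correlated} /
#'   \code{uncorrelated}; other values ignored).
#' @param categories list (one element per pair) of character vectors of
#'   category labels; a pair may carry several.
#' @param alternative \code{greater} (enrichment, default) or
#'   \code{less}.
#' @return data.frame \code{category}, \code{n11}, \code{n12},
#'   \code{n21}, \code{n22}, \code{odds_ratio}, \code{p_one_tailed},
#'   \code{p_fdr}.
#' @export
fisherEnrichment <- function(labels, categories,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(labels) == length(categories))
  keep <- labels %in% c("correlated", "uncorrelated")
  labels <- labels[keep]
  categories <- categories[keep]
  nCorr <- sum(labels == "correlated")
  nUnc <- sum(labels == "uncorrelated")
  cats <- sort(unique(unlist(categories)))
  rows <- lapply(cats, function(ct) {
    has <- vapply(categories, function(v) ct %in% v, logical(1))
    n11 <- sum(has & labels == "correlated")
    n21 <- sum(has & labels == "uncorrelated")
    n12 <- nCorr - n11
    n22 <- nUnc - n21
    if ((n11 + n21) == 0 || (n11 + n12) == 0) {
      message("category ", ct, " skipped: zero margin")
      return(NULL)
    }
    data.frame(category = ct, n11 = n11, n12 = n12, n21 = n21, n22 = n22,
               odds_ratio = if (n12 * n21 > 0)
                 (n11 * n22) / (n12 * n21) else if (n11 * n22 > 0)
                   Inf else 0,
               p_one_tailed = hypergeomP(n11, n12, n21, n22, alternative))
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(category = character(0), n11 = integer(0),
                      n12 = integer(0), n21 = integer(0), n22 = integer(0),
                      odds_ratio = numeric(0), p_one_tailed = numeric(0),
                      p_fdr = numeric(0)))
  res$p_fdr <- p.adjust(res$p_one_tailed, method = "BH")
  res[order(res$p_one_tailed), ]
}
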
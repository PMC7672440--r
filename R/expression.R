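#' Normalize an expression matrix
#'
#' Applies a natural-log transform (optional; synthetic matrices arrive on
#' the log scale already) followed by quantile normalization, after which
#' every sample column carries the identical sorted value vector (the
#' column-wise mean of order statistics; ties receive the mean of their
#' tied order-statistic means).
#'
#' @param mat numeric genes x samples matrix with gene ids as rownames.
#' @param log take \code{ln(x)} first (requires positive values).
#' @return normalized matrix of the same shape.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' normalizeExpression(m, log = FALSE)
#' @export
normalizeExpression <- function(mat, log = TRUE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("expression matrix must not contain missing values")
  if (log) {
    if (any(mat <= 0))
      stop("log transform requires strictly positive raw values")
    mat <- base::log(mat)
  }
  if (ncol(mat) == 1L) return(mat)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Pearson correlation of each TF-TG pair
#'
#' Fills the \code{pearson_r} column of the pair table with the Pearson
#' correlation of the TF's and target's expression profiles. Pairs whose
#' genes are absent from the matrix, or involve a zero-variance profile,
#' are dropped with a message.
#'
#' @param expr normalized genes x samples matrix (rownames = gene ids).
#' @param pairs pair data.frame with \code{tf_id} and \code{tg_id}.
#' @return the pair table with \code{pearson_r} set.
#' @export
pairCorrelation <- function(expr, pairs) {
  if (ncol(expr) < 2L) stop("need at least 2 samples for correlation")
  present <- pairs$tf_id %in% rownames(expr) &
    pairs$tg_id %in% rownames(expr)
  if (any(!present))
    message(sum(!present), " pair(s) dropped: gene absent from matrix")
  pairs <- pairs[present, , drop = FALSE]
  genes <- unique(c(pairs$tf_id, pairs$tg_id))
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  z <- sweep(sub - rowMeans(sub), 1, ifelse(sds > 0, sds, 1), "/")
  r <- rowSums(z[pairs$tf_id, , drop = FALSE] *
                 z[pairs$tg_id, , drop = FALSE]) / (ncol(sub) - 1)
  bad <- sds[pairs$tf_id] == 0 | sds[pairs$tg_id] == 0
  if (any(bad))
    message(sum(bad), " pair(s) dropped: zero-variance profile")
  pairs$pearson_r <- pmin(1, pmax(-1, r))
  pairs <- pairs[!bad, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# Mean all-against-all pairwise correlation of a gene set.
meanPairwiseR <- function(expr, genes) {
  cm <- cor(t(expr[genes, , drop = FALSE]))
  mean(cm[upper.tri(cm)])
}

#' Select "active" TFs against a resampling null
#'
#' A TF's activity signal is the mean all-against-all pairwise Pearson
#' correlation among its target genes (subsampled to \code{tgCap} when it
#' has more). For each TF a size-matched random set of non-targets (genes
#' never assigned to that TF, the TF itself excluded) provides one null
#' mean; the activity threshold is the \code{percentile}-th percentile of
#' the null means pooled over all TFs (a per-TF threshold is available via
#' \code{perTF}). A TF is active when its observed mean exceeds the
#' threshold. TFs with fewer than two targets in the matrix are reported
#' inactive by default.
#'
#' @param expr normalized genes x samples matrix.
#' @param pairs pair table (defines each TF's target set).
#' @param percentile null percentile, default 97.5.
#' @param tgCap cap on targets entering the statistic, default 3000.
#' @param seed integer seed for the subsampling and null draws.
#' @param perTF use each TF's own null mean distribution-free threshold
#'   instead of the pooled percentile (default FALSE, pooled).
#' @param thresholdOverride optional fixed threshold replacing the
#'   recomputed one.
#' @return data.frame with columns \code{tf_id}, \code{n_tg},
#'   \code{mean_tg_r}, \code{null_mean_r}, \code{threshold},
#'   \code{is_active}.
#' @export
selectActiveTFs <- function(expr, pairs, percentile = 97.5, tgCap = 3000,
                            seed = 1L, perTF = FALSE,
                            thresholdOverride = NULL) {
  set.seed(seed)
  tfs <- sort(unique(pairs$tf_id))
  allGenes <- rownames(expr)
  res <- data.frame(tf_id = tfs, n_tg = NA_integer_,
                    mean_tg_r = NA_real_, null_mean_r = NA_real_)
  for (i in seq_along(tfs)) {
    tgs <- unique(pairs$tg_id[pairs$tf_id == tfs[i]])
    tgs <- intersect(tgs, allGenes)
    res$n_tg[i] <- length(tgs)
    if (length(tgs) < 2L) next
    use <- if (length(tgs) > tgCap) sample(tgs, tgCap) else tgs
    res$mean_tg_r[i] <- meanPairwiseR(expr, use)
    nonTG <- setdiff(allGenes, c(tgs, tfs[i]))
    if (length(nonTG) < length(use)) {
      warning("fewer non-targets than targets for ", tfs[i],
              "; sampling all available")
      nullSet <- nonTG
    } else nullSet <- sample(nonTG, length(use))
    if (length(nullSet) >= 2L)
      res$null_mean_r[i] <- meanPairwiseR(expr, nullSet)
  }
  few <- is.na(res$mean_tg_r)
  if (any(few))
    message(sum(few), " TF(s) with < 2 usable targets: inactive by default")
  if (!is.null(thresholdOverride)) {
    res$threshold <- thresholdOverride
  } else if (perTF) {
    res$threshold <- res$null_mean_r
  } else {
    res$threshold <- quantile(res$null_mean_r, percentile / 100,
                              na.rm = TRUE, names = FALSE)
  }
  res$is_active <- !is.na(res$mean_tg_r) & res$mean_tg_r > res$threshold
  res
}

#' Label pairs as correlated / uncorrelated / excluded
#'
#' Applies the class definition used throughout the analysis: pairs with
#' \code{r > hi} are \code{correlated}, pairs with
#' \code{band[1] < r < band[2]} are \code{uncorrelated}, and everything
#' else (boundaries included, by strict inequality) is \code{excluded}.
#' When an active-TF table is supplied, only pairs of active TFs are
#' retained.
#'
#' @param pairs pair table with \code{pearson_r} set.
#' @param activeTFs optional result of [selectActiveTFs()].
#' @param hi correlated threshold, default 0.4.
#' @param band uncorrelated open interval, default \code{c(-0.1, 0.1)}.
#' @return the filtered pair table with \code{label} filled.
#' @export
labelPairs <- function(pairs, activeTFs = NULL, hi = 0.4,
                       band = c(-0.1, 0.1)) {
  if (anyNA(pairs$pearson_r))
    stop("pearson_r must be set before labeling")
  if (!is.null(activeTFs))
    pairs <- pairs[pairs$tf_id %in%
                     activeTFs$tf_id[activeTFs$is_active], , drop = FALSE]
  r <- pairs$pearson_r
  pairs$label <- ifelse(r > hi, "correlated",
                        ifelse(r > band[1] & r < band[2], "uncorrelated",
                               "excluded"))
  rownames(pairs) <- NULL
  pairs
}

#' Concordance of two per-pair correlation vectors
#'
#' Pearson correlation between correlation coefficients computed for the
#' same pairs from two expression datasets (e.g. microarray vs RNA-seq).
#'
#' @param rA,rB numeric vectors of per-pair correlations, same pair order.
#' @return Pearson correlation coefficient.
#' @export
concordance <- function(rA, rB) {
  if (length(rA) != length(rB)) stop("correlation vectors differ in length")
  if (length(rA) < 3L) stop("need at least 3 pairs")
  cor(rA, rB)
}
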
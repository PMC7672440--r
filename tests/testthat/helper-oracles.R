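# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: the scanner oracle enumerates windows with
# scalar arithmetic, the Fisher oracle sums hypergeometric terms built
# from choose(), and the adjacency oracle works on an explicit matrix.

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

reverseComplement1 <- function(s) {
  paste(rev(REV_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# scalar log-odds of one window under a PWM (probs L x 4, bg length 4)
oracleWindowScore <- function(probs, bg, window) {
  chars <- strsplit(window, "")[[1]]
  s <- 0
  for (i in seq_along(chars)) {
    j <- match(chars[i], c("A", "C", "G", "T"))
    s <- s + log2((probs[i, j] + 1e-4) / bg[j])
  }
  s
}

# exhaustive enumeration of every window on both strands with relative
# scores; returns the same columns as scanPromoter()
oracleScan <- function(pwm, seq, relThreshold = 0.8) {
  probs <- pwmProbs(pwm)
  bg <- pwmBackground(pwm)
  L <- nrow(probs)
  lo <- hi <- 0
  for (i in seq_len(L)) {
    cell <- log2((probs[i, ] + 1e-4) / bg)
    lo <- lo + min(cell)
    hi <- hi + max(cell)
  }
  rows <- list()
  for (start in seq_len(nchar(seq) - L + 1)) {
    w <- substr(seq, start, start + L - 1)
    for (strand in c("+", "-")) {
      ww <- if (strand == "+") w else reverseComplement1(w)
      # minus-strand scoring uses the complemented background
      bgUse <- if (strand == "+") bg else rev(bg)
      sc <- if (strand == "+") oracleWindowScore(probs, bg, w) else {
        # score the reverse complement of the window against the motif
        oracleWindowScore(probs, bg, reverseComplement1(w))
      }
      rel <- if (hi > lo) (sc - lo) / (hi - lo) else 1
      if (rel >= relThreshold)
        rows[[length(rows) + 1]] <-
          data.frame(start = start - 1L, end = start - 1L + L,
                     strand = strand, score = sc, rel_score = rel)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      rel_score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# exact one-tailed Fisher p by enumerating all tables with fixed margins
oracleFisherGreater <- function(n11, n12, n21, n22) {
  m1 <- n11 + n12   # correlated margin
  m2 <- n21 + n22
  k <- n11 + n21    # category margin
  tot <- m1 + m2
  num <- 0
  den <- choose(tot, k)
  for (a in max(0, k - m2):min(k, m1)) {
    if (a >= n11) num <- num + choose(m1, a) * choose(m2, k - a)
  }
  num / den
}

# quadratic-time interval overlap counts (0-based half-open)
oracleOverlapCount <- function(regions, track) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(track$chrom == regions$chrom[i] &
          track$start < regions$end[i] &
          regions$start[i] < track$end)
  }, numeric(1))
}

# random small PWM for property tests
randomPWM <- function(L, seed) {
  set.seed(seed)
  probs <- t(vapply(seq_len(L), function(i) {
    p <- stats::runif(4)
    p / sum(p)
  }, numeric(4)))
  motifPWM(paste0("tf", seed), probs)
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-built tree tables for interaction-depth fixtures
handTree <- function(left, right, var) data.frame(left = left,
                                                  right = right, var = var)

# small annotation with explicit isoforms for bookkeeping tests
toyAnnotation <- function() {
  genes <- data.frame(
    gene_id = c("tf1", "g1", "g2"),
    chrom = "chr1", strand = c("+", "+", "-"),
    gene_start = c(1000L, 5000L, 9000L),
    gene_end = c(2000L, 6500L, 10000L),
    tss = c(1000L, 5000L, 9999L),
    is_tf = c(TRUE, FALSE, FALSE),
    upstream_gene_distance = c(NA, 3000L, 2500L))
  isoforms <- data.frame(
    gene_id = c("tf1", "g1", "g1", "g2"),
    isoform_id = c("tf1.1", "g1.1", "g1.2", "g2.1"),
    mrna_len = c(900L, 100L, 200L, 800L),
    protein_len = c(250L, 100L, 250L, 180L),
    utr5_len = c(40L, 30L, 60L, 25L),
    utr3_len = c(100L, 80L, 120L, 90L),
    utr5_has_intron = c(FALSE, FALSE, TRUE, FALSE))
  geneAnnotationSet(genes, isoforms)
}
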
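#' Log-odds score of a PWM against a sequence window
#'
#' Scores a window of the motif's length as
#' \code{sum_i log2((p[i, base_i] + eps) / bg[base_i])} with a pseudocount
#' \code{eps = 1e-4} guarding zero probability cells.
#'
#' @param pwm a [MotifPWM-class].
#' @param window character string of length \code{motifLength(pwm)}
#'   containing only A/C/G/T.
#' @return numeric log2-odds score.
#' @examples
#' pwm <- motifPWM("tf1", diag(4)[rep(1, 3), ])  # poly-A one-hot
#' pwmLogOdds(pwm, "AAA")
#' @export
pwmLogOdds <- function(pwm, window) {
  idx <- match(strsplit(toupper(window), "")[[1]], DNA_BASES)
  L <- motifLength(pwm)
  if (length(idx) != L)
    stop("window length must equal the motif length (", L, ")")
  if (anyNA(idx))
    stop("window contains ambiguity codes; only A/C/G/T are scorable")
  p <- pwm@probs
  sum(log2((p[cbind(seq_len(L), idx)] + 1e-4) / pwm@background[idx]))
}

# Per-column score bounds; relative score = (score - min) / (max - min).
scoreBounds <- function(pwm) {
  lo <- log2((pwm@probs + 1e-4) / rep(pwm@background, each = nrow(pwm@probs)))
  c(min = sum(apply(lo, 1, min)), max = sum(apply(lo, 1, max)))
}

# Reverse complement of a PWM (for minus-strand scanning of the forward
# string): positions reversed, bases complemented, background complemented.
reverseComplementPWM <- function(pwm) {
  comp <- c(4L, 3L, 2L, 1L)
  p <- pwm@probs[rev(seq_len(nrow(pwm@probs))), comp, drop = FALSE]
  colnames(p) <- DNA_BASES
  motifPWM(pwm@tfId, p, pwm@background[comp])
}

# Vectorized log-odds of all windows of a base-index vector.
scoreAllWindows <- function(lodds, idx) {
  L <- nrow(lodds)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(L)) {
    s <- s + lodds[cbind(i, idx[seq.int(i, i + n - 1L)])]
  }
  s
}

#' Scan a promoter sequence with a PWM at a relative-score threshold
#'
#' Every window whose relative score --- \code{(score - min) / (max - min)}
#' with the per-column minimal and maximal attainable log-odds --- reaches
#' \code{relThreshold} is reported. Both strands are scanned by default
#' (binding events carry no strand of their own); windows containing
#' ambiguity codes are skipped.
#'
#' @param pwm a [MotifPWM-class].
#' @param promoterSeq promoter sequence (character or
#'   [Biostrings::DNAString]), written 5' to 3' on the gene's coding strand
#'   ending at the base just upstream of the TSS.
#' @param relThreshold minimal relative score in (0, 1], default 0.8.
#' @param bothStrands scan the reverse strand as well (default TRUE).
#' @return data.frame with columns \code{start} (0-based offset in the
#'   promoter), \code{end} (half-open), \code{strand}, \code{score},
#'   \code{rel_score}.
#' @examples
#' pwm <- motifPWM("tf1", diag(4)[c(1, 2, 3), ])  # consensus ACG
#' scanPromoter(pwm, "TTACGTT")
#' @export
scanPromoter <- function(pwm, promoterSeq, relThreshold = 0.8,
                         bothStrands = TRUE) {
  stopifnot(relThreshold > 0, relThreshold <= 1)
  seqc <- toupper(as.character(promoterSeq))
  L <- motifLength(pwm)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      rel_score = numeric(0))
  if (nchar(seqc) < L) {
    warning("promoter shorter than the motif; no windows to scan")
    return(empty)
  }
  idx <- match(strsplit(seqc, "")[[1]], DNA_BASES)
  b <- scoreBounds(pwm)
  span <- b["max"] - b["min"]
  strandSet <- if (bothStrands) c("+", "-") else "+"
  out <- lapply(strandSet, function(strand) {
    pw <- if (strand == "+") pwm else reverseComplementPWM(pwm)
    lodds <- log2((pw@probs + 1e-4) /
                    rep(pw@background, each = L))
    # Ambiguous windows score NA and are dropped below.
    s <- scoreAllWindows(lodds, idx)
    rel <- if (span > 0) (s - b["min"]) / span else rep(1, length(s))
    keep <- which(!is.na(rel) & rel >= relThreshold)
    data.frame(start = keep - 1L, end = keep - 1L + L,
               strand = rep(strand, length(keep)),
               score = unname(s[keep]), rel_score = unname(rel[keep]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Signed distance from a TFBS interval to a TSS
#'
#' Distance from the TSS to the nearest boundary of the hit interval
#' (0-based half-open coordinates): 0 if the interval covers the TSS,
#' otherwise the gap between interval and TSS base, signed negative when
#' the hit lies upstream in the gene's coding orientation (mirrored for
#' minus-strand genes).
#'
#' @param start,end hit interval, 0-based half-open.
#' @param tss 0-based coordinate of the TSS base.
#' @param strand gene strand, \code{"+"} or \code{"-"}.
#' @return signed integer distance in bp.
#' @examples
#' tfbsDistance(940, 950, 1000, "+")  # hit [TSS-60, TSS-50) -> -50
#' @export
tfbsDistance <- function(start, end, tss, strand = "+") {
  raw <- ifelse(start <= tss & tss < end, 0L,
                ifelse(end <= tss, -(tss - end), start - (tss + 1L)))
  ifelse(strand == "-", -raw, raw)
}

# Distance of a promoter-string hit to the TSS: the promoter string covers
# [-promoterLen, -1] in coding orientation, so the hit's TSS-proximal edge
# offset is end - promoterLen (book-ended hits give 0 per the gap
# convention of tfbsDistance()).
promoterHitDistance <- function(end, promoterLen) {
  as.integer(end) - as.integer(promoterLen)
}

# Genomic interval of a promoter-string hit for one gene.
promoterHitGenomic <- function(start, end, tss, strand, promoterLen) {
  if (strand == "+") {
    gs <- tss - promoterLen + start
    data.frame(gstart = gs, gend = gs + (end - start))
  } else {
    ge <- tss + promoterLen - start + 1L
    data.frame(gstart = ge - (end - start), gend = ge)
  }
}

#' Build TF-TG regulatory pairs from promoter scans
#'
#' Scans every retained gene's promoter with every TF's PWM and creates a
#' pair (TF, gene) whenever at least one hit's TSS distance falls inside
#' \code{promoterWindow}. Genes (and TFs) whose annotated 5'UTR length is
#' zero are removed before pairing; self-pairs are retained. The pair-level
#' distance is the hit distance closest to the TSS (minimum absolute value,
#' ties broken toward the upstream hit).
#'
#' @param annotation a [GeneAnnotationSet-class].
#' @param promoters named character vector or
#'   [Biostrings::DNAStringSet] of promoter sequences (coding orientation,
#'   ending at TSS-1), named by gene id.
#' @param pwms named list of [MotifPWM-class] objects; names are TF gene
#'   ids and every annotated TF must have one.
#' @param promoterWindow signed bp window defining the promoter, default
#'   \code{c(-500, -1)}.
#' @param relThreshold relative-score threshold, default 0.8.
#' @param bothStrands passed to [scanPromoter()].
#' @return list with elements \code{pairs} (data.frame \code{tf_id},
#'   \code{tg_id}, \code{closest_tfbs_distance}, \code{pearson_r = NA},
#'   \code{label = "unlabeled"}) and \code{hits} (data.frame of every
#'   retained hit with promoter-relative and genomic coordinates).
#' @export
buildPairs <- function(annotation, promoters, pwms,
                       promoterWindow = c(-500, -1), relThreshold = 0.8,
                       bothStrands = TRUE) {
  genes <- geneTable(annotation)
  iso <- isoformTable(annotation)
  promoters <- setNames(toupper(as.character(promoters)),
                        names(promoters))
  # 5'UTR filter: a gene whose shortest annotated 5'UTR is 0 is dropped.
  minUtr5 <- tapply(iso$utr5_len, iso$gene_id, min)
  keep <- genes$gene_id[!(genes$gene_id %in%
                            names(minUtr5)[minUtr5 == 0])]
  genes <- genes[genes$gene_id %in% keep & genes$gene_id %in%
                   names(promoters), , drop = FALSE]
  tfs <- genes$gene_id[genes$is_tf]
  missing <- setdiff(tfs, names(pwms))
  if (length(missing))
    stop("no PWM available for TF(s): ", paste(missing, collapse = ", "))
  hitList <- vector("list", length(tfs) * nrow(genes))
  k <- 0L
  for (tf in tfs) {
    pwm <- pwms[[tf]]
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      pl <- nchar(promoters[[g$gene_id]])
      h <- scanPromoter(pwm, promoters[[g$gene_id]], relThreshold,
                        bothStrands)
      if (!nrow(h)) next
      d <- promoterHitDistance(h$end, pl)
      inWin <- d >= promoterWindow[1] & d <= promoterWindow[2]
      if (!any(inWin)) next
      h <- h[inWin, , drop = FALSE]
      d <- d[inWin]
      gcoord <- do.call(rbind, lapply(seq_len(nrow(h)), function(j)
        promoterHitGenomic(h$start[j], h$end[j], g$tss, g$strand, pl)))
      k <- k + 1L
      hitList[[k]] <- data.frame(
        tf_id = tf, gene_id = g$gene_id, chrom = g$chrom,
        start = h$start, end = h$end, gstart = gcoord$gstart,
        gend = gcoord$gend, strand_of_hit = h$strand,
        distance = d, rel_score = h$rel_score)
    }
  }
  hits <- if (k) do.call(rbind, hitList[seq_len(k)]) else
    data.frame(tf_id = character(0), gene_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               gstart = integer(0), gend = integer(0),
               strand_of_hit = character(0), distance = integer(0),
               rel_score = numeric(0))
  pairs <- if (nrow(hits)) {
    sp <- split(hits$distance, paste(hits$tf_id, hits$gene_id, sep = "\r"))
    closest <- vapply(sp, function(d) {
      best <- d[abs(d) == min(abs(d))]
      # ties at equal |distance| resolve toward the upstream hit
      if (length(best) > 1L) min(best) else best
    }, numeric(1))
    key <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    data.frame(tf_id = key[, 1], tg_id = key[, 2],
               closest_tfbs_distance = as.integer(closest),
               pearson_r = NA_real_, label = "unlabeled")
  } else {
    data.frame(tf_id = character(0), tg_id = character(0),
               closest_tfbs_distance = integer(0),
               pearson_r = numeric(0), label = character(0))
  }
  pairs <- pairs[order(pairs$tf_id, pairs$tg_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, hits = hits)
}

#' Summaries of TFBS-TSS distances per TF and per target gene
#'
#' Means and standard deviations of the signed TFBS-TSS distance over all
#' hits inside \code{window} (default -1000..+500 bp), computed per TF
#' (over all its hits) and per target gene (over all hits in its
#' promoter), plus per-TF target counts and per-gene regulator counts from
#' the pair table. TFs/genes without an in-window hit get \code{NA}
#' (imputed downstream); a single in-window hit yields SD 0.
#'
#' @param hits hit table from [buildPairs()].
#' @param pairs pair table from [buildPairs()].
#' @param window signed bp window, default \code{c(-1000, 500)}.
#' @return list of data.frames \code{tf} (\code{tf_id}, \code{dist_mean},
#'   \code{dist_sd}, \code{n_targets}) and \code{tg} (\code{gene_id},
#'   \code{dist_mean}, \code{dist_sd}, \code{n_regulators}).
#' @export
tfbsDistanceStats <- function(hits, pairs, window = c(-1000, 500)) {
  inWin <- hits[hits$distance >= window[1] & hits$distance <= window[2], ,
                drop = FALSE]
  summarise <- function(d) {
    c(mean = mean(d), sd = if (length(d) >= 2) sd(d) else 0)
  }
  statBy <- function(byCol) {
    if (!nrow(inWin))
      return(data.frame(id = character(0), dist_mean = numeric(0),
                        dist_sd = numeric(0)))
    sp <- split(inWin$distance, inWin[[byCol]])
    m <- t(vapply(sp, summarise, numeric(2)))
    data.frame(id = names(sp), dist_mean = m[, "mean"], dist_sd = m[, "sd"],
               row.names = NULL)
  }
  tf <- statBy("tf_id")
  names(tf)[1] <- "tf_id"
  tg <- statBy("gene_id")
  names(tg)[1] <- "gene_id"
  nTargets <- as.data.frame(table(pairs$tf_id), stringsAsFactors = FALSE)
  names(nTargets) <- c("tf_id", "n_targets")
  nReg <- as.data.frame(table(pairs$tg_id), stringsAsFactors = FALSE)
  names(nReg) <- c("gene_id", "n_regulators")
  tf <- merge(nTargets, tf, by = "tf_id", all = TRUE)
  tg <- merge(nReg, tg, by = "gene_id", all = TRUE)
  tf$n_targets[is.na(tf$n_targets)] <- 0L
  tg$n_regulators[is.na(tg$n_regulators)] <- 0L
  list(tf = tf, tg = tg)
}
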
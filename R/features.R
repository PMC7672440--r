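#' Sequence entropy of a binding motif
#'
#' Per-position Shannon entropy \code{S_i = -sum_j p_ij ln p_ij} (with
#' \code{0 ln 0 = 0}), averaged over positions (SE), plus the core-motif
#' entropy: the mean of the five smallest \code{S_i} (all positions when
#' the motif is shorter than five).
#'
#' @param pwm a [MotifPWM-class].
#' @param base logarithm base, default natural log (nats).
#' @return named numeric: \code{se}, \code{core5_se}.
#' @examples
#' motifEntropy(motifPWM("tf", matrix(0.25, 2, 4)))  # ln 4 everywhere
#' @export
motifEntropy <- function(pwm, base = exp(1)) {
  p <- pwmProbs(pwm)
  s <- -rowSums(ifelse(p > 0, p * log(p, base = base), 0))
  c(se = mean(s), core5_se = mean(sort(s)[seq_len(min(5, length(s)))]))
}

#' Length and base composition of a binding motif
#'
#' Base percentages are the column-probability sums divided by the motif
#' length; the AT/GC ratio contrasts double- versus triple-hydrogen-bonded
#' base pairs and AG/TC contrasts purines versus pyrimidines, both with a
#' small denominator guard.
#'
#' @param pwm a [MotifPWM-class].
#' @return named numeric: \code{length}, \code{pct_a} .. \code{pct_t},
#'   \code{at_gc_ratio}, \code{ag_tc_ratio}.
#' @export
motifComposition <- function(pwm) {
  p <- pwmProbs(pwm)
  freq <- colSums(p)
  pct <- freq / nrow(p)
  eps <- 1e-9
  atgc <- (freq["A"] + freq["T"]) / (freq["G"] + freq["C"] + eps)
  agtc <- (freq["A"] + freq["G"]) / (freq["T"] + freq["C"] + eps)
  if (freq["G"] + freq["C"] < eps || freq["T"] + freq["C"] < eps)
    message("degenerate motif composition for ", tfId(pwm),
            ": ratio denominator guarded")
  c(length = nrow(p), pct_a = unname(pct["A"]), pct_c = unname(pct["C"]),
    pct_g = unname(pct["G"]), pct_t = unname(pct["T"]),
    at_gc_ratio = unname(atgc), ag_tc_ratio = unname(agtc))
}

#' Position of each TF in the TF-TF regulatory network
#'
#' From the directed TF -> target graph implied by the pair list: a TF's
#' in-degree counts the distinct TFs that have it as a target, its
#' out-degree the distinct TFs it targets, and the in/(in+out) ratio
#' locates it between the top (ratio 0) and bottom (ratio 1) of the
#' regulatory hierarchy; TFs without any TF-TF edge get ratio 0 and are
#' flagged. Per-gene regulator counts and per-TF target counts over the
#' whole pair list are returned alongside.
#'
#' @param pairs pair table (\code{tf_id}, \code{tg_id}).
#' @param tfIds ids of all genes that are TFs.
#' @return list of data.frames \code{tf} (\code{tf_id}, \code{in_degree},
#'   \code{out_degree}, \code{in_ratio}, \code{no_edges}) and \code{gene}
#'   (\code{gene_id}, \code{n_regulators}).
#' @export
regulatoryNetworkFeatures <- function(pairs, tfIds) {
  tfEdges <- unique(pairs[pairs$tg_id %in% tfIds,
                          c("tf_id", "tg_id"), drop = FALSE])
  inDeg <- table(factor(tfEdges$tg_id, levels = tfIds))
  outDeg <- table(factor(tfEdges$tf_id, levels = tfIds))
  tot <- as.integer(inDeg) + as.integer(outDeg)
  tf <- data.frame(tf_id = tfIds,
                   in_degree = as.integer(inDeg),
                   out_degree = as.integer(outDeg),
                   in_ratio = ifelse(tot > 0, as.integer(inDeg) / tot, 0),
                   no_edges = tot == 0)
  gene <- as.data.frame(table(pairs$tg_id), stringsAsFactors = FALSE)
  names(gene) <- c("gene_id", "n_regulators")
  list(tf = tf, gene = gene)
}

#' Protein-interaction features of TFs
#'
#' Unweighted shortest-path (BFS hop) distance from each TF to the
#' polymerase node, node degree, and a self-interaction flag. A TF absent
#' from the graph gets the sentinel distance 2000 with degree 0; a TF in a
#' component without the polymerase node gets sentinel distance 1000.
#'
#' @param edges data.frame of undirected edges (\code{from}, \code{to});
#'   loop edges mark self-interactions.
#' @param polIIId node id of the polymerase subunit; must be present.
#' @param tfIds TF ids to report on.
#' @return data.frame \code{tf_id}, \code{ppi_distance_to_polII},
#'   \code{ppi_degree}, \code{ppi_self_interaction}.
#' @export
ppiFeatures <- function(edges, polIIId, tfIds) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- igraph::V(g)$name
  if (!polIIId %in% nodes)
    stop("polymerase node '", polIIId, "' is missing from the graph")
  present <- tfIds[tfIds %in% nodes]
  res <- data.frame(tf_id = tfIds,
                    ppi_distance_to_polII = 2000,
                    ppi_degree = 0L,
                    ppi_self_interaction = 0L)
  if (length(present)) {
    d <- igraph::distances(g, v = present, to = polIIId)[, 1]
    d[is.infinite(d)] <- 1000
    deg <- igraph::degree(g, v = present, loops = FALSE)
    selfLoop <- vapply(present, function(v)
      any(edges$from == v & edges$to == v), logical(1))
    i <- match(present, res$tf_id)
    res$ppi_distance_to_polII[i] <- d
    res$ppi_degree[i] <- deg
    res$ppi_self_interaction[i] <- as.integer(selfLoop)
  }
  res
}

#' Mono- and dinucleotide composition of a promoter
#'
#' Mononucleotide percentages over unambiguous bases, and counts of all 16
#' ordered dinucleotides from a sliding window of length 2 with step 1
#' (windows containing ambiguity codes are not counted).
#'
#' @param seq promoter sequence (character or DNAString).
#' @return named numeric of length 20: \code{pct_a} .. \code{pct_t}, then
#'   \code{aa}, \code{ac}, ... \code{tt} counts.
#' @examples
#' promoterComposition("ACGT")
#' @export
promoterComposition <- function(seq) {
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  mono <- Biostrings::letterFrequency(s, DNA_BASES)
  tot <- sum(mono)
  di <- Biostrings::dinucleotideFrequency(s, step = 1)
  out <- c(if (tot > 0) 100 * mono / tot else rep(0, 4), di)
  names(out) <- c(paste0("pct_", tolower(DNA_BASES)),
                  tolower(names(di)))
  out
}

#' TATA-box presence in the proximal promoter
#'
#' Flags a gene when the consensus \code{TATAWA} (W = A or T) occurs in
#' forward orientation on the coding strand within the 60 bp immediately
#' upstream of the TSS. Promoters shorter than 60 bp are scanned in full
#' with a message.
#'
#' @param promoterSeq promoter sequence in coding orientation ending at
#'   TSS-1.
#' @return integer flag, 1 when present.
#' @examples
#' tataBox(paste0(strrep("C", 60), "TATAAA", strrep("C", 20)))
#' @export
tataBox <- function(promoterSeq) {
  s <- toupper(as.character(promoterSeq))
  n <- nchar(s)
  if (n < 60) message("promoter shorter than 60 bp; scanning what exists")
  window <- substr(s, max(1L, n - 59L), n)
  hit <- Biostrings::matchPattern("TATAWA", Biostrings::DNAString(window),
                                  fixed = FALSE)
  as.integer(length(hit) > 0)
}

#' Isoform-aggregated annotation features per gene
#'
#' Minimum, mean and maximum of mRNA, protein, 5'UTR and 3'UTR lengths
#' over a gene's isoforms, the isoform count, the spread between longest
#' and shortest encoded protein, whether any isoform's 5'UTR overlaps an
#' intron, and the distance to the closest upstream gene.
#'
#' @param annotation a [GeneAnnotationSet-class].
#' @return data.frame with one row per gene.
#' @export
annotationFeatures <- function(annotation) {
  iso <- isoformTable(annotation)
  genes <- geneTable(annotation)
  agg <- function(col) {
    m <- vapply(split(iso[[col]], iso$gene_id),
                function(x) c(min(x), mean(x), max(x)), numeric(3))
    out <- as.data.frame(t(m))
    names(out) <- paste0(col, c("_min", "_mean", "_max"))
    out$gene_id <- rownames(out)
    out
  }
  res <- Reduce(function(a, b) merge(a, b, by = "gene_id"),
                lapply(c("mrna_len", "protein_len", "utr5_len",
                         "utr3_len"), agg))
  extras <- data.frame(
    gene_id = names(split(iso$protein_len, iso$gene_id)),
    isoform_count = as.integer(table(iso$gene_id)[
      names(split(iso$protein_len, iso$gene_id))]),
    protein_len_diff = vapply(split(iso$protein_len, iso$gene_id),
                              function(x) max(x) - min(x), numeric(1)),
    utr5_intron = vapply(split(iso$utr5_has_intron, iso$gene_id),
                         function(x) as.integer(any(x)), integer(1)))
  res <- merge(res, extras, by = "gene_id")
  merge(res, genes[, c("gene_id", "upstream_gene_distance")],
        by = "gene_id", all.x = TRUE)
}

bedToGRanges <- function(df) {
  if (is.null(df) || !nrow(df))
    return(GenomicRanges::GRanges())
  if (is.unsorted(order(df$chrom, df$start))) df <- df[order(df$chrom,
                                                             df$start), ]
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

# Promoter / TSS+-100 / gene-body regions of each gene, coding-aware,
# as a GRangesList-like list of GRanges (0-based half-open in, 1-based
# GRanges out).
geneRegions <- function(genes, promoterLen = 500L, tssFlank = 100L) {
  promStart <- ifelse(genes$strand == "+", genes$tss - promoterLen,
                      genes$tss + 1L)
  promEnd <- promStart + promoterLen
  list(
    promoter = GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(pmax(1L, promStart + 1L), promEnd)),
    tss = GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(pmax(1L, genes$tss - tssFlank + 1L),
                       genes$tss + tssFlank + 1L)),
    body = GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(genes$gene_start + 1L, genes$gene_end)))
}

#' Methylation, open-chromatin and mark-type features
#'
#' Per target gene: counts of differentially methylated regions from each
#' track in the promoter (-500..-1), around the TSS (+-100 bp) and in the
#' gene body; counts of stable DHS (intervals present in all condition
#' tracks, i.e. their intersection) and dynamic DHS (union minus stable)
#' in promoter and gene body; and the fraction of configured epigenetic
#' mark types with at least one feature for the gene. Per pair: flags for
#' whether the pair's closest TFBS interval falls in a stable or dynamic
#' DHS. Any interval overlapping a region by >= 1 bp counts once.
#'
#' @param dmrTracks named list of interval data.frames (\code{chrom},
#'   \code{start}, \code{end}; 0-based half-open), may be empty.
#' @param dhsTracks named list of >= 1 condition tracks, same format.
#' @param annotation a [GeneAnnotationSet-class].
#' @param pairs pair table with \code{closest_tfbs_distance}.
#' @param hits hit table from [buildPairs()] (genomic coordinates of the
#'   closest hit are looked up here).
#' @param promoterLen promoter length used for the promoter region.
#' @return list with \code{gene} (per-gene counts and
#'   \code{epimark_pct}) and \code{pair} (\code{tf_id}, \code{tg_id},
#'   \code{tfbs_in_stable_dhs}, \code{tfbs_in_dynamic_dhs}).
#' @export
epigeneticFeatures <- function(dmrTracks, dhsTracks, annotation, pairs,
                               hits, promoterLen = 500L) {
  if (!length(dhsTracks)) stop("need at least one DHS condition track")
  genes <- geneTable(annotation)
  regions <- geneRegions(genes, promoterLen)
  dmrGR <- lapply(dmrTracks, bedToGRanges)
  dhsGR <- lapply(dhsTracks, bedToGRanges)
  stable <- Reduce(GenomicRanges::intersect, dhsGR)
  dynamic <- GenomicRanges::setdiff(
    Reduce(GenomicRanges::union, dhsGR), stable)
  gene <- data.frame(gene_id = genes$gene_id)
  for (nm in names(dmrGR)) {
    for (reg in c("promoter", "tss", "body")) {
      gene[[paste0(nm, "_", reg)]] <-
        GenomicRanges::countOverlaps(regions[[reg]], dmrGR[[nm]])
    }
  }
  gene$dhs_stable_promoter <-
    GenomicRanges::countOverlaps(regions$promoter, stable)
  gene$dhs_dynamic_promoter <-
    GenomicRanges::countOverlaps(regions$promoter, dynamic)
  gene$dhs_stable_body <-
    GenomicRanges::countOverlaps(regions$body, stable)
  gene$dhs_dynamic_body <-
    GenomicRanges::countOverlaps(regions$body, dynamic)
  # mark types: each DMR track is one type; stable and dynamic DHS are
  # two more. A type is present when the gene's promoter or body has >= 1.
  nTypes <- length(dmrGR) + 2L
  presentCount <- rowSums(cbind(
    vapply(names(dmrGR), function(nm)
      gene[[paste0(nm, "_promoter")]] + gene[[paste0(nm, "_body")]] > 0,
      logical(nrow(gene))),
    stable_dhs = gene$dhs_stable_promoter + gene$dhs_stable_body > 0,
    dynamic_dhs = gene$dhs_dynamic_promoter + gene$dhs_dynamic_body > 0))
  gene$epimark_pct <- presentCount / nTypes
  # pair flags: the closest hit of each pair, looked up by distance
  pairFlags <- pairs[, c("tf_id", "tg_id")]
  pairFlags$tfbs_in_stable_dhs <- 0L
  pairFlags$tfbs_in_dynamic_dhs <- 0L
  if (nrow(hits) && nrow(pairs)) {
    key <- paste(hits$tf_id, hits$gene_id, hits$distance)
    idx <- match(paste(pairs$tf_id, pairs$tg_id,
                       pairs$closest_tfbs_distance), key)
    ok <- !is.na(idx)
    if (any(ok)) {
      hGR <- GenomicRanges::GRanges(hits$chrom[idx[ok]],
        IRanges::IRanges(hits$gstart[idx[ok]] + 1L, hits$gend[idx[ok]]))
      pairFlags$tfbs_in_stable_dhs[ok] <-
        as.integer(GenomicRanges::countOverlaps(hGR, stable) > 0)
      pairFlags$tfbs_in_dynamic_dhs[ok] <-
        as.integer(GenomicRanges::countOverlaps(hGR, dynamic) > 0)
    }
  }
  list(gene = gene, pair = pairFlags)
}

#' Features of adjacent genes
#'
#' For each gene and each boundary-to-boundary distance threshold: the
#' mean expression of neighboring genes, the mean number of promoter TFBS
#' hits in neighbors, and the number of distinct TFs with hits in both the
#' gene's and at least one neighbor's promoter. Genes without a neighbor
#' inside a threshold get zero counts and a missing mean expression
#' (imputed downstream).
#'
#' @param annotation a [GeneAnnotationSet-class].
#' @param expr expression matrix (rownames = gene ids).
#' @param hits hit table from [buildPairs()].
#' @param thresholds distances in bp, default \code{c(500, 1000, 2000,
#'   5000)}.
#' @return data.frame, one row per gene, three columns per threshold.
#' @export
adjacentGeneFeatures <- function(annotation, expr, hits,
                                 thresholds = c(500, 1000, 2000, 5000)) {
  genes <- geneTable(annotation)
  n <- nrow(genes)
  meanExpr <- rowMeans(expr)
  hitTFs <- split(hits$tf_id, hits$gene_id)
  nHits <- vapply(hitTFs, length, integer(1))
  res <- data.frame(gene_id = genes$gene_id)
  gap <- matrix(Inf, n, n)
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    s <- genes$gene_start[i]; e <- genes$gene_end[i]
    g <- pmax(outer(s, e, function(a, b) a - b),
              outer(e, s, function(a, b) b - a))
    g <- pmax(g, 0)
    diag(g) <- Inf
    gap[i, i] <- g
  }
  for (thr in thresholds) {
    lab <- function(x) sprintf("adj_%s_%gkb", x, thr / 1000)
    me <- nb <- sh <- numeric(n)
    for (i in seq_len(n)) {
      nbr <- genes$gene_id[which(gap[i, ] <= thr)]
      if (!length(nbr)) {
        me[i] <- NA_real_; nb[i] <- 0; sh[i] <- 0
        next
      }
      inExpr <- nbr[nbr %in% names(meanExpr)]
      me[i] <- if (length(inExpr)) mean(meanExpr[inExpr]) else NA_real_
      nb[i] <- mean(ifelse(nbr %in% names(nHits), nHits[nbr], 0))
      own <- hitTFs[[genes$gene_id[i]]]
      sh[i] <- length(intersect(unique(own),
                                unique(unlist(hitTFs[nbr]))))
    }
    res[[lab("mean_expr")]] <- me
    res[[lab("mean_tfbs")]] <- nb
    res[[lab("shared_tfbs")]] <- sh
  }
  res
}

# Median imputation per column; returns list(values, mask).
imputeMedian <- function(df, idCol) {
  mask <- as.data.frame(lapply(df, is.na))
  mask[[idCol]] <- FALSE
  for (cl in setdiff(names(df), idCol)) {
    x <- df[[cl]]
    if (anyNA(x)) {
      med <- median(x, na.rm = TRUE)
      if (is.na(med)) med <- 0
      x[is.na(x)] <- med
      df[[cl]] <- x
    }
  }
  list(values = df, mask = mask)
}

featureRegistry <- function(dmrNames) {
  tfFeat <- rbind(
    data.frame(name = c("motif_length", "motif_entropy",
                        "motif_core_entropy", "motif_pct_a", "motif_pct_c",
                        "motif_pct_g", "motif_pct_t", "motif_at_gc_ratio",
                        "motif_ag_tc_ratio", "tfbs_dist_mean_tf",
                        "tfbs_dist_sd_tf", "n_targets_tf",
                        "net_in_degree_tf", "net_out_degree_tf",
                        "net_in_ratio_tf"),
               category = "tfbs_info"),
    data.frame(name = c("half_life_tf", "phospho_sites_tf",
                        "ppi_distance_to_polII", "ppi_degree_tf",
                        "ppi_self_interaction_tf", "mirna_sites_mrna_tf",
                        "mirna_sites_intron_tf",
                        "mirna_max_energy_ratio_tf", "mirna_mimic_sites_tf",
                        "mirna_mimic_max_energy_ratio_tf", "dbd_count_tf",
                        "dbd1_rel_start_tf", "dbd2_rel_start_tf"),
               category = "post_tx_ptm_ppi"),
    data.frame(name = c(outer(c("mrna_len", "protein_len", "utr5_len",
                                "utr3_len"),
                              c("_min_tf", "_mean_tf", "_max_tf"),
                              paste0),
                        "isoform_count_tf", "protein_len_diff_tf",
                        "utr5_intron_tf", "upstream_distance_tf",
                        "tata_tf", "age_tf",
                        paste0("prom_pct_", tolower(DNA_BASES), "_tf"),
                        paste0("prom_", tolower(c(t(outer(DNA_BASES,
                          DNA_BASES, paste0)))), "_tf")),
               category = "genomic_annotation"))
  tfFeat$source <- "TF"
  tgFeat <- rbind(
    data.frame(name = c("tfbs_dist_mean_tg", "tfbs_dist_sd_tg",
                        "n_regulators_tg"),
               category = "tfbs_info"),
    data.frame(name = c("half_life_tg", "mirna_sites_mrna_tg",
                        "mirna_sites_intron_tg",
                        "mirna_max_energy_ratio_tg", "mirna_mimic_sites_tg",
                        "mirna_mimic_max_energy_ratio_tg"),
               category = "post_tx_ptm_ppi"),
    data.frame(name = c(outer(c("mrna_len", "protein_len", "utr5_len",
                                "utr3_len"),
                              c("_min_tg", "_mean_tg", "_max_tg"),
                              paste0),
                        "isoform_count_tg", "protein_len_diff_tg",
                        "utr5_intron_tg", "upstream_distance_tg",
                        "tata_tg", "age_tg",
                        paste0("prom_pct_", tolower(DNA_BASES), "_tg"),
                        paste0("prom_", tolower(c(t(outer(DNA_BASES,
                          DNA_BASES, paste0)))), "_tg"),
                        c(t(outer(c("adj_mean_expr", "adj_mean_tfbs",
                                    "adj_shared_tfbs"),
                                  c("_0.5kb", "_1kb", "_2kb", "_5kb"),
                                  paste0)))),
               category = "genomic_annotation"),
    data.frame(name = c(c(t(outer(dmrNames, c("_promoter", "_tss",
                                              "_body"), paste0))),
                        "dhs_stable_promoter_tg", "dhs_dynamic_promoter_tg",
                        "dhs_stable_body_tg", "dhs_dynamic_body_tg",
                        "epimark_pct_tg"),
               category = "epigenetics"))
  tgFeat$source <- "TG"
  pairFeat <- data.frame(
    name = c("pair_tfbs_distance", "half_life_product", "age_difference",
             "tfbs_in_stable_dhs", "tfbs_in_dynamic_dhs"),
    category = c("tfbs_info", "post_tx_ptm_ppi", "genomic_annotation",
                 "epigenetics", "epigenetics"),
    source = "pair")
  rbind(tfFeat, tgFeat, pairFeat)
}

#' Assemble the imputed pairs-by-features matrix
#'
#' Joins the TF-level, TG-level and pair-level feature blocks onto the
#' pair rows. Missing values are imputed with the per-column median,
#' separately within the TF table and within the TG table, and the
#' imputed cells are recorded in a mask. Pair-level derived columns (the
#' half-life product, the TG-minus-TF age difference) use the imputed
#' inputs.
#'
#' @param pairs labeled pair table (from [labelPairs()]).
#' @param annotation a [GeneAnnotationSet-class].
#' @param promoters named promoter sequences.
#' @param pwms named list of [MotifPWM-class].
#' @param hits hit table from [buildPairs()].
#' @param expr normalized expression matrix.
#' @param aux auxiliary-table list as produced by [generateAuxTables()]
#'   (or read from files with the same schemas).
#' @return a [FeatureMatrix-class].
#' @export
assembleFeatures <- function(pairs, annotation, promoters, pwms, hits,
                             expr, aux) {
  genes <- geneTable(annotation)
  tfIds <- sort(unique(pairs$tf_id))
  tgIds <- sort(unique(pairs$tg_id))
  stats <- tfbsDistanceStats(hits, pairs)
  net <- regulatoryNetworkFeatures(pairs, genes$gene_id[genes$is_tf])
  annF <- annotationFeatures(annotation)
  epi <- epigeneticFeatures(aux$dmrTracks, aux$dhsTracks, annotation,
                            pairs, hits)
  adj <- adjacentGeneFeatures(annotation, expr, hits)
  promComp <- t(vapply(names(promoters), function(g)
    promoterComposition(promoters[[g]]), numeric(20)))
  colnames(promComp) <- paste0("prom_", colnames(promComp))
  tata <- vapply(names(promoters), function(g) tataBox(promoters[[g]]),
                 integer(1))

  mergeOn <- function(base, tab, key) {
    merge(base, tab, by = key, all.x = TRUE, sort = FALSE)
  }
  # ---- TF block ----
  motif <- t(vapply(tfIds, function(tf) {
    c(motifComposition(pwms[[tf]])[c("length", "pct_a", "pct_c", "pct_g",
                                     "pct_t", "at_gc_ratio",
                                     "ag_tc_ratio")],
      motifEntropy(pwms[[tf]]))
  }, numeric(9)))
  tfTab <- data.frame(tf_id = tfIds,
                      motif_length = motif[, "length"],
                      motif_entropy = motif[, "se"],
                      motif_core_entropy = motif[, "core5_se"],
                      motif_pct_a = motif[, "pct_a"],
                      motif_pct_c = motif[, "pct_c"],
                      motif_pct_g = motif[, "pct_g"],
                      motif_pct_t = motif[, "pct_t"],
                      motif_at_gc_ratio = motif[, "at_gc_ratio"],
                      motif_ag_tc_ratio = motif[, "ag_tc_ratio"])
  st <- stats$tf; names(st) <- c("tf_id", "n_targets_tf",
                                 "tfbs_dist_mean_tf", "tfbs_dist_sd_tf")
  tfTab <- mergeOn(tfTab, st, "tf_id")
  nt <- net$tf
  names(nt) <- c("tf_id", "net_in_degree_tf", "net_out_degree_tf",
                 "net_in_ratio_tf", "no_edges")
  tfTab <- mergeOn(tfTab, nt[, 1:4], "tf_id")
  hl <- aux$halfLife; names(hl) <- c("tf_id", "half_life_tf")
  tfTab <- mergeOn(tfTab, hl, "tf_id")
  ph <- aux$phospho; names(ph) <- c("tf_id", "phospho_sites_tf")
  tfTab <- mergeOn(tfTab, ph, "tf_id")
  ppi <- ppiFeatures(aux$ppiEdges, aux$polIIId, tfIds)
  names(ppi) <- c("tf_id", "ppi_distance_to_polII", "ppi_degree_tf",
                  "ppi_self_interaction_tf")
  tfTab <- mergeOn(tfTab, ppi, "tf_id")
  mi <- aux$mirna
  names(mi) <- c("tf_id", "mirna_sites_mrna_tf", "mirna_sites_intron_tf",
                 "mirna_max_energy_ratio_tf", "mirna_mimic_sites_tf",
                 "mirna_mimic_max_energy_ratio_tf")
  tfTab <- mergeOn(tfTab, mi, "tf_id")
  db <- aux$dbd
  names(db) <- c("tf_id", "dbd_count_tf", "dbd1_rel_start_tf",
                 "dbd2_rel_start_tf")
  tfTab <- mergeOn(tfTab, db, "tf_id")
  af <- annF
  names(af) <- c("tf_id",
                 paste0(rep(c("mrna_len", "protein_len", "utr5_len",
                              "utr3_len"), each = 3),
                        c("_min_tf", "_mean_tf", "_max_tf")),
                 "isoform_count_tf", "protein_len_diff_tf",
                 "utr5_intron_tf", "upstream_distance_tf")
  tfTab <- mergeOn(tfTab, af, "tf_id")
  ag <- aux$ages; names(ag) <- c("tf_id", "age_tf")
  tfTab <- mergeOn(tfTab, ag, "tf_id")
  pc <- data.frame(tf_id = rownames(promComp), promComp,
                   tata = tata[rownames(promComp)])
  names(pc) <- c("tf_id", paste0(colnames(promComp), "_tf"), "tata_tf")
  tfTab <- mergeOn(tfTab, pc, "tf_id")

  # ---- TG block ----
  st <- stats$tg; names(st) <- c("gene_id", "n_regulators_tg",
                                 "tfbs_dist_mean_tg", "tfbs_dist_sd_tg")
  tgTab <- data.frame(gene_id = tgIds)
  tgTab <- mergeOn(tgTab, st, "gene_id")
  hl <- aux$halfLife; names(hl) <- c("gene_id", "half_life_tg")
  tgTab <- mergeOn(tgTab, hl, "gene_id")
  mi <- aux$mirna
  names(mi) <- c("gene_id", "mirna_sites_mrna_tg", "mirna_sites_intron_tg",
                 "mirna_max_energy_ratio_tg", "mirna_mimic_sites_tg",
                 "mirna_mimic_max_energy_ratio_tg")
  tgTab <- mergeOn(tgTab, mi, "gene_id")
  af <- annF
  names(af) <- c("gene_id",
                 paste0(rep(c("mrna_len", "protein_len", "utr5_len",
                              "utr3_len"), each = 3),
                        c("_min_tg", "_mean_tg", "_max_tg")),
                 "isoform_count_tg", "protein_len_diff_tg",
                 "utr5_intron_tg", "upstream_distance_tg")
  tgTab <- mergeOn(tgTab, af, "gene_id")
  ag <- aux$ages; names(ag) <- c("gene_id", "age_tg")
  tgTab <- mergeOn(tgTab, ag, "gene_id")
  pc <- data.frame(gene_id = rownames(promComp), promComp,
                   tata = tata[rownames(promComp)])
  names(pc) <- c("gene_id", paste0(colnames(promComp), "_tg"), "tata_tg")
  tgTab <- mergeOn(tgTab, pc, "gene_id")
  aj <- adj
  names(aj) <- c("gene_id", names(adj)[-1])
  tgTab <- mergeOn(tgTab, aj, "gene_id")
  ep <- epi$gene
  names(ep) <- c("gene_id",
                 paste0(names(epi$gene)[-1],
                        ifelse(grepl("^(dhs|epimark)", names(epi$gene)[-1]),
                               "_tg", "")))
  tgTab <- mergeOn(tgTab, ep, "gene_id")

  dropped <- !(pairs$tf_id %in% tfTab$tf_id &
                 pairs$tg_id %in% tgTab$gene_id)
  if (any(dropped))
    message(sum(dropped), " pair(s) dropped: gene missing from all tables")
  pairs <- pairs[!dropped, , drop = FALSE]

  tfImp <- imputeMedian(tfTab, "tf_id")
  tgImp <- imputeMedian(tgTab, "gene_id")
  iTF <- match(pairs$tf_id, tfImp$values$tf_id)
  iTG <- match(pairs$tg_id, tgImp$values$gene_id)
  tfBlock <- tfImp$values[iTF, -1, drop = FALSE]
  tgBlock <- tgImp$values[iTG, -1, drop = FALSE]
  epiIdx <- match(paste(pairs$tf_id, pairs$tg_id),
                  paste(epi$pair$tf_id, epi$pair$tg_id))
  pairBlock <- data.frame(
    pair_tfbs_distance = pairs$closest_tfbs_distance,
    half_life_product = tfBlock$half_life_tf * tgBlock$half_life_tg,
    age_difference = tgBlock$age_tg - tfBlock$age_tf,
    tfbs_in_stable_dhs = epi$pair$tfbs_in_stable_dhs[epiIdx],
    tfbs_in_dynamic_dhs = epi$pair$tfbs_in_dynamic_dhs[epiIdx])
  reg <- featureRegistry(names(aux$dmrTracks))
  values <- cbind(tfBlock, tgBlock, pairBlock)
  values <- as.matrix(values[, reg$name])
  rownames(values) <- paste(pairs$tf_id, pairs$tg_id, sep = ":")
  mask <- cbind(as.matrix(tfImp$mask[iTF, -1, drop = FALSE]),
                as.matrix(tgImp$mask[iTG, -1, drop = FALSE]),
                matrix(FALSE, nrow(pairs), ncol(pairBlock),
                       dimnames = list(NULL, names(pairBlock))))
  mask <- mask[, reg$name, drop = FALSE]
  rownames(mask) <- rownames(values)
  new("FeatureMatrix", values = values, featureInfo = reg,
      pairInfo = pairs[, c("tf_id", "tg_id", "pearson_r", "label")],
      imputed = mask)
}
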
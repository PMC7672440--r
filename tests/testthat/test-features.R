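test_that("motif entropy follows the closed forms", {
  expect_equal(unname(motifEntropy(motifPWM("t", matrix(0.25, 3, 4)))["se"]),
               log(4))
  expect_equal(unname(motifEntropy(motifPWM("t", diag(4)[c(2, 2), ]))["se"]),
               0)
  two <- motifPWM("t", rbind(c(0.5, 0.5, 0, 0), rep(0.25, 4)))
  expect_equal(unname(motifEntropy(two)["se"]), (log(2) + log(4)) / 2,
               tolerance = 1e-9)
  expect_equal(unname(motifEntropy(two)["core5_se"]),
               (log(2) + log(4)) / 2)  # N < 5 uses all positions
  # bounds and the core relation for long motifs
  for (s in 1:25) {
    pwm <- randomPWM(5 + s %% 4, s)
    e <- motifEntropy(pwm)
    expect_true(all(e >= 0 & e <= log(4) + 1e-12))
    expect_lte(e["core5_se"], e["se"] + 1e-12)
  }
  # log2 output on request
  expect_equal(unname(motifEntropy(motifPWM("t", matrix(0.25, 2, 4)),
                                   base = 2)["se"]), 2)
})

test_that("motif composition ratios match hand computation", {
  pwm <- motifPWM("t", matrix(rep(c(0.4, 0.1, 0.1, 0.4), 3), 3, 4,
                              byrow = TRUE))
  mc <- motifComposition(pwm)
  expect_equal(unname(mc["at_gc_ratio"]), 4, tolerance = 1e-6)
  expect_equal(unname(mc["ag_tc_ratio"]), 1, tolerance = 1e-6)
  u <- motifComposition(motifPWM("t", matrix(0.25, 5, 4)))
  expect_equal(unname(u[c("at_gc_ratio", "ag_tc_ratio")]), c(1, 1),
               tolerance = 1e-6)
  expect_equal(unname(u[c("pct_a", "pct_t")]), c(0.25, 0.25))
  # degenerate poly-A motif hits the denominator guard
  expect_message(pa <- motifComposition(motifPWM("t", diag(4)[c(1, 1), ])),
                 "guard")
  expect_gt(unname(pa["at_gc_ratio"]), 1e6)
})

test_that("regulatory-network degrees match an adjacency-matrix oracle", {
  tfs <- sprintf("t%d", 1:5)
  # hand-built digraph among TFs plus two non-TF targets
  pairs <- data.frame(
    tf_id = c("t1", "t1", "t2", "t3", "t3", "t4", "t1"),
    tg_id = c("t2", "t3", "t3", "t1", "g1", "t1", "g2"))
  adj <- matrix(0, 5, 5, dimnames = list(tfs, tfs))
  for (i in seq_len(nrow(pairs)))
    if (pairs$tg_id[i] %in% tfs) adj[pairs$tf_id[i], pairs$tg_id[i]] <- 1
  net <- regulatoryNetworkFeatures(pairs, tfs)
  expect_equal(net$tf$out_degree, unname(rowSums(adj)))
  expect_equal(net$tf$in_degree, unname(colSums(adj)))
  # two regulators and two TF-targets give ratio 0.5 (t1: in t3,t4)
  expect_equal(net$tf$in_ratio[net$tf$tf_id == "t1"], 0.5)
  expect_equal(net$tf$in_ratio[net$tf$tf_id == "t2"], 0.5)
  # a top-level TF (no regulators, one TF-target) has ratio 0
  expect_equal(net$tf$in_ratio[net$tf$tf_id == "t4"], 0)
  expect_false(net$tf$no_edges[net$tf$tf_id == "t4"])
  # a TF with no edges at all is flagged with ratio 0
  expect_equal(net$tf$in_ratio[net$tf$tf_id == "t5"], 0)
  expect_true(net$tf$no_edges[net$tf$tf_id == "t5"])
  # per-gene regulator counts cover non-TF targets
  expect_equal(net$gene$n_regulators[net$gene$gene_id == "g1"], 1)
})

test_that("interaction-network features use the stated sentinels", {
  edges <- data.frame(
    from = c("tfA", "P1", "tfB", "tfC", "tfC"),
    to = c("P1", "PolII", "PolII", "orphan", "tfC"))
  res <- ppiFeatures(edges, "PolII", c("tfA", "tfB", "tfC", "tfD"))
  expect_equal(res$ppi_distance_to_polII[res$tf_id == "tfA"], 2)
  expect_equal(res$ppi_distance_to_polII[res$tf_id == "tfB"], 1)
  expect_equal(res$ppi_distance_to_polII[res$tf_id == "tfC"], 1000)
  expect_equal(res$ppi_distance_to_polII[res$tf_id == "tfD"], 2000)
  expect_equal(res$ppi_degree[res$tf_id == "tfD"], 0)
  expect_equal(res$ppi_self_interaction[res$tf_id == "tfC"], 1)
  expect_equal(res$ppi_self_interaction[res$tf_id == "tfA"], 0)
  expect_error(ppiFeatures(edges, "missing", "tfA"), "missing")
})

test_that("promoter composition counts sliding dinucleotide windows", {
  pc <- promoterComposition("ACGT")
  expect_equal(unname(pc[c("ac", "cg", "gt")]), c(1, 1, 1))
  expect_equal(sum(pc[5:20]), 3)  # P - 1 windows
  pa <- promoterComposition("AAAA")
  expect_equal(unname(pa["aa"]), 3)
  expect_equal(unname(pa["pct_a"]), 100)
  long <- randomSeq(500, 9)
  expect_equal(sum(promoterComposition(long)[5:20]), 499)
})

test_that("TATA-box detection is forward-only within 60 bp of the TSS", {
  expect_equal(tataBox(paste0(strrep("C", 100), "TATAAA",
                              strrep("C", 24))), 1)  # at -30
  expect_equal(tataBox(paste0(strrep("C", 100), "TATATA",
                              strrep("C", 4))), 1)   # W = T, at -10
  # reverse-complement occurrence only (TTTATA revcomp of TATAAA)
  expect_equal(tataBox(paste0(strrep("C", 100), "TTTATA",
                              strrep("C", 24))), 0)
  # a match farther than 60 bp upstream does not count
  expect_equal(tataBox(paste0("TATAAA", strrep("C", 100))), 0)
  expect_message(short <- tataBox("CCTATAAACC"), "shorter")
  expect_equal(short, 1)
})

test_that("annotation aggregates equal a spreadsheet-style oracle", {
  af <- annotationFeatures(toyAnnotation())
  g1 <- af[af$gene_id == "g1", ]
  expect_equal(g1$protein_len_mean, 175)
  expect_equal(g1$utr5_len_min, 30)
  expect_equal(g1$utr5_len_max, 60)
  expect_equal(g1$isoform_count, 2)
  expect_equal(g1$utr5_intron, 1L)
  single <- af[af$gene_id == "g2", ]
  expect_equal(single$mrna_len_min, single$mrna_len_max)
  expect_equal(single$mrna_len_min, single$mrna_len_mean)
})

test_that("DHS stability split and DMR counts match definitions", {
  ann <- toyAnnotation()
  core <- data.frame(chrom = "chr1", start = 4600, end = 4700)
  only1 <- data.frame(chrom = "chr1", start = 4800, end = 4900)
  tracks <- list(a = rbind(core, only1), b = core, c = core, d = core)
  dmr <- list(dmr_x = data.frame(chrom = "chr1", start = c(4550, 5500),
                                 end = c(4650, 5600)))
  pairs <- data.frame(tf_id = "tf1", tg_id = "g1",
                      closest_tfbs_distance = -350L)
  hits <- data.frame(tf_id = "tf1", gene_id = "g1", chrom = "chr1",
                     start = 140L, end = 150L, gstart = 4640L,
                     gend = 4650L, strand_of_hit = "+",
                     distance = -350L, rel_score = 1)
  ep <- epigeneticFeatures(dmr, tracks, ann, pairs, hits)
  g1 <- ep$gene[ep$gene$gene_id == "g1", ]
  # g1 promoter is [4500, 5000): core DHS stable, only1 dynamic
  expect_equal(g1$dhs_stable_promoter, 1)
  expect_equal(g1$dhs_dynamic_promoter, 1)
  expect_equal(g1$dmr_x_promoter, 1)
  expect_equal(g1$dmr_x_body, 1)
  # mark types: 1 DMR track + stable + dynamic = 3 of 3 present
  expect_equal(g1$epimark_pct, 1)
  tf1 <- ep$gene[ep$gene$gene_id == "tf1", ]
  expect_equal(tf1$epimark_pct, 0)
  # the pair's closest TFBS interval [4640, 4650) overlaps the stable DHS
  expect_equal(ep$pair$tfbs_in_stable_dhs, 1L)
  expect_equal(ep$pair$tfbs_in_dynamic_dhs, 0L)
})

test_that("interval overlap counts equal a quadratic brute-force oracle", {
  for (s in 1:15) {
    set.seed(s)
    track <- data.frame(chrom = "chr1",
                        start = sample(0:2000, 40, replace = TRUE))
    track$end <- track$start + sample(10:200, 40, replace = TRUE)
    regions <- data.frame(chrom = "chr1",
                          start = sample(0:2000, 12, replace = TRUE))
    regions$end <- regions$start + sample(50:400, 12, replace = TRUE)
    regGR <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
    got <- GenomicRanges::countOverlaps(regGR,
                                        regcouple:::bedToGRanges(track))
    expect_equal(unname(got), oracleOverlapCount(regions, track))
  }
})

test_that("adjacent-gene features respect thresholds and nest", {
  genes <- data.frame(
    gene_id = c("a", "b", "c"),
    chrom = "chr1", strand = "+",
    gene_start = c(0L, 1300L, 50000L),
    gene_end = c(1000L, 2000L, 51000L),
    tss = c(0L, 1300L, 50000L), is_tf = FALSE,
    upstream_gene_distance = NA_integer_)
  iso <- data.frame(gene_id = genes$gene_id,
                    isoform_id = paste0(genes$gene_id, ".1"),
                    mrna_len = 500L, protein_len = 100L, utr5_len = 50L,
                    utr3_len = 50L, utr5_has_intron = FALSE)
  ann <- geneAnnotationSet(genes, iso)
  expr <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  hits <- data.frame(tf_id = "t1", gene_id = c("a", "b"), chrom = "chr1",
                     start = 0L, end = 10L, gstart = 0L, gend = 10L,
                     strand_of_hit = "+", distance = -10L, rel_score = 1)
  adj <- adjacentGeneFeatures(ann, expr, hits)
  cIdx <- adj$gene_id == "c"
  expect_true(all(adj[cIdx, grep("tfbs", names(adj))] == 0))  # isolated
  expect_true(all(is.na(adj[cIdx, grep("mean_expr", names(adj))])))
  # a and b are 300 bp apart and share t1 at every threshold
  aIdx <- adj$gene_id == "a"
  for (thr in c("0.5kb", "1kb", "2kb", "5kb"))
    expect_equal(adj[aIdx, paste0("adj_shared_tfbs_", thr)], 1)
  # neighbor sets nest: counts can only grow with the threshold
  expect_true(all(diff(unlist(
    adj[aIdx, paste0("adj_mean_tfbs_", c("0.5kb", "1kb", "2kb",
                                         "5kb"))])) >= 0))
})

test_that("assembled features are complete, tagged and imputed by median", {
  sim <- simulateRegulationData(simConfig(nTF = 6, nGene = 80,
                                          nSample = 20, seed = 55,
                                          missingFrac = 0.2))
  built <- buildPairs(sim$annotation, sim$promoters, sim$pwms)
  expr <- normalizeExpression(sim$expression, log = FALSE)
  pairs <- pairCorrelation(expr, built$pairs)
  pairs$label <- "unlabeled"
  fm <- assembleFeatures(pairs, sim$annotation, sim$promoters, sim$pwms,
                         built$hits, expr, sim$aux)
  v <- featureValues(fm)
  expect_false(anyNA(v))
  info <- featureInfo(fm)
  expect_true(all(info$source %in% c("TF", "TG", "pair")))
  expect_true(all(info$category %in%
                    c("tfbs_info", "post_tx_ptm_ppi",
                      "genomic_annotation", "epigenetics")))
  expect_gt(ncol(v), 120)
  expect_lt(ncol(v), 165)
  # imputed cells carry the column median of the source table
  mask <- imputedMask(fm)
  expect_gt(sum(mask), 0)
  hlCol <- "half_life_tf"
  miss <- mask[, hlCol]
  if (any(miss)) {
    tfVals <- sim$aux$halfLife$half_life[
      match(unique(pairs$tf_id), sim$aux$halfLife$gene_id)]
    expect_equal(unique(v[miss, hlCol]),
                 median(tfVals, na.rm = TRUE))
  }
  # derived pair columns
  expect_equal(v[, "half_life_product"],
               v[, "half_life_tf"] * v[, "half_life_tg"])
  expect_equal(v[, "age_difference"], v[, "age_tg"] - v[, "age_tf"])
  expect_true(all(v[, "age_difference"] >= -12 &
                    v[, "age_difference"] <= 12))
  # TF-sourced columns are constant within a TF
  tfCols <- info$name[info$source == "TF"]
  byTf <- split(seq_len(nrow(v)), pairInfo(fm)$tf_id)
  for (cl in tfCols[c(1, 10, 25)])
    for (idx in byTf) expect_equal(length(unique(v[idx, cl])), 1)
})
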
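test_that("log-odds scoring matches hand computation", {
  oneHot <- motifPWM("t", diag(4)[c(1, 2, 3), ])
  expect_equal(pwmLogOdds(oneHot, "ACG"), 3 * log2(1.0001 / 0.25),
               tolerance = 1e-10)
  unif <- motifPWM("t", matrix(0.25, 4, 4))
  expect_equal(pwmLogOdds(unif, "ACGT"), 4 * log2(0.2501 / 0.25),
               tolerance = 1e-10)
  expect_error(pwmLogOdds(oneHot, "ACN"), "ambiguity")
  expect_error(pwmLogOdds(oneHot, "AC"), "length")
})

test_that("scores stay inside the per-column bounds", {
  for (s in 1:20) {
    pwm <- randomPWM(4, s)
    w <- randomSeq(4, s + 100)
    b <- regcouple:::scoreBounds(pwm)
    sc <- pwmLogOdds(pwm, w)
    expect_gte(sc, b["min"] - 1e-9)
    expect_lte(sc, b["max"] + 1e-9)
  }
})

test_that("the scanner equals exhaustive window enumeration", {
  for (case in 1:200) {
    L <- 2 + (case %% 5)
    n <- 8 + (case %% 23)
    pwm <- randomPWM(L, case)
    seq <- randomSeq(n, case + 5000)
    thr <- c(0.5, 0.7, 0.8)[1 + case %% 3]
    got <- scanPromoter(pwm, seq, relThreshold = thr)
    want <- oracleScan(pwm, seq, relThreshold = thr)
    expect_equal(nrow(got), nrow(want), label = paste("case", case))
    if (nrow(got)) {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_equal(got$rel_score, want$rel_score, tolerance = 1e-9)
    }
  }
})

test_that("a planted consensus is the unique perfect hit", {
  pwm <- randomPWM(6, 77)  # informative, random
  probs <- pwmProbs(pwm)
  # sharpen to near one-hot so off-consensus windows score low
  probs <- probs * 0.02 + diag(4)[max.col(probs), ] * 0.98
  pwm <- motifPWM("t", probs)
  cons <- consensusSeq(pwm)
  seq <- paste0(strrep("A", 10), cons, strrep("C", 10))
  hits <- scanPromoter(pwm, seq, relThreshold = 0.99)
  expect_equal(nrow(hits[hits$strand == "+", ]), 1)
  expect_equal(hits$start[hits$strand == "+"], 10)
  expect_equal(hits$rel_score[hits$strand == "+"], 1, tolerance = 1e-9)
  # threshold 1.0 with no consensus present
  none <- scanPromoter(pwm, strrep("A", 30), relThreshold = 1)
  expect_equal(nrow(none), 0)
})

test_that("promoters shorter than the motif yield an empty warning", {
  pwm <- motifPWM("t", matrix(0.25, 6, 4))
  expect_warning(h <- scanPromoter(pwm, "ACG"), "shorter")
  expect_equal(nrow(h), 0)
})

test_that("TFBS-TSS distances follow the nearest-edge gap convention", {
  expect_equal(tfbsDistance(940, 950, 1000, "+"), -50)
  expect_equal(tfbsDistance(995, 1005, 1000, "+"), 0)   # covers the TSS
  expect_equal(tfbsDistance(1051, 1061, 1000, "-"), -50)  # mirrored
  expect_equal(tfbsDistance(1001, 1011, 1000, "+"), 0)  # book-ended
  expect_equal(tfbsDistance(900, 950, 1000, "-"), 50)   # downstream on -
})

test_that("pair building recovers exactly the planted pairs", {
  sim <- simulateRegulationData(simConfig(nTF = 5, nGene = 60,
                                          nSample = 5,
                                          entropyLevels = 0.1,
                                          seed = 41))
  built <- buildPairs(sim$annotation, sim$promoters, sim$pwms)
  planted <- paste(sim$plan$tf_id, sim$plan$tg_id)
  got <- paste(built$pairs$tf_id, built$pairs$tg_id)
  expect_true(all(planted %in% got))  # 100% recall
  # every planted offset is among that pair's hit distances, and the
  # pair-level distance is never farther from the TSS than the plant
  hk <- paste(built$hits$tf_id, built$hits$gene_id, built$hits$distance)
  expect_true(all(paste(sim$plan$tf_id, sim$plan$tg_id,
                        sim$plan$offset) %in% hk))
  one <- built$pairs[got %in% planted, ]
  m <- match(paste(one$tf_id, one$tg_id), planted)
  expect_true(all(abs(one$closest_tfbs_distance) <=
                    abs(sim$plan$offset[m])))
})

test_that("genes without an annotated 5'UTR are excluded from pairing", {
  ann <- toyAnnotation()
  iso <- isoformTable(ann)
  iso$utr5_len[iso$gene_id == "g1"] <- 0L
  ann0 <- geneAnnotationSet(geneTable(ann), iso)
  pwm <- motifPWM("tf1", diag(4)[c(1, 2, 3, 4, 1, 2), ])
  proms <- c(tf1 = randomSeq(200, 1), g1 = randomSeq(200, 2),
             g2 = randomSeq(200, 3))
  # plant the consensus in both promoters
  substr(proms[["g1"]], 100, 105) <- consensusSeq(pwm)
  substr(proms[["g2"]], 100, 105) <- consensusSeq(pwm)
  built <- buildPairs(ann0, proms, list(tf1 = pwm))
  expect_false("g1" %in% built$pairs$tg_id)
  expect_true("g2" %in% built$pairs$tg_id)
})

test_that("a TF without a PWM is an error listing the TF", {
  expect_error(buildPairs(toyAnnotation(),
                          c(tf1 = "ACGT", g1 = "ACGT", g2 = "ACGT"),
                          list()),
               "tf1")
})

test_that("distance summaries use the sample SD and the stats window", {
  hits <- data.frame(tf_id = "tf1", gene_id = c("g1", "g2", "g3"),
                     chrom = "chr1", start = 0L, end = 10L,
                     gstart = 0L, gend = 10L, strand_of_hit = "+",
                     distance = c(-100L, -300L, -1200L), rel_score = 1)
  pairs <- data.frame(tf_id = "tf1", tg_id = c("g1", "g2", "g3"),
                      closest_tfbs_distance = c(-100L, -300L, -1200L))
  st <- tfbsDistanceStats(hits, pairs)
  expect_equal(st$tf$dist_mean, -200)       # -1200 outside the window
  expect_equal(st$tf$dist_sd, 141.42, tolerance = 1e-4)
  expect_equal(st$tf$n_targets, 3)          # counts come from the pairs
  one <- tfbsDistanceStats(hits[1, ], pairs[1, ])
  expect_equal(one$tg$dist_sd, 0)           # single hit
})
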
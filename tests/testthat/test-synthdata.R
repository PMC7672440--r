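test_that("simulation outputs are byte-identical under a fixed seed", {
  cfg <- simConfig(nTF = 4, nGene = 20, nSample = 5, seed = 11)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  writeSimulation(simulateRegulationData(cfg), d1)
  writeSimulation(simulateRegulationData(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty genome is generated without error", {
  g <- generateGenome(simConfig(nTF = 0, nGene = 0, nSample = 5))
  expect_equal(nrow(geneTable(g$annotation)), 0)
  expect_length(g$promoters, 0)
})

test_that("isoform length bookkeeping reports min and max", {
  af <- annotationFeatures(toyAnnotation())
  g1 <- af[af$gene_id == "g1", ]
  expect_equal(g1$mrna_len_min, 100)
  expect_equal(g1$mrna_len_max, 200)
  expect_equal(g1$protein_len_diff, 150)
})

test_that("PWM columns hit their entropy targets", {
  cfg0 <- simConfig(nTF = 3, nGene = 10, nSample = 5,
                    entropyLevels = 0, seed = 2)
  pwms0 <- generatePWMs(cfg0)
  for (p in pwms0) {
    expect_true(all(pwmProbs(p) %in% c(0, 1)))  # one-hot columns
    expect_equal(unname(motifEntropy(p)["se"]), 0)
  }
  cfgU <- simConfig(nTF = 2, nGene = 10, nSample = 5,
                    entropyLevels = log(4), seed = 2)
  for (p in generatePWMs(cfgU))
    expect_equal(unname(pwmProbs(p)), matrix(0.25, motifLength(p), 4),
                 tolerance = 1e-9)
  cfgM <- simConfig(nTF = 6, nGene = 10, nSample = 5,
                    entropyLevels = c(0.2, 0.7, 1.1), seed = 3)
  for (i in seq_along(pw <- generatePWMs(cfgM))) {
    target <- rep_len(c(0.2, 0.7, 1.1), 6)[i]
    expect_lt(abs(motifEntropy(pw[[i]])["se"] - target), 0.1)
    expect_true(all(abs(rowSums(pwmProbs(pw[[i]])) - 1) < 1e-9))
  }
})

test_that("a planted motif is recovered by the scanner at its offset", {
  sim <- simulateRegulationData(simConfig(nTF = 3, nGene = 30,
                                          nSample = 5, seed = 4))
  row <- sim$plan[1, ]
  hits <- scanPromoter(sim$pwms[[row$tf_id]],
                       sim$promoters[[row$tg_id]])
  P <- nchar(sim$promoters[[row$tg_id]])
  d <- hits$end - P
  expect_true(row$offset %in% d)
})

test_that("an out-of-window planted offset errors naming the pair", {
  pwms <- list(tf1 = motifPWM("tf1", diag(4)[c(1, 2, 3), ]))
  prom <- c(g5 = strrep("A", 50))
  expect_error(
    plantMotifs(pwms, prom,
                data.frame(tf_id = "tf1", tg_id = "g5", offset = -60)),
    "tf1.*g5")
})

test_that("coupled-pair correlation matches the analytic value", {
  sim <- simulateRegulationData(simConfig(nTF = 10, nGene = 300,
                                          nSample = 2000, fracCoupled = 0.5,
                                          couplingBeta = 1, noiseSd = 1,
                                          seed = 21))
  cp <- coupledPairs(sim$truth)
  r <- vapply(seq_len(nrow(cp)), function(i)
    cor(sim$expression[cp$tf_id[i], ], sim$expression[cp$tg_id[i], ]),
    numeric(1))
  expect_lt(abs(mean(r) - 1 / sqrt(2)), 0.05)
  expect_equal(unique(expectedPairR(sim$truth)$expected_r[
    paste(expectedPairR(sim$truth)$tf_id,
          expectedPairR(sim$truth)$tg_id) %in%
      paste(cp$tf_id, cp$tg_id)]), 1 / sqrt(2))
})

test_that("beta = 0 gives independent pairs and tiny sigma near-perfect r", {
  sim0 <- simulateRegulationData(simConfig(nTF = 10, nGene = 200,
                                           nSample = 2000,
                                           fracCoupled = 0.5,
                                           couplingBeta = 0, seed = 22))
  cp <- coupledPairs(sim0$truth)
  r0 <- vapply(seq_len(nrow(cp)), function(i)
    cor(sim0$expression[cp$tf_id[i], ], sim0$expression[cp$tg_id[i], ]),
    numeric(1))
  expect_lt(abs(mean(r0)), 3 / sqrt(2000))
  simP <- simulateRegulationData(simConfig(nTF = 4, nGene = 60,
                                           nSample = 500,
                                           fracCoupled = 0.5,
                                           couplingBeta = 1,
                                           noiseSd = 1e-6, seed = 23))
  cpP <- coupledPairs(simP$truth)
  rP <- vapply(seq_len(nrow(cpP)), function(i)
    cor(simP$expression[cpP$tf_id[i], ], simP$expression[cpP$tg_id[i], ]),
    numeric(1))
  expect_true(all(rP > 0.999))
})

test_that("the expression matrix is complete and determined by the seed", {
  sim <- simulateRegulationData(simConfig(nTF = 3, nGene = 30,
                                          nSample = 10, seed = 5))
  expect_false(anyNA(sim$expression))
  expect_equal(dim(sim$expression), c(30, 10))
})

test_that("planted feature shifts are realized at the configured effect", {
  shifts <- c(ppi_distance_to_polII = 0.8, half_life_tf = -0.6,
              age_tg = 0.5)
  cfg <- simConfig(nTF = 400, nGene = 5000, nSample = 3,
                   fracCoupled = 0.5, targetsPerTf = 10,
                   featureShifts = shifts, missingFrac = 0, seed = 31)
  sim <- simulateRegulationData(cfg)
  expect_gte(nrow(plantedHits(sim$truth)), 2000)
  aux <- sim$aux
  plan <- sim$plan
  coupled <- paste(plan$tf_id, plan$tg_id) %in%
    paste(coupledPairs(sim$truth)$tf_id, coupledPairs(sim$truth)$tg_id)
  dObs <- function(v) {
    a <- v[coupled]; b <- v[!coupled]
    (mean(a) - mean(b)) / sqrt(((length(a) - 1) * var(a) +
                                  (length(b) - 1) * var(b)) /
                                 (length(a) + length(b) - 2))
  }
  ppi <- ppiFeatures(aux$ppiEdges, aux$polIIId, unique(plan$tf_id))
  dPpi <- dObs(ppi$ppi_distance_to_polII[match(plan$tf_id, ppi$tf_id)])
  expect_true(dPpi > 0.65 && dPpi < 0.95)
  hl <- aux$halfLife$half_life[match(plan$tf_id, aux$halfLife$gene_id)]
  expect_lt(abs(dObs(hl) - (-0.6)), 0.15)
  ag <- aux$ages$phylostratum[match(plan$tg_id, aux$ages$gene_id)]
  expect_lt(abs(dObs(ag) - 0.5), 0.15)
})

test_that("zero shifts leave auxiliary features at null effect sizes", {
  cfg <- simConfig(nTF = 400, nGene = 5000, nSample = 3,
                   fracCoupled = 0.5, targetsPerTf = 10,
                   missingFrac = 0, seed = 32)
  sim <- simulateRegulationData(cfg)
  plan <- sim$plan
  coupled <- paste(plan$tf_id, plan$tg_id) %in%
    paste(coupledPairs(sim$truth)$tf_id, coupledPairs(sim$truth)$tg_id)
  dObs <- function(v) {
    a <- v[coupled]; b <- v[!coupled]
    (mean(a) - mean(b)) / sqrt(((length(a) - 1) * var(a) +
                                  (length(b) - 1) * var(b)) /
                                 (length(a) + length(b) - 2))
  }
  hl <- sim$aux$halfLife$half_life[match(plan$tf_id,
                                         sim$aux$halfLife$gene_id)]
  mi <- sim$aux$mirna$sites_mrna[match(plan$tg_id,
                                       sim$aux$mirna$gene_id)]
  ag <- sim$aux$ages$phylostratum[match(plan$tg_id,
                                        sim$aux$ages$gene_id)]
  expect_lt(abs(dObs(hl)), 0.1)
  expect_lt(abs(dObs(mi)), 0.1)
  expect_lt(abs(dObs(ag)), 0.1)
})

test_that("unknown shift names error listing the valid names", {
  expect_error(simConfig(featureShifts = c(bogus_feature = 1)),
               "bogus_feature.*valid names")
})

test_that("the interaction graph always contains the polymerase node", {
  sim <- simulateRegulationData(simConfig(nTF = 5, nGene = 40,
                                          nSample = 5, seed = 6))
  expect_true("PolII" %in% unlist(sim$aux$ppiEdges))
  expect_equal(sim$aux$polIIId, "PolII")
})

test_that("identical DHS condition tracks make every site stable", {
  ann <- toyAnnotation()
  track <- data.frame(chrom = "chr1", start = c(600, 5200),
                      end = c(800, 5400))
  tracks <- list(a = track, b = track, c = track, d = track)
  pairs <- data.frame(tf_id = "tf1", tg_id = "g1",
                      closest_tfbs_distance = -100L)
  hits <- data.frame(tf_id = "tf1", gene_id = "g1", chrom = "chr1",
                     start = 390L, end = 400L, gstart = 4890L,
                     gend = 4900L, strand_of_hit = "+",
                     distance = -100L, rel_score = 1)
  ep <- epigeneticFeatures(list(), tracks, ann, pairs, hits)
  expect_true(all(ep$gene$dhs_dynamic_promoter == 0))
  expect_true(all(ep$gene$dhs_dynamic_body == 0))
  expect_gt(sum(ep$gene$dhs_stable_promoter), 0)
})
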
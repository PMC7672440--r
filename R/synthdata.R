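#' Configure the synthetic regulatory-genomics simulation
#'
#' Returns a validated [SimConfig-class]. Defaults describe a desk-scale
#' study: 20 TFs among 300 genes, 200 expression samples, 500-bp
#' promoters, 8-12 bp motifs at moderate information content, and a latent
#' activity model with \code{couplingBeta = 1}, \code{noiseSd = 1} (so a
#' coupled pair's expected Pearson correlation is
#' \code{1/sqrt(2) = 0.7071}).
#'
#' @param nTF,nGene,nSample problem sizes.
#' @param promoterLen promoter length (bp).
#' @param motifLenRange motif length range (bp).
#' @param entropyLevels target mean per-position entropies in nats,
#'   recycled over TFs.
#' @param couplingBeta,noiseSd latent-activity effect size and noise SD.
#' @param fracCoupled fraction of TFs whose pairs are coupled when
#'   \code{activeTfIds} is not given.
#' @param activeTfIds explicit coupled TF ids.
#' @param targetsPerTf planted targets per TF.
#' @param featureShifts named Cohen's-D-scale shifts planted into
#'   auxiliary features (see [validShiftFeatures()]).
#' @param missingFrac missing-cell fraction in auxiliary tables.
#' @param ppiAbsentFrac,ppiDisconnectedFrac fractions of TFs missing from
#'   / disconnected within the protein-interaction graph.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nTF = 20, nGene = 300, nSample = 200,
                      promoterLen = 500, motifLenRange = c(8, 12),
                      entropyLevels = c(0.1, 0.25, 0.4),
                      couplingBeta = 1, noiseSd = 1, fracCoupled = 0.25,
                      activeTfIds = character(0), targetsPerTf = 10,
                      featureShifts = numeric(0), missingFrac = 0.05,
                      ppiAbsentFrac = 0, ppiDisconnectedFrac = 0,
                      seed = 1L) {
  if (length(featureShifts)) {
    bad <- setdiff(names(featureShifts), validShiftFeatures())
    if (length(bad))
      stop("unknown feature name(s) in featureShifts: ",
           paste(bad, collapse = ", "), "; valid names are: ",
           paste(validShiftFeatures(), collapse = ", "))
  }
  new("SimConfig", nTF = as.integer(nTF), nGene = as.integer(nGene),
      nSample = as.integer(nSample), promoterLen = as.integer(promoterLen),
      motifLenRange = as.integer(motifLenRange),
      entropyLevels = as.numeric(entropyLevels),
      couplingBeta = as.numeric(couplingBeta),
      noiseSd = as.numeric(noiseSd), fracCoupled = as.numeric(fracCoupled),
      activeTfIds = as.character(activeTfIds),
      targetsPerTf = as.integer(targetsPerTf),
      featureShifts = featureShifts,
      missingFrac = as.numeric(missingFrac),
      ppiAbsentFrac = as.numeric(ppiAbsentFrac),
      ppiDisconnectedFrac = as.numeric(ppiDisconnectedFrac),
      seed = as.integer(seed))
}

#' Auxiliary features accepting a planted class shift
#'
#' Names usable in \code{featureShifts} of [simConfig()]; each is a column
#' of the assembled feature panel whose coupled-vs-uncoupled standardized
#' mean difference the generator controls.
#' @return character vector of feature names.
#' @export
validShiftFeatures <- function() {
  c("half_life_tf", "half_life_tg", "phospho_sites_tf",
    "ppi_distance_to_polII", "ppi_degree_tf",
    "mirna_sites_mrna_tf", "mirna_sites_mrna_tg",
    "mirna_sites_intron_tf", "mirna_sites_intron_tg",
    "mirna_max_energy_ratio_tf", "mirna_max_energy_ratio_tg",
    "mirna_mimic_sites_tf", "mirna_mimic_sites_tg",
    "mirna_mimic_max_energy_ratio_tf", "mirna_mimic_max_energy_ratio_tg",
    "age_tf", "age_tg")
}

# Deterministic per-stage sub-seed below 2^31.
subSeed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  as.integer((as.numeric(seed) * 1009 + sum(u * seq_along(u))) %%
               2147483641)
}

simGeneIds <- function(config) sprintf("G%04d", seq_len(config@nGene))

simActiveTfs <- function(config) {
  ids <- simGeneIds(config)[seq_len(config@nTF)]
  if (length(config@activeTfIds)) config@activeTfIds
  else ids[seq_len(round(config@fracCoupled * config@nTF))]
}

#' Generate gene models and promoter sequences
#'
#' Lays genes head-to-tail on one chromosome with random intergenic gaps,
#' assigns strand, TSS (gene start on +, last base on -), 1-3 isoforms
#' with mRNA/protein/UTR lengths and 5'UTR-intron flags, and the distance
#' to the closest upstream gene. A small fraction of non-TF genes is given
#' a zero-length 5'UTR (these are later filtered out of pairing).
#' Promoter sequences of \code{promoterLen} bp are drawn from a uniform
#' background composition, in coding orientation ending at TSS-1.
#'
#' @param config a [SimConfig-class].
#' @return list with \code{annotation} ([GeneAnnotationSet-class]) and
#'   \code{promoters} (named character vector of sequences).
#' @export
generateGenome <- function(config) {
  validObject(config)
  set.seed(subSeed(config@seed, "genome"))
  n <- config@nGene
  ids <- simGeneIds(config)
  if (n == 0L) {
    ann <- geneAnnotationSet(
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), gene_start = integer(0),
                 gene_end = integer(0), tss = integer(0),
                 is_tf = logical(0), upstream_gene_distance = integer(0)),
      data.frame(gene_id = character(0), isoform_id = character(0),
                 mrna_len = integer(0), protein_len = integer(0),
                 utr5_len = integer(0), utr3_len = integer(0),
                 utr5_has_intron = logical(0)))
    return(list(annotation = ann, promoters = character(0)))
  }
  gaps <- sample(200:6000, n, replace = TRUE)
  lens <- sample(800:3000, n, replace = TRUE)
  gstart <- config@promoterLen + 100L + cumsum(gaps) +
    c(0L, cumsum(lens[-n]))
  gend <- gstart + lens
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", gstart, gend - 1L)
  # upstream neighbor in coding orientation: previous gene for +, next for -
  gapPrev <- c(NA_integer_, gstart[-1] - gend[-n])
  gapNext <- c(gstart[-1] - gend[-n], NA_integer_)
  upstream <- ifelse(strand == "+", gapPrev, gapNext)
  isTF <- seq_len(n) <= config@nTF
  genes <- data.frame(gene_id = ids, chrom = "chr1", strand = strand,
                      gene_start = gstart, gene_end = gend, tss = tss,
                      is_tf = isTF, upstream_gene_distance = upstream)
  nIso <- sample(1:3, n, replace = TRUE)
  zeroUtr <- !isTF & runif(n) < 0.03
  isoList <- lapply(seq_len(n), function(i) {
    k <- nIso[i]
    mrna <- sort(sample(500:round(lens[i] * 0.9), k))
    utr5 <- if (zeroUtr[i]) rep(0L, k) else sample(20:200, k, replace = TRUE)
    utr3 <- sample(50:300, k, replace = TRUE)
    prot <- pmax(50L, (mrna - utr5 - utr3) %/% 3L)
    data.frame(gene_id = ids[i],
               isoform_id = sprintf("%s.%d", ids[i], seq_len(k)),
               mrna_len = mrna, protein_len = prot, utr5_len = utr5,
               utr3_len = utr3,
               utr5_has_intron = runif(k) < 0.15)
  })
  ann <- geneAnnotationSet(genes, do.call(rbind, isoList))
  proms <- vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, config@promoterLen, replace = TRUE),
          collapse = ""), "")
  names(proms) <- ids
  list(annotation = ann, promoters = proms)
}

# One PWM column with per-position entropy H (nats): (1-3a, a, a, a)
# with the dominant base at `base`; a solved so -sum p ln p = H.
entropyColumn <- function(H, base) {
  col <- rep(0, 4)
  if (H <= 1e-12) {
    col[base] <- 1
    return(col)
  }
  f <- function(a) {
    p <- c(1 - 3 * a, rep(a, 3))
    -sum(ifelse(p > 0, p * log(p), 0)) - H
  }
  a <- if (abs(H - log(4)) < 1e-12) 0.25 else
    stats::uniroot(f, c(1e-12, 0.25), tol = 1e-12)$root
  col[] <- a
  col[base] <- 1 - 3 * a
  col
}

#' Generate PWMs with controlled positional entropy
#'
#' One PWM per TF; motif lengths drawn from \code{motifLenRange} and every
#' column built to carry exactly the TF's target per-position entropy
#' (\code{entropyLevels} recycled over TFs), with a random consensus base
#' per position. Backgrounds are uniform.
#'
#' @param config a [SimConfig-class].
#' @return named list of [MotifPWM-class], names = TF gene ids.
#' @export
generatePWMs <- function(config) {
  validObject(config)
  set.seed(subSeed(config@seed, "pwms"))
  tfIds <- simGeneIds(config)[seq_len(config@nTF)]
  levels <- rep_len(config@entropyLevels, config@nTF)
  lens <- sample(seq(config@motifLenRange[1], config@motifLenRange[2]),
                 config@nTF, replace = TRUE)
  pwms <- lapply(seq_len(config@nTF), function(i) {
    probs <- t(vapply(seq_len(lens[i]), function(j)
      entropyColumn(levels[i], sample.int(4, 1)), numeric(4)))
    colnames(probs) <- DNA_BASES
    motifPWM(tfIds[i], probs)
  })
  names(pwms) <- tfIds
  pwms
}

#' Plant motif consensus sequences into promoters
#'
#' Writes the consensus of each pair's TF motif into the target's promoter
#' so that the hit's TSS-proximal edge sits at the requested signed offset
#' (e.g. offset -60 occupies \code{[TSS-60-L, TSS-60)} and is later
#' reported by the scanner at distance -60).
#'
#' @param pwms named list of [MotifPWM-class].
#' @param promoters named character vector of promoter sequences.
#' @param plan data.frame with \code{tf_id}, \code{tg_id}, \code{offset}
#'   (signed bp, in \code{[-promoterLen + L, -1]}).
#' @return the updated promoter vector.
#' @export
plantMotifs <- function(pwms, promoters, plan) {
  if (is.null(plan) || !nrow(plan)) return(promoters)
  P <- nchar(promoters[1])
  for (i in seq_len(nrow(plan))) {
    tf <- plan$tf_id[i]; tg <- plan$tg_id[i]; off <- plan$offset[i]
    L <- motifLength(pwms[[tf]])
    if (off > -1 || off - L < -P)
      stop("planted offset ", off, " outside promoter window for pair (",
           tf, ", ", tg, ")")
    s <- P + off - L + 1L  # 1-based substring start
    substr(promoters[[tg]], s, s + L - 1L) <- consensusSeq(pwms[[tf]])
  }
  promoters
}

#' Generate the expression matrix from the latent-activity model
#'
#' Each TF has a per-sample latent activity drawn once and shared by all
#' its coupled targets; the TF's own expression equals that activity, a
#' coupled target's is \code{beta * activity + Normal(0, noiseSd)}, and
#' every other gene is independent standard normal. A per-gene baseline
#' shifts means without touching correlations. By construction a coupled
#' pair's expected Pearson correlation is
#' \code{beta / sqrt(beta^2 + noiseSd^2)} and the matrix is complete and
#' log-scale.
#'
#' @param config a [SimConfig-class].
#' @param truth a [GroundTruth-class] listing the coupled pairs.
#' @return numeric genes x samples matrix, dimnames set.
#' @export
generateExpression <- function(config, truth) {
  validObject(config)
  set.seed(subSeed(config@seed, "expression"))
  ids <- simGeneIds(config)
  ns <- config@nSample
  tfIds <- ids[seq_len(config@nTF)]
  expr <- matrix(rnorm(length(ids) * ns), length(ids), ns,
                 dimnames = list(ids, sprintf("S%04d", seq_len(ns))))
  activity <- matrix(rnorm(config@nTF * ns), config@nTF, ns,
                     dimnames = list(tfIds, NULL))
  expr[tfIds, ] <- activity
  cp <- coupledPairs(truth)
  if (nrow(cp)) {
    dupTg <- duplicated(cp$tg_id)
    if (any(dupTg))
      message(sum(dupTg), " target(s) coupled to several TFs: ",
              "first TF used")
    cp <- cp[!dupTg, , drop = FALSE]
    for (i in seq_len(nrow(cp)))
      expr[cp$tg_id[i], ] <- config@couplingBeta * activity[cp$tf_id[i], ] +
        rnorm(ns, 0, config@noiseSd)
  }
  expr + rnorm(length(ids), 6, 1)  # per-gene baseline, recycled by row
}

# Entity-level value with a planted class shift: N(mu, s), coupled
# entities moved by shift * s.
shiftedValues <- function(n, mu, s, coupled, shift) {
  rnorm(n, mu, s) + shift * s * as.numeric(coupled)
}

injectMissing <- function(x, frac) {
  if (frac <= 0) return(x)
  x[runif(length(x)) < frac] <- NA
  x
}

#' Generate auxiliary tables, interaction network and interval tracks
#'
#' Produces every non-expression input of the feature panel: per-gene
#' mRNA half-lives, phosphosite counts (TFs), phylostrata (ages 1-13),
#' miRNA target-site tables, DNA-binding-domain positions, TF family
#' labels, GO-style term assignments, a protein-interaction edge list
#' containing a designated \code{"PolII"} node, five differential
#' methylation tracks (CpG/CHG/CHH from one source, CpG/CHH from a
#' second) and four open-chromatin (DHS) condition tracks sharing a
#' common core (so stable and dynamic DHS are both non-empty).
#'
#' Configured \code{featureShifts} are applied post-hoc at the entity
#' level; because coupled and uncoupled TFs draw their targets from
#' disjoint gene pools, entity shifts carry through to the pair
#' populations at the configured Cohen's D. The interaction-network
#' distance shift is planted structurally via chain lengths to the PolII
#' node.
#'
#' @param config a [SimConfig-class].
#' @param truth a [GroundTruth-class].
#' @param annotation the [GeneAnnotationSet-class] from
#'   [generateGenome()].
#' @return named list of data.frames: \code{halfLife}, \code{phospho},
#'   \code{ages}, \code{mirna}, \code{dbd}, \code{tfFamilies},
#'   \code{goTerms}, \code{ppiEdges} (+ \code{polIIId}), \code{dmrTracks}
#'   (list of 5), \code{dhsTracks} (list of 4).
#' @export
generateAuxTables <- function(config, truth, annotation) {
  validObject(config)
  set.seed(subSeed(config@seed, "aux"))
  ids <- simGeneIds(config)
  tfIds <- ids[seq_len(config@nTF)]
  coupledTFs <- unique(coupledPairs(truth)$tf_id)
  coupledTGs <- unique(coupledPairs(truth)$tg_id)
  tfCoupled <- ids %in% coupledTFs
  tgCoupled <- ids %in% coupledTGs
  sh <- function(nm) {
    s <- config@featureShifts[nm]
    if (is.na(s)) 0 else unname(s)
  }
  mf <- config@missingFrac

  halfLife <- data.frame(
    gene_id = ids,
    half_life = injectMissing(pmax(0.5,
      shiftedValues(length(ids), 10, 3, tfCoupled, sh("half_life_tf")) +
        3 * sh("half_life_tg") * as.numeric(tgCoupled)), mf))
  phospho <- data.frame(
    tf_id = tfIds,
    n_phospho = injectMissing(round(pmax(0,
      shiftedValues(config@nTF, 8, 3, tfCoupled[seq_len(config@nTF)],
                    sh("phospho_sites_tf")))), mf))
  ages <- data.frame(
    gene_id = ids,
    phylostratum = injectMissing(pmin(13, pmax(1, round(
      shiftedValues(length(ids), 7, 2.5, tfCoupled, sh("age_tf")) +
        2.5 * sh("age_tg") * as.numeric(tgCoupled)))), mf))
  mirna <- data.frame(
    gene_id = ids,
    sites_mrna = round(pmax(0,
      shiftedValues(length(ids), 5, 2, tfCoupled, sh("mirna_sites_mrna_tf")) +
        2 * sh("mirna_sites_mrna_tg") * as.numeric(tgCoupled))),
    sites_intron = round(pmax(0,
      shiftedValues(length(ids), 2, 1.5, tfCoupled,
                    sh("mirna_sites_intron_tf")) +
        1.5 * sh("mirna_sites_intron_tg") * as.numeric(tgCoupled))),
    max_energy_ratio = pmin(1, pmax(0,
      shiftedValues(length(ids), 0.5, 0.12, tfCoupled,
                    sh("mirna_max_energy_ratio_tf")) +
        0.12 * sh("mirna_max_energy_ratio_tg") * as.numeric(tgCoupled))),
    mimic_sites = round(pmax(0,
      shiftedValues(length(ids), 1.5, 1, tfCoupled,
                    sh("mirna_mimic_sites_tf")) +
        sh("mirna_mimic_sites_tg") * as.numeric(tgCoupled))),
    mimic_max_energy_ratio = pmin(1, pmax(0,
      shiftedValues(length(ids), 0.4, 0.12, tfCoupled,
                    sh("mirna_mimic_max_energy_ratio_tf")) +
        0.12 * sh("mirna_mimic_max_energy_ratio_tg") *
          as.numeric(tgCoupled))))
  mirna$sites_mrna <- injectMissing(mirna$sites_mrna, mf)
  mirna$max_energy_ratio <- injectMissing(mirna$max_energy_ratio, mf)

  dbdCount <- sample(1:2, config@nTF, replace = TRUE, prob = c(0.7, 0.3))
  dbd1 <- runif(config@nTF, 0, 0.7)
  dbd2 <- ifelse(dbdCount == 2,
                 pmin(0.95, dbd1 + runif(config@nTF, 0.05, 0.25)),
                 NA_real_)
  dbd <- data.frame(tf_id = tfIds, dbd_count = dbdCount,
                    dbd1_rel_start = dbd1, dbd2_rel_start = dbd2)

  fams <- c("WRKY", "MYB", "NAC", "AP2-EREBP", "bZIP", "bHLH")
  famProbC <- c(0.35, 0.25, 0.15, 0.1, 0.1, 0.05)
  famProbU <- c(0.05, 0.1, 0.15, 0.3, 0.25, 0.15)
  tfFamilies <- data.frame(
    tf_id = tfIds,
    family = vapply(seq_len(config@nTF), function(i)
      sample(fams, 1, prob = if (tfCoupled[i]) famProbC else famProbU), ""))

  terms <- sprintf("GO:%04d", 1:8)
  goTerms <- do.call(rbind, lapply(seq_along(ids), function(i) {
    k <- sample(0:3, 1)
    if (!k) return(NULL)
    data.frame(gene_id = ids[i],
               term = sample(terms, k,
                             prob = if (tgCoupled[i])
                               c(3, 3, rep(1, 6)) else rep(1, 8)))
  }))

  # Interaction graph: one chain per TF to the PolII node (the chain
  # length IS the planted distance), leaf neighbors padding the degree,
  # occasional self-loops.
  nTF <- config@nTF
  hop <- pmax(1, round(shiftedValues(nTF, 6, 2, tfCoupled[seq_len(nTF)],
                                     sh("ppi_distance_to_polII"))))
  leaves <- round(pmax(0, shiftedValues(nTF, 3, 2,
                                        tfCoupled[seq_len(nTF)],
                                        sh("ppi_degree_tf"))))
  loops <- runif(nTF) < 0.15
  absent <- runif(nTF) < config@ppiAbsentFrac
  discon <- !absent & runif(nTF) < config@ppiDisconnectedFrac
  edges <- list(data.frame(from = "PolII", to = "PPI_anchor"))
  for (i in seq_len(nTF)) {
    if (absent[i]) next
    tf <- tfIds[i]
    if (discon[i]) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = tf, to = paste0("ISO_", tf))
    } else {
      chain <- c(tf, if (hop[i] > 1)
        sprintf("PPI_%s_%d", tf, seq_len(hop[i] - 1L)), "PolII")
      edges[[length(edges) + 1L]] <-
        data.frame(from = chain[-length(chain)], to = chain[-1])
    }
    if (leaves[i] > 0)
      edges[[length(edges) + 1L]] <-
        data.frame(from = tf, to = sprintf("LEAF_%s_%d", tf,
                                           seq_len(leaves[i])))
    if (loops[i])
      edges[[length(edges) + 1L]] <- data.frame(from = tf, to = tf)
  }
  ppiEdges <- do.call(rbind, edges)

  chromLen <- max(geneTable(annotation)$gene_end, 0L) + 1000L
  randTrack <- function(nInt) {
    start <- sort(sample.int(max(chromLen - 250L, 1L), nInt,
                             replace = TRUE))
    data.frame(chrom = "chr1", start = start,
               end = start + sample(50:200, nInt, replace = TRUE))
  }
  dmrNames <- c("dmr_cpg_1001g", "dmr_chg_1001g", "dmr_chh_1001g",
                "dmr_cpg_nh", "dmr_chh_nh")
  dmrTracks <- lapply(dmrNames, function(nm)
    randTrack(max(2L, config@nGene * 2L)))
  names(dmrTracks) <- dmrNames
  core <- randTrack(max(2L, round(config@nGene * 0.8)))
  dhsNames <- c("dhs_light", "dhs_heat", "dhs_leaf", "dhs_flower")
  dhsTracks <- lapply(dhsNames, function(nm) {
    extra <- randTrack(max(1L, round(config@nGene * 0.5)))
    tr <- rbind(core, extra)
    tr[order(tr$start), ]
  })
  names(dhsTracks) <- dhsNames

  list(halfLife = halfLife, phospho = phospho, ages = ages, mirna = mirna,
       dbd = dbd, tfFamilies = tfFamilies, goTerms = goTerms,
       ppiEdges = ppiEdges, polIIId = "PolII", dmrTracks = dmrTracks,
       dhsTracks = dhsTracks)
}

#' Run the whole synthetic-data generator
#'
#' Generates genome + promoters, PWMs, a planted pair plan (coupled TFs
#' draw targets from one half of the eligible genes, uncoupled TFs from
#' the other), plants the motifs, derives the ground truth, and simulates
#' expression and auxiliary tables. Fully deterministic given the config
#' seed.
#'
#' @param config a [SimConfig-class].
#' @return list with elements \code{config}, \code{annotation},
#'   \code{promoters}, \code{pwms}, \code{plan}, \code{truth},
#'   \code{expression}, \code{aux}.
#' @export
simulateRegulationData <- function(config = simConfig()) {
  validObject(config)
  genome <- generateGenome(config)
  pwms <- generatePWMs(config)
  set.seed(subSeed(config@seed, "plan"))
  ids <- simGeneIds(config)
  tfIds <- ids[seq_len(config@nTF)]
  activeTfs <- simActiveTfs(config)
  iso <- isoformTable(genome$annotation)
  minUtr5 <- tapply(iso$utr5_len, iso$gene_id, min)
  eligible <- setdiff(ids[!(ids %in% names(minUtr5)[minUtr5 == 0])], tfIds)
  half <- length(eligible) %/% 2L
  poolA <- eligible[seq_len(half)]           # targets of coupled TFs
  poolB <- eligible[-seq_len(half)]
  # coupled targets are drawn without replacement across the coupled TFs
  # so each coupled TG has exactly one regulator (its pair correlation is
  # then the analytic beta / sqrt(beta^2 + sigma^2), undiluted)
  freeA <- poolA
  plan <- do.call(rbind, lapply(tfIds, function(tf) {
    coupledTF <- tf %in% activeTfs
    pool <- if (coupledTF) freeA else poolB
    k <- min(config@targetsPerTf, length(pool))
    if (!k) return(NULL)
    tg <- sample(pool, k)
    if (coupledTF) freeA <<- setdiff(freeA, tg)
    data.frame(tf_id = tf, tg_id = tg, offset = NA_integer_)
  }))
  # offsets are drawn per promoter so planted motifs never overlap
  # (overlaps would overwrite one another and break recall)
  occupied <- list()
  for (i in seq_len(nrow(plan))) {
    tg <- plan$tg_id[i]
    L <- motifLength(pwms[[plan$tf_id[i]]])
    cand <- sample(seq(L - config@promoterLen, -1L))
    for (off in cand) {
      slots <- occupied[[tg]]
      if (is.null(slots) ||
          !any(off - L < slots[, 2] & slots[, 1] < off)) {
        plan$offset[i] <- off
        occupied[[tg]] <- rbind(slots, c(off - L, off))
        break
      }
    }
    if (is.na(plan$offset[i]))
      stop("could not place a non-overlapping motif in promoter of ", tg)
  }
  promoters <- plantMotifs(pwms, genome$promoters, plan)
  beta <- config@couplingBeta; sigma <- config@noiseSd
  coupled <- plan$tf_id %in% activeTfs
  truth <- new("GroundTruth",
               coupledPairs = plan[coupled, c("tf_id", "tg_id")],
               plantedHits = plan,
               expectedPairR = data.frame(
                 tf_id = plan$tf_id, tg_id = plan$tg_id,
                 expected_r = ifelse(coupled,
                                     beta / sqrt(beta^2 + sigma^2), 0)),
               informativeFeatures = as.character(
                 names(config@featureShifts)[config@featureShifts != 0]))
  expr <- generateExpression(config, truth)
  aux <- generateAuxTables(config, truth, genome$annotation)
  list(config = config, annotation = genome$annotation,
       promoters = promoters, pwms = pwms, plan = plan, truth = truth,
       expression = expr, aux = aux)
}

#' Simulate a labeled pairs-by-features dataset for classifier benchmarks
#'
#' Direct feature-level simulation for studying the classifier in
#' isolation: pairs carry a TF and a TG id (so component-disjoint splits
#' apply), a small set of informative features separates the classes at a
#' chosen standardized effect size, and the remaining features are
#' independent noise.
#'
#' @param nTF,nTG,pairsPerTf pair-population structure.
#' @param nInformative,nNoise feature counts.
#' @param effect standardized mean difference of informative features.
#' @param prevalence fraction of pairs labeled \code{correlated}.
#' @param seed integer seed.
#' @return list with \code{x} (matrix), \code{pairs} (data.frame
#'   \code{tf_id}, \code{tg_id}, \code{label}) and
#'   \code{informative} (feature names).
#' @export
simulatePairClassification <- function(nTF = 50, nTG = 1000,
                                       pairsPerTf = 100, nInformative = 3,
                                       nNoise = 100, effect = 0.8,
                                       prevalence = 0.09, seed = 1L) {
  set.seed(seed)
  tfs <- sprintf("TF%03d", seq_len(nTF))
  tgs <- sprintf("TG%04d", seq_len(nTG))
  pairs <- do.call(rbind, lapply(tfs, function(tf)
    data.frame(tf_id = tf,
               tg_id = sample(tgs, min(pairsPerTf, nTG)))))
  n <- nrow(pairs)
  y <- rbinom(n, 1, prevalence)
  pairs$label <- ifelse(y == 1, "correlated", "uncorrelated")
  informative <- sprintf("informative_%d", seq_len(nInformative))
  x <- cbind(
    matrix(rnorm(n * nInformative, mean = effect * y), n, nInformative,
           dimnames = list(NULL, informative)),
    matrix(rnorm(n * nNoise), n, nNoise,
           dimnames = list(NULL, sprintf("noise_%03d", seq_len(nNoise)))))
  list(x = x, pairs = pairs, informative = informative)
}
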
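#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis with its default:
#' promoter window -500..-1 bp, 80% relative scan threshold, 97.5th
#' percentile active-TF null with a 3000-target cap, correlated label at
#' r > 0.4 and uncorrelated inside (-0.1, 0.1), feature clustering at
#' r > 0.85, and a forest of 3000 trees, 5 candidate variables per
#' split, node size 150, 20 component-disjoint repeats.
#'
#' @param mode \code{synthetic} (inputs generated from \code{sim}) or
#'   \code{real} (inputs read from \code{paths}).
#' @param sim a [SimConfig-class] (synthetic mode).
#' @param paths named list of input paths (real mode): requires
#'   \code{gff}, \code{fasta}, \code{pwms}, \code{expression};
#'   optionally \code{halfLife}, \code{phospho}, \code{ages},
#'   \code{mirna}, \code{dbd}, \code{tfFamilies}, \code{ppiEdges},
#'   \code{dmr} (vector of BEDs), \code{dhs} (vector of BEDs).
#' @param promoterWindow,scanThreshold pair-building knobs.
#' @param percentile,tgCap active-TF selection knobs.
#' @param hi,band labeling thresholds.
#' @param clusterThreshold feature-merging correlation threshold.
#' @param rf named list of cross-validation knobs (\code{repeats},
#'   \code{nTrees}, \code{varsPerSplit}, \code{minNode},
#'   \code{trainFrac}, \code{mdaPermutations}, \code{interactions},
#'   \code{baseline}).
#' @param logExpression take ln() of the expression input (FALSE for
#'   synthetic matrices, which are log-scale by construction).
#' @param seed top-level seed; per-stage sub-seeds are derived from it.
#' @return a validated list of class \code{regcouplePipelineConfig}.
#' @export
pipelineConfig <- function(mode = c("synthetic", "real"),
                           sim = simConfig(), paths = list(),
                           promoterWindow = c(-500, -1),
                           scanThreshold = 0.8, percentile = 97.5,
                           tgCap = 3000, hi = 0.4, band = c(-0.1, 0.1),
                           clusterThreshold = 0.85,
                           rf = list(), logExpression = (mode[1] == "real"),
                           seed = 1L) {
  mode <- match.arg(mode)
  rfDefaults <- list(repeats = 20, nTrees = 3000, varsPerSplit = 5,
                     minNode = 150, trainFrac = 0.8, mdaPermutations = 5,
                     interactions = TRUE, baseline = FALSE)
  rf <- utils::modifyList(rfDefaults, rf)
  if (mode == "real") {
    need <- c("gff", "fasta", "pwms", "expression")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stop("real mode requires input path(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(mode = mode, sim = sim, paths = paths,
                 promoterWindow = promoterWindow,
                 scanThreshold = scanThreshold, percentile = percentile,
                 tgCap = tgCap, hi = hi, band = band,
                 clusterThreshold = clusterThreshold, rf = rf,
                 logExpression = logExpression, seed = as.integer(seed)),
            class = "regcouplePipelineConfig")
}

readRealInputs <- function(paths) {
  aux <- list(polIIId = "PolII", dmrTracks = list(), dhsTracks = list())
  readTsv <- function(p) if (!is.null(p)) read.delim(p) else NULL
  aux$halfLife <- readTsv(paths$halfLife)
  aux$phospho <- readTsv(paths$phospho)
  aux$ages <- readTsv(paths$ages)
  aux$mirna <- readTsv(paths$mirna)
  aux$dbd <- readTsv(paths$dbd)
  aux$tfFamilies <- readTsv(paths$tfFamilies)
  aux$goTerms <- readTsv(paths$goTerms)
  aux$ppiEdges <- readTsv(paths$ppiEdges)
  if (!is.null(paths$polIIId)) aux$polIIId <- paths$polIIId
  if (!is.null(paths$dmr))
    aux$dmrTracks <- setNames(lapply(paths$dmr, readBedTrack),
                              tools::file_path_sans_ext(basename(paths$dmr)))
  if (!is.null(paths$dhs))
    aux$dhsTracks <- setNames(lapply(paths$dhs, readBedTrack),
                              tools::file_path_sans_ext(basename(paths$dhs)))
  list(annotation = readGeneAnnotation(paths$gff),
       promoters = readPromoters(paths$fasta),
       pwms = readPWMs(paths$pwms),
       expression = readExpressionMatrix(paths$expression),
       aux = aux)
}

#' Run the full pipeline
#'
#' Sequences the stages: data generation (or loading), pair construction
#' by promoter scanning, expression normalization and pair correlation,
#' active-TF selection, labeling, feature assembly, feature clustering,
#' the univariate screen, TF-family enrichment, and cross-validated
#' Random Forest classification. Returns all stage outputs plus a run
#' manifest with the record counts at every filter step; reruns with the
#' same configuration are identical.
#'
#' @param config a [pipelineConfig()] result.
#' @return list with elements \code{pairs}, \code{hits},
#'   \code{activeTFs}, \code{labeled}, \code{features},
#'   \code{clustered}, \code{screen}, \code{enrichment}, \code{cv},
#'   \code{manifest} (and \code{sim} in synthetic mode).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "regcouplePipelineConfig"))
  inputs <- if (config$mode == "synthetic") {
    sim <- simulateRegulationData(config$sim)
    c(sim[c("annotation", "promoters", "pwms", "expression", "aux")],
      list(sim = sim))
  } else {
    readRealInputs(config$paths)
  }
  built <- buildPairs(inputs$annotation, inputs$promoters, inputs$pwms,
                      promoterWindow = config$promoterWindow,
                      relThreshold = config$scanThreshold)
  expr <- normalizeExpression(inputs$expression,
                              log = config$logExpression)
  pairs <- pairCorrelation(expr, built$pairs)
  active <- selectActiveTFs(expr, pairs, percentile = config$percentile,
                            tgCap = config$tgCap,
                            seed = subSeed(config$seed, "active"))
  labeled <- labelPairs(pairs, active, hi = config$hi, band = config$band)
  fm <- assembleFeatures(labeled, inputs$annotation, inputs$promoters,
                         inputs$pwms, built$hits, expr, inputs$aux)
  cl <- clusterFeatures(fm, rThreshold = config$clusterThreshold)
  scr <- univariateScreen(cl$matrix, pairInfo(fm)$label)
  enr <- if (!is.null(inputs$aux$tfFamilies)) {
    fam <- setNames(inputs$aux$tfFamilies$family,
                    inputs$aux$tfFamilies$tf_id)
    fisherEnrichment(pairInfo(fm)$label,
                     as.list(unname(fam[pairInfo(fm)$tf_id])))
  } else NULL
  rf <- config$rf
  cv <- crossValidate(cl$matrix, pairInfo(fm),
                      repeats = rf$repeats, seed = subSeed(config$seed,
                                                           "cv"),
                      nTrees = rf$nTrees,
                      varsPerSplit = rf$varsPerSplit,
                      minNode = rf$minNode, trainFrac = rf$trainFrac,
                      mdaPermutations = rf$mdaPermutations,
                      interactions = rf$interactions,
                      baseline = rf$baseline)
  manifest <- list(
    mode = config$mode, seed = config$seed,
    n_genes = nrow(geneTable(inputs$annotation)),
    n_tfs = sum(geneTable(inputs$annotation)$is_tf),
    n_samples = ncol(expr),
    n_pairs_built = nrow(built$pairs),
    n_hits = nrow(built$hits),
    n_pairs_correlated_computed = nrow(pairs),
    n_active_tfs = sum(active$is_active),
    active_threshold = unique(active$threshold)[1],
    n_pairs_active = nrow(labeled),
    n_correlated = sum(labeled$label == "correlated"),
    n_uncorrelated = sum(labeled$label == "uncorrelated"),
    n_excluded = sum(labeled$label == "excluded"),
    n_features = ncol(featureValues(fm)),
    n_imputed_cells = sum(imputedMask(fm)),
    n_clusters = cl$nClusters,
    cv_median_roc_auc = median(cvAucs(cv)$roc_auc),
    cv_median_pr_auc = median(cvAucs(cv)$pr_auc))
  out <- list(pairs = pairs, hits = built$hits, activeTFs = active,
              labeled = labeled, features = fm, clustered = cl,
              screen = scr, enrichment = enr, cv = cv,
              manifest = manifest)
  if (config$mode == "synthetic") out$sim <- inputs$sim
  out
}
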
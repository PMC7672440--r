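#' @import methods
#' @importFrom stats cor sd median quantile rnorm runif rbinom p.adjust
#'   wilcox.test fisher.test phyper setNames complete.cases
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix for a transcription-factor binding motif
#'
#' A \code{MotifPWM} stores the per-position base probabilities of a binding
#' motif together with the background base composition used for log-odds
#' scoring. Rows are motif positions, columns are the bases A, C, G, T.
#'
#' @slot tfId identifier of the transcription factor owning the motif.
#' @slot probs numeric L x 4 matrix of per-position base probabilities;
#'   every row sums to 1.
#' @slot background numeric length-4 vector of background base frequencies
#'   (sums to 1).
#'
#' @seealso [motifPWM()], [scanPromoter()], [motifEntropy()]
#' @export
setClass("MotifPWM",
  representation(tfId = "character", probs = "matrix",
                 background = "numeric"))

setValidity("MotifPWM", function(object) {
  p <- object@probs
  msg <- character()
  if (nrow(p) < 1L) msg <- c(msg, "motif length must be >= 1")
  if (ncol(p) != 4L || !identical(colnames(p), DNA_BASES))
    msg <- c(msg, "probs must have columns A, C, G, T")
  if (any(p < 0)) msg <- c(msg, "probabilities must be non-negative")
  if (any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "each position's probabilities must sum to 1 (+/- 1e-9)")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be a length-4 composition summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MotifPWM
#'
#' @param tfId TF identifier.
#' @param probs L x 4 numeric matrix of base probabilities (columns in
#'   A, C, G, T order; column names are set if absent).
#' @param background background base frequencies, default uniform.
#' @return A [MotifPWM-class] object.
#' @examples
#' pwm <- motifPWM("tf1", matrix(0.25, 4, 4))
#' motifLength(pwm)
#' @export
motifPWM <- function(tfId, probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  colnames(probs) <- DNA_BASES
  background <- as.numeric(background)
  names(background) <- DNA_BASES
  new("MotifPWM", tfId = as.character(tfId), probs = probs,
      background = background)
}

#' Gene models with isoform metrics
#'
#' Container for the gene annotation a promoter-scanning run needs: gene
#' coordinates (0-based half-open, as for BED intervals), strand, the TSS
#' position, a TF flag, the distance to the closest upstream gene, and a
#' per-isoform table of transcript metrics (mRNA/protein/UTR lengths and
#' whether the 5'UTR overlaps an intron).
#'
#' @slot genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{gene_start}, \code{gene_end}, \code{tss},
#'   \code{is_tf}, \code{upstream_gene_distance}.
#' @slot isoforms data.frame with columns \code{gene_id},
#'   \code{isoform_id}, \code{mrna_len}, \code{protein_len},
#'   \code{utr5_len}, \code{utr3_len}, \code{utr5_has_intron}.
#' @export
setClass("GeneAnnotationSet",
  representation(genes = "data.frame", isoforms = "data.frame"))

setValidity("GeneAnnotationSet", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "strand", "gene_start", "gene_end",
            "tss", "is_tf", "upstream_gene_distance")
  if (!all(need %in% names(g)))
    return(paste("genes table must have columns:",
                 paste(need, collapse = ", ")))
  if (nrow(g) && any(g$gene_start >= g$gene_end))
    return("gene_start must be < gene_end")
  ni <- c("gene_id", "isoform_id", "mrna_len", "protein_len",
          "utr5_len", "utr3_len", "utr5_has_intron")
  if (!all(ni %in% names(object@isoforms)))
    return(paste("isoforms table must have columns:",
                 paste(ni, collapse = ", ")))
  TRUE
})

#' Construct a GeneAnnotationSet
#' @param genes gene-level data.frame (see [GeneAnnotationSet-class]).
#' @param isoforms isoform-level data.frame.
#' @return A [GeneAnnotationSet-class].
#' @export
geneAnnotationSet <- function(genes, isoforms) {
  new("GeneAnnotationSet", genes = as.data.frame(genes),
      isoforms = as.data.frame(isoforms))
}

#' Configuration of the synthetic regulatory-genomics simulation
#'
#' Holds every knob of the generator: problem sizes, promoter length, motif
#' length and target per-position entropy levels, the latent-activity
#' expression model (\code{couplingBeta}, \code{noiseSd}), which TFs are
#' coupled to their targets, and post-hoc standardized shifts planted into
#' auxiliary feature tables. All randomness derives from \code{seed}.
#'
#' @slot nTF,nGene,nSample problem sizes.
#' @slot promoterLen promoter length in bp (default 500).
#' @slot motifLenRange length-2 integer range of motif lengths.
#' @slot entropyLevels target mean per-position motif entropies (nats),
#'   recycled over TFs; must lie in [0, ln 4].
#' @slot couplingBeta,noiseSd latent model: a coupled target's expression is
#'   beta * activity + Normal(0, noiseSd), so its expected correlation with
#'   the TF is beta / sqrt(beta^2 + noiseSd^2).
#' @slot fracCoupled fraction of TFs whose planted pairs are coupled
#'   (used when \code{activeTfIds} is empty).
#' @slot activeTfIds ids of the coupled ("active") TFs.
#' @slot targetsPerTf planted target genes per TF.
#' @slot featureShifts named numeric vector of Cohen's-D-scale shifts
#'   planted between coupled and uncoupled pairs in auxiliary features.
#' @slot missingFrac fraction of missing cells injected into auxiliary
#'   tables (exercises imputation).
#' @slot ppiAbsentFrac,ppiDisconnectedFrac fractions of TFs left out of the
#'   protein-interaction graph / placed in a component without the
#'   polymerase node.
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
  representation(nTF = "integer", nGene = "integer", nSample = "integer",
                 promoterLen = "integer", motifLenRange = "integer",
                 entropyLevels = "numeric", couplingBeta = "numeric",
                 noiseSd = "numeric", fracCoupled = "numeric",
                 activeTfIds = "character", targetsPerTf = "integer",
                 featureShifts = "numeric", missingFrac = "numeric",
                 ppiAbsentFrac = "numeric", ppiDisconnectedFrac = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSample < 3L) msg <- c(msg, "nSample must be >= 3")
  if (object@fracCoupled < 0 || object@fracCoupled > 1)
    msg <- c(msg, "fracCoupled must lie in [0, 1]")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (any(object@entropyLevels < 0) ||
      any(object@entropyLevels > log(4) + 1e-12))
    msg <- c(msg, "entropyLevels must lie in [0, ln 4]")
  if (object@promoterLen < max(object@motifLenRange))
    msg <- c(msg, "promoterLen must be >= the longest configured motif")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic simulation
#'
#' Records which TF-TG pairs were coupled in expression, where each motif
#' instance was planted (signed offset of the TSS-proximal edge), the
#' analytically expected Pearson correlation of every planted pair, and
#' which auxiliary features carry a planted class shift.
#'
#' @slot coupledPairs data.frame of \code{tf_id}, \code{tg_id}.
#' @slot plantedHits data.frame of \code{tf_id}, \code{tg_id},
#'   \code{offset} (signed bp, negative = upstream of the TSS).
#' @slot expectedPairR data.frame of \code{tf_id}, \code{tg_id},
#'   \code{expected_r}.
#' @slot informativeFeatures names of features carrying a planted shift.
#' @export
setClass("GroundTruth",
  representation(coupledPairs = "data.frame", plantedHits = "data.frame",
                 expectedPairR = "data.frame",
                 informativeFeatures = "character"))

setValidity("GroundTruth", function(object) {
  r <- object@expectedPairR$expected_r
  if (length(r) && (any(r < -1) || any(r > 1)))
    return("expected_r must lie in [-1, 1]")
  key <- function(d) paste(d$tf_id, d$tg_id)
  if (!all(key(object@coupledPairs) %in% key(object@plantedHits)))
    return("every coupled pair must have a planted motif hit")
  TRUE
})

#' Pairs-by-features matrix with provenance
#'
#' The assembled, imputed feature panel: one row per TF-TG pair, one column
#' per feature, plus per-feature provenance (whether the value describes
#' the TF, the TG, or the pair) and category, the pair metadata (ids,
#' Pearson r, class label), and a mask of imputed cells.
#'
#' @slot values numeric pairs x features matrix with no missing values.
#' @slot featureInfo data.frame with columns \code{name}, \code{source}
#'   (one of TF, TG, pair) and \code{category} (one of tfbs_info,
#'   post_tx_ptm_ppi, genomic_annotation, epigenetics).
#' @slot pairInfo data.frame with columns \code{tf_id}, \code{tg_id},
#'   \code{pearson_r}, \code{label}.
#' @slot imputed logical matrix marking imputed cells.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", featureInfo = "data.frame",
                 pairInfo = "data.frame", imputed = "matrix"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (anyNA(object@values)) msg <- c(msg, "values must contain no NA")
  if (nrow(object@featureInfo) != ncol(object@values))
    msg <- c(msg, "featureInfo must describe every column")
  if (!all(object@featureInfo$source %in% c("TF", "TG", "pair")))
    msg <- c(msg, "feature source must be TF, TG or pair")
  cats <- c("tfbs_info", "post_tx_ptm_ppi", "genomic_annotation",
            "epigenetics")
  if (!all(object@featureInfo$category %in% cats))
    msg <- c(msg, paste("feature category must be one of:",
                        paste(cats, collapse = ", ")))
  if (nrow(object@pairInfo) != nrow(object@values))
    msg <- c(msg, "pairInfo must describe every row")
  if (!identical(dim(object@imputed), dim(object@values)))
    msg <- c(msg, "imputed mask must match values in shape")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result of the pair classifier
#'
#' Per-repeat ROC/PR areas under the curve, per-feature permutation
#' importance (mean decrease in accuracy), conditional-depth feature
#' interactions, and (optionally) the permuted-label baseline arm run on
#' identical splits.
#'
#' @slot aucs data.frame with one row per repeat (\code{repeat_id},
#'   \code{roc_auc}, \code{pr_auc}, split bookkeeping columns).
#' @slot mda data.frame of \code{feature}, \code{mda} averaged over repeats.
#' @slot interactions data.frame of conditional-depth interaction records.
#' @slot baseline data.frame like \code{aucs} for the permuted-label arm
#'   (zero rows when not requested).
#' @export
setClass("CVResult",
  representation(aucs = "data.frame", mda = "data.frame",
                 interactions = "data.frame", baseline = "data.frame"))

setValidity("CVResult", function(object) {
  a <- object@aucs
  if (nrow(a) &&
      (any(a$roc_auc < 0 | a$roc_auc > 1) ||
       any(a$pr_auc < 0 | a$pr_auc > 1)))
    return("AUC values must lie in [0, 1]")
  TRUE
})
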
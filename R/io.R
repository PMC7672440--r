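#' Write / read PWMs as JASPAR-style probability text
#'
#' One record per motif: a \code{>id} header, four probability rows in
#' A/C/G/T order (\code{A [ 0.1 0.9 ... ]}), and one \code{#background}
#' line.
#'
#' @param pwms named list of [MotifPWM-class].
#' @param file path.
#' @return \code{writePWMs} returns the path invisibly; \code{readPWMs}
#'   the named list of motifs.
#' @export
writePWMs <- function(pwms, file) {
  lines <- unlist(lapply(pwms, function(p) {
    probs <- t(pwmProbs(p))
    c(paste0(">", tfId(p)),
      vapply(seq_len(4), function(i)
        sprintf("%s [ %s ]", DNA_BASES[i],
                paste(sprintf("%.17g", probs[i, ]), collapse = " ")),
        ""),
      paste0("#background ",
             paste(sprintf("%.17g", pwmBackground(p)),
                   collapse = " ")))
  }))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writePWMs
#' @export
readPWMs <- function(file) {
  lines <- readLines(file)
  starts <- grep("^>", lines)
  pwms <- lapply(seq_along(starts), function(i) {
    id <- sub("^>", "", lines[starts[i]])
    rows <- lapply(lines[starts[i] + 1:4], function(ln) {
      as.numeric(strsplit(gsub(".*\\[|\\]", "", ln), "\\s+")[[1]][-1])
    })
    bgLine <- lines[starts[i] + 5]
    bg <- if (grepl("^#background", bgLine))
      as.numeric(strsplit(bgLine, "\\s+")[[1]][-1]) else rep(0.25, 4)
    motifPWM(id, t(do.call(rbind, rows)), bg)
  })
  names(pwms) <- vapply(pwms, tfId, "")
  pwms
}

#' Write / read promoter sequences as FASTA
#' @param promoters named character vector of sequences.
#' @param file path.
#' @return \code{readPromoters} returns a named character vector.
#' @export
writePromoters <- function(promoters, file) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(toupper(promoters)), file)
  invisible(file)
}

#' @rdname writePromoters
#' @export
readPromoters <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

#' Write / read gene annotation as GFF3
#'
#' Genes and their isoforms (as mRNA features carrying the transcript
#' metrics as attributes) with the usual coordinate conversion: internal
#' 0-based half-open, GFF3 1-based closed. The TSS is recomputed from
#' strand and coordinates on import.
#'
#' @param annotation a [GeneAnnotationSet-class].
#' @param file path.
#' @return \code{readGeneAnnotation} returns a
#'   [GeneAnnotationSet-class].
#' @export
writeGeneAnnotation <- function(annotation, file) {
  g <- geneTable(annotation)
  iso <- isoformTable(annotation)
  geneGR <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$gene_start + 1L, g$gene_end),
    strand = g$strand, type = "gene", ID = g$gene_id,
    is_tf = as.character(g$is_tf),
    upstream_gene_distance = as.character(g$upstream_gene_distance))
  gi <- match(iso$gene_id, g$gene_id)
  mrnaGR <- GenomicRanges::GRanges(
    g$chrom[gi], IRanges::IRanges(g$gene_start[gi] + 1L, g$gene_end[gi]),
    strand = g$strand[gi], type = "mRNA", ID = iso$isoform_id,
    Parent = iso$gene_id, mrna_len = as.character(iso$mrna_len),
    protein_len = as.character(iso$protein_len),
    utr5_len = as.character(iso$utr5_len),
    utr3_len = as.character(iso$utr3_len),
    utr5_has_intron = as.character(iso$utr5_has_intron))
  rtracklayer::export(c(geneGR, mrnaGR), file, format = "gff3")
  invisible(file)
}

#' @rdname writeGeneAnnotation
#' @export
readGeneAnnotation <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  # attribute columns vanish when every record left them unset
  attrCol <- function(nm) {
    if (is.null(mc[[nm]])) rep(NA_character_, length(gr)) else
      as.character(mc[[nm]])
  }
  isGene <- mc$type == "gene"
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  genes <- data.frame(
    gene_id = as.character(mc$ID[isGene]),
    chrom = as.character(GenomicRanges::seqnames(gr))[isGene],
    strand = strand[isGene],
    gene_start = start0[isGene], gene_end = end0[isGene],
    tss = ifelse(strand[isGene] == "+", start0[isGene],
                 end0[isGene] - 1L),
    is_tf = as.logical(attrCol("is_tf")[isGene]),
    upstream_gene_distance =
      suppressWarnings(as.integer(attrCol("upstream_gene_distance")[
        isGene])))
  isM <- mc$type == "mRNA"
  parent <- vapply(mc$Parent[isM], function(p) as.character(p)[1], "")
  isoforms <- data.frame(
    gene_id = parent,
    isoform_id = as.character(mc$ID[isM]),
    mrna_len = as.integer(attrCol("mrna_len")[isM]),
    protein_len = as.integer(attrCol("protein_len")[isM]),
    utr5_len = as.integer(attrCol("utr5_len")[isM]),
    utr3_len = as.integer(attrCol("utr3_len")[isM]),
    utr5_has_intron = as.logical(attrCol("utr5_has_intron")[isM]))
  geneAnnotationSet(genes, isoforms)
}

#' Write / read an interval track as BED
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' shift is applied beyond the import round trip.
#'
#' @param track data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param file path.
#' @return \code{readBedTrack} returns such a data.frame, sorted.
#' @export
writeBedTrack <- function(track, file) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L,
                                                track$end))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname writeBedTrack
#' @export
readBedTrack <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  df[order(df$chrom, df$start), ]
}

#' Write / read an expression matrix as TSV
#' @param mat genes x samples matrix with dimnames.
#' @param file path.
#' @return \code{readExpressionMatrix} returns the matrix.
#' @export
writeExpressionMatrix <- function(mat, file) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read the ground-truth manifest as JSON
#' @param truth a [GroundTruth-class].
#' @param file path.
#' @return \code{readGroundTruth} returns a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, file) {
  jsonlite::write_json(
    list(coupled_pairs = coupledPairs(truth),
         planted_hits = plantedHits(truth),
         expected_pair_r = expectedPairR(truth),
         informative_features = informativeFeatures(truth),
         note = paste("expression model: Gaussian latent activity;",
                      "an assumption of the generator, not an estimate",
                      "from real data")),
    file, dataframe = "columns", digits = NA)
  invisible(file)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("GroundTruth",
      coupledPairs = as.data.frame(j$coupled_pairs),
      plantedHits = as.data.frame(j$planted_hits),
      expectedPairR = as.data.frame(j$expected_pair_r),
      informativeFeatures = as.character(j$informative_features))
}

#' Write every output of a simulation to a directory
#'
#' FASTA promoters, GFF3 annotation, PWM text, expression and auxiliary
#' TSVs, one BED per DMR/DHS track, and the ground-truth JSON.
#'
#' @param sim result of [simulateRegulationData()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writePromoters(sim$promoters, p("promoters.fa"))
  writeGeneAnnotation(sim$annotation, p("annotation.gff3"))
  writePWMs(sim$pwms, p("pwms.txt"))
  writeExpressionMatrix(sim$expression, p("expression.tsv"))
  writeGroundTruth(sim$truth, p("ground_truth.json"))
  for (nm in c("halfLife", "phospho", "ages", "mirna", "dbd",
               "tfFamilies", "goTerms", "ppiEdges"))
    write.table(sim$aux[[nm]], p(paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  for (nm in names(sim$aux$dmrTracks))
    writeBedTrack(sim$aux$dmrTracks[[nm]], p(paste0(nm, ".bed")))
  for (nm in names(sim$aux$dhsTracks))
    writeBedTrack(sim$aux$dhsTracks[[nm]], p(paste0(nm, ".bed")))
  invisible(list.files(dir, full.names = TRUE))
}
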
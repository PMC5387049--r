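#' @importFrom Biostrings readDNAStringSet DNAStringSet writeXStringSet
#' @importFrom rtracklayer import export
NULL

## Key used everywhere to identify a unique exon or interval.
#' @keywords internal
intervalKey <- function(contig, strand, start, end) {
  sprintf("%s:%s:%d-%d", contig, strand, as.integer(start), as.integer(end))
}

## Exons of one transcript in transcription (5'->3') order.
#' @keywords internal
orderExonsTx <- function(gr) {
  gr <- gr[order(start(gr))]
  if (as.character(strand(gr))[1] == "-") gr <- rev(gr)
  gr
}

#' Load a genome and its multi-transcript annotation
#'
#' Reads a (multi-contig) FASTA and a GFF3 or GTF annotation, assembles one
#' exon set per transcript, and applies structural pre-filtering: transcripts
#' with exons outside contig bounds, zero-length exons, overlapping exons, or
#' exons on mixed contigs/strands are dropped with a warning. GFF3/GTF
#' 1-based inclusive coordinates are kept in \code{GRanges} convention; all
#' interval arithmetic downstream treats them as closed intervals.
#'
#' @param fastaPath path to the genome FASTA.
#' @param annotationPath path to a GFF3 (\code{.gff}/\code{.gff3}) or GTF
#'   (\code{.gtf}) annotation with exon features.
#' @param format annotation dialect; \code{"auto"} guesses from the extension.
#' @return a list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{transcripts} (a \code{GRangesList} of exons, one element per
#'   transcript, with a \code{gene_id} metadata column).
#' @export
loadGenomeAnnotation <- function(fastaPath, annotationPath,
                                 format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(fastaPath)) stop("FASTA not found: ", fastaPath)
  if (!file.exists(annotationPath))
    stop("annotation not found: ", annotationPath)
  genome <- readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (format == "auto") {
    format <- if (grepl("\\.gtf$", annotationPath, ignore.case = TRUE))
      "gtf" else "gff3"
  }
  ann <- import(annotationPath, format = format)
  ex <- ann[tolower(as.character(ann$type)) == "exon"]
  if (!length(ex)) stop("annotation contains no exon features")

  if (format == "gtf") {
    txId <- as.character(mcols(ex)$transcript_id)
    geneId <- as.character(mcols(ex)$gene_id)
  } else {
    parent <- mcols(ex)$Parent
    txId <- vapply(parent, function(p) as.character(p)[1], character(1))
    ## map transcript -> gene through the mRNA/transcript features
    txFeat <- ann[tolower(as.character(ann$type)) %in%
                    c("mrna", "transcript")]
    txGene <- setNames(
      vapply(mcols(txFeat)$Parent, function(p)
        if (length(p)) as.character(p)[1] else NA_character_, character(1)),
      as.character(mcols(txFeat)$ID))
    geneId <- unname(txGene[txId])
    if (anyNA(geneId)) {
      gid <- mcols(ex)$gene_id
      if (!is.null(gid)) geneId[is.na(geneId)] <- gid[is.na(geneId)]
      geneId[is.na(geneId)] <- txId[is.na(geneId)]
    }
  }

  exBare <- GRanges(seqnames(ex), IRanges(start(ex), end(ex)),
                    strand = strand(ex))
  txList <- S4Vectors::split(exBare, txId)
  txGeneMap <- vapply(split(geneId, txId), `[`, character(1), 1)

  contigLen <- setNames(width(genome), names(genome))
  keep <- vapply(seq_along(txList), function(i) {
    gr <- txList[[i]]
    ctg <- as.character(seqnames(gr))
    if (length(unique(ctg)) != 1L) return(FALSE)
    if (length(unique(as.character(strand(gr)))) != 1L) return(FALSE)
    if (!ctg[1] %in% names(contigLen)) return(FALSE)
    if (any(width(gr) < 1L)) return(FALSE)
    if (any(start(gr) < 1L) || any(end(gr) > contigLen[ctg[1]])) return(FALSE)
    gr <- gr[order(start(gr))]
    if (length(gr) > 1L && any(start(gr)[-1] <= end(gr)[-length(gr)]))
      return(FALSE)  # overlapping exons within one transcript
    TRUE
  }, logical(1))
  if (any(!keep)) {
    warning(sprintf(
      "pre-filtering dropped %d transcript(s) with structural problems: %s",
      sum(!keep), paste(head(names(txList)[!keep], 5), collapse = ", ")))
  }
  txList <- txList[keep]
  if (!length(txList)) stop("no transcripts left after pre-filtering")
  txList <- endoapply(txList, function(gr) gr[order(start(gr))])
  mcols(txList)$gene_id <- unname(txGeneMap[names(txList)])
  list(genome = genome, transcripts = txList)
}

#' @importFrom S4Vectors endoapply
NULL

## Extract a sense-strand lowercase-RNA subsequence from a cached character
## genome. `start`/`end` are 1-based closed genomic coordinates.
#' @keywords internal
senseSubseq <- function(genomeChar, contig, start, end, strand) {
  s <- substring(genomeChar[contig], start, end)
  s <- dnaToRna(s)
  minus <- strand == "-"
  if (any(minus)) s[minus] <- rnaReverseComplement(s[minus])
  s
}

#' Extract unique introns and their splice-site sequences
#'
#' Pools the transcripts of each gene, takes the gaps between consecutive
#' exons of every transcript, and deduplicates introns by
#' (gene, contig, strand, start, end); identical intervals shared by two
#' genes are kept once per gene. Donor and acceptor sequences are reported on
#' the sense (transcribed) strand in lowercase RNA: minus-strand introns are
#' reverse-complemented so \code{donor_seq} begins at the transcribed 5' end,
#' and DNA t is rendered as u. Introns shorter than
#' \code{donorLen + acceptorLen} get truncated, non-overlapping sequences
#' (donor takes the first half, rounded up). Introns whose splice sequences
#' contain an ambiguous base are flagged \code{has_n} and excluded from
#' consensus discovery downstream.
#'
#' @param transcripts \code{GRangesList} of exons per transcript with a
#'   \code{gene_id} metadata column (as from \code{loadGenomeAnnotation}).
#' @param genome named \code{DNAStringSet} (or named character vector).
#' @param donorLen,acceptorLen number of intron bases kept on each side
#'   (default 10, minimum 2).
#' @return an \code{\linkS4class{IntronSet}}.
#' @export
extractIntrons <- function(transcripts, genome, donorLen = 10L,
                           acceptorLen = 10L) {
  stopifnot(donorLen >= 2L, acceptorLen >= 2L)
  genomeChar <- if (is.character(genome)) genome else
    setNames(as.character(genome), names(genome))
  geneOf <- mcols(transcripts)$gene_id
  if (is.null(geneOf)) geneOf <- names(transcripts)

  ## flatten the exon hierarchy once; per-transcript GRanges subsetting is
  ## far too slow at genome scale
  u <- unlist(transcripts, use.names = FALSE)
  txIdx <- rep(seq_along(transcripts), S4Vectors::elementNROWS(transcripts))
  ex <- data.frame(
    tx = txIdx, gene_id = geneOf[txIdx],
    contig = as.character(seqnames(u)), strand = as.character(strand(u)),
    start = start(u), end = end(u), stringsAsFactors = FALSE)
  ex <- ex[order(ex$tx, ex$start), , drop = FALSE]
  nEx <- nrow(ex)
  rows <- NULL
  if (nEx > 1L) {
    i <- which(ex$tx[-nEx] == ex$tx[-1L])  # consecutive exons, same tx
    if (length(i)) {
      istart <- ex$end[i] + 1L
      iend <- ex$start[i + 1L] - 1L
      if (any(iend < istart))
        stop("zero-length intron encountered; transcripts were not pre-filtered")
      rows <- data.frame(
        gene_id = ex$gene_id[i], contig = ex$contig[i],
        strand = ex$strand[i], start = istart, end = iend,
        upstream_exon = intervalKey(ex$contig[i], ex$strand[i],
                                    ex$start[i], ex$end[i]),
        downstream_exon = intervalKey(ex$contig[i + 1L], ex$strand[i + 1L],
                                      ex$start[i + 1L], ex$end[i + 1L]),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(rows) || !nrow(rows)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character(), donor_seq = character(),
                           acceptor_seq = character())
    return(IntronSet(gr))
  }
  ## minus strand: the transcription-order flanks computed above are inverted
  minus <- rows$strand == "-"
  if (any(minus)) {
    tmp <- rows$upstream_exon[minus]
    rows$upstream_exon[minus] <- rows$downstream_exon[minus]
    rows$downstream_exon[minus] <- tmp
  }
  ## deduplicate by (gene, contig, strand, interval) but remember every
  ## distinct flanking-exon pair a transcript assigned to the interval
  ikey <- paste(rows$gene_id, rows$contig, rows$strand, rows$start, rows$end,
                sep = "\r")
  pairStr <- paste(rows$upstream_exon, rows$downstream_exon, sep = "|")
  flankPairs <- vapply(split(pairStr, ikey), function(p)
    paste(unique(p), collapse = ";"), character(1))
  rows <- rows[!duplicated(ikey), , drop = FALSE]
  rows$flank_pairs <- unname(flankPairs[paste(rows$gene_id, rows$contig,
                                              rows$strand, rows$start,
                                              rows$end, sep = "\r")])

  bad <- rows$start < 1L |
    rows$end > nchar(genomeChar)[match(rows$contig, names(genomeChar))]
  if (any(bad)) stop("intron interval outside contig bounds")

  len <- rows$end - rows$start + 1L
  dl <- pmin(donorLen, pmax(ceiling(len / 2), 0L))
  al <- pmin(acceptorLen, len - dl)
  plus <- rows$strand == "+"
  donor <- acceptor <- character(nrow(rows))
  donor[plus] <- senseSubseq(genomeChar, rows$contig[plus], rows$start[plus],
                             rows$start[plus] + dl[plus] - 1L, "+")
  acceptor[plus] <- senseSubseq(genomeChar, rows$contig[plus],
                                rows$end[plus] - al[plus] + 1L,
                                rows$end[plus], "+")
  donor[!plus] <- senseSubseq(genomeChar, rows$contig[!plus],
                              rows$end[!plus] - dl[!plus] + 1L,
                              rows$end[!plus], "-")
  acceptor[!plus] <- senseSubseq(genomeChar, rows$contig[!plus],
                                 rows$start[!plus],
                                 rows$start[!plus] + al[!plus] - 1L, "-")

  gr <- GRanges(rows$contig, IRanges(rows$start, rows$end),
                strand = rows$strand)
  mcols(gr) <- DataFrame(
    gene_id = rows$gene_id, donor_seq = donor, acceptor_seq = acceptor,
    upstream_exon = rows$upstream_exon,
    downstream_exon = rows$downstream_exon,
    flank_pairs = rows$flank_pairs)
  hasN <- hasAmbiguousBase(paste0(donor, acceptor))
  if (any(hasN))
    message(sprintf(
      "%d intron(s) with ambiguous bases in splice sequences excluded from consensus discovery",
      sum(hasN)))
  mcols(gr)$has_n <- hasN
  IntronSet(gr)
}

#' Write an IntronSet as TSV
#'
#' One row per unique intron: gene_id, contig, strand, start, end (1-based
#' closed), donor_seq, acceptor_seq, and the class label when assigned.
#'
#' @param introns an \code{IntronSet}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeIntronTsv <- function(introns, path) {
  gr <- intronRanges(introns)
  df <- data.frame(
    gene_id = mcols(gr)$gene_id,
    contig = as.character(seqnames(gr)),
    strand = as.character(strand(gr)),
    start = start(gr), end = end(gr),
    donor_seq = mcols(gr)$donor_seq,
    acceptor_seq = mcols(gr)$acceptor_seq,
    intron_class = mcols(gr)$intron_class,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
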
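#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames strand start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

EXON_TYPES <- c("R", "S", "A3", "A5", "ME", "APr", "APA")

## ---------------------------------------------------------------------------
## IntronSet
## ---------------------------------------------------------------------------

#' IntronSet: unique introns of one or more genes
#'
#' Wraps a \linkS4class{GRanges} of unique introns (0-based half-open
#' coordinates are used internally by the extractor and converted to the
#' 1-based closed convention of \code{GRanges} on construction). Metadata
#' columns carry, per intron: \code{gene_id}, sense-strand lowercase RNA
#' \code{donor_seq} (intron 5' prefix) and \code{acceptor_seq} (intron 3'
#' suffix), the flanking exon keys in transcription order
#' (\code{upstream_exon}, \code{downstream_exon}), the flanking exon types
#' (\code{upstream_type}, \code{downstream_type}), the intron class label
#' (\code{intron_class}) once assigned, and \code{has_n} flagging introns
#' whose splice sequences contain ambiguous bases (excluded from consensus
#' discovery, which has no branch for N).
#'
#' @slot ranges a \code{GRanges} with the metadata columns above.
#' @export
setClass("IntronSet", representation(ranges = "GRanges"))

setValidity("IntronSet", function(object) {
  gr <- object@ranges
  need <- c("gene_id", "donor_seq", "acceptor_seq")
  miss <- setdiff(need, colnames(mcols(gr)))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (length(gr)) {
    if (any(!as.character(strand(gr)) %in% c("+", "-")))
      return("intron strand must be '+' or '-'")
    seqs <- c(mcols(gr)$donor_seq, mcols(gr)$acceptor_seq)
    if (any(grepl("[^acgun]", seqs)))
      return("donor/acceptor sequences must be lowercase RNA (a,c,g,u,n)")
  }
  TRUE
})

#' Construct an IntronSet
#' @param ranges GRanges with the required metadata columns.
#' @return an \code{IntronSet}.
#' @export
IntronSet <- function(ranges) {
  mc <- mcols(ranges)
  if (is.null(mc$has_n))
    mc$has_n <- hasAmbiguousBase(paste0(mc$donor_seq, mc$acceptor_seq))
  for (col in c("upstream_exon", "downstream_exon",
                "upstream_type", "downstream_type", "intron_class")) {
    if (is.null(mc[[col]])) mc[[col]] <- rep(NA_character_, length(ranges))
  }
  mcols(ranges) <- mc
  new("IntronSet", ranges = ranges)
}

#' @describeIn IntronSet number of unique introns.
#' @param x,object an \code{IntronSet}.
#' @export
setMethod("length", "IntronSet", function(x) length(x@ranges))

#' Accessors for IntronSet
#'
#' \code{intronRanges} returns the underlying \code{GRanges};
#' \code{donorSeqs}/\code{acceptorSeqs} the sense-strand splice sequences;
#' \code{geneIds} the owning gene of each intron; \code{intronClasses} the
#' assigned class labels (NA before \code{labelIntrons}).
#'
#' @param x an \code{IntronSet}.
#' @return see description.
#' @name IntronSet-accessors
NULL

#' @rdname IntronSet-accessors
#' @export
intronRanges <- function(x) x@ranges

#' @rdname IntronSet-accessors
#' @export
donorSeqs <- function(x) mcols(x@ranges)$donor_seq

#' @rdname IntronSet-accessors
#' @export
acceptorSeqs <- function(x) mcols(x@ranges)$acceptor_seq

#' @rdname IntronSet-accessors
#' @export
geneIds <- function(x) mcols(x@ranges)$gene_id

#' @rdname IntronSet-accessors
#' @export
intronClasses <- function(x) mcols(x@ranges)$intron_class

setMethod("show", "IntronSet", function(object) {
  gr <- object@ranges
  cat(sprintf("IntronSet with %d unique introns over %d gene(s)\n",
              length(gr), length(unique(mcols(gr)$gene_id))))
  cl <- mcols(gr)$intron_class
  if (length(gr) && !all(is.na(cl))) {
    tab <- sort(table(cl), decreasing = TRUE)
    cat("  classes: ",
        paste(sprintf("%s=%d", names(head(tab, 6)), head(tab, 6)),
              collapse = ", "),
        if (length(tab) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## QuaternaryTree
## ---------------------------------------------------------------------------

#' QuaternaryTree: prefix/suffix count tree over the RNA alphabet
#'
#' A flattened quaternary tree. Each node is a row of \code{nodes}:
#' \code{path} is the motif spelled in natural sequence orientation (for the
#' acceptor direction, \code{path} is the intron 3' suffix, indexed from the
#' 3' end inward), \code{depth} its length, \code{count} the number of input
#' sequences passing through the node, \code{parent_count} the count of its
#' parent (the root count, i.e. the number of input sequences, for depth-1
#' nodes), \code{prob} the conditional branch probability
#' \code{count/parent_count}, and \code{entropy} the Shannon entropy (bits)
#' of the node's children count distribution (0 for childless nodes).
#'
#' @slot nodes data.frame as described.
#' @slot direction `"donor-prefix"` or `"acceptor-suffix"`.
#' @slot nSequences number of sequences inserted.
#' @slot maxDepth maximum node depth.
#' @export
setClass("QuaternaryTree", representation(
  nodes = "data.frame", direction = "character",
  nSequences = "integer", maxDepth = "integer"))

setValidity("QuaternaryTree", function(object) {
  if (!object@direction %in% c("donor-prefix", "acceptor-suffix"))
    return("direction must be 'donor-prefix' or 'acceptor-suffix'")
  need <- c("path", "depth", "count", "parent_count", "prob", "entropy")
  if (!all(need %in% names(object@nodes)))
    return("nodes must have columns path, depth, count, parent_count, prob, entropy")
  if (nrow(object@nodes)) {
    if (any(object@nodes$prob <= 0 | object@nodes$prob > 1))
      return("branch probabilities must be in (0, 1]")
    if (any(object@nodes$entropy < 0 | object@nodes$entropy > 2 + 1e-9))
      return("child entropies must be in [0, 2] bits")
  }
  TRUE
})

#' @describeIn QuaternaryTree node table accessor.
#' @param x,object a \code{QuaternaryTree}.
#' @export
treeNodes <- function(x) x@nodes

setMethod("show", "QuaternaryTree", function(object) {
  cat(sprintf("QuaternaryTree (%s): %d sequences, %d nodes, max depth %d\n",
              object@direction, object@nSequences, nrow(object@nodes),
              object@maxDepth))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## PairedConsensusTable
## ---------------------------------------------------------------------------

#' PairedConsensusTable: ranked paired donor/acceptor consensus motifs
#'
#' Rank-ordered paired consensus sequences written donor_acceptor
#' (e.g. \code{guaagu_ag}): \code{motifs} has columns \code{rank},
#' \code{donor}, \code{acceptor}, \code{count}, where \code{count} is the
#' number of introns exclusively assigned to the pair by most-specific match,
#' and \code{totalIntrons} is the size of the intron universe (the rank-0
#' "ALL" row of the serialized table).
#'
#' @slot motifs data.frame(rank, donor, acceptor, count).
#' @slot totalIntrons integer.
#' @export
setClass("PairedConsensusTable", representation(
  motifs = "data.frame", totalIntrons = "integer"))

setValidity("PairedConsensusTable", function(object) {
  m <- object@motifs
  need <- c("rank", "donor", "acceptor", "count")
  if (!all(need %in% names(m)))
    return("motifs must have columns rank, donor, acceptor, count")
  if (nrow(m)) {
    if (any(diff(m$count) > 0))
      return("counts must be non-increasing with rank")
    if (!identical(as.integer(m$rank), seq_len(nrow(m))))
      return("ranks must be 1..n in order")
    if (anyDuplicated(paste(m$donor, m$acceptor, sep = "_")))
      return("duplicate donor_acceptor motifs")
    if (sum(m$count) > object@totalIntrons)
      return("sum of motif counts exceeds totalIntrons")
    if (any(!grepl("^(gu|gc|au)", m$donor)))
      return("donor motifs must begin with a valid donor core (gu, gc, au)")
    if (any(!grepl("(ag|ac)$", m$acceptor)))
      return("acceptor motifs must end with a valid acceptor core (ag, ac)")
  }
  TRUE
})

#' Construct a PairedConsensusTable
#' @param motifs data.frame with donor, acceptor, count (rank recomputed).
#' @param totalIntrons intron universe size.
#' @return a \code{PairedConsensusTable}.
#' @export
PairedConsensusTable <- function(motifs, totalIntrons) {
  motifs <- motifs[order(-motifs$count, motifs$donor, motifs$acceptor), ,
                   drop = FALSE]
  motifs$rank <- seq_len(nrow(motifs))
  rownames(motifs) <- NULL
  new("PairedConsensusTable",
      motifs = motifs[, c("rank", "donor", "acceptor", "count")],
      totalIntrons = as.integer(totalIntrons))
}

#' Accessors for PairedConsensusTable
#' @param x a \code{PairedConsensusTable}.
#' @return \code{consensusMotifs}: the motif data.frame; \code{motifStrings}:
#'   donor_acceptor strings in rank order; \code{totalIntrons}: universe size.
#' @name PairedConsensusTable-accessors
NULL

#' @rdname PairedConsensusTable-accessors
#' @export
consensusMotifs <- function(x) x@motifs

#' @rdname PairedConsensusTable-accessors
#' @export
motifStrings <- function(x) paste(x@motifs$donor, x@motifs$acceptor, sep = "_")

#' @rdname PairedConsensusTable-accessors
#' @export
totalIntrons <- function(x) x@totalIntrons

setMethod("length", "PairedConsensusTable", function(x) nrow(x@motifs))

setMethod("show", "PairedConsensusTable", function(object) {
  cat(sprintf("PairedConsensusTable: %d motifs over %d introns\n",
              nrow(object@motifs), object@totalIntrons))
  print(head(object@motifs, 10))
  if (nrow(object@motifs) > 10) cat("  ...\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## SplicingCodeTable
## ---------------------------------------------------------------------------

#' SplicingCodeTable: per (motif rank x intron class) enrichment calls
#'
#' Long-format table of Fisher exact results: one row per motif rank and
#' intron class with upper-tail (enrichment) and lower-tail (depletion)
#' p-values and significance flags at \code{alpha}. Tables transcribed from
#' a printed code grid may carry NA p-values with flags set.
#'
#' @slot entries data.frame(motif_rank, upstream, downstream, class,
#'   p_up, p_down, sig_up, sig_down).
#' @slot alpha significance threshold used for the flags.
#' @export
setClass("SplicingCodeTable", representation(
  entries = "data.frame", alpha = "numeric"))

setValidity("SplicingCodeTable", function(object) {
  need <- c("motif_rank", "upstream", "downstream", "class",
            "p_up", "p_down", "sig_up", "sig_down")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  e <- object@entries
  if (nrow(e)) {
    pv <- c(e$p_up, e$p_down)
    pv <- pv[!is.na(pv)]
    if (length(pv) && (any(pv < 0) || any(pv > 1)))
      return("p-values must lie in [0, 1]")
    if (any(e$upstream == "APA") || any(e$downstream == "APr"))
      return("invalid intron class: APA cannot be upstream, APr cannot be downstream")
  }
  TRUE
})

#' Accessors for SplicingCodeTable
#' @param x a \code{SplicingCodeTable}.
#' @param rank motif rank (integer).
#' @return \code{codeEntries}: the long data.frame; \code{enrichedClasses}/
#'   \code{depletedClasses}: class labels flagged significant for a rank.
#' @name SplicingCodeTable-accessors
NULL

#' @rdname SplicingCodeTable-accessors
#' @export
codeEntries <- function(x) x@entries

#' @rdname SplicingCodeTable-accessors
#' @export
enrichedClasses <- function(x, rank) {
  e <- x@entries
  sort(unique(e$class[e$motif_rank == rank & e$sig_up %in% TRUE]))
}

#' @rdname SplicingCodeTable-accessors
#' @export
depletedClasses <- function(x, rank) {
  e <- x@entries
  sort(unique(e$class[e$motif_rank == rank & e$sig_down %in% TRUE]))
}

setMethod("show", "SplicingCodeTable", function(object) {
  e <- object@entries
  cat(sprintf(
    "SplicingCodeTable: %d motif ranks x %d classes, alpha = %g (%d up, %d down)\n",
    length(unique(e$motif_rank)), length(unique(e$class)), object@alpha,
    sum(e$sig_up %in% TRUE), sum(e$sig_down %in% TRUE)))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## MutationReport
## ---------------------------------------------------------------------------

#' MutationReport: predicted effect of a splice-site point mutation
#'
#' @slot spec the parsed mutation (list from \code{parseIvsMutation}).
#' @slot wildMotif,mutantMotif one-row data.frame from the consensus table,
#'   or NULL when the sequence matches no consensus (the "not on the table"
#'   outcome that itself predicts aberrant splicing).
#' @slot wildEnriched,mutantEnriched,gained,lost character vectors of intron
#'   class labels; gained/lost are the set differences mutant vs wild.
#' @slot cryptic data.frame(position, motif) of candidate cryptic donor
#'   sites in the mutant intron 5' region.
#' @export
setClass("MutationReport", representation(
  spec = "list", wildMotif = "ANY", mutantMotif = "ANY",
  wildEnriched = "character", mutantEnriched = "character",
  gained = "character", lost = "character", cryptic = "data.frame"))

setValidity("MutationReport", function(object) {
  if (!setequal(object@gained, setdiff(object@mutantEnriched, object@wildEnriched)))
    return("gained must equal mutantEnriched \\ wildEnriched")
  if (!setequal(object@lost, setdiff(object@wildEnriched, object@mutantEnriched)))
    return("lost must equal wildEnriched \\ mutantEnriched")
  TRUE
})

setMethod("show", "MutationReport", function(object) {
  fmt <- function(m) if (is.null(m)) "none" else
    sprintf("%s_%s (rank %d, %d introns)", m$donor, m$acceptor, m$rank, m$count)
  s <- object@spec
  cat(sprintf("MutationReport IVS%d%+d%s>%s\n", s$intron_ordinal, s$offset,
              toupper(s$ref_base), toupper(s$alt_base)))
  cat("  wild motif:   ", fmt(object@wildMotif), "\n")
  cat("  mutant motif: ", fmt(object@mutantMotif), "\n")
  cat("  enriched wild:   ",
      paste(object@wildEnriched, collapse = ", "), "\n")
  cat("  enriched mutant: ",
      paste(object@mutantEnriched, collapse = ", "), "\n")
  cat("  gained: ", paste(object@gained, collapse = ", "),
      " | lost: ", paste(object@lost, collapse = ", "), "\n", sep = "")
  if (nrow(object@cryptic))
    cat(sprintf("  cryptic donor candidates: %d (first at +%d, %s)\n",
                nrow(object@cryptic), object@cryptic$position[1],
                object@cryptic$motif[1]))
  invisible(NULL)
})
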
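#' Default motif plan for the synthetic generator
#'
#' Four planted paired consensus families. Two canonical families target the
#' two most abundant intron classes (R-R and S-S); two U12-like families
#' (one au_ac, one gu_ag core, echoing the two observed U12-type cores) are
#' planted together in dedicated minor-spliceosome genes so that within-gene
#' co-occurrence structure is present. Motifs are full window length
#' (10 nt donor, 10 nt acceptor) so that each family terminates in tree
#' nodes with branch probability 1 and child entropy 0, making the families
#' identifiable under the percentile selection rule; each family carries an
#' adenosine at a position where the background model never places one (see
#' \code{simulationConfig}), so background sequence cannot contaminate a
#' family's deep branches.
#'
#' @return data.frame(donor, acceptor, class, prob, group).
#' @export
defaultMotifPlan <- function() {
  data.frame(
    donor    = c("guaagucuca", "gugaguacua", "auauccuugg", "guauccuuca"),
    acceptor = c("uucuucuaag", "ucucuucaag", "uuccuuacac", "cuuccuuaag"),
    class    = c("R-R", "S-S", "R-R", "R-R"),
    prob     = 0.85,
    group    = c("main", "main", "u12", "u12"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate a compact alternatively-spliced genome: ~840 genes whose
#' archetypes instantiate all seven exon types, yielding ~5,000 unique
#' introns; ~15% of genes are dedicated minor-spliceosome (U12-like) genes.
#' The background splice-site model uses canonical gu...ag cores with
#' positionally biased-random interiors — interior donor/acceptor positions
#' draw from \{c,g,u\} (pyrimidine-heavy, adenine-free) — so that discovery
#' is non-trivial, planted families (which carry early adenosines) stay
#' separable from background, and the gu_ag invariant holds for every
#' non-U12 intron. Set the interior frequencies to a full 4-letter
#' distribution for stress tests.
#'
#' @param seed integer seed; the generator is deterministic given the config.
#' @param nGenes number of genes (one contig each).
#' @param u12GeneFraction fraction of genes dedicated to the U12-like motif
#'   group (single-transcript, 8 exons).
#' @param eventMix probabilities over gene archetypes
#'   \code{R, S, A5, A3, ME, APr, APA} for non-U12 genes; must sum to 1.
#' @param exonLength,intronLength uniform sampling ranges (bases).
#' @param extLength boundary shift used by the A5/A3 archetypes.
#' @param donorLen,acceptorLen splice-window sizes written by the generator
#'   (match the extractor defaults).
#' @param motifPlan data.frame(donor, acceptor, class, prob, group): motifs
#'   planted at introns of the target class in genes of the group, each with
#'   the stated per-intron probability.
#' @param bgDonorFreq,bgAcceptorFreq base frequencies (named a,c,g,u) for
#'   background window interiors.
#' @param plantBranchpoint write the U12 branch-point consensus
#'   \code{uuccuuaac} 17-25 bases upstream of the 3' end of every U12-group
#'   intron.
#' @param pad flanking intergenic bases per contig end.
#' @return a validated config list of class \code{spliceSimConfig}.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 840L,
                             u12GeneFraction = 0.15,
                             eventMix = c(R = 0.25, S = 0.20, A5 = 0.20,
                                          A3 = 0.10, ME = 0.10,
                                          APr = 0.075, APA = 0.075),
                             exonLength = c(80L, 160L),
                             intronLength = c(90L, 200L),
                             extLength = 30L,
                             donorLen = 10L, acceptorLen = 10L,
                             motifPlan = defaultMotifPlan(),
                             bgDonorFreq = c(a = 0, c = 0.4, g = 0.2,
                                             u = 0.4),
                             bgAcceptorFreq = c(a = 0, c = 0.4, g = 0.2,
                                                u = 0.4),
                             plantBranchpoint = TRUE,
                             pad = 25L) {
  stopifnot(
    nGenes >= 1, u12GeneFraction >= 0, u12GeneFraction <= 1,
    abs(sum(eventMix) - 1) < 1e-8, all(eventMix >= 0),
    setequal(names(eventMix), c("R", "S", "A5", "A3", "ME", "APr", "APA")),
    length(exonLength) == 2, length(intronLength) == 2,
    donorLen >= 2, acceptorLen >= 2,
    abs(sum(bgDonorFreq) - 1) < 1e-8, abs(sum(bgAcceptorFreq) - 1) < 1e-8)
  checkRnaAlphabet(c(motifPlan$donor, motifPlan$acceptor), "motif plan")
  if (any(nchar(motifPlan$donor) > donorLen) ||
      any(nchar(motifPlan$acceptor) > acceptorLen))
    stop("infeasible geometry: planted motif longer than its splice window")
  if (intronLength[1] < donorLen + acceptorLen + 25L)
    stop("infeasible geometry: introns too short for splice windows and a branch point")
  if (any(motifPlan$prob < 0 | motifPlan$prob > 1))
    stop("planting probabilities must lie in [0, 1]")
  structure(list(
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    u12GeneFraction = u12GeneFraction, eventMix = eventMix,
    exonLength = as.integer(exonLength),
    intronLength = as.integer(intronLength),
    extLength = as.integer(extLength),
    donorLen = as.integer(donorLen), acceptorLen = as.integer(acceptorLen),
    motifPlan = motifPlan, bgDonorFreq = bgDonorFreq,
    bgAcceptorFreq = bgAcceptorFreq,
    plantBranchpoint = plantBranchpoint, pad = as.integer(pad)),
    class = "spliceSimConfig")
}

## Gene archetypes: exon layout (sense space), transcripts (exon-id vectors
## in transcription order) and planted exon types.
#' @keywords internal
geneArchetype <- function(archetype, cfg) {
  el <- function(n = 1L) sample(seq(cfg$exonLength[1], cfg$exonLength[2]), n,
                                replace = TRUE)
  il <- function(n = 1L) sample(seq(cfg$intronLength[1],
                                    cfg$intronLength[2]), n, replace = TRUE)
  chain <- function(k, types) {
    les <- el(k); lis <- il(k - 1L)
    st <- cumsum(c(1L, head(les, -1L) + lis))
    list(exons = data.frame(id = seq_len(k), start = st,
                            end = st + les - 1L, type = types),
         transcripts = list(seq_len(k)))
  }
  ext <- cfg$extLength
  switch(archetype,
    "R" = chain(6L, rep("R", 6L)),
    "U12" = chain(8L, rep("R", 8L)),
    "S" = {
      g <- chain(8L, c("R", rep("S", 6L), "R"))
      g$transcripts <- c(g$transcripts,
                         lapply(2:7, function(i) setdiff(1:8, i)))
      g
    },
    "A5" = {
      les <- el(4L); lis <- il(3L)
      e1 <- c(1L, les[1])
      e2 <- c(e1[2] + lis[1] + 1L, e1[2] + lis[1] + les[2])
      e3 <- c(e2[2] + lis[2] + 1L, e2[2] + lis[2] + les[3])
      e3x <- c(e3[1], e3[2] + ext)                  # extended donor boundary
      e4 <- c(e3x[2] + lis[3] + 1L, e3x[2] + lis[3] + les[4])
      list(exons = data.frame(
             id = 1:5,
             start = c(e1[1], e2[1], e3[1], e3x[1], e4[1]),
             end = c(e1[2], e2[2], e3[2], e3x[2], e4[2]),
             type = c("R", "R", "A5", "A5", "R")),
           transcripts = list(c(1L, 2L, 3L, 5L), c(1L, 2L, 4L, 5L)))
    },
    "A3" = {
      les <- el(4L); lis <- il(3L)
      e1 <- c(1L, les[1])
      e2x <- c(e1[2] + lis[1] + 1L, e1[2] + lis[1] + ext + les[2])
      e2 <- c(e2x[1] + ext, e2x[2])                 # shifted acceptor
      e3 <- c(e2x[2] + lis[2] + 1L, e2x[2] + lis[2] + les[3])
      e4 <- c(e3[2] + lis[3] + 1L, e3[2] + lis[3] + les[4])
      list(exons = data.frame(
             id = 1:5,
             start = c(e1[1], e2[1], e2x[1], e3[1], e4[1]),
             end = c(e1[2], e2[2], e2x[2], e3[2], e4[2]),
             type = c("R", "A3", "A3", "R", "R")),
           transcripts = list(c(1L, 2L, 4L, 5L), c(1L, 3L, 4L, 5L)))
    },
    "ME" = {
      g <- chain(4L, c("R", "ME", "ME", "R"))
      g$transcripts <- list(c(1L, 2L, 4L), c(1L, 3L, 4L))
      g
    },
    "APr" = {
      g <- chain(4L, c("APr", "APr", "R", "R"))
      g$transcripts <- list(c(1L, 3L, 4L), c(2L, 3L, 4L))
      g
    },
    "APA" = {
      g <- chain(4L, c("R", "R", "APA", "APA"))
      g$transcripts <- list(c(1L, 2L, 3L), c(1L, 2L, 4L))
      g
    },
    stop("unknown archetype: ", archetype))
}

#' Simulate a toy alternatively-spliced genome with ground truth
#'
#' Emits a multi-contig genome (one gene per contig, random strand), a
#' multi-transcript annotation, and a ground-truth record of every planted
#' exon type, intron class and motif. Planted motifs are written at the
#' intron boundaries of introns whose class matches a motif-plan row for the
#' gene's group, with the row's probability; when several rows of a group
#' target the same class they are cycled across the gene's eligible introns
#' (so the group's motifs co-occur within genes). Background splice windows
#' are \code{gu} + biased interior / biased interior + \code{ag}. The run is
#' fully deterministic given the config (which includes the seed).
#'
#' @param config a \code{spliceSimConfig} from \code{simulationConfig}.
#' @param dir optional output directory; when given, writes
#'   \code{genome.fa}, \code{annotation.gff3} and \code{truth_introns.tsv}.
#' @return list with \code{genome} (DNAStringSet), \code{transcripts}
#'   (GRangesList with gene_id metadata, as from
#'   \code{loadGenomeAnnotation}), \code{truth} (lists \code{genes},
#'   \code{exons}, \code{introns}), \code{config}, and \code{paths} when
#'   files were written.
#' @export
simulateGenome <- function(config = simulationConfig(), dir = NULL) {
  stopifnot(inherits(config, "spliceSimConfig"))
  cfg <- config
  withSeed(cfg$seed, {
    nU12 <- round(cfg$nGenes * cfg$u12GeneFraction)
    archetypes <- character(cfg$nGenes)
    isU12 <- rep(FALSE, cfg$nGenes)
    if (nU12 > 0) {
      u12idx <- sample(cfg$nGenes, nU12)
      isU12[u12idx] <- TRUE
    }
    archetypes[isU12] <- "U12"
    archetypes[!isU12] <- sample(names(cfg$eventMix), sum(!isU12),
                                 replace = TRUE, prob = cfg$eventMix)
    strands <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)

    dl <- cfg$donorLen; al <- cfg$acceptorLen
    mkPlan <- function(g) {
      p <- cfg$motifPlan[cfg$motifPlan$group == g, , drop = FALSE]
      list(class = p$class, prob = p$prob,
           donor = p$donor, acceptor = p$acceptor,
           donorCh = strsplit(p$donor, "", fixed = TRUE),
           acceptorCh = strsplit(p$acceptor, "", fixed = TRUE))
    }
    planMain <- mkPlan("main")
    planU12 <- mkPlan("u12")
    BP_CHARS <- strsplit("uuccuuaac", "", fixed = TRUE)[[1]]

    genomeSeqs <- character(cfg$nGenes)
    contigs <- sprintf("ctg%04d", seq_len(cfg$nGenes))
    geneIds <- sprintf("g%04d", seq_len(cfg$nGenes))
    txRows <- list()
    exonTruth <- vector("list", cfg$nGenes)
    intronTruth <- vector("list", cfg$nGenes)

    for (i in seq_len(cfg$nGenes)) {
      arch <- archetypes[i]
      group <- if (isU12[i]) "u12" else "main"
      g <- geneArchetype(arch, cfg)
      ex <- g$exons
      ex$start <- ex$start + cfg$pad
      ex$end <- ex$end + cfg$pad
      L <- max(ex$end) + cfg$pad

      ## unique introns in sense space with flanking exon ids
      ups <- unlist(lapply(g$transcripts, function(tx) tx[-length(tx)]))
      dns <- unlist(lapply(g$transcripts, function(tx) tx[-1L]))
      ui <- match(ups, ex$id); di <- match(dns, ex$id)
      irows <- data.frame(
        start = ex$end[ui] + 1L, end = ex$start[di] - 1L,
        up_type = ex$type[ui], dn_type = ex$type[di],
        stringsAsFactors = FALSE)
      irows <- irows[!duplicated(irows[c("start", "end")]), , drop = FALSE]
      irows <- irows[order(irows$start, irows$end), , drop = FALSE]
      irows$class <- paste(irows$up_type, irows$dn_type, sep = "-")

      seqv <- sample(RNA_BASES, L, replace = TRUE)
      plan <- if (group == "u12") planU12 else planMain
      classCounter <- new.env(parent = emptyenv())
      writtenDonor <- integer(0)
      writtenAcceptor <- integer(0)
      irows$planted <- NA_character_
      istarts <- irows$start; iends <- irows$end; iclasses <- irows$class

      for (r in seq_along(istarts)) {
        ist <- istarts[r]; ien <- iends[r]
        ri <- which(plan$class == iclasses[r])
        if (length(ri) > 1L) {
          cnt <- if (is.null(classCounter[[iclasses[r]]])) 0L else
            classCounter[[iclasses[r]]]
          classCounter[[iclasses[r]]] <- cnt + 1L
          ri <- ri[1L + (cnt %% length(ri))]
        }
        ## one planting decision per intron, both windows together
        plantIt <- length(ri) == 1L && runif(1) < plan$prob[ri]
        ## donor window (skip if shared with an already-written intron)
        if (!ist %in% writtenDonor) {
          dch <- if (plantIt) {
            c(plan$donorCh[[ri]],
              sample(RNA_BASES, dl - length(plan$donorCh[[ri]]),
                     replace = TRUE, prob = cfg$bgDonorFreq))
          } else c("g", "u", sample(RNA_BASES, dl - 2L, replace = TRUE,
                                    prob = cfg$bgDonorFreq))
          seqv[ist:(ist + dl - 1L)] <- dch
          writtenDonor <- c(writtenDonor, ist)
        }
        ## acceptor window
        if (!ien %in% writtenAcceptor) {
          ach <- if (plantIt) {
            c(sample(RNA_BASES, al - length(plan$acceptorCh[[ri]]),
                     replace = TRUE, prob = cfg$bgAcceptorFreq),
              plan$acceptorCh[[ri]])
          } else c(sample(RNA_BASES, al - 2L, replace = TRUE,
                          prob = cfg$bgAcceptorFreq), "a", "g")
          seqv[(ien - al + 1L):ien] <- ach
          writtenAcceptor <- c(writtenAcceptor, ien)
        }
        if (group == "u12" && cfg$plantBranchpoint)
          seqv[(ien - 24L):(ien - 16L)] <- BP_CHARS
      }

      ## post-hoc ground truth: exact full-pair match against the group plan
      senseStr <- paste(seqv, collapse = "")
      dWin <- substring(senseStr, irows$start, irows$start + dl - 1L)
      aWin <- substring(senseStr, irows$end - al + 1L, irows$end)
      if (length(plan$donor)) {
        ord <- orderBySpecificity(plan$donor, plan$acceptor)
        for (p in ord) {
          hit <- is.na(irows$planted) &
            startsWith(dWin, plan$donor[p]) &
            endsWith(aWin, plan$acceptor[p])
          irows$planted[hit] <- paste(plan$donor[p], plan$acceptor[p],
                                      sep = "_")
        }
      }
      irows$donor_window <- dWin
      irows$acceptor_window <- aWin

      ## strand placement: genomic DNA and flipped coordinates for '-'
      str <- strands[i]
      dna <- toupper(chartr("u", "t", senseStr))
      flip <- function(s, e) if (str == "+") cbind(s, e) else
        cbind(L - e + 1L, L - s + 1L)
      if (str == "-")
        dna <- paste(rev(strsplit(chartr("ACGT", "TGCA", dna),
                                  "")[[1]]), collapse = "")
      genomeSeqs[i] <- dna

      exG <- flip(ex$start, ex$end)
      exonTruth[[i]] <- data.frame(
        gene_id = geneIds[i],
        key = intervalKey(contigs[i], str, exG[, 1], exG[, 2]),
        type = ex$type, stringsAsFactors = FALSE)
      inG <- flip(irows$start, irows$end)
      intronTruth[[i]] <- data.frame(
        gene_id = geneIds[i], contig = contigs[i], strand = str,
        start = inG[, 1], end = inG[, 2], class = irows$class,
        planted_motif = irows$planted,
        canonical = startsWith(irows$donor_window, "gu"),
        group = group, stringsAsFactors = FALSE)

      for (t in seq_along(g$transcripts)) {
        ids <- g$transcripts[[t]]
        exT <- ex[match(ids, ex$id), ]
        co <- flip(exT$start, exT$end)
        o <- order(co[, 1])
        txRows[[length(txRows) + 1L]] <- data.frame(
          tx = sprintf("%s.t%d", geneIds[i], t), gene = geneIds[i],
          contig = contigs[i], strand = str,
          start = co[o, 1], end = co[o, 2], stringsAsFactors = FALSE)
      }
    }

    genome <- DNAStringSet(setNames(genomeSeqs, contigs))
    exAll <- do.call(rbind, txRows)
    transcripts <- S4Vectors::split(
      GRanges(exAll$contig, IRanges(exAll$start, exAll$end),
              strand = exAll$strand),
      factor(exAll$tx, levels = unique(exAll$tx)))
    mcols(transcripts)$gene_id <- exAll$gene[!duplicated(exAll$tx)]
    truth <- list(
      genes = data.frame(gene_id = geneIds, contig = contigs,
                         strand = strands, archetype = archetypes,
                         group = ifelse(isU12, "u12", "main"),
                         stringsAsFactors = FALSE),
      exons = do.call(rbind, exonTruth),
      introns = do.call(rbind, intronTruth))
    out <- list(genome = genome, transcripts = transcripts, truth = truth,
                config = cfg, paths = NULL)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fa <- file.path(dir, "genome.fa")
      gff <- file.path(dir, "annotation.gff3")
      tr <- file.path(dir, "truth_introns.tsv")
      writeXStringSet(genome, fa)
      writeAnnotation(transcripts, gff, format = "gff3")
      write.table(truth$introns, tr, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths <- list(fasta = fa, gff3 = gff, truth = tr)
    }
    out
  })
}

#' Write a transcript annotation as GFF3 or GTF
#'
#' Deterministic plain-text writer (no timestamp headers) for the
#' gene/mRNA/exon feature hierarchy used throughout the package.
#'
#' @param transcripts \code{GRangesList} of exons with \code{gene_id}
#'   metadata (names are transcript ids).
#' @param path output file.
#' @param format \code{"gff3"} or \code{"gtf"}.
#' @return the path, invisibly.
#' @export
writeAnnotation <- function(transcripts, path, format = c("gff3", "gtf")) {
  format <- match.arg(format)
  geneOf <- mcols(transcripts)$gene_id
  if (is.null(geneOf)) geneOf <- names(transcripts)
  lines <- if (format == "gff3") "##gff-version 3" else character(0)
  for (g in unique(geneOf)) {
    idx <- which(geneOf == g)
    allEx <- unlist(GenomicRanges::GRangesList(
      unname(transcripts[idx])), use.names = FALSE)
    ctg <- as.character(seqnames(allEx))[1]
    str <- as.character(strand(allEx))[1]
    if (format == "gff3")
      lines <- c(lines, sprintf(
        "%s\tspliceCode\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
        ctg, min(start(allEx)), max(end(allEx)), str, g))
    for (t in idx) {
      txid <- names(transcripts)[t]
      gr <- transcripts[[t]]
      if (format == "gff3") {
        lines <- c(lines, sprintf(
          "%s\tspliceCode\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
          ctg, min(start(gr)), max(end(gr)), str, txid, g))
        lines <- c(lines, sprintf(
          "%s\tspliceCode\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          ctg, start(gr), end(gr), str, txid))
      } else {
        lines <- c(lines, sprintf(
          "%s\tspliceCode\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          ctg, start(gr), end(gr), str, g, txid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

FIXTURE_FILES <- c(
  table1 = "table1_consensus_human.tsv",
  table2 = "table2_splicing_code_human.tsv",
  atp7a = "atp7a_intron6_synthetic.tsv",
  lkb1 = "lkb1_intron2_synthetic.tsv")

FIXTURE_MD5 <- c(
  table1 = "34acea488710bc44e73112e9e27c733a",
  table2 = "531fb5857b0b565cb07a2f2012e45c7e",
  atp7a = "38ade3287ca7fd2c49567cb58f4aa7d8",
  lkb1 = "e78f997eabdbf2b220de297f4e43b63e")

#' Load a packaged fixture
#'
#' \describe{
#' \item{table1}{the 42-row ranked paired-consensus table for human introns
#'   (plus the rank-0 ALL row), as a
#'   \code{\linkS4class{PairedConsensusTable}}.}
#' \item{table2}{the human splicing-code grid (significant enriched and
#'   depleted ranks per intron class), as a
#'   \code{\linkS4class{SplicingCodeTable}} with NA p-values and flags set.}
#' \item{atp7a}{ATP7A intron 6 splice-junction sequences: the published
#'   junction features (donor begins \code{guaagu}, acceptor ends \code{ag},
#'   a second \code{guaag} donor motif 50 bases downstream of the authentic
#'   donor) on a synthetic interior — the full intron sequence is not
#'   public, so everything outside those features is constructed
#'   (hence the \code{_synthetic} file name).}
#' \item{lkb1}{LKB1 intron 2 splice-junction sequences (U12-type,
#'   donor begins \code{auauccuu}, acceptor ends \code{ac}), synthetic
#'   interior likewise.}
#' }
#' File integrity is verified against stored MD5 checksums.
#'
#' @param name one of \code{"table1"}, \code{"table2"}, \code{"atp7a"},
#'   \code{"lkb1"}.
#' @return see description; the sequence fixtures are lists with
#'   \code{gene}, \code{intron_ordinal}, \code{donor_region},
#'   \code{acceptor_region}.
#' @export
loadFixture <- function(name = c("table1", "table2", "atp7a", "lkb1")) {
  name <- match.arg(name)
  path <- system.file("extdata", FIXTURE_FILES[[name]],
                      package = "spliceCode", mustWork = TRUE)
  digest <- unname(tools::md5sum(path))
  if (!identical(digest, unname(FIXTURE_MD5[[name]])))
    stop(sprintf("fixture '%s' failed its checksum (%s)", name, digest))
  switch(name,
    table1 = readConsensusTsv(path),
    table2 = {
      df <- read.delim(path, stringsAsFactors = FALSE)
      entries <- data.frame(
        motif_rank = df$rank, upstream = df$upstream,
        downstream = df$downstream,
        class = paste(df$upstream, df$downstream, sep = "-"),
        p_up = NA_real_, p_down = NA_real_,
        sig_up = df$direction == "up", sig_down = df$direction == "down",
        stringsAsFactors = FALSE)
      new("SplicingCodeTable", entries = entries, alpha = 0.001)
    },
    {
      df <- read.delim(path, stringsAsFactors = FALSE)
      list(gene = df$gene[1],
           intron_ordinal = as.integer(df$intron_ordinal[1]),
           donor_region = df$donor_region[1],
           acceptor_region = df$acceptor_region[1])
    })
}
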
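test_that("a toy FASTA + GFF3 parses into one 3-exon transcript", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  gff <- file.path(dir, "g.gff3")
  writeLines(c(">chr1", randomDna(1000)), fa)
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t900\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t900\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tParent=t1",
    "chr1\ttest\texon\t801\t900\t.\t+\t.\tParent=t1"), gff)
  res <- loadGenomeAnnotation(fa, gff)
  expect_length(res$transcripts, 1L)
  expect_equal(length(res$transcripts[[1]]), 3L)
  expect_equal(S4Vectors::mcols(res$transcripts)$gene_id, "g1")
})

test_that("pre-filtering drops transcripts with structural problems", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  gff <- file.path(dir, "g.gff3")
  writeLines(c(">chr1", randomDna(500)), fa)
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t900\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t900\t.\t+\t.\tID=tBad;Parent=g1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=tBad",
    "chr1\ttest\texon\t401\t900\t.\t+\t.\tParent=tBad",  # beyond contig
    "chr1\ttest\tmRNA\t1\t300\t.\t+\t.\tID=tOverlap;Parent=g1",
    "chr1\ttest\texon\t1\t150\t.\t+\t.\tParent=tOverlap",
    "chr1\ttest\texon\t100\t300\t.\t+\t.\tParent=tOverlap",  # overlapping
    "chr1\ttest\tmRNA\t1\t300\t.\t+\t.\tID=tOk;Parent=g1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=tOk",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tParent=tOk"), gff)
  expect_warning(res <- loadGenomeAnnotation(fa, gff), "pre-filtering")
  expect_identical(names(res$transcripts), "tOk")
})

test_that("GTF and GFF3 dialects yield identical transcript models", {
  sim <- simulateGenome(simulationConfig(seed = 11, nGenes = 6))
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gff <- writeAnnotation(sim$transcripts, file.path(dir, "a.gff3"), "gff3")
  gtf <- writeAnnotation(sim$transcripts, file.path(dir, "a.gtf"), "gtf")
  a <- loadGenomeAnnotation(fa, gff)
  b <- loadGenomeAnnotation(fa, gtf)
  expect_identical(sort(names(a$transcripts)), sort(names(b$transcripts)))
  for (tx in names(a$transcripts)) {
    expect_identical(as.data.frame(a$transcripts[[tx]]),
                     as.data.frame(b$transcripts[[tx]]))
  }
  expect_identical(
    S4Vectors::mcols(a$transcripts)$gene_id[order(names(a$transcripts))],
    S4Vectors::mcols(b$transcripts)$gene_id[order(names(b$transcripts))])
})

test_that("intron extraction follows the strand conventions", {
  base <- strsplit(randomDna(300), "")[[1]]
  seq <- paste(base, collapse = "")
  grl <- makeGene(list(rbind(c(1, 100), c(201, 300))))
  genome <- makeGenome(seq)
  introns <- extractIntrons(grl, genome)
  gr <- intronRanges(introns)
  expect_equal(start(gr), 101L)
  expect_equal(end(gr), 200L)
  expect_identical(donorSeqs(introns), dnaToRna(substr(seq, 101, 110)))
  expect_identical(acceptorSeqs(introns), dnaToRna(substr(seq, 191, 200)))

  ## minus strand: donor is the reverse complement of the last intron bases
  grlM <- makeGene(list(rbind(c(1, 100), c(201, 300))), strand = "-")
  intM <- extractIntrons(grlM, genome)
  expect_identical(donorSeqs(intM),
                   rnaReverseComplement(dnaToRna(substr(seq, 191, 200))))
  expect_identical(acceptorSeqs(intM),
                   rnaReverseComplement(dnaToRna(substr(seq, 101, 110))))
  ## flanks are in transcription order
  expect_match(S4Vectors::mcols(intronRanges(intM))$upstream_exon,
               "201-300$")
})

test_that("single-exon transcripts yield no introns", {
  grl <- makeGene(list(rbind(c(1, 100))))
  introns <- extractIntrons(grl, makeGenome(randomDna(200)))
  expect_length(introns, 0L)
})

test_that("each n-exon transcript contributes n-1 introns before dedup", {
  sim <- simulateGenome(simulationConfig(seed = 3, nGenes = 25))
  nIntrons <- sum(vapply(sim$transcripts, length, integer(1)) - 1L)
  introns <- extractIntrons(sim$transcripts, sim$genome)
  ## after dedup there can only be fewer
  expect_lte(length(introns), nIntrons)
  ## single-transcript genes are not deduplicated at all
  single <- sim$truth$genes$gene_id[
    sim$truth$genes$archetype %in% c("R", "U12")]
  for (g in single) {
    k <- sum(geneIds(introns) == g)
    tx <- sim$transcripts[S4Vectors::mcols(sim$transcripts)$gene_id == g]
    expect_equal(k, length(tx[[1]]) - 1L)
  }
})

test_that("short introns get truncated non-overlapping splice windows", {
  seq <- randomDna(300)
  ## intron of 12 bases: [101, 112]
  grl <- makeGene(list(rbind(c(1, 100), c(113, 200))))
  introns <- extractIntrons(grl, makeGenome(seq), donorLen = 10,
                            acceptorLen = 10)
  d <- donorSeqs(introns); a <- acceptorSeqs(introns)
  expect_equal(nchar(d) + nchar(a), 12L)
  expect_identical(paste0(d, a), dnaToRna(substr(seq, 101, 112)))
})

test_that("ambiguous bases flag introns out of consensus discovery", {
  seq <- paste0(randomDna(100), "GTNNG", randomDna(95), "TTTAG",
                randomDna(100))
  grl <- makeGene(list(rbind(c(1, 100), c(201, 300))))
  expect_message(introns <- extractIntrons(grl, makeGenome(seq)),
                 "ambiguous")
  expect_true(S4Vectors::mcols(intronRanges(introns))$has_n)
})

test_that("intron TSV serialization round-trips the key columns", {
  sim <- simulateGenome(simulationConfig(seed = 5, nGenes = 8))
  introns <- labelIntrons(extractIntrons(sim$transcripts, sim$genome),
                          sim$transcripts)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeIntronTsv(introns, path)
  back <- read.delim(path)
  expect_equal(nrow(back), length(introns))
  expect_setequal(back$intron_class, unique(intronClasses(introns)))
})
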
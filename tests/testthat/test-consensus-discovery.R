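test_that("an invariant donor family forms a single deterministic path", {
  tr <- buildQuaternaryTree(rep("guaagu", 300), "donor-prefix")
  nd <- treeNodes(tr)
  expect_equal(nrow(nd), 6L)
  expect_true(all(nd$prob == 1))
  expect_true(all(nd$entropy == 0))
  expect_true(all(nd$count == 300L))
  expect_identical(selectConservedBranches(tr), "guaagu")
})

test_that("child entropy is the Shannon entropy of the children counts", {
  tr <- buildQuaternaryTree(c(rep("guaag", 200), rep("gugag", 100)),
                            "donor-prefix")
  nd <- treeNodes(tr)
  expect_equal(nd$entropy[nd$path == "gu"],
               -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3)),
               tolerance = 1e-12)
  expect_equal(nd$count[nd$path == "gu"], 300L)
  expect_equal(nd$prob[nd$path == "gua"], 2 / 3, tolerance = 1e-12)
})

test_that("acceptor trees index sequences from the 3' end inward", {
  tr <- buildQuaternaryTree(rep("ag", 100), "acceptor-suffix")
  nd <- treeNodes(tr)
  expect_identical(nd$path[nd$depth == 1], "g")
  expect_identical(nd$path[nd$depth == 2], "ag")
  expect_equal(nd$count, c(100L, 100L))
})

test_that("tree counts are conserved at every node", {
  set.seed(42)
  seqs <- vapply(sample(3:8, 400, replace = TRUE), function(n)
    paste(sample(c("a", "c", "g", "u"), n, replace = TRUE), collapse = ""),
    character(1))
  for (dir in c("donor-prefix", "acceptor-suffix")) {
    tr <- buildQuaternaryTree(seqs, dir, maxDepth = 8)
    nd <- treeNodes(tr)
    for (i in seq_len(nrow(nd))) {
      kids <- nd[nd$depth == nd$depth[i] + 1L &
                   startsWith(nd$key, nd$key[i]), ]
      terminating <- sum(nchar(seqs) == nd$depth[i] &
                           (if (dir == "donor-prefix")
                             seqs == nd$key[i]
                            else vapply(strsplit(seqs, ""), function(ch)
                              paste(rev(ch), collapse = ""),
                              character(1)) == nd$key[i]))
      expect_equal(sum(kids$count) + terminating, nd$count[i])
    }
  }
})

test_that("families below the count floor are never selected", {
  tr <- buildQuaternaryTree(rep("guaagu", 99), "donor-prefix")
  expect_identical(selectConservedBranches(tr, minCount = 100),
                   character(0))
})

test_that("branch selection matches the brute-force enumeration oracle", {
  set.seed(7)
  families <- c("guaagu", "gugagu", "gcaagu", "guuugu", "guaugu")
  counts <- c(500, 300, 200, 150, 120)
  for (noise in c(0, 0.02)) {
    seqs <- unlist(mapply(noisySeqs, families, counts, noise,
                          SIMPLIFY = FALSE))
    for (dir in c("donor-prefix", "acceptor-suffix")) {
      tr <- buildQuaternaryTree(seqs, dir, maxDepth = 6)
      got <- selectConservedBranches(tr, minCount = 100)
      want <- oracleConservedMotifs(seqs, dir, minCount = 100,
                                    maxDepth = 6)
      expect_identical(got, want)
    }
  }
})

test_that("exactly planted families are recovered from a background mixture", {
  set.seed(13)
  bg <- vapply(seq_len(1500), function(i)
    paste0("gu", paste(sample(c("c", "g", "u"), 8, replace = TRUE,
                              prob = c(.4, .2, .4)), collapse = "")),
    character(1))
  seqs <- c(rep("guaagucuca", 500), rep("guacuguacu", 300), bg)
  got <- selectConservedBranches(
    buildQuaternaryTree(seqs, "donor-prefix", maxDepth = 10),
    minCount = 100)
  expect_true(all(c("guaagucuca", "guacuguacu") %in% got))
})

test_that("paired table construction recovers planted pairs exactly", {
  sim <- simulateGenome(simulationConfig(seed = 31, nGenes = 250))
  introns <- extractIntrons(sim$transcripts, sim$genome)
  tab <- buildPairedConsensusTable(introns)
  expect_equal(totalIntrons(tab), length(introns))
  planted <- table(sim$truth$introns$planted_motif)
  m <- consensusMotifs(tab)
  got <- setNames(m$count, paste(m$donor, m$acceptor, sep = "_"))
  bigEnough <- planted[planted >= 100]
  expect_true(all(names(bigEnough) %in% names(got)))
  expect_equal(got[names(bigEnough)],
               setNames(as.integer(bigEnough), names(bigEnough)))
  ## ranks ordered by non-increasing count
  expect_true(all(diff(m$count) <= 0))
  expect_lte(sum(m$count), totalIntrons(tab))
})

test_that("whole-table construction agrees with the brute-force oracle", {
  set.seed(19)
  n <- 450
  donors <- c(rep("guaagu", 180), rep("gugagu", 140),
              vapply(seq_len(n - 320), function(i)
                paste0("gu", paste(sample(c("c", "g", "u"), 4,
                                          replace = TRUE), collapse = "")),
                character(1)))
  acceptors <- c(rep("ucuaag", 320), vapply(seq_len(n - 320), function(i)
    paste0(paste(sample(c("c", "g", "u"), 4, replace = TRUE),
                 collapse = ""), "ag"), character(1)))
  donors <- sample(donors); acceptors <- sample(acceptors)
  tab <- buildPairedConsensusTable(list(donor = donors,
                                        acceptor = acceptors),
                                   minCount = 100, maxDepth = 6)
  ## oracle: enumerate conserved motifs on each side, pair, assign, prune
  dm <- oracleConservedMotifs(donors, "donor-prefix", 100, maxDepth = 6)
  am <- oracleConservedMotifs(acceptors, "acceptor-suffix", 100,
                              maxDepth = 6)
  dm <- dm[nchar(dm) >= 2 & grepl("^(gu|gc|au)", dm)]
  am <- am[nchar(am) >= 2 & grepl("(ag|ac)$", am)]
  pairs <- expand.grid(donor = dm, acceptor = am,
                       stringsAsFactors = FALSE)
  repeat {
    idx <- oracleAssign(donors, acceptors, pairs)
    cnt <- tabulate(idx, nbins = nrow(pairs))
    if (all(cnt >= 100) || !nrow(pairs)) break
    pairs <- pairs[cnt >= 100, , drop = FALSE]
  }
  pairs$count <- cnt
  pairs <- pairs[order(-pairs$count, pairs$donor, pairs$acceptor), ]
  m <- consensusMotifs(tab)
  expect_equal(m$donor, pairs$donor)
  expect_equal(m$acceptor, pairs$acceptor)
  expect_equal(m$count, pairs$count)
})

test_that("most-specific matching reproduces the worked junction examples", {
  tab <- loadFixture("table1")
  atp7a <- loadFixture("atp7a")
  wild <- assignMotif(atp7a$donor_region, atp7a$acceptor_region, tab)
  expect_equal(wild$rank, 3L)          # guaagu_ag
  expect_identical(wild$donor, "guaagu")

  md2 <- assignMotif(sub("^guaag", "guaaa", atp7a$donor_region),
                     atp7a$acceptor_region, tab)
  expect_identical(md2$donor, "guaa")  # guaa_ag

  lkb1 <- loadFixture("lkb1")
  expect_equal(assignMotif(lkb1$donor_region, lkb1$acceptor_region,
                           tab)$rank, 37L)
  ## the gu-core U12 donor paired with an ac acceptor is not on the table
  expect_null(assignMotif(sub("^au", "gu", lkb1$donor_region),
                          lkb1$acceptor_region, tab))
})

test_that("assignment is exclusive, disjoint, and specificity-dominant", {
  tab <- loadFixture("table1")
  set.seed(5)
  donors <- paste0("guaagu", vapply(seq_len(300), function(i)
    paste(sample(c("a", "c", "g", "u"), 4, replace = TRUE),
          collapse = ""), character(1)))
  acceptors <- rep("uuuuccuuag", 300)
  ranks <- vapply(seq_along(donors), function(i)
    assignMotif(donors[i], acceptors[i], tab)$rank, integer(1))
  ## donors starting guaagu can never fall back to guaag_ag or guaa_ag
  expect_true(all(ranks == 3L))
  ## vectorized assignment agrees with the scalar rule
  oracle <- oracleAssign(donors, acceptors, consensusMotifs(tab))
  expect_equal(ranks, consensusMotifs(tab)$rank[oracle])
})

test_that("table comparison reports shared-motif fractions", {
  tab <- loadFixture("table1")
  expect_equal(compareMotifTables(tab, tab)$fractionA, 1.0)
  half <- PairedConsensusTable(consensusMotifs(tab)[1:21, ],
                               totalIntrons(tab))
  expect_equal(compareMotifTables(tab, half)$fractionA, 0.5)
  other <- PairedConsensusTable(
    data.frame(donor = "gugggg", acceptor = "ggag", count = 500L), 1000L)
  expect_equal(compareMotifTables(tab, other)$fractionA, 0.0)
})

test_that("consensus TSV serialization round-trips", {
  tab <- loadFixture("table1")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeConsensusTsv(tab, path)
  back <- readConsensusTsv(path)
  expect_equal(consensusMotifs(back), consensusMotifs(tab))
  expect_equal(totalIntrons(back), totalIntrons(tab))
})
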
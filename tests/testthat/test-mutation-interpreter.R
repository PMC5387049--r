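test_that("IVS notation parses and malformed strings error", {
  m <- parseIvsMutation("IVS6+5G>A")
  expect_equal(m$intron_ordinal, 6L)
  expect_equal(m$offset, 5L)
  expect_identical(m$ref_base, "g")
  expect_identical(m$alt_base, "a")
  m2 <- parseIvsMutation("IVS2+1A>G")
  expect_equal(m2$intron_ordinal, 2L)
  expect_identical(c(m2$ref_base, m2$alt_base), c("a", "g"))
  m3 <- parseIvsMutation("IVS3-2A>C")
  expect_equal(m3$offset, -2L)
  expect_error(parseIvsMutation("IVS6*5G>A"), "malformed")
  expect_error(parseIvsMutation("IVS6+5X>A"), "malformed")
})

test_that("the ATP7A donor-site mutations shift the enriched classes", {
  tab <- loadFixture("table1")
  code <- loadFixture("table2")
  atp7a <- loadFixture("atp7a")

  md2 <- interpretMutation(atp7a$donor_region, atp7a$acceptor_region,
                           "IVS6+5G>A", tab, code)
  expect_identical(md2@wildMotif$donor, "guaagu")
  expect_identical(md2@mutantMotif$donor, "guaa")
  expect_identical(md2@mutantEnriched, "S-S")
  ## the printed code grid lists the wild-type motif under S-S as well, so
  ## the mutation narrows the enriched set rather than adding to it
  expect_length(md2@gained, 0L)
  expect_setequal(md2@lost, setdiff(enrichedClasses(code, 3L), "S-S"))

  ohs <- interpretMutation(atp7a$donor_region, atp7a$acceptor_region,
                           "IVS6+6T>A", tab, code)
  expect_identical(ohs@mutantMotif$donor, "guaag")
  expect_setequal(ohs@mutantEnriched, c("A3-S", "R-R"))
  expect_setequal(ohs@gained, "A3-S")
})

test_that("core-consensus loss leaves no motif but cryptic candidates", {
  tab <- loadFixture("table1")
  code <- loadFixture("table2")
  atp7a <- loadFixture("atp7a")
  md1 <- interpretMutation(atp7a$donor_region, atp7a$acceptor_region,
                           "IVS6+1G>A", tab, code)
  expect_null(md1@mutantMotif)
  expect_length(md1@mutantEnriched, 0L)
  ## downstream guaag candidates at +5 and +50 survive the gu > au loss
  expect_equal(md1@cryptic$position, c(5L, 50L))
  expect_setequal(md1@cryptic$motif, "guaag")
})

test_that("the LKB1 au>gu donor gain still matches nothing on the table", {
  tab <- loadFixture("table1")
  code <- loadFixture("table2")
  lkb1 <- loadFixture("lkb1")
  pjs <- interpretMutation(lkb1$donor_region, lkb1$acceptor_region,
                           "IVS2+1A>G", tab, code)
  expect_equal(pjs@wildMotif$rank, 37L)     # auauccuu_ac
  expect_null(pjs@mutantMotif)
  expect_identical(pjs@lost, enrichedClasses(code, 37L))
})

test_that("self-interpretation is a no-op for every fixture intron", {
  tab <- loadFixture("table1")
  code <- loadFixture("table2")
  for (name in c("atp7a", "lkb1")) {
    fx <- loadFixture(name)
    ref <- substr(fx$donor_region, 3, 3)
    noop <- interpretMutation(fx$donor_region, fx$acceptor_region,
                              sprintf("IVS1+3%s>%s", toupper(ref),
                                      toupper(ref)), tab, code)
    expect_identical(noop@wildMotif, noop@mutantMotif)
    expect_length(noop@gained, 0L)
    expect_length(noop@lost, 0L)
  }
})

test_that("mutations beyond every motif length never change the motif", {
  tab <- loadFixture("table1")
  atp7a <- loadFixture("atp7a")
  maxLen <- max(nchar(consensusMotifs(tab)$donor))
  for (off in seq(maxLen + 1L, maxLen + 5L)) {
    ref <- substr(atp7a$donor_region, off, off)
    alt <- setdiff(c("a", "c", "g", "u"), ref)[1]
    rep <- interpretMutation(atp7a$donor_region, atp7a$acceptor_region,
                             sprintf("IVS6+%d%s>%s", off, toupper(ref),
                                     toupper(alt)), tab)
    expect_identical(rep@wildMotif, rep@mutantMotif)
  }
})

test_that("reference mismatches and out-of-window offsets are errors", {
  tab <- loadFixture("table1")
  atp7a <- loadFixture("atp7a")
  expect_error(interpretMutation(atp7a$donor_region,
                                 atp7a$acceptor_region,
                                 "IVS6+5T>A", tab), "reference mismatch")
  expect_error(interpretMutation(atp7a$donor_region,
                                 atp7a$acceptor_region,
                                 "IVS6+99G>A", tab), "beyond")
})

test_that("acceptor-side mutations edit the 3' suffix symmetrically", {
  tab <- loadFixture("table1")
  atp7a <- loadFixture("atp7a")
  ## -1 is the last intron base (the g of the ag core)
  rep <- interpretMutation(atp7a$donor_region, atp7a$acceptor_region,
                           "IVS6-1G>C", tab)
  expect_null(rep@mutantMotif)          # ac acceptor with a gu donor
})

test_that("cryptic scans report most-specific donor motifs in order", {
  tab <- loadFixture("table1")
  ## a/u spacers avoid incidental gu/gc dinucleotide donors
  seqA <- paste0(strrep("au", 24), "a", "guaag", strrep("au", 23))
  expect_equal(crypticSiteScan(seqA, tab, window = 100),
               data.frame(position = 50L, motif = "guaag"))
  expect_equal(nrow(crypticSiteScan(strrep("au", 50), tab)), 0L)
  seqB <- paste0(strrep("au", 4), "a", "gugagu", strrep("au", 12), "a",
                 "gcaag", strrep("au", 27))
  hits <- crypticSiteScan(seqB, tab, window = 50)
  ## gugagu itself carries a second gu dinucleotide at +14, which together
  ## with the following spacer base reads as the gua donor
  expect_equal(hits$position, c(10L, 14L, 41L))
  expect_equal(hits$motif, c("gugagu", "gua", "gcaag"))
})

test_that("acceptor-side cryptic scanning finds motif ends from the 3' end", {
  tab <- loadFixture("table1")
  seq <- paste0(strrep("u", 40), "cag", strrep("u", 17))
  hits <- crypticSiteScan(seq, tab, window = 30, side = "acceptor")
  expect_true("cag" %in% hits$motif)
})
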
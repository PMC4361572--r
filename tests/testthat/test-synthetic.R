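test_that("zero substitution rates give identical sequences everywhere", {
  cfg <- smallSimConfig(seed = 2,
                        m = c(phylum = 0, class = 0, order = 0, family = 0,
                              genus = 0, organism = 0, sequence = 0))
  sim <- simulateDataset(cfg)
  seqs <- as.character(alignedSeqs(sim$alignment))
  expect_equal(length(unique(seqs)), 1L)
  dm <- distanceMatrix(sim$alignment)
  expect_true(all(distValues(dm) == 0))
  # group means are exactly 0 at every rank
  gt <- groupDistanceTable(dm, sim$alignment, rank = "genus")
  expect_true(all(gt$mean[gt$n > 1] == 0))
})

test_that("the same config and seed reproduce the dataset exactly", {
  s1 <- simulateDataset(smallSimConfig(seed = 9))
  s2 <- simulateDataset(smallSimConfig(seed = 9))
  expect_identical(as.character(alignedSeqs(s1$alignment)),
                   as.character(alignedSeqs(s2$alignment)))
  expect_identical(s1$lineageTable, s2$lineageTable)
  expect_identical(s1$guideNewick, s2$guideNewick)
  s3 <- simulateDataset(smallSimConfig(seed = 10))
  expect_false(identical(as.character(alignedSeqs(s1$alignment)),
                         as.character(alignedSeqs(s3$alignment))))
})

test_that("config validation rejects saturating or malformed settings", {
  expect_error(simConfig(m = c(phylum = 0.96, class = 0.1, order = 0.1,
                               family = 0.1, genus = 0.1, organism = 0.1,
                               sequence = 0.1)), "19/20")
  expect_error(simConfig(L = 0), "L must be")
  expect_error(simConfig(hgtRate = 1.5), "hgtRate")
  expect_error(simConfig(fanout = list(phylum = 0, class = 1, order = 1,
                                       family = 1, genus = 1,
                                       organism = 1)), "fan-outs")
})

test_that("closed-form expected p-distance matches its defining chain", {
  expect_equal(expectedPDistance(0.1), 0.1, tolerance = 1e-12)
  expect_equal(expectedPDistance(numeric(0)), 0)
  expect_equal(expectedPDistance(c(0, 0, 0)), 0)
  expect_equal(expectedPDistance(c(0.1, 0.1)),
               1 - (1 / 20 + (19 / 20) * (1 - 2 / 19)^2),
               tolerance = 1e-12)
  expect_equal(expectedPDistance(c(0.1, 0.1)), 0.18947, tolerance = 1e-4)
  expect_error(expectedPDistance(0.96), "19/20")
})

test_that("simulated distances match the closed form within binomial error", {
  # sites are iid, so one long pair is a tight Monte-Carlo check
  cfg <- simConfig(fanout = list(phylum = 2, class = 1, order = 1,
                                 family = 1, genus = 1, organism = 1),
                   seqsPerOrganism = 1, L = 20000, seed = 5)
  sim <- simulateDataset(cfg)
  accs <- accessions(sim$alignment)
  d <- distValues(distanceMatrix(sim$alignment))
  exp_d <- expectedLeafDistance(sim, accs[1], accs[2])
  se <- sqrt(exp_d * (1 - exp_d) / 20000)
  expect_lt(abs(d[1, 2] - exp_d), 3 * se)
  # same-organism pair: path is two terminal branches
  cfg2 <- simConfig(fanout = list(phylum = 1, class = 1, order = 1,
                                  family = 1, genus = 1, organism = 1),
                    seqsPerOrganism = 2, L = 20000,
                    m = c(phylum = 0.1, class = 0.1, order = 0.1,
                          family = 0.1, genus = 0.1, organism = 0.1,
                          sequence = 0.05), seed = 6)
  sim2 <- simulateDataset(cfg2)
  a2 <- accessions(sim2$alignment)
  exp2 <- expectedLeafDistance(sim2, a2[1], a2[2])
  expect_equal(exp2, expectedPDistance(c(0.05, 0.05)), tolerance = 1e-12)
  d2 <- distValues(distanceMatrix(sim2$alignment))
  se2 <- sqrt(exp2 * (1 - exp2) / 20000)
  expect_lt(abs(d2[1, 2] - exp2), 3 * se2)
})

test_that("rank summary reproduces the configured fan-outs exactly", {
  cfg <- simConfig(fanout = list(phylum = 3, class = 2, order = 2,
                                 family = 1, genus = 2, organism = 2),
                   seqsPerOrganism = 2, L = 50, seed = 8)
  sim <- simulateDataset(cfg)
  rs <- rankSummary(sim$alignment)
  expect_equal(rs$distinct_count,
               c(3L, 6L, 12L, 12L, 24L, 48L))
  expect_equal(attr(rs, "n_records"), 96L)
})

test_that("transfer injection respects rate, clans and substreams", {
  base <- simulateDataset(smallSimConfig(seed = 14))
  # rate 0: identity, empty log
  h0 <- injectHgt(base, 0)
  expect_identical(as.character(alignedSeqs(h0$alignment)),
                   as.character(alignedSeqs(base$alignment)))
  expect_equal(nrow(h0$hgtEvents), 0L)
  # rate 1 at phylum crossing: every leaf receives from the other phylum
  h1 <- injectHgt(base, 1, crossingRank = "phylum")
  expect_equal(nrow(h1$hgtEvents), length(base$alignment))
  lin <- as.data.frame(taxonomy(base$alignment))
  phy <- setNames(lin$phylum, lin$accession)
  ok <- phy[h1$hgtEvents$recipient] != phy[h1$hgtEvents$donor]
  expect_true(all(ok))
  # lineage labels never move with the sequence
  expect_identical(as.data.frame(taxonomy(h1$alignment)), lin)
  # substream isolation: partial transfer leaves non-recipients untouched
  hp <- injectHgt(base, 0.3, crossingRank = "genus")
  untouched <- setdiff(accessions(base$alignment), hp$hgtEvents$recipient)
  expect_gt(length(untouched), 0)
  expect_identical(
    as.character(alignedSeqs(hp$alignment)[untouched]),
    as.character(alignedSeqs(base$alignment)[untouched]))
  expect_error(injectHgt(base, -0.1), "hgtRate")
})

test_that("a leaf with no eligible donor clan is skipped and logged", {
  cfg <- simConfig(fanout = list(phylum = 1, class = 1, order = 1,
                                 family = 1, genus = 1, organism = 2),
                   seqsPerOrganism = 2, L = 60, seed = 4)
  sim <- simulateDataset(cfg)
  h <- injectHgt(sim, 1, crossingRank = "phylum")   # only one phylum exists
  expect_true(all(h$hgtEvents$note == "skipped:no-donor"))
  expect_identical(as.character(alignedSeqs(h$alignment)),
                   as.character(alignedSeqs(sim$alignment)))
})

test_that("written datasets round-trip through the standard readers", {
  sim <- simulateDataset(smallSimConfig(seed = 20, hgtRate = 0.2))
  dir <- tempfile()
  files <- writeDataset(sim, dir)
  expect_true(all(file.exists(files)))
  aln <- readAlignmentFasta(files[["fasta"]])
  tbl <- readLineageTable(files[["lineage"]])
  bound <- bindTaxonomy(aln, tbl, "Bacteria")
  expect_setequal(accessions(bound), accessions(sim$alignment))
  truth <- jsonlite::read_json(files[["truth"]])
  expect_equal(truth$seed, sim$config$seed)
  expect_true(nzchar(truth$guide_newick))
  # guide tree parses and carries every accession as a tip
  gt <- ape::read.tree(text = truth$guide_newick)
  expect_setequal(gt$tip.label, accessions(sim$alignment))
})

test_that("the synthetic study table machinery hits its configured counts", {
  st <- simulateStudyTable(seed = 3, nTotal = 220, nFragments = 5,
                           nArchaea = 1, nEukaryota = 2, nComplete = 150,
                           taxa = c(phylum = 3, class = 5, order = 9,
                                    family = 15, genus = 30,
                                    organism = 120),
                           L = 80)
  expect_equal(length(st$alignment), 220L)
  fr <- filterFragments(st$alignment, st$table)
  expect_equal(length(fr$removed), 5L)
  bound <- bindTaxonomy(fr$kept, st$table, "Bacteria")
  expect_equal(length(bound), 150L)
  rs <- rankSummary(bound)
  expect_equal(rs$distinct_count, c(3L, 5L, 9L, 15L, 30L, 120L))
})

test_that("the synthetic worked pair reproduces its documented identity", {
  wp <- workedPairAlignment()
  expect_equal(Biostrings::width(wp), c(169L, 169L))
  ungapped <- Biostrings::width(wp) -
    Biostrings::letterFrequency(wp, "-")[, 1]
  expect_equal(unname(ungapped), c(155, 161))
  id <- percentIdentity(as.character(wp[[1]]), as.character(wp[[2]]))
  expect_equal(id, 100 * 82 / 169, tolerance = 1e-12)
  expect_equal(round(id, 3), 48.521)
})
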
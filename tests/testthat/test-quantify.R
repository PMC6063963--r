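# Read parsing, whitelisting, indel calling and rate quantification.

cleanPipeline <- function(design, truth, cfg) {
  sim <- simulateIntegrations(design, cfg)
  d0 <- simulateReads(sim, truth, 0)
  obs0 <- parseReadPairs(d0$read1, d0$read2, design)
  list(sim = sim, d0 = d0, obs0 = obs0)
}

test_that("error-free simulated reads parse back to their exact origin", {
  design <- smallDesign(nGroups = 2, lengths = 19:21, mismatchGroups = 1)
  cfg <- simConfig(seed = 31, synthesisErrorRate = 0, synthesisIndelRate = 0,
                   sequencingErrorRate = 0, integrationsPerMember = 5,
                   readsPerRbc = 1)
  truth <- simulateTruth(design, cfg)
  p <- cleanPipeline(design, truth, cfg)
  obs <- p$obs0
  expect_true(all(obs$anchorOk))
  expect_identical(obs$memberId, p$d0$info$memberId)
  expect_identical(obs$rbc, p$d0$info$rbc)
  expect_true(all(obs$hammingStatus == "exact"))
  m <- designMembers(design)
  i <- match(obs$memberId, m$memberId)
  expect_identical(obs$spacerRegion, m$spacer[i])
  expect_identical(obs$targetRegion,
                   pairscreen:::.paddedTarget(designLayout(design),
                                              m$target)[i])
})

test_that("a substituted Hamming barcode is corrected; broken anchors fail", {
  design <- smallDesign(nGroups = 1, lengths = 19:19, mismatchGroups = 0)
  cfg <- simConfig(seed = 33, synthesisErrorRate = 0, synthesisIndelRate = 0,
                   sequencingErrorRate = 0, integrationsPerMember = 3,
                   readsPerRbc = 1)
  truth <- simulateTruth(design, cfg)
  p <- cleanPipeline(design, truth, cfg)
  r2 <- as.character(p$d0$read2)
  lay <- designLayout(design)
  # corrupt one base inside the (reverse-complemented) barcode field of read 2
  bcPos <- nchar(lay@downstream) + 5L
  substr(r2[1], bcPos, bcPos) <- setdiff(c("A", "C", "G", "T"),
                                         substr(r2[1], bcPos, bcPos))[1]
  obs <- parseReadPairs(p$d0$read1, Biostrings::DNAStringSet(r2), design)
  expect_identical(obs$hammingStatus[1], "corrected")
  expect_identical(obs$memberId[1], p$d0$info$memberId[1])

  # scrambled anchors: reverse the upstream segment of read 1
  r1 <- as.character(p$d0$read1)
  substr(r1[2], 1, 20) <- paste(rev(strsplit(substr(r1[2], 1, 20), "")[[1]]),
                                collapse = "")
  obs2 <- parseReadPairs(Biostrings::DNAStringSet(r1), p$d0$read2, design)
  expect_false(obs2$anchorOk[2])
  expect_true(obs2$anchorOk[1])
})

test_that("indel calling separates intact, cut-site indels, and discards", {
  tgt <- "ATCGTTAAGCGGCCGGATCTACGTACGT"     # padded expected region
  expect_identical(callIndel(tgt, tgt), "intact")
  # 3-nt deletion spanning the cut site (3 bp 5' of the PAM = 3' end here)
  del <- paste0(substr(tgt, 1, 22), substr(tgt, 26, 28))
  expect_identical(callIndel(del, tgt), "indel")
  # 1-nt insertion at the cut boundary
  ins <- paste0(substr(tgt, 1, 25), "A", substr(tgt, 26, 28))
  expect_identical(callIndel(ins, tgt), "indel")
  # substitution only, same length: synthesis/PCR/sequencing error -> discard
  subv <- tgt
  substr(subv, 24, 24) <- "A"
  expect_identical(callIndel(subv, tgt), "discard")
  # deletion far outside the cut window -> discard
  far <- substr(tgt, 2, 28)
  expect_identical(callIndel(far, tgt, window = 4), "discard")
  # vectorized and deterministic
  expect_identical(callIndel(c(tgt, del, subv), tgt),
                   c("intact", "indel", "discard"))
})

test_that("whitelist admits exactly clean, supported, unambiguous cassettes", {
  obs <- S4Vectors::DataFrame(
    memberId = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L),
    rbc      = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "CCCCCCCC",
                 "GGGGGGGG", "GGGGGGGG", "TTTTTTTT", "TTTTTTTT", "GGGGGGGG"),
    spacerRegion = "S", targetRegion = "T", anchorOk = TRUE,
    hammingStatus = "exact")
  design <- smallDesign(nGroups = 1, lengths = 19:21, mismatchGroups = 0)
  m <- designMembers(design)[1:3, ]
  m$memberId <- 1:3
  m$spacer <- "S"
  m$target <- "T"
  fake <- design
  fake@members <- m
  # make the padded expected target equal "T" by a window-1 layout
  fake@layout@targetWindow <- 1L
  # member 1 rBC CCCCCCCC has one read with a target error
  obs$targetRegion[4] <- "X"
  wl <- buildWhitelist(obs, fake, minReadsPerRbc = 2L)
  key <- paste(wl$memberId, wl$rbc)
  expect_true("1 AAAAAAAA" %in% key)        # clean, 2 reads
  expect_false("1 CCCCCCCC" %in% key)       # one unclean supporting read
  expect_false("2 GGGGGGGG" %in% key)       # rBC shared with member 3
  expect_false("3 GGGGGGGG" %in% key)
  expect_true("3 TTTTTTTT" %in% key)        # clean, 2 reads -> admitted
  expect_equal(wl$day0Reads[key == "1 AAAAAAAA"], 2L)

  # read-support threshold
  wl3 <- buildWhitelist(obs, fake, minReadsPerRbc = 3L)
  expect_equal(nrow(wl3), 0L)
  expect_warning(buildWhitelist(obs[0, ], fake), "empty")
})

test_that("Day-0 whitelist equals the truth log under synthesis errors", {
  design <- smallDesign(nGroups = 3, lengths = 19:21, mismatchGroups = 1)
  cfg <- simConfig(seed = 37, synthesisErrorRate = 0.05,
                   synthesisIndelRate = 0.1, sequencingErrorRate = 0,
                   integrationsPerMember = 10, readsPerRbc = 3)
  truth <- simulateTruth(design, cfg)
  p <- cleanPipeline(design, truth, cfg)
  wl <- buildWhitelist(p$obs0, design, minReadsPerRbc = 2L)
  tw <- truthWhitelist(p$sim)
  expect_setequal(paste(wl$memberId, wl$rbc), paste(tw$memberId, tw$rbc))
})

test_that("indel rates conserve read counts and respect the whitelist", {
  design <- smallDesign(nGroups = 2, lengths = 19:21, mismatchGroups = 1)
  cfg <- simConfig(seed = 41, synthesisErrorRate = 0.03,
                   synthesisIndelRate = 0.1, sequencingErrorRate = 0,
                   integrationsPerMember = 12, readsPerRbc = 3)
  truth <- simulateTruth(design, cfg)
  p <- cleanPipeline(design, truth, cfg)
  wl <- buildWhitelist(p$obs0, design)
  d3 <- simulateReads(p$sim, truth, 3)
  obs3 <- parseReadPairs(d3$read1, d3$read2, design)
  rates <- computeIndelRates(obs3, design, wl, minRbc = 5L)

  expect_equal(nrow(rates), nrow(designMembers(design)))
  expect_identical(rates$nReads, rates$nIntact + rates$nIndel + rates$nDiscarded)
  expect_true(all(rates$indelRate >= 0 & rates$indelRate <= 1, na.rm = TRUE))
  expect_identical(rates$excluded, rates$nRbc < 5L)
  # whitelisting never increases read counts
  unfiltered <- computeIndelRates(obs3, design, NULL, minRbc = 5L)
  expect_true(all(rates$nReads <= unfiltered$nReads))
  # members with zero whitelisted reads have an absent rate
  expect_true(all(is.na(rates$indelRate[rates$nReads - rates$nDiscarded == 0])))
})

test_that("error-free rates match the forward model within binomial bounds", {
  design <- smallDesign(nGroups = 2, lengths = 19:21, mismatchGroups = 2)
  cfg <- simConfig(seed = 43, synthesisErrorRate = 0, synthesisIndelRate = 0,
                   sequencingErrorRate = 0, integrationsPerMember = 30,
                   readsPerRbc = 2)
  truth <- simulateTruth(design, cfg)
  p <- cleanPipeline(design, truth, cfg)
  wl <- buildWhitelist(p$obs0, design)
  d3 <- simulateReads(p$sim, truth, 3)
  obs3 <- parseReadPairs(d3$read1, d3$read2, design)
  rates <- computeIndelRates(obs3, design, wl, minRbc = 0L)
  pTrue <- memberEditProb(design, truth)[as.character(rates$memberId)]
  ok <- withinBinomCI(round(rates$indelRate * rates$nRbc), rates$nRbc, pTrue)
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("off:on ratios normalize by the matched member and gate at 2%", {
  rec <- data.frame(memberId = 1:4,
                    nRbc = 25L, nReads = 100L, nIntact = 50L, nIndel = 50L,
                    nDiscarded = 0L,
                    indelRate = c(0.25, 0.05, 0.01, 0.002),
                    excluded = FALSE)
  design <- smallDesign(nGroups = 2, lengths = 19:19, mismatchGroups = 2)
  m <- designMembers(design)
  # members: group1 matched, group1 single_mm, group2 matched, group2 single_mm
  keep <- c(which(m$category == "matched" & m$groupId == 1)[1],
            which(m$category == "single_mismatch" & m$groupId == 1)[1],
            which(m$category == "matched" & m$groupId == 2)[1],
            which(m$category == "single_mismatch" & m$groupId == 2)[1])
  fake <- design
  fake@members <- m[keep, ]
  fake@members$memberId <- 1:4
  fake@members$barcode <- m$barcode[keep]

  rr <- offOnRatios(rec, fake)
  expect_equal(rr$offOnRatio[1], 1)                 # matched
  expect_equal(rr$offOnRatio[2], 0.05 / 0.25)       # 0.20
  # group 2 on-target is 1% (< 2%): whole group-length absent
  expect_true(is.na(rr$offOnRatio[3]))
  expect_true(is.na(rr$offOnRatio[4]))
})

test_that("tolerance aggregation localizes a penalized position", {
  design <- smallDesign(nGroups = 1, lengths = 20:20, mismatchGroups = 1)
  truth <- manualTruth(design, g = 0.6, fill = 1, positionF = list(`5` = 0.5))
  cfg <- simConfig(seed = 47, synthesisErrorRate = 0, synthesisIndelRate = 0,
                   sequencingErrorRate = 0, integrationsPerMember = 200,
                   integrationDist = "constant", readsPerRbc = 1)
  sim <- simulateIntegrations(design, cfg)
  d0 <- simulateReads(sim, truth, 0)
  obs0 <- parseReadPairs(d0$read1, d0$read2, design)
  wl <- buildWhitelist(obs0, design, minReadsPerRbc = 1L)
  d3 <- simulateReads(sim, truth, 3)
  obs3 <- parseReadPairs(d3$read1, d3$read2, design)
  rates <- computeIndelRates(obs3, design, wl, minRbc = 20L)
  rr <- offOnRatios(rates, design)
  agg <- aggregateTolerance(rr, design, by = "position")
  at5 <- agg$mean[agg$position == 5]
  elsewhere <- agg$mean[agg$position != 5]
  expect_lt(abs(at5 - 0.5), 0.12)
  expect_true(all(abs(elsewhere - 1) < 0.2))
  # strata counts: 3 single-mismatch members per (length, position) stratum
  expect_equal(sum(agg$n), sum(rr$category == "single_mismatch" &
                                 !is.na(rr$offOnRatio)))
  # single-member stratum mean equals that member's ratio
  one <- rr[rr$category == "single_mismatch" & !is.na(rr$offOnRatio), ][1, ]
  aggOne <- aggregateTolerance(rr[rr$memberId %in%
                                    c(one$memberId,
                                      rr$memberId[rr$category == "matched"]), ],
                               design, by = "position")
  expect_equal(aggOne$mean[1], one$offOnRatio)
  expect_equal(aggOne$n[1], 1)
})

test_that("replicate concordance is perfect for identical inputs and monotone in retention", {
  set.seed(59)
  rec <- data.frame(memberId = 1:50, nRbc = rep(c(5L, 15L, 30L), length.out = 50),
                    indelRate = runif(50))
  rc <- replicateConcordance(rec, rec, thresholds = c(1L, 10L, 20L))
  expect_equal(rc$r2, rep(1, 3))
  expect_true(all(diff(rc$retainedFraction) <= 0))
  # fewer than 3 shared members -> absent
  tiny <- replicateConcordance(rec[1:2, ], rec[1:2, ], thresholds = 1L)
  expect_true(is.na(tiny$r2))
})

test_that("replicate R2 improves as the rBC threshold rises", {
  design <- smallDesign(nGroups = 1, lengths = 19:24, mismatchGroups = 1)
  truth <- simulateTruth(design, simConfig(seed = 57))   # shared biology
  replicate_rates <- function(seed) {
    cfg <- simConfig(seed = seed, synthesisErrorRate = 0,
                     synthesisIndelRate = 0, sequencingErrorRate = 0,
                     integrationsPerMember = 5, readsPerRbc = 1)
    sim <- simulateIntegrations(design, cfg)
    d0 <- simulateReads(sim, truth, 0)
    wl <- buildWhitelist(parseReadPairs(d0$read1, d0$read2, design), design,
                         minReadsPerRbc = 1L)
    d3 <- simulateReads(sim, truth, 3)
    computeIndelRates(parseReadPairs(d3$read1, d3$read2, design), design,
                      wl, minRbc = 0L)
  }
  # trend test over repeated independent replicate pairs: members kept at a
  # higher rBC threshold are measured with less binomial noise, so R2 rises
  # while the retained fraction falls
  diffs <- vapply(1:2, function(k) {
    rc <- replicateConcordance(replicate_rates(570 + 2 * k),
                               replicate_rates(571 + 2 * k),
                               thresholds = c(2L, 7L))
    expect_true(all(diff(rc$retainedFraction) <= 0))
    rc$r2[2] - rc$r2[1]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("whitelisting suppresses synthesis-driven false-positive indels", {
  design <- smallDesign(nGroups = 2, lengths = 19:21, mismatchGroups = 0)
  truth <- manualTruth(design, g = 0, fill = 1)     # editing off
  cfg <- simConfig(seed = 53, synthesisErrorRate = 0.025,
                   synthesisIndelRate = 0.15, sequencingErrorRate = 0,
                   integrationsPerMember = 60, readsPerRbc = 2)
  sim <- simulateIntegrations(design, cfg)
  d0 <- simulateReads(sim, truth, 0)
  obs0 <- parseReadPairs(d0$read1, d0$read2, design)
  wl <- buildWhitelist(obs0, design)
  d3 <- simulateReads(sim, truth, 3)
  obs3 <- parseReadPairs(d3$read1, d3$read2, design)
  filtered <- computeIndelRates(obs3, design, wl, minRbc = 0L)
  unfiltered <- computeIndelRates(obs3, design, NULL, minRbc = 0L)
  expect_true(all(filtered$indelRate < 0.005, na.rm = TRUE))
  expect_gt(mean(unfiltered$indelRate, na.rm = TRUE),
            mean(filtered$indelRate, na.rm = TRUE))
  expect_gt(mean(unfiltered$indelRate, na.rm = TRUE), 0.025)
})
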
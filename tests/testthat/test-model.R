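# Mismatch-penalty model: featurization, prediction, fitting, convergence,
# scoring and ranking.

test_that("featurization uses PAM-proximal positions and RNA:DNA classes", {
  expect_equal(nrow(mismatchDescriptors("GACGT", "GACGT")), 0L)
  # substitution at the PAM-proximal base (last string character)
  d <- mismatchDescriptors("GACGT", "GACGA")
  expect_equal(d$position, 1L)
  expect_equal(d$rna, "U")        # spacer base T faces the complement of A
  expect_equal(d$dna, "T")
  expect_equal(d$type, "rU:dT")
  # hand-enumerated all-positions-different toy pair of length 5:
  # spacer GACGT vs target TGTAC, PAM-proximal positions 1..5
  d5 <- mismatchDescriptors("GACGT", "TGTAC")
  expect_equal(d5$position, 1:5)
  expect_equal(d5$type,
               c("rU:dG", "rG:dT", "rC:dA", "rA:dC", "rG:dA"))
  expect_true(all(d5$typeIndex %in% 1:12))
  # every descriptor is a non-Watson-Crick pairing by construction
  wc <- c(rA = "T", rC = "G", rG = "C", rU = "A")
  expect_true(all(wc[paste0("r", d5$rna)] != d5$dna))
  expect_error(mismatchDescriptors("GACGT", "GACGTA"), "bulged")
})

test_that("prediction multiplies penalties; additive form agrees to 1e-10", {
  f <- matrix(1, 21, 12)
  expect_equal(predictIndelRate(0.7, NULL, f), 0.7)
  f[1, 3] <- 0.25
  d <- data.frame(position = 1L, typeIndex = 3L)
  expect_equal(predictIndelRate(0.8, d, f), 0.2)
  f[5, 2] <- 0.5
  f[9, 7] <- 0.1
  d2 <- data.frame(position = c(5L, 9L), typeIndex = c(2L, 7L))
  expect_equal(predictIndelRate(1, d2, f), 0.05)

  set.seed(61)
  for (k in 1:25) {
    L <- sample(19:24, 1)
    ddG <- matrix(rexp(L * 12), L, 12)
    nm <- sample(0:4, 1)
    pos <- sample(L, nm)
    ty <- sample(12, nm, replace = TRUE)
    d <- data.frame(position = pos, typeIndex = ty)
    g <- runif(1)
    mult <- predictIndelRate(g, d, exp(-ddG))
    addv <- g * exp(-sum(ddG[cbind(pos, ty)]))
    expect_equal(mult, addv, tolerance = 1e-10)
  }
  expect_error(predictIndelRate(1, data.frame(position = 30L, typeIndex = 1L),
                                f), "exceeds")
})

test_that("map fit recovers penalties from noiseless data", {
  set.seed(71)
  L <- 19L
  ddG <- matrix(rexp(L * 12), L, 12)
  f <- exp(-ddG)
  d <- modelObs(f, nGuides = 16, L = L, noiseSd = 0, nDouble = 50, seed = 72)
  # noiseless data: the error sd reflects it, so the prior barely biases
  fit <- fitPenaltyModel(d$obs, L, modelConfig(mode = "map", errorSd = 0.01))
  well <- fit@nObs >= 3
  expect_gt(sum(well), 100)
  expect_true(all(abs(fit@f[well] - f[well]) < 0.02))
  # guide activities recovered (match by name: factor levels are sorted)
  est <- fit@guideActivity
  expect_true(all(abs(est$g[match(d$guides, est$guide)] - d$g) < 0.02))
})

test_that("a single off-target observation gives the closed form f = I/g", {
  obs <- data.frame(guide = "g1", rate = c(0.5, 0.1),
                    cells = c("", "7"))
  fit <- fitPenaltyModel(obs, 19L, modelConfig(mode = "map", errorSd = 1e-3))
  expect_equal(unname(fit@f[7]), 0.2, tolerance = 0.01)
  expect_equal(fit@guideActivity$g, 0.5, tolerance = 0.01)
})

test_that("with no mismatch effect the penalties shrink toward zero", {
  set.seed(73)
  L <- 19L
  f1 <- matrix(1, L, 12)
  d <- modelObs(f1, nGuides = 10, L = L, noiseSd = 0, nDouble = 30, seed = 74)
  fit <- fitPenaltyModel(d$obs, L, modelConfig(mode = "map"))
  expect_true(all(fit@f[fit@nObs > 0] > 0.95))
})

test_that("prior-dominated cells are flagged; unfitted guides warn", {
  obs <- data.frame(guide = "g1", rate = c(0.5, 0.2), cells = c("", "3"))
  fit <- fitPenaltyModel(obs, 19L, modelConfig(mode = "map"))
  expect_equal(sum(fit@nObs), 1L)
  expect_equal(sum(fit@nObs == 0), 19L * 12L - 1L)
  expect_warning(
    fitPenaltyModel(data.frame(guide = "g2", rate = 0.1, cells = "5"),
                    19L, modelConfig(mode = "map")),
    "weakly identified")
})

test_that("mcmc fit samples the posterior and reports R-hat", {
  set.seed(81)
  L <- 19L
  ddG <- matrix(rexp(L * 12), L, 12)
  f <- exp(-ddG)
  d <- modelObs(f, nGuides = 4, L = L, noiseSd = 0.1, nDouble = 40, seed = 82)
  cfg <- modelConfig(mode = "mcmc", nChains = 2L, nSamples = 700L,
                     nWarmup = 200L, seed = 5L)
  fit <- fitPenaltyModel(d$obs, L, cfg)
  expect_identical(fit@mode, "mcmc")
  expect_true(all(is.finite(fit@rhat)))
  expect_false(is.na(fit@converged))
  # intervals are ordered and contain the point estimate
  cov <- fit@nObs > 0
  expect_true(all(fit@fLower[cov] <= fit@fUpper[cov]))
  expect_true(all(fit@f[cov] >= fit@fLower[cov] - 1e-9 &
                    fit@f[cov] <= fit@fUpper[cov] + 1e-9))
  # prior sanity: unobserved cells sit at the Exponential prior, mean ddG ~ 1
  un <- fit@nObs == 0
  expect_gt(sum(un), 10)
  expect_lt(abs(mean(fit@ddG[un]) - 1), 0.15)
  # determinism of seeded chains
  fit2 <- fitPenaltyModel(d$obs, L, cfg)
  expect_identical(fit@ddG, fit2@ddG)
})

test_that("convergence checks follow the R-hat rule", {
  # identical stationary chains: R-hat near 1
  set.seed(91)
  good <- coda::mcmc.list(coda::mcmc(cbind(x = rnorm(600))),
                          coda::mcmc(cbind(x = rnorm(600))))
  expect_lt(pairscreen:::.computeRhat(good)["x"], 1.05)
  # chains stuck in disjoint modes: R-hat far above 1.1
  badChains <- coda::mcmc.list(coda::mcmc(cbind(x = rnorm(600, 0, 0.1))),
                               coda::mcmc(cbind(x = rnorm(600, 5, 0.1))))
  expect_gt(pairscreen:::.computeRhat(badChains)["x"], 1.1)
  # single chain: R-hat undefined
  expect_error(pairscreen:::.computeRhat(
    coda::mcmc.list(coda::mcmc(cbind(x = rnorm(100))))), "two chains")

  # map mode: not applicable, never FALSE
  obs <- data.frame(guide = "g1", rate = c(0.5, 0.1), cells = c("", "7"))
  mapFit <- fitPenaltyModel(obs, 19L, modelConfig(mode = "map"))
  conv <- checkConvergence(mapFit)
  expect_true(is.na(conv))
  expect_match(attr(conv, "reason"), "not applicable")
})

test_that("penalties behind low-activity guides are less certain", {
  set.seed(95)
  L <- 19L
  ddG <- matrix(rexp(L * 12), L, 12)
  f <- exp(-ddG)
  cfg <- modelConfig(mode = "mcmc", nChains = 2L, nSamples = 500L,
                     nWarmup = 150L, seed = 9L)
  hi <- modelObs(f, nGuides = 3, L = L, noiseSd = 0.1, nDouble = 0,
                 gRange = c(0.7, 0.9), seed = 96)
  lo <- modelObs(f, nGuides = 3, L = L, noiseSd = 0.1, nDouble = 0,
                 gRange = c(0.01, 0.05), seed = 96)   # same spacers, low g
  fitHi <- fitPenaltyModel(hi$obs, L, cfg)
  fitLo <- fitPenaltyModel(lo$obs, L, cfg)
  cov <- fitHi@nObs > 0 & fitLo@nObs > 0
  widthHi <- mean((fitHi@fUpper - fitHi@fLower)[cov])
  widthLo <- mean((fitLo@fUpper - fitLo@fLower)[cov])
  expect_gt(widthLo, widthHi)
})

test_that("specificity scores are monotone and rank candidates correctly", {
  set.seed(97)
  L <- 20L
  spacer <- paste0("G", paste(sample(BASES, L - 1, TRUE), collapse = ""))
  f <- matrix(runif(L * 12, 0.05, 0.95), L, 12)

  expect_equal(unname(specificityScore(spacer, spacer, f)), 1)
  # single mismatch scores its single factor
  v <- enumerateVariants(spacer, "single_mismatch")
  for (k in sample(nrow(v), 10)) {
    d <- mismatchDescriptors(spacer, v$target[k])
    expect_equal(unname(specificityScore(spacer, v$target[k], f)),
                 f[d$position, d$typeIndex])
  }
  # superset of mismatches never scores higher
  for (k in 1:20) {
    vd <- enumerateVariants(spacer, "double_mismatch")
    j <- sample(nrow(vd), 1)
    dd <- mismatchDescriptors(spacer, vd$target[j])
    # corresponding single-mismatch subset site
    chars <- strsplit(spacer, "")[[1]]
    tchars <- strsplit(vd$target[j], "")[[1]]
    i1 <- L - dd$position[1] + 1
    sub1 <- chars; sub1[i1] <- tchars[i1]
    subsite <- paste(sub1, collapse = "")
    expect_lte(specificityScore(spacer, vd$target[j], f),
               specificityScore(spacer, subsite, f))
  }
  # bulged candidate: absent with a reason
  s <- specificityScore(spacer, substr(spacer, 1, L - 1), f)
  expect_true(is.na(s))
  expect_match(attr(s, "reason")[1], "length")

  # ranking: perfect match, then its 1-mm subset, then the 2-mm superset
  vd <- enumerateVariants(spacer, "double_mismatch")
  dd <- mismatchDescriptors(spacer, vd$target[1])
  chars <- strsplit(spacer, "")[[1]]
  tchars <- strsplit(vd$target[1], "")[[1]]
  i1 <- L - dd$position[1] + 1
  sub1 <- chars; sub1[i1] <- tchars[i1]
  cands <- c(vd$target[1], paste(sub1, collapse = ""), spacer)
  rk <- rankOffTargets(spacer, cands, f)
  expect_equal(rk$nMismatch, c(0L, 1L, 2L))
  expect_equal(rk$site[1], spacer)

  # Spearman correlation against provided activities
  acts <- specificityScore(spacer, cands, f)
  rk1 <- rankOffTargets(spacer, cands, f, activities = as.numeric(acts))
  expect_equal(attr(rk1, "spearman"), 1)
  rk2 <- rankOffTargets(spacer, cands, f, activities = -as.numeric(acts))
  expect_equal(attr(rk2, "spearman"), -1)
  expect_equal(nrow(rankOffTargets(spacer, character(0), f)), 0L)
})

test_that("penalty matrices and fits round-trip through TSV", {
  obs <- data.frame(guide = "g1", rate = c(0.5, 0.1), cells = c("", "7"))
  fit <- fitPenaltyModel(obs, 19L, modelConfig(mode = "map"))
  path <- tempfile(fileext = ".tsv")
  writePenaltyMatrix(fit, path)
  f <- readPenaltyMatrix(path)
  expect_equal(f[, ], fit@f[, ], tolerance = 1e-12)
  expect_equal(attr(f, "ddG")[, ], fit@ddG[, ], tolerance = 1e-12)

  ga <- tempfile(fileext = ".tsv")
  writeGuideActivity(fit, ga)
  back <- utils::read.table(ga, header = TRUE, sep = "\t")
  expect_equal(back$g, fit@guideActivity$g, tolerance = 1e-12)

  dj <- tempfile(fileext = ".json")
  writeFitDiagnostics(fit, dj)
  diag <- jsonlite::read_json(dj, simplifyVector = TRUE)
  expect_identical(diag$mode, "map")
  expect_equal(diag$priorDominatedCells, sum(fit@nObs == 0))
})

test_that("indelObservations extracts the fitting table for one length", {
  design <- smallDesign(nGroups = 1, lengths = 19:20, mismatchGroups = 1)
  m <- designMembers(design)
  rec <- data.frame(memberId = m$memberId, nRbc = 25L,
                    indelRate = runif(nrow(m)), excluded = FALSE)
  rec$excluded[1] <- TRUE
  obs <- indelObservations(rec, design, 19L)
  expect_true(all(nchar(obs$spacer) == 19L))
  # the excluded member (memberId 1, a length-19 member) is dropped
  expect_equal(nrow(obs), sum(m$spacerLength == 19L) - 1L)
  expect_true(all(obs$rate >= 0 & obs$rate <= 1))
  expect_setequal(unique(obs$guide), "g1_19")
})
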
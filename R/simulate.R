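# Synthetic screen generator: ground-truth penalties and guide activities,
# lentiviral integrations with synthesis errors and rBC tagging, and
# paired-end reads for any timepoint, all deterministic given the seed.

#' Simulation configuration
#'
#' Defaults emulate the pooled-screen regime of the assay: per-molecule
#' oligo-synthesis substitutions and indels on the variable region (spacer +
#' target) at rates giving roughly a quarter of molecules error-free, ~30
#' independent lentiviral integrations (rBCs) per member, a small Illumina-like
#' sequencing substitution rate, and Day 0/3/14 timepoints with editing
#' saturating after Day 3.
#'
#' @param seed integer seed fixing every draw.
#' @param synthesisErrorRate per-base substitution probability on the variable
#'   region at synthesis (default 0.025).
#' @param synthesisIndelRate per-oligo probability of a single synthesis indel
#'   in the variable region (default 0.15).
#' @param integrationsPerMember mean number of integrations (rBCs) per member.
#' @param integrationDist `"poisson"` (default) or `"constant"`.
#' @param readsPerRbc reads sequenced per integration per timepoint.
#' @param readsDist `"constant"` (default) or `"poisson"`.
#' @param sequencingErrorRate per-base substitution probability on reads.
#' @param timepoints day labels of the experiment.
#' @param saturation named per-day multiplier on the editing probability
#'   (Day 0 is pre-nuclease; editing saturates after Day 3).
#' @param readLength paired-end read length (2 x 150 bp sequencing).
#' @param guideActivityShape Beta(shape1, shape2) for guide activities g.
#' @param bulgePenalty named multiplicative factors for bulges at PAM-proximal
#'   positions 1-18 (`proximal`) and beyond (`distal`); bulges are minimally
#'   tolerated proximally and near-completely tolerated distally.
#' @return A validated configuration list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L,
                      synthesisErrorRate = 0.025,
                      synthesisIndelRate = 0.15,
                      integrationsPerMember = 30,
                      integrationDist = c("poisson", "constant"),
                      readsPerRbc = 5,
                      readsDist = c("constant", "poisson"),
                      sequencingErrorRate = 0.001,
                      timepoints = c(0, 3, 14),
                      saturation = c("0" = 0, "3" = 1, "14" = 1.25),
                      readLength = 150L,
                      guideActivityShape = c(2, 2),
                      bulgePenalty = c(proximal = 0.05, distal = 0.9)) {
  integrationDist <- match.arg(integrationDist)
  readsDist <- match.arg(readsDist)
  rates <- c(synthesisErrorRate, synthesisIndelRate, sequencingErrorRate)
  stopifnot(all(rates >= 0 & rates <= 1),
            all(as.character(timepoints) %in% names(saturation)),
            readLength >= 50L)
  structure(list(seed = as.integer(seed),
                 synthesisErrorRate = synthesisErrorRate,
                 synthesisIndelRate = synthesisIndelRate,
                 integrationsPerMember = integrationsPerMember,
                 integrationDist = integrationDist,
                 readsPerRbc = readsPerRbc, readsDist = readsDist,
                 sequencingErrorRate = sequencingErrorRate,
                 timepoints = timepoints, saturation = saturation,
                 readLength = as.integer(readLength),
                 guideActivityShape = guideActivityShape,
                 bulgePenalty = bulgePenalty),
            class = "simConfig")
}

#' Simulate the ground truth of a screen
#'
#' Guide activities g are drawn from a Beta distribution on [0,1]; additive
#' penalties ddG(position, type) are drawn iid from Exponential(mean 1) per
#' spacer length and mapped to multiplicative penalties f = exp(-ddG) in
#' (0,1]. Deterministic given the config seed.
#'
#' @param design a [GuideTargetDesign-class].
#' @param config a [simConfig()].
#' @return A [ScreenTruth-class].
#' @export
simulateTruth <- function(design, config = simConfig()) {
  m <- designMembers(design)
  stopifnot(nrow(m) > 0L)
  set.seed(.subSeed(config$seed, 1L))
  guides <- unique(as.data.frame(m[, c("groupId", "spacerLength")]))
  guides <- guides[order(guides$groupId, guides$spacerLength), ]
  g <- stats::rbeta(nrow(guides), config$guideActivityShape[1L],
                    config$guideActivityShape[2L])
  lengths <- sort(unique(m$spacerLength))
  penalties <- lapply(lengths, function(L) {
    ddG <- matrix(stats::rexp(L * 12L, rate = 1), L, 12L,
                  dimnames = list(seq_len(L), MM_TYPES))
    exp(-ddG)
  })
  names(penalties) <- lengths
  new("ScreenTruth",
      guideActivity = DataFrame(groupId = guides$groupId,
                                spacerLength = guides$spacerLength, g = g),
      penalties = penalties,
      bulgePenalty = config$bulgePenalty)
}

#' True editing probability of every member
#'
#' Matched members edit at their guide activity g; mismatched members at
#' g * prod f(position, type) over their mismatches; bulged members at
#' g * bulge factor (proximal if any bulge position <= 18, else distal);
#' scrambled controls at 0.
#'
#' @param design a [GuideTargetDesign-class].
#' @param truth a [ScreenTruth-class].
#' @return Numeric vector of editing probabilities, one per member, named by
#'   member id.
#' @export
memberEditProb <- function(design, truth) {
  m <- designMembers(design)
  ga <- truth@guideActivity
  key <- paste(m$groupId, m$spacerLength)
  g <- ga$g[match(key, paste(ga$groupId, ga$spacerLength))]
  p <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    cat_i <- m$category[i]
    if (cat_i == "scrambled") {
      p[i] <- 0
    } else if (cat_i %in% c("insertion", "deletion")) {
      pos <- as.integer(strsplit(m$positions[i], ",")[[1]])
      cls <- if (length(pos) && min(pos) <= 18L) "proximal" else "distal"
      p[i] <- g[i] * truth@bulgePenalty[[cls]]
    } else {
      f <- penaltyMatrix(truth@penalties[[as.character(m$spacerLength[i])]])
      d <- mismatchDescriptors(m$spacer[i], m$target[i])
      p[i] <- g[i] * prod(f[cbind(d$position, d$typeIndex)])
    }
  }
  names(p) <- m$memberId
  p
}

#' Simulate lentiviral integrations with synthesis errors
#'
#' Per member, an integration count is drawn and each integration is tagged
#' with a distinct random 8-nt rBC (within-member collisions are redrawn and
#' counted in `attr(simLog, "rbcRedraws")`). Synthesis substitutions hit each
#' base of the variable region (spacer + target) independently; with
#' probability `synthesisIndelRate` a single 1-bp indel is placed uniformly in
#' the variable region. The truth log records the synthesized sequences, the
#' error accounting, an `errorFree` flag (no substitutions and no indel), and
#' the latent editing quantile + indel operation reused by every timepoint so
#' that edits nest across days.
#'
#' @param design a [GuideTargetDesign-class].
#' @param config a [simConfig()].
#' @return A [ScreenSim-class].
#' @export
simulateIntegrations <- function(design, config = simConfig()) {
  m <- designMembers(design)
  stopifnot(nrow(m) > 0L)
  set.seed(.subSeed(config$seed, 2L))
  nInt <- switch(config$integrationDist,
                 poisson = stats::rpois(nrow(m), config$integrationsPerMember),
                 constant = rep(as.integer(config$integrationsPerMember),
                                nrow(m)))
  memberIdx <- rep(seq_len(nrow(m)), nInt)
  n <- length(memberIdx)

  # distinct rBC per integration within a member
  rbcLen <- designLayout(design)@rbcLength
  redraws <- 0L
  rbc <- .randomDna(n, rbcLen)
  repeat {
    dup <- duplicated(paste(memberIdx, rbc))
    if (!any(dup)) break
    redraws <- redraws + sum(dup)
    rbc[dup] <- .randomDna(sum(dup), rbcLen)
  }

  spacer <- m$spacer[memberIdx]
  target <- m$target[memberIdx]
  varLen <- nchar(spacer) + nchar(target)

  # synthesis substitutions on the concatenated variable region
  varSeq <- paste0(spacer, target)
  nSub <- stats::rbinom(n, varLen, config$synthesisErrorRate)
  varSeq <- .applyCountedSubs(varSeq, nSub)

  # at most one synthesis indel per oligo, uniform over the variable region
  hasIndel <- stats::runif(n) < config$synthesisIndelRate
  indelAt <- ifelse(hasIndel, 1L + floor(stats::runif(n) * varLen), NA_integer_)
  indelIns <- stats::runif(n) < 0.5
  insBase <- sample(DNA_ALPHABET, n, replace = TRUE)
  for (i in which(hasIndel)) {
    s <- varSeq[i]
    at <- indelAt[i]
    varSeq[i] <- if (indelIns[i])
      paste0(substr(s, 1L, at - 1L), insBase[i], substr(s, at, nchar(s)))
    else paste0(substr(s, 1L, at - 1L), substr(s, at + 1L, nchar(s)))
  }

  spLen <- nchar(m$spacer)[memberIdx]
  spLenObs <- spLen + ifelse(hasIndel & indelAt <= spLen,
                             ifelse(indelIns, 1L, -1L), 0L)
  spacerObs <- substr(varSeq, 1L, spLenObs)
  targetObs <- substr(varSeq, spLenObs + 1L, nchar(varSeq))

  errorFree <- nSub == 0L & !hasIndel

  # latent editing quantile: integration is edited at day d iff
  # editU < editProb * saturation(d), so edits nest across timepoints
  editU <- stats::runif(n)
  delSize <- pmin(1L + stats::rgeom(n, 0.3), 10L)
  editIns <- stats::runif(n) < 0.25
  editInsSeq <- .randomDna(n, 2L)
  editInsLen <- sample(1:2, n, replace = TRUE)

  log <- DataFrame(
    memberId = m$memberId[memberIdx],
    rbc = rbc,
    spacerObs = spacerObs,
    targetObs = targetObs,
    nSynthSub = nSub,
    synthIndel = hasIndel,
    errorFree = errorFree,
    editU = editU,
    editDelSize = delSize,
    editIsIns = editIns,
    editInsSeq = substr(editInsSeq, 1L, editInsLen))
  attr(log, "rbcRedraws") <- redraws
  new("ScreenSim", design = design, simLog = log, config = unclass(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# substitutions with a known per-string count (positions uniform, base != original)
.applyCountedSubs <- function(x, k) {
  hit <- which(k > 0L)
  for (i in hit) {
    chars <- strsplit(x[i], "")[[1]]
    pos <- sample.int(length(chars), min(k[i], length(chars)))
    for (p in pos) chars[p] <- sample(setdiff(DNA_ALPHABET, chars[p]), 1L)
    x[i] <- paste(chars, collapse = "")
  }
  x
}

# apply the integration's recorded cut-site indel to its synthesized target
.applyEditIndel <- function(target, delSize, isIns, insSeq, cutOffset) {
  L <- nchar(target)
  cut <- L - cutOffset              # boundary after this base (5' of PAM)
  if (isIns) {
    paste0(substr(target, 1L, cut), insSeq, substr(target, cut + 1L, L))
  } else {
    d <- min(delSize, L)
    from <- max(1L, cut - floor((d - 1L) / 2))
    to <- min(L, from + d - 1L)
    paste0(substr(target, 1L, from - 1L), substr(target, to + 1L, L))
  }
}

#' Simulate paired-end reads for a timepoint
#'
#' Day 0 reads reflect the synthesized cassettes unedited. For later days each
#' integration is edited with probability `editProb * saturation(day)`
#' (capped at 1), where `editProb = g * prod f` from the ground truth; edited
#' cassettes carry an indel at the cut site (3 bp 5' of the PAM by default:
#' geometric deletion sizes or 1-2 nt insertions). Read 1 runs from the
#' upstream constant through spacer, scaffold and rBC; read 2 is the reverse
#' complement of the cassette 3' end and covers the Hamming barcode, PAM and
#' target. Sequencing substitutions are injected at the configured rate.
#' Identical inputs give byte-identical reads.
#'
#' @param sim a [ScreenSim-class] from [simulateIntegrations()].
#' @param truth a [ScreenTruth-class] from [simulateTruth()].
#' @param day a timepoint label present in `config$timepoints`.
#' @param outPrefix optional path prefix; when given, gzipped FASTQ files
#'   `<prefix>_R1.fastq.gz` / `<prefix>_R2.fastq.gz` are written.
#' @return List with `read1`, `read2` ([Biostrings::DNAStringSet], names
#'   `m<member>:<rBC>:<day>:<i>`), and `info` (DataFrame with per-read
#'   `memberId`, `rbc`, `edited`).
#' @export
simulateReads <- function(sim, truth, day, outPrefix = NULL) {
  config <- sim@config
  if (!day %in% config$timepoints)
    stop("day ", day, " not among configured timepoints")
  lay <- designLayout(sim@design)
  m <- designMembers(sim@design)
  log <- sim@simLog
  dayIdx <- match(day, config$timepoints)
  set.seed(.subSeed(config$seed, 100L + dayIdx))

  sat <- config$saturation[[as.character(day)]]
  pEdit <- memberEditProb(sim@design, truth)
  p <- pmin(1, pEdit[match(log$memberId, m$memberId)] * sat)
  edited <- log$editU < p

  target <- log$targetObs
  if (any(edited)) {
    idx <- which(edited)
    target[idx] <- mapply(.applyEditIndel, target[idx],
                          log$editDelSize[idx], log$editIsIns[idx],
                          log$editInsSeq[idx],
                          MoreArgs = list(cutOffset = lay@cutOffset),
                          USE.NAMES = FALSE)
  }

  mi <- match(log$memberId, m$memberId)
  bc <- m$barcode[mi]
  # PAM-distal pad is fixed at synthesis from the designed target length;
  # synthesis and editing indels change only the target portion
  pad <- substring(lay@targetPad, 1L, lay@targetWindow - nchar(m$target[mi]))
  cassette <- paste0(lay@upstream, log$spacerObs, lay@scaffold, log$rbc,
                     lay@mid, pad, target, lay@pam, lay@linker, bc,
                     lay@downstream)

  nReads <- switch(config$readsDist,
                   constant = rep(as.integer(config$readsPerRbc), length(cassette)),
                   poisson = stats::rpois(length(cassette), config$readsPerRbc))
  intIdx <- rep(seq_along(cassette), nReads)
  cas <- cassette[intIdx]
  w <- nchar(cas)
  rl <- pmin(config$readLength, w)
  r1 <- substr(cas, 1L, rl)
  r2 <- .revcomp(substr(cas, w - rl + 1L, w))
  r1 <- .mutateBases(r1, config$sequencingErrorRate)
  r2 <- .mutateBases(r2, config$sequencingErrorRate)

  ids <- paste0("m", log$memberId[intIdx], ":", log$rbc[intIdx], ":", day,
                ":", sequence(nReads))
  read1 <- Biostrings::DNAStringSet(r1); names(read1) <- ids
  read2 <- Biostrings::DNAStringSet(r2); names(read2) <- ids
  info <- DataFrame(memberId = log$memberId[intIdx], rbc = log$rbc[intIdx],
                    edited = edited[intIdx])
  out <- list(read1 = read1, read2 = read2, info = info)
  if (!is.null(outPrefix)) {
    writeReadPairs(out, outPrefix)
    out$files <- paste0(outPrefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  }
  out
}

#' Write simulated read pairs as gzipped FASTQ
#'
#' @param reads list with `read1` and `read2` from [simulateReads()].
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
writeReadPairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (k in 1:2) {
    x <- reads[[k]]
    q <- Biostrings::PhredQuality(strrep("I", Biostrings::width(x)))
    Biostrings::writeXStringSet(x, paths[k], format = "fastq", qualities = q,
                                compress = TRUE)
  }
  invisible(paths)
}

#' Expected Day-0 whitelist from the truth log
#'
#' The (member, rBC) cassettes that are error-free at synthesis and whose rBC
#' is not shared across members (cross-member rBC collisions are excluded,
#' mirroring the whitelist's conflict rule). With constant read depth at or
#' above the whitelist's read-support threshold and no sequencing errors this
#' is exactly the whitelist [buildWhitelist()] recovers.
#'
#' @param sim a [ScreenSim-class].
#' @return DataFrame with `memberId`, `rbc`.
#' @export
truthWhitelist <- function(sim) {
  log <- sim@simLog
  shared <- log$rbc %in% log$rbc[duplicated(log$rbc)]
  keep <- log$errorFree & !shared
  DataFrame(memberId = log$memberId[keep], rbc = log$rbc[keep])
}

#' Write the ground truth as JSON
#' @param truth a [ScreenTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  obj <- list(guideActivity = as.data.frame(truth@guideActivity),
              penalties = lapply(truth@penalties, function(x)
                as.data.frame(as.table(x))),
              bulgePenalty = as.list(truth@bulgePenalty))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the integration truth log as TSV
#' @param sim a [ScreenSim-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthLog <- function(sim, path) {
  utils::write.table(as.data.frame(sim@simLog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
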
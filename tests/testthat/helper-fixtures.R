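# Shared fixtures and independent oracles, all built in code at test time.

BASE_MAP <- c(A = 0L, C = 1L, G = 2L, T = 3L)
BASES <- names(BASE_MAP)

# independent nearest-codeword oracle: plain Hamming distances against a
# fully enumerated codebook (no syndromes, no shared code path)
oracleHamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

oracleDecode <- function(observed, codebook) {
  d <- vapply(codebook, oracleHamming, integer(1), a = observed)
  dmin <- min(d)
  hits <- which(d == dmin)
  if (dmin == 0L) list(status = "exact", codeword = codebook[hits])
  else if (dmin == 1L && length(hits) == 1L)
    list(status = "corrected", codeword = codebook[hits])
  else list(status = "fail", codeword = NA_character_)
}

# corrupt `seq` at 1-based position `pos` by digit delta 1..3 under BASE_MAP
corruptAt <- function(seq, pos, delta) {
  b <- substr(seq, pos, pos)
  nb <- BASES[(BASE_MAP[[b]] + delta) %% 4L + 1L]
  paste0(substr(seq, 1L, pos - 1L), nb, substr(seq, pos + 1L, nchar(seq)))
}

# small library design shared across quantification tests
smallDesign <- function(nGroups = 2L, lengths = 19:21,
                        mismatchGroups = 1L, seed = 11L) {
  groups <- generateSpacerGroups(nGroups, seed = seed)
  plan <- variantPlan(groups, "matched", lengths)
  if (mismatchGroups > 0L)
    plan <- rbind(plan, variantPlan(groups[seq_len(mismatchGroups), ,
                                           drop = FALSE],
                                    "single_mismatch", lengths))
  bcs <- sampleBarcodes(400L, seed = seed + 1L)
  assembleLibrary(groups, plan, bcs, seed = seed + 2L)
}

# ground truth with hand-set penalties: f = fill everywhere, except an
# optional named list position -> value applied across all 12 types
manualTruth <- function(design, g = 0.5, fill = 1, positionF = list()) {
  m <- designMembers(design)
  guides <- unique(as.data.frame(m[, c("groupId", "spacerLength")]))
  guides <- guides[order(guides$groupId, guides$spacerLength), ]
  penalties <- lapply(sort(unique(m$spacerLength)), function(L) {
    f <- matrix(fill, L, 12L, dimnames = list(seq_len(L), MM_TYPES))
    for (p in names(positionF)) f[as.integer(p), ] <- positionF[[p]]
    f
  })
  names(penalties) <- sort(unique(m$spacerLength))
  new("ScreenTruth",
      guideActivity = S4Vectors::DataFrame(groupId = guides$groupId,
                                           spacerLength = guides$spacerLength,
                                           g = rep_len(g, nrow(guides))),
      penalties = penalties,
      bulgePenalty = c(proximal = 0.05, distal = 0.9))
}

# model-level observation generator: known (g, f), Gaussian noise
modelObs <- function(f, nGuides, L, noiseSd = 0.1, nDouble = 200L,
                     gRange = c(0.2, 0.9), seed = 1L) {
  set.seed(seed)
  spacers <- replicate(nGuides, paste0(
    "G", paste(sample(BASES, L - 1L, replace = TRUE), collapse = "")))
  g <- stats::runif(nGuides, gRange[1], gRange[2])
  obs <- lapply(seq_len(nGuides), function(j) {
    v <- enumerateVariants(spacers[j], c("matched", "single_mismatch"))
    if (nDouble > 0L) {
      vd <- enumerateVariants(spacers[j], "double_mismatch")
      v <- rbind(v, vd[sample(nrow(vd), min(nDouble, nrow(vd))), ])
    }
    rate <- vapply(seq_len(nrow(v)), function(i)
      predictIndelRate(g[j], mismatchDescriptors(spacers[j], v$target[i]), f),
      numeric(1))
    if (noiseSd > 0)
      rate <- pmin(pmax(rate + stats::rnorm(length(rate), 0, noiseSd), 0), 1)
    data.frame(guide = sprintf("g%02d", j), rate = rate,
               spacer = spacers[j], target = v$target,
               stringsAsFactors = FALSE)
  })
  list(obs = do.call(rbind, obs), g = g,
       guides = sprintf("g%02d", seq_len(nGuides)), spacers = spacers)
}

# exact binomial 95% CI coverage check used by recovery tests
withinBinomCI <- function(x, n, p, level = 0.95) {
  mapply(function(xi, ni, pi) {
    if (ni == 0L) return(NA)
    ci <- stats::binom.test(xi, ni)$conf.int
    pi >= ci[1] && pi <= ci[2]
  }, x, n, p)
}
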
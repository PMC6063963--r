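# Nonlinear mismatch-penalty model: the observed indel rate of guide j on a
# target with mismatch set M is modeled as
#     I_{j,M} = g_j * exp(-sum_k ddG_k) + eps = g_j * prod_k f(pos_k, type_k) + eps
# with ddG >= 0 under an Exponential(mean beta) prior, eps ~ Normal(0, sd),
# and g_j in [0,1]. Each spacer length is fitted on its own disjoint data,
# giving a separate penalty matrix f_L.

#' The 12 RNA:DNA mismatch classes
#'
#' Ordered pairs of spacer (RNA) base and the target-strand DNA base it faces;
#' the Watson-Crick partner is excluded, leaving 3 classes per RNA base.
#' @export
MM_TYPES <- c("rA:dA", "rA:dC", "rA:dG",
              "rC:dA", "rC:dC", "rC:dT",
              "rG:dA", "rG:dG", "rG:dT",
              "rU:dC", "rU:dG", "rU:dT")

#' Featurize a spacer/target pair into mismatch descriptors
#'
#' Positions are numbered PAM-proximally (position 1 adjacent to the PAM).
#' The target is given on the protospacer strand; at each position where it
#' differs from the spacer, the descriptor records the spacer (RNA) base and
#' the complementary-strand DNA base it faces, which is never a Watson-Crick
#' partner of the RNA base. A perfect match yields zero descriptors. Bulged
#' (unequal-length) pairs are rejected: bulges are outside the model.
#'
#' @param spacer spacer sequence (DNA letters; U is written T).
#' @param target target sequence on the protospacer strand, same length.
#' @return data.frame with `position`, `rna`, `dna`, `type`, `typeIndex`,
#'   `cell` (the column-major linear index `(typeIndex-1)*L + position` into
#'   the L x 12 penalty matrix).
#' @examples
#' mismatchDescriptors("GACGT", "GACGT")       # empty: perfect match
#' mismatchDescriptors("GACGT", "GACGA")       # one descriptor, position 1
#' @export
mismatchDescriptors <- function(spacer, target) {
  if (nchar(spacer) != nchar(target))
    stop("spacer and target lengths differ (", nchar(spacer), " vs ",
         nchar(target), "); bulged pairs are outside the mismatch model")
  L <- nchar(spacer)
  s <- strsplit(spacer, "")[[1]]
  t <- strsplit(target, "")[[1]]
  idx <- which(s != t)
  if (length(idx) == 0L)
    return(data.frame(position = integer(0), rna = character(0),
                      dna = character(0), type = character(0),
                      typeIndex = integer(0), cell = integer(0)))
  pos <- L - idx + 1L                      # PAM-proximal numbering
  rna <- ifelse(s[idx] == "T", "U", s[idx])
  dna <- unname(.COMP[t[idx]])
  type <- paste0("r", rna, ":d", dna)
  typeIndex <- match(type, MM_TYPES)
  ord <- order(pos)
  data.frame(position = pos, rna = rna, dna = dna, type = type,
             typeIndex = typeIndex,
             cell = (typeIndex - 1L) * L + pos)[ord, , drop = FALSE]
}

#' Predicted indel rate under a penalty matrix
#'
#' `g * prod f(position, type)` over the descriptors; equals `g` for an empty
#' mismatch set. The additive and multiplicative parameterizations agree:
#' `g * exp(-sum ddG) == g * prod f`.
#'
#' @param g guide activity in [0,1].
#' @param descriptors data.frame from [mismatchDescriptors()] (or NULL/empty
#'   for a matched target).
#' @param penalty a [PenaltyFit-class] or a bare L x 12 matrix of f values.
#' @return Predicted indel rate.
#' @export
predictIndelRate <- function(g, descriptors, penalty) {
  f <- penaltyMatrix(penalty)
  if (is.null(descriptors) || nrow(descriptors) == 0L) return(g)
  if (any(descriptors$position > nrow(f)))
    stop("descriptor position exceeds the penalty matrix length")
  g * prod(f[cbind(descriptors$position, descriptors$typeIndex)])
}

#' Model configuration
#'
#' Defaults mirror the published sampler settings: Exponential prior with
#' mean 1 on the additive penalties, Gaussian error sd 0.1 (as estimated from
#' replicate comparisons), 8 chains of 1500 draws with the first 500 discarded
#' as warmup, and convergence declared when every R-hat is below 1.1. The
#' `map` mode replaces sampling with a deterministic penalized point estimate
#' and is the default for reproducible pipelines.
#'
#' @param priorMean mean of the Exponential prior on ddG (beta, default 1).
#' @param errorSd Gaussian error sd on observed rates (default 0.1).
#' @param nChains,nSamples,nWarmup MCMC settings (8, 1500, 500).
#' @param rhatThreshold convergence threshold on R-hat (1.1).
#' @param mode `"map"` or `"mcmc"`.
#' @param seed integer seed (fixes MCMC chains and map initialization).
#' @return Configuration list of class `modelConfig`.
#' @export
modelConfig <- function(priorMean = 1, errorSd = 0.1, nChains = 8L,
                        nSamples = 1500L, nWarmup = 500L,
                        rhatThreshold = 1.1, mode = c("map", "mcmc"),
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(priorMean > 0, errorSd > 0, nWarmup < nSamples, nChains >= 1L)
  structure(list(priorMean = priorMean, errorSd = errorSd,
                 nChains = as.integer(nChains),
                 nSamples = as.integer(nSamples),
                 nWarmup = as.integer(nWarmup),
                 rhatThreshold = rhatThreshold, mode = mode,
                 seed = as.integer(seed)),
            class = "modelConfig")
}

#' Extract model observations from screen output
#'
#' Joins rate records to the design and returns the fitting table for one
#' spacer length: raw indel rates (not off:on ratios; the guide activity g_j
#' absorbs on-target activity) of matched, single- and double-mismatch
#' members, excluding bulged and scrambled members and members flagged
#' excluded.
#'
#' @param records data.frame from [computeIndelRates()].
#' @param design a [GuideTargetDesign-class].
#' @param length spacer length to extract.
#' @return data.frame with `guide`, `rate`, `spacer`, `target`.
#' @export
indelObservations <- function(records, design, length) {
  mem <- designMembers(design)
  i <- match(records$memberId, mem$memberId)
  df <- data.frame(guide = paste0("g", mem$groupId[i], "_", mem$spacerLength[i]),
                   rate = records$indelRate,
                   spacer = mem$spacer[i], target = mem$target[i],
                   spacerLength = mem$spacerLength[i],
                   category = mem$category[i],
                   excluded = records$excluded,
                   stringsAsFactors = FALSE)
  df <- df[df$spacerLength == length & !df$excluded & !is.na(df$rate) &
             df$category %in% c("matched", "single_mismatch",
                                "double_mismatch", "double_transversion"), ]
  df[, c("guide", "rate", "spacer", "target")]
}

# normalize observations to guide index + cell list
.prepObs <- function(observations, L) {
  stopifnot(all(c("guide", "rate") %in% names(observations)))
  if (!is.null(observations$cells)) {
    cells <- observations$cells
    if (is.character(cells))
      cells <- lapply(strsplit(cells, ","), function(x)
        as.integer(x[nzchar(x)]))
  } else {
    stopifnot(all(nchar(observations$spacer) == L),
              all(nchar(observations$target) == L))
    cells <- lapply(seq_len(nrow(observations)), function(i)
      mismatchDescriptors(observations$spacer[i], observations$target[i])$cell)
  }
  guide <- factor(observations$guide)
  nCell <- L * 12L
  stopifnot(all(unlist(cells) >= 1L), all(unlist(cells) <= nCell))
  list(rate = observations$rate, guide = guide, cells = cells, nCell = nCell)
}

#' Fit the mismatch-penalty model for one spacer length
#'
#' `map` mode minimizes the exact negative log posterior (Gaussian likelihood
#' plus Exponential prior, g constrained to [0,1], ddG >= 0) with L-BFGS-B and
#' an analytic gradient; it is deterministic. `mcmc` mode samples the same
#' posterior by Gibbs/Metropolis MCMC (JAGS) with the configured chains and
#' warmup, reporting per-parameter R-hat. Cells with no observations are
#' prior-dominated (visible in `fit@nObs`); guides without a matched
#' observation are fitted but weakly identified (a warning lists them).
#'
#' @param observations data.frame with columns `guide`, `rate` and either
#'   `spacer` + `target` (featurized internally) or `cells` (list column or
#'   comma-separated string of penalty-cell indices). See
#'   [indelObservations()].
#' @param length spacer length L; all observations must be from guides of
#'   this length.
#' @param config a [modelConfig()].
#' @return A [PenaltyFit-class].
#' @export
fitPenaltyModel <- function(observations, length, config = modelConfig()) {
  L <- as.integer(length)
  p <- .prepObs(observations, L)
  nMm <- lengths(p$cells)
  hasMatched <- tapply(nMm == 0L, p$guide, any)
  if (!all(hasMatched))
    warning("guide(s) without a matched observation are weakly identified: ",
            paste(names(hasMatched)[!hasMatched], collapse = ", "))
  nObs <- matrix(0L, L, 12L, dimnames = list(seq_len(L), MM_TYPES))
  tab <- table(unlist(p$cells))
  nObs[as.integer(names(tab))] <- as.integer(tab)

  fit <- if (config$mode == "map") .fitMap(p, L, config)
  else .fitMcmc(p, L, config)

  dimnames(fit$ddG) <- dimnames(nObs)
  dimnames(fit$f) <- dimnames(nObs)
  new("PenaltyFit", spacerLength = L, ddG = fit$ddG, f = fit$f,
      fLower = fit$fLower, fUpper = fit$fUpper,
      guideActivity = fit$guideActivity, nObs = nObs,
      rhat = fit$rhat, converged = fit$converged, mode = config$mode,
      config = unclass(config))
}

.fitMap <- function(p, L, config) {
  nCell <- p$nCell
  J <- nlevels(p$guide)
  N <- length(p$rate)
  gi <- as.integer(p$guide)
  obsIdx <- rep(seq_len(N), lengths(p$cells))
  X <- Matrix::sparseMatrix(i = obsIdx, j = unlist(p$cells),
                            x = 1, dims = c(N, nCell))
  sd2 <- config$errorSd^2
  beta <- config$priorMean
  y <- p$rate

  negLogPost <- function(theta) {
    ddG <- theta[seq_len(nCell)]
    g <- theta[nCell + seq_len(J)]
    eta <- as.numeric(X %*% ddG)
    mu <- g[gi] * exp(-eta)
    sum((y - mu)^2) / (2 * sd2) + sum(ddG) / beta
  }
  gradient <- function(theta) {
    ddG <- theta[seq_len(nCell)]
    g <- theta[nCell + seq_len(J)]
    E <- exp(-as.numeric(X %*% ddG))
    mu <- g[gi] * E
    r <- y - mu
    gd <- as.numeric(Matrix::crossprod(X, r * mu)) / sd2 + 1 / beta
    gg <- -vapply(seq_len(J), function(j) sum(r[gi == j] * E[gi == j]),
                  numeric(1)) / sd2
    c(gd, gg)
  }

  matchedRate <- tapply(y[lengths(p$cells) == 0L],
                        p$guide[lengths(p$cells) == 0L], mean)
  matchedRate <- matchedRate[!is.na(matchedRate)]
  g0 <- rep(mean(y), J)
  g0[match(names(matchedRate), levels(p$guide))] <- matchedRate
  g0 <- pmin(pmax(g0, 0.02), 0.98)
  theta0 <- c(rep(0.2, nCell), g0)
  opt <- stats::optim(theta0, negLogPost, gradient, method = "L-BFGS-B",
                      lower = c(rep(0, nCell), rep(0, J)),
                      upper = c(rep(30, nCell), rep(1, J)),
                      control = list(maxit = 3000L, factr = 1e7))
  ddG <- matrix(opt$par[seq_len(nCell)], L, 12L)
  g <- opt$par[nCell + seq_len(J)]
  na <- matrix(NA_real_, L, 12L)
  list(ddG = ddG, f = exp(-ddG), fLower = na, fUpper = na,
       guideActivity = data.frame(guide = levels(p$guide), g = g,
                                  gLower = NA_real_, gUpper = NA_real_,
                                  stringsAsFactors = FALSE),
       rhat = NA_real_, converged = NA)
}

.jagsModelString <- "
model {
  for (i in 1:N) {
    mu[i] <- g[guide[i]] * exp(-(D[c1[i]] + D[c2[i]]))
    y[i] ~ dnorm(mu[i], tau)
  }
  for (c in 1:C) {
    ddG[c] ~ dexp(lambda)
    D[c] <- ddG[c]
  }
  D[C + 1] <- 0
  for (j in 1:J) {
    g[j] ~ dunif(0, 1)
  }
}
"

.fitMcmc <- function(p, L, config) {
  nCell <- p$nCell
  if (any(lengths(p$cells) > 2L))
    stop("mcmc mode supports up to two mismatches per observation")
  pad <- nCell + 1L
  c1 <- vapply(p$cells, function(x) if (length(x) >= 1L) x[1L] else pad,
               integer(1))
  c2 <- vapply(p$cells, function(x) if (length(x) >= 2L) x[2L] else pad,
               integer(1))
  J <- nlevels(p$guide)
  data <- list(N = length(p$rate), y = p$rate, guide = as.integer(p$guide),
               c1 = c1, c2 = c2, C = nCell, J = J,
               tau = 1 / config$errorSd^2, lambda = 1 / config$priorMean)
  inits <- lapply(seq_len(config$nChains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = .subSeed(config$seed, 7000L + k)))
  model <- rjags::jags.model(textConnection(.jagsModelString), data = data,
                             inits = inits, n.chains = config$nChains,
                             n.adapt = min(500L, config$nWarmup), quiet = TRUE)
  stats::update(model, config$nWarmup, progress.bar = "none")
  samples <- rjags::coda.samples(model, c("ddG", "g"),
                                 n.iter = config$nSamples - config$nWarmup,
                                 progress.bar = "none")
  rhat <- .computeRhat(samples)
  big <- as.matrix(do.call(rbind, samples))
  ddGcols <- grep("^ddG\\[", colnames(big))
  gcols <- grep("^g\\[", colnames(big))
  ddGidx <- as.integer(sub("^ddG\\[(\\d+)\\]$", "\\1", colnames(big)[ddGcols]))
  gidx <- as.integer(sub("^g\\[(\\d+)\\]$", "\\1", colnames(big)[gcols]))

  ddG <- matrix(NA_real_, L, 12L)
  fM <- matrix(NA_real_, L, 12L)
  fLo <- matrix(NA_real_, L, 12L)
  fHi <- matrix(NA_real_, L, 12L)
  for (k in seq_along(ddGcols)) {
    draws <- big[, ddGcols[k]]
    ddG[ddGidx[k]] <- mean(draws)
    fd <- exp(-draws)
    fM[ddGidx[k]] <- mean(fd)
    q <- stats::quantile(fd, c(0.025, 0.975), names = FALSE)
    fLo[ddGidx[k]] <- q[1L]
    fHi[ddGidx[k]] <- q[2L]
  }
  g <- numeric(J); gLo <- numeric(J); gHi <- numeric(J)
  for (k in seq_along(gcols)) {
    draws <- big[, gcols[k]]
    g[gidx[k]] <- mean(draws)
    q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    gLo[gidx[k]] <- q[1L]; gHi[gidx[k]] <- q[2L]
  }
  list(ddG = ddG, f = fM, fLower = fLo, fUpper = fHi,
       guideActivity = data.frame(guide = levels(p$guide), g = g,
                                  gLower = gLo, gUpper = gHi,
                                  stringsAsFactors = FALSE),
       rhat = rhat, converged = all(rhat < config$rhatThreshold, na.rm = TRUE))
}

# per-parameter potential scale reduction factor over an mcmc.list
.computeRhat <- function(samples) {
  if (coda::nchain(samples) < 2L)
    stop("R-hat requires at least two chains")
  gd <- coda::gelman.diag(samples, multivariate = FALSE, autoburnin = FALSE)
  structure(gd$psrf[, 1L], names = rownames(gd$psrf))
}

#' Check MCMC convergence of a fit
#'
#' TRUE iff the largest per-parameter R-hat is below the configured threshold.
#' For a map-mode fit the statistic is undefined and `NA` is returned with a
#' `"reason"` attribute (not `FALSE`). A fit sampled with a single chain is an
#' error: R-hat is undefined.
#'
#' @param fit a [PenaltyFit-class].
#' @param config optional [modelConfig()] overriding the fit's threshold.
#' @return Logical (or NA for map mode).
#' @export
checkConvergence <- function(fit, config = NULL) {
  if (fit@mode == "map") {
    out <- NA
    attr(out, "reason") <- "not applicable: map mode has no sampling chains"
    return(out)
  }
  if (!is.null(fit@config$nChains) && fit@config$nChains < 2L)
    stop("R-hat requires at least two chains")
  threshold <- if (!is.null(config)) config$rhatThreshold
  else fit@config$rhatThreshold
  max(fit@rhat, na.rm = TRUE) < threshold
}

#' Specificity score of candidate off-target sites
#'
#' The product of multiplicative penalties over the featurized mismatches of
#' each candidate: 1 for a perfect match, and monotone non-increasing in the
#' mismatch set (adding a mismatch never raises the score). Candidates whose
#' length differs from the spacer (bulged sites) get `NA` with the reason
#' recorded in `attr(, "reason")`.
#'
#' @param spacer spacer sequence.
#' @param candidates character vector of candidate protospacer-strand sites.
#' @param penalty a [PenaltyFit-class] or bare f matrix.
#' @return Numeric scores in [0,1] (NA for unscorable candidates).
#' @export
specificityScore <- function(spacer, candidates, penalty) {
  f <- penaltyMatrix(penalty)
  reason <- rep(NA_character_, length(candidates))
  score <- vapply(seq_along(candidates), function(i) {
    if (nchar(candidates[i]) != nchar(spacer)) {
      reason[i] <<- "length mismatch (bulged site)"
      return(NA_real_)
    }
    d <- mismatchDescriptors(spacer, candidates[i])
    if (nrow(d) == 0L) return(1)
    prod(f[cbind(d$position, d$typeIndex)])
  }, numeric(1))
  if (any(!is.na(reason))) attr(score, "reason") <- reason
  score
}

#' Rank candidate off-target sites
#'
#' Orders candidates by descending specificity score, breaking ties by fewer
#' mismatches and then lexicographically by site for determinism. When an
#' `activities` column of observed activities is supplied, the Spearman rank
#' correlation between scores and activities is attached as
#' `attr(, "spearman")`.
#'
#' @param spacer spacer sequence.
#' @param candidates character vector of candidate sites.
#' @param penalty a [PenaltyFit-class] or bare f matrix.
#' @param activities optional numeric vector of observed activities parallel
#'   to `candidates`.
#' @return data.frame with `site`, `score`, `nMismatch`, ordered.
#' @export
rankOffTargets <- function(spacer, candidates, penalty, activities = NULL) {
  if (length(candidates) == 0L)
    return(data.frame(site = character(0), score = numeric(0),
                      nMismatch = integer(0)))
  score <- specificityScore(spacer, candidates, penalty)
  nMm <- vapply(candidates, function(s) {
    if (nchar(s) != nchar(spacer)) NA_integer_
    else nrow(mismatchDescriptors(spacer, s))
  }, integer(1), USE.NAMES = FALSE)
  out <- data.frame(site = candidates, score = score, nMismatch = nMm,
                    stringsAsFactors = FALSE)
  if (!is.null(activities)) out$activity <- activities
  out <- out[order(-out$score, out$nMismatch, out$site, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(activities)) {
    ok <- !is.na(out$score) & !is.na(out$activity)
    attr(out, "spearman") <- if (sum(ok) >= 3L)
      stats::cor(out$score[ok], out$activity[ok], method = "spearman")
    else NA_real_
  }
  out
}

#' Read and write penalty matrices
#'
#' Long-format TSV: one row per (length, position, type) cell with the RNA and
#' DNA bases, f, ddG, interval bounds and observation count.
#'
#' @param fit a [PenaltyFit-class].
#' @param path file path.
#' @return `writePenaltyMatrix()` returns `path` invisibly;
#'   `readPenaltyMatrix()` returns the f matrix (with `ddG` attribute).
#' @export
writePenaltyMatrix <- function(fit, path) {
  L <- fit@spacerLength
  grid <- expand.grid(position = seq_len(L), typeIndex = seq_len(12L),
                      KEEP.OUT.ATTRS = FALSE)
  type <- MM_TYPES[grid$typeIndex]
  df <- data.frame(length = L, position = grid$position, type = type,
                   rna = substr(type, 2L, 2L), dna = substr(type, 5L, 5L),
                   f = fit@f[cbind(grid$position, grid$typeIndex)],
                   ddG = fit@ddG[cbind(grid$position, grid$typeIndex)],
                   fLower = fit@fLower[cbind(grid$position, grid$typeIndex)],
                   fUpper = fit@fUpper[cbind(grid$position, grid$typeIndex)],
                   nObs = fit@nObs[cbind(grid$position, grid$typeIndex)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePenaltyMatrix
#' @export
writeGuideActivity <- function(fit, path) {
  utils::write.table(fit@guideActivity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePenaltyMatrix
#' @export
writeFitDiagnostics <- function(fit, path) {
  obj <- list(mode = fit@mode, spacerLength = fit@spacerLength,
              converged = fit@converged,
              rhatMax = if (all(is.na(fit@rhat))) NA else max(fit@rhat),
              rhat = if (all(is.na(fit@rhat))) NULL else as.list(fit@rhat),
              priorDominatedCells = sum(fit@nObs == 0),
              nObservedCells = sum(fit@nObs > 0))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writePenaltyMatrix
#' @export
readPenaltyMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  L <- max(df$position)
  f <- matrix(NA_real_, L, 12L, dimnames = list(seq_len(L), MM_TYPES))
  ddG <- f
  ti <- match(df$type, MM_TYPES)
  f[cbind(df$position, ti)] <- df$f
  ddG[cbind(df$position, ti)] <- df$ddG
  attr(f, "ddG") <- ddG
  f
}
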
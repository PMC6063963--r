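# Quantification of paired-end cassette reads: read parsing against the
# cassette layout, Day-0 rBC whitelisting, indel calling with a cut-site
# window, per-member indel rates, off:on ratios, and summary aggregations.

# smallest match start >= minStart per subject, NA when none
.firstMatchStart <- function(mindex, minStart) {
  cnt <- S4Vectors::elementNROWS(mindex)
  out <- rep(NA_integer_, length(cnt))
  if (sum(cnt) == 0L) return(out)
  starts <- IRanges::start(unlist(mindex, use.names = FALSE))
  grp <- rep(seq_along(cnt), cnt)
  keep <- starts >= minStart
  if (!any(keep)) return(out)
  s <- starts[keep]
  g <- grp[keep]
  o <- order(g, s)
  first <- !duplicated(g[o])
  out[g[o][first]] <- s[o][first]
  out
}

#' Parse paired cassette reads into observations
#'
#' Read 2 is the reverse complement of the cassette 3' end, so the Hamming
#' barcode, linker and PAM sit at fixed offsets from its start regardless of
#' indels in the target; the constant `mid` anchor is located by pattern
#' matching (allowing `maxMismatch` substitutions) to delimit the target
#' region. Read 1 yields the spacer region (between the upstream and scaffold
#' anchors) and the rBC (immediately after the scaffold). Barcodes are decoded
#' with [decodeBarcode()] (exact or single-substitution corrected). Reads
#' whose anchors cannot be located are returned with `anchorOk = FALSE` and
#' counted, never silently dropped.
#'
#' @param read1,read2 [Biostrings::DNAStringSet] objects or FASTQ file paths
#'   (gzipped or plain).
#' @param design a [GuideTargetDesign-class].
#' @param spec the [BarcodeSpec-class] of the design's barcodes.
#' @param maxMismatch substitutions tolerated per anchor (default 1).
#' @return DataFrame, one row per read pair: `memberId` (NA when the barcode
#'   fails to decode or is not in the design), `rbc`, `spacerRegion`,
#'   `targetRegion`, `anchorOk`, `hammingStatus`.
#' @export
parseReadPairs <- function(read1, read2, design, spec = barcodeSpec(),
                           maxMismatch = 1L) {
  if (is.character(read1))
    read1 <- Biostrings::readDNAStringSet(read1, format = "fastq")
  if (is.character(read2))
    read2 <- Biostrings::readDNAStringSet(read2, format = "fastq")
  stopifnot(length(read1) == length(read2))
  lay <- designLayout(design)
  n <- length(read1)
  r1 <- as.character(read1)
  r2 <- as.character(read2)

  upLen <- nchar(lay@upstream)
  scafLen <- nchar(lay@scaffold)
  downLen <- nchar(lay@downstream)
  bcLen <- nchar(designMembers(design)$barcode[1L])
  linkLen <- nchar(lay@linker)
  pamLen <- nchar(lay@pam)
  rbcLen <- lay@rbcLength

  rcDown <- .revcomp(lay@downstream)
  rcLinker <- .revcomp(lay@linker)
  rcPam <- .revcomp(lay@pam)
  rcMid <- .revcomp(lay@mid)

  wide1 <- nchar(r1) >= upLen + 19L + scafLen + rbcLen
  wide2 <- nchar(r2) >= downLen + bcLen + linkLen + pamLen + 10L

  # ---- read 2: fixed-offset fields -------------------------------------
  bcSeq <- rep(NA_character_, n)
  anchor2 <- rep(FALSE, n)
  targetRegion <- rep(NA_character_, n)
  i2 <- which(wide2)
  if (length(i2)) {
    downOk <- .mismatchCount(substr(r2[i2], 1L, downLen), rcDown) <= maxMismatch
    linkOk <- .mismatchCount(
      substr(r2[i2], downLen + bcLen + 1L, downLen + bcLen + linkLen),
      rcLinker) <= maxMismatch
    pamOk <- .mismatchCount(
      substr(r2[i2], downLen + bcLen + linkLen + 1L,
             downLen + bcLen + linkLen + pamLen), rcPam) <= maxMismatch
    bcSeq[i2] <- .revcomp(substr(r2[i2], downLen + 1L, downLen + bcLen))

    # locate the rc(mid) anchor delimiting the target region
    tgtStart <- downLen + bcLen + linkLen + pamLen + 1L
    mids <- Biostrings::vmatchPattern(rcMid, Biostrings::DNAStringSet(r2[i2]),
                                      max.mismatch = maxMismatch)
    midStart <- .firstMatchStart(mids, tgtStart)
    midOk <- !is.na(midStart)
    ok <- downOk & linkOk & pamOk & midOk
    anchor2[i2] <- ok
    good <- which(ok)
    if (length(good))
      targetRegion[i2[good]] <- .revcomp(
        substr(r2[i2[good]], tgtStart, midStart[good] - 1L))
  }

  # ---- read 1: spacer region and rBC -----------------------------------
  anchor1 <- rep(FALSE, n)
  spacerRegion <- rep(NA_character_, n)
  rbc <- rep(NA_character_, n)
  i1 <- which(wide1)
  if (length(i1)) {
    upOk <- .mismatchCount(substr(r1[i1], 1L, upLen),
                           lay@upstream) <= maxMismatch
    scafs <- Biostrings::vmatchPattern(lay@scaffold,
                                       Biostrings::DNAStringSet(r1[i1]),
                                       max.mismatch = maxMismatch)
    scafStart <- .firstMatchStart(scafs, upLen + 1L)
    ok <- upOk & !is.na(scafStart) &
      (scafStart + scafLen + rbcLen - 1L) <= nchar(r1[i1])
    anchor1[i1] <- ok
    good <- which(ok)
    if (length(good)) {
      spacerRegion[i1[good]] <- substr(r1[i1[good]], upLen + 1L,
                                       scafStart[good] - 1L)
      rbc[i1[good]] <- substr(r1[i1[good]], scafStart[good] + scafLen,
                              scafStart[good] + scafLen + rbcLen - 1L)
    }
  }

  anchorOk <- anchor1 & anchor2

  # ---- barcode decode --------------------------------------------------
  hammingStatus <- rep("fail", n)
  memberId <- rep(NA_integer_, n)
  dec <- which(!is.na(bcSeq))
  if (length(dec)) {
    res <- decodeBarcode(bcSeq[dec], spec)
    hammingStatus[dec] <- res$status
    # map decoded codeword back to a designed member
    mem <- designMembers(design)
    okDec <- res$status != "fail"
    cw <- rep(NA_character_, length(dec))
    cw[okDec] <- encodeBarcode(res$dataWord[okDec], spec)
    mid2 <- mem$memberId[match(cw, mem$barcode)]
    hammingStatus[dec][okDec & is.na(mid2)] <- "fail"
    memberId[dec] <- mid2
  }
  hammingStatus[is.na(memberId)] <- "fail"

  DataFrame(memberId = memberId, rbc = rbc, spacerRegion = spacerRegion,
            targetRegion = targetRegion, anchorOk = anchorOk,
            hammingStatus = hammingStatus)
}

#' Build the Day-0 whitelist of error-free cassettes
#'
#' A (member, rBC) pair is admitted iff every supporting Day-0 read has intact
#' anchors and a spacer region and target region exactly matching the designed
#' sequences, and the pair is supported by at least `minReadsPerRbc` reads.
#' An rBC observed under two different Hamming barcodes is rejected outright.
#'
#' @param observations DataFrame from [parseReadPairs()] on the Day-0 sample.
#' @param design a [GuideTargetDesign-class].
#' @param minReadsPerRbc minimum read support per pair (default 2).
#' @return DataFrame with `memberId`, `rbc`, `day0Reads`.
#' @export
buildWhitelist <- function(observations, design, minReadsPerRbc = 2L) {
  if (nrow(observations) == 0L) {
    warning("no Day-0 observations; whitelist is empty")
    return(DataFrame(memberId = integer(0), rbc = character(0),
                     day0Reads = integer(0)))
  }
  obs <- observations[!is.na(observations$memberId) &
                        !is.na(observations$rbc), , drop = FALSE]
  mem <- designMembers(design)
  i <- match(obs$memberId, mem$memberId)
  expTarget <- .paddedTarget(designLayout(design), mem$target)
  clean <- obs$anchorOk &
    !is.na(obs$spacerRegion) & obs$spacerRegion == mem$spacer[i] &
    !is.na(obs$targetRegion) & obs$targetRegion == expTarget[i]

  key <- paste(obs$memberId, obs$rbc, sep = "\r")
  allClean <- tapply(clean, key, all)
  nReads <- tapply(clean, key, length)
  conflicted <- tapply(obs$memberId, obs$rbc, function(x) length(unique(x)) > 1L)

  keys <- names(allClean)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  memberId <- as.integer(vapply(parts, `[`, "", 1L))
  rbc <- vapply(parts, `[`, "", 2L)
  keep <- as.logical(allClean) & as.integer(nReads) >= minReadsPerRbc &
    !as.logical(conflicted[rbc])
  ord <- order(memberId[keep], rbc[keep])
  DataFrame(memberId = memberId[keep][ord], rbc = rbc[keep][ord],
            day0Reads = as.integer(nReads)[keep][ord])
}

#' Classify a target region against its designed sequence
#'
#' `intact` iff the observed region equals the expected sequence exactly;
#' `discard` for same-length regions with substitutions (substitutions cannot
#' be nuclease products and indicate synthesis/PCR/sequencing error) and for
#' regions whose indels fall entirely outside the cut-site window; `indel`
#' when a global gapped alignment places at least one insertion or deletion
#' overlapping the window around the cut site (`cutOffset` bp 5' of the PAM,
#' +/- `window` bp). Deterministic; ties resolve toward `discard`.
#'
#' @param observed character vector of observed target regions.
#' @param expected designed target sequence(s), recycled along `observed`.
#' @param cutOffset cut-site offset in bp 5' of the PAM (default 3).
#' @param window half-width of the indel window in bp (default 8).
#' @return Character vector in `c("intact", "indel", "discard")`.
#' @export
callIndel <- function(observed, expected, cutOffset = 3L, window = 8L) {
  n <- max(length(observed), length(expected))
  observed <- rep_len(observed, n)
  expected <- rep_len(expected, n)
  out <- rep("discard", n)
  out[observed == expected] <- "intact"
  sameLen <- nchar(observed) == nchar(expected) & observed != expected
  out[sameLen] <- "discard"
  todo <- which(nchar(observed) != nchar(expected))
  if (!length(todo)) return(out)

  key <- paste(observed[todo], expected[todo], sep = "\r")
  uniq <- !duplicated(key)
  verdict <- vapply(todo[uniq], function(i) {
    .indelVerdict(observed[i], expected[i], cutOffset, window)
  }, character(1))
  names(verdict) <- key[uniq]
  out[todo] <- verdict[key]
  out
}

# single-pair gapped comparison; expected-sequence coordinates
.indelVerdict <- function(observed, expected, cutOffset, window) {
  if (nchar(observed) == 0L) return("discard")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(observed), Biostrings::DNAString(expected),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 4, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cut <- nchar(expected) - cutOffset            # boundary after this base
  lo <- cut - window
  hi <- cut + window
  expPos <- cumsum(sub != "-")                  # expected coordinate per column
  hitWindow <- FALSE
  anyIndel <- FALSE
  for (k in seq_along(pat)) {
    if (sub[k] == "-") {                        # insertion between expPos and +1
      anyIndel <- TRUE
      b <- if (k == 1L) 0L else expPos[k]
      if (b >= lo && b <= hi) hitWindow <- TRUE
    } else if (pat[k] == "-") {                 # deletion of expected base expPos[k]
      anyIndel <- TRUE
      if (expPos[k] >= lo + 1L && expPos[k] <= hi) hitWindow <- TRUE
    }
  }
  if (anyIndel && hitWindow) "indel" else "discard"
}

#' Per-member indel rates from whitelisted reads
#'
#' Only reads whose (member, rBC) pair is whitelisted contribute (pass
#' `whitelist = NULL` explicitly for unfiltered quantification). Each
#' contributing read's target region is classified by [callIndel()];
#' `indelRate = nIndel / (nReads - nDiscarded)`. Members observed with fewer
#' than `minRbc` whitelisted rBCs are flagged `excluded`; members never
#' observed get `nReads = 0` and an absent rate, so dropouts are reported,
#' never omitted.
#'
#' @param observations DataFrame from [parseReadPairs()] on a post-nuclease
#'   sample.
#' @param design a [GuideTargetDesign-class].
#' @param whitelist DataFrame from [buildWhitelist()], or NULL for unfiltered
#'   quantification.
#' @param minRbc minimum whitelisted rBCs per member (default 20).
#' @param window indel window half-width passed to [callIndel()].
#' @return data.frame with one row per designed member: `memberId`, `nRbc`,
#'   `nReads`, `nIntact`, `nIndel`, `nDiscarded`, `indelRate`, `excluded`.
#' @export
computeIndelRates <- function(observations, design, whitelist, minRbc = 20L,
                              window = 8L) {
  mem <- designMembers(design)
  lay <- designLayout(design)
  obs <- observations[!is.na(observations$memberId) & observations$anchorOk &
                        !is.na(observations$targetRegion), , drop = FALSE]
  if (!is.null(whitelist)) {
    wkey <- paste(whitelist$memberId, whitelist$rbc)
    obs <- obs[paste(obs$memberId, obs$rbc) %in% wkey, , drop = FALSE]
  }
  expTarget <- .paddedTarget(lay, mem$target)[match(obs$memberId,
                                                    mem$memberId)]
  call <- callIndel(obs$targetRegion, expTarget, cutOffset = lay@cutOffset,
                    window = window)

  res <- data.frame(memberId = mem$memberId, nRbc = 0L, nReads = 0L,
                    nIntact = 0L, nIndel = 0L, nDiscarded = 0L,
                    indelRate = NA_real_, stringsAsFactors = FALSE)
  if (nrow(obs)) {
    byMember <- function(x, f) {
      v <- tapply(x, obs$memberId, f)
      out <- rep(0L, nrow(mem))
      i <- match(as.integer(names(v)), mem$memberId)
      out[i] <- as.integer(v)
      out
    }
    res$nReads <- byMember(call, length)
    res$nIntact <- byMember(call == "intact", sum)
    res$nIndel <- byMember(call == "indel", sum)
    res$nDiscarded <- byMember(call == "discard", sum)
    nrb <- tapply(obs$rbc, obs$memberId, function(x) length(unique(x)))
    res$nRbc[match(as.integer(names(nrb)), mem$memberId)] <- as.integer(nrb)
  }
  denom <- res$nReads - res$nDiscarded
  res$indelRate <- ifelse(denom > 0, res$nIndel / denom, NA_real_)
  res$excluded <- res$nRbc < minRbc
  res
}

#' Off:on-target ratios
#'
#' Each member's indel rate is normalized by the indel rate of the perfectly
#' matched member of the same group and spacer length. Ratios are computed
#' only for group-lengths whose matched (on-target) rate exceeds
#' `minOnTarget` (2% by default) and whose matched member is not excluded;
#' matched members themselves get ratio 1. A missing matched member leaves
#' the ratio absent with a diagnostic message.
#'
#' @param records data.frame from [computeIndelRates()].
#' @param design a [GuideTargetDesign-class].
#' @param minOnTarget on-target activity threshold (default 0.02).
#' @return `records` with `offOnRatio` and `onTargetRate` columns added.
#' @export
offOnRatios <- function(records, design, minOnTarget = 0.02) {
  mem <- designMembers(design)
  i <- match(records$memberId, mem$memberId)
  records$groupId <- mem$groupId[i]
  records$spacerLength <- mem$spacerLength[i]
  records$category <- mem$category[i]

  matched <- records[records$category == "matched", , drop = FALSE]
  key <- paste(records$groupId, records$spacerLength)
  mkey <- paste(matched$groupId, matched$spacerLength)
  missing <- setdiff(unique(key), mkey)
  if (length(missing))
    message("no matched member for group-length(s): ",
            paste(missing, collapse = "; "))
  j <- match(key, mkey)
  onRate <- ifelse(matched$excluded[j], NA_real_, matched$indelRate[j])
  ratio <- ifelse(!is.na(onRate) & onRate > minOnTarget,
                  records$indelRate / onRate, NA_real_)
  ratio[records$category == "matched" & !is.na(onRate) &
          onRate > minOnTarget] <- 1
  ratio[records$excluded] <- NA_real_
  records$onTargetRate <- onRate
  records$offOnRatio <- ratio
  records
}

#' Aggregate mismatch tolerance
#'
#' Summarizes off:on ratios (or, for `by = "length"` / `"category"`, indel
#' rates) across the library: mean with a 95% t confidence interval per
#' stratum. `by = "position"` gives single-mismatch tolerance by PAM-proximal
#' position and spacer length; `"type"` the 12 RNA:DNA mismatch classes;
#' `"position_pair"` double-mismatch tolerance by position pair; `"length"`
#' on-target efficiency of matched members by spacer length; `"category"`
#' activity by variant category. Empty strata are absent (count 0 rows are
#' not fabricated).
#'
#' @param records data.frame from [offOnRatios()].
#' @param design a [GuideTargetDesign-class].
#' @param by one of `"position"`, `"type"`, `"position_pair"`, `"length"`,
#'   `"category"`.
#' @return data.frame of strata with `n`, `mean`, `ciLo`, `ciHi`.
#' @export
aggregateTolerance <- function(records, design,
                               by = c("position", "type", "position_pair",
                                      "length", "category")) {
  by <- match.arg(by)
  mem <- designMembers(design)
  i <- match(records$memberId, mem$memberId)
  rec <- cbind(records,
               positions = mem$positions[i],
               spacer = mem$spacer[i],
               target = mem$target[i])

  summarize <- function(df, groupCols, valueCol) {
    df <- df[!is.na(df[[valueCol]]), , drop = FALSE]
    if (!nrow(df)) {
      out <- df[, groupCols, drop = FALSE]
      out$n <- integer(0); out$mean <- numeric(0)
      out$ciLo <- numeric(0); out$ciHi <- numeric(0)
      return(out)
    }
    key <- interaction(df[groupCols], drop = TRUE, lex.order = TRUE)
    agg <- lapply(split(df[[valueCol]], key), function(v) {
      m <- mean(v); n <- length(v)
      se <- if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_
      tq <- if (n > 1L) stats::qt(0.975, n - 1L) else NA_real_
      c(n = n, mean = m, ciLo = m - tq * se, ciHi = m + tq * se)
    })
    meta <- unique(df[groupCols])
    mkey <- interaction(meta, drop = TRUE, lex.order = TRUE)
    meta <- meta[match(names(agg), as.character(mkey)), , drop = FALSE]
    out <- cbind(meta, do.call(rbind, agg))
    rownames(out) <- NULL
    out[do.call(order, out[, seq_len(ncol(meta)), drop = FALSE]), ,
        drop = FALSE]
  }

  if (by == "position") {
    df <- rec[rec$category == "single_mismatch", , drop = FALSE]
    df$position <- as.integer(df$positions)
    summarize(df, c("spacerLength", "position"), "offOnRatio")
  } else if (by == "type") {
    df <- rec[rec$category == "single_mismatch", , drop = FALSE]
    if (nrow(df)) {
      df$type <- vapply(seq_len(nrow(df)), function(k) {
        mismatchDescriptors(df$spacer[k], df$target[k])$type[1L]
      }, character(1))
    } else df$type <- character(0)
    summarize(df, "type", "offOnRatio")
  } else if (by == "position_pair") {
    df <- rec[rec$category %in% c("double_mismatch", "double_transversion"), ,
              drop = FALSE]
    ps <- strsplit(df$positions, ",")
    df$position1 <- as.integer(vapply(ps, `[`, "", 1L))
    df$position2 <- as.integer(vapply(ps, `[`, "", 2L))
    summarize(df, c("position1", "position2"), "offOnRatio")
  } else if (by == "length") {
    df <- rec[rec$category == "matched", , drop = FALSE]
    summarize(df, "spacerLength", "indelRate")
  } else {
    summarize(rec, "category", "indelRate")
  }
}

#' Replicate concordance as a function of the rBC threshold
#'
#' For each minimum-rBC threshold, the Pearson R^2 of per-member indel rates
#' across two replicate record sets (members passing the threshold with a
#' defined rate in both) and the fraction of the library retained. Requires
#' at least 3 shared members per threshold, else NA.
#'
#' @param recordsA,recordsB data.frames from [computeIndelRates()] over the
#'   same design.
#' @param thresholds integer vector of minimum-rBC thresholds.
#' @return data.frame with `minRbc`, `nShared`, `r2`, `retainedFraction`.
#' @export
replicateConcordance <- function(recordsA, recordsB,
                                 thresholds = c(1L, 2L, 5L, 10L, 20L, 50L)) {
  stopifnot(identical(recordsA$memberId, recordsB$memberId))
  total <- nrow(recordsA)
  out <- lapply(thresholds, function(t) {
    pass <- recordsA$nRbc >= t & recordsB$nRbc >= t &
      !is.na(recordsA$indelRate) & !is.na(recordsB$indelRate)
    n <- sum(pass)
    r2 <- if (n >= 3L)
      stats::cor(recordsA$indelRate[pass], recordsB$indelRate[pass])^2
    else NA_real_
    data.frame(minRbc = t, nShared = n, r2 = r2,
               retainedFraction = n / total)
  })
  do.call(rbind, out)
}

#' Read and write quantification tables
#'
#' Whitelists and rate records are stored as TSV.
#'
#' @param x a whitelist DataFrame or rate-record data.frame.
#' @param path file path.
#' @return `write*` return `path` invisibly; `read*` return the table.
#' @export
writeWhitelist <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeWhitelist
#' @export
readWhitelist <- function(path) {
  DataFrame(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' @rdname writeWhitelist
#' @export
writeRates <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWhitelist
#' @export
readRates <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
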
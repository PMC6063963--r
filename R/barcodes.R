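# Quaternary Hamming (SECDED) DNA barcodes: encode, decode with
# single-substitution correction, composition filters, enumeration, and
# minimum-edit-distance subsampling.

# Coverage matrix of a spec: totalLength x (nCheck + 1) 0/1 matrix. Column k
# is the coverage set of check 2^(k-1); the last column is the overall parity
# covering every position. A codeword has every coverage sum == 0 mod 4.
.coverageMatrix <- function(spec) {
  r <- length(spec@checkPositions)
  total <- spec@totalLength
  cov <- matrix(0L, total, r + 1L)
  for (k in seq_len(r)) {
    cov[, k] <- as.integer(bitwAnd(seq_len(total), spec@checkPositions[k]) > 0L &
                             seq_len(total) < spec@parityPosition)
  }
  cov[, r + 1L] <- 1L
  cov
}

# Encode data-digit matrix (n x nData, values 0..3) into codeword digit matrix
# (n x totalLength). Check digits are the negated coverage sums of the data
# digits; the parity digit negates the sum of all preceding positions.
.encodeDigits <- function(D, spec) {
  n <- nrow(D)
  cw <- matrix(0L, n, spec@totalLength)
  cw[, spec@dataPositions] <- D
  for (k in seq_along(spec@checkPositions)) {
    cpos <- spec@checkPositions[k]
    covered <- spec@dataPositions[bitwAnd(spec@dataPositions, cpos) > 0L]
    if (length(covered))
      cw[, cpos] <- (-rowSums(cw[, covered, drop = FALSE])) %% 4L
  }
  cw[, spec@parityPosition] <-
    (-rowSums(cw[, -spec@parityPosition, drop = FALSE])) %% 4L
  cw
}

.asDataDigits <- function(dataWord, spec) {
  if (is.matrix(dataWord)) {
    D <- dataWord
  } else if (is.numeric(dataWord)) {
    D <- matrix(as.integer(dataWord), nrow = 1L)
  } else {
    bad <- !grepl(sprintf("^[%s]+$", paste(names(spec@baseMap), collapse = "")),
                  dataWord)
    if (any(bad))
      stop("invalid symbol in data word(s): ",
           paste(utils::head(dataWord[bad], 3L), collapse = ", "))
    if (any(nchar(dataWord) != spec@nData))
      stop("data words must have exactly ", spec@nData, " symbols")
    D <- .seqToDigits(dataWord, spec@baseMap)
  }
  if (ncol(D) != spec@nData)
    stop("data words must have exactly ", spec@nData, " symbols")
  if (any(is.na(D)) || any(D < 0L | D > 3L))
    stop("data word symbols must be in {0,1,2,3} / {A,C,G,T}")
  storage.mode(D) <- "integer"
  D
}

#' Encode data words into Hamming DNA barcodes
#'
#' Encodes quaternary data words into full barcodes under a [barcodeSpec()]
#' layout. Data words may be DNA strings of length `nData` (interpreted via
#' the spec's base map), an integer vector of digits, or an integer matrix
#' (one word per row). Encoding is deterministic and invertible by
#' [decodeBarcode()].
#'
#' @param dataWord character vector of DNA data words, or integer vector /
#'   matrix of digits 0..3.
#' @param spec a [BarcodeSpec-class].
#' @return Character vector of barcode sequences.
#' @examples
#' spec <- barcodeSpec()
#' encodeBarcode("AAAAAAAAAA", spec)  # the all-zero codeword
#' @export
encodeBarcode <- function(dataWord, spec = barcodeSpec()) {
  D <- .asDataDigits(dataWord, spec)
  .digitsToSeq(.encodeDigits(D, spec), spec@baseMap)
}

#' Decode observed barcodes with single-substitution correction
#'
#' Computes the coverage syndromes of each observed word. An all-zero syndrome
#' is an exact codeword. Otherwise the decoder performs a radius-1
#' nearest-codeword search expressed through the syndromes: a single
#' substitution of magnitude e at position p makes exactly the checks covering
#' p (and the parity) read e; the word is corrected only when the nonzero
#' syndromes are all equal and identify a unique position. Anything else --
#' inconsistent syndromes, ambiguous positions, wrong length, non-ACGT
#' letters -- fails. The decoder therefore never returns a wrong codeword for
#' observations within Hamming distance 1 of a true codeword.
#'
#' @param observed character vector of observed barcode sequences.
#' @param spec a [BarcodeSpec-class].
#' @return A data.frame with one row per input: `sequence`, `status`
#'   (`"exact"`, `"corrected"`, `"fail"`), `dataWord` (DNA, NA on failure),
#'   and `correctedPosition` (NA unless corrected).
#' @examples
#' spec <- barcodeSpec()
#' bc <- encodeBarcode("ACGTACGTAC", spec)
#' decodeBarcode(bc, spec)$status                    # "exact"
#' corrupt <- sub("^.", "T", bc)
#' decodeBarcode(corrupt, spec)$dataWord             # "ACGTACGTAC"
#' @export
decodeBarcode <- function(observed, spec = barcodeSpec()) {
  n <- length(observed)
  status <- rep("fail", n)
  dataWord <- rep(NA_character_, n)
  corrPos <- rep(NA_integer_, n)
  out <- function() data.frame(sequence = observed, status = status,
                               dataWord = dataWord,
                               correctedPosition = corrPos,
                               stringsAsFactors = FALSE)
  alphabet <- sprintf("^[%s]+$", paste(names(spec@baseMap), collapse = ""))
  ok <- !is.na(observed) & nchar(observed) == spec@totalLength &
    grepl(alphabet, observed)
  if (!any(ok)) return(out())

  M <- .seqToDigits(observed[ok], spec@baseMap)
  cov <- .coverageMatrix(spec)
  S <- (M %*% cov) %% 4L                      # syndromes, n_ok x (r+1)
  exact <- rowSums(S != 0L) == 0L

  # candidate correction: nonzero-syndrome mask must equal the coverage mask
  # of exactly one position, and all nonzero syndrome values must agree.
  r1 <- ncol(cov)
  posMask <- as.integer(cov %*% 2^(seq_len(r1) - 1L))   # mask per position
  obsMask <- as.integer((S != 0L) %*% 2^(seq_len(r1) - 1L))
  Sbig <- S
  Sbig[Sbig == 0L] <- 99L
  smin <- do.call(pmin, lapply(seq_len(ncol(S)), function(j) Sbig[, j]))
  smin[smin == 99L] <- 0L
  smax <- do.call(pmax, lapply(seq_len(ncol(S)), function(j) S[, j]))
  consistent <- !exact & smin == smax & smin > 0L
  hitPos <- match(obsMask, posMask)           # NA if no position matches
  maskCount <- tabulate(posMask, nbins = max(posMask))
  nHits <- ifelse(obsMask >= 1L & obsMask <= max(posMask),
                  maskCount[pmax(obsMask, 1L)], 0L)
  correctable <- consistent & !is.na(hitPos) & nHits == 1L

  Mc <- M
  if (any(correctable)) {
    idx <- which(correctable)
    Mc[cbind(idx, hitPos[idx])] <-
      (Mc[cbind(idx, hitPos[idx])] - smax[idx]) %% 4L
  }
  words <- .digitsToSeq(Mc[, spec@dataPositions, drop = FALSE], spec@baseMap)

  okIdx <- which(ok)
  status[okIdx[exact]] <- "exact"
  status[okIdx[correctable]] <- "corrected"
  keep <- exact | correctable
  dataWord[okIdx[keep]] <- words[keep]
  corrPos[okIdx[correctable]] <- hitPos[correctable]
  out()
}

#' Composition filters for barcode sequences
#'
#' TRUE iff the longest homopolymer run is at most `maxHomopolymer` bases and
#' the GC fraction lies in `[gcMin, gcMax]` (bounds inclusive). Sequences with
#' characters outside A/C/G/T never pass. The function is pure: the result
#' depends only on the sequence.
#'
#' @param x character vector of DNA sequences.
#' @param maxHomopolymer longest permitted single-nucleotide run (default 3,
#'   i.e. runs longer than 3 nt are excluded).
#' @param gcMin,gcMax inclusive GC-fraction bounds (defaults 0.30 and 0.70).
#' @return Logical vector.
#' @examples
#' barcodePassesFilters(c("ACGTACGTACGTACG", "AAAAAAAAAAAAAAA"))
#' @export
barcodePassesFilters <- function(x, maxHomopolymer = 3, gcMin = 0.30,
                                 gcMax = 0.70) {
  res <- rep(FALSE, length(x))
  ok <- !is.na(x) & .isDna(x)
  if (!any(ok)) return(res)
  xs <- x[ok]
  homo <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}", maxHomopolymer + 1L,
                  maxHomopolymer + 1L, maxHomopolymer + 1L, maxHomopolymer + 1L)
  runOk <- !grepl(homo, xs)
  gc <- nchar(gsub("[AT]", "", xs))
  len <- nchar(xs)
  eps <- 1e-9
  gcOk <- gc + eps >= gcMin * len & gc - eps <= gcMax * len
  res[ok] <- runOk & gcOk
  res
}

#' Enumerate all barcodes of a spec, optionally filtered
#'
#' Enumerates all `4^nData` data words, encodes each, and (by default) keeps
#' those passing [barcodePassesFilters()]. With the default 15-nt spec the
#' candidate pool is 4^10 = 1,048,576 barcodes and the default filters retain
#' 812,547 of them. Output is sorted lexicographically (C locale) and is
#' invariant across runs and platforms.
#'
#' @param spec a [BarcodeSpec-class].
#' @param maxHomopolymer,gcMin,gcMax filter parameters, see
#'   [barcodePassesFilters()].
#' @param applyFilters set FALSE to return the full unfiltered codebook.
#' @return Character vector of barcode sequences.
#' @export
generateBarcodes <- function(spec = barcodeSpec(), maxHomopolymer = 3,
                             gcMin = 0.30, gcMax = 0.70, applyFilters = TRUE) {
  n <- 4L^spec@nData
  v <- 0:(n - 1L)
  D <- matrix(0L, n, spec@nData)
  for (k in seq_len(spec@nData)) {
    D[, k] <- v %% 4L
    v <- v %/% 4L
  }
  cw <- .encodeDigits(D, spec)
  keep <- rep(TRUE, n)
  if (applyFilters) {
    gcVals <- spec@baseMap[c("G", "C")]
    gc <- rowSums(cw == gcVals[1L]) + rowSums(cw == gcVals[2L])
    len <- spec@totalLength
    eps <- 1e-9
    keep <- gc + eps >= gcMin * len & gc - eps <= gcMax * len &
      .maxRun(cw) <= maxHomopolymer
  }
  sort(.digitsToSeq(cw[keep, , drop = FALSE], spec@baseMap), method = "radix")
}

#' Subsample barcodes to a minimum pairwise edit distance
#'
#' Greedy selection after a seeded shuffle: a candidate is accepted iff its
#' Levenshtein distance to every already-accepted barcode is at least
#' `minEditDistance`. Deterministic given the seed. If the target size is
#' unreachable at the requested distance, the partial set is returned with a
#' warning and `attr(, "complete") = FALSE`.
#'
#' @param barcodes character vector of candidate barcodes.
#' @param nTarget number of barcodes requested.
#' @param minEditDistance minimum pairwise Levenshtein distance (default 3;
#'   the distance-2 neighbours excluded relative to the raw Hamming codebook
#'   arise from shifted alignments of equal-length words).
#' @param seed integer seed fixing the shuffle order.
#' @return Character vector of at most `nTarget` barcodes.
#' @export
subsampleBarcodes <- function(barcodes, nTarget, minEditDistance = 3,
                              seed = 1L) {
  stopifnot(nTarget >= 1L)
  if (nTarget > length(barcodes))
    stop("nTarget (", nTarget, ") exceeds the candidate pool (",
         length(barcodes), ")")
  set.seed(as.integer(seed))
  cand <- sample(barcodes)
  accepted <- character(0)
  for (b in cand) {
    if (length(accepted) == 0L ||
        min(utils::adist(b, accepted)) >= minEditDistance)
      accepted <- c(accepted, b)
    if (length(accepted) == nTarget) break
  }
  complete <- length(accepted) == nTarget
  if (!complete)
    warning("only ", length(accepted), " of ", nTarget,
            " barcodes reachable at edit distance >= ", minEditDistance)
  attr(accepted, "complete") <- complete
  accepted
}

#' Draw a deterministic set of valid barcodes without full enumeration
#'
#' Convenience for simulations and examples: encodes seeded-random data words,
#' applies the composition filters, and returns the first `n` unique
#' survivors. The full enumeration route is [generateBarcodes()].
#'
#' @param n number of barcodes.
#' @param spec a [BarcodeSpec-class].
#' @param seed integer seed.
#' @inheritParams generateBarcodes
#' @return Character vector of `n` barcode sequences.
#' @export
sampleBarcodes <- function(n, spec = barcodeSpec(), seed = 1L,
                           maxHomopolymer = 3, gcMin = 0.30, gcMax = 0.70) {
  set.seed(as.integer(seed))
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < 50L) {
    D <- matrix(sample(0:3, 3L * n * spec@nData, replace = TRUE),
                ncol = spec@nData)
    bc <- .digitsToSeq(.encodeDigits(D, spec), spec@baseMap)
    bc <- bc[barcodePassesFilters(bc, maxHomopolymer, gcMin, gcMax)]
    out <- unique(c(out, bc))
    tries <- tries + 1L
  }
  if (length(out) < n) stop("could not draw ", n, " filtered barcodes")
  out[seq_len(n)]
}

#' Read and write barcode lists
#'
#' Barcode lists are stored either as headerless one-sequence-per-line text or
#' as FASTA (identifiers are the list indices).
#'
#' @param barcodes character vector of barcodes.
#' @param path file path.
#' @param format `"text"` or `"fasta"`.
#' @return `readBarcodes()` returns a character vector; `writeBarcodes()`
#'   returns `path` invisibly.
#' @export
writeBarcodes <- function(barcodes, path, format = c("text", "fasta")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(barcodes, path)
  } else {
    x <- Biostrings::DNAStringSet(barcodes)
    names(x) <- seq_along(x)
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' @rdname writeBarcodes
#' @export
readBarcodes <- function(path, format = c("text", "fasta")) {
  format <- match.arg(format)
  if (format == "text") readLines(path)
  else unname(as.character(Biostrings::readDNAStringSet(path)))
}
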
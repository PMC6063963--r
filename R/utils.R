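# Internal string/digit helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T")

# complement lookup usable on plain character vectors of single bases
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.isDna <- function(x) grepl("^[ACGT]+$", x)

# Equal-width character vector -> integer digit matrix under baseMap.
# Rows follow the input order; invalid characters become NA.
.seqToDigits <- function(x, baseMap) {
  if (length(x) == 0L) return(matrix(integer(0), 0, 0))
  w <- unique(nchar(x))
  stopifnot(length(w) == 1L)
  bytes <- utf8ToInt(paste(x, collapse = ""))
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt(paste(names(baseMap), collapse = "")) + 1L] <- unname(baseMap)
  matrix(lut[bytes + 1L], ncol = w, byrow = TRUE)
}

# Integer digit matrix -> character vector of sequences under baseMap.
.digitsToSeq <- function(m, baseMap) {
  if (nrow(m) == 0L) return(character(0))
  letters4 <- names(sort(baseMap))
  cols <- lapply(seq_len(ncol(m)), function(j) letters4[m[, j] + 1L])
  do.call(paste0, cols)
}

# Longest single-symbol run per row of a digit matrix.
.maxRun <- function(m) {
  run <- rep(1L, nrow(m))
  mx <- rep(1L, nrow(m))
  if (ncol(m) < 2L) return(mx)
  for (j in 2:ncol(m)) {
    same <- m[, j] == m[, j - 1L]
    run <- ifelse(same, run + 1L, 1L)
    mx <- pmax(mx, run)
  }
  mx
}

# Random DNA strings (uses the current RNG stream).
.randomDna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_ALPHABET, n * width, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(width), function(j) m[, j]))
}

# Per-base substitution noise at rate `rate`; returns mutated strings.
# Number of errors per string is Binomial(width, rate); error positions are
# uniform without replacement and substitutions never reproduce the original base.
.mutateBases <- function(x, rate) {
  if (rate <= 0 || length(x) == 0L) return(x)
  w <- nchar(x)
  k <- stats::rbinom(length(x), w, rate)
  hit <- which(k > 0L)
  for (i in hit) {
    pos <- sample.int(w[i], k[i])
    chars <- strsplit(x[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_ALPHABET, chars[p]), 1L)
    }
    x[i] <- paste(chars, collapse = "")
  }
  x
}

# Count mismatches between each element of a fixed-width character vector and
# a single pattern of the same width.
.mismatchCount <- function(x, pattern) {
  if (length(x) == 0L) return(integer(0))
  stopifnot(all(nchar(x) == nchar(pattern)))
  pm <- utf8ToInt(pattern)
  m <- matrix(utf8ToInt(paste(x, collapse = "")), ncol = nchar(pattern), byrow = TRUE)
  as.integer(rowSums(m != matrix(pm, nrow(m), length(pm), byrow = TRUE)))
}

# Derived sub-seeds keep every stage independently reproducible while staying
# inside 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483647)
}
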
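#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

# ---------------------------------------------------------------------------
# BarcodeSpec
# ---------------------------------------------------------------------------

#' Layout of an error-correcting quaternary Hamming DNA barcode
#'
#' A `BarcodeSpec` fixes the geometry and arithmetic of the single-error
#' correcting (SECDED-style) DNA barcode: which positions carry data symbols,
#' which carry checksum symbols, where the overall parity symbol sits, and the
#' bijection between nucleotides and the integers 0..3. Checksum positions are
#' the powers of two (1, 2, 4, ...), each covering the positions whose binary
#' representation contains that power; the parity position is appended last and
#' covers every other position. Check and parity digits are chosen so that
#' every coverage sum is congruent to 0 mod 4 for a valid codeword.
#'
#' @slot nData number of data symbols (10 for the default 15-nt barcode).
#' @slot checkPositions positions of the checksum symbols.
#' @slot dataPositions positions of the data symbols.
#' @slot parityPosition position of the overall parity symbol (the last one).
#' @slot totalLength total barcode length in nucleotides.
#' @slot baseMap named integer vector mapping A/C/G/T to 0..3.
#'
#' @seealso [barcodeSpec()], [encodeBarcode()], [decodeBarcode()]
#' @export
setClass("BarcodeSpec", representation(
  nData = "integer",
  checkPositions = "integer",
  dataPositions = "integer",
  parityPosition = "integer",
  totalLength = "integer",
  baseMap = "integer"
))

setValidity("BarcodeSpec", function(object) {
  msg <- character(0)
  all_pos <- sort(c(object@checkPositions, object@dataPositions,
                    object@parityPosition))
  if (!identical(all_pos, seq_len(object@totalLength)))
    msg <- c(msg, "check, data and parity positions must partition 1..totalLength")
  if (object@totalLength !=
      object@nData + length(object@checkPositions) + 1L)
    msg <- c(msg, "totalLength must equal nData + nCheck + 1 (parity)")
  bm <- object@baseMap
  if (!setequal(names(bm), DNA_ALPHABET) || !setequal(bm, 0:3))
    msg <- c(msg, "baseMap must be a bijection {A,C,G,T} <-> {0,1,2,3}")
  if (length(msg)) msg else TRUE
})

#' Construct a barcode layout
#'
#' Builds the canonical layout for `nData` data symbols: the number of checksum
#' symbols is the smallest r with 2^r - 1 - r >= nData, checksum symbols sit at
#' positions 1, 2, 4, ..., data symbols fill the remaining positions in order,
#' and a single parity symbol is appended. The default (`nData = 10`) gives the
#' 15-nt barcode with checks at positions 1, 2, 4, 8 and parity at 15.
#'
#' @param nData number of data symbols (>= 1).
#' @param baseMap named integer vector mapping the four nucleotides to 0..3.
#' @return A [BarcodeSpec-class] object.
#' @examples
#' spec <- barcodeSpec()
#' spec
#' toy <- barcodeSpec(nData = 3L)  # 7-nt toy barcode, 64 codewords
#' @export
barcodeSpec <- function(nData = 10L, baseMap = c(A = 0L, C = 1L, G = 2L, T = 3L)) {
  nData <- as.integer(nData)
  stopifnot(nData >= 1L)
  r <- 0L
  while (2^r - 1 - r < nData) r <- r + 1L
  npos <- nData + r
  checks <- as.integer(2^(seq_len(r) - 1L))
  datapos <- setdiff(seq_len(npos), checks)
  new("BarcodeSpec",
      nData = nData,
      checkPositions = checks,
      dataPositions = as.integer(datapos),
      parityPosition = npos + 1L,
      totalLength = npos + 1L,
      baseMap = structure(as.integer(baseMap), names = names(baseMap)))
}

setMethod("show", "BarcodeSpec", function(object) {
  cat("BarcodeSpec:", object@totalLength, "nt (",
      object@nData, "data +", length(object@checkPositions),
      "check +1 parity )\n")
  cat("  checks at:", paste(object@checkPositions, collapse = ","),
      " parity at:", object@parityPosition, "\n")
  cat("  baseMap:", paste0(names(object@baseMap), "=", object@baseMap,
                           collapse = " "), "\n")
})

#' Total barcode length of a spec
#' @param spec a [BarcodeSpec-class].
#' @return integer length in nucleotides.
#' @export
barcodeLength <- function(spec) spec@totalLength

# ---------------------------------------------------------------------------
# CassetteLayout
# ---------------------------------------------------------------------------

#' Constant-segment layout of the guide-target cassette
#'
#' The cassette, on the sequenced strand 5'->3', is
#' `upstream | spacer | scaffold | rBC | mid | target | PAM | linker | Hamming
#' barcode | downstream`. The constant segments shipped as defaults are
#' synthetic stand-ins for the vector sequences (chosen to be mutually
#' dissimilar); every segment is configurable. The predicted blunt cut site
#' lies `cutOffset` bp 5' of the PAM, which with the 7-nt linker places the
#' Hamming barcode 16 bp downstream of the cut site.
#'
#' @slot upstream constant region sequenced at the start of read 1.
#' @slot scaffold constant tracrRNA-scaffold/cloning-site region between the
#'   spacer and the rBC.
#' @slot mid constant region between the rBC and the target site.
#' @slot pam the constant PAM (CAGGGT).
#' @slot linker constant region between the PAM and the Hamming barcode.
#' @slot downstream constant region after the Hamming barcode (start of read 2).
#' @slot rbcLength length of the randomized barcode (8).
#' @slot cutOffset cut-site offset in bp 5' of the PAM (3).
#' @slot oligoWindow permitted synthesized-oligo length range.
#' @slot targetPad constant filler placed PAM-distal of the target so the
#'   target segment occupies a fixed-width window; cassette and oligo lengths
#'   then vary only with spacer length.
#' @slot targetWindow fixed width of the padded target segment.
#' @export
setClass("CassetteLayout", representation(
  upstream = "character",
  scaffold = "character",
  mid = "character",
  pam = "character",
  linker = "character",
  downstream = "character",
  rbcLength = "integer",
  cutOffset = "integer",
  oligoWindow = "integer",
  targetPad = "character",
  targetWindow = "integer"
))

setValidity("CassetteLayout", function(object) {
  segs <- c(object@upstream, object@scaffold, object@mid, object@pam,
            object@linker, object@downstream, object@targetPad)
  if (!all(.isDna(segs)))
    return("all constant segments must be non-empty A/C/G/T strings")
  if (object@rbcLength < 1L) return("rbcLength must be >= 1")
  if (object@cutOffset < 0L) return("cutOffset must be >= 0")
  if (nchar(object@targetPad) < object@targetWindow - 18L)
    return("targetPad too short for the target window")
  TRUE
})

#' Construct a cassette layout
#'
#' @param upstream,scaffold,mid,pam,linker,downstream constant segments
#'   (see [CassetteLayout-class]).
#' @param rbcLength randomized-barcode length (default 8).
#' @param cutOffset predicted cut-site offset in bp 5' of the PAM (default 3).
#' @param oligoWindow integer length-2 vector of permitted oligo lengths.
#' @param targetPad,targetWindow constant PAM-distal filler and fixed width of
#'   the padded target segment (default 26: the longest variant, a 24-nt
#'   spacer's DNA-bulge target, is 25 nt).
#' @return A [CassetteLayout-class] object.
#' @export
cassetteLayout <- function(upstream = "CTTGTGGAAAGGACGAAACA",
                           scaffold = "GTTTAAGTACTCTGTGCTGG",
                           mid = "TCGGTACCTCAGCAA",
                           pam = "CAGGGT",
                           linker = "GTCTACT",
                           downstream = "CGACTCGGTGCCACT",
                           rbcLength = 8L,
                           cutOffset = 3L,
                           oligoWindow = c(110L, 170L),
                           targetPad = "ATCGTTAAGCGGCCTTAGCAGTCATG",
                           targetWindow = 26L) {
  new("CassetteLayout", upstream = upstream, scaffold = scaffold, mid = mid,
      pam = pam, linker = linker, downstream = downstream,
      rbcLength = as.integer(rbcLength), cutOffset = as.integer(cutOffset),
      oligoWindow = as.integer(oligoWindow), targetPad = targetPad,
      targetWindow = as.integer(targetWindow))
}

setMethod("show", "CassetteLayout", function(object) {
  cat("CassetteLayout: upstream|spacer|scaffold|rBC(", object@rbcLength,
      ")|mid|target|", object@pam, "|linker|barcode|downstream\n", sep = "")
  cat("  cut site ", object@cutOffset, " bp 5' of PAM; barcode ",
      object@cutOffset + nchar(object@pam) + nchar(object@linker),
      " bp downstream of the cut\n", sep = "")
})

# ---------------------------------------------------------------------------
# GuideTargetDesign
# ---------------------------------------------------------------------------

#' A pairwise guide-target library design
#'
#' Container for an assembled library: one row per member in `members`
#' (member id, group, spacer, target variant, PAM, Hamming barcode,
#' multiplicity), the spacer groups it was built from, and the cassette layout.
#'
#' @slot members a [S4Vectors::DataFrame] with columns `memberId`, `groupId`,
#'   `spacer`, `spacerLength`, `category`, `positions`, `target`, `pam`,
#'   `barcode`, `multiplicity`.
#' @slot groups a [S4Vectors::DataFrame] with columns `groupId`, `core18`,
#'   `ext` (PAM-distal extension bases for lengths 20-24).
#' @slot layout the [CassetteLayout-class].
#' @seealso [assembleLibrary()], [designMembers()]
#' @export
setClass("GuideTargetDesign", representation(
  members = "DataFrame",
  groups = "DataFrame",
  layout = "CassetteLayout"
))

setValidity("GuideTargetDesign", function(object) {
  m <- object@members
  need <- c("memberId", "groupId", "spacer", "spacerLength", "category",
            "positions", "target", "pam", "barcode", "multiplicity")
  if (!all(need %in% colnames(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (nrow(m)) {
    if (anyDuplicated(m$memberId)) return("memberId must be unique")
    if (anyDuplicated(m$barcode)) return("barcodes must not be reused")
  }
  TRUE
})

setMethod("show", "GuideTargetDesign", function(object) {
  cat("GuideTargetDesign:", nrow(object@members), "members,",
      nrow(object@groups), "spacer groups\n")
  if (nrow(object@members)) {
    tab <- table(object@members$category)
    cat("  categories:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

#' Accessors for a design
#'
#' `designMembers()` returns the member table, `designGroups()` the spacer
#' groups, `designLayout()` the cassette layout.
#'
#' @param design a [GuideTargetDesign-class].
#' @return A DataFrame (members, groups) or [CassetteLayout-class].
#' @export
designMembers <- function(design) design@members

#' @rdname designMembers
#' @export
designGroups <- function(design) design@groups

#' @rdname designMembers
#' @export
designLayout <- function(design) design@layout

# ---------------------------------------------------------------------------
# ScreenTruth / ScreenSim
# ---------------------------------------------------------------------------

#' Ground truth of a simulated screen
#'
#' Holds the simulated guide activities g_j, the per-length multiplicative
#' mismatch penalty matrices f_L (position x RNA:DNA mismatch type, entries in
#' (0,1]), and the bulge penalty factors, from which every simulated editing
#' probability derives as g * prod(f) (mismatches) or g * bulge factor.
#'
#' @slot guideActivity DataFrame with `groupId`, `spacerLength`, `g`.
#' @slot penalties named list (by spacer length) of L x 12 matrices of f.
#' @slot bulgePenalty named numeric, factors for `proximal` (positions 1-18)
#'   and `distal` (>18) bulges.
#' @export
setClass("ScreenTruth", representation(
  guideActivity = "DataFrame",
  penalties = "list",
  bulgePenalty = "numeric"
))

setMethod("show", "ScreenTruth", function(object) {
  cat("ScreenTruth:", nrow(object@guideActivity), "guides,",
      length(object@penalties), "penalty matrices (lengths",
      paste(names(object@penalties), collapse = ","), ")\n")
})

#' Simulated lentiviral integrations with their truth log
#'
#' One row of `simLog` per integration: the member it derives from, its rBC,
#' the synthesized (possibly erroneous) spacer and target, synthesis error
#' accounting, the latent editing quantile used to decide edit status per day,
#' and the indel operation applied if edited.
#'
#' @slot design the [GuideTargetDesign-class] simulated from.
#' @slot simLog DataFrame, one row per integration.
#' @slot config the simulation configuration list (see [simConfig()]).
#' @export
setClass("ScreenSim", representation(
  design = "GuideTargetDesign",
  simLog = "DataFrame",
  config = "list"
))

setMethod("show", "ScreenSim", function(object) {
  cat("ScreenSim:", nrow(object@simLog), "integrations over",
      nrow(object@design@members), "members; seed", object@config$seed, "\n")
  cat("  error-free cassettes:", sum(object@simLog$errorFree), "\n")
})

#' Accessors for a simulated screen
#' @param sim a [ScreenSim-class].
#' @return `simTruthLog()` the integration-level truth DataFrame;
#'   `simDesign()` the design.
#' @export
simTruthLog <- function(sim) sim@simLog

#' @rdname simTruthLog
#' @export
simDesign <- function(sim) sim@design

# ---------------------------------------------------------------------------
# PenaltyFit
# ---------------------------------------------------------------------------

#' Fitted mismatch-penalty model for one spacer length
#'
#' Result of [fitPenaltyModel()]: the additive penalties ddG (>= 0) and their
#' multiplicative form f = exp(-ddG) on a (position x mismatch type) grid,
#' per-guide activities, observation counts per cell, and MCMC diagnostics
#' when fitted by sampling.
#'
#' @slot spacerLength the spacer length L the fit applies to.
#' @slot ddG L x 12 matrix of additive penalties (posterior means in mcmc mode).
#' @slot f L x 12 matrix of multiplicative penalties exp(-ddG).
#' @slot fLower,fUpper L x 12 matrices of 95% interval bounds for f (NA in map
#'   mode).
#' @slot guideActivity data.frame with `guide`, `g`, `gLower`, `gUpper`.
#' @slot nObs L x 12 matrix of observation counts per cell; cells with 0 are
#'   prior-dominated.
#' @slot rhat named numeric of per-parameter R-hat (NA in map mode).
#' @slot converged logical: all R-hat below the threshold (NA in map mode).
#' @slot mode "map" or "mcmc".
#' @slot config the [modelConfig()] list used.
#' @export
setClass("PenaltyFit", representation(
  spacerLength = "integer",
  ddG = "matrix",
  f = "matrix",
  fLower = "matrix",
  fUpper = "matrix",
  guideActivity = "data.frame",
  nObs = "matrix",
  rhat = "numeric",
  converged = "logical",
  mode = "character",
  config = "list"
))

setMethod("show", "PenaltyFit", function(object) {
  cat("PenaltyFit (", object@mode, "): L = ", object@spacerLength, ", ",
      nrow(object@guideActivity), " guides\n", sep = "")
  cat("  median f =", signif(stats::median(object@f), 3),
      "; prior-dominated cells:", sum(object@nObs == 0), "\n")
  if (object@mode == "mcmc")
    cat("  max R-hat =", signif(max(object@rhat), 4),
        if (isTRUE(object@converged)) "(converged)" else "(NOT converged)", "\n")
})

#' Extract the multiplicative penalty matrix
#' @param fit a [PenaltyFit-class] (or a bare matrix, returned unchanged).
#' @return L x 12 matrix of f values.
#' @export
penaltyMatrix <- function(fit) {
  if (is(fit, "PenaltyFit")) fit@f else fit
}

#' Extract guide activity estimates
#' @param fit a [PenaltyFit-class].
#' @return data.frame with guide, g and interval bounds.
#' @export
guideActivity <- function(fit) fit@guideActivity
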
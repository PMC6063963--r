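# Pairwise guide-target library construction: spacer groups, target variant
# enumeration, barcode assignment, cassette and oligo emission.
#
# Position convention used throughout: position 1 is the PAM-proximal base of
# the protospacer; positions increase towards the PAM-distal 5' end of the
# spacer. String index of position p in a length-L spacer/target is L - p + 1.

VARIANT_CATEGORIES <- c("matched", "single_mismatch", "double_mismatch",
                        "double_transversion", "insertion", "deletion",
                        "scrambled")

.posToIdx <- function(pos, L) L - pos + 1L

#' Generate spacer groups
#'
#' Each group shares an 18-nt PAM-proximal core (positions 1-18); per-length
#' spacers (19-24 nt) extend the core at the PAM-distal 5' end, with the
#' 5'-most base forced to G for reliable U6-driven expression. If a reference
#' is supplied, any group whose core18 + PAM occurs exactly in the reference
#' (either strand) is rejected and regenerated, keeping the library orthogonal
#' to it; generation is deterministic given the seed.
#'
#' @param nGroups number of groups (>= 1).
#' @param seed integer seed.
#' @param reference optional orthogonality reference: a
#'   [Biostrings::DNAStringSet], or path to a FASTA file.
#' @param pam PAM appended when screening against the reference.
#' @param maxRetries bound on regeneration attempts per group.
#' @return DataFrame with `groupId`, `core18`, `ext` (5 PAM-distal bases used
#'   by lengths 20-24).
#' @export
generateSpacerGroups <- function(nGroups, seed = 1L, reference = NULL,
                                 pam = "CAGGGT", maxRetries = 1000L) {
  stopifnot(nGroups >= 1L)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  set.seed(as.integer(seed))
  core <- character(nGroups)
  ext <- character(nGroups)
  for (i in seq_len(nGroups)) {
    tries <- 0L
    repeat {
      cand <- .randomDna(1L, 18L)
      candExt <- .randomDna(1L, 5L)
      hit <- FALSE
      if (!is.null(reference)) {
        probe <- Biostrings::DNAString(paste0(cand, pam))
        hit <- sum(Biostrings::vcountPattern(probe, reference)) > 0 ||
          sum(Biostrings::vcountPattern(
            Biostrings::reverseComplement(probe), reference)) > 0
      }
      dup <- cand %in% core[seq_len(i - 1L)]
      if (!hit && !dup) break
      tries <- tries + 1L
      if (tries > maxRetries)
        stop("could not find a reference-orthogonal core18 after ",
             maxRetries, " attempts")
    }
    core[i] <- cand
    ext[i] <- candExt
  }
  DataFrame(groupId = seq_len(nGroups), core18 = core, ext = ext)
}

#' Spacer of a given length within a group
#'
#' Length L = 19 is `G` + core18; longer spacers interpose PAM-distal
#' extension bases between the forced 5' G and the core.
#'
#' @param groups DataFrame from [generateSpacerGroups()].
#' @param groupId group identifier.
#' @param length spacer length, 19-24.
#' @return Spacer sequence (character).
#' @export
groupSpacer <- function(groups, groupId, length) {
  stopifnot(length >= 19L, length <= 24L)
  i <- match(groupId, groups$groupId)
  if (is.na(i)) stop("unknown groupId: ", groupId)
  extPart <- if (length == 19L) "" else
    substr(groups$ext[i], 5L - (length - 20L), 5L)
  paste0("G", extPart, groups$core18[i])
}

#' Enumerate target-site variants of a spacer
#'
#' Targets are written on the protospacer strand, so the matched target is the
#' spacer with U read as T and all variants are written into the target DNA,
#' never the spacer. Counts follow the closed forms: `3L` single mismatches,
#' `9*choose(L,2)` double mismatches, `4*choose(L,2)` double transversions
#' (each position takes one of its two transversion substitutions), `4*(L+1)`
#' insertion candidates (a DNA bulge) and `L` deletion candidates (an RNA
#' bulge) before deduplication. Identical duplicate targets (e.g. deletions
#' inside a homopolymer run) are collapsed with their multiplicity recorded.
#' Scrambled controls are seeded shuffles of the matched target constrained to
#' differ at >= 50% of positions.
#'
#' @param spacer spacer sequence (length 19-24, 5' G).
#' @param categories subset of
#'   `c("matched","single_mismatch","double_mismatch","double_transversion",
#'   "insertion","deletion","scrambled")`.
#' @param nScrambled number of scrambled controls per spacer.
#' @param seed seed for scrambled-control generation.
#' @return data.frame with `category`, `positions` (comma-separated,
#'   PAM-proximal numbering), `target`, `multiplicity`.
#' @export
enumerateVariants <- function(spacer, categories = "matched", nScrambled = 1L,
                              seed = 1L) {
  L <- nchar(spacer)
  stopifnot(L >= 19L, L <= 24L, .isDna(spacer))
  bad <- setdiff(categories, VARIANT_CATEGORIES)
  if (length(bad)) stop("unknown variant category: ", paste(bad, collapse = ","))
  base <- strsplit(spacer, "")[[1]]
  out <- list()

  sub1 <- function(pos, nb) {
    chars <- base
    chars[.posToIdx(pos, L)] <- nb
    paste(chars, collapse = "")
  }
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))

  if ("matched" %in% categories)
    out$matched <- data.frame(category = "matched", positions = "",
                              target = spacer, multiplicity = 1L)

  if ("single_mismatch" %in% categories) {
    rows <- list()
    for (pos in seq_len(L)) {
      orig <- base[.posToIdx(pos, L)]
      for (nb in setdiff(DNA_ALPHABET, orig))
        rows[[length(rows) + 1L]] <- data.frame(
          category = "single_mismatch", positions = as.character(pos),
          target = sub1(pos, nb), multiplicity = 1L)
    }
    out$single <- do.call(rbind, rows)
  }

  doubleRows <- function(category, subsOf) {
    rows <- list()
    for (p1 in seq_len(L - 1L)) {
      for (p2 in (p1 + 1L):L) {
        o1 <- base[.posToIdx(p1, L)]
        o2 <- base[.posToIdx(p2, L)]
        for (n1 in subsOf(o1)) for (n2 in subsOf(o2)) {
          chars <- base
          chars[.posToIdx(p1, L)] <- n1
          chars[.posToIdx(p2, L)] <- n2
          rows[[length(rows) + 1L]] <- data.frame(
            category = category,
            positions = paste(p1, p2, sep = ","),
            target = paste(chars, collapse = ""), multiplicity = 1L)
        }
      }
    }
    do.call(rbind, rows)
  }
  if ("double_mismatch" %in% categories)
    out$double <- doubleRows("double_mismatch",
                             function(o) setdiff(DNA_ALPHABET, o))
  if ("double_transversion" %in% categories)
    out$transv <- doubleRows("double_transversion",
                             function(o) transversions[[o]])

  if ("insertion" %in% categories) {
    rows <- list()
    for (pos in 0:L) {      # insertion between positions pos and pos+1 (0 = PAM side)
      idx <- L - pos        # insert after string index idx
      for (nb in DNA_ALPHABET) {
        tgt <- paste0(substr(spacer, 1L, idx), nb,
                      substr(spacer, idx + 1L, L))
        rows[[length(rows) + 1L]] <- data.frame(
          category = "insertion", positions = as.character(pos),
          target = tgt, multiplicity = 1L)
      }
    }
    out$ins <- .collapseDuplicates(do.call(rbind, rows))
  }

  if ("deletion" %in% categories) {
    rows <- list()
    for (pos in seq_len(L)) {
      idx <- .posToIdx(pos, L)
      tgt <- paste0(substr(spacer, 1L, idx - 1L), substr(spacer, idx + 1L, L))
      rows[[length(rows) + 1L]] <- data.frame(
        category = "deletion", positions = as.character(pos),
        target = tgt, multiplicity = 1L)
    }
    out$del <- .collapseDuplicates(do.call(rbind, rows))
  }

  if ("scrambled" %in% categories) {
    set.seed(.subSeed(seed, sum(utf8ToInt(spacer))))
    rows <- list()
    for (k in seq_len(nScrambled)) {
      repeat {
        tgt <- paste(sample(base), collapse = "")
        if (sum(strsplit(tgt, "")[[1]] != base) >= ceiling(L / 2)) break
      }
      rows[[k]] <- data.frame(category = "scrambled", positions = "",
                              target = tgt, multiplicity = 1L)
    }
    out$scr <- do.call(rbind, rows)
  }

  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

.collapseDuplicates <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  first <- !duplicated(df$target)
  mult <- as.integer(table(df$target)[df$target[first]])
  res <- df[first, , drop = FALSE]
  res$multiplicity <- mult
  rownames(res) <- NULL
  res
}

#' Build a per-group variant plan
#'
#' Convenience constructor for the plan consumed by [assembleLibrary()]:
#' one row per (group, spacer length, category).
#'
#' @param groups DataFrame from [generateSpacerGroups()].
#' @param categories variant categories to include for every group/length.
#' @param lengths spacer lengths to include (default 19:24).
#' @return data.frame with `groupId`, `spacerLength`, `category`.
#' @export
variantPlan <- function(groups, categories = "matched", lengths = 19:24) {
  expand.grid(groupId = groups$groupId, spacerLength = as.integer(lengths),
              category = categories, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Assemble a guide-target library
#'
#' Enumerates the planned variants for every (group, length, category),
#' assigns each member a unique Hamming barcode by seeded shuffle, and
#' returns the full design. Regenerating with the same inputs and seed
#' reproduces the library byte-for-byte.
#'
#' @param groups DataFrame from [generateSpacerGroups()].
#' @param plan data.frame with `groupId`, `spacerLength`, `category` (see
#'   [variantPlan()]); an optional `nScrambled` column sets the number of
#'   scrambled controls for scrambled rows.
#' @param barcodes character vector of candidate barcodes (must be at least
#'   as many as members; shortfalls are an error).
#' @param seed integer seed for barcode assignment and scrambled controls.
#' @param layout a [CassetteLayout-class].
#' @return A [GuideTargetDesign-class].
#' @export
assembleLibrary <- function(groups, plan, barcodes, seed = 1L,
                            layout = cassetteLayout()) {
  plan$spacerLength <- as.integer(plan$spacerLength)
  stopifnot(all(plan$category %in% VARIANT_CATEGORIES))
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sp <- groupSpacer(groups, plan$groupId[i], plan$spacerLength[i])
    nScr <- if ("nScrambled" %in% names(plan)) plan$nScrambled[i] else 1L
    v <- enumerateVariants(sp, plan$category[i], nScrambled = nScr,
                           seed = .subSeed(seed, i))
    v$groupId <- plan$groupId[i]
    v$spacer <- sp
    v$spacerLength <- plan$spacerLength[i]
    rows[[i]] <- v
  }
  mem <- do.call(rbind, rows)
  n <- nrow(mem)
  if (n > length(barcodes))
    stop("barcode exhaustion: ", n, " members but only ", length(barcodes),
         " barcodes (short by ", n - length(barcodes), ")")
  set.seed(as.integer(seed))
  bc <- sample(barcodes)[seq_len(n)]
  members <- DataFrame(
    memberId = seq_len(n),
    groupId = mem$groupId,
    spacer = mem$spacer,
    spacerLength = mem$spacerLength,
    category = mem$category,
    positions = mem$positions,
    target = mem$target,
    pam = layout@pam,
    barcode = bc,
    multiplicity = mem$multiplicity)
  new("GuideTargetDesign", members = members, groups = groups, layout = layout)
}

# constant PAM-distal padding bringing the target segment to the layout's
# fixed window width, so cassette length varies only with spacer length
.paddedTarget <- function(layout, target) {
  need <- layout@targetWindow - nchar(target)
  if (any(need < 0L))
    stop("target longer than the layout's target window")
  paste0(substring(layout@targetPad, 1L, need), target)
}

#' Full cassette sequence of members
#'
#' Sequenced-strand cassette: upstream | spacer | scaffold | rBC | mid |
#' padded target | PAM | linker | barcode | downstream; the target segment is
#' padded PAM-distally to a fixed window. The rBC defaults to an
#' N-placeholder of the layout's rBC length.
#'
#' @param design a [GuideTargetDesign-class].
#' @param memberId member ids (default: all members).
#' @param rbc rBC sequence(s), recycled along members.
#' @return Named character vector of cassette sequences.
#' @export
cassetteSequence <- function(design, memberId = designMembers(design)$memberId,
                             rbc = NULL) {
  lay <- design@layout
  m <- design@members[match(memberId, design@members$memberId), , drop = FALSE]
  if (any(is.na(m$memberId))) stop("unknown memberId")
  if (is.null(rbc)) rbc <- strrep("N", lay@rbcLength)
  out <- paste0(lay@upstream, m$spacer, lay@scaffold, rbc, lay@mid,
                .paddedTarget(lay, m$target), lay@pam, lay@linker,
                m$barcode, lay@downstream)
  names(out) <- m$memberId
  out
}

#' Emit the synthesized oligo pool
#'
#' One FASTA record per member, covering the synthesized portion of the
#' cassette (everything except the rBC, which is ligated in later between the
#' scaffold and mid segments). Record identifiers are
#' `m<memberId>|g<groupId>|<category>`, so the member id round-trips through
#' the header. Oligo lengths outside the layout's permitted window are an
#' error listing the offenders.
#'
#' @param design a [GuideTargetDesign-class].
#' @param path optional FASTA output path.
#' @return A [Biostrings::DNAStringSet], invisibly if `path` is given.
#' @export
emitOligos <- function(design, path = NULL) {
  lay <- design@layout
  m <- design@members
  seqs <- paste0(lay@upstream, m$spacer, lay@scaffold, lay@mid,
                 .paddedTarget(lay, m$target), lay@pam, lay@linker,
                 m$barcode, lay@downstream)
  len <- nchar(seqs)
  bad <- len < lay@oligoWindow[1L] | len > lay@oligoWindow[2L]
  if (any(bad))
    stop("oligo length outside [", lay@oligoWindow[1L], ",",
         lay@oligoWindow[2L], "] for members: ",
         paste(utils::head(m$memberId[bad], 10L), collapse = ","))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0("m", m$memberId, "|g", m$groupId, "|", m$category)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(x, path)
    return(invisible(x))
  }
  x
}

#' Recover member ids from oligo FASTA headers
#' @param x a DNAStringSet from [emitOligos()] or its FASTA file re-read.
#' @return Integer vector of member ids.
#' @export
oligoMemberId <- function(x) {
  as.integer(sub("^m([0-9]+)\\|.*$", "\\1", names(x)))
}

#' Read and write design files
#'
#' The design TSV has one row per member with the columns of
#' [designMembers()]; groups and layout are stored in a JSON side-car written
#' next to the TSV (same path with extension `.json`), so a design
#' round-trips completely.
#'
#' @param design a [GuideTargetDesign-class].
#' @param path TSV file path.
#' @return `readDesign()` returns a [GuideTargetDesign-class];
#'   `writeDesign()` returns `path` invisibly.
#' @export
writeDesign <- function(design, path) {
  utils::write.table(as.data.frame(design@members), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lay <- design@layout
  meta <- list(
    groups = as.data.frame(design@groups),
    layout = list(upstream = lay@upstream, scaffold = lay@scaffold,
                  mid = lay@mid, pam = lay@pam, linker = lay@linker,
                  downstream = lay@downstream, rbcLength = lay@rbcLength,
                  cutOffset = lay@cutOffset, oligoWindow = lay@oligoWindow,
                  targetPad = lay@targetPad,
                  targetWindow = lay@targetWindow))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(positions = "character"),
                         stringsAsFactors = FALSE)
  m$positions[is.na(m$positions)] <- ""
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lay <- cassetteLayout(upstream = meta$layout$upstream,
                        scaffold = meta$layout$scaffold,
                        mid = meta$layout$mid, pam = meta$layout$pam,
                        linker = meta$layout$linker,
                        downstream = meta$layout$downstream,
                        rbcLength = meta$layout$rbcLength,
                        cutOffset = meta$layout$cutOffset,
                        oligoWindow = meta$layout$oligoWindow,
                        targetPad = meta$layout$targetPad,
                        targetWindow = meta$layout$targetWindow)
  new("GuideTargetDesign", members = DataFrame(m),
      groups = DataFrame(meta$groups), layout = lay)
}
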
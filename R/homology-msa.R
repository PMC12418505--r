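#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
NULL

# species id of each MSA row under the "species|accession" convention;
# a bare row id is itself the species id
msaRowSpecies <- function(msa) {
  ids <- names(msa@alignment)
  sub("\\|.*$", "", ids)
}

#' @describeIn readMsa row ids of an alignment
#' @param msa a ReferenceMsa
#' @export
msaRowIds <- function(msa) names(msa@alignment)

#' @describeIn readMsa the ungapped reference sequence
#' @export
referenceSequence <- function(msa) {
  gsub("-", "", as.character(msa@alignment[[msa@reference]]), fixed = TRUE)
}

#' @export
setMethod("show", "ReferenceMsa", function(object) {
  cat(sprintf("ReferenceMsa: %d rows x %d columns, reference '%s'\n",
              length(object@alignment), width(object@alignment)[1],
              object@reference))
})

#' Select the top significant homology hit per species
#'
#' For one query protein, keeps at most one hit per species: the hit with
#' minimal e-value, ties broken by maximal bit score, then by input order.
#' Hits above the e-value threshold are discarded; species with no passing
#' hit are absent from the result (downstream they count as not conserved).
#'
#' @param hits data.frame as from [readHitTable()]; all rows must share one
#'   `query_accession`.
#' @param threshold e-value significance threshold (default 1e-5).
#' @return data.frame with one row per species that has a passing hit.
#' @examples
#' hits <- data.frame(query_accession = "P1",
#'                    subject_accession = c("a", "b"),
#'                    species_id = c("mouse", "mouse"),
#'                    e_value = c(1e-10, 1e-3), bit_score = c(200, 50))
#' selectTopHits(hits)  # keeps the 1e-10 hit
#' @export
selectTopHits <- function(hits, threshold = 1e-5) {
  if (length(unique(hits$query_accession)) > 1) {
    stop("selectTopHits expects hits for a single query")
  }
  hits <- hits[hits$e_value <= threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(hits)
  }
  hits$.ord <- seq_len(nrow(hits))
  keep <- do.call(rbind, lapply(split(hits, hits$species_id), function(h) {
    h <- h[h$e_value == min(h$e_value), , drop = FALSE]
    h <- h[h$bit_score == max(h$bit_score), , drop = FALSE]
    h[which.min(h$.ord), , drop = FALSE]
  }))
  keep <- keep[order(keep$.ord), , drop = FALSE]
  keep$.ord <- NULL
  rownames(keep) <- NULL
  keep
}

#' Alignment parameters for the built-in pairwise aligner
#'
#' @param substitutionMatrix name of a Biostrings substitution matrix
#'   (default BLOSUM62).
#' @param gapOpening nonnegative gap-open penalty (default 11).
#' @param gapExtension nonnegative gap-extend penalty (default 1).
#' @return list of validated parameters.
#' @export
alignmentParams <- function(substitutionMatrix = "BLOSUM62",
                            gapOpening = 11, gapExtension = 1) {
  stopifnot(gapOpening >= 0, gapExtension >= 0)
  list(substitutionMatrix = substitutionMatrix,
       gapOpening = gapOpening, gapExtension = gapExtension)
}

# pairwise global alignment of one subject to the reference; returns the two
# aligned strings
alignPair <- function(refSeq, subjSeq, params) {
  pa <- pairwiseAlignment(Biostrings::AAString(refSeq),
                          Biostrings::AAString(subjSeq),
                          type = "global",
                          substitutionMatrix = params$substitutionMatrix,
                          gapOpening = params$gapOpening,
                          gapExtension = params$gapExtension)
  list(ref = as.character(alignedPattern(pa)),
       subj = as.character(alignedSubject(pa)))
}

#' Build a reference-anchored star alignment
#'
#' Each subject is aligned globally to the reference and the pairwise
#' alignments are merged through shared reference coordinates: for every
#' inter-residue gap slot of the reference the maximum insertion length over
#' subjects is allocated. Ungapping the reference row always reproduces the
#' reference sequence, which is the only property conservation scoring
#' relies on. Externally produced alignments can be loaded with [readMsa()]
#' instead.
#'
#' @param reference named character scalar or AAStringSet of length 1 (the
#'   reference protein; the name becomes the reference row id).
#' @param subjects AAStringSet of subject sequences; names become row ids
#'   (use `"species|accession"`).
#' @param params see [alignmentParams()].
#' @return a [ReferenceMsa-class].
#' @export
buildStarMsa <- function(reference, subjects, params = alignmentParams()) {
  if (is(reference, "XStringSet")) {
    refName <- names(reference)[1]
    refSeq <- as.character(reference[[1]])
  } else {
    refName <- names(reference)[1]
    if (is.null(refName)) refName <- "reference"
    refSeq <- as.character(reference[[1]])
  }
  if (length(subjects) == 0) stop("buildStarMsa needs >= 1 subject")
  subjSeqs <- as.character(subjects)
  pairs <- lapply(subjSeqs, alignPair, refSeq = refSeq, params = params)

  n <- nchar(refSeq)
  # insertion length after reference position i (slot i+1; slot 1 = before
  # position 1) for each pairwise alignment
  insLen <- function(pair) {
    refChars <- strsplit(pair$ref, "")[[1]]
    slots <- integer(n + 1L)
    pos <- 0L
    for (ch in refChars) {
      if (ch == "-") slots[pos + 1L] <- slots[pos + 1L] + 1L else pos <- pos + 1L
    }
    slots
  }
  allSlots <- vapply(pairs, insLen, integer(n + 1L))
  if (is.null(dim(allSlots))) allSlots <- matrix(allSlots, ncol = 1L)
  maxSlots <- apply(allSlots, 1L, max)

  refChars <- strsplit(refSeq, "")[[1]]
  buildRow <- function(pair = NULL, slots = NULL) {
    # walks the pairwise alignment emitting, per slot, the subject's inserted
    # residues padded to the slot width, then the subject residue aligned to
    # the next reference position
    out <- character(0)
    if (is.null(pair)) { # reference row
      for (i in seq_len(n + 1L)) {
        out <- c(out, strrep("-", maxSlots[i]),
                 if (i <= n) refChars[i] else character(0))
      }
      return(paste(out, collapse = ""))
    }
    refA <- strsplit(pair$ref, "")[[1]]
    subjA <- strsplit(pair$subj, "")[[1]]
    pos <- 0L
    ins <- character(0)
    pieces <- character(0)
    emit <- function(slotIns, resChar, slotIdx) {
      pad <- strrep("-", maxSlots[slotIdx] - nchar(slotIns))
      paste0(slotIns, pad, resChar)
    }
    for (j in seq_along(refA)) {
      if (refA[j] == "-") {
        ins <- c(ins, subjA[j])
      } else {
        pos <- pos + 1L
        pieces <- c(pieces, emit(paste(ins, collapse = ""), subjA[j], pos))
        ins <- character(0)
      }
    }
    trail <- paste(ins, collapse = "")
    pieces <- c(pieces, paste0(trail,
                               strrep("-", maxSlots[n + 1L] - nchar(trail))))
    paste(pieces, collapse = "")
  }
  rows <- c(buildRow(), vapply(pairs, function(p) buildRow(pair = p), ""))
  names(rows) <- c(refName, names(subjects))
  new("ReferenceMsa", alignment = AAStringSet(rows), reference = refName)
}

#' Map reference residue positions to alignment columns
#'
#' @param msa a [ReferenceMsa-class].
#' @return integer vector: element `i` is the alignment column of reference
#'   position `i`; length equals the ungapped reference length.
#' @examples
#' msa <- new("ReferenceMsa",
#'            alignment = Biostrings::AAStringSet(c(H = "A-CD", M = "ABCD")),
#'            reference = "H")
#' mapReferencePositions(msa)  # c(1, 3, 4)
#' @export
mapReferencePositions <- function(msa) {
  stopifnot(is(msa, "ReferenceMsa"))
  refRow <- strsplit(as.character(msa@alignment[[msa@reference]]), "")[[1]]
  which(refRow != "-")
}
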
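# shared fixture builders; everything is generated in code at test time

makeMsa <- function(rows, reference = names(rows)[1]) {
  new("ReferenceMsa", alignment = Biostrings::AAStringSet(rows),
      reference = reference)
}

# a small registry: 2 primates, 2 other mammals, 2 fish, 2 fungi
tinyRegistry <- function() {
  speciesRegistry(data.frame(
    species_id = c("pri1", "pri2", "mam1", "mam2", "fish1", "fish2",
                   "fun1", "fun2"),
    base_group = rep(c("primates", "other_mammals", "fish", "fungi"),
                     each = 2)))
}

tinySites <- function(accession, positions, residues, evidence = 10L) {
  data.frame(accession = accession, residue = residues, position = positions,
             evidence_count = evidence, stringsAsFactors = FALSE)
}

# independent brute-force conservation scanner used as the oracle: walks the
# raw alignment strings character by character, never calling the package's
# mapping helpers
oracleScan <- function(msa, position, stEquivalent = TRUE) {
  rows <- as.character(msa@alignment)
  ref <- rows[[msa@reference]]
  refChars <- strsplit(ref, "")[[1]]
  # locate the column of the position-th non-gap reference character
  seen <- 0L
  col <- NA_integer_
  for (j in seq_along(refChars)) {
    if (refChars[j] != "-") {
      seen <- seen + 1L
      if (seen == position) { col <- j; break }
    }
  }
  refRes <- refChars[col]
  out <- logical(0)
  for (id in setdiff(names(rows), msa@reference)) {
    subj <- substr(rows[[id]], col, col)
    conserved <- if (subj %in% c("-", "X") || refRes %in% c("-", "X")) {
      FALSE
    } else if (subj == refRes) {
      TRUE
    } else {
      stEquivalent && refRes %in% c("S", "T") && subj %in% c("S", "T")
    }
    out[id] <- conserved
  }
  out
}

# random gapped MSA over a given species set; reference has no leading
# constraints, rows may contain gaps and X
randomMsa <- function(nspecies, len, refLen = NULL) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  refSeq <- paste(sample(aa, len, replace = TRUE), collapse = "")
  # insert random gaps into reference and subjects independently at shared width
  width <- len + sample(0:5, 1)
  placeRow <- function(seqChars) {
    gaps <- width - length(seqChars)
    pos <- sort(sample(width, gaps))
    row <- character(width)
    row[pos] <- "-"
    row[setdiff(seq_len(width), pos)] <- seqChars
    paste(row, collapse = "")
  }
  rows <- c(REF = placeRow(strsplit(refSeq, "")[[1]]))
  for (i in seq_len(nspecies)) {
    chars <- sample(c(aa, "X"), width, replace = TRUE,
                    prob = c(rep(1, 20), 2) / 22)
    ngap <- sample(0:width, 1)
    chars[sample(width, ngap)] <- "-"
    rows[sprintf("sp%02d|acc%d", i, i)] <- paste(chars, collapse = "")
  }
  makeMsa(rows)
}
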
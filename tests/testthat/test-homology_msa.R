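test_that("selectTopHits keeps the minimal-e-value hit per species", {
  hits <- data.frame(
    query_accession = "Q",
    subject_accession = c("m1", "m2", "f1"),
    species_id = c("mouse", "mouse", "fly"),
    e_value = c(1e-10, 1e-3, 1e-4),
    bit_score = c(200, 60, 50), stringsAsFactors = FALSE)
  top <- selectTopHits(hits, threshold = 1e-5)
  expect_equal(nrow(top), 1)                       # fly fails the threshold
  expect_equal(top$subject_accession, "m1")

  # e-value ties break by bit score, then input order
  tie <- data.frame(query_accession = "Q",
                    subject_accession = c("a", "b", "c"),
                    species_id = "mouse", e_value = 1e-8,
                    bit_score = c(50, 80, 80), stringsAsFactors = FALSE)
  expect_equal(selectTopHits(tie)$subject_accession, "b")

  expect_error(selectTopHits(data.frame(query_accession = c("Q1", "Q2"),
                                        subject_accession = "x",
                                        species_id = "m", e_value = 1e-9,
                                        bit_score = 1)),
               "single query")
})

test_that("selectTopHits is invariant under input shuffling (modulo order tie-break)", {
  set.seed(11)
  hits <- data.frame(
    query_accession = "Q",
    subject_accession = sprintf("s%02d", 1:20),
    species_id = sample(c("m", "f", "y", "w"), 20, replace = TRUE),
    e_value = 10^-sample(6:30, 20, replace = TRUE),
    bit_score = sample(50:300, 20), stringsAsFactors = FALSE)
  # make minima unique so the order tie-break never engages
  hits <- hits[!duplicated(paste(hits$species_id, hits$e_value)), ]
  ref <- selectTopHits(hits)
  for (i in 1:5) {
    sh <- hits[sample(nrow(hits)), ]
    got <- selectTopHits(sh)
    expect_equal(got[order(got$species_id), ], ref[order(ref$species_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("buildStarMsa anchors subjects to the reference", {
  ref <- c(REF = "ACDE")
  # identity subject: gapless two-row MSA
  msa <- buildStarMsa(ref, Biostrings::AAStringSet(c("m|a" = "ACDE")))
  expect_equal(unname(Biostrings::width(msa@alignment)), c(4L, 4L))
  expect_identical(as.character(msa@alignment[["REF"]]), "ACDE")

  # deletion subject: brute-force enumeration of all global alignments under
  # the configured scoring confirms the optimal placement of the single gap
  msa2 <- buildStarMsa(ref, Biostrings::AAStringSet(c("m|a" = "ACE")))
  subjRow <- as.character(msa2@alignment[["m|a"]])
  expect_identical(referenceSequence(msa2), "ACDE")
  expect_equal(lengths(regmatches(subjRow, gregexpr("-", subjRow))), 1)

  data("BLOSUM62", package = "Biostrings", envir = environment())
  enumerate <- function(a, b) {
    # all global alignments as pairs of aligned strings
    if (nchar(a) == 0 && nchar(b) == 0) return(list(c("", "")))
    out <- list()
    if (nchar(a) > 0 && nchar(b) > 0) {
      for (al in enumerate(substr(a, 2, nchar(a)), substr(b, 2, nchar(b)))) {
        out <- c(out, list(c(paste0(substr(a, 1, 1), al[1]),
                             paste0(substr(b, 1, 1), al[2]))))
      }
    }
    if (nchar(a) > 0) {
      for (al in enumerate(substr(a, 2, nchar(a)), b)) {
        out <- c(out, list(c(paste0(substr(a, 1, 1), al[1]),
                             paste0("-", al[2]))))
      }
    }
    if (nchar(b) > 0) {
      for (al in enumerate(a, substr(b, 2, nchar(b)))) {
        out <- c(out, list(c(paste0("-", al[1]),
                             paste0(substr(b, 1, 1), al[2]))))
      }
    }
    out
  }
  scoreAln <- function(al, open = 11, ext = 1) {
    a <- strsplit(al[1], "")[[1]]; b <- strsplit(al[2], "")[[1]]
    s <- 0; inGapA <- FALSE; inGapB <- FALSE
    for (i in seq_along(a)) {
      if (a[i] == "-") {
        s <- s - ext - (!inGapA) * open; inGapA <- TRUE; inGapB <- FALSE
      } else if (b[i] == "-") {
        s <- s - ext - (!inGapB) * open; inGapB <- TRUE; inGapA <- FALSE
      } else {
        s <- s + BLOSUM62[a[i], b[i]]; inGapA <- inGapB <- FALSE
      }
    }
    s
  }
  alns <- enumerate("ACDE", "ACE")
  scores <- vapply(alns, scoreAln, numeric(1))
  best <- alns[[which.max(scores)]]
  expect_identical(subjRow, best[2])
  expect_identical(as.character(msa2@alignment[["REF"]]), best[1])

  expect_error(buildStarMsa(ref, Biostrings::AAStringSet()), "subject")
})

test_that("star MSA of identical subjects is gapless and multi-subject merging preserves the reference", {
  ref <- c(REF = "MKVLSTAY")
  subj <- Biostrings::AAStringSet(c("a|1" = "MKVLSTAY", "b|2" = "MKVLSTAY",
                                    "c|3" = "MKVLSTAY"))
  msa <- buildStarMsa(ref, subj)
  expect_false(any(grepl("-", as.character(msa@alignment))))

  subj2 <- Biostrings::AAStringSet(c("a|1" = "MKVLSTAY", "b|2" = "MKVSTAY",
                                     "c|3" = "MKVLWWSTAY"))
  msa2 <- buildStarMsa(ref, subj2)
  expect_identical(referenceSequence(msa2), "MKVLSTAY")
  expect_gte(Biostrings::width(msa2@alignment)[1], 8L)
  # every subject row ungaps to its input sequence
  for (id in names(subj2)) {
    expect_identical(gsub("-", "", as.character(msa2@alignment[[id]])),
                     as.character(subj2[[id]]))
  }
})

test_that("mapReferencePositions is the gap-aware bijection", {
  msa <- makeMsa(c(H = "A-CD", M = "ABCD"))
  expect_equal(mapReferencePositions(msa), c(1L, 3L, 4L))
  gapless <- makeMsa(c(H = "ACD", M = "ACD"))
  expect_equal(mapReferencePositions(gapless), 1:3)

  # property: map size equals ungapped length and recovers each residue
  set.seed(7)
  for (i in 1:20) {
    msa <- randomMsa(nspecies = 3, len = sample(5:30, 1))
    pm <- mapReferencePositions(msa)
    refSeq <- referenceSequence(msa)
    expect_length(pm, nchar(refSeq))
    refRow <- as.character(msa@alignment[[msa@reference]])
    for (p in seq_along(pm)) {
      expect_identical(substr(refRow, pm[p], pm[p]), substr(refSeq, p, p))
    }
  }
})
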
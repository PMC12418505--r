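#' Propagate phosphosites to aligned species sequences
#'
#' For every site and every subject row of its alignment, a phosphosite is
#' predicted in the target sequence when both the residue aligned with the
#' reference phosphosite and the residue aligned with its +1 neighbor are
#' conserved (Ser/Thr substitutions allowed where the reference residue is S
#' or T). The +1 comparison is made at the column of reference position + 1
#' by default; `plus1Mode = "target_adjacent"` instead compares the target's
#' own next residue. Reference C-terminal sites have no +1 residue to
#' compare, produce no predictions, and are returned in the skipped-site
#' report. Predicted positions are 1-based coordinates in the ungapped target
#' sequence.
#'
#' @param msa a [ReferenceMsa-class].
#' @param sites data.frame of phosphosites on the reference protein.
#' @param registry a [SpeciesRegistry-class]; predictions are restricted to
#'   registry species.
#' @param stEquivalent apply the Ser/Thr substitution rule.
#' @param plus1Mode `"column"` (reference-anchored, default) or
#'   `"target_adjacent"`.
#' @return list with `predictions` (data.frame: species_id, accession,
#'   position, residue, plus1_residue, source_accession, source_position,
#'   source_residue) and `skipped` (data.frame of C-terminal sites).
#' @export
propagateSites <- function(msa, sites, registry,
                           stEquivalent = TRUE,
                           plus1Mode = c("column", "target_adjacent")) {
  plus1Mode <- match.arg(plus1Mode)
  posmap <- mapReferencePositions(msa)
  refSeq <- referenceSequence(msa)
  n <- nchar(refSeq)
  rows <- setdiff(msaRowIds(msa), msa@reference)
  rowSpecies <- msaRowSpecies(msa)[match(rows, msaRowIds(msa))]
  inReg <- rowSpecies %in% speciesIds(registry)
  rows <- rows[inReg]
  rowSpecies <- rowSpecies[inReg]

  alnChars <- lapply(rows, function(r) {
    strsplit(as.character(msa@alignment[[r]]), "")[[1]]
  })
  names(alnChars) <- rows
  # target (ungapped) position of each alignment column, per row
  targetPos <- lapply(alnChars, function(ch) cumsum(ch != "-"))

  preds <- list()
  skipped <- list()
  for (i in seq_len(nrow(sites))) {
    pos <- sites$position[i]
    if (pos < 1 || pos > n) {
      stop(sprintf("site position %d outside reference 1..%d", pos, n))
    }
    refRes <- substr(refSeq, pos, pos)
    if (pos >= n) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        accession = sites$accession[i], position = pos, residue = refRes,
        reason = "no +1 residue (reference C-terminal)",
        stringsAsFactors = FALSE)
      next
    }
    col <- posmap[pos]
    col1 <- posmap[pos + 1L]
    refRes1 <- substr(refSeq, pos + 1L, pos + 1L)
    for (j in seq_along(rows)) {
      ch <- alnChars[[j]]
      subjRes <- ch[col]
      if (!residueConserved(refRes, subjRes, stEquivalent)) next
      if (plus1Mode == "column") {
        subjRes1 <- ch[col1]
      } else {
        tpos1 <- targetPos[[j]][col] + 1L
        nt <- targetPos[[j]][length(ch)]
        subjRes1 <- if (tpos1 > nt) "-" else {
          ch[which(targetPos[[j]] == tpos1 & ch != "-")[1]]
        }
      }
      if (!residueConserved(refRes1, subjRes1, stEquivalent)) next
      acc <- sub("^[^|]*\\|", "", rows[j])
      preds[[length(preds) + 1L]] <- data.frame(
        species_id = rowSpecies[j], accession = acc,
        position = targetPos[[j]][col], residue = subjRes,
        plus1_residue = subjRes1,
        source_accession = sites$accession[i], source_position = pos,
        source_residue = refRes, stringsAsFactors = FALSE)
    }
  }
  emptyPred <- data.frame(species_id = character(0), accession = character(0),
                          position = integer(0), residue = character(0),
                          plus1_residue = character(0),
                          source_accession = character(0),
                          source_position = integer(0),
                          source_residue = character(0),
                          stringsAsFactors = FALSE)
  emptySkip <- data.frame(accession = character(0), position = integer(0),
                          residue = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  list(predictions = if (length(preds)) do.call(rbind, preds) else emptyPred,
       skipped = if (length(skipped)) do.call(rbind, skipped) else emptySkip)
}

#' Validate propagated predictions against an evidence table
#'
#' Per residue class (Ser/Thr pooled and Tyr): the fraction of predictions
#' with any experimental evidence, and the fraction of evidenced predictions
#' supported by strong evidence (evidence count >= `minStrong`, default 5).
#'
#' @param predictions prediction data.frame from [propagateSites()].
#' @param evidence data.frame with accession, position, evidence_count in
#'   target coordinates.
#' @param minStrong strong-evidence threshold.
#' @return data.frame: residue_class, n_predictions, n_evidenced,
#'   percent_any_evidence, n_strong, percent_strong_of_evidenced.
#' @export
validatePredictions <- function(predictions, evidence, minStrong = 5L) {
  if (nrow(predictions) == 0) stop("empty prediction set")
  evKey <- paste(evidence$accession, evidence$position, sep = ":")
  evCount <- evidence$evidence_count
  names(evCount) <- evKey
  predKey <- paste(predictions$accession, predictions$position, sep = ":")
  cls <- ifelse(predictions$residue == "Y", "Y", "ST")
  out <- lapply(c("ST", "Y"), function(cl) {
    keys <- unique(predKey[cls == cl])
    if (length(keys) == 0) {
      return(data.frame(residue_class = cl, n_predictions = 0L,
                        n_evidenced = 0L, percent_any_evidence = NA_real_,
                        n_strong = 0L,
                        percent_strong_of_evidenced = NA_real_,
                        stringsAsFactors = FALSE))
    }
    has <- keys %in% evKey
    strong <- has & evCount[keys] >= minStrong
    strong[is.na(strong)] <- FALSE
    data.frame(residue_class = cl, n_predictions = length(keys),
               n_evidenced = sum(has),
               percent_any_evidence = 100 * mean(has),
               n_strong = sum(strong),
               percent_strong_of_evidenced =
                 if (any(has)) 100 * sum(strong) / sum(has) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize predictions per species and group
#'
#' Counts of predicted Ser, Thr and Tyr phosphosites per species, with the
#' species' base group attached, plus per-group totals.
#'
#' @param predictions prediction data.frame from [propagateSites()] (rows
#'   from several alignments may be concatenated).
#' @param registry a [SpeciesRegistry-class].
#' @return list with `per_species` and `per_group` data.frames.
#' @export
summarizeByGroup <- function(predictions, registry) {
  st <- speciesTable(registry)
  perSp <- do.call(rbind, lapply(st$species_id, function(s) {
    sel <- predictions$species_id == s
    data.frame(species_id = s,
               base_group = st$base_group[st$species_id == s],
               n_ser = sum(sel & predictions$residue == "S"),
               n_thr = sum(sel & predictions$residue == "T"),
               n_tyr = sum(sel & predictions$residue == "Y"),
               stringsAsFactors = FALSE)
  }))
  perSp$n_total <- perSp$n_ser + perSp$n_thr + perSp$n_tyr
  perGrp <- do.call(rbind, lapply(groupNames(registry), function(g) {
    sel <- perSp$species_id %in% groupMembers(registry, g)
    data.frame(group = g, n_species = sum(sel),
               n_ser = sum(perSp$n_ser[sel]), n_thr = sum(perSp$n_thr[sel]),
               n_tyr = sum(perSp$n_tyr[sel]),
               n_total = sum(perSp$n_total[sel]), stringsAsFactors = FALSE)
  }))
  list(per_species = perSp, per_group = perGrp)
}
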
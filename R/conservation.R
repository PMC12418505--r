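#' @importFrom stats t.test quantile median
NULL

# the Ser/Thr substitution-tolerance comparison for one residue pair.
# refRes is the reference residue at the compared position; subjRes the
# aligned residue in the subject row. Gaps and X never match; S/T are
# mutually conserving only when the reference residue itself is S or T.
residueConserved <- function(refRes, subjRes, stEquivalent = TRUE) {
  if (subjRes %in% c("-", "X") || refRes %in% c("-", "X")) return(FALSE)
  if (subjRes == refRes) return(TRUE)
  stEquivalent && refRes %in% c("S", "T") && subjRes %in% c("S", "T")
}

#' Is a reference site conserved in one aligned species row?
#'
#' A site counts as conserved when the subject residue in the column mapped
#' from the reference position equals the reference residue, or when both are
#' Ser/Thr and the substitution-tolerance rule is on (a Thr aligned with a
#' reference Ser counts, and vice versa). Gaps and ambiguity codes never
#' count.
#'
#' @param msa a [ReferenceMsa-class].
#' @param position 1-based position in the ungapped reference sequence.
#' @param row row id of the species sequence.
#' @param stEquivalent apply the Ser/Thr substitution rule (never applies to
#'   Tyr, which only matches itself).
#' @return logical scalar.
#' @export
siteConserved <- function(msa, position, row, stEquivalent = TRUE) {
  posmap <- mapReferencePositions(msa)
  if (position < 1 || position > length(posmap)) {
    stop(sprintf("position %d beyond reference length %d", position, length(posmap)))
  }
  if (!row %in% names(msa@alignment)) stop(sprintf("no row '%s' in MSA", row))
  col <- posmap[position]
  refRes <- substr(as.character(msa@alignment[[msa@reference]]), col, col)
  subjRes <- substr(as.character(msa@alignment[[row]]), col, col)
  residueConserved(refRes, subjRes, stEquivalent)
}

# per-site flags for every row of one MSA; returns list(conserved, plus1)
# logical vectors named by row id (reference row excluded), plus1 all NA when
# the site is reference C-terminal
siteFlagsForMsa <- function(msa, position, stEquivalent = TRUE) {
  posmap <- mapReferencePositions(msa)
  n <- length(posmap)
  if (position < 1 || position > n) {
    stop(sprintf("position %d beyond reference length %d", position, n))
  }
  rows <- setdiff(names(msa@alignment), msa@reference)
  refChars <- strsplit(as.character(msa@alignment[[msa@reference]]), "")[[1]]
  col <- posmap[position]
  refRes <- refChars[col]
  cons <- vapply(rows, function(r) {
    subjRes <- substr(as.character(msa@alignment[[r]]), col, col)
    residueConserved(refRes, subjRes, stEquivalent)
  }, logical(1))
  if (position < n) {
    col1 <- posmap[position + 1L]
    refRes1 <- refChars[col1]
    plus1 <- vapply(rows, function(r) {
      subjRes <- substr(as.character(msa@alignment[[r]]), col1, col1)
      residueConserved(refRes1, subjRes, stEquivalent)
    }, logical(1))
  } else {
    plus1 <- rep(NA, length(rows))
    names(plus1) <- rows
  }
  list(conserved = cons, plus1 = plus1)
}

#' Compute conservation profiles for a set of phosphosites
#'
#' For every site, a conservation flag and a +1-residue flag are computed for
#' every registry species. Species without a row in the site's alignment get
#' flag `FALSE` (the full group is always the percentage denominator).
#' Multiple rows for one species (not expected after top-hit selection) are
#' reduced by any().
#'
#' @param msas named list of [ReferenceMsa-class], keyed by reference
#'   protein accession.
#' @param sites data.frame of phosphosites ([readSiteTable()]); sites whose
#'   accession has no alignment are scored all-FALSE.
#' @param registry a [SpeciesRegistry-class].
#' @param stEquivalent apply the Ser/Thr substitution rule.
#' @return a [SiteConservation-class] (sites x species).
#' @export
profileSites <- function(msas, sites, registry, stEquivalent = TRUE) {
  sp <- speciesIds(registry)
  ns <- nrow(sites)
  cons <- matrix(FALSE, ns, length(sp), dimnames = list(NULL, sp))
  plus1 <- matrix(NA, ns, length(sp), dimnames = list(NULL, sp))
  for (acc in unique(sites$accession)) {
    idx <- which(sites$accession == acc)
    msa <- msas[[acc]]
    if (is.null(msa)) {
      plus1[idx, ] <- FALSE    # no alignment: nothing conserved, +1 defined
      next
    }
    posmap <- mapReferencePositions(msa)
    n <- length(posmap)
    mat <- as.matrix(msa@alignment)   # rows x columns, single characters
    refRow <- mat[msa@reference, ]
    subjIds <- setdiff(rownames(mat), msa@reference)
    rowsp <- msaRowSpecies(msa)[match(subjIds, msaRowIds(msa))]
    keep <- rowsp %in% sp
    subjIds <- subjIds[keep]
    rowsp <- rowsp[keep]
    flagsAt <- function(pos) {
      col <- posmap[pos]
      refRes <- refRow[col]
      subj <- mat[subjIds, col]
      ok <- !(subj %in% c("-", "X")) & !(refRes %in% c("-", "X")) &
        (subj == refRes |
           (stEquivalent & refRes %in% c("S", "T") & subj %in% c("S", "T")))
      ok
    }
    for (i in idx) {
      pos <- sites$position[i]
      if (pos < 1 || pos > n) {
        stop(sprintf("site %s:%d outside reference 1..%d", acc, pos, n))
      }
      refRes <- refRow[posmap[pos]]
      if (refRes != sites$residue[i]) {
        stop(sprintf("site %s:%d expects %s but reference has %s",
                     acc, pos, sites$residue[i], refRes))
      }
      fl <- flagsAt(pos)
      cterm <- pos >= n
      if (!cterm) {
        plus1[i, ] <- FALSE
        fl1 <- flagsAt(pos + 1L)
      }
      # one row per species after top-hit selection; duplicates reduced by any()
      consRow <- tapply(fl, rowsp, any)
      cons[i, names(consRow)] <- as.logical(consRow)
      if (!cterm) {
        p1Row <- tapply(fl1, rowsp, any)
        plus1[i, names(p1Row)] <- as.logical(p1Row)
      }
    }
  }
  se <- SummarizedExperiment(
    assays = list(conserved = cons, plus1 = plus1),
    rowData = DataFrame(sites),
    colData = DataFrame(speciesTable(registry), row.names = sp),
    metadata = list(registry = registry))
  new("SiteConservation", se)
}

#' Per-group conservation percentages
#'
#' `groupPercent[i, g]` = 100 x (conserved species of group g at site i) /
#' |g|. Species missing from the alignment count as not conserved, so the
#' denominator is always the full group size.
#'
#' @param x a [SiteConservation-class].
#' @param assayName `"conserved"` (default) or `"plus1"` (NA flags count as
#'   not conserved there).
#' @return numeric matrix, sites x groups, values in \[0, 100\].
#' @export
groupPercent <- function(x, assayName = "conserved") {
  stopifnot(is(x, "SiteConservation"))
  reg <- metadata(x)$registry
  m <- assay(x, assayName)
  cols <- lapply(groupNames(reg), function(g) {
    members <- groupMembers(reg, g)
    sub <- m[, members, drop = FALSE]
    sub[is.na(sub)] <- FALSE
    100 * rowSums(sub) / length(members)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- groupNames(reg)
  out
}

#' Average per-protein conservation profiles by residue class
#'
#' Averages the group-percentage vectors of a protein's sites of one residue
#' class (Ser/Thr pooled, or Tyr), the protein-level summary used for
#' clustering. Proteins with no site of the class are absent from the result.
#'
#' @param x a [SiteConservation-class].
#' @param residueClass `"ST"` or `"Y"`.
#' @return matrix proteins x groups (rownames are accessions).
#' @export
proteinProfiles <- function(x, residueClass = c("ST", "Y")) {
  residueClass <- match.arg(residueClass)
  keep <- if (residueClass == "ST") {
    rowData(x)$residue %in% c("S", "T")
  } else {
    rowData(x)$residue == "Y"
  }
  if (!any(keep)) {
    return(matrix(numeric(0), 0, length(groupNames(metadata(x)$registry)),
                  dimnames = list(NULL, groupNames(metadata(x)$registry))))
  }
  gp <- groupPercent(x)[keep, , drop = FALSE]
  acc <- rowData(x)$accession[keep]
  sums <- rowsum(gp, acc)
  counts <- table(acc)
  sums / as.vector(counts[rownames(sums)])
}

#' Classify a disorder score
#'
#' Scores above 0.5 (strict) are disordered.
#'
#' @param score numeric in \[0,1\] (vectorized).
#' @return character vector, `"ordered"` or `"disordered"`.
#' @export
classifyDisorder <- function(score) {
  if (any(score < 0 | score > 1)) stop("disorder score outside [0,1]")
  ifelse(score > 0.5, "disordered", "ordered")
}

#' Tukey box statistics
#'
#' Box from first to third quartile; whiskers extend to the farthest data
#' point within 1.5 x IQR of the box; points beyond are outliers.
#'
#' @param values numeric vector.
#' @return list with q1, median, q3, whisker_low, whisker_high, outliers.
#' @export
boxStats <- function(values) {
  values <- values[!is.na(values)]
  qs <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lowFence <- qs[1] - 1.5 * iqr
  highFence <- qs[3] + 1.5 * iqr
  inside <- values[values >= lowFence & values <= highFence]
  list(q1 = qs[1], median = qs[2], q3 = qs[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lowFence | values > highFence]))
}

#' Compare two groups of conservation values
#'
#' Tukey box statistics per arm plus a Welch (unequal-variance) two-sample
#' t test. Used e.g. to compare ordered vs disordered regions or
#' interaction-evidenced vs other sites, per residue type.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each for the test).
#' @return list with `stats_a`, `stats_b`, `t_statistic`, `p_value` (the test
#'   fields are NA when either arm has < 2 values or zero combined variance).
#' @export
compareGroups <- function(values_a, values_b) {
  sa <- boxStats(values_a)
  sb <- boxStats(values_b)
  tt <- NULL
  if (length(values_a) >= 2 && length(values_b) >= 2 &&
      (stats::var(values_a) > 0 || stats::var(values_b) > 0)) {
    tt <- t.test(values_a, values_b, var.equal = FALSE)
  }
  list(stats_a = sa, stats_b = sb,
       t_statistic = if (is.null(tt)) {
         if (isTRUE(all.equal(mean(values_a), mean(values_b)))) 0 else NA_real_
       } else unname(tt$statistic),
       p_value = if (is.null(tt)) {
         if (isTRUE(all.equal(mean(values_a), mean(values_b)))) 1 else NA_real_
       } else tt$p.value)
}

#' @export
setMethod("show", "SiteConservation", function(object) {
  cat(sprintf("SiteConservation: %d sites x %d species (%d groups)\n",
              nrow(object), ncol(object),
              length(groupNames(metadata(object)$registry))))
})
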
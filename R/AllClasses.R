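#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' SpeciesRegistry: species and overlapping taxon groups
#'
#' Holds the species under analysis together with a named system of taxon
#' groups. Base groups partition the species (every species belongs to
#' exactly one); broader groups (e.g. mammals, vertebrates, animals) are
#' unions of base groups, so a species can belong to several groups at once.
#' Conservation percentages are always computed per group with the full group
#' size as denominator.
#'
#' @slot species a [S4Vectors::DataFrame] with columns `species_id`,
#'   `display_name`, `proteome_id` and `base_group`.
#' @slot groups named list of character vectors of `species_id`s; contains
#'   every base group plus the broader groups.
#' @slot broader named list mapping each broader-group name to the base
#'   groups whose union it must equal.
#'
#' @seealso [speciesRegistry()], [defaultRegistry()]
#' @export
setClass("SpeciesRegistry",
  representation(
    species = "DataFrame",
    groups = "list",
    broader = "list"
  )
)

setValidity("SpeciesRegistry", function(object) {
  sp <- object@species
  msgs <- character()
  need <- c("species_id", "display_name", "proteome_id", "base_group")
  if (!all(need %in% colnames(sp))) {
    return(sprintf("species table must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sp$species_id)) {
    msgs <- c(msgs, "duplicated species_id")
  }
  base <- setdiff(names(object@groups), names(object@broader))
  if (!all(sp$base_group %in% base)) {
    msgs <- c(msgs, "every species must belong to a base group present in 'groups'")
  }
  for (g in names(object@groups)) {
    if (!all(object@groups[[g]] %in% sp$species_id)) {
      msgs <- c(msgs, sprintf("group '%s' names unknown species", g))
    }
  }
  for (b in names(object@broader)) {
    want <- sort(unlist(object@groups[object@broader[[b]]], use.names = FALSE))
    have <- sort(object@groups[[b]])
    if (!identical(want, have)) {
      msgs <- c(msgs, sprintf("broader group '%s' is not the union of its base groups", b))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ReferenceMsa: a reference-anchored multiple sequence alignment
#'
#' An alignment of one reference protein (the sequence carrying annotated
#' phosphosites) with candidate orthologues from other species. All rows have
#' equal aligned length and ungapping the reference row reproduces the
#' reference protein sequence. Subject row ids follow the
#' `"species|accession"` convention; a row id without `|` is taken to be a
#' bare species id.
#'
#' @slot alignment an [Biostrings::AAStringSet] of equal-width aligned rows,
#'   names are row ids.
#' @slot reference the row id of the reference sequence.
#'
#' @seealso [readMsa()], [buildStarMsa()], [mapReferencePositions()]
#' @export
setClass("ReferenceMsa",
  representation(
    alignment = "AAStringSet",
    reference = "character"
  )
)

setValidity("ReferenceMsa", function(object) {
  aln <- object@alignment
  if (length(aln) < 1) return("alignment has no rows")
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    return("alignment rows must have unique names")
  }
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1) {
    bad <- names(aln)[w != w[1]][1]
    return(sprintf("aligned rows have unequal lengths (offending record: %s)", bad))
  }
  if (length(object@reference) != 1 || !(object@reference %in% names(aln))) {
    return("reference must name exactly one alignment row")
  }
  TRUE
})

#' SiteConservation: per-site, per-species conservation flags
#'
#' A [SummarizedExperiment::SummarizedExperiment] with phosphosites as rows
#' and registry species as columns. Assay `"conserved"` holds the logical
#' site-conservation flag (Ser/Thr substitution rule applied; gaps, X and
#' species missing from the alignment are `FALSE`). Assay `"plus1"` holds the
#' conservation flag of the reference +1 residue, `NA` for reference
#' C-terminal sites. The registry lives in `metadata(x)$registry`.
#'
#' @seealso [profileSites()], [groupPercent()]
#' @export
setClass("SiteConservation", contains = "SummarizedExperiment")

setValidity("SiteConservation", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("conserved", "plus1") %in% a)) {
    return("assays 'conserved' and 'plus1' are required")
  }
  if (!is(metadata(object)$registry, "SpeciesRegistry")) {
    return("metadata(x)$registry must be a SpeciesRegistry")
  }
  need <- c("accession", "residue", "position")
  if (!all(need %in% colnames(rowData(object)))) {
    return("rowData must carry accession, residue, position")
  }
  TRUE
})
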
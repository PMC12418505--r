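#' @importFrom utils read.delim write.table
#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet width
NULL

stopFormat <- function(fmt, ...) stop(sprintf(paste0("format error: ", fmt), ...),
                                      call. = FALSE)

#' Read a proteome FASTA
#'
#' Sequences are uppercased on read; characters outside the 20 standard
#' amino-acid letters plus X are rejected (X never counts as conserved
#' downstream).
#'
#' @param path FASTA file.
#' @param species_id optional species id stored in `mcols()`.
#' @return an [Biostrings::AAStringSet], names are accessions.
#' @export
readProteome <- function(path, species_id = NA_character_) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  seqs <- readAAStringSet(path)
  if (length(seqs) == 0) stopFormat("empty FASTA: %s", path)
  # keep first token of header as accession
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(seqs))) {
    stopFormat("duplicated accession in %s: %s", path,
               names(seqs)[duplicated(names(seqs))][1])
  }
  seqs <- AAStringSet(toupper(as.character(seqs)))
  if (any(width(seqs) == 0)) stopFormat("empty sequence in %s", path)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", as.character(seqs))
  if (any(bad)) {
    stopFormat("non-standard residue in record %s", names(seqs)[bad][1])
  }
  S4Vectors::mcols(seqs)$species_id <- species_id
  seqs
}

#' Write a proteome FASTA
#' @param seqs an AAStringSet
#' @param path output file
#' @export
writeProteome <- function(seqs, path) {
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an aligned FASTA into a ReferenceMsa
#'
#' All records must have equal aligned length. The reference row is the first
#' record by default (alignments conventionally place the reference sequence
#' at the top), overridable by id.
#'
#' @param path aligned FASTA.
#' @param reference row id of the reference sequence, or `NULL` for the first
#'   record.
#' @return a [ReferenceMsa-class].
#' @export
readMsa <- function(path, reference = NULL) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  rows <- tryCatch(readAAStringSet(path),
                   error = function(e) stopFormat("unreadable FASTA %s: %s",
                                                  path, conditionMessage(e)))
  if (length(rows) < 2) stopFormat("alignment %s needs >= 2 records", path)
  names(rows) <- vapply(strsplit(names(rows), "\\s+"), `[`, "", 1L)
  w <- width(rows)
  if (length(unique(w)) != 1) {
    stopFormat("unequal aligned lengths in %s (offending record: %s)",
               path, names(rows)[w != w[1]][1])
  }
  rows <- AAStringSet(toupper(as.character(rows)))
  if (is.null(reference)) reference <- names(rows)[1]
  new("ReferenceMsa", alignment = rows, reference = reference)
}

#' Write a ReferenceMsa as aligned FASTA
#' @param msa a ReferenceMsa
#' @param path output file
#' @export
writeMsa <- function(msa, path) {
  stopifnot(is(msa, "ReferenceMsa"))
  writeXStringSet(msa@alignment, path)
  invisible(path)
}

#' Read a phosphosite table
#'
#' TSV with header columns `accession`, `residue`, `position`,
#' `evidence_count`. Rows below the evidence threshold are dropped; the
#' default threshold of 5 defines the gold-standard set (at least five pieces
#' of positive identification evidence).
#'
#' @param path TSV file.
#' @param min_evidence minimum evidence count to keep a row.
#' @return data.frame of sites (1-based positions).
#' @export
readSiteTable <- function(path, min_evidence = 5L) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "residue", "position", "evidence_count")
  if (!all(need %in% colnames(df))) {
    stopFormat("site table %s must have columns %s", path,
               paste(need, collapse = ", "))
  }
  df$residue <- toupper(df$residue)
  bad <- !df$residue %in% c("S", "T", "Y")
  if (any(bad)) stopFormat("residue not in {S,T,Y} at row %d", which(bad)[1])
  if (!is.numeric(df$position) || any(df$position < 1) ||
      any(df$position != as.integer(df$position))) {
    stopFormat("positions must be positive integers (1-based)")
  }
  df$position <- as.integer(df$position)
  df$evidence_count <- as.integer(df$evidence_count)
  if (any(is.na(df$evidence_count)) || any(df$evidence_count < 0)) {
    stopFormat("evidence_count must be a nonnegative integer")
  }
  df[df$evidence_count >= min_evidence, , drop = FALSE]
}

#' Write a phosphosite table
#' @param sites data.frame as returned by [readSiteTable()]
#' @param path output file
#' @export
writeSiteTable <- function(sites, path) {
  writeTsv(sites[c("accession", "residue", "position", "evidence_count")], path)
}

#' Read InterProScan TSV domain spans
#'
#' InterProScan's TSV dialect has no header; columns 1 (protein accession),
#' 7 (start), 8 (stop) and 12 (InterPro id) are used, rows lacking an
#' InterPro id (empty or "-") are skipped. `file_rank` records the original
#' row order, which drives the first-match rule when a site falls in several
#' overlapping domains.
#'
#' @param path InterProScan TSV.
#' @return data.frame with accession, start, stop, interpro_id, file_rank
#'   (coordinates 1-based inclusive).
#' @export
readInterproTsv <- function(path) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", fill = TRUE, quote = "")
  if (ncol(df) < 12) stopFormat("%s has fewer than 12 columns", path)
  out <- data.frame(accession = df[[1]], start_chr = df[[7]], stop_chr = df[[8]],
                    interpro_id = df[[12]], file_rank = seq_len(nrow(df)),
                    stringsAsFactors = FALSE)
  out <- out[!(out$interpro_id %in% c("", "-", NA)), , drop = FALSE]
  if (any(grepl("[^0-9]", out$start_chr)) || any(grepl("[^0-9]", out$stop_chr))) {
    stopFormat("non-integer coordinates in %s", path)
  }
  out$start <- as.integer(out$start_chr)
  out$stop <- as.integer(out$stop_chr)
  if (any(out$start > out$stop)) {
    stopFormat("start > stop at input row %d", out$file_rank[out$start > out$stop][1])
  }
  rownames(out) <- NULL
  out[c("accession", "start", "stop", "interpro_id", "file_rank")]
}

#' Read a 12-column tabular homology hit file
#'
#' The standard tabular alignment-output dialect: query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore. The species id is parsed from the subject field using
#' the `"species|accession"` convention; a subject without `|` yields
#' `NA` species.
#'
#' @param path hit table (no header).
#' @return data.frame with query_accession, subject_accession, species_id,
#'   e_value, bit_score.
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stopFormat("%s is not 12-column tabular output", path)
  subj <- as.character(df[[2]])
  hasbar <- grepl("|", subj, fixed = TRUE)
  species <- ifelse(hasbar, sub("\\|.*$", "", subj), NA_character_)
  acc <- ifelse(hasbar, sub("^[^|]*\\|", "", subj), subj)
  ev <- as.numeric(df[[11]])
  if (any(is.na(ev)) || any(ev < 0)) stopFormat("invalid e-value in %s", path)
  data.frame(query_accession = as.character(df[[1]]),
             subject_accession = acc, species_id = species,
             e_value = ev, bit_score = as.numeric(df[[12]]),
             stringsAsFactors = FALSE)
}

#' Read a species registry TSV
#'
#' Columns: species_id, display_name, proteome_id, base_group. Broader
#' groups are rebuilt from the default scheme.
#'
#' @param path TSV with header.
#' @param broader broader-group scheme, see [speciesRegistry()].
#' @return a [SpeciesRegistry-class].
#' @export
readRegistry <- function(path, broader = defaultBroaderScheme()) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "base_group") %in% colnames(df))) {
    stopFormat("registry %s needs species_id and base_group columns", path)
  }
  speciesRegistry(df, broader = broader)
}

#' Write a species registry TSV
#' @param registry a SpeciesRegistry
#' @param path output file
#' @export
writeRegistry <- function(registry, path) {
  writeTsv(speciesTable(registry), path)
}

#' Read a kinase-score table (site -> kinase -> score)
#' @param path TSV with header columns accession, position, kinase, score.
#' @return data.frame.
#' @export
readKinaseScores <- function(path) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "kinase", "score")
  if (!all(need %in% colnames(df))) {
    stopFormat("kinase score table %s needs columns %s", path,
               paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  df
}

#' Read an orthologue-group membership table (group -> species)
#' @param path TSV with header columns group_id, species_id (one row per
#'   group x species).
#' @return data.frame.
#' @export
readOrthoGroups <- function(path) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("group_id", "species_id") %in% colnames(df))) {
    stopFormat("orthologue table %s needs group_id and species_id", path)
  }
  df
}

#' Read a disorder-score table
#' @param path TSV with header columns accession, position, score (scores in
#'   \[0,1\]).
#' @return data.frame.
#' @export
readDisorderScores <- function(path) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "score")
  if (!all(need %in% colnames(df))) {
    stopFormat("disorder table %s needs columns %s", path,
               paste(need, collapse = ", "))
  }
  if (any(df$score < 0 | df$score > 1)) stopFormat("disorder scores outside [0,1]")
  df
}

#' Read an evidence table keyed by target coordinates
#' @param path TSV with header columns accession, position, evidence_count.
#' @return data.frame.
#' @export
readEvidenceTable <- function(path) {
  if (!file.exists(path)) stopFormat("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "evidence_count")
  if (!all(need %in% colnames(df))) {
    stopFormat("evidence table %s needs columns %s", path,
               paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df$evidence_count <- as.integer(df$evidence_count)
  df
}

#' Write a data.frame as a headered TSV
#' @param df data.frame
#' @param path output file
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
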
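#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
NULL

#' Assemble a run configuration
#'
#' Collects every tunable of the study with the standard defaults: e-value
#' threshold 1e-5 for top-hit selection, evidence threshold 5 (the
#' gold-standard cut), k = 10 clusters per residue class, significance
#' alpha 0.1 on BH-adjusted p values, strong-evidence threshold 5.
#'
#' @param msa_dir directory of aligned FASTA files (one per reference
#'   protein, file name `<accession>.afa`), or `NULL` when `msas` is given.
#' @param msas named list of [ReferenceMsa-class] (in-memory alternative).
#' @param sites site table path or data.frame.
#' @param registry registry path or [SpeciesRegistry-class].
#' @param annotation term-annotation path (two-column TSV term_id, accession)
#'   or named list.
#' @param interpro InterProScan TSV path or spans data.frame.
#' @param kinase_scores path or data.frame (see [readKinaseScores()]).
#' @param ortho_groups path or data.frame (see [readOrthoGroups()]).
#' @param evidence path or data.frame (see [readEvidenceTable()]).
#' @param e_value top-hit e-value threshold.
#' @param min_evidence gold-standard evidence threshold.
#' @param k clusters per residue class.
#' @param alpha BH-adjusted significance threshold.
#' @param min_strong strong-evidence threshold for validation.
#' @param excluded_groups groups excluded from kinase conservation.
#' @param linkage,standardize,st_equivalent,plus1_mode module flags (see the
#'   respective functions).
#' @param templates label-template catalog.
#' @return list of class `run_config`.
#' @export
runConfig <- function(msa_dir = NULL, msas = NULL, sites = NULL,
                      registry = NULL, annotation = NULL, interpro = NULL,
                      kinase_scores = NULL, ortho_groups = NULL,
                      evidence = NULL,
                      e_value = 1e-5, min_evidence = 5L, k = 10L,
                      alpha = 0.1, min_strong = 5L,
                      excluded_groups = character(0),
                      linkage = "complete", standardize = FALSE,
                      st_equivalent = TRUE, plus1_mode = "column",
                      templates = defaultTemplates()) {
  stopifnot(e_value > 0, alpha >= 0, alpha <= 1, k >= 1, min_strong >= 0)
  structure(as.list(environment()), class = "run_config")
}

resolveMsas <- function(config) {
  if (!is.null(config$msas)) return(config$msas)
  if (is.null(config$msa_dir) || !dir.exists(config$msa_dir)) {
    stop(sprintf("input error: MSA directory not found: %s",
                 if (is.null(config$msa_dir)) "<unset>" else config$msa_dir))
  }
  files <- list.files(config$msa_dir, pattern = "\\.(afa|fa|fasta)$",
                      full.names = TRUE)
  msas <- lapply(files, readMsa)
  names(msas) <- sub("\\.(afa|fa|fasta)$", "", basename(files))
  msas
}

resolveInput <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(sprintf("input error: missing %s: %s", what, x))
    return(reader(x))
  }
  x
}

readAnnotationTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopFormat("annotation %s needs two columns", path)
  split(df[[2]], df[[1]])
}

#' Write a term-annotation map as two-column TSV
#' @param annotation named list term -> accessions
#' @param path output file
#' @export
writeAnnotationTsv <- function(annotation, path) {
  df <- data.frame(term_id = rep(names(annotation),
                                 vapply(annotation, length, 1L)),
                   accession = unlist(annotation, use.names = FALSE))
  writeTsv(df, path)
}

writeManifest <- function(outDir, config, inputs, extra = list()) {
  cfg <- config
  cfg$msas <- if (is.null(config$msas)) NULL else
    sprintf("<%d in-memory alignments>", length(config$msas))
  for (f in c("sites", "registry", "annotation", "interpro", "kinase_scores",
              "ortho_groups", "evidence", "templates")) {
    if (!is.null(cfg[[f]]) && !is.character(cfg[[f]])) {
      cfg[[f]] <- sprintf("<in-memory %s>", f)
    }
  }
  checks <- list()
  for (p in inputs) {
    if (is.character(p) && length(p) == 1 && file.exists(p)) {
      checks[[p]] <- unname(md5sum(p))
    }
  }
  write_json(list(config = cfg, input_md5 = checks, extra = extra),
             file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, force = TRUE)
}

#' Run the conservation study end to end
#'
#' Loads the sites, registry and alignments, computes site and protein
#' conservation profiles, clusters and labels both residue classes, runs
#' term enrichment per cluster (when annotation is supplied), domain fold
#' enrichment (when InterPro spans are supplied), and kinase conservation
#' with the site-vs-kinase regression (when kinase inputs are supplied).
#' Writes `site_conservation.tsv`, `protein_profiles.tsv`, `clusters.tsv`,
#' `terms.tsv`, `domains.tsv`, `kinase_conservation.tsv` and a
#' `manifest.json` recording parameters and input checksums. On error,
#' partial outputs in `outDir` are removed.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created).
#' @return invisibly, a list of the in-memory results.
#' @export
runConservationStudy <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  registry <- resolveInput(config$registry, readRegistry, "registry")
  if (is.null(registry)) stop("input error: registry is required")
  sites <- resolveInput(config$sites,
                        function(p) readSiteTable(p, config$min_evidence),
                        "site table")
  if (is.null(sites)) stop("input error: site table is required")
  if (is.data.frame(config$sites)) {
    sites <- sites[sites$evidence_count >= config$min_evidence, , drop = FALSE]
  }
  msas <- resolveMsas(config)

  message(sprintf("loaded %d sites (evidence >= %d) on %d proteins; %d alignments",
                  nrow(sites), config$min_evidence,
                  length(unique(sites$accession)), length(msas)))

  sc <- profileSites(msas, sites, registry,
                     stEquivalent = config$st_equivalent)
  gp <- groupPercent(sc)
  siteOut <- cbind(as.data.frame(rowData(sc)), round(gp, 4))
  f <- file.path(outDir, "site_conservation.tsv")
  writeTsv(siteOut, f); written <- c(written, f)

  profs <- list(ST = proteinProfiles(sc, "ST"), Y = proteinProfiles(sc, "Y"))
  profOut <- do.call(rbind, lapply(names(profs), function(cl) {
    if (nrow(profs[[cl]]) == 0) return(NULL)
    cbind(data.frame(accession = rownames(profs[[cl]]), residue_class = cl),
          round(as.data.frame(profs[[cl]]), 4))
  }))
  f <- file.path(outDir, "protein_profiles.tsv")
  writeTsv(profOut, f); written <- c(written, f)

  clusterings <- list()
  clustOut <- list()
  for (cl in names(profs)) {
    m <- profs[[cl]]
    if (nrow(m) < max(2L, config$k)) next
    cc <- clusterProfiles(m, k = config$k, linkage = config$linkage,
                          standardize = config$standardize)
    cc <- labelClusters(cc, m, config$templates)
    clusterings[[cl]] <- cc
    clustOut[[cl]] <- data.frame(
      accession = names(cc$assignments), residue_class = cl,
      cluster = unname(cc$assignments),
      label = cc$labels[as.character(cc$assignments)],
      support = round(cc$support[as.character(cc$assignments)], 4),
      stringsAsFactors = FALSE)
  }
  f <- file.path(outDir, "clusters.tsv")
  writeTsv(do.call(rbind, clustOut), f); written <- c(written, f)

  annotation <- if (is.character(config$annotation)) {
    resolveInput(config$annotation, readAnnotationTsv, "annotation")
  } else config$annotation
  termOut <- NULL
  if (!is.null(annotation) && length(clusterings)) {
    background <- unique(sites$accession)
    termOut <- do.call(rbind, lapply(names(clusterings), function(cl) {
      cc <- clusterings[[cl]]
      do.call(rbind, lapply(sort(unique(cc$assignments)), function(cid) {
        members <- names(cc$assignments)[cc$assignments == cid]
        res <- hypergeomEnrich(members, background, annotation,
                               alpha = config$alpha)
        if (nrow(res) == 0) return(NULL)
        cbind(data.frame(residue_class = cl, cluster = cid), res)
      }))
    }))
  }
  f <- file.path(outDir, "terms.tsv")
  writeTsv(if (is.null(termOut)) data.frame(note = "no annotation supplied")
           else termOut, f)
  written <- c(written, f)

  spans <- resolveInput(config$interpro, readInterproTsv, "InterPro TSV")
  domOut <- NULL
  if (!is.null(spans) && length(clusterings)) {
    siteKey <- paste(sites$accession, sites$position, sep = ":")
    domainMap <- mapSitesToDomains(sites, spans)
    names(domainMap) <- siteKey
    domOut <- do.call(rbind, lapply(names(clusterings), function(cl) {
      cc <- clusterings[[cl]]
      keepRes <- if (cl == "ST") c("S", "T") else "Y"
      bgKeys <- siteKey[sites$residue %in% keepRes]
      bgKeys <- bgKeys[!is.na(domainMap[bgKeys])]
      if (length(bgKeys) == 0) return(NULL)
      do.call(rbind, lapply(sort(unique(cc$assignments)), function(cid) {
        members <- names(cc$assignments)[cc$assignments == cid]
        patKeys <- bgKeys[sites$accession[match(bgKeys, siteKey)] %in% members]
        if (length(patKeys) == 0) return(NULL)
        res <- domainFoldEnrichment(patKeys, bgKeys, domainMap)
        if (nrow(res) == 0) return(NULL)
        cbind(data.frame(residue_class = cl, cluster = cid,
                         label = cc$labels[as.character(cid)]), res)
      }))
    }))
  }
  f <- file.path(outDir, "domains.tsv")
  writeTsv(if (is.null(domOut)) data.frame(note = "no InterPro spans supplied")
           else domOut, f)
  written <- c(written, f)

  kin <- resolveInput(config$kinase_scores, readKinaseScores, "kinase scores")
  og <- resolveInput(config$ortho_groups, readOrthoGroups, "orthologue groups")
  kinOut <- NULL
  regression <- NULL
  if (!is.null(kin) && !is.null(og)) {
    ogSplit <- split(og$species_id, og$group_id)
    # kinase id doubles as its orthologue-group key in the extract
    kinCons <- lapply(ogSplit, kinaseConservation, registry = registry,
                      excludedGroups = config$excluded_groups)
    kinOut <- do.call(rbind, lapply(names(kinCons), function(kid) {
      kc <- kinCons[[kid]]
      cbind(data.frame(kinase = kid, n_species = length(kc$species_present)),
            as.data.frame(t(round(kc$group_percent, 4))))
    }))
    # regression pairs: per site, its top kinase(s); ties contribute one
    # pair per tied kinase
    sitePct <- overallPercent(sc, config$excluded_groups)
    names(sitePct) <- paste(sites$accession, sites$position, sep = ":")
    reg <- registry
    keepSp <- setdiff(speciesIds(reg),
                      unlist(lapply(config$excluded_groups, groupMembers,
                                    x = reg)))
    kinOverall <- vapply(kinCons, function(kc) {
      100 * length(intersect(kc$species_present, keepSp)) / length(keepSp)
    }, numeric(1))
    pairs <- do.call(rbind, lapply(
      split(kin, paste(kin$accession, kin$position, sep = ":")),
      function(ks) {
        key <- paste(ks$accession[1], ks$position[1], sep = ":")
        if (!key %in% names(sitePct)) return(NULL)
        top <- topKinases(stats::setNames(ks$score, ks$kinase))
        kk <- intersect(top$kinases, names(kinOverall))
        if (length(kk) == 0) return(NULL)
        data.frame(site_percent = sitePct[[key]],
                   kinase_percent = unname(kinOverall[kk]))
      }))
    if (!is.null(pairs) && nrow(pairs) >= 3) {
      regression <- regressConservation(pairs)
    }
  }
  f <- file.path(outDir, "kinase_conservation.tsv")
  writeTsv(if (is.null(kinOut)) data.frame(note = "no kinase inputs supplied")
           else kinOut, f)
  written <- c(written, f)

  writeManifest(outDir, config,
                inputs = config[c("sites", "registry", "annotation",
                                  "interpro", "kinase_scores",
                                  "ortho_groups")],
                extra = list(n_sites = nrow(sites), n_msas = length(msas),
                             regression = regression))
  ok <- TRUE
  invisible(list(site_conservation = sc, protein_profiles = profs,
                 clusterings = clusterings, terms = termOut,
                 domains = domOut, kinases = kinOut,
                 regression = regression))
}

#' Run the propagation study end to end
#'
#' Propagates every phosphosite through its alignment to all registry
#' species, writes `predictions.tsv`, the per-species/per-group summary,
#' the skipped-site report, and `validation.tsv` when an evidence table is
#' supplied.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created).
#' @return invisibly, a list with predictions, skipped, summary, validation.
#' @export
runPropagationStudy <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  registry <- resolveInput(config$registry, readRegistry, "registry")
  if (is.null(registry)) stop("input error: registry is required")
  sites <- resolveInput(config$sites,
                        function(p) readSiteTable(p, config$min_evidence),
                        "site table")
  if (is.null(sites)) stop("input error: site table is required")
  if (is.data.frame(config$sites)) {
    sites <- sites[sites$evidence_count >= config$min_evidence, , drop = FALSE]
  }
  msas <- resolveMsas(config)

  preds <- list()
  skipped <- list()
  for (acc in unique(sites$accession)) {
    msa <- msas[[acc]]
    if (is.null(msa)) next
    res <- propagateSites(msa, sites[sites$accession == acc, , drop = FALSE],
                          registry, stEquivalent = config$st_equivalent,
                          plus1Mode = config$plus1_mode)
    preds[[acc]] <- res$predictions
    skipped[[acc]] <- res$skipped
  }
  emptyPred <- data.frame(species_id = character(0), accession = character(0),
                          position = integer(0), residue = character(0),
                          plus1_residue = character(0),
                          source_accession = character(0),
                          source_position = integer(0),
                          source_residue = character(0),
                          stringsAsFactors = FALSE)
  predictions <- do.call(rbind, c(preds, list(emptyPred)))
  skippedAll <- do.call(rbind, skipped)
  if (is.null(skippedAll)) {
    skippedAll <- data.frame(accession = character(0), position = integer(0),
                             residue = character(0), reason = character(0))
  }
  rownames(predictions) <- rownames(skippedAll) <- NULL

  grp <- speciesTable(registry)$base_group[
    match(predictions$species_id, speciesIds(registry))]
  f <- file.path(outDir, "predictions.tsv")
  writeTsv(cbind(predictions[, "species_id", drop = FALSE], group = grp,
                 predictions[, -1, drop = FALSE]), f)
  written <- c(written, f)

  summ <- summarizeByGroup(predictions, registry)
  f <- file.path(outDir, "predictions_per_species.tsv")
  writeTsv(summ$per_species, f); written <- c(written, f)
  f <- file.path(outDir, "predictions_per_group.tsv")
  writeTsv(summ$per_group, f); written <- c(written, f)
  f <- file.path(outDir, "skipped_sites.tsv")
  writeTsv(skippedAll, f); written <- c(written, f)

  validation <- NULL
  evidence <- resolveInput(config$evidence, readEvidenceTable, "evidence")
  if (!is.null(evidence) && nrow(predictions) > 0) {
    # validate only the species whose proteome the evidence table covers
    evSpecies <- unique(
      predictions$species_id[predictions$accession %in% evidence$accession])
    validation <- do.call(rbind, lapply(evSpecies, function(s) {
      p <- predictions[predictions$species_id == s, , drop = FALSE]
      cbind(data.frame(species_id = s),
            validatePredictions(p, evidence, config$min_strong))
    }))
    f <- file.path(outDir, "validation.tsv")
    writeTsv(validation, f); written <- c(written, f)
  } else {
    message("no evidence table supplied; validation skipped")
  }

  writeManifest(outDir, config,
                inputs = config[c("sites", "registry", "evidence")],
                extra = list(n_predictions = nrow(predictions),
                             n_skipped = nrow(skippedAll)))
  ok <- TRUE
  invisible(list(predictions = predictions, skipped = skippedAll,
                 summary = summ, validation = validation))
}
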
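#' @importFrom stats runif
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# stable 31-adic string hash, kept below 2^31 so it can seed R's RNG
hashString <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# evaluate expr under a local RNG stream; the caller's RNG state is restored
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed %% 2147483647L)
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# a residue that never counts as conserved against refRes: for S/T references
# neither S nor T may come out (that would be conserving under the
# substitution rule); for others anything but the residue itself
nonConservingResidue <- function(refRes) {
  pool <- if (refRes %in% c("S", "T")) setdiff(AA20, c("S", "T"))
          else setdiff(AA20, refRes)
  sample(pool, 1L)
}

#' Archetype specification for the simulator
#'
#' An archetype is a planted conservation pattern: each base group gets a
#' per-site substitution probability (the chance that a phosphosite or +1
#' column is mutated to a non-conserving residue in a species of that group).
#' Low probability = conserved group.
#'
#' @param template a [labelTemplate()] naming the pattern being planted.
#' @param n number of proteins to generate for the archetype.
#' @param groupSub named numeric vector: base group -> substitution
#'   probability in \[0,1\] at site/+1 columns.
#' @return list of class `sim_archetype`.
#' @export
simArchetype <- function(template, n, groupSub) {
  stopifnot(all(groupSub >= 0 & groupSub <= 1), n >= 1)
  structure(list(template = template, n = n, groupSub = groupSub),
            class = "sim_archetype")
}

#' Simulation configuration
#'
#' Collects every knob of the generator; a single integer seed drives one
#' root stream, with per-protein substreams derived by stable hashing of the
#' accession (adding proteins does not perturb existing ones).
#'
#' @param seed integer root seed.
#' @param registry a [SpeciesRegistry-class] (default the 100-species panel).
#' @param archetypes list of [simArchetype()] (default four patterns, 50
#'   proteins each).
#' @param sitesPerProtein integer range (min, max) of phosphosites per
#'   protein.
#' @param proteinLength integer range of reference protein lengths.
#' @param residueProbs probabilities of S, T, Y for planted phosphosites
#'   (default the observed gold-standard mix 16978:2747:986).
#' @param decoyFraction fraction of species per protein replaced by
#'   nonhomologous decoys (absent from the alignment, hence never conserved).
#' @param stSwapRate probability that a conserved S/T site is emitted as the
#'   other hydroxyl residue (exercises the substitution rule).
#' @param backgroundRate per-residue mutation probability away from
#'   site/+1 columns.
#' @param noisePoints within-archetype noise: per-protein jitter on the
#'   substitution probabilities, uniform in +/- noisePoints/100 (default 10
#'   percentage points).
#' @param evidenceCoverageST,evidenceCoverageY fraction of true propagated
#'   Ser/Thr (Tyr) sites in the validation species that carry evidence
#'   (defaults 0.82 and 0.75, the evidence rates reported for mouse).
#' @param strongFraction fraction of evidenced sites with strong evidence
#'   (count >= 5; default 0.61).
#' @param backgroundEvidenceRate evidence rate among non-predicted S/T/Y
#'   residues of the validation proteome (default 0.059, the PSP-wide rate
#'   implied by the reported 14x enrichment over random picking).
#' @param backgroundStrongFraction strong fraction within background evidence
#'   (default 0.2, implied by the reported 43x strong-evidence enrichment).
#' @param validationSpecies species id used for evidence generation.
#' @param plantedTerms list of planted term enrichments:
#'   `list(term =, archetype = index, size =, fold =)`.
#' @param nullTerms number of unenriched terms drawn uniformly.
#' @param nullTermSize proteins per null term.
#' @return list of class `sim_config`.
#' @export
simulationConfig <- function(seed = 1L,
                             registry = defaultRegistry(),
                             archetypes = NULL,
                             sitesPerProtein = c(2L, 5L),
                             proteinLength = c(120L, 240L),
                             residueProbs = c(S = 16978, T = 2747, Y = 986) / 20711,
                             decoyFraction = 0.02,
                             stSwapRate = 0.15,
                             backgroundRate = 0.05,
                             noisePoints = 10,
                             evidenceCoverageST = 0.82,
                             evidenceCoverageY = 0.75,
                             strongFraction = 0.61,
                             backgroundEvidenceRate = 0.059,
                             backgroundStrongFraction = 0.2,
                             validationSpecies = "other_mammals_01",
                             plantedTerms = NULL,
                             nullTerms = 10L,
                             nullTermSize = 20L) {
  if (is.null(archetypes)) archetypes <- standardArchetypes()
  if (is.null(plantedTerms)) {
    plantedTerms <- lapply(seq_along(archetypes), function(i) {
      list(term = sprintf("TERM:planted%02d", i), archetype = i,
           size = 20L, fold = 4)
    })
  }
  stopifnot(decoyFraction >= 0, decoyFraction <= 1,
            stSwapRate >= 0, stSwapRate <= 1,
            backgroundRate >= 0, backgroundRate <= 1)
  structure(list(seed = as.integer(seed), registry = registry,
                 archetypes = archetypes, sitesPerProtein = sitesPerProtein,
                 proteinLength = proteinLength, residueProbs = residueProbs,
                 decoyFraction = decoyFraction, stSwapRate = stSwapRate,
                 backgroundRate = backgroundRate, noisePoints = noisePoints,
                 evidenceCoverageST = evidenceCoverageST,
                 evidenceCoverageY = evidenceCoverageY,
                 strongFraction = strongFraction,
                 backgroundEvidenceRate = backgroundEvidenceRate,
                 backgroundStrongFraction = backgroundStrongFraction,
                 validationSpecies = validationSpecies,
                 plantedTerms = plantedTerms, nullTerms = nullTerms,
                 nullTermSize = nullTermSize),
            class = "sim_config")
}

#' Simulate one orthologue set
#'
#' Emits, for every registry species, an orthologue of the reference protein:
#' phosphosite and +1 columns are mutated to a non-conserving residue with
#' the archetype's per-group probability (conserved S/T columns are emitted
#' as the other hydroxyl residue at `stSwapRate`, exercising the substitution
#' rule); background positions mutate at `backgroundRate`; decoy species get
#' no alignment row (no significant homology). Planted flags are recorded by
#' construction, independently of the conservation scorer.
#'
#' @param reference named character scalar: the reference sequence (name =
#'   accession).
#' @param sites data.frame of phosphosites on the reference.
#' @param groupSub named numeric: base group -> substitution probability.
#' @param config a [simulationConfig()].
#' @param seed substream seed for this protein.
#' @return list with `msa` ([ReferenceMsa-class]), `conserved` and `plus1`
#'   (logical matrices sites x species; `plus1` NA at C-terminal sites),
#'   `decoys` (species ids left out of the alignment).
#' @export
simulateOrthologSet <- function(reference, sites, groupSub, config,
                                seed = config$seed) {
  registry <- config$registry
  base <- baseGroupNames(registry)
  if (!all(base %in% names(groupSub))) {
    stop(sprintf("substitution probability missing for group '%s'",
                 setdiff(base, names(groupSub))[1]))
  }
  acc <- names(reference)[1]
  refSeq <- reference[[1]]
  n <- nchar(refSeq)
  refChars <- strsplit(refSeq, "")[[1]]
  sp <- speciesIds(registry)
  spGroup <- speciesTable(registry)$base_group
  withSeed(seed, {
    cons <- matrix(FALSE, nrow(sites), length(sp), dimnames = list(NULL, sp))
    plus1 <- matrix(NA, nrow(sites), length(sp), dimnames = list(NULL, sp))
    cterm <- sites$position >= n
    plus1[!cterm, ] <- FALSE
    nDecoy <- round(config$decoyFraction * length(sp))
    decoys <- if (nDecoy > 0) sample(sp, nDecoy) else character(0)
    rows <- character(0)
    for (si in seq_along(sp)) {
      s <- sp[si]
      if (s %in% decoys) next
      p <- groupSub[[spGroup[si]]]
      chars <- refChars
      # background mutations first; site and +1 columns are then overwritten
      mut <- runif(n) < config$backgroundRate
      chars[mut] <- vapply(refChars[mut],
                           function(r) sample(setdiff(AA20, r), 1L), "")
      for (i in seq_len(nrow(sites))) {
        pos <- sites$position[i]
        refRes <- refChars[pos]
        if (runif(1) < p) {
          chars[pos] <- nonConservingResidue(refRes)
        } else {
          cons[i, s] <- TRUE
          chars[pos] <- if (refRes %in% c("S", "T") &&
                            runif(1) < config$stSwapRate) {
            setdiff(c("S", "T"), refRes)
          } else refRes
        }
        if (!cterm[i]) {
          refRes1 <- refChars[pos + 1L]
          if (runif(1) < p) {
            chars[pos + 1L] <- nonConservingResidue(refRes1)
          } else {
            plus1[i, s] <- TRUE
            chars[pos + 1L] <- if (refRes1 %in% c("S", "T") &&
                                   runif(1) < config$stSwapRate) {
              setdiff(c("S", "T"), refRes1)
            } else refRes1
          }
        }
      }
      rows[sprintf("%s|%s_%s", s, acc, s)] <- paste(chars, collapse = "")
    }
    aln <- c(stats::setNames(refSeq, acc), rows)
    msa <- new("ReferenceMsa", alignment = AAStringSet(aln), reference = acc)
    list(msa = msa, conserved = cons, plus1 = plus1, decoys = decoys)
  })
}

# random reference protein with planted phosphosites; site positions are
# spaced >= 2 apart and avoid the final residue so site and +1 columns never
# collide
simulateReference <- function(acc, config, seed) {
  withSeed(seed, {
    n <- sample(config$proteinLength[1]:config$proteinLength[2], 1L)
    chars <- sample(AA20, n, replace = TRUE)
    nSites <- sample(config$sitesPerProtein[1]:config$sitesPerProtein[2], 1L)
    candidates <- seq(2L, n - 2L)
    pos <- integer(0)
    for (k in seq_len(nSites)) {
      ok <- candidates[!candidates %in% c(pos, pos - 1L, pos + 1L, pos + 2L)]
      if (length(ok) == 0) break
      pos <- c(pos, if (length(ok) == 1) ok else sample(ok, 1L))
    }
    pos <- sort(pos)
    res <- sample(names(config$residueProbs), length(pos), replace = TRUE,
                  prob = config$residueProbs)
    chars[pos] <- res
    ev <- sample(5:40, length(pos), replace = TRUE)
    list(sequence = stats::setNames(paste(chars, collapse = ""), acc),
         sites = data.frame(accession = acc, residue = res, position = pos,
                            evidence_count = ev, stringsAsFactors = FALSE))
  })
}

#' Simulate a full study bundle
#'
#' Generates a multi-archetype protein set with orthologue alignments,
#' planted per-site conservation flags, annotation maps with planted term
#' enrichments, and an evidence table for the validation species in which the
#' stated fraction of true propagated sites carries (strong) evidence plus a
#' background of evidenced residues elsewhere in the proteome. Identical
#' configurations (including seed) reproduce identical bundles.
#'
#' @param config a [simulationConfig()].
#' @return list (the truth bundle): `registry`, `sites`, `msas`,
#'   `references` (AAStringSet), `archetype` (accession -> planted template
#'   name), `conserved` / `plus1` (planted flag matrices, rows follow
#'   `sites`), `annotation`, `plantedTerms`, `evidence`,
#'   `targetProteome`, `config`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  registry <- config$registry
  refs <- character(0)
  msas <- list()
  siteList <- list()
  archetype <- character(0)
  consList <- list()
  plus1List <- list()
  pidx <- 0L
  for (ai in seq_along(config$archetypes)) {
    arch <- config$archetypes[[ai]]
    for (j in seq_len(arch$n)) {
      pidx <- pidx + 1L
      acc <- sprintf("SIM%04d", pidx)
      seed <- (config$seed + hashString(acc)) %% 2147483647L
      ref <- simulateReference(acc, config, seed)
      # one jitter per protein: a protein is uniformly somewhat more or less
      # conserved than its archetype, shifting all groups together
      jitter <- withSeed(seed + 1L, runif(1, -config$noisePoints / 100,
                                          config$noisePoints / 100))
      groupSub <- pmin(1, pmax(0, arch$groupSub + jitter))
      names(groupSub) <- names(arch$groupSub)
      ortho <- simulateOrthologSet(ref$sequence, ref$sites, groupSub,
                                   config, seed = seed + 2L)
      refs[acc] <- ref$sequence[[1]]
      msas[[acc]] <- ortho$msa
      siteList[[acc]] <- ref$sites
      archetype[acc] <- arch$template$name
      consList[[acc]] <- ortho$conserved
      plus1List[[acc]] <- ortho$plus1
    }
  }
  sites <- do.call(rbind, siteList)
  rownames(sites) <- NULL
  conserved <- do.call(rbind, consList)
  plus1 <- do.call(rbind, plus1List)

  accs <- names(refs)
  annotation <- withSeed(config$seed + 7L, {
    ann <- list()
    for (pt in config$plantedTerms) {
      share <- sum(archetype == config$archetypes[[pt$archetype]]$template$name) /
        length(accs)
      q <- min(1, pt$fold * share)
      inArch <- accs[archetype ==
                       config$archetypes[[pt$archetype]]$template$name]
      outArch <- setdiff(accs, inArch)
      nIn <- round(q * pt$size)
      nOut <- pt$size - nIn
      ann[[pt$term]] <- c(sample(inArch, min(nIn, length(inArch))),
                          sample(outArch, min(nOut, length(outArch))))
    }
    for (t in seq_len(config$nullTerms)) {
      ann[[sprintf("TERM:null%02d", t)]] <-
        sample(accs, min(config$nullTermSize, length(accs)))
    }
    ann
  })

  # evidence for the validation species, from the planted truth (site AND +1
  # conserved), not from the propagation code
  vs <- config$validationSpecies
  evidence <- withSeed(config$seed + 11L, {
    rows <- list()
    predicted <- character(0)
    for (i in seq_len(nrow(sites))) {
      if (!isTRUE(conserved[i, vs]) || !isTRUE(plus1[i, vs])) next
      acc <- sites$accession[i]
      tacc <- sprintf("%s_%s", acc, vs)
      key <- paste(tacc, sites$position[i], sep = ":")
      predicted <- c(predicted, key)
      cov <- if (sites$residue[i] == "Y") config$evidenceCoverageY
             else config$evidenceCoverageST
      if (runif(1) < cov) {
        strong <- runif(1) < config$strongFraction
        rows[[length(rows) + 1L]] <- data.frame(
          accession = tacc, position = sites$position[i],
          evidence_count = if (strong) sample(5:30, 1L) else sample(1:4, 1L),
          stringsAsFactors = FALSE)
      }
    }
    # background evidence on other S/T/Y residues of the validation proteome
    for (acc in accs) {
      msa <- msas[[acc]]
      rid <- msaRowIds(msa)[msaRowSpecies(msa) == vs]
      if (length(rid) == 0) next
      seqv <- gsub("-", "", as.character(msa@alignment[[rid]]), fixed = TRUE)
      tacc <- sub("^[^|]*\\|", "", rid)
      chars <- strsplit(seqv, "")[[1]]
      sty <- which(chars %in% c("S", "T", "Y"))
      sty <- sty[!paste(tacc, sty, sep = ":") %in% predicted]
      hit <- sty[runif(length(sty)) < config$backgroundEvidenceRate]
      if (length(hit)) {
        strong <- runif(length(hit)) < config$backgroundStrongFraction
        rows[[length(rows) + 1L]] <- data.frame(
          accession = tacc, position = hit,
          evidence_count = ifelse(strong,
                                  sample(5:30, length(hit), replace = TRUE),
                                  sample(1:4, length(hit), replace = TRUE)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(accession = character(0), position = integer(0),
                 evidence_count = integer(0), stringsAsFactors = FALSE)
  })

  targetRows <- character(0)
  for (acc in accs) {
    msa <- msas[[acc]]
    rid <- msaRowIds(msa)[msaRowSpecies(msa) == vs]
    if (length(rid) == 0) next
    targetRows[sub("^[^|]*\\|", "", rid)] <-
      gsub("-", "", as.character(msa@alignment[[rid]]), fixed = TRUE)
  }

  list(registry = registry, sites = sites, msas = msas,
       references = AAStringSet(refs), archetype = archetype,
       conserved = conserved, plus1 = plus1, annotation = annotation,
       plantedTerms = config$plantedTerms, evidence = evidence,
       targetProteome = AAStringSet(targetRows), config = config)
}

#' Standard four-archetype catalog for the simulator
#'
#' High in all species; high in vertebrates & invertebrates; high in
#' primates; medium in vertebrates except fish — 50 proteins each by default.
#'
#' @param n proteins per archetype.
#' @return list of [simArchetype()].
#' @export
standardArchetypes <- function(n = 50L) {
  base <- names(defaultGroupSizes())
  mk <- function(default, special = numeric(0)) {
    p <- rep(default, length(base))
    names(p) <- base
    p[names(special)] <- special
    p
  }
  tpl <- defaultTemplates()
  list(
    simArchetype(tpl[[1]], n, mk(0.02)),
    simArchetype(tpl[[2]], n, mk(0.04, c(fungi = 0.9, plants = 0.9,
                                         protists = 0.9))),
    simArchetype(tpl[[6]], n, mk(0.9, c(primates = 0.04))),
    simArchetype(tpl[[4]], n, mk(0.9, c(primates = 0.3, other_mammals = 0.3,
                                        birds = 0.3, reptiles = 0.3,
                                        amphibians = 0.3, fish = 0.95)))
  )
}
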
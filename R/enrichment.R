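#' @importFrom stats phyper p.adjust
NULL

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement and clamping at
#' 1; output order matches input order.
#'
#' @param p numeric vector of raw p values in \[0,1\].
#' @return adjusted p values, same order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values outside [0,1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation test for a protein cluster
#'
#' For each annotation term, tests whether the cluster contains more
#' annotated proteins than expected from a draw of the cluster size out of
#' the background: p = P(X >= k) with X hypergeometric(N, K, n), where N is
#' the background size, K the annotated background proteins, n the cluster
#' size and k the annotated cluster proteins. P values are BH-adjusted across
#' all tested terms; terms are flagged significant at adjusted p < alpha
#' (default 0.1).
#'
#' @param cluster character vector of accessions (must be a subset of
#'   `background`).
#' @param background character vector of accessions (the analyzed-protein
#'   universe).
#' @param annotation named list: term id -> character vector of annotated
#'   accessions.
#' @param alpha significance threshold on the adjusted p value.
#' @param minTermSize terms annotating fewer background proteins are skipped.
#' @return data.frame: term, k, n, K, N, p, p_adj, significant; ordered by p.
#' @export
hypergeomEnrich <- function(cluster, background, annotation,
                            alpha = 0.1, minTermSize = 2L) {
  cluster <- unique(cluster)
  background <- unique(background)
  if (!all(cluster %in% background)) {
    stop("cluster must be a subset of the background")
  }
  N <- length(background)
  n <- length(cluster)
  rows <- lapply(names(annotation), function(term) {
    ann <- intersect(unique(annotation[[term]]), background)
    K <- length(ann)
    if (K < minTermSize) return(NULL)
    k <- length(intersect(ann, cluster))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  }
  rows$p_adj <- bhAdjust(rows$p)
  rows$significant <- rows$p_adj < alpha
  rows <- rows[order(rows$p, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Map phosphosites to domains with the first-match rule
#'
#' Each site maps to the domain span of its protein covering the position
#' (1-based inclusive) with the lowest file rank; when several overlapping
#' predictions cover a site only the first mapped domain term is kept. Sites
#' covered by no span map to `NA`.
#'
#' @param sites data.frame with accession and position.
#' @param spans data.frame from [readInterproTsv()].
#' @return character vector of InterPro ids (or NA), one per site row.
#' @export
mapSitesToDomains <- function(sites, spans) {
  spans <- spans[order(spans$file_rank), , drop = FALSE]
  byAcc <- split(spans, spans$accession)
  vapply(seq_len(nrow(sites)), function(i) {
    sp <- byAcc[[sites$accession[i]]]
    if (is.null(sp)) return(NA_character_)
    hit <- sp$start <= sites$position[i] & sites$position[i] <= sp$stop
    if (!any(hit)) return(NA_character_)
    sp$interpro_id[which(hit)[1]]
  }, character(1))
}

#' Domain fold enrichment of a conservation pattern
#'
#' For each domain: fold = (a/b) / (A/B) with a = pattern sites mapped to the
#' domain, b = all pattern sites mapped to any domain, A = background sites
#' mapped to the domain, B = all background sites mapped to any domain.
#' Domains with fewer than two mapped background sites are excluded. Also
#' reports the percentage of pattern sites mapped to the domain (100*a/b) and
#' log2(fold); the top-10 domains by percent mapped are the usual report.
#'
#' @param patternKeys character keys ("accession:position") of sites with the
#'   pattern of interest; must be a subset of `backgroundKeys`.
#' @param backgroundKeys character keys of all background sites.
#' @param domainMap named character vector: site key -> InterPro id (NA =
#'   unmapped).
#' @param minDomainSites minimum mapped background sites per domain
#'   (default 2).
#' @return data.frame: interpro_id, a, b, A, B, fold, log2_fold,
#'   percent_mapped; ordered by percent_mapped decreasing.
#' @export
domainFoldEnrichment <- function(patternKeys, backgroundKeys, domainMap,
                                 minDomainSites = 2L) {
  if (!all(patternKeys %in% backgroundKeys)) {
    stop("pattern sites must be a subset of background sites")
  }
  bgDom <- domainMap[backgroundKeys]
  bgDom <- bgDom[!is.na(bgDom)]
  patDom <- domainMap[patternKeys]
  patDom <- patDom[!is.na(patDom)]
  B <- length(bgDom)
  b <- length(patDom)
  if (B == 0 || b == 0) stop("no domain-mapped sites in pattern or background")
  domA <- table(bgDom)
  keep <- names(domA)[domA >= minDomainSites]
  rows <- lapply(keep, function(d) {
    a <- sum(patDom == d)
    A <- as.integer(domA[[d]])
    fold <- (a / b) / (A / B)
    data.frame(interpro_id = d, a = a, b = b, A = A, B = B, fold = fold,
               log2_fold = log2(fold), percent_mapped = 100 * a / b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$percent_mapped, out$interpro_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validation enrichment factor for propagated predictions
#'
#' Compares the evidence rate among predictions with the rate expected by
#' picking residues of the stated types at random in the target proteome:
#' observed = |predictions with evidence| / |predictions|; background =
#' |evidenced residues| / |residues of the stated types in the proteome|;
#' factor = observed / background.
#'
#' @param predictions data.frame with accession and position (target
#'   coordinates).
#' @param evidence data.frame with accession and position of evidenced sites.
#' @param proteome AAStringSet of the target proteome.
#' @param residues residue types considered (default S, T, Y).
#' @return list with observed_rate, background_rate, factor, n_predictions,
#'   n_residues.
#' @export
enrichmentFactor <- function(predictions, evidence, proteome,
                             residues = c("S", "T", "Y")) {
  if (nrow(predictions) == 0) stop("empty prediction set")
  if (length(proteome) == 0) stop("empty proteome")
  nRes <- sum(vapply(as.character(proteome), function(s) {
    sum(strsplit(s, "")[[1]] %in% residues)
  }, numeric(1)))
  if (nRes == 0) stop("proteome has no residues of the stated types")
  predKey <- unique(paste(predictions$accession, predictions$position, sep = ":"))
  evKey <- unique(paste(evidence$accession, evidence$position, sep = ":"))
  observed <- mean(predKey %in% evKey)
  # evidenced residues counted per proteome record, so the rate is taken over
  # the proteome actually supplied (replicated records replicate evidence)
  evByAcc <- table(sub(":.*$", "", evKey))
  nEv <- sum(vapply(names(proteome), function(a) {
    if (a %in% names(evByAcc)) as.numeric(evByAcc[[a]]) else 0
  }, numeric(1)))
  background <- nEv / nRes
  list(observed_rate = observed, background_rate = background,
       factor = if (background > 0) observed / background else NA_real_,
       n_predictions = length(predKey), n_residues = nRes)
}
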
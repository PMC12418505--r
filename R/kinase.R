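#' @importFrom stats lm coef
NULL

#' Top-ranked kinase match(es) for a site
#'
#' Returns every kinase attaining the maximum likelihood score (several
#' kinases are selected when they tie at the maximum).
#'
#' @param scores named numeric vector: kinase id -> score.
#' @return list with `kinases` (character) and `score` (the shared maximum).
#' @export
topKinases <- function(scores) {
  if (length(scores) == 0) stop("empty kinase score map")
  mx <- max(scores)
  list(kinases = names(scores)[scores == mx], score = mx)
}

#' Kinase conservation from orthologue-group membership
#'
#' A kinase counts as conserved in a registry species when that species
#' appears in the kinase's orthologue group. Species outside the registry are
#' ignored; excluded groups (e.g. birds, when their orthologue annotations
#' are unreliable) are omitted from the output.
#'
#' @param members character vector of species ids in the orthologue group.
#' @param registry a [SpeciesRegistry-class].
#' @param excludedGroups group names to drop from the output.
#' @return list with `species_present` and `group_percent` (named numeric,
#'   non-excluded groups only).
#' @export
kinaseConservation <- function(members, registry, excludedGroups = character(0)) {
  present <- intersect(members, speciesIds(registry))
  groups <- setdiff(groupNames(registry), excludedGroups)
  pct <- vapply(groups, function(g) {
    gm <- groupMembers(registry, g)
    100 * length(intersect(present, gm)) / length(gm)
  }, numeric(1))
  list(species_present = present, group_percent = pct)
}

#' Regress site conservation on kinase conservation
#'
#' Ordinary least-squares fit of overall phosphosite conservation against the
#' conservation of the site's top-matched kinase, summarized by R-squared.
#' Sites with several tied top kinases contribute one pair per tied kinase.
#'
#' @param pairs data.frame with columns `site_percent` and `kinase_percent`
#'   (>= 3 rows).
#' @return list with slope, intercept, r_squared (NA with a warning when the
#'   predictor has zero variance).
#' @export
regressConservation <- function(pairs) {
  if (nrow(pairs) < 3) stop("need >= 3 pairs for the regression")
  if (var(pairs$kinase_percent) == 0) {
    warning("zero variance in the predictor; R-squared undefined")
    return(list(slope = NA_real_, intercept = mean(pairs$site_percent),
                r_squared = NA_real_))
  }
  fit <- lm(site_percent ~ kinase_percent, data = pairs)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Overall conservation percentage across non-excluded species
#'
#' The scalar conservation summary used for the site-vs-kinase regression:
#' the percentage of all registry species (optionally minus excluded groups)
#' in which the site is conserved.
#'
#' @param x a [SiteConservation-class].
#' @param excludedGroups base groups whose species are dropped from the
#'   denominator.
#' @return numeric vector, one value per site.
#' @export
overallPercent <- function(x, excludedGroups = character(0)) {
  reg <- metadata(x)$registry
  drop <- unique(unlist(lapply(excludedGroups, groupMembers, x = reg)))
  keep <- setdiff(speciesIds(reg), drop)
  m <- assay(x, "conserved")[, keep, drop = FALSE]
  100 * rowSums(m) / length(keep)
}
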
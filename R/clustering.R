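#' @importFrom stats dist hclust cutree var
NULL

#' Define a conservation label template
#'
#' A template names a conservation pattern by constraining some groups to
#' High (group percentage >= 75) or Medium (>= 50); unconstrained groups can
#' take any value. At least one group must be constrained.
#'
#' @param name descriptive label.
#' @param requirements named character vector, values `"High"` or `"Medium"`,
#'   names are registry group names.
#' @return list of class `label_template`.
#' @export
labelTemplate <- function(name, requirements) {
  if (length(requirements) == 0) stop("template needs >= 1 constrained group")
  if (!all(requirements %in% c("High", "Medium"))) {
    stop("requirements must be 'High' or 'Medium'")
  }
  structure(list(name = name, requirements = requirements),
            class = "label_template")
}

#' Default label-template catalog
#'
#' Descriptive conservation patterns over the default group system, ordered
#' most-specific first (the documented tie-break for cluster labeling).
#'
#' @return list of [labelTemplate()] objects.
#' @export
defaultTemplates <- function() {
  vertBase <- c("primates", "other_mammals", "birds", "fish", "reptiles",
                "amphibians")
  animBase <- c(vertBase, "insects_invertebrates")
  allBase <- c(animBase, "fungi", "plants", "protists")
  req <- function(groups, level) stats::setNames(rep(level, length(groups)),
                                                 groups)
  list(
    labelTemplate("High in all species", req(allBase, "High")),
    labelTemplate("High in vertebrates & invertebrates",
                  req(animBase, "High")),
    labelTemplate("High in vertebrates", req(vertBase, "High")),
    labelTemplate("Medium in vertebrates except fish",
                  req(setdiff(vertBase, "fish"), "Medium")),
    labelTemplate("High in mammals",
                  req(c("primates", "other_mammals"), "High")),
    labelTemplate("High in primates", req("primates", "High")),
    labelTemplate("Medium in vertebrates", req(vertBase, "Medium")),
    labelTemplate("Medium in mammals",
                  req(c("primates", "other_mammals"), "Medium")),
    labelTemplate("Medium in primates", req("primates", "Medium"))
  )
}

#' Cluster conservation-profile vectors
#'
#' Agglomerative hierarchical clustering on Euclidean distances between
#' group-percentage vectors, tree cut into exactly `k` clusters. Raw
#' percentages are used by default; set `standardize` to scale columns.
#'
#' @param profiles numeric matrix (proteins or sites) x groups, rownames are
#'   ids.
#' @param k number of clusters (default 10).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default "complete").
#' @param standardize scale columns to unit variance before distances.
#' @return list with `assignments` (named integer vector in 1..k, names =
#'   rownames), `labels` (empty, see [labelClusters()]), `support`, `tree`.
#' @export
clusterProfiles <- function(profiles, k = 10L, linkage = "complete",
                            standardize = FALSE) {
  n <- nrow(profiles)
  if (k < 1 || k > n) stop(sprintf("k must be in 1..%d", n))
  m <- profiles
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1
    m <- scale(m, center = TRUE, scale = sds)
  }
  tree <- hclust(dist(m, method = "euclidean"), method = linkage)
  assignments <- cutree(tree, k = k)
  names(assignments) <- rownames(profiles)
  list(assignments = assignments, labels = character(0),
       support = numeric(0), tree = tree)
}

#' Does a profile match a label template?
#'
#' TRUE iff every constrained group meets its threshold: High requires the
#' group percentage >= 75, Medium >= 50 (both inclusive).
#'
#' @param profile named numeric vector of group percentages.
#' @param template a [labelTemplate()].
#' @return logical scalar.
#' @export
matchTemplate <- function(profile, template) {
  req <- template$requirements
  unknown <- setdiff(names(req), names(profile))
  if (length(unknown)) {
    stop(sprintf("template '%s' constrains unknown group '%s'",
                 template$name, unknown[1]))
  }
  thr <- ifelse(req == "High", 75, 50)
  all(profile[names(req)] >= thr)
}

#' Label clusters from a template catalog
#'
#' Per cluster, templates are tried in catalog order (catalogs are ordered
#' most-specific first) and the first template matched by at least 50% of the
#' cluster's members is assigned, with that matching fraction as support;
#' when no template reaches 50% the cluster is "mixed". Walking the catalog
#' most-specific first means a cluster that is, say, highly conserved
#' everywhere is labeled "High in all species" even though broader labels
#' (whose constraints are a subset) necessarily match at least as many
#' members.
#'
#' @param clustering result of [clusterProfiles()].
#' @param profiles the matrix passed to [clusterProfiles()].
#' @param templates list of [labelTemplate()] (default [defaultTemplates()]).
#' @return the clustering list with `labels` and `support` filled (named by
#'   cluster id).
#' @export
labelClusters <- function(clustering, profiles, templates = defaultTemplates()) {
  if (length(templates) == 0) stop("empty template catalog")
  assignments <- clustering$assignments
  ids <- sort(unique(assignments))
  matchMat <- vapply(templates, function(tpl) {
    apply(profiles, 1L, matchTemplate, template = tpl)
  }, logical(nrow(profiles)))
  if (is.null(dim(matchMat))) matchMat <- matrix(matchMat, nrow = 1L)
  labels <- character(length(ids))
  support <- numeric(length(ids))
  names(labels) <- names(support) <- as.character(ids)
  for (cid in ids) {
    sel <- assignments == cid
    frac <- colSums(matchMat[sel, , drop = FALSE]) / sum(sel)
    best <- which(frac >= 0.5)[1]   # first (most specific) passing template
    if (!is.na(best)) {
      labels[as.character(cid)] <- templates[[best]]$name
      support[as.character(cid)] <- frac[best]
    } else {
      labels[as.character(cid)] <- "mixed"
      support[as.character(cid)] <- max(frac)
    }
  }
  clustering$labels <- labels
  clustering$support <- support
  clustering
}
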
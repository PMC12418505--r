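#' Construct a SpeciesRegistry
#'
#' Builds the registry from a species table and (optionally) a broader-group
#' scheme. Base groups are taken from the `base_group` column; each broader
#' group is defined as the union of named base groups. The default broader
#' scheme mirrors the eukaryote taxonomy used throughout the package:
#' mammals = primates + other mammals; vertebrates = mammals + birds + fish +
#' reptiles + amphibians; animals = vertebrates + insects/invertebrates.
#'
#' @param species data.frame with columns `species_id`, `display_name`,
#'   `proteome_id`, `base_group` (missing display/proteome columns are filled
#'   from `species_id`).
#' @param broader named list: broader-group name -> character vector of base
#'   groups. Base groups absent from `species` are dropped from the scheme.
#' @return a [SpeciesRegistry-class] object.
#' @examples
#' sp <- data.frame(species_id = c("hs", "mm", "dm"),
#'                  base_group = c("primates", "other_mammals",
#'                                 "insects_invertebrates"))
#' reg <- speciesRegistry(sp)
#' groupNames(reg)
#' @export
speciesRegistry <- function(species, broader = defaultBroaderScheme()) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (is.null(species$display_name)) species$display_name <- species$species_id
  if (is.null(species$proteome_id)) species$proteome_id <- species$species_id
  base <- unique(species$base_group)
  groups <- lapply(base, function(g) species$species_id[species$base_group == g])
  names(groups) <- base
  broader <- lapply(broader, intersect, y = base)
  broader <- broader[vapply(broader, length, 1L) > 0L]
  for (b in names(broader)) {
    groups[[b]] <- unlist(groups[broader[[b]]], use.names = FALSE)
  }
  new("SpeciesRegistry",
      species = DataFrame(species[c("species_id", "display_name",
                                    "proteome_id", "base_group")]),
      groups = groups, broader = broader)
}

#' Default broader-group scheme
#'
#' @return named list mapping mammals, vertebrates and animals to their
#'   constituent base groups.
#' @export
defaultBroaderScheme <- function() {
  list(
    mammals = c("primates", "other_mammals"),
    vertebrates = c("primates", "other_mammals", "birds", "fish",
                    "reptiles", "amphibians"),
    animals = c("primates", "other_mammals", "birds", "fish",
                "reptiles", "amphibians", "insects_invertebrates")
  )
}

#' Default base-group sizes (100 eukaryotic species)
#'
#' Primates 18, other mammals 32, birds 12, fish 5, reptiles 4, amphibians 2,
#' insects/invertebrates 11, fungi 4, plants 7, protists 5.
#'
#' @return named integer vector.
#' @export
defaultGroupSizes <- function() {
  c(primates = 18L, other_mammals = 32L, birds = 12L, fish = 5L,
    reptiles = 4L, amphibians = 2L, insects_invertebrates = 11L,
    fungi = 4L, plants = 7L, protists = 5L)
}

#' Build the default 100-species registry
#'
#' Generates a registry with synthetic species ids (`primates_01`, ...) whose
#' base-group sizes match the default eukaryote panel; broader groups come out
#' as mammals (50), vertebrates (73) and animals (84). Used by the simulator
#' and wherever a registry is not supplied.
#'
#' @param sizes named integer vector of base-group sizes.
#' @return a [SpeciesRegistry-class] with `sum(sizes)` species.
#' @examples
#' reg <- defaultRegistry()
#' length(speciesIds(reg))   # 100
#' @export
defaultRegistry <- function(sizes = defaultGroupSizes()) {
  species <- do.call(rbind, lapply(names(sizes), function(g) {
    ids <- sprintf("%s_%02d", g, seq_len(sizes[[g]]))
    data.frame(species_id = ids, display_name = ids,
               proteome_id = paste0("UP_", ids), base_group = g,
               stringsAsFactors = FALSE)
  }))
  speciesRegistry(species)
}

#' @describeIn speciesRegistry all species ids in the registry
#' @param x a SpeciesRegistry
#' @export
speciesIds <- function(x) {
  stopifnot(is(x, "SpeciesRegistry"))
  x@species$species_id
}

#' @describeIn speciesRegistry names of all groups (base then broader)
#' @export
groupNames <- function(x) {
  stopifnot(is(x, "SpeciesRegistry"))
  names(x@groups)
}

#' @describeIn speciesRegistry names of the base groups only
#' @export
baseGroupNames <- function(x) {
  stopifnot(is(x, "SpeciesRegistry"))
  setdiff(names(x@groups), names(x@broader))
}

#' @describeIn speciesRegistry species ids belonging to a group
#' @param group a group name
#' @export
groupMembers <- function(x, group) {
  stopifnot(is(x, "SpeciesRegistry"))
  if (!group %in% names(x@groups)) {
    stop(sprintf("unknown group '%s'", group))
  }
  x@groups[[group]]
}

#' @describeIn speciesRegistry the species table as a data.frame
#' @export
speciesTable <- function(x) {
  stopifnot(is(x, "SpeciesRegistry"))
  as.data.frame(x@species)
}

#' @export
setMethod("show", "SpeciesRegistry", function(object) {
  cat(sprintf("SpeciesRegistry: %d species, %d base groups, %d broader groups\n",
              nrow(object@species),
              length(baseGroupNames(object)), length(object@broader)))
  sz <- vapply(object@groups, length, 1L)
  cat("  ", paste(sprintf("%s=%d", names(sz), sz), collapse = " "), "\n", sep = "")
})
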
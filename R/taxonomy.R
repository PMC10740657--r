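#' Ecological Response Unit (ERU) taxonomy
#'
#' An ERU taxonomy is a data frame describing the vegetation types that make
#' up a landscape: one row per ERU with its life zone, dominant lifeform and
#' whether it counts as forest or woodland. [eru_taxonomy()] returns the
#' default taxonomy for the foothills and mountains of the Southwestern US:
#' the subalpine, montane and woodland-zone ERUs used in species habitat
#' models, plus grassland, shrubland, riparian, desert and alpine classes so
#' that downslope vegetation transitions can be expressed.
#'
#' Zones `subalpine`, `montane` and `woodland` are forest-or-woodland by
#' definition; `shrubland`, `grassland`, `desert` and `alpine` are not.
#' In the default taxonomy the `shrub` lifeform coincides exactly with the
#' shrubland zone (desert scrub classes are coded `herb` by convention so
#' that the shrub transition rule keys unambiguously on upland shrub types).
#' Riparian systems are carried in the taxonomy but are never projected to
#' or from: they cannot be modelled from upland climate envelopes.
#'
#' @param extra optional data frame of additional ERUs with the same columns,
#'   appended after validation.
#' @return A data frame of class `eru_taxonomy` with columns `eru_id`,
#'   `name`, `zone`, `lifeform`, `is_forest_or_woodland`.
#' @examples
#' tax <- eru_taxonomy()
#' subset(tax, zone == "montane")
#' @export
eru_taxonomy <- function(extra = NULL) {
  tax <- data.frame(
    eru_id = c("SFF", "BPF",
               "MCA", "MCD", "PPF", "PPE",
               "PJO", "MPO", "MEW", "PJS", "PJE", "PJD", "PJG", "JUG",
               "CPG", "MSG",
               "GAM", "MMS",
               "RIP",
               "CDS",
               "ALP"),
    name = c("Spruce-fir forest", "Bristlecone pine forest",
             "Mixed conifer with aspen", "Mixed conifer - frequent fire",
             "Ponderosa pine forest", "Ponderosa pine - evergreen oak forest",
             "Pinyon-juniper woodland", "Madrean pinyon-oak woodland",
             "Madrean encinal woodland", "Pinyon-juniper sagebrush",
             "Pinyon-juniper evergreen shrub", "Pinyon-juniper deciduous shrub",
             "Pinyon-juniper grass", "Juniper grass",
             "Colorado Plateau / Great Basin grassland",
             "Montane / subalpine grassland",
             "Gambel oak shrubland", "Mountain mahogany mixed shrubland",
             "Riparian", "Chihuahuan desert scrub", "Alpine tundra"),
    zone = c("subalpine", "subalpine",
             "montane", "montane", "montane", "montane",
             rep("woodland", 8),
             "grassland", "grassland",
             "shrubland", "shrubland",
             "riparian", "desert", "alpine"),
    lifeform = c(rep("tree", 14), "herb", "herb", "shrub", "shrub",
                 "tree", "herb", "herb"),
    stringsAsFactors = FALSE
  )
  tax$is_forest_or_woodland <- tax$zone %in% c("subalpine", "montane", "woodland")
  if (!is.null(extra)) {
    tax <- rbind(tax, extra[, names(tax)])
  }
  validate_taxonomy(tax)
  class(tax) <- c("eru_taxonomy", "data.frame")
  tax
}

validate_taxonomy <- function(tax) {
  needed <- c("eru_id", "name", "zone", "lifeform", "is_forest_or_woodland")
  if (!all(needed %in% names(tax)))
    stop("taxonomy must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(tax$eru_id))
    stop("duplicate eru_id in taxonomy")
  zones <- c("subalpine", "montane", "woodland", "shrubland", "grassland",
             "riparian", "desert", "alpine")
  bad <- setdiff(tax$zone, zones)
  if (length(bad))
    stop("unknown zone(s): ", paste(bad, collapse = ", "))
  fw <- tax$zone %in% c("subalpine", "montane", "woodland")
  nf <- tax$zone %in% c("shrubland", "grassland", "desert", "alpine")
  if (any(fw & !tax$is_forest_or_woodland) || any(nf & tax$is_forest_or_woodland))
    stop("is_forest_or_woodland inconsistent with zone")
  invisible(tax)
}

#' Generalized vegetation vocabulary
#'
#' Maps ERU ids to the coarser vegetation labels used when summarizing
#' territory transitions: ponderosa pine, pine-oak and frequent-fire mixed
#' conifer forests are combined into "Dry Forest"; the pinyon-juniper group
#' collapses to "Pinyon-Juniper"; Madrean woodlands to "Madrean Woodland";
#' shrublands other than Gambel oak to "Upland Shrub".
#'
#' @param taxonomy an `eru_taxonomy`.
#' @return Named character vector: names are ERU ids, values generalized
#'   vegetation labels.
#' @export
eru_generalization <- function(taxonomy = eru_taxonomy()) {
  g <- character(nrow(taxonomy))
  names(g) <- taxonomy$eru_id
  g[taxonomy$zone == "woodland"] <- "Pinyon-Juniper"
  g[names(g) %in% c("MPO", "MEW")] <- "Madrean Woodland"
  g[names(g) %in% c("PPF", "PPE", "MCD")] <- "Dry Forest"
  g[names(g) == "MCA"] <- "Mixed Conifer with Aspen"
  g[names(g) %in% c("SFF", "BPF")] <- "Spruce-Fir Forest"
  g[taxonomy$zone == "riparian"] <- "Riparian"
  g[names(g) == "GAM"] <- "Gambel Oak Shrubland"
  g[names(g) == "MMS"] <- "Upland Shrub"
  g[taxonomy$zone == "grassland"] <- "Grassland"
  g[taxonomy$zone == "desert"] <- "Desert Scrub"
  g[taxonomy$zone == "alpine"] <- "Alpine"
  g
}

#' @export
print.eru_taxonomy <- function(x, ...) {
  cat("ERU taxonomy:", nrow(x), "vegetation types\n")
  print.data.frame(x, ...)
  invisible(x)
}
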
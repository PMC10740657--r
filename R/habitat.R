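#' Species habitat profile
#'
#' A habitat profile defines a species' breeding habitat as a set of ERUs
#' (vegetation types) and the model zones where the profile applies. A
#' distinct 2090 zone set allows for projected range expansion (e.g. a
#' species at the northern edge of its range gaining zones to the north);
#' it defaults to the current zone set.
#'
#' @param species species id/name.
#' @param erus non-empty character vector of ERU ids.
#' @param zones integer vector of model-zone ids where the profile applies.
#' @param zones_2090 zone set for projected habitat; defaults to `zones`.
#' @param buffer_m habitat buffer distance in metres (default 1000).
#' @return Object of class `species_profile`.
#' @export
species_profile <- function(species, erus, zones, zones_2090 = zones,
                            buffer_m = 1000) {
  if (!length(erus)) stop("profile ERU set must be non-empty")
  structure(list(species = species, erus = unique(erus),
                 zones = unique(zones), zones_2090 = unique(zones_2090),
                 buffer_m = buffer_m),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("species_profile:", x$species, "\n")
  cat("  ERUs:", paste(x$erus, collapse = " "), "\n")
  cat("  zones:", paste(x$zones, collapse = " "),
      "| 2090 zones:", paste(x$zones_2090, collapse = " "), "\n")
  invisible(x)
}

#' Default habitat profiles for the eight montane owl species
#'
#' Vegetation-based breeding habitat profiles for the eight owl species of
#' Southwestern montane woodlands and forests, expressed against the
#' default taxonomy and the default four-zone synthetic partition (zone 1
#' southmost, zone `n_zones` northmost). Montane-forest specialists
#' (flammulated and northern saw-whet owls) exclude pinyon-juniper and
#' Madrean pinyon-oak woodland, where breeding records are largely
#' restricted to the ecotone with ponderosa pine. The whiskered
#' screech-owl, a species entering the region from the south, gains two
#' zones in its 2090 set to allow projected northward expansion; the boreal
#' owl is confined to the northern zones; the northern saw-whet owl to all
#' but the southmost zone. The table is a starting point and user-editable.
#'
#' @param taxonomy an [eru_taxonomy()].
#' @param n_zones number of model zones on the target landscape.
#' @return Named list of [species_profile()] objects.
#' @export
default_owl_profiles <- function(taxonomy = eru_taxonomy(), n_zones = 4) {
  tz <- function(zone) taxonomy$eru_id[taxonomy$zone %in% zone]
  montane <- tz("montane")
  subalpine <- tz("subalpine")
  woodland <- tz("woodland")
  madrean <- intersect(c("MPO", "MEW"), taxonomy$eru_id)
  all_z <- seq_len(n_zones)
  north2 <- tail(all_z, 2)
  profs <- list(
    flammulated_owl = species_profile("flammulated_owl", montane, all_z),
    western_screech_owl = species_profile("western_screech_owl", woodland, all_z),
    whiskered_screech_owl = species_profile(
      "whiskered_screech_owl",
      unique(c("PPF", "PPE", madrean)),
      zones = 1L, zones_2090 = c(1L, 2L)),
    great_horned_owl = species_profile(
      "great_horned_owl", c(subalpine, montane, woodland), all_z),
    northern_pygmy_owl = species_profile(
      "northern_pygmy_owl", c(subalpine, montane, woodland), all_z),
    long_eared_owl = species_profile(
      "long_eared_owl", c(subalpine, montane, woodland), all_z),
    boreal_owl = species_profile("boreal_owl", subalpine, north2),
    northern_saw_whet_owl = species_profile(
      "northern_saw_whet_owl", c(subalpine, montane), all_z[-1])
  )
  profs
}

#' Render a habitat profile to a habitat map
#'
#' Current habitat (no projection supplied): a cell is habitat iff its ERU
#' is in the profile and its model zone in the profile's current zone set.
#' Projected habitat: the zone test uses the 2090 zone set and the
#' vegetation test uses the 2090 projection, either inclusively (any
#' candidate ERU in the profile; the default, erring towards inclusion
#' where envelopes overlap) or by the single most-likely ERU.
#'
#' @param profile a [species_profile()].
#' @param landscape a [landscape()].
#' @param projection optional [project_landscape()] result for 2090 habitat.
#' @param mode `"inclusive"` (default) or `"most_likely"`.
#' @return An unbuffered [habitat_map()] with matching provenance.
#' @export
render_habitat <- function(profile, landscape, projection = NULL,
                           mode = c("inclusive", "most_likely")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "species_profile"),
            inherits(landscape, "landscape"))
  unknown <- setdiff(profile$erus, landscape$taxonomy$eru_id)
  if (length(unknown))
    stop("profile ERU id(s) not in taxonomy: ", paste(unknown, collapse = ", "))
  zones_present <- unique(as.vector(landscape$zone))
  if (is.null(projection)) {
    bad <- setdiff(profile$zones, zones_present)
    if (length(bad))
      stop("profile zone id(s) not on landscape: ", paste(bad, collapse = ", "))
    mask <- matrix(as.vector(landscape$eru) %in% profile$erus &
                     as.vector(landscape$zone) %in% profile$zones,
                   landscape$nrow, landscape$ncol)
    habitat_map(landscape, mask, "current")
  } else {
    stopifnot(inherits(projection, "eru_projection"))
    bad <- setdiff(profile$zones_2090, zones_present)
    if (length(bad))
      stop("profile 2090 zone id(s) not on landscape: ",
           paste(bad, collapse = ", "))
    veg <- if (mode == "inclusive") {
      candidate_member(projection, profile$erus)
    } else {
      matrix(as.vector(projection$most_likely) %in% profile$erus,
             landscape$nrow, landscape$ncol)
    }
    mask <- veg & matrix(as.vector(landscape$zone) %in% profile$zones_2090,
                         landscape$nrow, landscape$ncol)
    habitat_map(landscape, mask, "projected")
  }
}

round_to_nearest_5 <- function(x) {
  # nearest multiple of 5, ties away from zero
  sign(x) * floor(abs(x) / 5 + 0.5) * 5
}

#' Habitat change summary
#'
#' Compares current and projected habitat maps on the same landscape:
#' extents, raw percent change, percent change rounded to the nearest 5
#' (ties away from zero — the display convention that reproduces published
#' regional percentages from their extent pairs), and the persisted /
#' gained / lost area decomposition (projected = persisted + gained).
#'
#' @param current,projected [habitat_map()]s over the same landscape.
#' @param species optional species id carried into the output.
#' @return Object of class `change_summary` (also a one-row data frame):
#'   `current_ha`, `projected_ha`, `pct_change_raw`, `pct_change_rounded`,
#'   `persisted_ha`, `gained_ha`, `lost_ha`. Percent change is `NA` when
#'   the current extent is zero.
#' @examples
#' # arithmetic alone: a 4,684,000 -> 714,000 ha contraction is -85%
#' percent_change(4684000, 714000)
#' @export
change_summary <- function(current, projected, species = NA_character_) {
  stopifnot(inherits(current, "habitat_map"), inherits(projected, "habitat_map"))
  if (!identical(dim(current$mask), dim(projected$mask)))
    stop("maps must share a landscape")
  a <- current$landscape$cell_area_ha
  cur_ha <- extent_ha(current)
  proj_ha <- extent_ha(projected)
  persisted <- sum(current$mask & projected$mask) * a
  gained <- sum(!current$mask & projected$mask) * a
  lost <- sum(current$mask & !projected$mask) * a
  pc <- percent_change(cur_ha, proj_ha)
  out <- data.frame(species = species,
                    current_ha = cur_ha, projected_ha = proj_ha,
                    pct_change_raw = pc["raw"],
                    pct_change_rounded = pc["rounded"],
                    persisted_ha = persisted, gained_ha = gained,
                    lost_ha = lost, row.names = NULL)
  class(out) <- c("change_summary", "data.frame")
  out
}

#' Percent change in habitat extent
#'
#' @param current_ha,projected_ha extents in hectares (vectorized).
#' @return Named numeric (or 2-column matrix when vectorized): `raw` percent
#'   change `100 * (projected - current) / current` and `rounded`, its value
#'   rounded to the nearest multiple of 5 with ties away from zero. `NA`
#'   when the current extent is zero.
#' @export
percent_change <- function(current_ha, projected_ha) {
  raw <- ifelse(current_ha == 0, NA_real_,
                100 * (projected_ha - current_ha) / current_ha)
  res <- cbind(raw = raw, rounded = round_to_nearest_5(raw))
  if (length(current_ha) == 1L) res[1, ] else res
}

#' Classify occurrence records against a habitat map
#'
#' Point-in-cell test against the unbuffered mask, then against the
#' buffered mask for the remainder: every record is within the model,
#' within the buffer only, or outside; the three counts partition the
#' total. Records off the landscape are counted as outside, with a warning.
#'
#' @param records data frame with `x`, `y` in metres.
#' @param map unbuffered [habitat_map()].
#' @param buffer_distance buffer in metres (default 1000).
#' @return Object of class `capture_table` (one-row data frame):
#'   `within_model`, `within_buffer`, `outside_buffer`, `total`.
#' @export
capture_records <- function(records, map, buffer_distance = 1000) {
  stopifnot(inherits(map, "habitat_map"))
  ls <- map$landscape
  rc <- point_to_cell(ls, records$x, records$y)
  off <- is.na(rc[, "row"])
  if (any(off))
    warning(sum(off), " record(s) off the landscape; counted as outside")
  inside <- !off
  idx <- (rc[inside, "col"] - 1L) * ls$nrow + rc[inside, "row"]
  in_model <- logical(nrow(records))
  in_model[inside] <- map$mask[idx]
  buf <- buffer_mask(map, buffer_distance)
  in_buf <- logical(nrow(records))
  in_buf[inside] <- buf$mask[idx]
  within_model <- sum(in_model)
  within_buffer <- sum(in_buf & !in_model)
  outside <- nrow(records) - within_model - within_buffer
  out <- data.frame(within_model = within_model,
                    within_buffer = within_buffer,
                    outside_buffer = outside,
                    total = nrow(records))
  class(out) <- c("capture_table", "data.frame")
  out
}

#' Thin detection points to non-overlapping buffers
#'
#' Greedy thinning for clustered detection data: walk the points in input
#' order and keep each one whose disc of radius `radius_m` does not overlap
#' the disc of an already-kept point (i.e. centres at least `2 * radius_m`
#' apart). The result depends on input order; sort first if a different
#' priority is wanted.
#'
#' @param points data frame with `x`, `y` in metres.
#' @param radius_m disc radius in metres (default 250, the conventional
#'   independence radius for call-survey detections).
#' @return The kept subset of `points`, original order.
#' @export
thin_detections <- function(points, radius_m = 250) {
  if (!nrow(points)) return(points)
  keep <- logical(nrow(points))
  kx <- ky <- numeric(0)
  min2 <- (2 * radius_m)^2
  for (i in seq_len(nrow(points))) {
    if (!length(kx) ||
        all((points$x[i] - kx)^2 + (points$y[i] - ky)^2 >= min2)) {
      keep[i] <- TRUE
      kx <- c(kx, points$x[i]); ky <- c(ky, points$y[i])
    }
  }
  points[keep, , drop = FALSE]
}

#' Overlay territories on current and projected vegetation
#'
#' Fills each territory's current vegetation label (the generalized label
#' of the ERU at its cell) and projected label (the generalized label of
#' the cell's most-likely 2090 ERU).
#'
#' @param territories data frame with `territory_id`, `x`, `y`.
#' @param landscape a [landscape()].
#' @param projection a [project_landscape()] result.
#' @param generalization named character vector mapping every ERU id to a
#'   generalized vegetation label; default [eru_generalization()].
#' @return `territories` with `current_veg` and `projected_veg` filled.
#' @export
overlay_territories <- function(territories, landscape, projection,
                                generalization = eru_generalization(landscape$taxonomy)) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(projection, "eru_projection"))
  missing_g <- setdiff(unique(as.vector(landscape$eru)), names(generalization))
  if (length(missing_g))
    stop("generalization map missing ERU(s): ",
         paste(missing_g, collapse = ", "))
  rc <- point_to_cell(landscape, territories$x, territories$y)
  off <- is.na(rc[, "row"])
  if (any(off))
    stop("territory id(s) off the landscape: ",
         paste(territories$territory_id[off], collapse = ", "))
  idx <- (rc[, "col"] - 1L) * landscape$nrow + rc[, "row"]
  territories$current_veg <-
    unname(generalization[as.vector(landscape$eru)[idx]])
  territories$projected_veg <-
    unname(generalization[as.vector(projection$most_likely)[idx]])
  territories
}

veg_label_order <- c("Dry Forest", "Mixed Conifer with Aspen",
                     "Spruce-Fir Forest", "Pinyon-Juniper",
                     "Madrean Woodland", "Riparian", "Upland Shrub",
                     "Gambel Oak Shrubland", "Grassland", "Desert Scrub",
                     "Alpine")

#' Cross-tabulate territory vegetation transitions
#'
#' @param territories data frame with `current_veg` and `projected_veg`
#'   filled (see [overlay_territories()] or [flammulated_territories()]).
#' @return Object of class `transition_matrix`: integer `counts` matrix
#'   (rows = current, columns = projected), `row_totals`, `col_totals`,
#'   `total`.
#' @export
transition_matrix <- function(territories) {
  if (anyNA(territories$current_veg) || anyNA(territories$projected_veg))
    stop("territory vegetation labels must be filled before tabulation")
  labs <- union(territories$current_veg, territories$projected_veg)
  labs <- c(intersect(veg_label_order, labs), setdiff(labs, veg_label_order))
  counts <- table(factor(territories$current_veg, levels = labs),
                  factor(territories$projected_veg, levels = labs))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 total = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$total))
  cat("territory vegetation transitions (current rows, projected columns):\n")
  print(m)
  invisible(x)
}

#' Habitat-profile retention percentages from a transition matrix
#'
#' Three headline percentages for a set of profile vegetation labels:
#' the share of territories currently inside the profile, the share of all
#' territories projected to remain inside it, and — among territories
#' currently inside — the share moving to a queried set of labels.
#'
#' @param matrix a [transition_matrix()].
#' @param profile_labels labels constituting the species' habitat profile.
#' @param query_labels optional labels for the third percentage.
#' @return Named numeric: `pct_currently_in_profile`,
#'   `pct_remaining_in_profile`, and (if `query_labels` given)
#'   `pct_current_to_query`. Zero denominators give `NA`.
#' @export
profile_retention <- function(matrix, profile_labels, query_labels = NULL) {
  stopifnot(inherits(matrix, "transition_matrix"))
  labs <- rownames(matrix$counts)
  if (!all(profile_labels %in% labs))
    stop("profile label(s) not in matrix: ",
         paste(setdiff(profile_labels, labs), collapse = ", "))
  total <- matrix$total
  in_rows <- labs %in% profile_labels
  in_cols <- colnames(matrix$counts) %in% profile_labels
  n_current <- sum(matrix$counts[in_rows, , drop = FALSE])
  out <- c(
    pct_currently_in_profile = if (total > 0) 100 * n_current / total else NA_real_,
    pct_remaining_in_profile = if (total > 0)
      100 * sum(matrix$counts[in_rows, in_cols, drop = FALSE]) / total
    else NA_real_
  )
  if (!is.null(query_labels)) {
    q_cols <- colnames(matrix$counts) %in% query_labels
    out["pct_current_to_query"] <- if (n_current > 0)
      100 * sum(matrix$counts[in_rows, q_cols, drop = FALSE]) / n_current
    else NA_real_
  }
  out
}
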
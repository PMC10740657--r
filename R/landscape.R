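#' Gridded landscape of vegetation types
#'
#' A `landscape` is the spatial substrate of the habitat model: a regular
#' grid of square cells, each carrying one ERU id, one model-zone id and an
#' elevation. Model zones are the biogeographic regions used to constrain
#' where a species habitat profile applies. Coordinates are planar metres;
#' cell (1,1) has its centre at the origin, x increasing with column and y
#' with row.
#'
#' @param eru character matrix of ERU ids (rows x cols).
#' @param zone integer matrix of model-zone ids, same dimensions.
#' @param elevation numeric matrix of elevations in metres, same dimensions.
#' @param cell_size cell edge length in metres (square cells).
#' @param taxonomy an [eru_taxonomy()] covering every ERU id on the grid.
#' @return An object of class `landscape`.
#' @seealso [habitat_map()], [extent_ha()], [patch_statistics()]
#' @export
landscape <- function(eru, zone, elevation, cell_size = 100,
                      taxonomy = eru_taxonomy()) {
  stopifnot(is.matrix(eru), is.matrix(zone), is.matrix(elevation))
  if (!all(dim(eru) == dim(zone)) || !all(dim(eru) == dim(elevation)))
    stop("eru, zone and elevation must have identical dimensions")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number of metres")
  if (anyNA(eru) || anyNA(zone))
    stop("every cell must have exactly one ERU id and one model-zone id")
  unknown <- setdiff(unique(as.vector(eru)), taxonomy$eru_id)
  if (length(unknown))
    stop("ERU id(s) not in taxonomy: ", paste(unknown, collapse = ", "))
  storage.mode(zone) <- "integer"
  structure(list(
    eru = eru, zone = zone, elevation = elevation,
    nrow = nrow(eru), ncol = ncol(eru),
    cell_size = cell_size,
    cell_area_ha = cell_size^2 / 1e4,
    taxonomy = taxonomy
  ), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d cells of %g m (%.2f ha each), %.0f ha total\n",
              x$nrow, x$ncol, x$cell_size, x$cell_area_ha,
              x$nrow * x$ncol * x$cell_area_ha))
  cat("ERUs:", paste(sort(unique(as.vector(x$eru))), collapse = " "), "\n")
  cat("model zones:", paste(sort(unique(as.vector(x$zone))), collapse = " "), "\n")
  invisible(x)
}

#' Boolean habitat mask over a landscape
#'
#' A `habitat_map` wraps a logical cell mask together with its provenance
#' (`current` or `projected`) and buffering state. All extent, patch and
#' capture statistics derive from these masks.
#'
#' @param landscape a [landscape()].
#' @param mask logical matrix with the landscape's dimensions.
#' @param provenance `"current"` or `"projected"`.
#' @param buffered logical; has a buffer already been applied?
#' @param buffer_distance buffer distance in metres (0 if unbuffered).
#' @return An object of class `habitat_map`.
#' @export
habitat_map <- function(landscape, mask, provenance = c("current", "projected"),
                        buffered = FALSE, buffer_distance = 0) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(landscape, "landscape"), is.logical(mask))
  if (!all(dim(mask) == c(landscape$nrow, landscape$ncol)))
    stop("mask dimensions must match the landscape")
  mask[is.na(mask)] <- FALSE
  structure(list(landscape = landscape, mask = mask,
                 provenance = provenance, buffered = buffered,
                 buffer_distance = buffer_distance),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("habitat_map (%s%s): %d of %d cells true, %.1f ha\n",
              x$provenance,
              if (x$buffered) sprintf(", buffered %g m", x$buffer_distance) else "",
              sum(x$mask), length(x$mask), extent_ha(x)))
  invisible(x)
}

#' Habitat extent in hectares
#'
#' @param map a [habitat_map()].
#' @return Number of true cells times cell area, in hectares.
#' @export
extent_ha <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  sum(map$mask) * map$landscape$cell_area_ha
}

#' Buffer a habitat mask
#'
#' Expands a mask by Euclidean distance between cell centres: an output cell
#' is true iff its centre lies within `distance` metres of the centre of any
#' true input cell (cells at exactly the distance are included). A 1 km
#' buffer is the conventional allowance for positional uncertainty in both
#' habitat mapping and occurrence records.
#'
#' @param map an unbuffered [habitat_map()].
#' @param distance buffer distance in metres, `>= 0`.
#' @return A `habitat_map` with the same provenance, `buffered = TRUE`.
#' @examples
#' ls <- synthetic_landscape(synthetic_config(nrow = 40, ncol = 40, seed = 1))
#' hm <- habitat_map(ls, ls$eru == "PPF")
#' extent_ha(buffer_mask(hm, 1000)) >= extent_ha(hm)
#' @export
buffer_mask <- function(map, distance) {
  stopifnot(inherits(map, "habitat_map"))
  if (!is.numeric(distance) || length(distance) != 1 || is.na(distance) ||
      distance < 0)
    stop("buffer distance must be a single non-negative number of metres")
  if (map$buffered)
    stop("map is already buffered")
  cs <- map$landscape$cell_size
  r <- floor(distance / cs)
  out <- map$mask
  if (any(map$mask) && r >= 0) {
    # dilate by OR-ing shifted copies for every cell offset within the radius
    nr <- nrow(out); nc <- ncol(out)
    for (dy in -r:r) {
      for (dx in -r:r) {
        if ((dx == 0 && dy == 0) || (dx^2 + dy^2) * cs^2 > distance^2) next
        src_r <- max(1, 1 - dy):min(nr, nr - dy)
        src_c <- max(1, 1 - dx):min(nc, nc - dx)
        out[src_r + dy, src_c + dx] <- out[src_r + dy, src_c + dx] |
          map$mask[src_r, src_c]
      }
    }
  }
  habitat_map(map$landscape, out, map$provenance,
              buffered = TRUE, buffer_distance = distance)
}

# connected-component labels of a logical matrix; 0 = background
label_components <- function(mask, connectivity = c("rook", "queen")) {
  connectivity <- match.arg(connectivity)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx_all <- which(mask)
  if (!length(idx_all)) return(labels)
  row_of <- ((idx_all - 1L) %% nr) + 1L
  # neighbour index offsets (column-major), guarded against row wrap below
  current <- 0L
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    labels[start] <- current
    frontier <- start
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      cand <- c(frontier[r > 1L] - 1L,            # up
                frontier[r < nr] + 1L,            # down
                frontier - nr,                    # left
                frontier + nr)                    # right
      if (connectivity == "queen") {
        cand <- c(cand,
                  frontier[r > 1L] - 1L - nr, frontier[r > 1L] - 1L + nr,
                  frontier[r < nr] + 1L - nr, frontier[r < nr] + 1L + nr)
      }
      cand <- cand[cand >= 1L & cand <= nr * nc]
      cand <- unique(cand[mask[cand] & labels[cand] == 0L])
      labels[cand] <- current
      frontier <- cand
    }
  }
  labels
}

#' Patch statistics of a habitat mask
#'
#' Identifies patches as connected components of true cells (the raster
#' analogue of dissolving adjacent habitat polygons) and summarizes their
#' areas. `rook` adjacency (shared edges) is the default, matching a
#' polygon dissolve on shared boundaries; `queen` additionally joins cells
#' touching only at corners and is offered for sensitivity checks.
#'
#' @param map a [habitat_map()].
#' @param connectivity `"rook"` (4-neighbour, default) or `"queen"`
#'   (8-neighbour).
#' @return An object of class `patch_stats`: list with `n_patches`,
#'   `areas_ha` (per-patch, descending), `min_ha`, `max_ha`, `mean_ha`,
#'   `sd_ha` (sample SD; 0 for a single patch) and `connectivity`. For an
#'   empty mask the summaries are `NA` and `n_patches` is 0.
#' @export
patch_statistics <- function(map, connectivity = c("rook", "queen")) {
  connectivity <- match.arg(connectivity)
  stopifnot(inherits(map, "habitat_map"))
  labels <- label_components(map$mask, connectivity)
  k <- max(labels)
  if (k == 0L) {
    out <- list(n_patches = 0L, areas_ha = numeric(0),
                min_ha = NA_real_, max_ha = NA_real_,
                mean_ha = NA_real_, sd_ha = NA_real_,
                connectivity = connectivity)
  } else {
    areas <- as.numeric(tabulate(labels[labels > 0L], k)) *
      map$landscape$cell_area_ha
    areas <- sort(areas, decreasing = TRUE)
    out <- list(n_patches = k, areas_ha = areas,
                min_ha = min(areas), max_ha = max(areas),
                mean_ha = mean(areas),
                sd_ha = if (k > 1L) stats::sd(areas) else 0,
                connectivity = connectivity)
  }
  class(out) <- "patch_stats"
  out
}

#' @export
print.patch_stats <- function(x, ...) {
  if (x$n_patches == 0L) {
    cat("patch_stats: empty mask (0 patches)\n")
  } else {
    cat(sprintf(
      "patch_stats (%s): %d patches, %.2f-%.2f ha (mean %.2f +/- %.2f)\n",
      x$connectivity, x$n_patches, x$min_ha, x$max_ha, x$mean_ha, x$sd_ha))
  }
  invisible(x)
}

# map planar (x, y) metres to cell indices (nearest centre); NA off-grid
point_to_cell <- function(landscape, x, y) {
  cs <- landscape$cell_size
  col <- as.integer(round(x / cs)) + 1L
  row <- as.integer(round(y / cs)) + 1L
  off <- row < 1L | row > landscape$nrow | col < 1L | col > landscape$ncol
  row[off] <- NA_integer_; col[off] <- NA_integer_
  cbind(row = row, col = col)
}

cell_centre <- function(landscape, row, col) {
  cs <- landscape$cell_size
  cbind(x = (col - 1) * cs, y = (row - 1) * cs)
}
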
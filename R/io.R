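#' Write a numeric matrix as an Esri ASCII grid
#'
#' Plain-text raster format (`ncols`/`nrows` header then row-major values,
#' top row first) readable by every desktop GIS. Integer-coded layers (ERU
#' codes, masks) and continuous layers (elevation, climate, vulnerability)
#' are both supported.
#'
#' @param m numeric or logical matrix (row 1 = top).
#' @param path output file.
#' @param cell_size cell edge in metres.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(m, path, cell_size = 100, nodata = -9999) {
  if (is.logical(m)) m <- m * 1L
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           "xllcorner 0", "yllcorner 0",
           paste("cellsize", cell_size),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @return List: `matrix`, `cell_size`, `nodata` (nodata cells are `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  cs <- val("cellsize"); nd <- val("NODATA_value")
  body <- lines[-(1:6)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nd] <- NA
  list(matrix = m, cell_size = cs, nodata = nd)
}

#' Write landscape layers to a directory
#'
#' Emits `eru.asc` (integer codes), `zone.asc`, `elevation.asc` and the
#' sidecar code table `eru_codes.csv` (columns `code`, `eru_id`, `name`,
#' `zone`, `lifeform`, `is_forest_or_woodland`).
#'
#' @param landscape a [landscape()].
#' @param dir output directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tax <- landscape$taxonomy
  code <- matrix(match(landscape$eru, tax$eru_id),
                 landscape$nrow, landscape$ncol)
  write_ascii_grid(code, file.path(dir, "eru.asc"), landscape$cell_size)
  write_ascii_grid(landscape$zone, file.path(dir, "zone.asc"),
                   landscape$cell_size)
  write_ascii_grid(landscape$elevation, file.path(dir, "elevation.asc"),
                   landscape$cell_size)
  codes <- data.frame(code = seq_len(nrow(tax)), tax)
  utils::write.csv(codes, file.path(dir, "eru_codes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read landscape layers written by [write_landscape()]
#'
#' @param dir directory containing `eru.asc`, `zone.asc`, `elevation.asc`
#'   and `eru_codes.csv`.
#' @return A [landscape()].
#' @export
read_landscape <- function(dir) {
  codes <- utils::read.csv(file.path(dir, "eru_codes.csv"),
                           stringsAsFactors = FALSE)
  g <- read_ascii_grid(file.path(dir, "eru.asc"))
  zone <- read_ascii_grid(file.path(dir, "zone.asc"))$matrix
  elev <- read_ascii_grid(file.path(dir, "elevation.asc"))$matrix
  tax <- codes[, c("eru_id", "name", "zone", "lifeform",
                   "is_forest_or_woodland")]
  validate_taxonomy(tax)
  class(tax) <- c("eru_taxonomy", "data.frame")
  eru <- matrix(codes$eru_id[g$matrix], nrow(g$matrix), ncol(g$matrix))
  landscape(eru, matrix(as.integer(zone), nrow(zone), ncol(zone)),
            elev, cell_size = g$cell_size, taxonomy = tax)
}

#' Write / read climate envelopes as CSV
#'
#' Long format with columns `eru_id`, `variable`, `mean`, `sd`.
#'
#' @param envelopes a `climate_envelopes` data frame.
#' @param path CSV file.
#' @export
write_envelopes <- function(envelopes, path) {
  utils::write.csv(as.data.frame(envelopes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelopes
#' @export
read_envelopes <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  envelope_matrices(env)   # validates
  class(env) <- c("climate_envelopes", "data.frame")
  env
}
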
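#' Climate-envelope vulnerability score
#'
#' Standardized departure of a projected climate value from an ERU's
#' pre-1990 envelope for one variable:
#' \deqn{VS = \frac{|\bar{x} - Val|}{2 s}}
#' where \eqn{\bar{x}} is the envelope mean, \eqn{Val} the projected 2090
#' value at the location, and \eqn{s} the inter-annual pre-1990 standard
#' deviation for the ERU. The score is zero when the projected value sits
#' at the envelope mean, symmetric in the sign of the departure, and equals
#' 1 at a departure of two standard deviations.
#'
#' @param mean envelope mean \eqn{\bar{x}} (vectorized).
#' @param sd inter-annual SD \eqn{s}, strictly positive.
#' @param value projected value \eqn{Val}.
#' @return Non-negative score, unitless.
#' @examples
#' vulnerability_score(120, 5, 140)  # 2
#' @export
vulnerability_score <- function(mean, sd, value) {
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("sd must be strictly positive")
  abs(mean - value) / (2 * sd)
}

# long envelope data frame -> list(mean = eru x var matrix, sd = ...)
envelope_matrices <- function(envelopes) {
  stopifnot(all(c("eru_id", "variable", "mean", "sd") %in% names(envelopes)))
  if (any(envelopes$sd <= 0)) stop("envelope sd must be > 0 for every variable")
  erus <- unique(envelopes$eru_id)
  vars <- unique(envelopes$variable)
  per_eru <- table(envelopes$eru_id)
  if (length(unique(per_eru)) != 1 || unique(per_eru) != length(vars))
    stop("variable list must be identical across all envelopes")
  m <- matrix(NA_real_, length(erus), length(vars),
              dimnames = list(erus, vars))
  s <- m
  m[cbind(envelopes$eru_id, envelopes$variable)] <- envelopes$mean
  s[cbind(envelopes$eru_id, envelopes$variable)] <- envelopes$sd
  if (anyNA(m)) stop("incomplete envelope table")
  list(mean = m, sd = s, erus = erus, vars = vars)
}

#' Aggregate multi-variable vulnerability
#'
#' Combines the per-variable vulnerability scores of a location against one
#' ERU envelope into a single score, by their mean (default) or maximum.
#'
#' @param cell_climate named numeric vector of projected values, one per
#'   climate variable.
#' @param envelope data frame with `variable`, `mean`, `sd` rows for one ERU.
#' @param method `"mean"` or `"max"`.
#' @return Single non-negative score.
#' @export
aggregate_vulnerability <- function(cell_climate, envelope,
                                    method = c("mean", "max")) {
  method <- match.arg(method)
  if (!setequal(names(cell_climate), envelope$variable))
    stop("variable sets of cell climate and envelope do not match")
  v <- vulnerability_score(envelope$mean, envelope$sd,
                           cell_climate[envelope$variable])
  if (method == "mean") mean(v) else max(v)
}

#' Candidate future ERUs for one location
#'
#' An envelope admits the location if the projected value of every climate
#' variable lies within `k` inter-annual SDs of the envelope mean (default
#' `k = 2`, so admission coincides with a per-variable vulnerability score
#' of at most 1). Overlapping envelopes can admit more than one outcome;
#' all admitting ERUs are returned. If no envelope admits the location, the
#' single ERU minimizing the mean aggregate vulnerability is returned, so
#' the candidate set is never empty.
#'
#' @param cell_climate named numeric vector of projected 2090 values.
#' @param envelopes `climate_envelopes` data frame.
#' @param k envelope half-width in SD units, `> 0`.
#' @return Character vector of ERU ids.
#' @export
candidate_future_erus <- function(cell_climate, envelopes, k = 2) {
  if (!nrow(envelopes)) stop("empty envelope set")
  if (k <= 0) stop("k must be > 0")
  em <- envelope_matrices(envelopes)
  val <- cell_climate[em$vars]
  dep <- abs(sweep(em$mean, 2, val))              # |val - mean| per eru x var
  admitted <- rowSums(dep <= k * em$sd) == length(em$vars)
  if (any(admitted)) {
    em$erus[admitted]
  } else {
    agg <- rowMeans(dep / (2 * em$sd))
    em$erus[which.min(agg)]
  }
}

#' Apply vegetation transition rules to a candidate set
#'
#' Narrows climate-admissible outcomes by successional realism: upland
#' shrub types are never projected to convert to woodlands or forests
#' (site factors, shrub recruitment strategies and fire regimes perpetuate
#' shrub dominance), so a shrubland cell may only transition to shrubland,
#' grassland or desert types. Woodlands and forests at their lower ecotone
#' may be projected to grassland or shrubland. Riparian types are never
#' produced as candidates (they cannot be modelled from upland envelopes).
#' If filtering empties the set the current ERU is retained: a cell is
#' never projected to no vegetation.
#'
#' @param current_eru the cell's current ERU id.
#' @param candidates non-empty character vector of candidate ERU ids.
#' @param taxonomy an [eru_taxonomy()].
#' @return Character vector of ERU ids, never empty.
#' @export
apply_transition_rules <- function(current_eru, candidates,
                                   taxonomy = eru_taxonomy()) {
  if (!length(candidates)) stop("candidates must be non-empty")
  zone_of <- taxonomy$zone[match(candidates, taxonomy$eru_id)]
  keep <- zone_of != "riparian"
  cur_zone <- taxonomy$zone[match(current_eru, taxonomy$eru_id)]
  if (identical(cur_zone, "shrubland")) {
    keep <- keep & zone_of %in% c("shrubland", "grassland", "desert")
  }
  out <- candidates[keep]
  if (!length(out)) current_eru else out
}

#' Project a landscape's vegetation to 2090
#'
#' For every cell: score the projected climate against each ERU envelope,
#' collect the admitting envelopes (see [candidate_future_erus()]), narrow
#' them by the transition rules, and record both the full candidate set
#' (the inclusive interpretation, which errs towards inclusion for habitat
#' profiles where envelopes overlap) and the single most-likely ERU (lowest
#' aggregate vulnerability; ties broken by taxonomy order). The aggregate
#' vulnerability of each cell's current ERU is recorded alongside. Riparian
#' cells are carried through unchanged: riparian systems have no envelope
#' and are excluded from projection.
#'
#' @param landscape a [landscape()].
#' @param climate_2090 named list of projected climate matrices.
#' @param envelopes `climate_envelopes` data frame covering every
#'   non-riparian ERU present on the landscape.
#' @param k envelope half-width in SD units.
#' @param aggregation `"mean"` (default) or `"max"` multi-variable
#'   combination.
#' @return Object of class `eru_projection`: `candidates` (cells x ERU
#'   logical matrix), `most_likely` (character matrix), `vs_current`
#'   (numeric matrix; `NA` for riparian cells), plus bookkeeping fields.
#' @export
project_landscape <- function(landscape, climate_2090, envelopes, k = 2,
                              aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(landscape, "landscape"))
  if (k <= 0) stop("k must be > 0")
  em <- envelope_matrices(envelopes)
  if (!all(em$vars %in% names(climate_2090)))
    stop("climate surfaces missing variable(s): ",
         paste(setdiff(em$vars, names(climate_2090)), collapse = ", "))
  tax <- landscape$taxonomy
  riparian_ids <- tax$eru_id[tax$zone == "riparian"]
  present <- unique(as.vector(landscape$eru))
  need <- setdiff(present, riparian_ids)
  lacking <- setdiff(need, em$erus)
  if (length(lacking))
    stop("missing envelope for ERU(s): ", paste(lacking, collapse = ", "))

  ncell <- landscape$nrow * landscape$ncol
  vals <- vapply(em$vars, function(v) as.vector(climate_2090[[v]]),
                 numeric(ncell))                       # ncell x nvar
  n_eru <- length(em$erus)
  admit <- matrix(TRUE, ncell, n_eru, dimnames = list(NULL, em$erus))
  agg <- matrix(0, ncell, n_eru, dimnames = list(NULL, em$erus))
  for (j in seq_len(n_eru)) {
    dep <- abs(sweep(vals, 2, em$mean[j, ]))
    admit[, j] <- rowSums(sweep(dep, 2, k * em$sd[j, ], `<=`)) ==
      length(em$vars)
    vsj <- sweep(dep, 2, 2 * em$sd[j, ], `/`)
    agg[, j] <- if (aggregation == "mean") rowMeans(vsj) else
      apply(vsj, 1, max)
  }
  # cells admitted by no envelope fall back to the minimum-mean-VS envelope
  agg_mean <- if (aggregation == "mean") agg else {
    am <- matrix(0, ncell, n_eru)
    for (j in seq_len(n_eru)) {
      dep <- abs(sweep(vals, 2, em$mean[j, ]))
      am[, j] <- rowMeans(sweep(dep, 2, 2 * em$sd[j, ], `/`))
    }
    am
  }
  none <- rowSums(admit) == 0L
  if (any(none)) {
    best <- max.col(-agg_mean[none, , drop = FALSE], ties.method = "first")
    admit[cbind(which(none), best)] <- TRUE
  }

  cur <- as.vector(landscape$eru)
  cur_zone <- tax$zone[match(cur, tax$eru_id)]
  # transition rules, vectorized over cells
  ok_zone <- tax$zone[match(em$erus, tax$eru_id)]
  shrub_ok <- ok_zone %in% c("shrubland", "grassland", "desert")
  is_shrub_cell <- cur_zone == "shrubland"
  if (any(is_shrub_cell))
    admit[is_shrub_cell, !shrub_ok] <- FALSE
  # emptied sets retain the current ERU (persistence fallback)
  emptied <- rowSums(admit) == 0L
  if (any(emptied)) {
    jj <- match(cur[emptied], em$erus)
    keep <- !is.na(jj)
    admit[cbind(which(emptied)[keep], jj[keep])] <- TRUE
  }
  # riparian cells are not projected: candidate set is the cell itself
  is_rip <- cur_zone == "riparian"
  if (any(is_rip)) admit[is_rip, ] <- FALSE

  # most likely: minimal aggregate VS among candidates, ties by taxonomy order
  tax_rank <- match(em$erus, tax$eru_id)
  ord <- order(tax_rank)
  score <- agg
  score[!admit] <- Inf
  score_o <- score[, ord, drop = FALSE]
  pick <- max.col(-score_o, ties.method = "first")
  most <- em$erus[ord][pick]
  most[is_rip] <- cur[is_rip]

  jcur <- match(cur, em$erus)
  vs_cur <- ifelse(is.na(jcur), NA_real_, agg[cbind(seq_len(ncell), jcur)])

  structure(list(
    landscape = landscape,
    eru_ids = em$erus,
    candidates = admit,
    riparian_cells = is_rip,
    most_likely = matrix(most, landscape$nrow, landscape$ncol),
    vs_current = matrix(vs_cur, landscape$nrow, landscape$ncol),
    k = k, aggregation = aggregation
  ), class = "eru_projection")
}

#' Candidate membership for one ERU
#'
#' @param projection an [project_landscape()] result.
#' @param eru_ids character vector of ERU ids.
#' @return Logical matrix: cell is `TRUE` if any of `eru_ids` is among its
#'   2090 candidates (riparian cells match their own, unchanged, ERU).
#' @export
candidate_member <- function(projection, eru_ids) {
  stopifnot(inherits(projection, "eru_projection"))
  ls <- projection$landscape
  hit <- eru_ids[eru_ids %in% projection$eru_ids]
  v <- if (length(hit))
    rowSums(projection$candidates[, hit, drop = FALSE]) > 0
  else rep(FALSE, ls$nrow * ls$ncol)
  rip_keep <- projection$riparian_cells & as.vector(ls$eru) %in% eru_ids
  matrix(v | rip_keep, ls$nrow, ls$ncol)
}

#' @export
print.eru_projection <- function(x, ...) {
  ls <- x$landscape
  cur <- as.vector(ls$eru)
  incl <- x$candidates[cbind(seq_along(cur),
                             match(cur, x$eru_ids))]
  incl[is.na(incl)] <- x$riparian_cells[is.na(incl)]
  cat(sprintf(
    "eru_projection (k = %g, %s aggregation): %d cells, %.1f%% retain current ERU among candidates\n",
    x$k, x$aggregation, length(cur), 100 * mean(incl)))
  cat("mean vulnerability of current ERUs:",
      sprintf("%.3f", mean(x$vs_current, na.rm = TRUE)), "\n")
  invisible(x)
}
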
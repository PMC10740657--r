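#' Spatially constrained randomization null for habitat model performance
#'
#' Tests whether a habitat model captures occurrence records better than
#' chance: each iteration draws `n` cells uniformly (with replacement) from
#' a sampling region — conventionally all woodland and forest cells,
#' optionally constrained to the species' model zones — and counts how many
#' fall inside the habitat mask. The headline metric is the number of
#' iterations whose capture count equals or exceeds the observed capture.
#' When the habitat mask spans the whole sampling region every random point
#' necessarily intersects it, so all iterations tie the model: a saturated
#' profile cannot outperform chance by construction.
#'
#' @param observed observed number of records captured by the habitat mask.
#' @param n number of records (points drawn per iteration).
#' @param sampling_mask logical matrix or [habitat_map()]: the region
#'   random points are drawn from; must be non-empty.
#' @param habitat_mask logical matrix or [habitat_map()] of modelled
#'   habitat, same dimensions.
#' @param iterations number of randomization iterations (default 500).
#' @param seed integer seed; fully determines the draws.
#' @return Object of class `randomization_result`: `observed`, `n`,
#'   `iterations`, `captures` (per-iteration counts), `n_outperform`.
#' @export
randomization_null <- function(observed, n, sampling_mask, habitat_mask,
                               iterations = 500, seed = 1L) {
  m_samp <- if (inherits(sampling_mask, "habitat_map")) sampling_mask$mask else sampling_mask
  m_hab <- if (inherits(habitat_mask, "habitat_map")) habitat_mask$mask else habitat_mask
  if (!identical(dim(m_samp), dim(m_hab)))
    stop("sampling and habitat masks must share dimensions")
  if (n < 1 || iterations < 1) stop("n and iterations must be >= 1")
  cells <- which(m_samp)
  if (!length(cells)) stop("sampling mask is empty")
  rng <- local_rng(seed, 600L)
  inside <- m_hab[cells]
  draws <- matrix(inside[ceiling(rng$runif(n * iterations) * length(cells))],
                  n, iterations)
  captures <- colSums(draws)
  structure(list(observed = observed, n = n, iterations = iterations,
                 captures = captures,
                 n_outperform = sum(captures >= observed)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomization null: observed %d/%d captured; %d of %d iterations equal or outperform\n",
    x$observed, x$n, x$n_outperform, x$iterations))
  invisible(x)
}

#' One-tailed two-proportion z-test against the randomization null
#'
#' Compares the observed capture proportion `observed / n` with the pooled
#' null proportion `sum(captures) / (n * iterations)` using a pooled
#' two-proportion z statistic with a Yates-style continuity correction
#' (`(1/n1 + 1/n2) / 2`, capped so it never overshoots the difference).
#' The alternative is one-sided: the model captures a greater proportion
#' than random samples. When the pooled proportion is degenerate (0 or 1)
#' the z statistic is undefined and the p-value comes from the exact
#' comparison of the two proportions.
#'
#' @param observed observed captures.
#' @param n number of records.
#' @param null_captures per-iteration null capture counts (from
#'   [randomization_null()]).
#' @param n_per_iter points per iteration (defaults to `n`).
#' @return List: `z`, `p_value`, `p_observed`, `p_null`, `degenerate`.
#' @export
one_tailed_z <- function(observed, n, null_captures, n_per_iter = n) {
  if (n < 1 || length(null_captures) < 1) stop("n and iterations must be >= 1")
  n1 <- n
  n2 <- n_per_iter * length(null_captures)
  p1 <- observed / n1
  p2 <- sum(null_captures) / n2
  pbar <- (observed + sum(null_captures)) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    return(list(z = NA_real_, p_value = if (p1 <= p2) 1 else 0,
                p_observed = p1, p_null = p2, degenerate = TRUE))
  }
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  d <- p1 - p2
  cc <- min((1 / n1 + 1 / n2) / 2, abs(d))
  z <- (d - sign(d) * cc) / se
  list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
       p_observed = p1, p_null = p2, degenerate = FALSE)
}

#' McNemar paired change test with the any-cell correction rule
#'
#' Tests whether the proportion of records inside the mapped habitat
#' differs between current and projected conditions, from the paired 2x2
#' table of concordant (`a` in/in, `d` out/out) and discordant (`b` in
#' current only, `c` in projected only) counts. The statistic is
#' `(b - c)^2 / (b + c)`, with the continuity-corrected form
#' `(|b - c| - 1)^2 / (b + c)` applied whenever any of the four cell
#' counts is below 5 (the rule used in the published analysis; common
#' practice conditions on the discordant cells only, so the trigger is
#' switchable). The corrected form is applied verbatim even when `b = c`
#' (where [stats::mcnemar.test()] skips its correction instead).
#'
#' @param b records inside current habitat but outside projected.
#' @param c records outside current habitat but inside projected.
#' @param a,d concordant counts (in/in and out/out).
#' @param correct `"any_cell_lt5"` (default), `"always"`, or `"never"`.
#' @return Object of class `mcnemar_result`: the four counts, `statistic`,
#'   `p_value` (upper tail of chi-square, 1 df), `correction_applied`.
#'   With `b + c = 0` the statistic is undefined and returned as `NA`.
#' @examples
#' mcnemar_change(b = 9, c = 0, a = 8, d = 3)   # chi-square 7.11
#' @export
mcnemar_change <- function(b, c, a = 0, d = 0,
                           correct = c("any_cell_lt5", "always", "never")) {
  correct <- match.arg(correct)
  counts <- base::c(a = a, b = b, c = c, d = d)  # param c shadows base::c
  if (any(counts < 0)) stop("counts must be non-negative")
  apply_cc <- switch(correct,
                     any_cell_lt5 = any(counts < 5),
                     always = TRUE,
                     never = FALSE)
  if (b + c == 0) {
    message("no discordant pairs (b + c = 0); McNemar statistic undefined")
    stat <- NA_real_
    p <- NA_real_
  } else {
    stat <- if (apply_cc) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, statistic = stat,
                 p_value = p, correction_applied = apply_cc),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf(
    "McNemar paired change test%s: chi-square = %s, p = %s (b = %d, c = %d)\n",
    if (x$correction_applied) " (continuity corrected)" else "",
    if (is.na(x$statistic)) "NA" else sprintf("%.2f", x$statistic),
    if (is.na(x$p_value)) "NA" else sprintf("%.4f", x$p_value),
    x$b, x$c))
  invisible(x)
}
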
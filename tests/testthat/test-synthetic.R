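test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- synthetic_config(nrow = 40, ncol = 40, seed = 11)
  a <- synthetic_landscape(cfg)
  b <- synthetic_landscape(cfg)
  expect_identical(a$eru, b$eru)
  expect_identical(a$elevation, b$elevation)
  expect_identical(synthetic_climate(a, cfg, TRUE),
                   synthetic_climate(b, cfg, TRUE))
  cfg2 <- synthetic_config(nrow = 40, ncol = 40, seed = 12)
  expect_false(identical(synthetic_landscape(cfg2)$elevation, a$elevation))
})

test_that("flat single-band configuration yields a uniform landscape", {
  cfg <- synthetic_config(
    nrow = 10, ncol = 10, seed = 1, n_hills = 0,
    bands = data.frame(eru_id = "PPF", low = 2250, high = 2550),
    elev_range = c(2400, 2400), n_riparian_corridors = 0)
  ls <- synthetic_landscape(cfg)
  expect_true(all(ls$eru == "PPF"))
  expect_true(all(ls$elevation == 2400))
})

test_that("mean elevations of generated vegetation types follow the gradient", {
  cfg <- synthetic_config(nrow = 100, ncol = 100, seed = 5)
  ls <- synthetic_landscape(cfg)
  means <- tapply(as.vector(ls$elevation), as.vector(ls$eru), mean)
  ord <- c("CDS", "CPG", "PJO", "MCA", "SFF", "ALP")  # desert ... alpine
  expect_true(all(diff(means[ord]) > 0))
  # bands must cover the generated elevation range
  bad <- synthetic_config(nrow = 10, ncol = 10, seed = 1,
                          elev_range = c(500, 4000))
  expect_error(synthetic_landscape(bad), "cover")
})

test_that("climate surfaces follow the lapse-rate model and the uplift substitution", {
  cfg <- clean_config(nrow = 30, ncol = 100, seed = 2, offset = 0)
  ls <- synthetic_landscape(cfg)
  now <- synthetic_climate(ls, cfg, warmed = FALSE)
  warm <- synthetic_climate(ls, cfg, warmed = TRUE)
  expect_identical(now[names(now)], warm[names(warm)])  # offset 0: identical
  cfg3 <- clean_config(nrow = 30, ncol = 100, seed = 2, offset = 300)
  warm3 <- synthetic_climate(ls, cfg3, warmed = TRUE)
  for (v in names(now)) {
    # noise-free: warmed value equals the unwarmed value 300 m lower
    expect_equal(warm3[[v]],
                 cfg$intercept[[v]] + cfg$lapse[[v]] * (ls$elevation - 300),
                 tolerance = 1e-10)
  }
  # flat terrain, no noise: constant surface
  flat <- synthetic_config(
    nrow = 8, ncol = 8, seed = 1, n_hills = 0,
    bands = data.frame(eru_id = "PPF", low = 2250, high = 2550),
    elev_range = c(2400, 2400), n_riparian_corridors = 0,
    noise_sd = c(var1 = 0, var2 = 0, var3 = 0, var4 = 0, var5 = 0))
  lsf <- synthetic_landscape(flat)
  cf <- synthetic_climate(lsf, flat)
  expect_true(all(vapply(cf, function(m) diff(range(m)) == 0, logical(1))))
})

test_that("envelopes carry cellwise means and the configured inter-annual SD", {
  cfg <- clean_config(nrow = 30, ncol = 100, seed = 2)
  ls <- synthetic_landscape(cfg)
  clim <- synthetic_climate(ls, cfg)
  env <- fit_envelopes(ls, clim, cfg$interannual_sd)
  # means match direct computation per ERU/variable
  for (e in c("PPF", "SFF")) {
    for (v in c("var1", "var2")) {
      expect_equal(env$mean[env$eru_id == e & env$variable == v],
                   mean(clim[[v]][ls$eru == e]))
    }
  }
  # x-bar ordering across an elevation split follows the lapse sign
  m_low <- env$mean[env$eru_id == "CDS" & env$variable == "var1"]
  m_high <- env$mean[env$eru_id == "SFF" & env$variable == "var1"]
  expect_true((m_high - m_low) * sign(cfg$lapse[["var1"]]) > 0)
  # configured SD is passed through verbatim; non-positive SD is rejected
  sd5 <- cfg$interannual_sd; sd5[] <- 5
  env5 <- fit_envelopes(ls, clim, sd5)
  expect_true(all(env5$sd == 5))
  expect_error(fit_envelopes(ls, clim, sd5 * 0), "> 0")
  # riparian gets no envelope
  expect_false("RIP" %in% env$eru_id)
})

test_that("occurrence placement respects the commission fraction", {
  cfg <- synthetic_config(nrow = 60, ncol = 60, seed = 9, n_points = 100,
                          commission = 0.2, position_error_sd = 0)
  ls <- synthetic_landscape(cfg)
  hab <- render_habitat(default_owl_profiles()$flammulated_owl, ls)
  occ <- synthetic_occurrences(hab, ls, cfg)
  cap <- capture_records(occ, hab, 1000)
  expect_equal(cap$within_model, 80)          # (1 - 0.2) * 100 by construction
  expect_equal(cap$total, 100)
  # commission 0: everything inside; commission 1: nothing inside
  cfg0 <- synthetic_config(nrow = 60, ncol = 60, seed = 9, n_points = 50,
                           commission = 0, position_error_sd = 0)
  expect_equal(capture_records(synthetic_occurrences(hab, ls, cfg0), hab,
                               1000)$within_model, 50)
  cfg1 <- synthetic_config(nrow = 60, ncol = 60, seed = 9, n_points = 50,
                           commission = 1, position_error_sd = 0)
  expect_equal(capture_records(synthetic_occurrences(hab, ls, cfg1), hab,
                               1000)$within_model, 0)
  expect_true(all(occ$precision_m <= 1000))
})

test_that("territory fixture reproduces the published marginals", {
  terr <- flammulated_territories()
  expect_equal(nrow(terr), 148)
  tm <- transition_matrix(terr)
  expect_equal(tm$total, 148)
  expect_equal(unname(tm$counts["Dry Forest", "Pinyon-Juniper"]), 122L)
  expect_equal(unname(tm$col_totals[c("Dry Forest", "Madrean Woodland",
                                      "Pinyon-Juniper", "Riparian",
                                      "Gambel Oak Shrubland")]),
               c(5L, 9L, 124L, 7L, 3L))
  expect_equal(unname(tm$row_totals["Dry Forest"]), 132L)
  expect_equal(unname(tm$col_totals["Riparian"]), 7L)
})
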
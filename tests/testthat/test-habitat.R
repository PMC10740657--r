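test_that("habitat rendering honours profile vegetation and zone sets", {
  cfg <- synthetic_config(nrow = 50, ncol = 50, seed = 21)
  ls <- synthetic_landscape(cfg)
  tax <- ls$taxonomy
  # all forest+woodland profile: mask equals all forest/woodland cells
  all_fw <- species_profile("generalist", tax$eru_id[tax$is_forest_or_woodland],
                            1:4)
  hm <- render_habitat(all_fw, ls)
  expect_identical(hm$mask,
                   matrix(tax$is_forest_or_woodland[match(ls$eru, tax$eru_id)] &
                            TRUE, ls$nrow, ls$ncol))
  # zone exclusion leaves no habitat in the excluded zone
  p13 <- species_profile("sub", tax$eru_id[tax$is_forest_or_woodland], c(1L, 3L))
  hm13 <- render_habitat(p13, ls)
  expect_equal(sum(hm13$mask & ls$zone == 2), 0)
  expect_error(render_habitat(species_profile("bad", "NOPE", 1L), ls), "NOPE")
  expect_error(render_habitat(species_profile("bad", "PPF", 99L), ls), "99")
})

test_that("projected rendering is inclusive by default and respects 2090 zones", {
  cfg <- synthetic_config(nrow = 60, ncol = 60, seed = 8, warming_offset_m = 0)
  ls <- synthetic_landscape(cfg)
  clim <- synthetic_climate(ls, cfg, warmed = TRUE)
  env <- fit_envelopes(ls, clim, cfg$interannual_sd)
  proj <- project_landscape(ls, clim, env)
  prof <- species_profile("m", c("PPF", "MCA"), zones = 1:4,
                          zones_2090 = c(2L, 3L))
  cur <- render_habitat(prof, ls)
  fut <- render_habitat(prof, ls, proj)    # zero warming, inclusive
  # recovery: projection keeps at least the current habitat inside 2090 zones
  in_zone <- matrix(as.vector(ls$zone) %in% c(2L, 3L), ls$nrow, ls$ncol)
  expect_true(all(fut$mask[cur$mask & in_zone]))
  expect_equal(sum(fut$mask & !in_zone), 0)
  # inclusive is a superset of most-likely
  ml <- render_habitat(prof, ls, proj, mode = "most_likely")
  expect_true(all(fut$mask[ml$mask]))
})

test_that("percent change reproduces the published regional table arithmetic", {
  ext <- owl_extents()
  pc <- percent_change(ext$current_ha, ext$projected_ha)
  expect_equal(unname(pc[, "rounded"]),
               c(-85, -55, -5, -35, -75, -70, -85, -60))
  # worked examples at full precision
  expect_equal(unname(percent_change(4684000, 714000)["raw"]), -84.7566,
               tolerance = 1e-4)
  expect_equal(unname(percent_change(306000, 42000)["raw"]), -86.2745,
               tolerance = 1e-4)
  # rounding rule: nearest 5, ties away from zero
  expect_equal(unname(percent_change(1000, 1025)["rounded"]), 5)   # +2.5 -> 5
  expect_equal(unname(percent_change(1000, 975)["rounded"]), -5)   # -2.5 -> -5
  expect_equal(unname(percent_change(1000, 1020)["rounded"]), 0)   # +2 -> 0
})

test_that("change summaries decompose into persisted plus gained", {
  ls <- flat_landscape(20, 20)
  cur <- mask_map(ls, 1:100)
  fut <- mask_map(ls, 51:170, "projected")
  cs <- change_summary(cur, fut, "sp")
  expect_equal(cs$current_ha, 100)
  expect_equal(cs$projected_ha, 120)
  expect_equal(cs$persisted_ha + cs$gained_ha, cs$projected_ha)
  expect_equal(cs$lost_ha, 50)
  expect_equal(cs$pct_change_raw, 20)
  expect_equal(cs$pct_change_rounded, 20)
  # identical masks: zero everywhere
  cs0 <- change_summary(cur, habitat_map(ls, cur$mask, "projected"))
  expect_equal(cs0$pct_change_raw, 0)
  expect_equal(cs0$gained_ha + cs0$lost_ha, 0)
  # empty current habitat: change undefined, reported absent
  csNA <- change_summary(mask_map(ls), fut)
  expect_true(is.na(csNA$pct_change_raw) && is.na(csNA$pct_change_rounded))
  expect_equal(abs(cs$pct_change_rounded - cs$pct_change_raw) <= 2.5, TRUE)
})

test_that("record capture partitions the total across model, buffer, outside", {
  ls <- flat_landscape(50, 50)
  hm <- mask_map(ls, as.matrix(expand.grid(20:30, 20:30)))
  # record 500 m from nearest habitat cell: inside the 1 km buffer only
  rec <- data.frame(x = (19 - 1) * 100, y = (30 + 5 - 1) * 100)
  cap <- capture_records(rec, hm, 1000)
  expect_equal(cap$within_buffer, 1)
  expect_equal(cap$within_model, 0)
  # all records on habitat cells
  recs_in <- data.frame(x = c(1900, 2500), y = c(1900, 2500))
  expect_equal(capture_records(recs_in, hm, 1000)$within_model, 2)
  # partition property on random inputs, including off-landscape points
  set.seed(2)
  for (rep in 1:5) {
    recs <- data.frame(x = runif(40, -500, 5500), y = runif(40, -500, 5500))
    cap <- suppressWarnings(capture_records(recs, hm, 1000))
    expect_equal(cap$within_model + cap$within_buffer + cap$outside_buffer,
                 cap$total)
    expect_equal(cap$total, 40)
  }
})

test_that("detection thinning keeps only non-overlapping discs, in input order", {
  pts <- data.frame(x = c(0, 100, 600, 1200, 1210), y = 0)
  kept <- thin_detections(pts, radius_m = 250)
  expect_equal(kept$x, c(0, 600, 1200))        # 100 and 1210 overlap earlier discs
  expect_equal(nrow(thin_detections(pts[0, ])), 0)
  # order dependence is intentional: reversing changes the kept set
  kept_rev <- thin_detections(pts[5:1, ], radius_m = 250)
  expect_equal(sort(kept_rev$x), c(100, 600, 1210))
})

test_that("territory overlay assigns generalized labels from both periods", {
  cfg <- synthetic_config(nrow = 60, ncol = 60, seed = 31, warming_offset_m = 0)
  ls <- synthetic_landscape(cfg)
  clim <- synthetic_climate(ls, cfg, warmed = TRUE)
  env <- fit_envelopes(ls, clim, cfg$interannual_sd)
  proj <- project_landscape(ls, clim, env)
  gen <- eru_generalization(ls$taxonomy)
  # a territory on a ponderosa pine cell is Dry Forest
  ppf <- which(ls$eru == "PPF")[1]
  row <- ((ppf - 1) %% ls$nrow) + 1; col <- ((ppf - 1) %/% ls$nrow) + 1
  terr <- data.frame(territory_id = 1L, x = (col - 1) * 100, y = (row - 1) * 100)
  out <- overlay_territories(terr, ls, proj)
  expect_equal(out$current_veg, "Dry Forest")
  # zero warming: projected label equals current label for every territory.
  # Equal-width bands put every band mean at its centre, so the most-likely
  # ERU of an unchanged climate is the cell's own ERU everywhere.
  eq_bands <- data.frame(
    eru_id = c("CDS", "CPG", "GAM", "PJO", "PPF", "MCA", "SFF", "ALP"),
    low = seq(1000, 3100, 300), high = seq(1300, 3400, 300))
  cfge <- clean_config(nrow = 40, ncol = 150, seed = 31, offset = 0,
                       bands = eq_bands)
  lse <- synthetic_landscape(cfge)
  clime <- synthetic_climate(lse, cfge, warmed = TRUE)
  enve <- fit_envelopes(lse, clime, cfge$interannual_sd)
  proje <- project_landscape(lse, clime, enve)
  habe <- render_habitat(default_owl_profiles()$flammulated_owl, lse)
  terrs <- synthetic_territories(habe, lse, n = 60, seed = 2)
  terrs <- overlay_territories(terrs, lse, proje)
  expect_equal(terrs$projected_veg, terrs$current_veg)
  # off-landscape territories are an error naming the ids
  bad <- data.frame(territory_id = 99L, x = -5000, y = 0)
  expect_error(overlay_territories(bad, ls, proj), "99")
})

test_that("transition matrices cross-tabulate with consistent totals", {
  one <- data.frame(current_veg = "Dry Forest", projected_veg = "Dry Forest")
  tm1 <- transition_matrix(one)
  expect_equal(dim(tm1$counts), c(1, 1))
  expect_equal(tm1$total, 1)
  terr <- flammulated_territories()
  tm <- transition_matrix(terr)
  expect_equal(sum(tm$row_totals), tm$total)
  expect_equal(sum(tm$col_totals), tm$total)
  expect_equal(unname(tm$counts["Mixed Conifer with Aspen", "Dry Forest"]), 4L)
})

test_that("profile retention percentages match the published breeding-population summary", {
  tm <- transition_matrix(flammulated_territories())
  prof <- c("Dry Forest", "Mixed Conifer with Aspen")
  ret <- profile_retention(tm, prof, c("Madrean Woodland", "Pinyon-Juniper"))
  expect_equal(unname(ret["pct_currently_in_profile"]), 100 * 136 / 148)
  expect_equal(unname(ret["pct_remaining_in_profile"]), 100 * 5 / 148)
  expect_equal(unname(ret["pct_current_to_query"]), 100 * 131 / 136)
  expect_lt(ret["pct_remaining_in_profile"], 10)
  expect_gt(ret["pct_current_to_query"], 80)
  expect_error(profile_retention(tm, "Tundra"), "Tundra")
})
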
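# tiny in-code fixtures shared across tests

# uniform single-ERU landscape of given size
flat_landscape <- function(nr = 10, nc = 10, eru = "PPF", zone = 1L,
                           elev = 2400, cell_size = 100) {
  landscape(matrix(eru, nr, nc), matrix(as.integer(zone), nr, nc),
            matrix(elev, nr, nc), cell_size = cell_size)
}

mask_map <- function(ls, idx = integer(), provenance = "current") {
  m <- matrix(FALSE, ls$nrow, ls$ncol)
  m[idx] <- TRUE
  habitat_map(ls, m, provenance)
}

# noise-free deterministic config: plane elevation, no jitter, no riparian
clean_config <- function(nrow = 80, ncol = 120, seed = 1L, offset = 300, ...) {
  base <- synthetic_config(nrow = nrow, ncol = ncol, seed = seed,
                           warming_offset_m = offset, ...)
  synthetic_config(nrow = nrow, ncol = ncol, seed = seed,
                   warming_offset_m = offset,
                   n_hills = 0, edge_jitter_m = 0, jitter_prob = 0,
                   n_riparian_corridors = 0,
                   noise_sd = base$noise_sd * 0, ...)
}

# small overlapping two-envelope set for candidate tests
two_envelopes <- function(mean_a = c(v1 = 100, v2 = 50),
                          mean_b = c(v1 = 112, v2 = 56),
                          sd = c(v1 = 5, v2 = 3)) {
  env <- data.frame(
    eru_id = rep(c("PPF", "PJO"), each = 2),
    variable = rep(c("v1", "v2"), 2),
    mean = c(mean_a, mean_b),
    sd = rep(sd, 2))
  class(env) <- c("climate_envelopes", "data.frame")
  env
}
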
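# Shared fixtures: unit-parameter sets for hand arithmetic, a small
# plate for I/O tests, and an omega = 0 helper for the analytic oracle.

ones_rna_params <- function(...) {
  rna_only_params(alpha_X = 1, alpha_Y = 1, alpha_Z = 1, alpha_GFP = 1,
                  gamma = 1, omega = 1, delta_X = 1, delta_Y = 1,
                  delta_Z = 1, delta_GFP = 1, K_ara = 1, K_IPTG = 1,
                  m = 1, n = 1, S_G = 1, ...)
}

ones_hybrid_params <- function(...) {
  hybrid_params(alpha_X = 1, alpha_Y = 1, alpha_Z = 1, alpha_T = 1,
                alpha_G = 1, gamma = 1, omega = 1, delta_X = 1,
                delta_Y = 1, delta_Z = 1, delta_CY = 1, delta_CZ = 1,
                delta_T = 1, delta_G = 1, K_IPTG = 1, n = 1, k_atc = 1,
                k_off = 1, S_G = 1, ...)
}

# omega = 0 exactly, via the decoy structural override (the constructor
# domain is strictly positive)
zero_omega <- function(params) {
  apply_variant(params, circuit_variant("decoy"))
}

# two sample wells + one blank on a short grid, constant signals
tiny_plate <- function(times = seq(0, 50, by = 10), f_sample = 150,
                       f_blank = 50, od = 0.5) {
  n <- length(times)
  wells <- list(
    list(well_id = "A1", raw_fluorescence = rep(f_sample, n),
         od600 = rep(od, n),
         condition = inducer_condition(iptg = 500, arabinose = 6600),
         variant_id = "base", replicate = 1L, is_blank = FALSE),
    list(well_id = "A2", raw_fluorescence = rep(f_sample, n) + 10,
         od600 = rep(od, n),
         condition = inducer_condition(iptg = 500, arabinose = 6600),
         variant_id = "base", replicate = 2L, is_blank = FALSE),
    list(well_id = "B1", raw_fluorescence = rep(f_blank, n),
         od600 = rep(0.035, n),
         condition = inducer_condition(), variant_id = "blank",
         replicate = 1L, is_blank = TRUE))
  plate_reader_dataset(wells, times)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)),
            tol)
}
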
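test_that("Hill activation matches closed form and respects its domain", {
  expect_equal(hill_activation(0, 100, 2), 0)
  for (h in c(0.5, 1, 2, 4))
    expect_equal(hill_activation(100, 100, h), 0.5)
  expect_equal(hill_activation(500, 125, 1), 0.8)  # 500/625
  # monotone and strictly below 1
  I <- c(0, 1, 10, 100, 1e4, 1e8)
  v <- hill_activation(I, 50, 1.7)
  expect_false(is.unsorted(v))
  expect_true(all(v < 1))
  expect_error(hill_activation(10, -1, 1), "K must be")
  expect_error(hill_activation(10, 1, 0), "h must be")
  expect_error(hill_activation(-1, 1, 1), ">= 0")
})

test_that("induced plasmid pools follow the IPTG Hill curve", {
  p <- rna_only_params()
  expect_equal(unname(induced_plasmids(p, inducer_condition(iptg = 0))),
               c(0, 0))
  p2 <- rna_only_params(P_Y_total = 2, K_IPTG = 40, n = 3)
  ip <- induced_plasmids(p2, inducer_condition(iptg = 40))
  expect_equal(ip[["PY_star"]], 1.0)  # half of 2 at I = K
  p3 <- rna_only_params(K_IPTG = 125, n = 1)
  ip3 <- induced_plasmids(p3, inducer_condition(iptg = 500))
  expect_equal(ip3[["PZ_star"]], 0.8)
  expect_true(all(ip3 >= 0 & ip3 <= c(p3[["P_Y_total"]],
                                      p3[["P_Z_total"]])))
})

test_that("RNA-only right-hand side reproduces hand-computed derivatives", {
  p <- ones_rna_params()
  cond <- inducer_condition(iptg = 1, arabinose = 1)
  # extinction fixed point at zero inducers
  d0 <- rna_only_rhs(0, c(X = 0, Y = 0, Z = 0, GFP = 0), p,
                     inducer_condition())[[1]]
  expect_equal(unname(d0), rep(0, 4))
  # all-ones state, Hill = 1/2, PY* = PZ* = 1/2
  d <- rna_only_rhs(0, c(X = 1, Y = 1, Z = 1, GFP = 1), p, cond)[[1]]
  expect_equal(unname(d), c(-1.5, -1.5, -1.5, 0))
  expect_error(rna_only_rhs(0, c(X = -1, Y = 0, Z = 0, GFP = 0), p, cond),
               "negative state")
})

test_that("RNA-only rhs vanishes at the closed-form steady state", {
  p <- zero_omega(rna_only_params())
  cond <- inducer_condition(iptg = 500, arabinose = 6600)
  ss <- closed_form_steady_state_rna_only(p, cond)
  d <- rna_only_rhs(0, ss, p, cond)[[1]]
  expect_lt(max(abs(d)), 1e-9 * max(ss))
})

test_that("closed-form steady state matches hand arithmetic and Hill monotonicity", {
  p <- zero_omega(ones_rna_params())
  expect_equal(closed_form_steady_state_rna_only(
    p, inducer_condition(arabinose = 0)),
    c(X = 0, Y = 0, Z = 0, GFP = 0))
  ss <- closed_form_steady_state_rna_only(
    p, inducer_condition(iptg = 1, arabinose = 1))
  expect_equal(unname(ss), c(0.25, 0.125, 0.125, 0.125))
  # steady state non-decreasing in IPTG at fixed arabinose
  lad <- sapply(c(0, 1, 5, 50, 500), function(i)
    closed_form_steady_state_rna_only(
      p, inducer_condition(iptg = i, arabinose = 1))[["GFP"]])
  expect_false(is.unsorted(lad))
  expect_error(closed_form_steady_state_rna_only(
    ones_rna_params(), inducer_condition()), "omega = 0")
})

test_that("hybrid right-hand side reproduces hand-computed derivatives", {
  p <- ones_hybrid_params()
  # zero state with no TetR production and no inducers stays put
  pv <- apply_variant(p, circuit_variant("noTetR"))
  s0 <- setNames(rep(0, 8), c("X","Y","Z","C_XY","C_XZ","T","PZ_rep","G"))
  pv0 <- pv; pv0[["alpha_Y"]] <- 1e-300  # alpha_Y = 0 limit
  d <- hybrid_rhs(0, s0, pv0, inducer_condition())[[1]]
  expect_equal(unname(d), rep(0, 8), tolerance = 1e-250)
  # absorbing repressed boundary without relief
  p_norel <- hybrid_params(k_off = 1e-300)
  s <- s0; s[["PZ_rep"]] <- p_norel[["P_Z_total"]]
  d2 <- hybrid_rhs(0, s, p_norel, inducer_condition())[[1]]
  expect_equal(d2[["PZ_rep"]], 0, tolerance = 1e-250)
  # all-ones parameters, half-filled state (hand-evaluated oracle)
  s5 <- setNames(rep(0.5, 8), names(s0))
  d3 <- hybrid_rhs(0, s5, p, inducer_condition(iptg = 1, atc = 0))[[1]]
  expect_equal(unname(d3),
               c(-0.5, 0.25, -0.5, -0.25, -0.25, -0.25, -0.25, 0))
  # invariant violation
  sbad <- s5; sbad[["PZ_rep"]] <- 2
  expect_error(hybrid_rhs(0, sbad, p, inducer_condition()),
               "PZ_rep exceeds")
})

test_that("free parameter sets have the documented size and content", {
  rna <- free_parameter_names("rna_only")
  expect_length(rna, 15)
  expect_true("S_G" %in% rna)
  expect_false(any(c("P_X_total", "P_Y_total", "P_Z_total") %in% rna))
  hyb <- free_parameter_names("hybrid")
  expect_false(any(duplicated(hyb)))
  expect_length(intersect(hyb, c("P_X_total", "P_Y_total", "P_Z_total")),
                0)
  expect_error(free_parameter_names("other"))
})

test_that("variant presets override the intended parameters", {
  p <- rna_only_params()
  expect_equal(apply_variant(p, circuit_variant("decoy"))[["omega"]], 0)
  expect_equal(apply_variant(p, circuit_variant("insulated"))[["alpha_Y"]],
               5 * p[["alpha_Y"]])
  expect_true(isTRUE(circuit_variant("constitutive")$
                       override_map$structure_constitutive_Y))
  h <- hybrid_params()
  expect_equal(apply_variant(h, circuit_variant("noTetR"))[["alpha_T"]], 0)
  dT <- sapply(c("ASV", "AAV", "LVA"), function(v)
    apply_variant(h, circuit_variant(v))[["delta_T"]])
  expect_false(is.unsorted(dT, strictly = TRUE))
  expect_error(circuit_variant("ASV",
                               delta_T_tags = c(ASV = 1, AAV = 0.5,
                                                LVA = 2)),
               "increasing")
})

test_that("parameter constructors reject invalid values", {
  expect_error(rna_only_params(alpha_X = -1), "non-positive")
  expect_error(rna_only_params(m = 0), "non-positive")
  expect_error(hybrid_params(k_off = -0.1), "k_off")
  expect_error(as_iffl_params(c(alpha_X = 1), "rna_only"))
  # Hill coefficients are continuous positive reals
  expect_silent(rna_only_params(m = 1.7, n = 0.8))
})
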
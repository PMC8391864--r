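test_that("with no production the state decays exponentially", {
  p <- rna_only_params()
  init <- c(X = 3, Y = 0, Z = 0, GFP = 2)
  # horizon chosen so the decayed values stay well above the absolute
  # tolerance, where a relative comparison is meaningful
  tr <- simulate_circuit("rna_only", p, inducer_condition(), init = init,
                         grid = time_grid(100))
  expect_rel_equal(tr$states[, "X"], init[["X"]] *
                     exp(-p[["delta_X"]] * tr$times), 1e-4)
  expect_rel_equal(tr$states[, "GFP"], init[["GFP"]] *
                     exp(-p[["delta_GFP"]] * tr$times), 1e-4)
})

test_that("long-horizon simulation reaches the analytic steady state", {
  p <- zero_omega(rna_only_params())
  cond <- inducer_condition(iptg = 125, arabinose = 1650)
  tr <- simulate_circuit("rna_only", p, cond, grid = time_grid(3000),
                         variant = circuit_variant("decoy"))
  ss <- closed_form_steady_state_rna_only(p, cond)
  expect_rel_equal(tr$states[nrow(tr$states), ], ss, 1e-4)
})

test_that("compiled and R-level right-hand sides integrate identically", {
  for (model in c("rna_only", "hybrid")) {
    params <- if (model == "rna_only") rna_only_params()
              else hybrid_params()
    cond <- if (model == "rna_only")
      inducer_condition(iptg = 500, arabinose = 6600)
    else inducer_condition(iptg = 1000, atc = 40)
    grid <- time_grid(120)
    a <- simulate_circuit(model, params, cond, grid,
                          options = list(compiled = TRUE))
    b <- simulate_circuit(model, params, cond, grid,
                          options = list(compiled = FALSE))
    expect_equal(a$states, b$states, tolerance = 1e-6)
  }
})

test_that("adaptive stiff solver agrees with a fixed-step rk4 reference", {
  # coarse version of the integrator cross-check (the full 0.01-min
  # reference runs in the acceptance suite)
  p <- hybrid_params()
  cond <- inducer_condition(iptg = 200, atc = 40)
  grid <- time_grid(200)
  a <- simulate_circuit("hybrid", p, cond, grid)
  ref <- simulate_circuit("hybrid", p, cond, time_grid(200, cadence = 0.05),
                          options = list(method = "rk4"))
  idx <- match(grid$times, ref$times)
  dev <- abs(a$states - ref$states[idx, ])
  scale <- apply(abs(ref$states[idx, ]), 2, max)
  expect_lt(max(sweep(dev, 2, pmax(scale, 1e-12), "/")), 1e-3)
})

test_that("grid refinement only interpolates, never changes the dynamics", {
  p <- rna_only_params()
  cond <- inducer_condition(iptg = 500, arabinose = 6600)
  opts <- list(rtol = 1e-8, atol = 1e-11)  # test at matching precision
  coarse <- simulate_circuit("rna_only", p, cond, time_grid(300),
                             options = opts)
  fine <- simulate_circuit("rna_only", p, cond,
                           time_grid(300, cadence = 5), options = opts)
  expect_rel_equal(fine$states[nrow(fine$states), ],
                   coarse$states[nrow(coarse$states), ], 1e-6)
})

test_that("simulation is deterministic", {
  p <- hybrid_params()
  cond <- inducer_condition(iptg = 1000, atc = 400)
  a <- simulate_circuit("hybrid", p, cond)
  b <- simulate_circuit("hybrid", p, cond)
  expect_identical(a$states, b$states)
})

test_that("trajectories stay non-negative under random parameter draws", {
  for (model in c("rna_only", "hybrid")) {
    nominal <- if (model == "rna_only") rna_only_params()
               else hybrid_params()
    draws <- sample_perturbations(nominal, 0.5, n_draws = 5, seed = 99)
    cond <- if (model == "rna_only")
      inducer_condition(iptg = 31.2, arabinose = 412.5)
    else inducer_condition(iptg = 100, atc = 200)
    for (k in seq_len(nrow(draws))) {
      tr <- simulate_circuit(model, as_iffl_params(draws[k, ], model),
                             cond)
      expect_true(all(tr$states >= 0))
    }
  }
})

test_that("zero inducers leave both circuits extinguished", {
  tr <- simulate_circuit("rna_only", rna_only_params(),
                         inducer_condition())
  expect_true(all(tr$states == 0))
  trh <- simulate_circuit("hybrid", hybrid_params(), inducer_condition())
  # Y is constitutive so it accumulates, but GFP requires IPTG-driven Z
  expect_true(all(trh$states[, "G"] == 0))
  expect_gt(max(trh$states[, "Y"]), 0)
})

test_that("hybrid plasmid pools are conserved", {
  p <- hybrid_params()
  tr <- simulate_circuit("hybrid", p, inducer_condition(iptg = 1000,
                                                        atc = 4))
  expect_true(all(tr$states[, "PZ_rep"] <= p[["P_Z_total"]] + 1e-7))
  expect_gt(max(tr$states[, "PZ_rep"]), 0.5)  # repression engages
})

test_that("transcription onset delay holds the circuit at zero until tau", {
  p <- rna_only_params()
  cond <- inducer_condition(iptg = 500, arabinose = 6600)
  tr <- simulate_circuit("rna_only", p, cond,
                         options = list(tau_T7 = 60))
  expect_true(all(tr$states[tr$times < 60, ] == 0))
  expect_gt(max(tr$states[tr$times > 70, "X"]), 0)
  # delayed trajectory is the undelayed one shifted in onset
  plain <- simulate_circuit("rna_only", p, cond)
  expect_lt(tr$states[tr$times == 100, "GFP"],
            plain$states[plain$times == 100, "GFP"])
})

test_that("observed GFP is the scaled latent GFP", {
  tr <- simulate_circuit("rna_only", rna_only_params(),
                         inducer_condition(iptg = 500, arabinose = 6600))
  tc1 <- observed_gfp(tr, 1)
  expect_equal(tc1$signal, unname(tr$states[, "GFP"]))
  tc2 <- observed_gfp(tr, 2)
  expect_equal(tc2$signal, 2 * tc1$signal)
  expect_true(all(tc2$signal >= 0))
  expect_true(all(tc2$mask))
  expect_error(observed_gfp(tr, 0), "S_G")
})

test_that("degenerate grids and initial states are rejected", {
  expect_error(time_grid(0), "t_end > t_start")
  expect_error(time_grid(10, cadence = -1))
  expect_error(simulate_circuit("rna_only", rna_only_params(),
                                inducer_condition(),
                                init = c(X = -1, Y = 0, Z = 0, GFP = 0)),
               "non-negative")
  expect_length(default_grid("rna_only")$times, 31)
  expect_length(default_grid("hybrid")$times, 49)
})
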
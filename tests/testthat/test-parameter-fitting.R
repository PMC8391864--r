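# Small noiseless fitting fixture: two conditions, single replicate.
fit_fixture <- function(model = "rna_only", conds = NULL) {
  theta <- if (model == "rna_only") rna_only_params() else hybrid_params()
  if (is.null(conds))
    conds <- if (model == "rna_only")
      list(inducer_condition(iptg = 500, arabinose = 6600),
           inducer_condition(iptg = 7.81, arabinose = 103.1))
    else
      list(inducer_condition(iptg = 1000, atc = 40),
           inducer_condition(iptg = 20, atc = 400))
  proto <- synthetic_protocol(model, noise_cv = 0, replicates = 1,
                              conditions = conds, seed = 3)
  syn <- synthesize_dataset(model, theta, proto)
  data <- suppressWarnings(prepare_fit_data(syn$dataset, model))
  list(theta = theta, data = data)
}

test_that("the objective is zero at the generating parameters", {
  fx <- fit_fixture()
  expect_lt(sse_objective(fx$theta, fx$data, "rna_only"), 1e-10)
})

test_that("a constant offset contributes k * c^2 to the objective", {
  fx <- fit_fixture()
  data <- fx$data
  c0 <- 7.5
  data[[1]]$timecourse$signal <- data[[1]]$timecourse$signal + c0
  k <- sum(data[[1]]$timecourse$mask)
  expect_equal(sse_objective(fx$theta, data, "rna_only"), k * c0^2,
               tolerance = 1e-6)
})

test_that("fully masked data is rejected, masked values are ignored", {
  fx <- fit_fixture()
  data <- fx$data
  base <- sse_objective(fx$theta, data, "rna_only")
  data[[1]]$timecourse$signal[!data[[1]]$timecourse$mask] <- 1e9
  expect_equal(sse_objective(fx$theta, data, "rna_only"), base)
  data[[1]]$timecourse$mask[] <- FALSE
  expect_error(sse_objective(fx$theta, data, "rna_only"), "masked")
})

test_that("fitting from the truth is a fixed point", {
  fx <- fit_fixture()
  fit <- suppressMessages(fit_rna_only(
    fx$data, fx$theta,
    fit_config(n_restarts = 1, max_iterations = 300)))
  expect_lt(fit$objective, 1e-8)
  expect_rel_equal(coef(fit), unclass(fx$theta)[fit$free_names], 1e-6)
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$objective, fit$trace[1])
})

test_that("log-space search never proposes non-positive parameters", {
  fx <- fit_fixture()
  init <- unclass(fx$theta)
  init[free_parameter_names("rna_only")] <-
    init[free_parameter_names("rna_only")] * 1.2
  fit <- suppressMessages(fit_rna_only(
    fx$data, as_iffl_params(init, "rna_only"),
    fit_config(n_restarts = 1, max_iterations = 60, audit = TRUE)))
  for (p in fit$eval_log) expect_true(all(p > 0))
})

test_that("seeded restarts are reproducible", {
  fx <- fit_fixture()
  cfg <- fit_config(n_restarts = 2, max_iterations = 40, seed = 8)
  f1 <- suppressMessages(fit_rna_only(fx$data, fx$theta, cfg))
  f2 <- suppressMessages(fit_rna_only(fx$data, fx$theta, cfg))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$trace, f2$trace)
})

test_that("bounded fitting honours the box exactly", {
  fx <- fit_fixture("hybrid")
  free <- free_parameter_names("hybrid")
  theta_f <- unclass(fx$theta)[free]
  # collapsed bounds return the pinned point
  pin <- lapply(theta_f, function(v) c(v, v))
  fit <- suppressMessages(fit_hybrid(
    fx$data, fx$theta, fit_config(bounds = pin, n_restarts = 1,
                                  max_iterations = 20)))
  expect_equal(coef(fit), theta_f)
  # wide bounds with an off-centre start: every candidate inside the box
  box <- lapply(theta_f, function(v) c(v / 10, v * 10))
  init <- unclass(fx$theta)
  init[free] <- pmin(pmax(theta_f * 1.5, theta_f / 10), theta_f * 10)
  fit2 <- suppressMessages(fit_hybrid(
    fx$data, as_iffl_params(init, "hybrid"),
    fit_config(bounds = box, n_restarts = 1, max_iterations = 40,
               audit = TRUE)))
  for (p in fit2$eval_log) {
    expect_true(all(p >= vapply(box, `[`, 0, 1)[names(p)] - 1e-12))
    expect_true(all(p <= vapply(box, `[`, 0, 2)[names(p)] + 1e-12))
  }
  # init outside bounds and missing bounds are rejected
  bad <- box; bad$alpha_X <- c(10, 20)
  expect_error(iffl_fit("hybrid", fx$data, fx$theta,
                        fit_config(bounds = bad)),
               "outside bounds")
  expect_error(fit_hybrid(fx$data, fx$theta, fit_config()), "bounds")
  expect_error(fit_rna_only(fx$data, fx$theta,
                            fit_config(bounds = box)),
               "unconstrained")
})

test_that("the alpha_GFP x S_G rescaling degeneracy leaves the objective flat", {
  fx <- fit_fixture()
  base <- sse_objective(fx$theta, fx$data, "rna_only")
  resc <- unclass(fx$theta)
  resc["alpha_GFP"] <- resc["alpha_GFP"] * 2
  resc["S_G"] <- resc["S_G"] / 2
  shifted <- sse_objective(as_iffl_params(resc, "rna_only"), fx$data,
                           "rna_only")
  denom <- max(base, 1)
  expect_lt(abs(shifted - base) / denom, 0.01)
})

test_that("validation mirrors training residuals and flags overlap", {
  fx <- fit_fixture()
  fit <- suppressMessages(fit_rna_only(
    fx$data, fx$theta, fit_config(n_restarts = 1, max_iterations = 50)))
  expect_identical(nrow(validate_fit(fit, list())), 0L)
  res <- expect_warning(validate_fit(fit, fx$data), "overlap")
  expect_true(all(res$overlaps_train))
  # RMSE on the training set equals the training residual
  expect_equal(sum(res$rmse^2 * res$n), fit$objective, tolerance = 1e-6)
  # held-out noiseless conditions from the truth fit near-perfectly
  held <- fit_fixture("rna_only",
                      list(inducer_condition(iptg = 125,
                                             arabinose = 412.5)))$data
  out <- validate_fit(fit, held)
  expect_false(out$overlaps_train)
  expect_lt(out$nrmse, 0.01)
})

test_that("objectives are invariant to data entry order", {
  fx <- fit_fixture()
  expect_equal(sse_objective(fx$theta, fx$data, "rna_only"),
               sse_objective(fx$theta, rev(fx$data), "rna_only"))
})
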
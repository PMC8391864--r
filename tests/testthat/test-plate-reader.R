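test_that("plate tables round-trip through both CSV dialects", {
  ds <- tiny_plate()
  for (dialect in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_plate_table(ds, path, dialect)
    back <- read_plate_table(path)
    expect_equal(length(back$wells), length(ds$wells))
    expect_equal(back$times, ds$times)
    for (i in seq_along(ds$wells)) {
      expect_equal(back$wells[[i]]$raw_fluorescence,
                   ds$wells[[i]]$raw_fluorescence)
      expect_equal(back$wells[[i]]$od600, ds$wells[[i]]$od600)
      expect_equal(back$wells[[i]]$condition, ds$wells[[i]]$condition)
      expect_equal(back$wells[[i]]$is_blank, ds$wells[[i]]$is_blank)
    }
  }
})

test_that("schema violations are reported with row context", {
  ds <- tiny_plate()
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(ds, path, "long")
  df <- read.csv(path)
  df$od600[df$well_id == "A1"][3] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_plate_table(path), "A1.*cycle 3")
  df$od600 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_plate_table(path), "od600")
  # no blank well
  ds2 <- ds
  ds2$wells <- ds2$wells[1:2]
  expect_error(plate_reader_dataset(ds2$wells, ds2$times), "blank")
  expect_error(read_plate_table("no/such/file.csv"), "not found")
})

test_that("normalization subtracts the blank and divides by OD600", {
  ds <- tiny_plate(f_sample = 150, f_blank = 50, od = 0.5)
  tcs <- normalize_dataset(ds)
  expect_length(tcs, 2)  # blanks excluded
  expect_equal(tcs[[1]]$signal, rep(200, 6))  # (150 - 50) / 0.5
  # F = blank everywhere -> identically zero
  ds0 <- tiny_plate(f_sample = 50, f_blank = 50)
  expect_equal(normalize_dataset(ds0)[[1]]$signal, rep(0, 6))
  # all-blank dataset refuses
  dsb <- tiny_plate()
  for (i in seq_along(dsb$wells)) dsb$wells[[i]]$is_blank <- TRUE
  expect_error(normalize_dataset(dsb), "only blank")
})

test_that("normalization is scale-equivariant and masks low-OD points", {
  ds <- tiny_plate()
  ds3 <- ds
  for (i in seq_along(ds3$wells))
    ds3$wells[[i]]$raw_fluorescence <- 3 * ds3$wells[[i]]$raw_fluorescence
  expect_equal(normalize_dataset(ds3)[[1]]$signal,
               3 * normalize_dataset(ds)[[1]]$signal)
  # OD below the floor at early cycles -> masked, value kept
  ds$wells[[1]]$od600[1:2] <- 0.01
  tc <- normalize_dataset(ds, od_floor = 0.02)[[1]]
  expect_equal(tc$mask, c(FALSE, FALSE, rep(TRUE, 4)))
  expect_equal(tc$signal[1], (150 - 50) / 0.01)
  # OD exactly zero is masked, never a division blow-up
  ds$wells[[1]]$od600[1] <- 0
  tc0 <- normalize_dataset(ds)[[1]]
  expect_false(tc0$mask[1])
  expect_true(all(is.finite(tc0$signal)))
})

test_that("analysis windows match the two circuit protocols", {
  tc <- gfp_timecourse(default_grid("rna_only")$times, rep(1, 31))
  w <- apply_analysis_window(tc, "rna_only")
  expect_equal(sum(w$mask), 12)  # t = 90..200 inclusive
  expect_equal(range(w$times[w$mask]), c(90, 200))
  tch <- gfp_timecourse(default_grid("hybrid")$times, rep(1, 49))
  wh <- apply_analysis_window(tch, "hybrid")
  expect_equal(range(wh$times[wh$mask]), c(50, 300))
  # identity window changes nothing
  full <- apply_analysis_window(tc, window = c(0, 300))
  expect_equal(full$mask, tc$mask)
  expect_error(apply_analysis_window(tc, window = c(1000, 2000)),
               "excludes every point")
})

test_that("masking changes eligibility, never the stored values", {
  tc <- gfp_timecourse(default_grid("rna_only")$times, seq_len(31) * 1.0)
  w <- apply_analysis_window(tc, "rna_only")
  expect_equal(w$signal, tc$signal)
  w$mask <- rep(TRUE, 31)  # unmask restores the original exactly
  expect_equal(w$signal, tc$signal)
})

test_that("replicate aggregation gives pointwise mean and sample s.d.", {
  times <- seq(0, 40, 10)
  mk <- function(v) gfp_timecourse(times, rep(v, 5))
  agg <- aggregate_replicates(list(mk(1), mk(1), mk(1)))
  expect_equal(agg$signal, rep(1, 5))
  expect_equal(agg$sd, rep(0, 5))
  agg2 <- aggregate_replicates(list(mk(1), mk(3)))
  expect_equal(agg2$signal, rep(2, 5))
  expect_equal(agg2$sd, rep(sqrt(2), 5))
  # mask intersects
  a <- mk(1); a$mask[1] <- FALSE
  expect_equal(aggregate_replicates(list(a, mk(2)))$mask,
               c(FALSE, rep(TRUE, 4)))
  expect_error(aggregate_replicates(list()), "no time courses")
  expect_error(aggregate_replicates(list(mk(1),
                                         gfp_timecourse(times + 1,
                                                        rep(1, 5)))),
               "different grids")
  expect_warning(aggregate_replicates(list(mk(1))), "single replicate")
})
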
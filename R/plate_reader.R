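#' Raw plate-reader dataset
#'
#' Container for one plate run: per-well raw GFP fluorescence and OD600
#' vectors on a shared time grid, with per-well metadata (inducer
#' condition, circuit variant, replicate index, blank flag).  At least
#' one blank (medium-only) well is required for normalization.
#'
#' @param wells List of well records; each a list with fields `well_id`,
#'   `raw_fluorescence`, `od600`, `condition` ([inducer_condition()]),
#'   `variant_id`, `replicate`, `is_blank`.
#' @param times Shared time vector (min).
#' @return Object of class `plate_reader_dataset`.
#' @export
plate_reader_dataset <- function(wells, times) {
  if (!length(wells)) stop("dataset needs at least one well")
  for (w in wells) {
    if (length(w$raw_fluorescence) != length(times) ||
        length(w$od600) != length(times))
      stop(sprintf("well %s: vector length does not match time grid",
                   w$well_id))
    bad <- which(!is.finite(w$od600) | !is.finite(w$raw_fluorescence))
    if (length(bad))
      stop(sprintf("well %s: missing or non-finite value at cycle %d",
                   w$well_id, bad[1]))
    if (any(w$od600 < 0))
      stop(sprintf("well %s: negative OD600", w$well_id))
  }
  if (!any(vapply(wells, function(w) isTRUE(w$is_blank), logical(1))))
    stop("dataset contains no blank well (required for normalization)")
  structure(list(wells = wells, times = as.numeric(times)),
            class = "plate_reader_dataset")
}

#' @export
print.plate_reader_dataset <- function(x, ...) {
  nb <- sum(vapply(x$wells, function(w) isTRUE(w$is_blank), logical(1)))
  cat(sprintf("<plate_reader_dataset> %d wells (%d blank), %d cycles, t = %g-%g min\n",
              length(x$wells), nb, length(x$times), min(x$times),
              max(x$times)))
  invisible(x)
}

.long_cols <- c("well_id", "time_min", "fluorescence", "od600", "iptg_uM",
                "arabinose_uM", "atc_nM", "variant", "replicate",
                "is_blank")

#' Write / read plate-reader tables as CSV
#'
#' Two dialects are supported.  Long form has one row per well and cycle
#' with columns `well_id, time_min, fluorescence, od600, iptg_uM,
#' arabinose_uM, atc_nM, variant, replicate, is_blank`.  Wide form has
#' one row per well with the metadata columns followed by per-cycle
#' fluorescence columns `F_000, F_010, ...` and OD columns
#' `OD_000, OD_010, ...` whose suffix is the time in minutes.
#'
#' @param dataset A [plate_reader_dataset()].
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"` (reading: `"auto"` detects from
#'   the header).
#' @return `read_plate_table` returns a validated
#'   [plate_reader_dataset()]; `write_plate_table` returns `path`
#'   invisibly.
#' @export
write_plate_table <- function(dataset, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  tms <- dataset$times
  meta <- function(w) data.frame(
    well_id = w$well_id,
    iptg_uM = w$condition$iptg, arabinose_uM = w$condition$arabinose,
    atc_nM = w$condition$atc, variant = w$variant_id,
    replicate = w$replicate, is_blank = w$is_blank,
    stringsAsFactors = FALSE)
  if (dialect == "long") {
    rows <- lapply(dataset$wells, function(w) {
      m <- meta(w)[rep(1, length(tms)), , drop = FALSE]
      cbind(m[, "well_id", drop = FALSE],
            data.frame(time_min = tms, fluorescence = w$raw_fluorescence,
                       od600 = w$od600),
            m[, setdiff(names(m), "well_id")])
    })
    df <- do.call(rbind, rows)[, .long_cols]
  } else {
    suff <- sprintf("%03d", as.integer(round(tms)))
    rows <- lapply(dataset$wells, function(w) {
      fv <- as.list(w$raw_fluorescence); names(fv) <- paste0("F_", suff)
      ov <- as.list(w$od600); names(ov) <- paste0("OD_", suff)
      cbind(meta(w), as.data.frame(fv), as.data.frame(ov))
    })
    df <- do.call(rbind, rows)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_table
#' @export
read_plate_table <- function(path, dialect = c("auto", "long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "auto")
    dialect <- if ("time_min" %in% names(df)) "long" else "wide"

  if (dialect == "long") {
    missing <- setdiff(.long_cols, names(df))
    if (length(missing))
      stop("long-form table missing column(s): ",
           paste(missing, collapse = ", "))
    ids <- unique(df$well_id)
    times <- sort(unique(df$time_min))
    wells <- lapply(ids, function(id) {
      sub <- df[df$well_id == id, ]
      sub <- sub[order(sub$time_min), ]
      if (nrow(sub) != length(times) || any(sub$time_min != times))
        stop(sprintf("well %s: ragged rows (cycles differ across wells)",
                     id))
      bad <- which(is.na(sub$od600))
      if (length(bad))
        stop(sprintf("well %s: missing OD600 at cycle %d (t = %g min)",
                     id, bad[1], sub$time_min[bad[1]]))
      bad <- which(is.na(sub$fluorescence))
      if (length(bad))
        stop(sprintf("well %s: missing fluorescence at cycle %d", id,
                     bad[1]))
      list(well_id = id, raw_fluorescence = sub$fluorescence,
           od600 = sub$od600,
           condition = inducer_condition(iptg = sub$iptg_uM[1],
                                         arabinose = sub$arabinose_uM[1],
                                         atc = sub$atc_nM[1]),
           variant_id = as.character(sub$variant[1]),
           replicate = sub$replicate[1],
           is_blank = as.logical(sub$is_blank[1]))
    })
  } else {
    fcols <- grep("^F_", names(df), value = TRUE)
    ocols <- grep("^OD_", names(df), value = TRUE)
    if (!length(ocols)) stop("wide-form table has no OD_* columns")
    if (length(fcols) != length(ocols))
      stop("wide-form table: F_* and OD_* column counts differ")
    times <- as.numeric(sub("^F_", "", fcols))
    o <- order(times); times <- times[o]
    fcols <- fcols[o]; ocols <- paste0("OD_", sprintf("%03d", times))
    wells <- lapply(seq_len(nrow(df)), function(i) {
      odv <- as.numeric(df[i, ocols])
      bad <- which(is.na(odv))
      if (length(bad))
        stop(sprintf("well %s: missing OD600 at cycle %d",
                     df$well_id[i], bad[1]))
      list(well_id = df$well_id[i],
           raw_fluorescence = as.numeric(df[i, fcols]), od600 = odv,
           condition = inducer_condition(iptg = df$iptg_uM[i],
                                         arabinose = df$arabinose_uM[i],
                                         atc = df$atc_nM[i]),
           variant_id = as.character(df$variant[i]),
           replicate = df$replicate[i],
           is_blank = as.logical(df$is_blank[i]))
    })
  }
  plate_reader_dataset(wells, times)
}

#' Normalize raw plate-reader wells to per-cell GFP signal
#'
#' Applies the standard plate-reader normalization: the per-cycle mean
#' fluorescence of the blank (medium-only) wells is subtracted from each
#' sample well, and the result is divided by that well's OD600.  The
#' blank is time-varying (a per-cycle mean), since medium
#' autofluorescence drifts over a run.  Cycles whose OD600 falls below
#' `od_floor` are masked rather than dropped, so early low-density
#' points never produce division blow-ups; the values at masked points
#' are retained.
#'
#' @param dataset A [plate_reader_dataset()] with >= 1 blank well.
#' @param od_floor OD600 below which a point is masked (default 0.02).
#' @return List of [gfp_timecourse()], one per non-blank well, carrying
#'   the well's condition/variant/replicate in `meta`.
#' @examples
#' # (F - blank)/OD: (150 - 50)/0.5 = 200
#' @export
normalize_dataset <- function(dataset, od_floor = 0.02) {
  stopifnot(inherits(dataset, "plate_reader_dataset"))
  blank_flags <- vapply(dataset$wells, function(w) isTRUE(w$is_blank),
                        logical(1))
  if (all(blank_flags)) stop("dataset contains only blank wells")
  blanks <- dataset$wells[blank_flags]
  blank_mean <- rowMeans(
    vapply(blanks, function(w) w$raw_fluorescence,
           numeric(length(dataset$times))))
  lapply(dataset$wells[!blank_flags], function(w) {
    mask <- w$od600 >= od_floor
    od_safe <- ifelse(w$od600 > 0, w$od600, NA_real_)
    signal <- (w$raw_fluorescence - blank_mean) / od_safe
    signal[is.na(signal)] <- 0  # only ever at masked (OD = 0) points
    gfp_timecourse(times = dataset$times, signal = signal, mask = mask,
                   condition = w$condition,
                   meta = list(well_id = w$well_id,
                               variant_id = w$variant_id,
                               replicate = w$replicate))
  })
}

#' Analysis-window masking
#'
#' Masks the time-course points outside the circuit's trusted analysis
#' window: the first 90 min and everything beyond 200 min for the
#' RNA-only circuit, the first 50 min and beyond 300 min for the hybrid
#' circuit.  Early points are unreliable because OD600 is still very
#' low; late points because the GFP signal becomes unreliable once cells
#' reach stationary phase.  Masking is combined (intersected) with any
#' existing mask; values are never altered.
#'
#' @param tc A [gfp_timecourse()].
#' @param circuit `"rna_only"` or `"hybrid"` (selects the default
#'   window).
#' @param window Optional `c(t_lo, t_hi)` override (min, inclusive).
#' @return The time course with its mask restricted to the window.
#' @export
apply_analysis_window <- function(tc, circuit = c("rna_only", "hybrid"),
                                  window = NULL) {
  if (is.null(window)) {
    circuit <- match.arg(circuit)
    window <- if (circuit == "rna_only") c(90, 200) else c(50, 300)
  }
  keep <- tc$times >= window[1] & tc$times <= window[2]
  tc$mask <- tc$mask & keep
  if (!any(tc$mask))
    stop("analysis window excludes every point of the time course")
  tc$meta$window <- window
  tc
}

#' Aggregate biological replicates
#'
#' Pointwise mean and sample standard deviation over replicate time
#' courses sharing a grid.  The aggregate mask is the intersection of
#' the input masks.
#'
#' @param tcs Non-empty list of [gfp_timecourse()] on identical grids.
#' @return A [gfp_timecourse()] whose `signal` is the replicate mean and
#'   `sd` the per-point sample standard deviation; with a single
#'   replicate the s.d. is reported as 0 and `meta$single_replicate` is
#'   flagged (with a warning).
#' @export
aggregate_replicates <- function(tcs) {
  if (!length(tcs)) stop("no time courses to aggregate")
  t0 <- tcs[[1]]$times
  for (tc in tcs)
    if (length(tc$times) != length(t0) || any(tc$times != t0))
      stop("replicate time courses are on different grids")
  sig <- vapply(tcs, function(tc) tc$signal, numeric(length(t0)))
  sig <- matrix(sig, nrow = length(t0))
  msk <- vapply(tcs, function(tc) tc$mask, logical(length(t0)))
  msk <- matrix(msk, nrow = length(t0))
  single <- length(tcs) == 1L
  if (single)
    warning("single replicate: standard deviation reported as 0")
  sdv <- if (single) rep(0, length(t0)) else apply(sig, 1, stats::sd)
  gfp_timecourse(times = t0, signal = rowMeans(sig),
                 mask = apply(msk, 1, all), sd = sdv,
                 condition = tcs[[1]]$condition,
                 meta = c(tcs[[1]]$meta,
                          list(n_replicates = length(tcs),
                               single_replicate = single)))
}
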
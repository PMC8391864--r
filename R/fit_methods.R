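#' @export
print.iffl_fit <- function(x, ...) {
  cat(sprintf("<iffl_fit> %s model, %d free parameters\n", x$model_id,
              length(x$free_names)))
  cat(sprintf("  objective (SSE): %.6g  converged: %s  evaluations: %d\n",
              x$objective, x$converged, x$n_evaluations))
  cat(sprintf("  %d training condition(s); restarts: %s\n",
              length(x$data),
              paste(signif(x$restart_objectives, 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.iffl_fit <- function(object, ...) {
  unclass(object$params)[object$free_names]
}

#' @export
summary.iffl_fit <- function(object, ...) {
  per_cond <- validate_fit_quietly(object)
  out <- list(fit = object, coefficients = coef(object),
              per_condition = per_cond)
  class(out) <- "summary.iffl_fit"
  out
}

validate_fit_quietly <- function(fit) {
  suppressWarnings(validate_fit(fit, fit$data))
}

#' @export
print.summary.iffl_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted free parameters:\n")
  print(signif(x$coefficients, 5))
  cat("\nTraining residuals by condition:\n")
  df <- x$per_condition[, c("condition", "rmse", "nrmse", "n")]
  df$rmse <- signif(df$rmse, 4); df$nrmse <- signif(df$nrmse, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predict observed GFP time courses from a fitted model
#'
#' Simulates the fitted parameters at the requested conditions and
#' returns the scaled observed signal `S_G * GFP(t)`.
#'
#' @param object An `iffl_fit`.
#' @param conditions List of [inducer_condition()] (default: the
#'   training conditions).
#' @param grid [time_grid()] (default: the grid of the training data).
#' @param ... Unused.
#' @return List of [gfp_timecourse()], one per condition.
#' @export
predict.iffl_fit <- function(object, conditions = NULL, grid = NULL, ...) {
  if (is.null(conditions))
    conditions <- lapply(object$data, function(e) e$condition)
  if (is.null(grid))
    grid <- grid_from_times(object$data[[1]]$timecourse$times)
  lapply(conditions, function(cond) {
    tr <- simulate_circuit(object$model_id, object$params, cond,
                           grid = grid, variant = object$variant,
                           options = object$sim_options)
    observed_gfp(tr, object$params[["S_G"]])
  })
}

#' @export
fitted.iffl_fit <- function(object, ...) {
  preds <- predict(object)
  lapply(seq_along(object$data), function(i) {
    tc <- object$data[[i]]$timecourse
    p <- preds[[i]]
    p$mask <- tc$mask
    p
  })
}

#' @export
residuals.iffl_fit <- function(object, ...) {
  preds <- predict(object)
  lapply(seq_along(object$data), function(i) {
    tc <- object$data[[i]]$timecourse
    gfp_timecourse(times = tc$times,
                   signal = tc$signal - preds[[i]]$signal,
                   mask = tc$mask, condition = tc$condition)
  })
}

#' @export
plot.iffl_fit <- function(x, which = seq_along(x$data), ...) {
  preds <- predict(x)
  n <- length(which)
  mf <- grDevices::n2mfrow(n)
  op <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in which) {
    tc <- x$data[[i]]$timecourse
    ylim <- range(tc$signal, preds[[i]]$signal)
    graphics::plot(tc$times, tc$signal, pch = 16, cex = 0.6,
                   col = ifelse(tc$mask, "black", "grey70"),
                   xlab = "time (min)", ylab = "GFP (fluor/OD)",
                   main = format_condition(tc$condition), ylim = ylim,
                   ...)
    graphics::lines(preds[[i]]$times, preds[[i]]$signal, col = "red3")
  }
  invisible(x)
}
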
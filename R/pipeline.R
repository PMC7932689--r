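#' Step records for a whole walking dataset
#'
#' Segments the bout into tripod stance windows and summarises each
#' one against the CoM track ([step_summary()]).  The Froude number
#' uses the measured leg length from the metadata when available.
#'
#' @param ds A `walking_dataset`.
#' @return A data.frame of step records.
#' @export
analyze_steps <- function(ds) {
  windows <- tripod_step_windows(ds$footfalls)
  leg_len <- if (!is.null(ds$meta$R_real)) ds$meta$R_real else NULL
  g <- if (!is.null(ds$meta$g)) ds$meta$g else 9.807
  rows <- lapply(seq_len(nrow(windows)), function(i)
    tryCatch(step_summary(windows[i, ], ds$com, leg_length = leg_len, g = g),
             error = function(e) NULL))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit SLIP and ARSLIP to every eligible step of a dataset
#'
#' Applies the eligibility filter (single-support fraction >= 0.25),
#' shifts each step's CoM horizontal position to the step's effective
#' foothold, and runs the constrained multi-start fit for both models
#' ([fit_step_models()]).
#'
#' @param ds A `walking_dataset` with metadata `m` and `R_real`.
#' @param seed Integer seed (start draws derive from it per step).
#' @param n_starts Multi-start count per model and step.
#' @param min_ssf Minimum single-support fraction.
#' @param models `"both"` (default) or `"arslip"` only.
#' @return A list: `records` (the eligible step records), `fits` (per
#'   step, elements `slip` and `arslip`), `params` (data.frame of
#'   fitted constants per step, for [fit_fly_tripod()]).
#' @export
fit_dataset <- function(ds, seed = 1L, n_starts = 32L, min_ssf = 0.25,
                        models = c("both", "arslip")) {
  models <- match.arg(models)
  records <- filter_steps(analyze_steps(ds), min_ssf = min_ssf)
  m <- ds$meta$m; R_real <- ds$meta$R_real
  g <- if (!is.null(ds$meta$g)) ds$meta$g else 9.807
  fits <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    com_rel <- data.frame(t = ds$com$t, x = ds$com$x - rec$foothold,
                          z = ds$com$z)
    window <- c(rec$t_start, rec$t_end)
    fits[[i]] <- if (models == "both")
      fit_step_models(com_rel, window, R_real, m, g,
                      seed = seed + i, n_starts = n_starts)
    else list(arslip = fit_step(com_rel, window, "arslip", R_real, m, g,
                                seed = seed + i, n_starts = n_starts))
  }
  ar <- lapply(fits, `[[`, "arslip")
  params <- data.frame(
    step_id = records$step_id,
    L = records$L, r_m = records$r_m,
    k_s_fit = vapply(ar, function(f) if (f$converged) f$k_s else NA_real_,
                     numeric(1)),
    k_a_fit = vapply(ar, function(f) if (f$converged) f$k_a else NA_real_,
                     numeric(1)),
    R_fit = vapply(ar, function(f) if (f$converged) f$R else NA_real_,
                   numeric(1)),
    objective_arslip = vapply(ar, `[[`, numeric(1), "objective"))
  if (models == "both")
    params$objective_slip <- vapply(fits, function(f) f$slip$objective,
                                    numeric(1))
  list(records = records, fits = fits, params = params)
}
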
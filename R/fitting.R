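#' Read a kinetic extraction dataset from CSV
#'
#' Expected header: `temperature_C, enzyme_pct, method, time_min,
#' yield_mg_per_g` with optional `sd_mg_per_g` and `n_reps`. Enzyme-free runs
#' are encoded as `enzyme_pct = 0`; `method` is `"US"` (ultrasound) or
#' `"MS"` (magnetic stirring).
#'
#' @param path CSV path.
#' @return A validated data.frame (class `kinetic_dataset`).
#' @export
read_kinetics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_kinetics(df)
}

#' Write a kinetic dataset to CSV
#' @param dataset A kinetic dataset data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

validate_kinetics <- function(df) {
  required <- c("temperature_C", "enzyme_pct", "method", "time_min",
                "yield_mg_per_g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("kinetic dataset is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$time_min < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(df$yield_mg_per_g < 0)) stop("yields must be >= 0", call. = FALSE)
  if (!all(df$method %in% c("US", "MS"))) {
    stop("method must be 'US' or 'MS'", call. = FALSE)
  }
  dup <- stats::aggregate(time_min ~ temperature_C + enzyme_pct + method,
                          df, function(t) anyDuplicated(t) > 0)
  if (any(dup$time_min)) {
    stop("duplicate time points within a condition", call. = FALSE)
  }
  class(df) <- c("kinetic_dataset", "data.frame")
  df
}

#' Estimate the effective diffusion coefficient for one condition
#'
#' Minimises the RMSE between observed yields and the yields simulated by
#' [solve_extraction()] over log10 of the Fourier-scaled rate De/r^2
#' (bounded 1-D search via [stats::optimize()], tolerance 1e-3 in log10
#' units). The fit is scale-free: the search runs on the dimensionless rate
#' and the result is also reported as De in m^2/s for the given radius.
#' Before optimising, the objective is evaluated on a 20-point scan of the
#' bounds; a non-finite value anywhere aborts with a model/data scale
#' mismatch error, and the scan also guards the optimizer (the returned
#' optimum is never worse than the best scan point).
#'
#' @param data Data frame with `time_min` and `yield_mg_per_g` for a single
#'   condition (at least 4 time points; a t = 0 row, if present, is not
#'   fitted but the model curve always starts at 0).
#' @param particle A [particle_spec()].
#' @param suspension A [suspension_spec()].
#' @param cs0_g_cm3 Initial solid concentration (see [cs0_from_content()]).
#' @param K Partition coefficient (default 1).
#' @param bounds_log10_rate Length-2 log10 bounds on the rate (1/min);
#'   default +/- 3 decades around the half-extraction heuristic
#'   `rate0 = 1 / t_half`. Must span at least 2 decades.
#' @param n_nodes Radial cells for the forward model.
#' @return Object of class `de_fit` with elements `rate_per_min`, `de_m2s`,
#'   `rmse`, `r_squared`, `aad`, `n_obs`, `converged`, `bounds_log10_rate`,
#'   `scan` (the 20-point bound scan) and `fitted` (observed vs fitted
#'   yields).
#' @export
fit_de <- function(data, particle = particle_spec(),
                   suspension = suspension_spec(),
                   cs0_g_cm3 = cs0_from_content(7.9),
                   K = 1, bounds_log10_rate = NULL, n_nodes = 101) {
  obs <- data[order(data$time_min), , drop = FALSE]
  obs <- obs[obs$time_min > 0, , drop = FALSE]
  if (nrow(obs) < 4) stop("need at least 4 positive-time points", call. = FALSE)
  times <- obs$time_min
  y <- obs$yield_mg_per_g

  if (is.null(bounds_log10_rate)) {
    t_half <- half_extraction_time(times, y)
    bounds_log10_rate <- log10(1 / t_half) + c(-3, 3)
  }
  if (diff(bounds_log10_rate) < 2) {
    stop("`bounds_log10_rate` must span at least 2 decades", call. = FALSE)
  }

  objective <- function(lr) {
    par <- diffusion_params(cs0_g_cm3, rate_per_min = 10^lr, K = K)
    prof <- solve_extraction(par, particle, suspension, c(0, times),
                             n_nodes = n_nodes)
    pred <- yield_curve(prof)$yield_mg_per_g[-1]
    rmse(pred, y)
  }

  scan_x <- seq(bounds_log10_rate[1], bounds_log10_rate[2], length.out = 20)
  scan_y <- vapply(scan_x, objective, numeric(1))
  if (any(!is.finite(scan_y))) {
    stop("model/data scale mismatch: objective non-finite on bound scan",
         call. = FALSE)
  }

  opt <- stats::optimize(objective, bounds_log10_rate, tol = 1e-3)
  best_lr <- opt$minimum
  best_val <- opt$objective
  if (min(scan_y) < best_val) {  # optimizer trapped in a local dip
    best_lr <- scan_x[which.min(scan_y)]
    best_val <- min(scan_y)
  }

  # a flat objective across >= 1 decade means the rate is not identifiable
  # (e.g. data already at equilibrium: any fast-enough rate fits exactly);
  # report the fastest-rate reading and flag it
  near <- scan_y <= best_val + max(1e-12, 1e-6 * best_val)
  flat <- sum(near) >= 2 && diff(range(scan_x[near])) >= 1
  if (flat) {
    best_lr <- bounds_log10_rate[2]
    warning("rate not identifiable (objective flat up to the upper bound); ",
            "estimate not converged", call. = FALSE)
  }
  at_bound <- flat || min(abs(best_lr - bounds_log10_rate)) < 5e-3
  if (at_bound && !flat) {
    warning("De optimum at a search bound; estimate not converged",
            call. = FALSE)
  }

  rate <- 10^best_lr
  par <- diffusion_params(cs0_g_cm3, rate_per_min = rate, K = K)
  prof <- solve_extraction(par, particle, suspension, c(0, times),
                           n_nodes = n_nodes)
  pred <- yield_curve(prof)$yield_mg_per_g[-1]
  aad_val <- if (all(y > 0)) aad(pred, y) else NA_real_
  r2 <- if (stats::var(y) > 0) r_squared(pred, y) else NA_real_

  structure(
    list(rate_per_min = rate,
         de_m2s = de_from_rate(rate, particle$radius_cm),
         rmse = best_val, r_squared = r2, aad = aad_val,
         n_obs = length(y), converged = !at_bound,
         bounds_log10_rate = bounds_log10_rate,
         scan = data.frame(log10_rate = scan_x, rmse = scan_y),
         fitted = data.frame(time_min = times, observed = y,
                             predicted = pred)),
    class = "de_fit"
  )
}

# time at which the observed yield first crosses half its final value
# (linear interpolation); heuristic initial scale for the rate search
half_extraction_time <- function(times, yields) {
  target <- yields[length(yields)] / 2
  if (target <= 0) return(max(times) / 2)
  above <- which(yields >= target)
  if (!length(above)) return(max(times))
  i <- above[1]
  if (i == 1) return(times[1] * target / max(yields[1], target))
  t0 <- times[i - 1]; t1 <- times[i]
  y0 <- yields[i - 1]; y1 <- yields[i]
  if (y1 == y0) return(t1)
  t0 + (target - y0) * (t1 - t0) / (y1 - y0)
}

#' Fit the diffusion model to every experimental condition
#'
#' Groups the dataset by (temperature, enzyme, method), fits each group with
#' [fit_de()] and assembles a report table analogous to a per-condition
#' diffusion-coefficient summary. Per-condition failures are caught and
#' reported, not propagated.
#'
#' @param dataset A kinetic dataset (see [read_kinetics()]).
#' @param particle,suspension,K,n_nodes Passed to [fit_de()].
#' @param cs0_g_cm3 Scalar Cs0, or a function `(temperature_C, enzyme_pct,
#'   method) -> Cs0` for per-condition equilibria.
#' @param path Optional CSV path for the report.
#' @return data.frame with one row per condition: `temperature_C`,
#'   `enzyme_pct`, `method`, `de_m2s`, `rate_per_min`, `r_squared`,
#'   `rmse_mg_per_g`, `aad_pct`, `n_obs`, `converged`, `error`. The
#'   underlying `de_fit` objects are attached as attribute `"fits"`.
#' @export
fit_all_conditions <- function(dataset, particle = particle_spec(),
                               suspension = suspension_spec(),
                               cs0_g_cm3 = cs0_from_content(7.9),
                               K = 1, n_nodes = 101, path = NULL) {
  if (nrow(dataset) == 0L) {
    warning("empty kinetic dataset: nothing to fit", call. = FALSE)
    out <- data.frame(temperature_C = numeric(), enzyme_pct = numeric(),
                      method = character(), de_m2s = numeric(),
                      rate_per_min = numeric(), r_squared = numeric(),
                      rmse_mg_per_g = numeric(), aad_pct = numeric(),
                      n_obs = integer(), converged = logical(),
                      error = character())
    attr(out, "fits") <- list()
    return(out)
  }
  key <- interaction(dataset$temperature_C, dataset$enzyme_pct,
                     dataset$method, drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(dataset)), key)
  fits <- list()
  rows <- lapply(names(groups), function(g) {
    sub <- dataset[groups[[g]], , drop = FALSE]
    cond <- sub[1, c("temperature_C", "enzyme_pct", "method")]
    cs0 <- if (is.function(cs0_g_cm3)) {
      cs0_g_cm3(cond$temperature_C, cond$enzyme_pct, cond$method)
    } else cs0_g_cm3
    fit <- tryCatch(
      fit_de(sub, particle, suspension, cs0, K, n_nodes = n_nodes),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      data.frame(cond, de_m2s = NA_real_, rate_per_min = NA_real_,
                 r_squared = NA_real_, rmse_mg_per_g = NA_real_,
                 aad_pct = NA_real_, n_obs = nrow(sub), converged = FALSE,
                 error = conditionMessage(fit))
    } else {
      fits[[g]] <<- fit
      data.frame(cond, de_m2s = fit$de_m2s, rate_per_min = fit$rate_per_min,
                 r_squared = fit$r_squared, rmse_mg_per_g = fit$rmse,
                 aad_pct = fit$aad, n_obs = fit$n_obs,
                 converged = fit$converged, error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
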
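#' Configuration for the synthetic kinetic-data generator
#'
#' The defaults emulate the 48-run ultrasound design: 2 temperatures x 3
#' cellulase levels x 8 sampling times, front-loaded because extraction is
#' fast early and slow late. Replicate noise SDs are drawn uniformly from
#' the observed replicate-variability range 0.002-0.150 mg/g. The truth
#' maps (per-condition Fourier rate De/r^2 and equilibrium yield) can be
#' overridden; the defaults come from [default_truth()].
#'
#' @param temperatures Extraction temperatures, deg C.
#' @param enzymes Cellulase doses, % w/v (0 = no enzyme).
#' @param methods `"US"` (ultrasound) and/or `"MS"` (magnetic stirring,
#'   enzyme-free only).
#' @param times_min Sampling times per condition, min.
#' @param noise_sd_range Replicate noise SD range, mg/g.
#' @param n_reps Replicates per point.
#' @param seed Integer seed.
#' @param particle,suspension Geometry of the simulated system.
#' @param K Partition coefficient used by the forward model.
#' @param truth Optional truth table overriding [default_truth()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(temperatures = c(40, 50),
                             enzymes = c(0, 0.5, 1),
                             methods = "US",
                             times_min = c(2.5, 5, 10, 15, 20, 25, 30, 40),
                             noise_sd_range = c(0.002, 0.150),
                             n_reps = 3, seed = 1,
                             particle = particle_spec(),
                             suspension = suspension_spec(),
                             K = 1, truth = NULL) {
  stopifnot(length(temperatures) >= 1, length(enzymes) >= 1,
            length(methods) >= 1, length(times_min) >= 1,
            all(times_min > 0), length(noise_sd_range) == 2,
            noise_sd_range[1] >= 0, diff(noise_sd_range) >= 0, n_reps >= 1)
  structure(
    list(temperatures = temperatures, enzymes = enzymes, methods = methods,
         times_min = times_min, noise_sd_range = noise_sd_range,
         n_reps = n_reps, seed = seed, particle = particle,
         suspension = suspension, K = K, truth = truth),
    class = "generator_config"
  )
}

#' Full-factorial design grid of a generator configuration
#'
#' @param config A [generator_config()].
#' @return data.frame with one row per (temperature, enzyme, method, time),
#'   in stable lexicographic order.
#' @export
make_design <- function(config) {
  g <- expand.grid(time_min = config$times_min,
                   enzyme_pct = config$enzymes,
                   temperature_C = config$temperatures,
                   method = config$methods,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[c("temperature_C", "enzyme_pct", "method", "time_min")]
}

#' Default per-condition truth parameters
#'
#' Phenomenological maps embodying the orderings seen in fitted extraction
#' kinetics: at fixed temperature the rate grows with enzyme dose and with
#' ultrasound (vs stirring); the rate *falls* from 40 to 50 deg C
#' (heat-induced re-adsorption hinders internal diffusion) while the
#' equilibrium yield rises with temperature. The rates are Fourier-scaled
#' (1/min) and sized so half-extraction falls within roughly 1.5-10 min, in
#' line with most of the yield appearing inside the first 10 minutes.
#'
#' @param config A [generator_config()].
#' @return data.frame with one row per condition: `temperature_C`,
#'   `enzyme_pct`, `method`, `rate_per_min`, `equilibrium_mg_per_g`.
#' @export
default_truth <- function(config) {
  g <- unique(make_design(config)[c("temperature_C", "enzyme_pct", "method")])
  base_rate <- function(T, E, m) {
    # anchored relative rates; US > MS, enzyme raises, 50 C lowers
    us <- if (T < 45) 0.915 * (1 + 1.2 * E) else 0.430 * (1 + 0.7 * E)
    ms <- if (T < 45) 0.570 else 0.301
    0.01 * if (m == "US") us else ms
  }
  base_eq <- function(T, E, m) {
    eq <- if (T < 45) 2.8 + 0.2 * E else 4.2 + 0.2 * E
    if (m == "MS") eq <- eq * 0.8
    eq
  }
  g$rate_per_min <- mapply(base_rate, g$temperature_C, g$enzyme_pct, g$method)
  g$equilibrium_mg_per_g <- mapply(base_eq, g$temperature_C, g$enzyme_pct,
                                   g$method)
  rownames(g) <- NULL
  g
}

#' Simulate a kinetic extraction dataset
#'
#' For every design condition the mean yield curve is produced by the
#' forward diffusion model ([solve_extraction()] + [yield_curve()]) at the
#' condition's true rate, with the initial solid concentration set so the
#' equilibrium yield matches the truth map. Replicates add Gaussian noise
#' (SD drawn once per time point from `noise_sd_range`) truncated so yields
#' stay nonnegative; the dataset reports the replicate mean and SD. The true
#' parameters are attached as attribute `"truth"` (and written as a JSON
#' sidecar when `path` is given).
#'
#' @param config A [generator_config()].
#' @param path Optional CSV path; a `<path>.truth.json` sidecar is written
#'   alongside.
#' @return A `kinetic_dataset` data.frame with attribute `"truth"`.
#' @export
simulate_kinetics <- function(config, path = NULL) {
  truth <- config$truth %||% default_truth(config)
  conds <- unique(make_design(config)[c("temperature_C", "enzyme_pct",
                                        "method")])
  need <- merge(conds, truth, all.x = TRUE)
  if (any(is.na(need$rate_per_min)) || any(is.na(need$equilibrium_mg_per_g))) {
    stop("truth map is missing a design cell", call. = FALSE)
  }

  susp <- config$suspension
  rows <- with_seed(config$seed, {
    out <- lapply(seq_len(nrow(need)), function(i) {
      cond <- need[i, ]
      # Cs0 such that the model's equilibrium yield equals the truth value
      cs0 <- equilibrium_cs0(cond$equilibrium_mg_per_g, susp, config$K)
      par <- diffusion_params(cs0, rate_per_min = cond$rate_per_min,
                              K = config$K)
      prof <- solve_extraction(par, config$particle, susp,
                               c(0, config$times_min))
      mean_curve <- yield_curve(prof)$yield_mg_per_g[-1]
      sds <- stats::runif(length(mean_curve), config$noise_sd_range[1],
                          config$noise_sd_range[2])
      reps <- vapply(seq_along(mean_curve), function(k) {
        pmax(0, stats::rnorm(config$n_reps, mean_curve[k], sds[k]))
      }, numeric(config$n_reps))
      reps <- matrix(reps, nrow = config$n_reps)
      data.frame(temperature_C = cond$temperature_C,
                 enzyme_pct = cond$enzyme_pct, method = cond$method,
                 time_min = config$times_min,
                 yield_mg_per_g = colMeans(reps),
                 sd_mg_per_g = apply(reps, 2, stats::sd),
                 n_reps = config$n_reps,
                 true_mean = mean_curve)
    })
    do.call(rbind, out)
  })
  true_means <- rows$true_mean
  rows$true_mean <- NULL
  rownames(rows) <- NULL
  dataset <- validate_kinetics(rows)
  attr(dataset, "truth") <- truth
  attr(dataset, "true_means") <- true_means
  if (!is.null(path)) {
    write_kinetics(dataset, path)
    jsonlite::write_json(list(truth = truth, seed = config$seed,
                              K = config$K,
                              times_min = config$times_min),
                         paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  dataset
}

# Cs0 giving equilibrium yield `eq` (mg/g): at equilibrium
# CL = Cs0 Vs / (K^-1 ... ) with u_inf = K CL/Cs0 and mass balance
# Vs Cs_inf + VL CL_inf = Vs Cs0  =>  CL_inf = Cs0 Vs/(K Vs + VL) * K... :
# u_inf = w/alpha, w_inf = alpha/(1+alpha); yield = 1000 w Cs0 Vs / m
equilibrium_cs0 <- function(eq_mg_per_g, suspension, K = 1) {
  alpha <- bath_capacity(suspension, K)
  w_inf <- alpha / (1 + alpha)
  eq_mg_per_g * suspension$solid_mass_g /
    (1000 * w_inf * solid_volume(suspension))
}

#' Simulate a compound quantification table
#'
#' Produces a randomized table with the schema of the packaged hull
#' phenolic profile: 4 categories, ~17 compounds, means spanning roughly
#' 1-900 ug/g, structured missingness (some compounds undetected at the
#' lower temperature) and an optional injected temperature contrast so
#' ordination separation is testable. `effect_size = 0` gives exchangeable
#' conditions; large values put most variance on the injected contrast.
#'
#' @param n_compounds Number of compounds (default 17).
#' @param effect_size Log-scale magnitude of the injected 40-vs-50 deg C
#'   contrast (default 0.5).
#' @param seed Integer seed (required).
#' @param cv_range Range of per-entry coefficients of variation for the SDs.
#' @param missing_frac Fraction of compounds undetected at 40 deg C.
#' @return A `compound_table` (synthetic; accepted by every consumer of
#'   [read_compound_table()]).
#' @export
simulate_compound_table <- function(n_compounds = 17, effect_size = 0.5,
                                    seed, cv_range = c(0.01, 0.10),
                                    missing_frac = 0.15) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  labs <- c("40C_NE", "40C_0.5", "40C_1", "50C_NE", "50C_0.5", "50C_1")
  contrast <- c(-1, -1, -1, 1, 1, 1)  # temperature grouping
  cats <- rep(COMPOUND_CATEGORIES,
              times = pmax(1, round(n_compounds * c(9, 2, 3, 3) / 17)))
  cats <- cats[seq_len(n_compounds)]
  with_seed(seed, {
    base <- exp(stats::runif(n_compounds, log(1.5), log(900)))
    load <- stats::rnorm(n_compounds)
    m <- outer(base, rep(1, 6)) *
      exp(effect_size * outer(load, contrast) +
            matrix(stats::rnorm(n_compounds * 6, 0, 0.1), n_compounds))
    cv <- matrix(stats::runif(n_compounds * 6, cv_range[1], cv_range[2]),
                 n_compounds)
    s <- m * cv
    n_miss <- round(missing_frac * n_compounds)
    if (n_miss > 0) {
      miss_rows <- sample(n_compounds, n_miss)
      m[miss_rows, 1:3] <- NA; s[miss_rows, 1:3] <- NA
    }
  })
  nm <- sprintf("compound_%02d", seq_len(n_compounds))
  dimnames(m) <- dimnames(s) <- list(nm, labs)
  structure(
    list(compounds = data.frame(compound = nm, category = cats,
                                rt_min = round(seq(10, 55,
                                                   length.out = n_compounds), 2),
                                stringsAsFactors = FALSE),
         mean = m, sd = s,
         conditions = parse_condition_labels(labs),
         missing_report = data.frame(compound = nm,
                                     n_missing = rowSums(is.na(m)))),
    class = "compound_table"
  )
}
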
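#' Spherical particle specification
#'
#' Describes the (monodisperse) particle population from which phenolics
#' diffuse. The default radius is half the surface-weighted mean diameter
#' D\[2,3\] = 49.00 um measured for hull particles by laser diffraction.
#'
#' @param radius_um Particle radius in micrometres. Must be positive.
#' @return An object of class `particle_spec` with elements `radius_um` and
#'   `radius_cm`.
#' @examples
#' particle_spec()          # 24.5 um default
#' particle_spec(50)
#' @export
particle_spec <- function(radius_um = 24.5) {
  if (!is.numeric(radius_um) || length(radius_um) != 1L ||
      !is.finite(radius_um) || radius_um <= 0) {
    stop("`radius_um` must be a single finite positive number", call. = FALSE)
  }
  structure(
    list(radius_um = radius_um, radius_cm = radius_um * 1e-4),
    class = "particle_spec"
  )
}

#' Suspension (solid + solvent bath) specification
#'
#' Defaults follow a 1:10 solid-to-liquid ratio in 60 mL of water. The solid
#' volume `Vs = solid_mass / solid_density` and the total particle contact
#' area `S = 3 Vs / r` (monodisperse spheres) are derived, never stored.
#'
#' @param solid_mass_g Mass of solid, g.
#' @param liquid_volume_ml Solvent volume VL, mL.
#' @param solid_density_g_cm3 Particle density, g/cm^3 (default 1.0).
#' @return Object of class `suspension_spec`.
#' @export
suspension_spec <- function(solid_mass_g = 6, liquid_volume_ml = 60,
                            solid_density_g_cm3 = 1.0) {
  vals <- c(solid_mass_g, liquid_volume_ml, solid_density_g_cm3)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("suspension parameters must all be finite and positive", call. = FALSE)
  }
  structure(
    list(solid_mass_g = solid_mass_g,
         liquid_volume_ml = liquid_volume_ml,
         solid_density_g_cm3 = solid_density_g_cm3),
    class = "suspension_spec"
  )
}

#' Solid volume of a suspension (cm^3)
#' @param suspension A [suspension_spec()].
#' @return Solid volume Vs in cm^3.
#' @export
solid_volume <- function(suspension) {
  suspension$solid_mass_g / suspension$solid_density_g_cm3
}

#' Total particle-solvent contact area (cm^2)
#'
#' For monodisperse spheres of radius r, S = 3 Vs / r.
#' @param suspension A [suspension_spec()].
#' @param particle A [particle_spec()].
#' @return Contact area in cm^2.
#' @export
contact_area <- function(suspension, particle) {
  3 * solid_volume(suspension) / particle$radius_cm
}

#' Dimensionless bath capacity alpha = VL / (K Vs)
#'
#' Controls the equilibrium extracted fraction alpha / (1 + alpha): a large
#' bath (or weak partition into the solid) extracts almost everything.
#'
#' @param suspension A [suspension_spec()].
#' @param K Interface partition coefficient (solid:liquid at equilibrium).
#' @return alpha, dimensionless.
#' @export
bath_capacity <- function(suspension, K = 1) {
  suspension$liquid_volume_ml / (K * solid_volume(suspension))
}

#' Diffusion model parameters
#'
#' Either `de_m2s` (effective diffusion coefficient, m^2/s) or
#' `rate_per_min` (the Fourier-scaled rate De/r^2, 1/min) may be given;
#' the other is derived from the particle radius at solve time.
#'
#' @param cs0_g_cm3 Initial uniform solid-phase concentration, g/cm^3.
#' @param de_m2s Effective diffusion coefficient, m^2/s.
#' @param rate_per_min Dimensionless-time rate De/r^2 in 1/min (alternative
#'   to `de_m2s`).
#' @param K Interface partition coefficient (default 1): at the particle
#'   surface the solid concentration equilibrates to `K * CL`.
#' @return Object of class `diffusion_params`.
#' @export
diffusion_params <- function(cs0_g_cm3, de_m2s = NULL, rate_per_min = NULL,
                             K = 1) {
  if (is.null(de_m2s) == is.null(rate_per_min)) {
    stop("give exactly one of `de_m2s` or `rate_per_min`", call. = FALSE)
  }
  chk <- c(cs0_g_cm3, K, de_m2s, rate_per_min)
  if (!all(is.finite(chk))) stop("non-finite diffusion parameter", call. = FALSE)
  if (cs0_g_cm3 < 0) stop("`cs0_g_cm3` must be >= 0", call. = FALSE)
  if (K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (!is.null(de_m2s) && de_m2s <= 0) stop("`de_m2s` must be > 0", call. = FALSE)
  if (!is.null(rate_per_min) && rate_per_min <= 0) {
    stop("`rate_per_min` must be > 0", call. = FALSE)
  }
  structure(
    list(cs0_g_cm3 = cs0_g_cm3, de_m2s = de_m2s,
         rate_per_min = rate_per_min, K = K),
    class = "diffusion_params"
  )
}

# De (m^2/s) <-> Fourier rate De/r^2 (1/min), r in cm:
#   De[cm^2/min] = rate * r^2;  m^2/s = cm^2/min / (1e4 * 60)
de_from_rate <- function(rate_per_min, radius_cm) {
  rate_per_min * radius_cm^2 / 6e5
}
rate_from_de <- function(de_m2s, radius_cm) {
  de_m2s * 6e5 / radius_cm^2
}

resolve_rate <- function(params, particle) {
  if (!is.null(params$rate_per_min)) params$rate_per_min
  else rate_from_de(params$de_m2s, particle$radius_cm)
}

#' Solid-phase concentration from total extractable content
#'
#' Converts a measured total content (mg of gallic-acid equivalents per g of
#' solid) into the initial solid-phase concentration Cs0 in g/cm^3:
#' `Cs0 = content * density / 1000`.
#'
#' @param content_mg_g Total extractable content, mg/g.
#' @param solid_density_g_cm3 Particle density, g/cm^3.
#' @return Cs0 in g/cm^3.
#' @export
cs0_from_content <- function(content_mg_g, solid_density_g_cm3 = 1.0) {
  content_mg_g * solid_density_g_cm3 / 1000
}

#' Solve finite-bath extraction from spherical particles
#'
#' Integrates Fick's second law in a sphere,
#' `dCs/dt = De (1/x^2) d/dx (x^2 dCs/dx)`, coupled to a well-mixed finite
#' solvent bath: the liquid concentration CL(t) grows by the diffusive flux
#' through the particle surface, and the surface solid concentration stays
#' equilibrated at `K * CL` (negligible external film resistance). Internally
#' the system is nondimensionalised (tau = De t / r^2, xi = x / r,
#' alpha = VL / (K Vs)) and discretised by a conservative cell-centred
#' finite-volume scheme, so that the discrete solid + liquid mass is conserved
#' to integrator tolerance. Time integration uses [deSolve::ode()] (lsoda,
#' banded Jacobian).
#'
#' @param params A [diffusion_params()].
#' @param particle A [particle_spec()].
#' @param suspension A [suspension_spec()].
#' @param times_min Sorted output times in minutes; the first must be 0.
#' @param n_nodes Number of radial cells (>= 11, default 101).
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `extraction_profile`: list with `xi_grid`
#'   (cell centres plus the 0 and 1 endpoints), `times_min`, `Cs_field`
#'   (time x xi matrix, g/cm^3), `CL_series` (g/mL), `extracted_fraction`,
#'   `alpha`, plus cell-level fields used for exact mass accounting.
#' @export
solve_extraction <- function(params, particle, suspension, times_min,
                             n_nodes = 101, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "diffusion_params"),
            inherits(particle, "particle_spec"),
            inherits(suspension, "suspension_spec"))
  if (!is.numeric(times_min) || length(times_min) < 1L ||
      !all(is.finite(times_min))) {
    stop("`times_min` must be finite numeric", call. = FALSE)
  }
  if (is.unsorted(times_min, strictly = TRUE) || times_min[1] != 0) {
    stop("`times_min` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (n_nodes < 11) stop("`n_nodes` must be >= 11", call. = FALSE)

  rate <- resolve_rate(params, particle)     # 1/min
  alpha <- bath_capacity(suspension, params$K)
  tau <- rate * times_min
  N <- as.integer(n_nodes)
  h <- 1 / N
  faces <- (0:N) * h
  centers <- (seq_len(N) - 0.5) * h
  dvol <- diff(faces^3)                      # cell volumes (sum to 1)
  face_area <- faces^2

  # state: u_1..u_N (cell-average Cs/Cs0), w (extracted fraction of solid load)
  deriv <- function(t, y, parms) {
    u <- y[1:N]
    w <- y[N + 1]
    usurf <- w / alpha                       # u(1,tau) = K CL / Cs0
    flux <- numeric(N + 1)                   # face fluxes xi^2 du/dxi
    flux[2:N] <- face_area[2:N] * diff(u) / h
    # xi = 1: second-order one-sided gradient through the interface value
    # and the two nearest cell centres (distances h/2 and 3h/2)
    flux[N + 1] <- (8 * usurf - 9 * u[N] + u[N - 1]) / (3 * h)
    du <- 3 * diff(flux) / dvol
    dw <- -3 * flux[N + 1]
    list(c(du, dw))
  }

  y0 <- c(rep(1, N), 0)
  if (length(tau) == 1L) {
    out <- matrix(c(0, y0), nrow = 1)
  } else {
    out <- deSolve::ode(y0, tau, deriv, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol,
                        jactype = "bandint", bandup = 2L, banddown = 2L)
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) {
      stop(sprintf(paste0("diffusion solver failed to converge ",
                          "(lsoda istate = %d, alpha = %.3g, max tau = %.3g); ",
                          "try more nodes or looser tolerances"),
                   istate[1], alpha, max(tau)), call. = FALSE)
    }
    if (nrow(out) != length(tau)) {
      stop("diffusion solver stopped before the final output time",
           call. = FALSE)
    }
  }

  u_cells <- out[, 1 + 1:N, drop = FALSE]
  w <- out[, N + 2]
  cs0 <- params$cs0_g_cm3
  vs <- solid_volume(suspension)
  vl <- suspension$liquid_volume_ml
  cl <- w * cs0 * vs / vl                    # g/mL
  usurf <- w / alpha
  # full reporting grid: symmetric centre value, cell centres, interface value
  xi_grid <- c(0, centers, 1)
  Cs_field <- cbind(u_cells[, 1], u_cells, usurf) * cs0
  dimnames(Cs_field) <- NULL
  if (times_min[1] == 0) Cs_field[1, ] <- cs0  # initial condition row

  structure(
    list(xi_grid = xi_grid, times_min = times_min,
         Cs_field = Cs_field, CL_series = cl, extracted_fraction = w,
         alpha = alpha, rate_per_min = rate,
         cs0_g_cm3 = cs0, K = params$K,
         Cs_cells = u_cells * cs0, cell_volumes = dvol,
         particle = particle, suspension = suspension, n_nodes = N),
    class = "extraction_profile"
  )
}

#' Volume-weighted mean solid concentration per output time
#'
#' The radial mean `<Cs>(t) = 3 * integral(Cs xi^2 dxi)` evaluated with the
#' solver's own cell volumes, so that `Vs <Cs> + VL CL` is conserved exactly
#' (to integrator tolerance).
#'
#' @param profile An `extraction_profile`.
#' @return Numeric vector, one mean per output time (g/cm^3).
#' @export
mean_solid_concentration <- function(profile) {
  as.numeric(profile$Cs_cells %*% profile$cell_volumes)
}

#' Total phenolic mass balance of a profile
#'
#' @param profile An `extraction_profile`.
#' @return data.frame with per-time solid mass, liquid mass and their total
#'   (g), for conservation checks.
#' @export
mass_balance <- function(profile) {
  vs <- solid_volume(profile$suspension)
  vl <- profile$suspension$liquid_volume_ml
  solid <- vs * mean_solid_concentration(profile)
  liquid <- vl * profile$CL_series
  data.frame(time_min = profile$times_min, solid_g = solid,
             liquid_g = liquid, total_g = solid + liquid)
}

#' Closed-form series solution for sphere-in-finite-bath extraction
#'
#' Independent eigenfunction-series oracle for diffusion out of a sphere into
#' a stirred bath of limited volume:
#' `Mt/Minf = 1 - sum_n 6 a (a+1) exp(-qn^2 tau) / (9 + 9a + qn^2 a^2)`
#' where the `qn` are the nonzero roots of `tan q = 3q / (3 + a q^2)` and
#' `a` is the bath capacity alpha. Roots are located by bracketed
#' root-finding in `(n pi, n pi + pi/2)`.
#'
#' Used as the analytical cross-check of [solve_extraction()]; it shares no
#' code with the numerical solver.
#'
#' @param alpha Bath capacity VL/(K Vs), > 0.
#' @param tau Dimensionless time De t / r^2, >= 0 (vectorised).
#' @param n_roots Number of series terms (>= 20).
#' @return Extracted fraction of the *equilibrium* amount, Mt/Minf in
#'   \[0, 1\].
#' @export
crank_series_fraction <- function(alpha, tau, n_roots = 200) {
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau < 0)) stop("`tau` must be >= 0", call. = FALSE)
  if (n_roots < 20) stop("`n_roots` must be >= 20", call. = FALSE)
  q <- crank_roots(alpha, n_roots)
  coef <- 6 * alpha * (alpha + 1) / (9 + 9 * alpha + q^2 * alpha^2)
  sapply(tau, function(tt) {
    if (tt == 0) return(0)  # exact; avoids series-truncation residue
    val <- 1 - sum(coef * exp(-q^2 * tt))
    min(max(val, 0), 1)
  })
}

# nonzero positive roots of tan(q) = 3 q / (3 + alpha q^2); the n-th root
# lies in (n pi, n pi + pi/2) where tan rises from 0 to +Inf past the
# bounded positive right-hand side
crank_roots <- function(alpha, n_roots) {
  f <- function(q) tan(q) - 3 * q / (3 + alpha * q^2)
  vapply(seq_len(n_roots), function(n) {
    lo <- n * pi + 1e-9
    hi <- n * pi + pi / 2 - 1e-9
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
      stop(sprintf("root bracketing failed on (%.6f, %.6f) for alpha = %g",
                   lo, hi, alpha), call. = FALSE)
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Extraction yield curve in mg per g of solid
#'
#' Maps the liquid-phase concentration series to the conventional yield unit
#' (mg of gallic-acid equivalents per g of solid):
#' `yield(t) = 1000 * CL(t) * VL / solid_mass`.
#'
#' @param profile An `extraction_profile`.
#' @param suspension A [suspension_spec()]; defaults to the one stored in the
#'   profile.
#' @return data.frame with `time_min` and `yield_mg_per_g`.
#' @export
yield_curve <- function(profile, suspension = profile$suspension) {
  data.frame(
    time_min = profile$times_min,
    yield_mg_per_g = 1000 * profile$CL_series *
      suspension$liquid_volume_ml / suspension$solid_mass_g
  )
}

#' Radial concentration snapshot at a time point
#'
#' Returns the solid-phase radial profile and the bath concentration at the
#' simulated time nearest to `t_min` (the time actually used is reported).
#' Suitable for rendering the intra-particle concentration gradient.
#'
#' @param profile An `extraction_profile`.
#' @param t_min Requested time, minutes.
#' @return List with `xi`, `Cs` (g/cm^3), `CL` (g/mL), `time_requested_min`,
#'   `time_used_min`.
#' @export
extraction_snapshot <- function(profile, t_min) {
  if (length(profile$times_min) == 0L) stop("empty profile", call. = FALSE)
  if (!is.finite(t_min)) stop("`t_min` must be finite", call. = FALSE)
  i <- which.min(abs(profile$times_min - t_min))
  used <- profile$times_min[i]
  if (abs(used - t_min) > sqrt(.Machine$double.eps) * max(1, t_min)) {
    message(sprintf("snapshot: using nearest simulated time %.4g min", used))
  }
  list(xi = profile$xi_grid, Cs = profile$Cs_field[i, ],
       CL = profile$CL_series[i],
       time_requested_min = t_min, time_used_min = used)
}

#' Tidy export of a spatio-temporal profile
#'
#' @param profile An `extraction_profile`.
#' @param path Optional CSV path; when given the data frame is also written.
#' @return data.frame with columns `time_min`, `xi`, `Cs_g_per_cm3`,
#'   `CL_g_per_mL`.
#' @export
profile_to_df <- function(profile, path = NULL) {
  df <- data.frame(
    time_min = rep(profile$times_min, each = length(profile$xi_grid)),
    xi = rep(profile$xi_grid, length(profile$times_min)),
    Cs_g_per_cm3 = as.vector(t(profile$Cs_field)),
    CL_g_per_mL = rep(profile$CL_series, each = length(profile$xi_grid))
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' @export
print.extraction_profile <- function(x, ...) {
  cat("extraction_profile:", length(x$times_min), "times x",
      length(x$xi_grid), "radial points\n")
  cat(sprintf("  alpha = %.4g, rate = %.4g /min, Cs0 = %.4g g/cm^3, K = %g\n",
              x$alpha, x$rate_per_min, x$cs0_g_cm3, x$K))
  cat(sprintf("  extracted fraction at t = %.4g min: %.4f\n",
              max(x$times_min), x$extracted_fraction[length(x$times_min)]))
  invisible(x)
}
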
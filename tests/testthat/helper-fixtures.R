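# shared fixtures built in code

fixture_table_path <- function() {
  system.file("extdata", "table2_phenolics.csv", package = "phenolflux")
}

default_particle <- particle_spec()

# suspension with alpha = VL / Vs for K = 1
suspension_alpha <- function(alpha) suspension_spec(6, alpha * 6, 1)

# small default-configuration profile reused across tests
quick_profile <- function(alpha = 10, rate = 1, cs0 = 0.0079, K = 1,
                          taus = c(0, 0.01, 0.05, 0.1, 0.5, 1, 2),
                          n_nodes = 101) {
  solve_extraction(diffusion_params(cs0, rate_per_min = rate, K = K),
                   default_particle, suspension_alpha(alpha * K),
                   taus / rate, n_nodes = n_nodes)
}

# Mt/Minf from a profile (K = 1 construction above keeps alpha exact)
profile_fraction <- function(profile) {
  profile$extracted_fraction * (1 + profile$alpha) / profile$alpha
}

# a tiny two-compound toy table for composition tests
toy_compound_table <- function(mean_a = 10, mean_b = 30,
                               category = c("flavanol", "flavanol")) {
  labs <- "40C_NE"
  m <- matrix(c(mean_a, mean_b), 2, 1, dimnames = list(c("A", "B"), labs))
  s <- matrix(0, 2, 1, dimnames = dimnames(m))
  structure(
    list(compounds = data.frame(compound = c("A", "B"), category = category,
                                rt_min = c(1, 2), stringsAsFactors = FALSE),
         mean = m, sd = s,
         conditions = data.frame(label = labs, temperature_C = 40,
                                 enzyme = "NE", stringsAsFactors = FALSE),
         missing_report = data.frame(compound = c("A", "B"),
                                     n_missing = c(0L, 0L))),
    class = "compound_table"
  )
}

anfis_features <- c("temperature_C", "time_min", "enzyme_pct")
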
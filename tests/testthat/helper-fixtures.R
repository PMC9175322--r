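# Shared fixture builders. Everything is generated in code; no stored data.

lad <- age_ladder()

# A Gompertz-Makeham rate matrix pair with known structure: comparator is the
# base schedule, reference has selected cells scaled.
gompertz_pair <- function(causes = c("preventable", "non_avoidable"),
                          shares = c(0.3, 0.7),
                          scale_cause = NULL, scale_rows = NULL,
                          scale_factor = 1) {
  mids <- age_midpoints()
  mx <- 2e-4 + 2e-5 * exp(0.115 * mids) + ifelse(mids < 1, 0.006, 0)
  base <- outer(mx, shares)
  colnames(base) <- causes
  ref <- base
  if (!is.null(scale_cause)) {
    ref[scale_rows, scale_cause] <- ref[scale_rows, scale_cause] * scale_factor
  }
  list(ref = rate_matrix(ref, country = "REF", sex = "male", period = "sim"),
       cmp = rate_matrix(base, country = "CMP", sex = "male", period = "sim"))
}

# Independent life-expectancy oracle: survival quadrature on a fine grid for
# an arbitrary hazard function (trapezoidal integration of exp(-H)).
quadrature_e0 <- function(hazard, upper = 130, dx = 0.01) {
  x <- seq(0, upper, by = dx)
  H <- cumsum(c(0, (hazard(x[-1]) + hazard(x[-length(x)])) / 2 * dx))
  S <- exp(-H)
  sum((S[-1] + S[-length(S)]) / 2 * dx)
}

# A random canonical long-format mortality fixture (integer deaths).
random_long_table <- function(n_causes = 4, countries = c("AAA", "BBB"),
                              years = 2015:2016, seed = 99) {
  set.seed(seed)
  grid <- expand.grid(country = countries, year = years, sex = "male",
                      age_lower = lad$lower, cause = paste0("C", 10 + seq_len(n_causes)),
                      stringsAsFactors = FALSE)
  grid$age_width <- lad$width[match(grid$age_lower, lad$lower)]
  grid$deaths <- rpois(nrow(grid), 20)
  mortality_table(grid)
}

# External life table with mildly different rates from the default hazard.
toy_external <- function(scale = 1.2, source = "synthetic-external") {
  mids <- age_midpoints()
  external_lifetable(scale * (2e-4 + 2e-5 * exp(0.115 * mids)), source = source)
}

write_scenario_fixture <- function(dir, seed = 7) {
  sc <- scenario_spec(
    hazard_spec(cause_mix = list(C10 = 0.25, C33 = 0.15, V40 = 0.2, I21 = 0.1,
                                 J80 = 0.3)),
    countries = c("REF", "CMP"),
    perturbations = list(list(country = "CMP", cause = "V40", age_from = 15,
                              age_to = 49, factor = 0.6)),
    population = 5e5, years = 2015:2016, sex = "male", seed = seed)
  pair <- make_country_pair(sc)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_long(pair$deaths, file.path(dir, "deaths.csv"))
  p <- as.data.frame(pair$population)
  utils::write.csv(p[order(p$country, p$year, p$sex, p$age_lower), ],
                   file.path(dir, "population.csv"), row.names = FALSE,
                   quote = FALSE)
  list(scenario = sc, pair = pair,
       mortality = file.path(dir, "deaths.csv"),
       population = file.path(dir, "population.csv"))
}
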
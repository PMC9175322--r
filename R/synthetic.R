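#' Specify a parametric mortality hazard with a cause mix
#'
#' The all-cause hazard is Gompertz--Makeham,
#' h(x) = makeham + level * exp(slope * x), plus an optional infant excess
#' added on \eqn{[0,1)} to mimic the infant mortality hump. The hazard is
#' split into causes by an age-dependent share mix: each element of
#' `cause_mix` is either a constant share or a function of age returning the
#' share; shares must sum to 1 at every age.
#'
#' @param makeham Age-independent background rate (per year, >= 0).
#' @param gompertz_level Gompertz level parameter (per year, > 0).
#' @param gompertz_slope Gompertz slope (per year, > 0).
#' @param infant_excess Extra hazard on the infant group (per year, >= 0).
#' @param cause_mix Named list of constant shares or functions of age.
#' @return An object of class `hazard_spec`.
#' @examples
#' hazard_spec(makeham = 5e-4, gompertz_level = 1e-4, gompertz_slope = 0.1,
#'             infant_excess = 0.008,
#'             cause_mix = list(preventable = 0.3, non_avoidable = 0.7))
#' @export
hazard_spec <- function(makeham = 2e-4, gompertz_level = 2e-5,
                        gompertz_slope = 0.115, infant_excess = 0.006,
                        cause_mix = list(all = 1)) {
  stopifnot(makeham >= 0, gompertz_level > 0, gompertz_slope > 0,
            infant_excess >= 0)
  if (is.null(names(cause_mix)) || any(names(cause_mix) == "")) {
    stop_validation("cause_mix must be a named list")
  }
  h <- structure(list(makeham = makeham, gompertz_level = gompertz_level,
                      gompertz_slope = gompertz_slope,
                      infant_excess = infant_excess, cause_mix = cause_mix),
                 class = "hazard_spec")
  # shares must sum to 1 on the whole ladder
  sh <- cause_shares(h, age_midpoints())
  if (any(sh < 0) || any(abs(rowSums(sh) - 1) > 1e-12)) {
    stop_validation("cause shares must be non-negative and sum to 1 at every age")
  }
  h
}

#' Evaluate the all-cause hazard of a `hazard_spec`
#' @param h A `hazard_spec`.
#' @param age Ages in years.
#' @return Hazard per person-year.
#' @export
hazard_at <- function(h, age) {
  stopifnot(inherits(h, "hazard_spec"))
  h$makeham + h$gompertz_level * exp(h$gompertz_slope * age) +
    ifelse(age < 1, h$infant_excess, 0)
}

cause_shares <- function(h, age) {
  sh <- vapply(h$cause_mix, function(s) {
    if (is.function(s)) vapply(age, s, numeric(1)) else rep(as.numeric(s),
                                                            length(age))
  }, numeric(length(age)))
  matrix(sh, nrow = length(age), dimnames = list(NULL, names(h$cause_mix)))
}

#' Exact rate matrix implied by a hazard specification
#'
#' Rates are the hazard evaluated at the canonical group midpoints (the open
#' 85+ group is evaluated at age 90), split across causes by the mix shares.
#' Row sums therefore equal the all-cause hazard at the midpoints by
#' construction.
#'
#' @param h A `hazard_spec`.
#' @param country,sex,period Metadata for the resulting matrix.
#' @return A [rate_matrix()].
#' @export
make_rates <- function(h, country = "SYN", sex = "total", period = "sim") {
  stopifnot(inherits(h, "hazard_spec"))
  mids <- age_midpoints()
  mx <- hazard_at(h, mids)
  sh <- cause_shares(h, mids)
  rate_matrix(mx * sh, country = country, sex = sex, period = period)
}

# Deterministic 31-bit hash of a cell label combined with the master seed;
# label-based so adding a cause never shifts another cell's draws.
cell_seed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  (h + (seed %% 2147483647) * 2654435) %% 2147483647
}

#' Simulate Poisson death counts from a rate matrix
#'
#' Draws deaths\[a,c\] ~ Poisson(rate\[a,c\] * person-years\[a\]) with one
#' RNG substream per (country, age, cause) cell, derived deterministically
#' from the master seed and the cell's labels, so results are reproducible
#' and adding or removing a cause leaves all other cells' draws unchanged.
#'
#' @param rm A [rate_matrix()].
#' @param pop A [population_table()] for the same stratum, or a numeric
#'   vector of person-years on the canonical ladder.
#' @param seed Master seed (integer).
#' @return A [mortality_table()] with the matrix's stratum metadata.
#' @export
simulate_counts <- function(rm, pop, seed) {
  stopifnot(inherits(rm, "rate_matrix"))
  if (inherits(pop, "population_table")) {
    py <- rep(NA_real_, length(rm$age_lower))
    py[match_ladder(pop$age_lower, pop$age_width)] <- pop$population
    if (anyNA(py)) stop_validation("population table does not cover the ladder")
  } else {
    py <- as.numeric(pop)
    if (length(py) != length(rm$age_lower)) {
      stop_validation("person-years vector must match the canonical ladder")
    }
  }
  if (any(py < 0)) stop_validation("negative person-years")
  lad <- age_ladder()
  causes <- colnames(rm$rates)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  recs <- expand.grid(age = seq_len(nrow(lad)), cause = causes,
                      stringsAsFactors = FALSE)
  deaths <- mapply(function(a, cz) {
    lambda <- rm$rates[a, cz] * py[a]
    if (lambda == 0) return(0)
    set.seed(cell_seed(seed, paste(rm$country, lad$lower[a], cz, sep = "|")))
    stats::rpois(1, lambda)
  }, recs$age, recs$cause)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  mortality_table(data.frame(
    country = rm$country, year = rm$period, sex = rm$sex,
    age_lower = lad$lower[recs$age], age_width = lad$width[recs$age],
    cause = recs$cause, deaths = deaths, stringsAsFactors = FALSE))
}

#' Specify a two-country synthetic scenario
#'
#' A scenario is a base hazard shared by both countries plus a list of
#' multiplicative perturbations (country, cause, age range, factor > 0)
#' applied to the exact rates of the named country before counts are drawn.
#' An age range `c(from, to)` selects every ladder group whose lower bound
#' lies in `[from, to]`.
#'
#' @param base A [hazard_spec()].
#' @param countries Character vector of two country labels; the first is the
#'   reference.
#' @param perturbations List of `list(country=, cause=, age_from=, age_to=,
#'   factor=)`.
#' @param population Person-years per age group: a scalar (same for all 19
#'   groups) or a length-19 vector.
#' @param years Integer vector of calendar years to simulate.
#' @param sex `"male"` or `"female"`.
#' @param seed Master seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(base, countries = c("REF", "CMP"),
                          perturbations = list(), population = 1e6,
                          years = 2015:2016, sex = "male", seed = 1) {
  stopifnot(inherits(base, "hazard_spec"), length(countries) == 2)
  lad <- age_ladder()
  pop <- if (length(population) == 1) rep(population, nrow(lad)) else
    as.numeric(population)
  if (length(pop) != nrow(lad) || any(pop <= 0)) {
    stop_validation("population must be a positive scalar or length-19 vector")
  }
  for (p in perturbations) {
    if (!all(c("country", "cause", "age_from", "age_to", "factor") %in% names(p))) {
      stop_format("each perturbation needs country, cause, age_from, age_to, factor")
    }
    if (!p$country %in% countries) {
      stop_validation("perturbation names unknown country: ", p$country)
    }
    if (!p$cause %in% names(base$cause_mix)) {
      stop_validation("perturbation names unknown cause: ", p$cause)
    }
    if (p$factor <= 0) stop_validation("perturbation factor must be > 0")
    if (!any(lad$lower >= p$age_from & lad$lower <= p$age_to)) {
      stop_validation("perturbation age range [", p$age_from, ", ", p$age_to,
                      "] selects no ladder group")
    }
  }
  structure(list(base = base, countries = countries,
                 perturbations = perturbations, population = pop,
                 years = as.integer(years), sex = sex, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Read a scenario from YAML
#'
#' YAML keys mirror the [scenario_spec()] arguments; `base` holds the hazard
#' parameters and a `cause_mix` mapping of constant shares.
#'
#' @param path YAML file path.
#' @return A `scenario_spec`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  b <- y$base
  base <- hazard_spec(makeham = b$makeham %||% 2e-4,
                      gompertz_level = b$gompertz_level %||% 2e-5,
                      gompertz_slope = b$gompertz_slope %||% 0.115,
                      infant_excess = b$infant_excess %||% 0.006,
                      cause_mix = b$cause_mix %||% list(all = 1))
  scenario_spec(base,
                countries = unlist(y$countries %||% c("REF", "CMP")),
                perturbations = y$perturbations %||% list(),
                population = unlist(y$population %||% 1e6),
                years = unlist(y$years %||% 2015:2016),
                sex = y$sex %||% "male",
                seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a two-country dataset from a scenario
#'
#' Builds the exact (noise-free) rate matrix for each country — the base
#' hazard with that country's perturbations applied — then draws Poisson
#' death counts per calendar year and assembles the matching population
#' table. The exact matrices are returned alongside the counts so
#' decomposition results can be checked against the known injected
#' differences.
#'
#' @param s A `scenario_spec`.
#' @return List with `deaths` ([mortality_table()], both countries and all
#'   years), `population` ([population_table()]), and `exact_rates` (named
#'   list of [rate_matrix()] per country, period-labelled with the pooled
#'   year range).
#' @export
make_country_pair <- function(s) {
  stopifnot(inherits(s, "scenario_spec"))
  lad <- age_ladder()
  period <- if (length(s$years) == 1) as.character(s$years) else
    paste(min(s$years), max(s$years), sep = "-")
  exact <- list()
  deaths <- list()
  pops <- list()
  for (co in s$countries) {
    rm0 <- make_rates(s$base, country = co, sex = s$sex, period = period)
    r <- rm0$rates
    for (p in s$perturbations) {
      if (p$country != co) next
      rows <- lad$lower >= p$age_from & lad$lower <= p$age_to
      r[rows, p$cause] <- r[rows, p$cause] * p$factor
    }
    exact[[co]] <- rate_matrix(r, country = co, sex = s$sex, period = period)
    for (yr in s$years) {
      rm_y <- rate_matrix(r, country = co, sex = s$sex, period = as.character(yr))
      deaths[[paste(co, yr)]] <-
        simulate_counts(rm_y, s$population, seed = s$seed + (yr - min(s$years)))
      pops[[paste(co, yr)]] <- data.frame(
        country = co, year = as.character(yr), sex = s$sex,
        age_lower = lad$lower, age_width = lad$width,
        population = s$population, stringsAsFactors = FALSE)
    }
  }
  list(deaths = mortality_table(do.call(rbind, lapply(deaths, as.data.frame))),
       population = population_table(do.call(rbind, pops)),
       exact_rates = exact)
}
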
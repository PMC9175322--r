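#' Assemble and validate a run configuration
#'
#' The configuration drives the end-to-end analysis: which country is the
#' reference, which are compared against it, the pooling years, the sexes
#' and measures to run, the input paths, and the decomposition settings.
#'
#' @param reference Reference country label (gaps are reference minus
#'   comparator).
#' @param comparators Character vector of comparator countries (must not
#'   include the reference).
#' @param years Integer vector of years to pool.
#' @param sexes Subset of `c("male", "female")`.
#' @param mortality,population Paths to canonical long CSVs.
#' @param scheme Path to an avoidability rule CSV, or `NULL` for the shipped
#'   default.
#' @param external Optional path to an external life table CSV; when set, a
#'   parallel sensitivity bundle with recalibrated rates is produced.
#' @param measures Subset of `c("LE", "LI")`.
#' @param n_steps Decomposition path steps.
#' @param age_cap Avoidability age cap in years.
#' @param output_dir Directory for the output bundle.
#' @param age_bins Optional list of `c(from, to)` presentation bins for the
#'   aggregated display tables (defaults to the full ladder).
#' @param seed Seed recorded in the run log (used by synthetic stages only).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(reference, comparators, years, sexes = c("male", "female"),
                       mortality, population, scheme = NULL, external = NULL,
                       measures = c("LE", "LI"), n_steps = 20, age_cap = 75,
                       output_dir = "avoidgap_out", age_bins = NULL, seed = 1) {
  if (reference %in% comparators) {
    stop_validation("reference country must not appear among comparators")
  }
  if (length(years) == 0) stop_validation("years must be non-empty")
  sexes <- match.arg(sexes, several.ok = TRUE)
  measures <- match.arg(measures, c("LE", "LI"), several.ok = TRUE)
  for (p in c(mortality, population, scheme, external)) {
    if (!file.exists(p)) stop_validation("input path does not exist: ", p)
  }
  structure(list(reference = reference, comparators = comparators,
                 years = as.integer(years), sexes = sexes,
                 mortality = mortality, population = population,
                 scheme = scheme, external = external, measures = measures,
                 n_steps = as.integer(n_steps), age_cap = age_cap,
                 output_dir = output_dir, age_bins = age_bins,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(reference = y$reference,
             comparators = unlist(y$comparators),
             years = unlist(y$years),
             sexes = unlist(y$sexes) %||% c("male", "female"),
             mortality = y$mortality, population = y$population,
             scheme = y$scheme, external = y$external,
             measures = unlist(y$measures) %||% c("LE", "LI"),
             n_steps = y$n_steps %||% 20, age_cap = y$age_cap %||% 75,
             output_dir = y$output_dir %||% "avoidgap_out",
             age_bins = y$age_bins, seed = y$seed %||% 1)
}

#' Run the full gap-decomposition analysis
#'
#' For every (comparator, sex) stratum: pools the requested years, collapses
#' ICD-10 causes into the five avoidability groups, converts counts and
#' exposure to rate matrices, computes LE and lifespan SD for reference and
#' comparator, and decomposes each requested gap by age and cause. Writes,
#' under `config$output_dir`:
#' \itemize{
#'   \item `summary.csv` — one row per (comparator, sex, measure) with the
#'     reference value, comparator value and signed gap (reference minus
#'     comparator);
#'   \item `contributions_<measure>_<comparator>_<sex>.csv` — full-precision
#'     age-by-cause contribution tables ([write_contributions()] format);
#'   \item `display_<measure>_<comparator>_<sex>.csv` — contributions
#'     aggregated to the configured presentation bins and rounded to 0.1
#'     years;
#'   \item with an external life table configured, the same set again under
#'     `sensitivity/` using recalibrated rates;
#'   \item `run_log.txt` — package version, seed, n_steps, and the residual
#'     of every decomposition.
#' }
#' Any stage error aborts the run with the stage and stratum named, and
#' partial outputs are removed.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the summary data frame and the
#'   `contribution_matrix` objects, keyed `<measure>_<comparator>_<sex>`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  created <- character(0)
  emit <- function(writer, path) {
    writer(path)
    created <<- c(created, path)
  }
  stage <- "setup"
  stratum <- ""
  ok <- FALSE
  on.exit(if (!ok) unlink(created), add = TRUE)

  result <- tryCatch({
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stage <- "read inputs"
    deaths <- read_long(config$mortality)
    popn <- read_population(config$population)
    scheme <- if (is.null(config$scheme)) default_scheme(config$age_cap) else
      load_scheme(config$scheme, config$age_cap)
    ext <- if (!is.null(config$external))
      read_external_lifetable(config$external)

    stage <- "pool years"
    deaths <- pool_years(deaths, config$years)
    popn <- pool_years(popn, config$years)
    stage <- "collapse causes"
    deaths <- collapse_causes(deaths, scheme)

    all_countries <- c(config$reference, config$comparators)
    missing_c <- setdiff(all_countries, unique(deaths$country))
    if (length(missing_c) > 0) {
      stop_validation("country(ies) absent from mortality data: ",
                      paste(missing_c, collapse = ", "))
    }

    strat_rates <- function(co, sx) {
      t_ <- deaths[deaths$country == co & deaths$sex == sx, , drop = FALSE]
      p_ <- popn[popn$country == co & popn$sex == sx, , drop = FALSE]
      class(t_) <- class(deaths); class(p_) <- class(popn)
      if (nrow(t_) == 0) stop_validation("no deaths for ", co, " ", sx)
      list(raw = to_rate_matrix(t_, p_), counts = t_)
    }

    summary_rows <- list()
    cms <- list()
    log_lines <- c(paste0("avoidgap version: ",
                          as.character(utils::packageVersion("avoidgap"))),
                   paste0("seed: ", config$seed),
                   paste0("n_steps: ", config$n_steps),
                   paste0("years: ", paste(config$years, collapse = ",")),
                   paste0("reference: ", config$reference))

    run_one <- function(rates_ref, rates_cmp, tag, subdir) {
      for (me in config$measures) {
        sex_arg <- if (rates_ref$sex %in% c("male", "female")) rates_ref$sex
          else "total"
        v_ref <- build_lifetable(all_cause_rates(rates_ref), sex = sex_arg)
        v_cmp <- build_lifetable(all_cause_rates(rates_cmp), sex = sex_arg)
        val <- switch(me, LE = life_expectancy, LI = lifespan_sd)
        g <- gap(me, val(v_ref), val(v_cmp))
        cm <- decompose_gap(me, rates_ref, rates_cmp, n_steps = config$n_steps)
        key <- paste(me, rates_cmp$country, rates_ref$sex, sep = "_")
        cms[[paste0(if (nzchar(subdir)) "sens_", key)]] <<- cm
        summary_rows[[paste(subdir, key)]] <<- data.frame(
          bundle = if (nzchar(subdir)) "sensitivity" else "main",
          measure = me, sex = rates_ref$sex,
          reference = config$reference, comparator = rates_cmp$country,
          reference_value = g$reference, comparator_value = g$comparator,
          gap = g$gap, stringsAsFactors = FALSE)
        base <- if (nzchar(subdir)) file.path(out, subdir) else out
        emit(function(p) write_contributions(cm, p),
             file.path(base, paste0("contributions_", key, ".csv")))
        disp <- aggregate_contributions(
          cm, age_bins = config$age_bins %||% default_identity_bins())
        disp$contribution_years <- round(disp$contribution_years, 1)
        emit(function(p) utils::write.csv(disp, p, row.names = FALSE,
                                          quote = FALSE),
             file.path(base, paste0("display_", key, ".csv")))
        log_lines <<- c(log_lines, sprintf(
          "%s%s: total_gap=%.6f residual=%.3e", tag, me, cm$total_gap,
          cm$residual))
      }
    }

    for (sx in config$sexes) {
      stage <- "rates"
      stratum <- paste(config$reference, sx)
      ref <- strat_rates(config$reference, sx)
      for (co in config$comparators) {
        stratum <- paste(co, sx)
        cmp <- strat_rates(co, sx)
        stage <- "decompose"
        run_one(ref$raw, cmp$raw, paste0(co, " ", sx, " "), "")
        if (!is.null(ext)) {
          stage <- "recalibrate"
          dir.create(file.path(out, "sensitivity"), showWarnings = FALSE)
          ref_adj <- recalibrate(ref$counts, ext)
          cmp_adj <- recalibrate(cmp$counts, ext)
          stage <- "decompose (sensitivity)"
          run_one(ref_adj, cmp_adj, paste0(co, " ", sx, " [sens] "),
                  "sensitivity")
        }
      }
    }

    stage <- "write summary"
    summ <- do.call(rbind, summary_rows)
    rownames(summ) <- NULL
    summ <- summ[order(summ$bundle, summ$measure, summ$comparator, summ$sex), ]
    emit(function(p) utils::write.csv(summ, p, row.names = FALSE, quote = FALSE),
         file.path(out, "summary.csv"))
    emit(function(p) writeLines(log_lines, p), file.path(out, "run_log.txt"))
    ok <- TRUE
    list(summary = summ, contributions = cms, output_dir = out)
  }, error = function(e) {
    stop_validation("run failed at stage '", stage, "' (", stratum, "): ",
                    conditionMessage(e))
  })
  invisible(result)
}

default_identity_bins <- function() {
  lad <- age_ladder()
  lapply(seq_len(nrow(lad)), function(i)
    c(lad$lower[i], if (lad$open[i]) Inf else lad$lower[i] + lad$width[i] - 1))
}

#' Aggregate a contribution matrix into presentation bins
#'
#' Sums contributions within user-chosen age bins and cause groups, e.g. for
#' figure-style reporting ("ages 15-49, preventable causes"). Bins must
#' partition the age ladder and groups must partition the cause axis, so the
#' grand total (and hence total gap minus residual) is conserved at any
#' binning.
#'
#' @param cm A `contribution_matrix`.
#' @param age_bins List of `c(from, to)` ranges; each ladder group's lower
#'   bound must fall in exactly one bin (`to = Inf` allowed for the last).
#' @param cause_groups Named list mapping group label to a character vector
#'   of cause labels; default: each cause is its own group.
#' @return A data frame `age_bin, cause_group, contribution_years` with
#'   attributes `total_gap` and `residual` carried over.
#' @export
aggregate_contributions <- function(cm, age_bins = NULL, cause_groups = NULL) {
  stopifnot(inherits(cm, "contribution_matrix"))
  if (is.null(age_bins)) age_bins <- default_identity_bins()
  causes <- colnames(cm$contributions)
  if (is.null(cause_groups)) {
    cause_groups <- stats::setNames(as.list(causes), causes)
  }
  lower <- cm$age_lower
  bin_of <- rep(NA_integer_, length(lower))
  for (i in seq_along(age_bins)) {
    b <- age_bins[[i]]
    hit <- lower >= b[1] & lower <= b[2]
    if (any(!is.na(bin_of[hit]))) {
      stop_validation("age bins overlap at lower bound(s) ",
                      paste(lower[hit & !is.na(bin_of)], collapse = ", "))
    }
    bin_of[hit] <- i
  }
  if (anyNA(bin_of)) {
    stop_validation("age bins do not cover lower bound(s) ",
                    paste(lower[is.na(bin_of)], collapse = ", "))
  }
  grp_of <- rep(NA_integer_, length(causes))
  for (i in seq_along(cause_groups)) {
    hit <- causes %in% cause_groups[[i]]
    if (any(!is.na(grp_of[hit]))) {
      stop_validation("cause groups overlap")
    }
    grp_of[hit] <- i
  }
  if (anyNA(grp_of)) {
    stop_validation("cause groups do not cover: ",
                    paste(causes[is.na(grp_of)], collapse = ", "))
  }
  bin_label <- vapply(age_bins, function(b)
    if (is.infinite(b[2])) paste0(b[1], "+") else paste0(b[1], "-", b[2]),
    character(1))
  agg <- expand.grid(age_bin = bin_label, cause_group = names(cause_groups),
                     stringsAsFactors = FALSE)
  agg$contribution_years <- mapply(function(bl, gl) {
    sum(cm$contributions[bin_of == match(bl, bin_label),
                         grp_of == match(gl, names(cause_groups)),
                         drop = FALSE])
  }, agg$age_bin, agg$cause_group)
  attr(agg, "total_gap") <- cm$total_gap
  attr(agg, "residual") <- cm$residual
  agg
}
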
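#' Construct and validate a mortality table
#'
#' A mortality table is a long-format data frame of death counts keyed by
#' (country, year, sex, age group, cause). Age groups must lie on the
#' canonical ladder (see [age_ladder()]); the `year` column is a character
#' label so pooled periods such as `"2015-2016"` are representable.
#'
#' @param df Data frame with columns `country`, `year`, `sex`, `age_lower`,
#'   `age_width`, `cause`, `deaths`.
#' @param allow_fractional Allow non-integer death counts (used after
#'   recalibration or pooling of adjusted counts). Raw data must be integer.
#' @return The validated data frame with class `mortality_table`.
#' @export
mortality_table <- function(df, allow_fractional = FALSE) {
  required <- c("country", "year", "sex", "age_lower", "age_width",
                "cause", "deaths")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_format("mortality table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$country <- as.character(df$country)
  df$year <- as.character(df$year)
  df$sex <- normalize_sex(df$sex)
  df$cause <- as.character(df$cause)
  df$deaths <- as.numeric(df$deaths)
  if (anyNA(df$deaths)) stop_validation("deaths contains missing values")
  if (any(df$deaths < 0)) {
    bad <- which(df$deaths < 0)[1]
    stop_validation("negative deaths at row ", bad, " (",
                    df$country[bad], ", ", df$year[bad], ", ", df$sex[bad],
                    ", age ", df$age_lower[bad], ", ", df$cause[bad], ")")
  }
  if (!allow_fractional && any(df$deaths != round(df$deaths))) {
    stop_validation("deaths must be non-negative integers in raw data")
  }
  idx <- match_ladder(df$age_lower, df$age_width)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop_validation("age group(s) not on the canonical ladder: ",
                    paste(unique(paste0("[", df$age_lower[bad], ", ",
                                        df$age_lower[bad] + df$age_width[bad],
                                        ")")), collapse = ", "))
  }
  df$age_lower <- as.integer(df$age_lower)
  df$age_width <- as.numeric(df$age_width)
  key <- paste(df$country, df$year, df$sex, df$age_lower, df$cause, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop_validation("duplicate key: (", d$country, ", ", d$year, ", ", d$sex,
                    ", age ", d$age_lower, ", ", d$cause, ")")
  }
  class(df) <- c("mortality_table", "data.frame")
  df
}

#' @export
print.mortality_table <- function(x, ...) {
  cat("<mortality_table> ", nrow(x), " records; ",
      length(unique(x$country)), " country(ies), ",
      length(unique(x$cause)), " cause(s), total deaths ",
      format(sum(x$deaths)), "\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Construct and validate a population table
#'
#' Person-years of exposure by (country, year, sex, age group). For a single
#' calendar year the mid-year population count is taken as person-years.
#'
#' @param df Data frame with columns `country`, `year`, `sex`, `age_lower`,
#'   `age_width`, `population`.
#' @return The validated data frame with class `population_table`.
#' @export
population_table <- function(df) {
  required <- c("country", "year", "sex", "age_lower", "age_width", "population")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_format("population table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$country <- as.character(df$country)
  df$year <- as.character(df$year)
  df$sex <- normalize_sex(df$sex)
  df$population <- as.numeric(df$population)
  if (anyNA(df$population) || any(df$population < 0)) {
    stop_validation("population must be non-negative and non-missing")
  }
  if (anyNA(match_ladder(df$age_lower, df$age_width))) {
    stop_validation("population age group(s) not on the canonical ladder")
  }
  df$age_lower <- as.integer(df$age_lower)
  df$age_width <- as.numeric(df$age_width)
  key <- paste(df$country, df$year, df$sex, df$age_lower, sep = "\r")
  if (anyDuplicated(key)) stop_validation("duplicate population key")
  class(df) <- c("population_table", "data.frame")
  df
}

#' Read a mortality table from the canonical long CSV
#'
#' The canonical schema has header
#' `country,year,sex,age_lower,age_width,cause,deaths`, one row per stratum,
#' with `age_width = Inf` for the open 85+ group. Rows whose age group is not
#' on the canonical ladder are rejected with an error.
#'
#' @param path Path to a CSV file.
#' @return A [mortality_table()].
#' @seealso [write_long()] for the inverse, [read_who_wide()] for the WHO
#'   Mortality Database wide dialect.
#' @export
read_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mortality_table(df)
}

#' Write a mortality table as canonical long CSV
#'
#' Output is canonicalized: rows sorted by (country, year, sex, age, cause),
#' UTF-8, no row names. `write_long(read_long(f))` is byte-identical to a
#' canonicalized `f`.
#'
#' @param t A [mortality_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long <- function(t, path) {
  stopifnot(inherits(t, "mortality_table"))
  o <- order(t$country, t$year, t$sex, t$age_lower, t$cause)
  out <- as.data.frame(t)[o, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a population table from CSV
#'
#' Schema: `country,year,sex,age_lower,age_width,population`.
#'
#' @param path Path to a CSV file.
#' @return A [population_table()].
#' @export
read_population <- function(path) {
  population_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read death counts in the WHO Mortality Database wide dialect
#'
#' The WHO dialect stores one row per (country, year, sex, cause) with death
#' counts spread over numbered age columns (`Deaths1`, `Deaths2`, ...). The
#' meaning of each column varies by the file's age format, so a mapping must
#' be supplied: a named list (or a YAML file of the same shape) from column
#' name to either `list(lower =, width =)`, the string `"unknown"` (deaths of
#' unspecified age; dropped with a logged count), or `"ignore"` (e.g. an
#' all-ages total column). Columns mapping to ages finer than the canonical
#' ladder are summed into their canonical group; a column spanning more than
#' one canonical group is rejected. Mapped columns absent from the file are
#' treated as zero with a warning. Empty cells are read as zero deaths with a
#' warning.
#'
#' @param path Path to the wide CSV. Must contain columns `country` (or
#'   `Country`), `year`, `sex`, `cause` plus the mapped age columns.
#' @param age_format Named list or path to a YAML file describing the age
#'   columns (see Details).
#' @return A [mortality_table()] on the canonical ladder.
#' @export
read_who_wide <- function(path, age_format) {
  if (is.character(age_format) && length(age_format) == 1) {
    age_format <- yaml::read_yaml(age_format)
  }
  if (is.null(names(age_format)) || any(names(age_format) == "")) {
    stop_format("age_format must be a named mapping of column name to age group")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("^Country$", "country", names(df))
  names(df) <- sub("^Year$", "year", names(df))
  names(df) <- sub("^Sex$", "sex", names(df))
  names(df) <- sub("^Cause$", "cause", names(df))
  for (k in c("country", "year", "sex", "cause")) {
    if (!k %in% names(df)) stop_format("wide file is missing column: ", k)
  }
  lad <- age_ladder()

  # Resolve each mapped column to a canonical ladder row (or a drop marker).
  spec <- list()
  for (col in names(age_format)) {
    v <- age_format[[col]]
    if (identical(v, "ignore")) next
    if (identical(v, "unknown")) {
      spec[[col]] <- NA_integer_  # unknown-age bucket
      next
    }
    if (!is.list(v) || is.null(v$lower) || is.null(v$width)) {
      stop_format("age_format entry for column '", col,
                  "' must be list(lower=, width=), \"unknown\" or \"ignore\"")
    }
    lower <- as.numeric(v$lower)
    width <- if (identical(v$width, "open") || is.infinite(as.numeric(v$width))) {
      Inf
    } else {
      as.numeric(v$width)
    }
    if (is.infinite(width)) {
      if (lower < 85) {
        stop_format("open-ended column '", col,
                    "' starts below 85 and cannot be placed on the ladder")
      }
      spec[[col]] <- nrow(lad)
    } else {
      hit <- which(lad$lower <= lower & lower + width <= lad$lower + lad$width)
      if (length(hit) != 1) {
        stop_format("column '", col, "' covers [", lower, ", ", lower + width,
                    "), which spans more than one canonical age group")
      }
      spec[[col]] <- hit
    }
  }
  unmapped <- setdiff(grep("^Deaths[0-9]+$", names(df), value = TRUE),
                      names(age_format))
  if (length(unmapped) > 0) {
    stop_format("unmapped age column(s): ", paste(unmapped, collapse = ", "))
  }

  absent <- setdiff(names(spec), names(df))
  if (length(absent) > 0) {
    warning("age column(s) missing from file, treated as zero deaths: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  present <- intersect(names(spec), names(df))

  n_empty <- 0L
  vals <- lapply(present, function(col) {
    x <- df[[col]]
    if (is.character(x)) {
      blank <- trimws(x) == "" | is.na(x)
      n_empty <<- n_empty + sum(blank)
      x[blank] <- "0"
      suppressWarnings(num <- as.numeric(x))
      if (anyNA(num)) {
        stop_validation("non-numeric deaths in column '", col, "': ",
                        paste(unique(x[is.na(num)]), collapse = ", "))
      }
      num
    } else {
      blank <- is.na(x)
      n_empty <<- n_empty + sum(blank)
      x[blank] <- 0
      as.numeric(x)
    }
  })
  names(vals) <- present
  if (n_empty > 0) {
    warning(n_empty, " empty deaths cell(s) treated as zero", call. = FALSE)
  }

  ladder_idx <- unlist(spec[present], use.names = FALSE)
  unknown_cols <- present[is.na(ladder_idx)]
  if (length(unknown_cols) > 0) {
    dropped <- sum(unlist(vals[unknown_cols]))
    if (dropped > 0) {
      log_msg("dropped ", format(dropped), " death(s) of unknown age")
    }
  }
  keep <- present[!is.na(ladder_idx)]
  ladder_idx <- ladder_idx[!is.na(ladder_idx)]

  # Accumulate (possibly sub-ladder) columns into their canonical group.
  long <- do.call(rbind, lapply(seq_along(keep), function(i) {
    g <- lad[ladder_idx[i], ]
    data.frame(country = df$country, year = df$year, sex = df$sex,
               age_lower = g$lower, age_width = g$width, cause = df$cause,
               deaths = vals[[keep[i]]], stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(
    deaths ~ country + year + sex + age_lower + age_width + cause,
    data = long, FUN = sum)
  mortality_table(agg)
}

#' Pool a table over calendar years
#'
#' Sums deaths (or person-years) over the requested years within each
#' (country, sex, age group, cause) stratum. The pooled period is labelled
#' `"<min>-<max>"` in the `year` column. Pooling a population table sums the
#' annual mid-year populations, i.e. each year contributes one person-year
#' per person — the standard approximation for multi-year exposure.
#'
#' @param t A [mortality_table()] or [population_table()].
#' @param years Integer vector of years to pool; all must be present in `t`.
#' @return A table of the same class with a single pooled period.
#' @export
pool_years <- function(t, years) {
  UseMethod("pool_years")
}

pool_impl <- function(t, years, value_col) {
  years <- as.character(sort(unique(as.integer(years))))
  have <- unique(t$year)
  absent <- setdiff(years, have)
  if (length(absent) > 0) {
    stop_validation("requested year(s) not present: ",
                    paste(absent, collapse = ", "),
                    "; available: ", paste(sort(have), collapse = ", "))
  }
  sub <- t[t$year %in% years, , drop = FALSE]
  label <- if (length(years) == 1) years else
    paste(years[1], years[length(years)], sep = "-")
  f <- stats::as.formula(paste(
    value_col, "~ country + sex + age_lower + age_width",
    if ("cause" %in% names(sub)) "+ cause" else ""))
  agg <- stats::aggregate(f, data = as.data.frame(sub), FUN = sum)
  agg$year <- label
  agg
}

#' @export
pool_years.mortality_table <- function(t, years) {
  mortality_table(pool_impl(t, years, "deaths"), allow_fractional = TRUE)
}

#' @export
pool_years.population_table <- function(t, years) {
  population_table(pool_impl(t, years, "population"))
}

#' Construct a rate matrix
#'
#' The age-by-cause matrix of central death rates for one population stratum
#' (one country, sex, period). Rows follow the canonical ladder; entries are
#' deaths per person-year. This is the covariate object the decomposition
#' operates on.
#'
#' @param rates Numeric 19-by-K matrix, `rownames` taken from the ladder,
#'   `colnames` the cause labels.
#' @param country,sex,period Stratum metadata.
#' @param calibrated_to Optional label of an external life table the rates
#'   were recalibrated to (see [recalibrate()]).
#' @return An object of class `rate_matrix`.
#' @export
rate_matrix <- function(rates, country = NA_character_, sex = NA_character_,
                        period = NA_character_, calibrated_to = NULL) {
  lad <- age_ladder()
  rates <- as.matrix(rates)
  if (nrow(rates) != nrow(lad)) {
    stop_validation("rate matrix must have ", nrow(lad),
                    " rows (canonical age ladder); got ", nrow(rates))
  }
  if (!all(is.finite(rates)) || any(rates < 0)) {
    stop_validation("rates must be finite and non-negative")
  }
  rownames(rates) <- lad$label
  if (is.null(colnames(rates))) {
    colnames(rates) <- paste0("cause", seq_len(ncol(rates)))
  }
  structure(list(rates = rates, age_lower = lad$lower, age_width = lad$width,
                 country = country, sex = sex, period = period,
                 calibrated_to = calibrated_to),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix> ", x$country, " ", x$sex, " ", x$period, ": ",
      nrow(x$rates), " ages x ", ncol(x$rates), " causes; all-cause m0 = ",
      signif(sum(x$rates[1, ]), 4), ", m85+ = ",
      signif(sum(x$rates[nrow(x$rates), ]), 4), "\n", sep = "")
  if (!is.null(x$calibrated_to)) cat("  calibrated to: ", x$calibrated_to, "\n")
  invisible(x)
}

#' All-cause age-specific rates of a rate matrix
#'
#' @param rm A [rate_matrix()].
#' @return Numeric vector of length 19 (row sums over causes).
#' @export
all_cause_rates <- function(rm) {
  stopifnot(inherits(rm, "rate_matrix"))
  rowSums(rm$rates)
}

#' Convert death counts and exposure to a rate matrix
#'
#' Computes central death rates m\[a,c\] = deaths / person-years for a single
#' stratum. `t` and `p` must be pooled over the same period and refer to the
#' same country and sex. Causes absent in an age group get rate 0.
#'
#' @param t A [mortality_table()] restricted to one (country, sex, period).
#' @param p A [population_table()] for the same stratum.
#' @return A [rate_matrix()].
#' @export
to_rate_matrix <- function(t, p) {
  stopifnot(inherits(t, "mortality_table"), inherits(p, "population_table"))
  for (k in c("country", "sex", "year")) {
    if (length(unique(t[[k]])) != 1 || length(unique(p[[k]])) != 1) {
      stop_validation("to_rate_matrix expects a single stratum; column '", k,
                      "' is not constant")
    }
    if (unique(t[[k]]) != unique(p[[k]])) {
      stop_validation("mortality and population tables disagree on ", k, ": ",
                      unique(t[[k]]), " vs ", unique(p[[k]]))
    }
  }
  lad <- age_ladder()
  causes <- sort(unique(t$cause))
  D <- matrix(0, nrow(lad), length(causes),
              dimnames = list(lad$label, causes))
  D[cbind(match_ladder(t$age_lower, t$age_width), match(t$cause, causes))] <-
    t$deaths
  P <- rep(NA_real_, nrow(lad))
  P[match_ladder(p$age_lower, p$age_width)] <- p$population
  need <- rowSums(D) > 0
  bad <- need & (is.na(P) | P <= 0)
  if (any(bad)) {
    stop_validation("zero or missing population with deaths > 0 in stratum (",
                    unique(t$country), ", ", unique(t$sex), ", ",
                    unique(t$year), "), age group(s): ",
                    paste(lad$label[bad], collapse = ", "))
  }
  P[is.na(P) | P == 0] <- 1  # rows with no deaths: rate is 0 regardless
  rate_matrix(D / P, country = unique(t$country), sex = unique(t$sex),
              period = unique(t$year))
}
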
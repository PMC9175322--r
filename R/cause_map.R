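AVOIDABILITY_CATEGORIES <- c("treatable", "preventable",
                             "treatable_and_preventable", "ihd",
                             "non_avoidable")

#' Avoidability classification categories
#'
#' The five mutually exclusive groups used throughout the package:
#' `treatable` (avoidable through good-quality healthcare, e.g. deaths around
#' childbirth), `preventable` (avoidable through public-health interventions,
#' e.g. injuries, drug- and alcohol-related deaths), `treatable_and_preventable`
#' (e.g. diabetes mellitus), `ihd` (ischaemic heart disease, kept as its own
#' group), and `non_avoidable` (everything else, plus every death at or above
#' the age cap).
#'
#' @return Character vector of the five category labels.
#' @export
avoidability_categories <- function() AVOIDABILITY_CATEGORIES

icd3_ok <- function(x) grepl("^[A-Z][0-9]{2}$", x)

#' Load an avoidability scheme from a rule file
#'
#' A scheme is an ordered list of inclusive ICD-10 code ranges, each mapped
#' to one of the five avoidability categories, plus an age cap. Rules are
#' evaluated in file order and the first match wins; overlapping ranges are
#' therefore legal (and logged). A terminal catch-all rule `A00`-`Z99` ->
#' `non_avoidable` is appended if the file does not already end in one, so
#' every syntactically valid code is classified.
#'
#' @param path CSV file with columns `range_start`, `range_end`, `category`
#'   (3-character ICD-10 codes, e.g. `V01,V99,preventable`).
#' @param age_cap Age in years at and above which every death is
#'   `non_avoidable` regardless of cause. The default 75 means deaths are
#'   capped at 74 completed years of age; applied by age-group lower bound,
#'   so group 70-74 can be avoidable and 75-79 cannot.
#' @return An object of class `avoidability_scheme`.
#' @seealso [default_scheme()] for the rule table shipped with the package.
#' @export
load_scheme <- function(path, age_cap = 75) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  for (k in c("range_start", "range_end", "category")) {
    if (!k %in% names(df)) stop_format("scheme file is missing column: ", k)
  }
  df$range_start <- toupper(trimws(df$range_start))
  df$range_end <- toupper(trimws(df$range_end))
  df$category <- trimws(df$category)
  for (i in seq_len(nrow(df))) {
    if (!icd3_ok(df$range_start[i]) || !icd3_ok(df$range_end[i])) {
      stop_validation("rule ", i, ": malformed ICD-10 code in range ",
                      df$range_start[i], "-", df$range_end[i])
    }
    if (df$range_start[i] > df$range_end[i]) {
      stop_validation("rule ", i, ": range start ", df$range_start[i],
                      " exceeds end ", df$range_end[i])
    }
    if (!df$category[i] %in% AVOIDABILITY_CATEGORIES) {
      stop_validation("rule ", i, ": unknown category '", df$category[i],
                      "' (must be one of ",
                      paste(AVOIDABILITY_CATEGORIES, collapse = ", "), ")")
    }
  }
  if (nrow(df) == 0 ||
      !(df$range_start[nrow(df)] == "A00" && df$range_end[nrow(df)] == "Z99" &&
        df$category[nrow(df)] == "non_avoidable")) {
    df <- rbind(df, data.frame(range_start = "A00", range_end = "Z99",
                               category = "non_avoidable"))
  }
  # flag overlaps among the explicit (non-catch-all) rules
  n <- nrow(df) - 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      later <- (i + 1):n
      ov <- df$range_start[later] <= df$range_end[i] &
        df$range_end[later] >= df$range_start[i]
      if (any(ov)) {
        log_msg("scheme rules overlap: rule ", i, " (", df$range_start[i], "-",
                df$range_end[i], ") with rule(s) ",
                paste(later[ov], collapse = ", "), "; order resolves them")
      }
    }
  }
  if (!is.numeric(age_cap) || length(age_cap) != 1 || age_cap <= 0) {
    stop_validation("age_cap must be a single positive number")
  }
  structure(list(rules = df, age_cap = age_cap),
            class = "avoidability_scheme")
}

#' The default avoidability scheme shipped with the package
#'
#' A compact rule table covering the major cause families of the
#' OECD/Eurostat avoidable-mortality framework (injuries, drug- and
#' alcohol-related deaths, maternal and perinatal causes, vaccine-preventable
#' and treatable infections, screening-detectable cancers, lung cancer,
#' diabetes, hypertensive disease, ischaemic heart disease) plus a
#' non-avoidable catch-all. It is a synthetic working default, not a
#' reproduction of the full published list; supply your own rule CSV to
#' [load_scheme()] for production analyses.
#'
#' @param age_cap Passed to [load_scheme()]; default 75.
#' @return An `avoidability_scheme`.
#' @export
default_scheme <- function(age_cap = 75) {
  load_scheme(system.file("extdata", "avoidable_scheme_default.csv",
                          package = "avoidgap", mustWork = TRUE),
              age_cap = age_cap)
}

#' @export
print.avoidability_scheme <- function(x, ...) {
  cat("<avoidability_scheme> ", nrow(x$rules), " ordered rules, age cap ",
      x$age_cap, " (deaths at ages >= ", x$age_cap,
      " are non-avoidable)\n", sep = "")
  print(x$rules, row.names = FALSE)
  invisible(x)
}

#' Classify ICD-10 codes into avoidability categories
#'
#' Applies the scheme's ordered first-match-wins rules to the 3-character
#' stem of each code (4-character codes such as `E10.1` or `E101` match via
#' their stem `E10`). Any death in an age group whose lower bound is at or
#' above the scheme's age cap is `non_avoidable` regardless of cause.
#' Syntactically invalid codes raise an error rather than falling through to
#' `non_avoidable`.
#'
#' @param code Character vector of ICD-10 codes.
#' @param age_lower Integer vector (recycled) of age-group lower bounds.
#' @param scheme An `avoidability_scheme`.
#' @return Character vector of category labels, same length as `code`.
#' @examples
#' sch <- default_scheme()
#' classify_icd10(c("V43", "E10", "I21", "I21"), c(30, 50, 60, 80), sch)
#' @export
classify_icd10 <- function(code, age_lower, scheme) {
  stopifnot(inherits(scheme, "avoidability_scheme"))
  code <- toupper(trimws(as.character(code)))
  ok <- grepl("^[A-Z][0-9]{2}(\\.?[0-9]{1,2})?$", code)
  if (!all(ok)) {
    stop_validation("syntactically invalid ICD-10 code(s): ",
                    paste(unique(code[!ok]), collapse = ", "))
  }
  stem <- substr(code, 1, 3)
  n <- max(length(code), length(age_lower))
  stem <- rep_len(stem, n)
  age_lower <- rep_len(age_lower, n)
  out <- rep(NA_character_, n)
  capped <- age_lower >= scheme$age_cap
  out[capped] <- "non_avoidable"
  todo <- which(!capped)
  r <- scheme$rules
  for (i in seq_len(nrow(r))) {
    if (length(todo) == 0) break
    hit <- stem[todo] >= r$range_start[i] & stem[todo] <= r$range_end[i]
    out[todo[hit]] <- r$category[i]
    todo <- todo[!hit]
  }
  out
}

#' Collapse ICD-10 causes into the five avoidability groups
#'
#' Replaces the cause axis of a mortality table with the five category
#' labels, summing deaths within each (country, year, sex, age group,
#' category). Total deaths are conserved exactly.
#'
#' @param t A [mortality_table()] whose `cause` labels are ICD-10 codes.
#' @param scheme An `avoidability_scheme`.
#' @return A [mortality_table()] with causes in
#'   [avoidability_categories()].
#' @export
collapse_causes <- function(t, scheme) {
  stopifnot(inherits(t, "mortality_table"))
  bad <- !grepl("^[A-Z][0-9]{2}(\\.?[0-9]{1,2})?$", toupper(trimws(t$cause)))
  if (any(bad)) {
    i <- which(bad)[1]
    stop_validation("invalid ICD-10 code '", t$cause[i], "' in record (",
                    t$country[i], ", ", t$year[i], ", ", t$sex[i], ", age ",
                    t$age_lower[i], ")")
  }
  cat_ <- classify_icd10(t$cause, t$age_lower, scheme)
  df <- as.data.frame(t)
  df$cause <- cat_
  agg <- stats::aggregate(
    deaths ~ country + year + sex + age_lower + age_width + cause,
    data = df, FUN = sum)
  mortality_table(agg, allow_fractional = TRUE)
}
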
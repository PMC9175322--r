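#' Read an external all-cause life table
#'
#' External life tables (e.g. IHME, UN or WHO model tables) supply all-cause
#' age-specific mortality rates for the recalibration sensitivity analysis.
#' The CSV has columns `age_lower,age_width,mx` and an optional
#' `# source: <label>` header line. The table must cover the full canonical
#' ladder; coarser ladders are rejected rather than interpolated.
#'
#' @param path CSV path.
#' @param source_label Overrides the label in the file header.
#' @return An object of class `external_lifetable`: numeric rate vector on
#'   the canonical ladder plus a `source` label.
#' @export
read_external_lifetable <- function(path, source_label = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  src <- grep("^# *source:", lines, value = TRUE)
  if (is.null(source_label)) {
    source_label <- if (length(src) > 0)
      trimws(sub("^# *source:", "", src[1])) else "external"
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, invert = TRUE,
                                            value = TRUE)))
  for (k in c("age_lower", "age_width", "mx")) {
    if (!k %in% names(df)) stop_format("external life table missing column: ", k)
  }
  external_lifetable(df$mx[order(match_ladder(df$age_lower, df$age_width))],
                     source = source_label,
                     .check_ladder = df[c("age_lower", "age_width")])
}

#' @rdname read_external_lifetable
#' @param mx All-cause rates on the canonical ladder (length 19).
#' @param source Source label.
#' @param .check_ladder Internal.
#' @export
external_lifetable <- function(mx, source = "external", .check_ladder = NULL) {
  lad <- age_ladder()
  if (!is.null(.check_ladder)) {
    idx <- match_ladder(.check_ladder$age_lower, .check_ladder$age_width)
    if (anyNA(idx) || length(idx) != nrow(lad) || anyDuplicated(idx)) {
      stop_validation("external life table must cover exactly the canonical ",
                      "ladder (19 groups); coarser ladders are not interpolated")
    }
  }
  mx <- as.numeric(mx)
  if (length(mx) != nrow(lad)) {
    stop_validation("external life table must have ", nrow(lad), " rates")
  }
  if (!all(is.finite(mx)) || any(mx <= 0)) {
    stop_validation("external rates must be strictly positive and finite")
  }
  structure(list(mx = mx, age_lower = lad$lower, age_width = lad$width,
                 source = source),
            class = "external_lifetable")
}

#' @export
print.external_lifetable <- function(x, ...) {
  cat("<external_lifetable> source: ", x$source, "; m0 = ", signif(x$mx[1], 4),
      ", m85+ = ", signif(x$mx[19], 4), "\n", sep = "")
  invisible(x)
}

#' Write an external life table as CSV
#' @param ext An `external_lifetable`.
#' @param path File path.
#' @export
write_external_lifetable <- function(ext, path) {
  stopifnot(inherits(ext, "external_lifetable"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# source: ", ext$source), con)
  utils::write.csv(data.frame(age_lower = ext$age_lower,
                              age_width = ext$age_width, mx = ext$mx),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population sizes implied by death counts and external rates
#'
#' For each age group, the population that would reproduce the external
#' life table's mortality rate given the observed all-cause death count:
#' P\[a\] = D\[a\] / m*\[a\]. Age groups with zero deaths get P = 0 and are
#' flagged (their cause mix is undefined downstream).
#'
#' @param all_cause_deaths Numeric vector of all-cause deaths on the
#'   canonical ladder (length 19).
#' @param ext An `external_lifetable`.
#' @return Numeric vector of person-years with attribute `undefined`
#'   (logical, `TRUE` where deaths were zero).
#' @examples
#' # one cell of the arithmetic: 30369 deaths at rate 0.0298
#' round(30369 / 0.0298)  # 1019094
#' @export
implied_population <- function(all_cause_deaths, ext) {
  stopifnot(inherits(ext, "external_lifetable"))
  D <- as.numeric(all_cause_deaths)
  if (length(D) != length(ext$mx)) {
    stop_validation("deaths vector must match the canonical ladder length")
  }
  if (any(D < 0) || !all(is.finite(D))) {
    stop_validation("deaths must be finite and non-negative")
  }
  bad <- D > 0 & ext$mx <= 0
  if (any(bad)) {
    stop_validation("non-positive external rate with deaths > 0 at age group ",
                    paste(age_ladder()$label[bad], collapse = ", "))
  }
  P <- ifelse(D > 0, D / ext$mx, 0)
  structure(P, undefined = D == 0)
}

#' Recalibrate cause-specific rates to an external life table
#'
#' Adjusts the age- and cause-specific mortality rates of one stratum so its
#' all-cause age-specific rates equal those of an external life table while
#' preserving the observed cause-of-death mix within each age group:
#' r\[a,c\] = D\[a,c\] / P\[a\] = m*\[a\] * D\[a,c\] / D\[a\], with P from
#' [implied_population()]. Row sums of the result equal the external rates
#' exactly wherever deaths were recorded; ages with zero recorded deaths get
#' a zero row (no cause mix to scale) and a logged note.
#'
#' @param t A [mortality_table()] pooled to a single (country, sex, period)
#'   stratum, with any cause axis.
#' @param ext An `external_lifetable`.
#' @return A [rate_matrix()] carrying `calibrated_to = ext$source`.
#' @export
recalibrate <- function(t, ext) {
  stopifnot(inherits(t, "mortality_table"), inherits(ext, "external_lifetable"))
  for (k in c("country", "sex", "year")) {
    if (length(unique(t[[k]])) != 1) {
      stop_validation("recalibrate expects a single stratum; column '", k,
                      "' is not constant")
    }
  }
  lad <- age_ladder()
  causes <- sort(unique(t$cause))
  D <- matrix(0, nrow(lad), length(causes), dimnames = list(lad$label, causes))
  D[cbind(match_ladder(t$age_lower, t$age_width), match(t$cause, causes))] <-
    t$deaths
  Dall <- rowSums(D)
  P <- implied_population(Dall, ext)
  empty <- attr(P, "undefined")
  if (any(empty)) {
    log_msg("no recorded deaths in age group(s) ",
            paste(lad$label[empty], collapse = ", "),
            "; recalibrated rates set to 0 there (cause mix undefined)")
  }
  r <- D
  r[!empty, ] <- D[!empty, , drop = FALSE] / P[!empty]
  r[empty, ] <- 0
  rate_matrix(r, country = unique(t$country), sex = unique(t$sex),
              period = unique(t$year), calibrated_to = ext$source)
}
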
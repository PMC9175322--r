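#' The canonical abridged age ladder
#'
#' All tables in the package live on the standard abridged ladder used by the
#' WHO Mortality Database: an infant group \eqn{[0,1)}, a childhood group
#' \eqn{[1,5)}, 5-year groups up to \eqn{[80,85)}, and an open-ended terminal
#' group 85+ — 19 groups in all. The open group is encoded with `width = Inf`.
#'
#' @return A data frame with one row per age group and columns `lower`
#'   (integer lower bound in years), `width` (years; `Inf` for the open
#'   group), `label` (e.g. `"1-4"`, `"85+"`) and `open` (logical).
#' @examples
#' age_ladder()
#' @export
age_ladder <- function() {
  lower <- c(0L, 1L, seq(5L, 85L, by = 5L))
  width <- c(1, 4, rep(5, 16), Inf)
  label <- ifelse(is.infinite(width), paste0(lower, "+"),
                  ifelse(width == 1, as.character(lower),
                         paste0(lower, "-", lower + width - 1)))
  data.frame(lower = lower, width = width, label = label,
             open = is.infinite(width))
}

#' Midpoints of the canonical age groups
#'
#' Closed groups get their arithmetic midpoint; the open 85+ group is
#' represented at age 90 (five years past its lower bound).
#'
#' @return Numeric vector of length 19.
#' @export
age_midpoints <- function() {
  lad <- age_ladder()
  ifelse(lad$open, lad$lower + 5, lad$lower + lad$width / 2)
}

# Check that (lower, width) pairs sit on the canonical ladder; returns the
# row index in age_ladder() or NA for off-ladder pairs.
match_ladder <- function(lower, width) {
  lad <- age_ladder()
  key <- paste(lad$lower, lad$width)
  match(paste(as.numeric(lower), as.numeric(width)), key)
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("avoidgap_format_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("avoidgap_validation_error", "error")))
}

# All logging goes to stderr so stdout stays clean for piped CSV output.
log_msg <- function(...) message("[avoidgap] ", ...)

normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- ifelse(s %in% c("1", "male", "m"), "male",
                ifelse(s %in% c("2", "female", "f"), "female", NA_character_))
  if (anyNA(out)) {
    stop_validation("unrecognized sex code(s): ",
                    paste(unique(s[is.na(out)]), collapse = ", "),
                    " (accepted: 1/2, male/female)")
  }
  out
}
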
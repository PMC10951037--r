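# Age handling: all ages live on a single days-post-conception scale so
# that prenatal ("pcw") and postnatal ("mos", "yrs") specimens can be
# ordered and correlated on one axis. Birth is fixed at 280 days (40
# gestational weeks); one month is 30.44 days and one year 365.25 days.
# The convention is configurable through the constants below.

#' Age-scale constants
#'
#' Days-post-conception conventions used to place prenatal and postnatal
#' age labels on a common axis: birth at 280 days (40 weeks), one month
#' = 30.44 days, one year = 365.25 days.
#'
#' @format A named numeric vector with elements `birth`, `week`, `month`,
#'   `year`, all in days.
#' @export
age_constants <- c(birth = 280, week = 7, month = 30.44, year = 365.25)

#' Parse developmental age labels
#'
#' Converts age labels in the BrainSpan dialect (`"12 pcw"`, `"4 mos"`,
#' `"8 yrs"`) to days post conception. Postnatal units are offset by the
#' birth constant (280 days), so `"4 mos"` is `280 + 4 * 30.44` days.
#'
#' @param label character vector of age labels. Each must match
#'   `"<n> pcw"`, `"<n> mos"` or `"<n> yrs"` (whitespace-tolerant,
#'   positive quantity).
#' @param constants named numeric vector as [age_constants].
#' @return A data frame with one row per label and columns `raw_label`,
#'   `days_post_conception` and `is_prenatal` (`TRUE` iff strictly before
#'   the birth constant).
#' @examples
#' parse_age(c("12 pcw", "4 mos", "40 yrs"))
#' @export
parse_age <- function(label, constants = age_constants) {
  label <- as.character(label)
  m <- regmatches(label,
                  regexec("^\\s*([0-9]+\\.?[0-9]*)\\s+(pcw|mos|yrs)\\s*$", label))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) {
    stop("unrecognized age label(s): ",
         paste(sQuote(label[bad]), collapse = ", "),
         " (expected '<n> pcw', '<n> mos' or '<n> yrs')", call. = FALSE)
  }
  qty <- as.numeric(vapply(m, `[`, character(1L), 2L))
  unit <- vapply(m, `[`, character(1L), 3L)
  if (any(qty <= 0)) {
    stop("non-positive age quantity in label(s): ",
         paste(sQuote(label[qty <= 0]), collapse = ", "), call. = FALSE)
  }
  days <- ifelse(unit == "pcw", qty * constants[["week"]],
          ifelse(unit == "mos", constants[["birth"]] + qty * constants[["month"]],
                 constants[["birth"]] + qty * constants[["year"]]))
  data.frame(raw_label = label,
             days_post_conception = days,
             is_prenatal = days < constants[["birth"]],
             stringsAsFactors = FALSE)
}

#' Format an age point back to its dialect label
#'
#' Inverse of [parse_age()]: an `AgePoint` data frame (or anything with a
#' `raw_label` column) is rendered back to the original labels, so that
#' parsing followed by formatting round-trips.
#'
#' @param age data frame as returned by [parse_age()].
#' @return character vector of labels.
#' @export
format_age <- function(age) {
  stopifnot(is.data.frame(age), "raw_label" %in% names(age))
  trimws(gsub("\\s+", " ", age$raw_label))
}
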
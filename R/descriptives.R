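# Descriptive layer: the counts-and-percents tables and median/IQR
# summaries a spontaneous-report case series is described with. Every
# table carries its denominator and the rule that produced it, because
# percent denominators legitimately differ by row group (all cases vs
# cases with the field known) and leaving them implicit makes published
# percentages irreproducible.

age_band_breaks <- c(0, 18, 45, 65, 75, Inf)
age_band_labels <- c("0-17", "18-44", "45-64", "65-74", "75+")

summary_table <- function(rows, denominator, denominator_rule) {
  structure(
    tibble(category = rows$category, count = as.integer(rows$count),
           percent = round_half_up(100 * rows$count / denominator, 1)),
    denominator = as.integer(denominator),
    denominator_rule = denominator_rule,
    class = c("summary_table", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("denominator: %d (%s)\n", attr(x, "denominator"),
              attr(x, "denominator_rule")))
  NextMethod()
}

#' Tabulate a categorical report characteristic among case reports
#'
#' Counts case reports by category with report-level semantics: for
#' multi-valued fields (`"ingredient"`), a report counts once per category
#' it carries, so counts may sum past the denominator. Percentages are
#' `100 * count / denominator`, rounded half-up to one decimal.
#'
#' @param store A `report_store`.
#' @param case_ids Character vector of case report ids.
#' @param field One of `"country"`, `"reporter_qualification"`, `"sex"`,
#'   `"age_band"` (bands 0-17 / 18-44 / 45-64 / 65-74 / 75+),
#'   `"drug_withdrawn"`, `"serious"` (a report is serious if any of its
#'   reactions is), or `"ingredient"` (suspected/interacting drugs).
#' @param denominator `"all_cases"` (default) or `"known"` (cases with the
#'   field non-missing; the convention for age bands and withdrawal).
#' @return A `summary_table` tibble (`category`, `count`, `percent`) with
#'   attributes `denominator` and `denominator_rule`.
#' @export
categorical_summary <- function(store, case_ids, field,
                                denominator = c("all_cases", "known")) {
  stopifnot(inherits(store, "report_store"))
  denominator <- match.arg(denominator)
  bad <- setdiff(case_ids, store$reports$report_id)
  if (length(bad) > 0) {
    validation_error(sprintf("case_ids not in store: %s",
                             paste(head(bad, 5), collapse = ", ")))
  }
  case_ids <- unique(case_ids)
  reps <- store$reports[store$reports$report_id %in% case_ids, ]

  if (field == "ingredient") {
    d <- store$drugs[store$drugs$report_id %in% case_ids &
                       store$drugs$role %in% c("suspected", "interacting"), ]
    per <- distinct(d[c("report_id", "ingredient")])
    vals <- per$ingredient
    n_known <- length(unique(per$report_id))
  } else if (field == "serious") {
    r <- store$reactions[store$reactions$report_id %in% case_ids &
                           !is.na(store$reactions$serious), ]
    per <- r |>
      group_by(.data$report_id) |>
      summarise(serious = any(.data$serious), .groups = "drop")
    vals <- ifelse(per$serious, "serious", "non_serious")
    n_known <- nrow(per)
  } else if (field == "age_band") {
    known <- reps$age_years[!is.na(reps$age_years)]
    vals <- as.character(cut(known, breaks = age_band_breaks,
                             labels = age_band_labels, right = FALSE))
    n_known <- length(known)
  } else {
    if (!field %in% names(reps)) {
      validation_error(sprintf("unknown report field: %s", field))
    }
    v <- reps[[field]]
    vals <- as.character(v[!is.na(v)])
    n_known <- length(vals)
  }
  denom <- if (denominator == "all_cases") length(case_ids) else n_known
  tab <- sort(table(vals), decreasing = TRUE)
  rows <- tibble(category = as.character(names(tab) %||% character()),
                 count = as.integer(tab))
  rows <- rows[order(-rows$count, rows$category), ]
  summary_table(rows, denom,
                if (denominator == "all_cases") "all case reports"
                else sprintf("case reports with non-missing %s", field))
}

#' Median, quartiles and range of a quantitative variable
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the R default); the convention is fixed so
#' interquartile ranges are reproducible.
#'
#' @param values Numeric vector; missing values are dropped.
#' @return A tibble with `median`, `q1`, `q3`, `min`, `max`, `n_nonmissing`.
#' @export
#' @examples
#' quantitative_summary(c(1, 2, 3))
quantitative_summary <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) validation_error("quantitative_summary: all values missing")
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  tibble(median = q[2], q1 = q[1], q3 = q[3],
         min = min(v), max = max(v), n_nonmissing = length(v))
}

#' Tabulate reaction outcomes among case reports
#'
#' The denominator is the number of case reports with a non-missing,
#' non-"unknown" outcome (reports "with available outcomes"). A report's
#' outcome is taken from its worst-ranked reaction outcome
#' (fatal > not_recovered > recovering > recovered) so multi-reaction
#' reports count once.
#'
#' @param store A `report_store`.
#' @param case_ids Character vector of case report ids.
#' @return A `summary_table` over `{recovered, recovering, not_recovered,
#'   fatal}` with the known-outcome denominator.
#' @export
outcome_summary <- function(store, case_ids) {
  stopifnot(inherits(store, "report_store"))
  # rank values double as positions in names(rank)
  rank <- c(recovered = 1, recovering = 2, not_recovered = 3, fatal = 4)
  r <- store$reactions[store$reactions$report_id %in% case_ids &
                         !is.na(store$reactions$outcome) &
                         store$reactions$outcome != "unknown", ]
  if (nrow(r) == 0) {
    out <- summary_table(tibble(category = character(), count = integer()),
                         0L, "case reports with available outcome")
    attr(out, "empty") <- TRUE
    return(out)
  }
  worst <- r |>
    group_by(.data$report_id) |>
    summarise(outcome = names(rank)[max(rank[.data$outcome])], .groups = "drop")
  tab <- table(factor(worst$outcome,
                      levels = c("recovered", "recovering", "not_recovered",
                                 "fatal")))
  summary_table(tibble(category = names(tab), count = as.integer(tab)),
                nrow(worst), "case reports with available outcome")
}

#' Rank the terms co-reported with the index event
#'
#' Report-level counts of the other reaction PTs among the cases, sorted by
#' count descending with lexicographic tie-break; percent of all cases.
#'
#' @param store A `report_store`.
#' @param case_ids Character vector of case report ids.
#' @param exclude Character vector of PTs to exclude (must contain the index
#'   event PT(s)).
#' @return A tibble with `pt`, `count`, `percent`.
#' @export
coreported_terms <- function(store, case_ids, exclude) {
  stopifnot(inherits(store, "report_store"))
  if (length(exclude) == 0) {
    validation_error("coreported_terms: exclude must contain the index PT(s)")
  }
  ex <- normalize_label(exclude)
  r <- store$reactions[store$reactions$report_id %in% case_ids &
                         !store$reactions$pt_key %in% ex, ]
  per <- distinct(r[c("report_id", "pt")])
  tab <- table(per$pt)
  out <- tibble(pt = as.character(names(tab) %||% character()),
                count = as.integer(tab))
  out <- out[order(-out$count, out$pt), ]
  out$percent <- round_half_up(100 * out$count / length(unique(case_ids)), 1)
  rownames(out) <- NULL
  out
}
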
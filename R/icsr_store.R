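# Relational ICSR store: one reports table plus child drug and reaction
# tables keyed by report_id, validated against the two dictionaries.
# Counting semantics throughout are report-level: a report contributes at
# most once to any count no matter how many of its entries match.

drug_roles <- c("suspected", "interacting", "concomitant")
outcome_levels <- c("recovered", "recovering", "not_recovered", "fatal", "unknown")
reporter_levels <- c("physician", "pharmacist", "other_health_professional",
                     "consumer", "lawyer")
seriousness_levels <- c("death", "life_threatening", "hospitalization",
                        "disabling", "congenital_anomaly",
                        "other_medically_important")

#' Assemble a validated report store from in-memory tables
#'
#' Validates the three relational tables, indexes them against the term and
#' drug dictionaries, and collects every rejected or flagged row in a
#' `rejects` list — nothing is silently dropped. Reports must have at least
#' one drug and one reaction; orphan child rows (no parent report) are
#' rejected; reaction PTs missing from the term dictionary are flagged but
#' their reports are kept.
#'
#' @param reports Data frame with columns `report_id`, `country`,
#'   `reporter_qualification`, `sex`, `age_years`, `drug_withdrawn`.
#' @param drugs Data frame with columns `report_id`, `ingredient`, `role`,
#'   `dose_amount`, `dose_unit`, `dose_interval_days`, `start_date`,
#'   `end_date`, `indication`.
#' @param reactions Data frame with columns `report_id`, `pt`, `onset_date`,
#'   `serious`, `seriousness_criteria` (`|`-separated), `outcome`.
#' @param term_dict A [term_dictionary()].
#' @param drug_dict A [drug_dictionary()].
#' @return An object of class `report_store`: a list with tibbles `reports`,
#'   `drugs`, `reactions`, the two dictionaries, and `rejects`.
#' @seealso [load_reports()], [match_reports()]
#' @export
report_store <- function(reports, drugs, reactions, term_dict, drug_dict) {
  stopifnot(inherits(term_dict, "term_dictionary"),
            inherits(drug_dict, "drug_dictionary"))
  reports <- as_tibble(reports)
  drugs <- as_tibble(drugs)
  reactions <- as_tibble(reactions)
  stopifnot_cols(reports, c("report_id"), "reports")
  stopifnot_cols(drugs, c("report_id", "ingredient", "role"), "drugs")
  stopifnot_cols(reactions, c("report_id", "pt"), "reactions")

  ensure_col <- function(df, col, default) {
    if (!col %in% names(df)) df[[col]] <- default
    df
  }
  for (col in c("country", "reporter_qualification", "sex")) {
    reports <- ensure_col(reports, col, NA_character_)
  }
  reports <- ensure_col(reports, "age_years", NA_real_)
  reports <- ensure_col(reports, "drug_withdrawn", NA)
  reports$report_id <- as.character(reports$report_id)
  reports$age_years <- as.numeric(reports$age_years)
  reports$drug_withdrawn <- as.logical(reports$drug_withdrawn)

  if (anyDuplicated(reports$report_id)) {
    validation_error(sprintf(
      "duplicate report_id(s): %s",
      paste(unique(reports$report_id[duplicated(reports$report_id)]),
            collapse = ", ")
    ))
  }
  bad_sex <- !is.na(reports$sex) & !reports$sex %in% c("female", "male")
  if (any(bad_sex)) validation_error("sex must be female/male or missing")
  bad_rep <- !is.na(reports$reporter_qualification) &
    !reports$reporter_qualification %in% reporter_levels
  if (any(bad_rep)) validation_error("unknown reporter_qualification value")
  bad_age <- !is.na(reports$age_years) &
    (reports$age_years < 0 | reports$age_years > 120)
  if (any(bad_age)) {
    validation_error("age_years outside [0, 120] for report(s): " %+%
                       paste(reports$report_id[bad_age], collapse = ", "))
  }

  drugs$report_id <- as.character(drugs$report_id)
  drugs$ingredient <- as.character(drugs$ingredient)
  bad_role <- is.na(drugs$role) | !drugs$role %in% drug_roles
  if (any(bad_role)) {
    validation_error(sprintf("unknown drug role: %s",
                             paste(unique(drugs$role[bad_role]), collapse = ", ")))
  }
  for (col in c("dose_unit", "indication")) {
    drugs <- ensure_col(drugs, col, NA_character_)
  }
  for (col in c("dose_amount", "dose_interval_days")) {
    drugs <- ensure_col(drugs, col, NA_real_)
    drugs[[col]] <- as.numeric(drugs[[col]])
  }
  bad_dose <- !is.na(drugs$dose_amount) & drugs$dose_amount <= 0
  if (any(bad_dose)) validation_error("dose_amount must be > 0 when present")
  drugs <- parse_date_col(drugs, "start_date")
  drugs <- parse_date_col(drugs, "end_date")
  bad_dates <- !is.na(drugs$start_date) & !is.na(drugs$end_date) &
    drugs$end_date < drugs$start_date
  if (any(bad_dates)) {
    validation_error("drug end_date before start_date for report(s): " %+%
                       paste(unique(drugs$report_id[bad_dates]), collapse = ", "))
  }

  reactions$report_id <- as.character(reactions$report_id)
  reactions$pt <- as.character(reactions$pt)
  reactions <- ensure_col(reactions, "serious", NA)
  reactions$serious <- as.logical(reactions$serious)
  reactions <- ensure_col(reactions, "seriousness_criteria", NA_character_)
  reactions <- ensure_col(reactions, "outcome", NA_character_)
  bad_out <- !is.na(reactions$outcome) & !reactions$outcome %in% outcome_levels
  if (any(bad_out)) {
    validation_error(sprintf("unknown outcome value: %s",
                             paste(unique(reactions$outcome[bad_out]), collapse = ", ")))
  }
  crit <- strsplit(ifelse(is.na(reactions$seriousness_criteria), "",
                          reactions$seriousness_criteria), "|", fixed = TRUE)
  bad_crit <- vapply(crit, function(x) any(!x %in% seriousness_levels), logical(1))
  if (any(bad_crit)) validation_error("unknown seriousness criterion")
  has_crit <- vapply(crit, length, integer(1)) > 0
  if (any(has_crit & (is.na(reactions$serious) | !reactions$serious))) {
    validation_error("seriousness_criteria present on a non-serious reaction")
  }
  reactions <- parse_date_col(reactions, "onset_date")

  # Orphan child rows and under-populated reports go to rejects.
  rejects <- list()
  orphan_d <- !drugs$report_id %in% reports$report_id
  orphan_r <- !reactions$report_id %in% reports$report_id
  rejects$orphan_drugs <- drugs[orphan_d, ]
  rejects$orphan_reactions <- reactions[orphan_r, ]
  drugs <- drugs[!orphan_d, ]
  reactions <- reactions[!orphan_r, ]

  incomplete <- setdiff(reports$report_id,
                        intersect(unique(drugs$report_id),
                                  unique(reactions$report_id)))
  rejects$incomplete_reports <- reports[reports$report_id %in% incomplete, ]
  reports <- reports[!reports$report_id %in% incomplete, ]
  drugs <- drugs[drugs$report_id %in% reports$report_id, ]
  reactions <- reactions[reactions$report_id %in% reports$report_id, ]

  reactions$pt_key <- normalize_label(reactions$pt)
  drugs$ingredient_key <- normalize_label(drugs$ingredient)
  rejects$unknown_pts <- sort(unique(reactions$pt[!reactions$pt_key %in%
                                                    term_dict$pt_key]))
  rejects$unknown_ingredients <-
    sort(unique(drugs$ingredient[!drugs$ingredient_key %in%
                                   drug_dict$ingredient_key]))
  n_rej <- nrow(rejects$orphan_drugs) + nrow(rejects$orphan_reactions) +
    nrow(rejects$incomplete_reports)
  if (n_rej > 0) {
    inform(sprintf(
      "report_store: rejected %d orphan drug row(s), %d orphan reaction row(s), %d incomplete report(s)",
      nrow(rejects$orphan_drugs), nrow(rejects$orphan_reactions),
      nrow(rejects$incomplete_reports)
    ))
  }

  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         term_dict = term_dict, drug_dict = drug_dict, rejects = rejects),
    class = "report_store"
  )
}

`%+%` <- function(a, b) paste0(a, b)

parse_date_col <- function(df, col) {
  if (is.null(df[[col]])) {
    df[[col]] <- as.Date(NA)
    df[[paste0(col, "_imputed")]] <- FALSE
    return(df)
  }
  if (inherits(df[[col]], "Date")) {
    df[[paste0(col, "_imputed")]] <- FALSE
    return(df)
  }
  parsed <- parse_report_date(df[[col]])
  df[[col]] <- parsed$date
  df[[paste0(col, "_imputed")]] <- parsed$imputed
  df
}

#' @export
print.report_store <- function(x, ...) {
  cat(sprintf(
    "<report_store> %d reports, %d drug rows, %d reaction rows\n",
    nrow(x$reports), nrow(x$drugs), nrow(x$reactions)
  ))
  if (length(x$rejects$unknown_pts) > 0) {
    cat(sprintf("  unknown PTs flagged: %d\n", length(x$rejects$unknown_pts)))
  }
  invisible(x)
}

#' Load a report store from three relational CSV files
#'
#' The three tables share the `report_id` key space; empty strings encode
#' missing values. See [report_store()] for validation and reject semantics.
#'
#' @param reports_path,drugs_path,reactions_path Paths to the reports,
#'   report-drugs and report-reactions CSV files.
#' @param term_dict A [term_dictionary()].
#' @param drug_dict A [drug_dictionary()].
#' @return A `report_store`.
#' @export
load_reports <- function(reports_path, drugs_path, reactions_path,
                         term_dict, drug_dict) {
  reports <- read_icsr_csv(reports_path, readr::cols(
    report_id = readr::col_character(), country = readr::col_character(),
    reporter_qualification = readr::col_character(),
    sex = readr::col_character(), age_years = readr::col_double(),
    drug_withdrawn = readr::col_logical()
  ))
  stopifnot_cols(reports, "report_id", reports_path)
  drugs <- read_icsr_csv(drugs_path, readr::cols(
    report_id = readr::col_character(), ingredient = readr::col_character(),
    role = readr::col_character(), dose_amount = readr::col_double(),
    dose_unit = readr::col_character(),
    dose_interval_days = readr::col_double(),
    start_date = readr::col_character(), end_date = readr::col_character(),
    indication = readr::col_character()
  ))
  stopifnot_cols(drugs, c("report_id", "ingredient", "role"), drugs_path)
  reactions <- read_icsr_csv(reactions_path, readr::cols(
    report_id = readr::col_character(), pt = readr::col_character(),
    onset_date = readr::col_character(), serious = readr::col_logical(),
    seriousness_criteria = readr::col_character(),
    outcome = readr::col_character()
  ))
  stopifnot_cols(reactions, c("report_id", "pt"), reactions_path)
  report_store(reports, drugs, reactions, term_dict, drug_dict)
}

#' Write a report store to the three relational CSV files
#'
#' @param store A `report_store`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "report_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reports = file.path(dir, "reports.csv"),
    drugs = file.path(dir, "report_drugs.csv"),
    reactions = file.path(dir, "report_reactions.csv"),
    meddra = file.path(dir, "meddra.csv"),
    atc = file.path(dir, "atc.csv")
  )
  rep_cols <- c("report_id", "country", "reporter_qualification", "sex",
                "age_years", "drug_withdrawn")
  drug_cols <- c("report_id", "ingredient", "role", "dose_amount",
                 "dose_unit", "dose_interval_days", "start_date", "end_date",
                 "indication")
  reac_cols <- c("report_id", "pt", "onset_date", "serious",
                 "seriousness_criteria", "outcome")
  readr::write_csv(store$reports[rep_cols], paths["reports"], na = "",
                   progress = FALSE)
  readr::write_csv(store$drugs[drug_cols], paths["drugs"], na = "",
                   progress = FALSE)
  readr::write_csv(store$reactions[reac_cols], paths["reactions"], na = "",
                   progress = FALSE)
  write_term_dictionary(store$term_dict, paths["meddra"])
  write_drug_dictionary(store$drug_dict, paths["atc"])
  invisible(paths)
}

#' Find the reports matching a term and/or drug query
#'
#' A report matches a term query iff at least one of its reactions' PTs is
#' in the expanded PT set, and a drug query iff at least one of its drug
#' entries has a matching ingredient *and* a role in the query's role
#' filter. When both queries are given the result is the intersection. A
#' report counts once no matter how many of its entries match.
#'
#' @param store A `report_store`.
#' @param term_query A [term_query()], or `NULL`.
#' @param drug_query A [drug_query()], or `NULL`.
#' @return Character vector of matching `report_id`s (sorted).
#' @export
match_reports <- function(store, term_query = NULL, drug_query = NULL) {
  stopifnot(inherits(store, "report_store"))
  if (is.null(term_query) && is.null(drug_query)) {
    validation_error("match_reports: give a term query, a drug query, or both")
  }
  ids <- NULL
  if (!is.null(term_query)) {
    pts <- normalize_label(expand_term_query(term_query, store$term_dict))
    ids <- unique(store$reactions$report_id[store$reactions$pt_key %in% pts])
  }
  if (!is.null(drug_query)) {
    ing <- normalize_label(expand_drug_query(drug_query, store$drug_dict))
    hit <- store$drugs$ingredient_key %in% ing &
      store$drugs$role %in% drug_query$roles
    dids <- unique(store$drugs$report_id[hit])
    ids <- if (is.null(ids)) dids else intersect(ids, dids)
  }
  sort(ids)
}

#' Time from drug start to reaction onset, in days
#'
#' For each report, onset date of the earliest dated matching reaction minus
#' the earliest start date among matching drug entries. Missing if either
#' date is absent. Negative values are returned but flagged implausible
#' (and are excluded from descriptive summaries by default); values
#' involving an imputed partial date are flagged imputed.
#'
#' @param store A `report_store`.
#' @param drug_query A [drug_query()] anchoring the start date.
#' @param term_query Optional [term_query()] restricting which reactions
#'   count; by default the earliest dated reaction of any PT is used.
#' @param report_ids Reports to evaluate; defaults to those matching both
#'   queries.
#' @return A tibble with columns `report_id`, `tto_days`, `implausible`,
#'   `imputed`.
#' @export
time_to_onset <- function(store, drug_query, term_query = NULL,
                          report_ids = NULL) {
  stopifnot(inherits(store, "report_store"))
  if (is.null(report_ids)) {
    report_ids <- match_reports(store, term_query, drug_query)
  }
  ing <- normalize_label(expand_drug_query(drug_query, store$drug_dict))
  d <- store$drugs[store$drugs$report_id %in% report_ids &
                     store$drugs$ingredient_key %in% ing &
                     store$drugs$role %in% drug_query$roles &
                     !is.na(store$drugs$start_date), ]
  empty_agg <- function(col) {
    out <- tibble(report_id = character(), x = as.Date(character()),
                  imp = logical())
    names(out)[2:3] <- c(col, paste0(col, "_imp"))
    out
  }
  starts <- if (nrow(d) == 0) empty_agg("start") else d |>
    group_by(.data$report_id) |>
    summarise(start = min(.data$start_date),
              start_imp = any(.data$start_date_imputed[.data$start_date == min(.data$start_date)]),
              .groups = "drop")
  r <- store$reactions[store$reactions$report_id %in% report_ids &
                         !is.na(store$reactions$onset_date), ]
  if (!is.null(term_query)) {
    pts <- normalize_label(expand_term_query(term_query, store$term_dict))
    r <- r[r$pt_key %in% pts, ]
  }
  onsets <- if (nrow(r) == 0) empty_agg("onset") else r |>
    group_by(.data$report_id) |>
    summarise(onset = min(.data$onset_date),
              onset_imp = any(.data$onset_date_imputed[.data$onset_date == min(.data$onset_date)]),
              .groups = "drop")
  out <- tibble(report_id = sort(report_ids)) |>
    left_join(starts, by = "report_id") |>
    left_join(onsets, by = "report_id")
  out$tto_days <- as.numeric(out$onset - out$start)
  out$implausible <- !is.na(out$tto_days) & out$tto_days < 0
  out$imputed <- !is.na(out$tto_days) &
    (out$start_imp %in% TRUE | out$onset_imp %in% TRUE)
  out[c("report_id", "tto_days", "implausible", "imputed")]
}

#' Convert a drug entry's dose to milligrams per month
#'
#' `dose_amount` (converted to mg) times 30 divided by the dosing interval
#' in days, the convention for monthly prophylactic injectables. Units not
#' convertible to mg give a missing result with a note.
#'
#' @param dose_amount Numeric vector of dose amounts.
#' @param dose_unit Character vector of units (`mg`, `g`, `ug`/`mcg`).
#' @param dose_interval_days Numeric vector of dosing intervals in days.
#' @return Numeric vector of mg-per-month doses.
#' @export
#' @examples
#' monthly_dose(70, "mg", 30)   # 70
#' monthly_dose(225, "mg", 30)  # 225
monthly_dose <- function(dose_amount, dose_unit, dose_interval_days) {
  unit <- tolower(trimws(as.character(dose_unit)))
  factor <- dplyr::case_when(
    unit == "mg" ~ 1,
    unit == "g" ~ 1000,
    unit %in% c("ug", "mcg", "µg") ~ 1e-3,
    TRUE ~ NA_real_
  )
  unknown <- !is.na(unit) & unit != "" & is.na(factor)
  if (any(unknown)) {
    inform(sprintf("monthly_dose: unconvertible unit(s) set to missing: %s",
                   paste(unique(unit[unknown]), collapse = ", ")))
  }
  out <- dose_amount * factor * 30 / dose_interval_days
  out[!is.finite(out)] <- NA_real_
  out
}
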
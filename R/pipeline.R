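# End-to-end study orchestration: load or simulate a store, identify the
# case series, emit the descriptive layer, the per-class / per-drug / HLT
# disproportionality screen and the comparative ICs, plus a machine-
# readable study report and run manifest. Every percentage and IC in the
# report recomputes from the emitted counts; the run fails (with a FAILED
# marker) if that self-check does not hold.

#' Configure a study run
#'
#' Exactly one data source must be given: the five table paths, a
#' [synthetic_config()] to simulate from, or an in-memory `report_store`.
#'
#' @param data Named list of paths (`reports`, `drugs`, `reactions`,
#'   `meddra`, `atc`), or `NULL`.
#' @param simulate A [synthetic_config()], or `NULL`.
#' @param store A `report_store`, or `NULL`.
#' @param event_pt Index event Preferred Term.
#' @param event_hlt Optional High Level Term for the sensitivity query.
#' @param drug_atc ATC prefix of the drug class of interest.
#' @param comparator_atc Named character vector of comparator ATC prefixes
#'   (may be empty).
#' @param ci_method,overlap Passed to [information_component()] and
#'   [comparative_ic()].
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (and used for
#'   simulation when `simulate` lacks one).
#' @return An object of class `study_config`.
#' @export
study_config <- function(data = NULL, simulate = NULL, store = NULL,
                         event_pt = "Raynaud's phenomenon",
                         event_hlt = NULL,
                         drug_atc = "N02CD",
                         comparator_atc = c(triptans = "N02CC"),
                         ci_method = c("gamma_quantile", "noren_approx"),
                         overlap = c("keep", "exclude"),
                         out_dir = "study_output", seed = 1L) {
  n_src <- sum(!is.null(data), !is.null(simulate), !is.null(store))
  if (n_src != 1) {
    validation_error("study_config: give exactly one of data, simulate, store")
  }
  if (!is.null(data)) {
    miss <- setdiff(c("reports", "drugs", "reactions", "meddra", "atc"),
                    names(data))
    if (length(miss) > 0) {
      validation_error(sprintf("study_config: data lacks path(s): %s",
                               paste(miss, collapse = ", ")))
    }
  }
  if (length(comparator_atc) > 0 &&
      any(startsWith(comparator_atc, drug_atc) |
            startsWith(drug_atc, comparator_atc))) {
    validation_error("study_config: comparator class overlaps the class of interest")
  }
  structure(
    list(data = data, simulate = simulate, store = store,
         event_pt = event_pt, event_hlt = event_hlt, drug_atc = drug_atc,
         comparator_atc = comparator_atc, ci_method = match.arg(ci_method),
         overlap = match.arg(overlap), out_dir = out_dir,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run the full disproportionality study
#'
#' Emits, under `config$out_dir`: the case listing; the descriptive tables
#' (drug shares, demographics, seriousness, outcomes, withdrawal, time to
#' onset, monthly dose, co-reported terms); the per-class and per-drug IC
#' screen with the optional HLT sensitivity row; one comparative IC per
#' comparator class; `study_report.json` with full-precision values and
#' explicit denominators; and `manifest.json` (package version, seed,
#' config hash). A self-consistency pass recomputes every percentage and
#' IC from the emitted counts before the report is declared valid.
#'
#' @param config A [study_config()].
#' @return The study report, invisibly (a list mirroring
#'   `study_report.json`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)
  res <- tryCatch(
    run_study_impl(config),
    error = function(e) {
      writeLines(conditionMessage(e), failed_marker)
      abort(sprintf("study run failed (marker at %s): %s", failed_marker,
                    conditionMessage(e)), class = "icsignal_error")
    }
  )
  invisible(res)
}

run_study_impl <- function(config) {
  inform(sprintf("run_study: loading data (%s)",
                 if (!is.null(config$data)) "files"
                 else if (!is.null(config$simulate)) "simulation"
                 else "in-memory store"))
  store <- if (!is.null(config$store)) {
    config$store
  } else if (!is.null(config$simulate)) {
    generate_store(config$simulate)$store
  } else {
    load_reports(config$data$reports, config$data$drugs,
                 config$data$reactions,
                 load_term_dictionary(config$data$meddra),
                 load_drug_dictionary(config$data$atc))
  }
  inform(sprintf(
    "run_study: %d reports; %d unknown PT(s), %d unknown ingredient(s) flagged",
    nrow(store$reports), length(store$rejects$unknown_pts),
    length(store$rejects$unknown_ingredients)
  ))

  event_q <- term_query("PT", config$event_pt)
  class_q <- drug_query("atc_prefix", config$drug_atc)
  case_ids <- match_reports(store, event_q, class_q)
  if (length(case_ids) == 0) {
    validation_error("run_study: no case reports match the event/drug query")
  }

  out <- config$out_dir
  wtsv <- function(df, name) {
    readr::write_tsv(as_tibble(df), file.path(out, name), na = "",
                     progress = FALSE)
  }
  case_listing <- store$reports[store$reports$report_id %in% case_ids, ]
  wtsv(case_listing, "case_listing.tsv")

  # Descriptive layer: every table keeps its denominator and rule.
  desc_fields <- c("ingredient", "sex", "age_band", "country",
                   "reporter_qualification", "serious", "drug_withdrawn")
  desc_denoms <- c(ingredient = "all_cases", sex = "known",
                   age_band = "known", country = "all_cases",
                   reporter_qualification = "all_cases", serious = "all_cases",
                   drug_withdrawn = "known")
  descriptives <- list()
  for (f in desc_fields) {
    st <- categorical_summary(store, case_ids, f, desc_denoms[[f]])
    descriptives[[f]] <- list(
      denominator = attr(st, "denominator"),
      denominator_rule = attr(st, "denominator_rule"),
      rows = as_tibble(st)
    )
    wtsv(st, paste0("summary_", f, ".tsv"))
  }
  oc <- outcome_summary(store, case_ids)
  descriptives$outcome <- list(denominator = attr(oc, "denominator"),
                               denominator_rule = attr(oc, "denominator_rule"),
                               rows = as_tibble(oc))
  wtsv(oc, "summary_outcome.tsv")

  tto <- time_to_onset(store, class_q, event_q, case_ids)
  tto_vals <- tto$tto_days[!is.na(tto$tto_days) & !tto$implausible]
  tto_sum <- if (length(tto_vals) > 0) quantitative_summary(tto_vals) else NULL
  if (!is.null(tto_sum)) wtsv(tto_sum, "summary_tto.tsv")
  age_sum <- if (any(!is.na(case_listing$age_years))) {
    quantitative_summary(case_listing$age_years)
  } else NULL

  cgrp_ing <- expand_drug_query(class_q, store$drug_dict)
  dose_rows <- store$drugs[store$drugs$report_id %in% case_ids &
                             store$drugs$ingredient_key %in%
                               normalize_label(cgrp_ing), ]
  dose_rows$mg_month <- monthly_dose(dose_rows$dose_amount,
                                     dose_rows$dose_unit,
                                     dose_rows$dose_interval_days)
  dosed <- dose_rows[!is.na(dose_rows$mg_month), ]
  dose_sum <- if (nrow(dosed) == 0) {
    tibble(ingredient = character(), median = numeric(), min = numeric(),
           max = numeric(), n = integer())
  } else {
    dosed |>
      group_by(.data$ingredient) |>
      summarise(median = median(.data$mg_month), min = min(.data$mg_month),
                max = max(.data$mg_month), n = n(), .groups = "drop")
  }
  wtsv(dose_sum, "summary_dose.tsv")

  cotab <- coreported_terms(store, case_ids, exclude = config$event_pt)
  wtsv(cotab, "coreported_terms.tsv")

  # Disproportionality screen: the class, each ingredient with >= 1 case
  # report, and the optional HLT sensitivity query.
  per_drug <- lapply(cgrp_ing, function(i) drug_query("ingredient_set", i))
  names(per_drug) <- cgrp_ing
  drug_qs <- c(setNames(list(class_q), config$drug_atc), per_drug)
  event_qs <- setNames(list(event_q), config$event_pt)
  if (!is.null(config$event_hlt)) {
    event_qs[[config$event_hlt]] <- term_query("HLT", config$event_hlt)
  }
  screen <- screen_all_pairs(store, drug_qs, event_qs, config$ci_method)
  wtsv(format_ic_table(screen), "ic_screen.tsv")

  comparative <- list()
  for (nm in names(config$comparator_atc)) {
    cres <- comparative_ic(store, event_q, class_q,
                           drug_query("atc_prefix", config$comparator_atc[[nm]]),
                           config$ci_method, config$overlap)
    comparative[[nm]] <- as_tibble(cres)
  }
  if (length(comparative) > 0) {
    comp_tbl <- bind_rows(comparative, .id = "comparator")
    wtsv(format_ic_table(comp_tbl), "comparative_ic.tsv")
  } else {
    comp_tbl <- NULL
  }

  report <- list(
    n_reports = nrow(store$reports),
    n_cases = length(case_ids),
    event_pt = config$event_pt, drug_atc = config$drug_atc,
    ci_method = config$ci_method, overlap = config$overlap,
    descriptives = descriptives,
    tto = tto_sum, age = age_sum, dose = dose_sum,
    coreported = cotab,
    screen = screen,
    comparative = comp_tbl,
    rejects = list(
      unknown_pts = store$rejects$unknown_pts,
      unknown_ingredients = store$rejects$unknown_ingredients,
      incomplete_reports = nrow(store$rejects$incomplete_reports)
    )
  )
  check_report_consistency(report)
  jsonlite::write_json(report, file.path(config$out_dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")

  manifest <- list(
    package = "icsignal",
    version = as.character(utils::packageVersion("icsignal")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "store")]),
    ci_method = config$ci_method, overlap = config$overlap
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  inform(sprintf("run_study: wrote study report to %s", config$out_dir))
  report
}

# Every emitted percentage must recompute from its count and denominator,
# and every IC from its four cells, before a report is declared valid.
check_report_consistency <- function(report) {
  for (d in report$descriptives) {
    if (d$denominator > 0 && nrow(d$rows) > 0) {
      expect <- round_half_up(100 * d$rows$count / d$denominator, 1)
      if (!isTRUE(all.equal(expect, d$rows$percent))) {
        validation_error("self-consistency: percent does not recompute from counts")
      }
    }
  }
  recheck <- function(df) {
    for (i in seq_len(nrow(df))) {
      r <- information_component(
        contingency_table(df$O[i], df$n_drug[i], df$n_event[i], df$N[i]),
        df$ci_method[i]
      )
      if (abs(r$ic - df$ic[i]) > 1e-8 || abs(r$ic025 - df$ic025[i]) > 1e-8) {
        validation_error("self-consistency: IC does not recompute from cells")
      }
    }
  }
  recheck(report$screen)
  if (!is.null(report$comparative)) recheck(report$comparative)
  invisible(TRUE)
}
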
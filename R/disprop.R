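# Case/non-case disproportionality: 2x2 report-count tables and the
# Bayesian Information Component (IC).
#
# The IC is the log2 of a shrunk observed-to-expected report-count ratio,
#   E   = n_drug * n_event / N
#   IC  = log2((O + 0.5) / (E + 0.5))
# with the observed count modelled as Poisson and the shrunk rate given a
# gamma posterior, Gamma(shape = O + 0.5, rate = E + 0.5). The 95% credible
# interval is read off the gamma quantiles (default), or from the published
# asymptotic approximation; IC025 > 0 is the conventional signal threshold.

#' Construct a 2x2 case/non-case contingency table
#'
#' All counts are report-level: `O` reports with both the drug of interest
#' and the event, `n_drug` with the drug, `n_event` with the event, `N` in
#' scope.
#'
#' @param O Observed drug-and-event report count.
#' @param n_drug Reports with the drug of interest.
#' @param n_event Reports with the event.
#' @param N Total reports in scope.
#' @return An object of class `contingency_table`.
#' @export
#' @examples
#' contingency_table(O = 99, n_drug = 55605, n_event = 142, N = 103065)
contingency_table <- function(O, n_drug, n_event, N) {
  x <- c(O = O, n_drug = n_drug, n_event = n_event, N = N)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    validation_error("contingency table cells must be non-negative integers")
  }
  if (O > min(n_drug, n_event) || n_drug > N || n_event > N) {
    validation_error(sprintf(
      "inconsistent contingency table: O=%d, n_drug=%d, n_event=%d, N=%d",
      O, n_drug, n_event, N
    ))
  }
  structure(list(O = as.integer(O), n_drug = as.integer(n_drug),
                 n_event = as.integer(n_event), N = as.integer(N)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> O=%d n_drug=%d n_event=%d N=%d\n",
              x$O, x$n_drug, x$n_event, x$N))
  invisible(x)
}

#' Build the 2x2 table for an event and drug query over a report store
#'
#' Counts are computed with report-level semantics over the scope (all
#' reports by default, or an explicit set of report ids, e.g. the
#' comparator-restricted scope).
#'
#' @param store A `report_store`.
#' @param event_query A [term_query()].
#' @param drug_query A [drug_query()].
#' @param scope Optional character vector of report ids delimiting the
#'   analysis population; default all reports in the store.
#' @return A [contingency_table()].
#' @export
build_table <- function(store, event_query, drug_query, scope = NULL) {
  stopifnot(inherits(store, "report_store"))
  if (is.null(scope)) {
    scope <- store$reports$report_id
  } else {
    scope <- intersect(store$reports$report_id, scope)
  }
  if (length(scope) == 0) validation_error("build_table: empty scope")
  ev <- intersect(match_reports(store, term_query = event_query), scope)
  dr <- intersect(match_reports(store, drug_query = drug_query), scope)
  contingency_table(O = length(intersect(ev, dr)), n_drug = length(dr),
                    n_event = length(ev), N = length(scope))
}

ic_point <- function(O, E) log2((O + 0.5) / (E + 0.5))

ic_interval <- function(O, E, ci_method) {
  if (ci_method == "gamma_quantile") {
    # Quantiles of the Gamma(O + 0.5, E + 0.5) posterior on 2^IC.
    c(log2(qgamma(0.025, shape = O + 0.5, rate = E + 0.5)),
      log2(qgamma(0.975, shape = O + 0.5, rate = E + 0.5)))
  } else {
    ic <- ic_point(O, E)
    s <- O + 0.5
    c(ic - 3.3 * s^(-0.5) - 2.0 * s^(-1.5),
      ic + 2.4 * s^(-0.5) - 0.5 * s^(-1.5))
  }
}

#' Information Component with 95% credible interval and signal flag
#'
#' Computes the shrunk IC point estimate `log2((O + 0.5) / (E + 0.5))` with
#' expected count `E = n_drug * n_event / N`, a 95% credible interval, and
#' the `IC025 > 0` signal flag.
#'
#' @param table A [contingency_table()].
#' @param ci_method `"gamma_quantile"` (quantiles of the
#'   Gamma(O + 0.5, E + 0.5) posterior; default) or `"noren_approx"` (the
#'   published closed-form asymptotic approximation).
#' @return An object of class `ic_result`: list with `table`, `E`, `ic`,
#'   `ic025`, `ic975`, `ci_method`, `is_signal`.
#' @export
#' @examples
#' tab <- contingency_table(O = 99, n_drug = 55605, n_event = 142, N = 103065)
#' information_component(tab)  # ic ~ 0.37, prints as 0.4
information_component <- function(table,
                                  ci_method = c("gamma_quantile", "noren_approx")) {
  stopifnot(inherits(table, "contingency_table"))
  ci_method <- match.arg(ci_method)
  if (table$N == 0) validation_error("information_component: N = 0")
  E <- table$n_drug * as.numeric(table$n_event) / table$N
  ic <- ic_point(table$O, E)
  ci <- ic_interval(table$O, E, ci_method)
  structure(
    list(table = table, E = E, ic = ic, ic025 = ci[1], ic975 = ci[2],
         ci_method = ci_method, is_signal = ci[1] > 0),
    class = "ic_result"
  )
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf(
    "IC %.1f (95%%CI: %.1f to %.1f) [%s]%s  O=%d E=%.2f\n",
    round_half_up(x$ic, 1), round_half_up(x$ic025, 1),
    round_half_up(x$ic975, 1), x$ci_method,
    if (x$is_signal) "  SIGNAL" else "", x$table$O, x$E
  ))
  invisible(x)
}

#' @method as_tibble ic_result
#' @export
as_tibble.ic_result <- function(x, ...) {
  tibble(O = x$table$O, n_drug = x$table$n_drug, n_event = x$table$n_event,
         N = x$table$N, E = x$E, ic = x$ic, ic025 = x$ic025, ic975 = x$ic975,
         ci_method = x$ci_method, is_signal = x$is_signal)
}

#' Comparator-restricted (comparative) disproportionality
#'
#' Restricts the analysis population to reports involving either the drug
#' class of interest or an active-comparator class, then computes the IC of
#' the event with the class of interest within that scope. This mitigates
#' indication-related confounding (e.g. comparing CGRP antagonists with
#' triptans, both used by migraine patients). Reports involving both
#' classes are assigned to the interest row under the default
#' `overlap = "keep"` policy, so the four cells are disjoint and sum to N;
#' `overlap = "exclude"` drops them from scope instead.
#'
#' @param store A `report_store`.
#' @param event_query A [term_query()].
#' @param drug_of_interest,comparator [drug_query()]s whose ingredient
#'   expansions must be disjoint.
#' @param ci_method Passed to [information_component()].
#' @param overlap `"keep"` (default) or `"exclude"`.
#' @return An `ic_result` whose table is the comparator-restricted 2x2.
#' @export
comparative_ic <- function(store, event_query, drug_of_interest, comparator,
                           ci_method = c("gamma_quantile", "noren_approx"),
                           overlap = c("keep", "exclude")) {
  stopifnot(inherits(store, "report_store"))
  ci_method <- match.arg(ci_method)
  overlap <- match.arg(overlap)
  ing_i <- normalize_label(expand_drug_query(drug_of_interest, store$drug_dict))
  ing_c <- normalize_label(expand_drug_query(comparator, store$drug_dict))
  shared <- intersect(ing_i, ing_c)
  if (length(shared) > 0) {
    validation_error(sprintf(
      "drug_of_interest and comparator expansions overlap: %s",
      paste(shared, collapse = ", ")
    ))
  }
  interest_ids <- match_reports(store, drug_query = drug_of_interest)
  comp_ids <- match_reports(store, drug_query = comparator)
  both <- intersect(interest_ids, comp_ids)
  scope <- union(interest_ids, comp_ids)
  if (overlap == "exclude" && length(both) > 0) {
    scope <- setdiff(scope, both)
    interest_ids <- setdiff(interest_ids, both)
  }
  ev <- intersect(match_reports(store, term_query = event_query), scope)
  tab <- contingency_table(
    O = length(intersect(ev, interest_ids)),
    n_drug = length(intersect(interest_ids, scope)),
    n_event = length(ev),
    N = length(scope)
  )
  information_component(tab, ci_method)
}

#' Screen every drug-class x event pair
#'
#' Computes one IC per (drug query, event query) pair over the whole store
#' and returns them ranked by `ic025` descending (the signal-detection
#' ordering), ties broken by `O` descending then by label. Pairs with
#' `O = 0` are retained.
#'
#' @param store A `report_store`.
#' @param drug_queries List of [drug_query()]s (optionally named; names
#'   become labels).
#' @param event_queries List of [term_query()]s.
#' @param ci_method Passed to [information_component()].
#' @return A tibble with one row per pair: `drug`, `event`, the four cells,
#'   `E`, `ic`, `ic025`, `ic975`, `ci_method`, `is_signal`.
#' @export
screen_all_pairs <- function(store, drug_queries, event_queries,
                             ci_method = c("gamma_quantile", "noren_approx")) {
  ci_method <- match.arg(ci_method)
  if (length(drug_queries) == 0 || length(event_queries) == 0) {
    validation_error("screen_all_pairs: empty query list")
  }
  dlab <- names(drug_queries) %||% rep(NA_character_, length(drug_queries))
  elab <- names(event_queries) %||% rep(NA_character_, length(event_queries))
  rows <- list()
  for (i in seq_along(drug_queries)) {
    for (j in seq_along(event_queries)) {
      res <- information_component(
        build_table(store, event_queries[[j]], drug_queries[[i]]), ci_method
      )
      row <- as_tibble(res)
      row$drug <- if (!is.na(dlab[i]) && nzchar(dlab[i])) dlab[i] else
        query_label(drug_queries[[i]])
      row$event <- if (!is.na(elab[j]) && nzchar(elab[j])) elab[j] else
        query_label(event_queries[[j]])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- bind_rows(rows)
  out <- out[order(-out$ic025, -out$O, out$drug, out$event), ]
  out <- out[c("drug", "event", "O", "n_drug", "n_event", "N", "E",
               "ic", "ic025", "ic975", "ci_method", "is_signal")]
  rownames(out) <- NULL
  out
}

#' Format screen results as a display table (one decimal)
#'
#' Machine consumers should use the full-precision tibble from
#' [screen_all_pairs()] or [as_tibble()] on an `ic_result`; this helper
#' renders the half-up one-decimal display convention.
#'
#' @param screen Tibble from [screen_all_pairs()].
#' @return A tibble with `ic`, `ic025`, `ic975` rounded half-up to 1 decimal.
#' @export
format_ic_table <- function(screen) {
  screen |>
    mutate(ic = round_half_up(.data$ic, 1),
           ic025 = round_half_up(.data$ic025, 1),
           ic975 = round_half_up(.data$ic975, 1))
}
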
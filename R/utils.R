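# Shared helpers: label canonicalisation, rounding and date conventions.

#' Canonicalise a terminology label for matching
#'
#' Matching of PT/HLT/SOC labels and ingredient names is case-insensitive
#' after whitespace normalisation, and typographic apostrophes are folded to
#' ASCII so that "Raynaud’s phenomenon" and "Raynaud's phenomenon" match.
#' The original spelling is preserved in dictionaries and stores; only the
#' comparison key is canonicalised.
#'
#' @param x Character vector of labels.
#' @return Character vector of canonical keys.
#' @keywords internal
normalize_label <- function(x) {
  x <- gsub("[‘’ʼ]", "'", x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Round half away from zero
#'
#' Percentages and ICs are displayed rounded half-up (5 rounds away from
#' zero), the convention of regulatory summary tables, rather than R's
#' default round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(15.15, 1)  # 15.2
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Condition constructors: all package errors carry a subclass so callers and
# tests can distinguish parse, validation and lookup failures.
icsignal_abort <- function(message, class) {
  abort(message, class = c(class, "icsignal_error"))
}
parse_error <- function(message) icsignal_abort(message, "icsignal_parse_error")
validation_error <- function(message) icsignal_abort(message, "icsignal_validation_error")
lookup_error <- function(message) icsignal_abort(message, "icsignal_lookup_error")

#' Parse ISO-8601 dates, resolving partial year-month dates
#'
#' Spontaneous reports commonly carry partial dates. Full `YYYY-MM-DD`
#' strings are parsed exactly; partial `YYYY-MM` strings are resolved to the
#' 15th of the month and flagged as imputed; anything else (including empty
#' strings) is missing.
#'
#' @param x Character vector of date strings.
#' @return A [tibble::tibble] with columns `date` (class `Date`) and
#'   `imputed` (logical).
#' @export
parse_report_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  full <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  part <- !is.na(x) & grepl("^\\d{4}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  # as.Date.character cannot infer a format from an empty vector
  if (any(full)) out[full] <- as.Date(x[full], format = "%Y-%m-%d")
  if (any(part)) out[part] <- as.Date(paste0(x[part], "-15"), format = "%Y-%m-%d")
  bad <- !is.na(x) & !full & !part
  if (any(bad)) {
    parse_error(sprintf(
      "unparseable date value(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  tibble(date = out, imputed = part)
}

# readr wrapper: consistent NA/encoding conventions for all package tables.
read_icsr_csv <- function(path, col_types) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = col_types, na = c(""), progress = FALSE)
}

stopifnot_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    parse_error(sprintf(
      "%s: missing required column(s): %s", path, paste(miss, collapse = ", ")
    ))
  }
}
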
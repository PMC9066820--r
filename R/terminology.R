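# MedDRA-style (PT -> HLT -> SOC) and ATC-style terminologies with query
# expansion. Only the three levels the analysis uses are modelled; there is
# no LLT/HLGT and no multi-axiality: each PT sits under exactly one HLT.

atc_code_rx <- "^[A-Z]\\d{2}[A-Z]{2}\\d{2}$"
# Any truncation of the full 7-character pattern is a valid prefix:
# A, A01, A01B, A01BC, A01BC02.
atc_prefix_rx <- "^[A-Z](\\d{2}([A-Z]([A-Z](\\d{2})?)?)?)?$"

#' Construct a PT/HLT/SOC term dictionary
#'
#' A term dictionary maps each Preferred Term (PT) to exactly one High Level
#' Term (HLT) and one System Organ Class (SOC). Labels are matched
#' case-insensitively after whitespace and apostrophe normalisation; the
#' original spellings are retained for display.
#'
#' @param table A data frame with character columns `pt`, `hlt`, `soc`.
#' @return An object of class `term_dictionary` (a tibble with canonical
#'   key columns).
#' @seealso [load_term_dictionary()], [expand_term_query()]
#' @export
term_dictionary <- function(table) {
  stopifnot_cols(table, c("pt", "hlt", "soc"), "term table")
  tab <- as_tibble(table)[c("pt", "hlt", "soc")]
  tab$pt <- as.character(tab$pt)
  tab$hlt <- as.character(tab$hlt)
  tab$soc <- as.character(tab$soc)
  if (any(is.na(tab$pt) | normalize_label(tab$pt) == "")) {
    validation_error("term dictionary: empty PT label")
  }
  tab$pt_key <- normalize_label(tab$pt)
  tab$hlt_key <- normalize_label(tab$hlt)
  tab$soc_key <- normalize_label(tab$soc)
  dup <- unique(tab$pt[duplicated(tab$pt_key)])
  if (length(dup) > 0) {
    validation_error(sprintf(
      "term dictionary: duplicate PT(s): %s", paste(dup, collapse = ", ")
    ))
  }
  structure(tab, class = c("term_dictionary", class(tab)))
}

#' Load a term dictionary from a CSV file
#'
#' Expects a UTF-8 CSV with header `pt,hlt,soc` (quoted fields allowed).
#'
#' @param path Path to the CSV file.
#' @return A [term_dictionary()].
#' @export
load_term_dictionary <- function(path) {
  df <- read_icsr_csv(path, readr::cols(.default = readr::col_character()))
  stopifnot_cols(df, c("pt", "hlt", "soc"), path)
  bad <- which(is.na(df$pt) | is.na(df$hlt) | is.na(df$soc))
  if (length(bad) > 0) {
    # +1 for the header line, so the number matches the file
    parse_error(sprintf(
      "%s: malformed row (empty pt/hlt/soc) at line %d", path, bad[1] + 1L
    ))
  }
  term_dictionary(df)
}

#' Write a term dictionary back to CSV
#'
#' @param dict A [term_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_dictionary <- function(dict, path) {
  readr::write_csv(as_tibble(dict)[c("pt", "hlt", "soc")], path, progress = FALSE)
  invisible(path)
}

#' Construct an ingredient/ATC drug dictionary
#'
#' One row per (ingredient, ATC code) pair; an ingredient may carry several
#' codes. Codes must be full 7-character ATC codes (e.g. `N02CD01`).
#'
#' @param table A data frame with character columns `ingredient`, `atc_code`.
#' @return An object of class `drug_dictionary`.
#' @seealso [load_drug_dictionary()], [expand_drug_query()]
#' @export
drug_dictionary <- function(table) {
  stopifnot_cols(table, c("ingredient", "atc_code"), "drug table")
  tab <- as_tibble(table)[c("ingredient", "atc_code")]
  tab$ingredient <- as.character(tab$ingredient)
  tab$atc_code <- toupper(as.character(tab$atc_code))
  if (any(is.na(tab$ingredient) | normalize_label(tab$ingredient) == "")) {
    validation_error("drug dictionary: empty ingredient label")
  }
  bad <- !is.na(tab$atc_code) & !grepl(atc_code_rx, tab$atc_code)
  if (any(bad)) {
    validation_error(sprintf(
      "drug dictionary: invalid ATC code(s): %s",
      paste(unique(tab$atc_code[bad]), collapse = ", ")
    ))
  }
  tab$ingredient_key <- normalize_label(tab$ingredient)
  tab <- dplyr::distinct(tab)
  structure(tab, class = c("drug_dictionary", class(tab)))
}

#' Load a drug dictionary from a CSV file
#'
#' Expects a UTF-8 CSV with header `ingredient,atc_code`, one row per
#' (ingredient, code) pair.
#'
#' @param path Path to the CSV file.
#' @return A [drug_dictionary()].
#' @export
load_drug_dictionary <- function(path) {
  df <- read_icsr_csv(path, readr::cols(.default = readr::col_character()))
  stopifnot_cols(df, c("ingredient", "atc_code"), path)
  drug_dictionary(df)
}

#' Write a drug dictionary back to CSV
#'
#' @param dict A [drug_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_dictionary <- function(dict, path) {
  readr::write_csv(as_tibble(dict)[c("ingredient", "atc_code")], path,
                   progress = FALSE)
  invisible(path)
}

#' Define an adverse-event term query
#'
#' A term query names either one Preferred Term or one High Level Term; HLT
#' queries expand to every PT under that HLT (the paper-style sensitivity
#' query for coding heterogeneity).
#'
#' @param level `"PT"` or `"HLT"`.
#' @param label The term label.
#' @return An object of class `term_query`.
#' @export
#' @examples
#' term_query("PT", "Raynaud's phenomenon")
term_query <- function(level = c("PT", "HLT"), label) {
  level <- match.arg(level)
  if (length(label) != 1 || is.na(label) || normalize_label(label) == "") {
    validation_error("term query label must be a single non-empty string")
  }
  structure(list(level = level, label = label), class = "term_query")
}

#' Define a drug query
#'
#' A drug query selects ingredients either by ATC code prefix (e.g. `"N02CD"`
#' for the CGRP-antagonist class) or by an explicit ingredient set, and
#' restricts which drug roles count as exposure. By default purely
#' concomitant drugs do not count: only suspected and interacting entries
#' contribute to observed counts, the usual convention for spontaneous
#' reports.
#'
#' @param mode `"atc_prefix"` or `"ingredient_set"`.
#' @param value A single ATC prefix, or a character vector of ingredients.
#' @param roles Drug roles that count as exposure; subset of
#'   `c("suspected", "interacting", "concomitant")`.
#' @return An object of class `drug_query`.
#' @export
#' @examples
#' drug_query("atc_prefix", "N02CD")
#' drug_query("ingredient_set", c("propranolol", "atenolol"))
drug_query <- function(mode = c("atc_prefix", "ingredient_set"), value,
                       roles = c("suspected", "interacting")) {
  mode <- match.arg(mode)
  if (length(roles) == 0) validation_error("drug query: empty role filter")
  roles <- match.arg(roles, c("suspected", "interacting", "concomitant"),
                     several.ok = TRUE)
  if (mode == "atc_prefix") {
    if (length(value) != 1 || is.na(value)) {
      validation_error("atc_prefix query takes exactly one prefix")
    }
    value <- toupper(value)
    if (!grepl(atc_prefix_rx, value)) {
      validation_error(sprintf("invalid ATC prefix: %s", value))
    }
  } else {
    value <- as.character(value)
    if (length(value) == 0 || any(is.na(value))) {
      validation_error("ingredient_set query needs >= 1 ingredient")
    }
  }
  structure(list(mode = mode, value = value, roles = roles),
            class = "drug_query")
}

#' Expand a term query to its set of Preferred Terms
#'
#' A PT-level query returns the singleton set containing that PT; an
#' HLT-level query returns every PT mapped to that HLT.
#'
#' @param query A [term_query()].
#' @param dict A [term_dictionary()].
#' @return Character vector of PT labels (dictionary spelling).
#' @export
expand_term_query <- function(query, dict) {
  stopifnot(inherits(query, "term_query"), inherits(dict, "term_dictionary"))
  key <- normalize_label(query$label)
  if (query$level == "PT") {
    hit <- dict$pt[dict$pt_key == key]
    if (length(hit) == 0) {
      lookup_error(sprintf("PT not in dictionary: %s", query$label))
    }
    return(hit)
  }
  hit <- dict$pt[dict$hlt_key == key]
  if (length(hit) == 0) {
    lookup_error(sprintf("HLT not in dictionary: %s", query$label))
  }
  sort(hit)
}

#' Expand a drug query to its set of ingredients
#'
#' ATC-prefix mode returns every ingredient having at least one code with
#' that prefix; an empty expansion is returned with a warning (callers
#' decide how to treat it). Ingredient-set mode validates every named
#' ingredient against the dictionary.
#'
#' @param query A [drug_query()].
#' @param dict A [drug_dictionary()].
#' @return Character vector of ingredient labels (dictionary spelling).
#' @export
expand_drug_query <- function(query, dict) {
  stopifnot(inherits(query, "drug_query"), inherits(dict, "drug_dictionary"))
  if (query$mode == "atc_prefix") {
    hit <- !is.na(dict$atc_code) & startsWith(dict$atc_code, query$value)
    out <- sort(unique(dict$ingredient[hit]))
    if (length(out) == 0) {
      warn(sprintf("ATC prefix %s matches no ingredient", query$value))
    }
    return(out)
  }
  keys <- normalize_label(query$value)
  unknown <- setdiff(keys, dict$ingredient_key)
  if (length(unknown) > 0) {
    validation_error(sprintf(
      "ingredient(s) not in dictionary: %s", paste(unknown, collapse = ", ")
    ))
  }
  sort(unique(dict$ingredient[dict$ingredient_key %in% keys]))
}

#' Short human-readable label for a query
#'
#' @param query A [term_query()] or [drug_query()].
#' @return A single string, used to label screen output rows.
#' @export
query_label <- function(query) {
  if (inherits(query, "term_query")) {
    return(query$label)
  }
  if (inherits(query, "drug_query")) {
    if (query$mode == "atc_prefix") return(query$value)
    return(paste(sort(query$value), collapse = "+"))
  }
  validation_error("not a query object")
}
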
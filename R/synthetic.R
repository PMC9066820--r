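# Synthetic spontaneous-report stores. The generator emulates the
# statistical structure a case/non-case analysis assumes: reports draw
# suspected drugs and reaction PTs independently from configured marginal
# reporting frequencies, with injected drug-event association multipliers
# (rho) raising the event probability when an associated drug is present.
#
# Every report must list >= 1 drug and >= 1 reaction, so zero rows are
# redrawn; this conditions the realised marginals upward. The generator
# therefore calibrates the raw Bernoulli probabilities by a fixed point
# q = m * (1 - prod(1 - q)) so that the *conditional* (post-redraw)
# marginals equal the configured ones. This requires the configured
# marginals to describe a population averaging more than one drug and one
# reaction per report (sum of marginals > 1), which spontaneous-report
# databases do.

default_drug_marginals <- function() {
  c(erenumab = 0.030, galcanezumab = 0.018, fremanezumab = 0.012,
    ubrogepant = 0.003, rimegepant = 0.003,
    sumatriptan = 0.100, rizatriptan = 0.050, zolmitriptan = 0.020,
    naratriptan = 0.010,
    propranolol = 0.080, metoprolol = 0.060, atenolol = 0.040,
    nadolol = 0.010, timolol = 0.010,
    amitriptyline = 0.080, topiramate = 0.080,
    paracetamol = 0.250, ibuprofen = 0.250)
}

default_event_marginals <- function() {
  c("Raynaud's phenomenon" = 0.0020, "Peripheral coldness" = 0.0030,
    "Headache" = 0.200, "Nausea" = 0.150, "Fatigue" = 0.150,
    "Dizziness" = 0.080, "Migraine" = 0.060, "Rash" = 0.060,
    "Arthralgia" = 0.050, "Myalgia" = 0.050, "Diarrhoea" = 0.080,
    "Injection site reaction" = 0.080, "Constipation" = 0.040,
    "Alopecia" = 0.030, "Condition aggravated" = 0.030,
    "Weight increased" = 0.040, "Skin discolouration" = 0.010)
}

cgrp_ingredients <- function() {
  c("erenumab", "galcanezumab", "fremanezumab", "ubrogepant", "rimegepant")
}

#' Configuration of the spontaneous-report simulator
#'
#' Defaults emulate a migraine-drug pharmacovigilance population: drug and
#' event marginal reporting frequencies for CGRP antagonists, triptans,
#' beta-blockers and common co-medications; one injected association between
#' the CGRP class and Raynaud's phenomenon whose multiplier (`rho = 26`)
#' implies a class-level IC of about 3.3 bits; demographics, time to onset
#' (log-normal, median 84 days, IQR roughly 18-383), monthly dosing,
#' seriousness, outcomes and field-level missingness patterned on published
#' Raynaud's case-series characteristics.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; generation is deterministic given it.
#' @param drug_marginals Named numeric: per-ingredient probability that a
#'   report lists the drug as suspected (post-redraw population marginal;
#'   must sum to > 1 so every report can carry a drug).
#' @param event_marginals Named numeric: per-PT baseline probability that a
#'   report lists the reaction (must sum to > 1).
#' @param associations List of `list(drugs =, pt =, rho =)`: when any of
#'   `drugs` is present the event's draw probability is multiplied by
#'   `rho >= 0` (capped below 1).
#' @param sex_p_female Probability a report's patient is female.
#' @param age_law `list(mean =, sd =, min =, max =)`: normal ages clamped to
#'   the range.
#' @param tto_law `list(meanlog =, sdlog =)` for log-normal
#'   time-to-onset in days.
#' @param outcome_probs,country_probs,reporter_probs Named probability maps
#'   (each sums to 1).
#' @param serious_p Probability a reaction is serious.
#' @param withdrawn_p Probability the suspect drug was withdrawn (among
#'   reports where withdrawal is documented).
#' @param missingness Named probabilities of missingness for `age`, `sex`,
#'   `country`, `reporter`, `start_date`, `onset_date`, `dose`, `outcome`,
#'   `drug_withdrawn`.
#' @param term_table,drug_table Dictionary tables (defaults:
#'   [migraine_term_table()], [migraine_drug_table()]).
#' @return An object of class `synthetic_config`.
#' @seealso [generate_store()]
#' @export
synthetic_config <- function(
    n_reports = 50000,
    seed = 20220131,
    drug_marginals = default_drug_marginals(),
    event_marginals = default_event_marginals(),
    associations = list(list(drugs = cgrp_ingredients(),
                             pt = "Raynaud's phenomenon", rho = 26)),
    sex_p_female = 0.925,
    age_law = list(mean = 46, sd = 13, min = 18, max = 75),
    tto_law = list(meanlog = log(84), sdlog = 2.27),
    outcome_probs = c(recovered = 0.277, recovering = 0.064,
                      not_recovered = 0.659, fatal = 0),
    serious_p = 0.152,
    withdrawn_p = 0.34,
    country_probs = c("United States of America" = 0.626, "Italy" = 0.101,
                      "Germany" = 0.051, "Spain" = 0.040, "Ireland" = 0.040,
                      "Netherlands" = 0.040, "Belgium" = 0.020,
                      "Switzerland" = 0.020, "Norway" = 0.020,
                      "Austria" = 0.010, "United Kingdom" = 0.010,
                      "Iceland" = 0.010, "Sweden" = 0.010, "Other" = 0.002),
    reporter_probs = c(physician = 0.468, pharmacist = 0.028,
                       other_health_professional = 0.147, consumer = 0.357),
    missingness = c(age = 0.41, sex = 0.06, country = 0, reporter = 0.10,
                    start_date = 0.35, onset_date = 0.35, dose = 0.50,
                    outcome = 0.52, drug_withdrawn = 0.30),
    term_table = migraine_term_table(),
    drug_table = migraine_drug_table()) {
  cfg <- list(
    n_reports = n_reports, seed = seed, drug_marginals = drug_marginals,
    event_marginals = event_marginals, associations = associations,
    sex_p_female = sex_p_female, age_law = age_law, tto_law = tto_law,
    outcome_probs = outcome_probs, serious_p = serious_p,
    withdrawn_p = withdrawn_p, country_probs = country_probs,
    reporter_probs = reporter_probs, missingness = missingness,
    term_table = as_tibble(term_table), drug_table = as_tibble(drug_table)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  bad <- character()
  chk01 <- function(x, what) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) bad <<- c(bad, what)
  }
  if (length(cfg$n_reports) != 1 || is.na(cfg$n_reports) ||
      cfg$n_reports < 1) bad <- c(bad, "n_reports")
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) bad <- c(bad, "seed")
  chk01(cfg$drug_marginals, "drug_marginals")
  chk01(cfg$event_marginals, "event_marginals")
  chk01(cfg$sex_p_female, "sex_p_female")
  chk01(cfg$serious_p, "serious_p")
  chk01(cfg$withdrawn_p, "withdrawn_p")
  chk01(cfg$missingness, "missingness")
  if (sum(cfg$drug_marginals) <= 1) {
    bad <- c(bad, "drug_marginals (must sum to > 1: every report lists >= 1 drug)")
  }
  if (sum(cfg$event_marginals) <= 1) {
    bad <- c(bad, "event_marginals (must sum to > 1: every report lists >= 1 reaction)")
  }
  for (p in list(cfg$outcome_probs, cfg$country_probs, cfg$reporter_probs)) {
    chk01(p, "category probabilities")
    if (abs(sum(p) - 1) > 1e-9) bad <- c(bad, "category probabilities (sum != 1)")
  }
  for (a in cfg$associations) {
    if (is.null(a$drugs) || is.null(a$pt) || is.null(a$rho) || a$rho < 0) {
      bad <- c(bad, "associations (need drugs, pt, rho >= 0)")
    } else {
      if (!all(a$drugs %in% names(cfg$drug_marginals))) {
        bad <- c(bad, sprintf("associations (drug not in drug_marginals: %s)",
                              paste(setdiff(a$drugs, names(cfg$drug_marginals)),
                                    collapse = ", ")))
      }
      if (!a$pt %in% names(cfg$event_marginals)) {
        bad <- c(bad, sprintf("associations (pt not in event_marginals: %s)", a$pt))
      }
    }
  }
  if (!all(names(cfg$drug_marginals) %in% cfg$drug_table$ingredient)) {
    bad <- c(bad, "drug_marginals (ingredient missing from drug_table)")
  }
  if (!all(names(cfg$event_marginals) %in% cfg$term_table$pt)) {
    bad <- c(bad, "event_marginals (pt missing from term_table)")
  }
  if (length(bad) > 0) {
    validation_error(paste0("invalid synthetic config field(s): ",
                            paste(unique(bad), collapse = "; ")))
  }
  invisible(cfg)
}

# Fixed-point calibration: raw Bernoulli probabilities q with
# q = m * (1 - prod(1 - q)), so that P(item present | >= 1 item) = m.
calibrate_marginals <- function(m, tol = 1e-13, max_iter = 100000) {
  q <- m
  for (i in seq_len(max_iter)) {
    p0 <- prod(1 - q)
    q_new <- pmin(m * (1 - p0), 0.999)
    if (max(abs(q_new - q)) < tol) {
      return(list(q = q_new, p0 = prod(1 - q_new)))
    }
    q <- q_new
  }
  validation_error("marginal calibration did not converge; marginals too close to an infeasible configuration")
}

# Draw an n x k presence matrix with per-column probabilities q, redrawing
# any all-FALSE row (optionally with row-specific probability matrix).
draw_presence <- function(n, q, pmat = NULL) {
  k <- length(q)
  draw_rows <- function(rows) {
    if (is.null(pmat)) {
      matrix(runif(length(rows) * k), ncol = k) <
        matrix(q, nrow = length(rows), ncol = k, byrow = TRUE)
    } else {
      matrix(runif(length(rows) * k), ncol = k) < pmat[rows, , drop = FALSE]
    }
  }
  out <- draw_rows(seq_len(n))
  repeat {
    empty <- which(rowSums(out) == 0)
    if (length(empty) == 0) break
    out[empty, ] <- draw_rows(empty)
  }
  out
}

#' Closed-form implied IC of an injected association
#'
#' For each configured association, the large-sample IC implied by the
#' generative model: `log2(p_cond / p_marg)` where `p_cond` is the event
#' probability given an associated drug and `p_marg` the marginal event
#' probability, both in the *generated population*. Both incorporate the
#' redraw conditioning (every report has >= 1 drug and >= 1 reaction),
#' computed from the calibrated draw probabilities under independence
#' between drugs; interactions between multiple associations sharing
#' reports are neglected.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with one row per association: `drugs`, `pt`, `rho`,
#'   `p_any_drug`, `p_cond`, `p_marg`, `implied_ic`.
#' @export
implied_ic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cal_d <- calibrate_marginals(config$drug_marginals)
  cal_e <- calibrate_marginals(config$event_marginals)
  rows <- lapply(config$associations, function(a) {
    q_a <- cal_d$q[a$drugs]
    p_any <- (1 - prod(1 - q_a)) / (1 - cal_d$p0)
    j <- match(a$pt, names(config$event_marginals))
    q_b <- cal_e$q[[j]]
    q_boost <- min(a$rho * q_b, 0.999)
    # event-redraw conditioning: reports whose boosted event is likelier
    # are less likely to come up empty, so renormalisation differs between
    # exposed and unexposed reports
    q_mod <- cal_e$q
    q_mod[j] <- q_boost
    p_cond <- q_boost / (1 - prod(1 - q_mod))
    p_base <- q_b / (1 - cal_e$p0)
    p_marg <- p_any * p_cond + (1 - p_any) * p_base
    tibble(drugs = paste(a$drugs, collapse = "+"), pt = a$pt, rho = a$rho,
           p_any_drug = p_any, p_cond = p_cond, p_marg = p_marg,
           implied_ic = log2(p_cond / p_marg))
  })
  bind_rows(rows)
}

#' Generate a synthetic report store
#'
#' Deterministic given `config$seed`. Each report draws suspected drugs and
#' reaction PTs independently from the calibrated marginals (zero-drug and
#' zero-reaction reports are redrawn so `n_reports` is exact); injected
#' associations multiply the event probability by `rho` when an associated
#' drug is present; demographics, dates, doses, seriousness, outcomes and
#' missingness follow the config.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `store` (a `report_store`) and `truth` (the
#'   [implied_ic()] tibble for the injected associations).
#' @export
#' @examples
#' sim <- generate_store(synthetic_config(n_reports = 500, seed = 7))
#' sim$store
generate_store <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_reports)
  ids <- sprintf("S%07d", seq_len(n))

  cal_d <- calibrate_marginals(config$drug_marginals)
  cal_e <- calibrate_marginals(config$event_marginals)
  drug_names <- names(config$drug_marginals)
  event_names <- names(config$event_marginals)

  drug_mat <- draw_presence(n, cal_d$q)

  # Event draw probabilities per report: baseline, overridden where an
  # associated drug is present.
  pmat <- matrix(cal_e$q, nrow = n, ncol = length(cal_e$q), byrow = TRUE)
  for (a in config$associations) {
    hit <- rowSums(drug_mat[, match(a$drugs, drug_names), drop = FALSE]) > 0
    j <- match(a$pt, event_names)
    pmat[hit, j] <- min(a$rho * cal_e$q[[j]], 0.999)
  }
  event_mat <- draw_presence(n, cal_e$q, pmat = pmat)

  miss <- config$missingness
  draw_missing <- function(x, p) replace(x, runif(length(x)) < p, NA)

  sex <- ifelse(runif(n) < config$sex_p_female, "female", "male")
  sex <- draw_missing(sex, miss[["sex"]])
  age <- round(rnorm(n, config$age_law$mean, config$age_law$sd))
  age <- pmin(pmax(age, config$age_law$min), config$age_law$max)
  age <- draw_missing(age, miss[["age"]])
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)
  country <- draw_missing(country, miss[["country"]])
  reporter <- sample(names(config$reporter_probs), n, replace = TRUE,
                     prob = config$reporter_probs)
  reporter <- draw_missing(reporter, miss[["reporter"]])
  withdrawn <- runif(n) < config$withdrawn_p
  withdrawn <- draw_missing(withdrawn, miss[["drug_withdrawn"]])

  reports <- tibble(
    report_id = ids, country = country, reporter_qualification = reporter,
    sex = sex, age_years = as.numeric(age), drug_withdrawn = withdrawn
  )

  # Drug rows: melt the presence matrix. Start dates uniform over a
  # three-year reporting window; doses from per-ingredient typical regimens.
  hits_d <- which(drug_mat, arr.ind = TRUE)
  ord <- order(hits_d[, 1], hits_d[, 2])
  hits_d <- hits_d[ord, , drop = FALSE]
  nd <- nrow(hits_d)
  ingredient <- drug_names[hits_d[, 2]]
  start <- as.Date("2019-01-01") + sample.int(1095, nd, replace = TRUE) - 1L
  start[runif(nd) < miss[["start_date"]]] <- NA
  dose_amount <- dose_for(ingredient)
  dose_na <- runif(nd) < miss[["dose"]]
  dose_amount[dose_na] <- NA
  drugs <- tibble(
    report_id = ids[hits_d[, 1]], ingredient = ingredient,
    role = "suspected", dose_amount = dose_amount,
    dose_unit = ifelse(is.na(dose_amount), NA_character_, "mg"),
    dose_interval_days = ifelse(is.na(dose_amount), NA_real_, 30),
    start_date = format(start, "%Y-%m-%d"), end_date = NA_character_,
    indication = "Migraine"
  )

  # Reaction rows: onset = report's earliest drug start + log-normal TTO.
  hits_e <- which(event_mat, arr.ind = TRUE)
  ord <- order(hits_e[, 1], hits_e[, 2])
  hits_e <- hits_e[ord, , drop = FALSE]
  ne <- nrow(hits_e)
  first_start <- rep(as.Date(NA), n)
  ok <- !is.na(start)
  if (any(ok)) {
    agg <- tapply(as.integer(start[ok]), hits_d[ok, 1], min)
    first_start[as.integer(names(agg))] <- as.Date(agg, origin = "1970-01-01")
  }
  # cap at ten years: keeps onset inside a plausible reporting window (the
  # heavy log-normal tail would otherwise produce unparseable far-future dates)
  tto <- pmin(round(rlnorm(ne, config$tto_law$meanlog, config$tto_law$sdlog)),
              3650)
  onset <- first_start[hits_e[, 1]] + tto
  onset[runif(ne) < miss[["onset_date"]]] <- NA
  serious <- runif(ne) < config$serious_p
  crit <- ifelse(serious,
                 sample(c("other_medically_important", "disabling",
                          "hospitalization"), ne, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2)),
                 NA_character_)
  outcome <- sample(names(config$outcome_probs), ne, replace = TRUE,
                    prob = config$outcome_probs)
  outcome[runif(ne) < miss[["outcome"]]] <- NA
  reactions <- tibble(
    report_id = ids[hits_e[, 1]], pt = event_names[hits_e[, 2]],
    onset_date = format(onset, "%Y-%m-%d"), serious = serious,
    seriousness_criteria = crit, outcome = outcome
  )

  store <- report_store(reports, drugs, reactions,
                        term_dictionary(config$term_table),
                        drug_dictionary(config$drug_table))
  list(store = store, truth = implied_ic(config))
}

# Typical monthly-regimen dose amounts (mg) per ingredient; generic 50 mg
# for anything without a listed regimen.
dose_for <- function(ingredient) {
  pick <- function(amounts, probs, n) {
    if (n == 0) return(numeric())
    sample(amounts, n, replace = TRUE, prob = probs)
  }
  out <- rep(50, length(ingredient))
  i <- ingredient == "erenumab"
  out[i] <- pick(c(70, 140), c(0.75, 0.25), sum(i))
  i <- ingredient == "galcanezumab"
  out[i] <- pick(c(120, 240), c(0.7, 0.3), sum(i))
  i <- ingredient == "fremanezumab"
  out[i] <- 225
  out
}
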
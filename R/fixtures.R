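# Deterministic fixture stores reproducing the published case-series
# structure: a 99-case Raynaud's series with background reports, and a
# count-faithful skeleton store realising the printed comparative 2x2
# cells. Both are constructed, not sampled, so every descriptive summary
# is exact.

#' Deterministic 99-case Raynaud's phenomenon study fixture
#'
#' A store of 99 case reports (Raynaud's phenomenon with a suspected
#' CGRP-targeting drug) plus 400 background reports, constructed so the
#' descriptive layer reproduces the published case-series counts: drug
#' shares 56 erenumab / 28 galcanezumab / 13 fremanezumab / 1 ubrogepant /
#' 1 rimegepant; 86 female of 93 with known sex; age bands 29 / 27 / 2
#' among 58 known (median 45, IQR 35-57, range 20-70); 15 serious
#' (6 disabling); outcomes 31 not recovered / 3 recovering / 13 recovered
#' among 47 known; drug withdrawn in 23 of 68 evaluable; time to onset
#' median 84 days (IQR 18-383) among 59 dated; monthly doses 70 mg
#' (erenumab), 225 mg (fremanezumab), 120 mg (galcanezumab); co-reported
#' terms led by arthralgia (7); co-suspect propranolol (3), rizatriptan and
#' nadolol (2 each).
#'
#' @return A `report_store` of 499 reports.
#' @export
study_fixture <- function() {
  case_ids <- sprintf("C%03d", 1:99)
  ingredient <- rep(c("erenumab", "galcanezumab", "fremanezumab",
                      "ubrogepant", "rimegepant"), c(56, 28, 13, 1, 1))

  ages <- c(20, 22:34, 35, 35,
            36, 37, 38, 39, 40, 41, 42, 42, 43, 43, 44, 44, 44,
            46, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 56,
            57, 57, 58, 59, 60, 61, 62, 63, 64, 58, 59, 60, 61, 62,
            65, 70)
  stopifnot(length(ages) == 58)
  age_years <- c(ages, rep(NA_real_, 41))

  sex <- rep(c("female", "male", NA), c(86, 7, 6))
  country <- rep(c("United States of America", "Italy", "Germany", "Spain",
                   "Ireland", "Netherlands", "Belgium", "Switzerland",
                   "Norway", "Austria", "United Kingdom", "Iceland",
                   "Sweden"),
                 c(62, 10, 5, 4, 4, 4, 2, 2, 2, 1, 1, 1, 1))
  reporter <- rep(c("physician", "pharmacist", "other_health_professional",
                    "consumer"), c(51, 3, 16, 29))
  withdrawn <- rep(c(TRUE, FALSE, NA), c(23, 45, 31))

  reports <- tibble(
    report_id = case_ids, country = country,
    reporter_qualification = reporter, sex = sex, age_years = age_years,
    drug_withdrawn = withdrawn
  )

  # 59 dated cases: start 2021-01-01, onset = start + TTO; the TTO set has
  # median 84 and IQR 18-383 under type-7 quantiles.
  tto <- c(2:15, 18, 18, 20:32, 84, 90:102, 383, 383, 400:413)
  stopifnot(length(tto) == 59)
  start_date <- c(rep("2021-01-01", 59), rep(NA_character_, 40))
  onset_date <- c(format(as.Date("2021-01-01") + tto, "%Y-%m-%d"),
                  rep(NA_character_, 40))

  # Doses: 20 erenumab (70 x15 / 140 x5), 10 galcanezumab (120 x7 / 240 x3,
  # cases 57-66), 6 fremanezumab (225, cases 85-90).
  dose_amount <- rep(NA_real_, 99)
  dose_amount[1:20] <- c(rep(70, 15), rep(140, 5))
  dose_amount[57:66] <- c(rep(120, 7), rep(240, 3))
  dose_amount[85:90] <- 225
  has_dose <- !is.na(dose_amount)

  case_drugs <- tibble(
    report_id = case_ids, ingredient = ingredient, role = "suspected",
    dose_amount = dose_amount,
    dose_unit = ifelse(has_dose, "mg", NA_character_),
    dose_interval_days = ifelse(has_dose, 30, NA_real_),
    start_date = start_date, end_date = NA_character_,
    indication = "Migraine"
  )
  cosuspect <- tibble(
    report_id = case_ids[c(40:42, 43:44, 45:46)],
    ingredient = rep(c("propranolol", "rizatriptan", "nadolol"), c(3, 2, 2)),
    role = "suspected", dose_amount = NA_real_, dose_unit = NA_character_,
    dose_interval_days = NA_real_, start_date = NA_character_,
    end_date = NA_character_, indication = NA_character_
  )

  serious <- rep(c(TRUE, FALSE), c(15, 84))
  crit <- rep(c("disabling", "other_medically_important", NA),
              c(6, 9, 84))
  outcome <- rep(c("not_recovered", "recovering", "recovered", NA),
                 c(31, 3, 13, 52))
  index_reactions <- tibble(
    report_id = case_ids, pt = "Raynaud's phenomenon",
    onset_date = onset_date, serious = serious,
    seriousness_criteria = crit, outcome = outcome
  )
  co_pt <- rep(c("Arthralgia", "Alopecia", "Condition aggravated",
                 "Constipation", "Fatigue", "Skin discolouration",
                 "Weight increased"), c(7, 5, 5, 4, 4, 4, 4))
  co_reactions <- tibble(
    report_id = case_ids[1:33], pt = co_pt, onset_date = NA_character_,
    serious = FALSE, seriousness_criteria = NA_character_,
    outcome = NA_character_
  )
  # The one case with gangrene and extremity necrosis (a serious,
  # disabling report).
  severe <- tibble(
    report_id = case_ids[1], pt = c("Gangrene", "Extremity necrosis"),
    onset_date = NA_character_, serious = TRUE,
    seriousness_criteria = "other_medically_important",
    outcome = NA_character_
  )

  bg_n <- c(142, 8, 50, 5, 80, 3, 40, 30, 20, 12, 10)
  bg_drug <- rep(c("sumatriptan", "erenumab", "sumatriptan", "sumatriptan",
                   "propranolol", "propranolol", "amitriptyline",
                   "topiramate", "erenumab", "galcanezumab", "ibuprofen"),
                 bg_n)
  bg_pt <- rep(c("Headache", "Peripheral coldness", "Nausea",
                 "Raynaud's phenomenon", "Fatigue", "Raynaud's phenomenon",
                 "Dizziness", "Nausea", "Headache", "Fatigue", "Rash"),
               bg_n)
  bg_ids <- sprintf("B%03d", seq_len(sum(bg_n)))
  bg_reports <- tibble(
    report_id = bg_ids, country = NA_character_,
    reporter_qualification = NA_character_, sex = NA_character_,
    age_years = NA_real_, drug_withdrawn = NA
  )
  bg_drugs <- tibble(
    report_id = bg_ids, ingredient = bg_drug, role = "suspected",
    dose_amount = NA_real_, dose_unit = NA_character_,
    dose_interval_days = NA_real_, start_date = NA_character_,
    end_date = NA_character_, indication = NA_character_
  )
  bg_reactions <- tibble(
    report_id = bg_ids, pt = bg_pt, onset_date = NA_character_,
    serious = FALSE, seriousness_criteria = NA_character_,
    outcome = NA_character_
  )

  report_store(
    bind_rows(reports, bg_reports),
    bind_rows(case_drugs, cosuspect, bg_drugs),
    bind_rows(index_reactions, co_reactions, severe, bg_reactions),
    term_dictionary(migraine_term_table()),
    drug_dictionary(migraine_drug_table())
  )
}

#' Count-faithful comparative-analysis fixture
#'
#' A skeleton store realising exactly the published comparative 2x2 cells:
#' 99 Raynaud's reports and 55,506 other-ADR reports with the CGRP class;
#' 43 Raynaud's and 47,417 other-ADR reports with triptans; 142 Raynaud's
#' and 129,222 other-ADR reports with the migraine beta-blockers. Every
#' report lists one suspected drug and one reaction; total 232,429 reports.
#'
#' @return A `report_store`.
#' @export
comparative_fixture <- function() {
  seg_n <- c(99, 55506, 43, 47417, 142, 129222)
  seg_drug <- rep(c("erenumab", "erenumab", "sumatriptan", "sumatriptan",
                    "propranolol", "propranolol"), seg_n)
  seg_pt <- rep(c("Raynaud's phenomenon", "Headache",
                  "Raynaud's phenomenon", "Headache",
                  "Raynaud's phenomenon", "Headache"), seg_n)
  n <- sum(seg_n)
  ids <- sprintf("K%06d", seq_len(n))
  reports <- tibble(
    report_id = ids, country = NA_character_,
    reporter_qualification = NA_character_, sex = NA_character_,
    age_years = NA_real_, drug_withdrawn = NA
  )
  drugs <- tibble(
    report_id = ids, ingredient = seg_drug, role = "suspected",
    dose_amount = NA_real_, dose_unit = NA_character_,
    dose_interval_days = NA_real_, start_date = NA_character_,
    end_date = NA_character_, indication = NA_character_
  )
  reactions <- tibble(
    report_id = ids, pt = seg_pt, onset_date = NA_character_,
    serious = NA, seriousness_criteria = NA_character_,
    outcome = NA_character_
  )
  report_store(reports, drugs, reactions,
               term_dictionary(migraine_term_table()),
               drug_dictionary(migraine_drug_table()))
}
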
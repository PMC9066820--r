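make_csv_fixture <- function(dir) {
  writeLines(c(
    "report_id,country,reporter_qualification,sex,age_years,drug_withdrawn",
    "A1,France,physician,female,45,TRUE",
    "A2,Italy,consumer,male,60,",
    "A3,,,,,",
    "A4,Spain,pharmacist,female,33,FALSE",
    "A5,France,physician,,20,"
  ), file.path(dir, "reports.csv"))
  writeLines(c(
    "report_id,ingredient,role,dose_amount,dose_unit,dose_interval_days,start_date,end_date,indication",
    "A1,erenumab,suspected,70,mg,30,2021-01-01,,Migraine",
    "A1,propranolol,concomitant,,,,,,",
    "A2,sumatriptan,suspected,,,,2020-06,,Migraine",
    "A3,erenumab,suspected,140,mg,30,,,",
    "A4,galcanezumab,suspected,120,mg,30,2021-02-01,2021-06-01,Migraine",
    "A4,sumatriptan,interacting,,,,,,",
    "A5,propranolol,suspected,,,,,,",
    "ZZ,erenumab,suspected,,,,,,"
  ), file.path(dir, "report_drugs.csv"))
  writeLines(c(
    "report_id,pt,onset_date,serious,seriousness_criteria,outcome",
    "A1,Raynaud's phenomenon,2021-03-26,TRUE,disabling,not_recovered",
    "A2,Headache,,FALSE,,recovered",
    "A3,Raynaud's phenomenon,,,,",
    "A4,Peripheral coldness,2021-03,FALSE,,recovering",
    "A5,Mystery term,,,,",
    "A5,Headache,,,,"
  ), file.path(dir, "report_reactions.csv"))
  dir
}

load_fixture_store <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  make_csv_fixture(dir)
  load_reports(file.path(dir, "reports.csv"),
               file.path(dir, "report_drugs.csv"),
               file.path(dir, "report_reactions.csv"),
               tiny_term_dict(), tiny_drug_dict())
}

test_that("relational loading links tables, rejects orphans, flags unknown PTs", {
  store <- load_fixture_store()
  expect_equal(nrow(store$reports), 5)
  # orphan drug row (report ZZ) rejected, store size unchanged
  expect_equal(nrow(store$rejects$orphan_drugs), 1)
  expect_equal(store$rejects$orphan_drugs$report_id, "ZZ")
  # unknown PT flagged, its report kept
  expect_equal(store$rejects$unknown_pts, "Mystery term")
  expect_true("A5" %in% store$reports$report_id)
  # partial dates resolved to the 15th and flagged imputed
  a2 <- store$drugs[store$drugs$report_id == "A2", ]
  expect_equal(a2$start_date, as.Date("2020-06-15"))
  expect_true(a2$start_date_imputed)
})

test_that("reports without a drug or a reaction are rejected with a record", {
  reports <- tibble::tibble(report_id = c("B1", "B2"))
  drugs <- tibble::tibble(report_id = "B1", ingredient = "erenumab",
                          role = "suspected")
  reactions <- tibble::tibble(report_id = c("B1", "B2"), pt = "Headache")
  expect_message(
    store <- report_store(reports, drugs, reactions,
                          tiny_term_dict(), tiny_drug_dict()),
    "incomplete"
  )
  expect_equal(store$reports$report_id, "B1")
  expect_equal(store$rejects$incomplete_reports$report_id, "B2")
})

test_that("store validation rejects bad values", {
  td <- tiny_term_dict(); dd <- tiny_drug_dict()
  base <- list(
    reports = tibble::tibble(report_id = "X1", age_years = 45),
    drugs = tibble::tibble(report_id = "X1", ingredient = "erenumab",
                           role = "suspected"),
    reactions = tibble::tibble(report_id = "X1", pt = "Headache")
  )
  bad_age <- base; bad_age$reports$age_years <- 150
  expect_error(report_store(bad_age$reports, bad_age$drugs,
                            bad_age$reactions, td, dd),
               class = "icsignal_validation_error")
  bad_role <- base; bad_role$drugs$role <- "bystander"
  expect_error(report_store(bad_role$reports, bad_role$drugs,
                            bad_role$reactions, td, dd),
               class = "icsignal_validation_error")
  bad_crit <- base
  bad_crit$reactions$serious <- FALSE
  bad_crit$reactions$seriousness_criteria <- "disabling"
  expect_error(report_store(bad_crit$reports, bad_crit$drugs,
                            bad_crit$reactions, td, dd),
               class = "icsignal_validation_error")
})

test_that("match_reports uses report-level, role-filtered semantics", {
  store <- tiny_store()
  both <- match_reports(store, raynaud_pt_query(), cgrp_query())
  expect_equal(both, c("R01", "R02"))
  # a report listing erenumab twice still counts once
  drug_only <- match_reports(store, drug_query = cgrp_query())
  expect_equal(drug_only, c("R01", "R02", "R03"))
  # intersection identity
  expect_equal(
    both,
    intersect(match_reports(store, term_query = raynaud_pt_query()),
              drug_only)
  )
  expect_error(match_reports(store), class = "icsignal_validation_error")
})

test_that("widening the role filter never shrinks the match set", {
  store <- load_fixture_store()
  q1 <- drug_query("ingredient_set", c("propranolol", "sumatriptan"),
                   roles = "suspected")
  q2 <- drug_query("ingredient_set", c("propranolol", "sumatriptan"),
                   roles = c("suspected", "interacting"))
  q3 <- drug_query("ingredient_set", c("propranolol", "sumatriptan"),
                   roles = c("suspected", "interacting", "concomitant"))
  m1 <- match_reports(store, drug_query = q1)
  m2 <- match_reports(store, drug_query = q2)
  m3 <- match_reports(store, drug_query = q3)
  expect_true(all(m1 %in% m2))
  expect_true(all(m2 %in% m3))
  expect_true("A1" %in% m3 && !"A1" %in% m2)  # concomitant-only propranolol
})

test_that("brute-force raw-row scan reproduces match_reports on random stores", {
  sim <- generate_store(null_sim_config(seed = 301, n = 100))
  store <- sim$store
  cases <- list(
    list(pt = "Raynaud's phenomenon", ing = NULL),
    list(pt = NULL, ing = c("erenumab", "propranolol")),
    list(pt = "Headache", ing = "sumatriptan")
  )
  for (cs in cases) {
    got <- match_reports(
      store,
      term_query = if (!is.null(cs$pt)) term_query("PT", cs$pt),
      drug_query = if (!is.null(cs$ing)) drug_query("ingredient_set", cs$ing)
    )
    want <- brute_force_match(store$reports, store$drugs, store$reactions,
                              pts = cs$pt, ingredients = cs$ing)
    expect_equal(got, want)
  }
  # HLT query against the PTs it covers
  hlt <- "Peripheral vasoconstriction, necrosis and vascular insufficiency"
  got <- match_reports(store, term_query = term_query("HLT", hlt))
  want <- brute_force_match(
    store$reports, store$drugs, store$reactions,
    pts = store$term_dict$pt[store$term_dict$hlt == hlt]
  )
  expect_equal(got, want)
})

test_that("time to onset is earliest-onset minus earliest-start in days", {
  store <- load_fixture_store()
  tto <- time_to_onset(store, cgrp_query(), raynaud_pt_query())
  a1 <- tto[tto$report_id == "A1", ]
  expect_equal(a1$tto_days, 84)  # 2021-01-01 -> 2021-03-26
  expect_false(a1$implausible)
  a3 <- tto[tto$report_id == "A3", ]
  expect_true(is.na(a3$tto_days))  # no start date

  # start == onset gives 0; onset before start is flagged implausible
  reports <- tibble::tibble(report_id = c("T1", "T2"))
  drugs <- tibble::tibble(
    report_id = c("T1", "T2"), ingredient = "erenumab", role = "suspected",
    start_date = c("2021-05-01", "2021-05-01")
  )
  reactions <- tibble::tibble(
    report_id = c("T1", "T2"), pt = "Raynaud's phenomenon",
    onset_date = c("2021-05-01", "2021-04-01")
  )
  st <- report_store(reports, drugs, reactions, tiny_term_dict(),
                     tiny_drug_dict())
  tto2 <- time_to_onset(st, cgrp_query(), raynaud_pt_query())
  expect_equal(tto2$tto_days, c(0, -30))
  expect_equal(tto2$implausible, c(FALSE, TRUE))
})

test_that("monthly dose converts to mg per month", {
  expect_equal(monthly_dose(70, "mg", 30), 70)
  expect_equal(monthly_dose(225, "mg", 30), 225)
  expect_equal(monthly_dose(1, "mg", 15), 2)
  expect_equal(monthly_dose(0.07, "g", 30), 70)
  expect_message(out <- monthly_dose(2, "IU", 30), "unconvertible")
  expect_true(is.na(out))
  expect_true(is.na(monthly_dose(70, "mg", NA)))
})

test_that("a store round-trips through write_store/load_reports", {
  dir <- withr::local_tempdir()
  store <- tiny_store()
  write_store(store, dir)
  re <- load_reports(file.path(dir, "reports.csv"),
                     file.path(dir, "report_drugs.csv"),
                     file.path(dir, "report_reactions.csv"),
                     load_term_dictionary(file.path(dir, "meddra.csv")),
                     load_drug_dictionary(file.path(dir, "atc.csv")))
  expect_equal(re$reports, store$reports)
  expect_equal(re$drugs$ingredient, store$drugs$ingredient)
  expect_equal(re$reactions$pt, store$reactions$pt)
})
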
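# Independent oracles and small in-code fixtures shared across tests.

# Brute-force report matcher operating on raw data frames, written
# independently of the package's indexing (simple per-report loops).
brute_force_match <- function(reports, drugs, reactions,
                              pts = NULL, ingredients = NULL,
                              roles = c("suspected", "interacting")) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  hit <- character()
  for (id in reports$report_id) {
    ok <- TRUE
    if (!is.null(pts)) {
      rx <- reactions[reactions$report_id == id, ]
      ok <- ok && any(norm(rx$pt) %in% norm(pts))
    }
    if (!is.null(ingredients)) {
      dx <- drugs[drugs$report_id == id, ]
      ok <- ok && any(norm(dx$ingredient) %in% norm(ingredients) &
                        dx$role %in% roles)
    }
    if (ok) hit <- c(hit, id)
  }
  sort(hit)
}

# Gamma-posterior quantile by numeric integration of the density written
# from scratch (log-density + integrate + uniroot), independent of
# qgamma/pgamma.
gamma_quantile_quadrature <- function(p, shape, rate) {
  dens <- function(x) {
    exp(shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x)
  }
  cdf <- function(q) integrate(dens, 0, q, rel.tol = 1e-10)$value
  mean <- shape / rate
  sd <- sqrt(shape) / rate
  uniroot(function(q) cdf(q) - p,
          lower = max(mean - 10 * sd, 1e-12), upper = mean + 10 * sd,
          tol = 1e-10)$root
}

# Minimal three-level term fixture.
tiny_term_dict <- function() {
  term_dictionary(tibble::tibble(
    pt = c("Raynaud's phenomenon", "Peripheral coldness", "Headache"),
    hlt = c("Peripheral Vasoconstriction, necrosis and vascular insufficiency",
            "Peripheral Vasoconstriction, necrosis and vascular insufficiency",
            "Headaches NEC"),
    soc = c("Vascular disorders", "Vascular disorders",
            "Nervous system disorders")
  ))
}

tiny_drug_dict <- function() {
  drug_dictionary(tibble::tibble(
    ingredient = c("erenumab", "galcanezumab", "sumatriptan", "propranolol"),
    atc_code = c("N02CD01", "N02CD02", "N02CC01", "C07AA05")
  ))
}

# A ten-report store: 3 reports with erenumab (one listed twice), 4 with
# the Raynaud's event, 2 with both.
tiny_store <- function() {
  ids <- sprintf("R%02d", 1:10)
  reports <- tibble::tibble(
    report_id = ids, country = NA_character_,
    reporter_qualification = NA_character_, sex = NA_character_,
    age_years = NA_real_, drug_withdrawn = NA
  )
  drugs <- tibble::tibble(
    report_id = c("R01", "R02", "R03", "R03", ids[4:10]),
    ingredient = c("erenumab", "erenumab", "erenumab", "erenumab",
                   rep("sumatriptan", 7)),
    role = "suspected",
    dose_amount = NA_real_, dose_unit = NA_character_,
    dose_interval_days = NA_real_, start_date = NA_character_,
    end_date = NA_character_, indication = NA_character_
  )
  reactions <- tibble::tibble(
    report_id = ids,
    pt = c("Raynaud's phenomenon", "Raynaud's phenomenon", "Headache",
           "Raynaud's phenomenon", "Raynaud's phenomenon",
           rep("Headache", 5)),
    onset_date = NA_character_, serious = FALSE,
    seriousness_criteria = NA_character_, outcome = NA_character_
  )
  report_store(reports, drugs, reactions, tiny_term_dict(), tiny_drug_dict())
}

raynaud_pt_query <- function() term_query("PT", "Raynaud's phenomenon")
cgrp_query <- function() drug_query("atc_prefix", "N02CD")

# Null simulator configuration (no injected association) with few drugs
# and events, for replicate studies.
null_sim_config <- function(seed, n = 2000) {
  synthetic_config(
    n_reports = n, seed = seed,
    drug_marginals = c(erenumab = 0.05, sumatriptan = 0.5,
                       propranolol = 0.4, paracetamol = 0.35),
    event_marginals = c("Raynaud's phenomenon" = 0.05, "Headache" = 0.5,
                        "Nausea" = 0.4, "Fatigue" = 0.35),
    associations = list()
  )
}
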
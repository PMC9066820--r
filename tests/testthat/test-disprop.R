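test_that("contingency tables enforce their invariants", {
  tab <- contingency_table(2, 3, 4, 10)
  expect_s3_class(tab, "contingency_table")
  expect_error(contingency_table(5, 3, 4, 10),
               class = "icsignal_validation_error")
  expect_error(contingency_table(2, 11, 4, 10),
               class = "icsignal_validation_error")
  expect_error(contingency_table(-1, 3, 4, 10),
               class = "icsignal_validation_error")
})

test_that("build_table counts reports with report-level semantics", {
  store <- tiny_store()
  tab <- build_table(store, raynaud_pt_query(), cgrp_query())
  expect_equal(unclass(tab)[c("O", "n_drug", "n_event", "N")],
               list(O = 2L, n_drug = 3L, n_event = 4L, N = 10L))
  # scope restricted to the three drug reports
  scoped <- build_table(store, raynaud_pt_query(), cgrp_query(),
                        scope = c("R01", "R02", "R03"))
  expect_equal(scoped$N, 3L)
  expect_equal(scoped$n_drug, 3L)
  expect_error(build_table(store, raynaud_pt_query(), cgrp_query(),
                           scope = "nope"),
               class = "icsignal_validation_error")
})

test_that("build_table agrees with a brute-force raw-row scan on 200 synthetic reports", {
  store <- generate_store(null_sim_config(seed = 88, n = 200))$store
  tab <- build_table(store, raynaud_pt_query(),
                     drug_query("ingredient_set", "erenumab"))
  ev <- brute_force_match(store$reports, store$drugs, store$reactions,
                          pts = "Raynaud's phenomenon")
  dr <- brute_force_match(store$reports, store$drugs, store$reactions,
                          ingredients = "erenumab")
  expect_equal(tab$O, length(intersect(ev, dr)))
  expect_equal(tab$n_drug, length(dr))
  expect_equal(tab$n_event, length(ev))
  expect_equal(tab$N, 200L)
})

test_that("IC point estimate follows the shrunk observed/expected ratio", {
  # O = E exactly: log2(10.5/10.5) = 0
  r0 <- information_component(contingency_table(10, 100, 100, 1000))
  expect_equal(r0$E, 10)
  expect_equal(r0$ic, 0)
  expect_false(r0$is_signal)
  # O = 0, n_drug = 0: log2(0.5/0.5) = 0 with a wide interval
  r00 <- information_component(contingency_table(0, 0, 100, 1000))
  expect_equal(r00$ic, 0)
  expect_gt(r00$ic975 - r00$ic025, 5)
  # invariant ordering
  expect_true(r00$ic025 <= r00$ic && r00$ic <= r00$ic975)
})

test_that("gamma-quantile interval matches numeric integration of the posterior", {
  cases <- list(c(O = 99, E = 76.61), c(O = 10, E = 5), c(O = 3, E = 9))
  for (cs in cases) {
    shape <- cs[["O"]] + 0.5
    rate <- cs[["E"]] + 0.5
    lo <- log2(gamma_quantile_quadrature(0.025, shape, rate))
    hi <- log2(gamma_quantile_quadrature(0.975, shape, rate))
    tab <- contingency_table(
      cs[["O"]], 1000, round(cs[["E"]] * 1e6 / 1000), 1e6
    )
    res <- information_component(tab)
    expect_equal(res$ic025, lo, tolerance = 1e-5)
    expect_equal(res$ic975, hi, tolerance = 1e-5)
  }
})

test_that("IC is monotone: increasing in O, decreasing in n_drug", {
  ics_O <- vapply(10:60, function(O) {
    information_component(contingency_table(O, 100, 200, 10000))$ic
  }, numeric(1))
  expect_true(all(diff(ics_O) > 0))
  ics_nd <- vapply(seq(100, 2000, by = 100), function(nd) {
    information_component(contingency_table(10, nd, 200, 10000))$ic
  }, numeric(1))
  expect_true(all(diff(ics_nd) < 0))
})

test_that("interval width shrinks in O at fixed O/E ratio", {
  widths <- vapply(c(5, 20, 80, 320), function(O) {
    tab <- contingency_table(O, 1000, O * 2 * 1000, 2e6)  # E = O
    r <- information_component(tab)
    r$ic975 - r$ic025
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("gamma and asymptotic IC025 agree within 0.15 bits for O >= 10", {
  for (O in c(10, 30, 100, 300)) {
    for (ratio in c(0.5, 1, 2)) {
      E <- O * ratio
      n_event <- round(E * 1e7 / 1e4)
      tab <- contingency_table(O, 1e4, n_event, 1e7)
      g <- information_component(tab, "gamma_quantile")
      a <- information_component(tab, "noren_approx")
      expect_lt(abs(g$ic025 - a$ic025), 0.15)
      expect_true(a$ic025 <= a$ic && a$ic <= a$ic975)
    }
  }
})

test_that("scaling all cells moves the IC toward log2(O/E) without flipping sign", {
  base <- c(O = 40, n_drug = 400, n_event = 500, N = 10000)  # E = 20
  for (k in c(2, 10, 100)) {
    tab0 <- do.call(contingency_table, as.list(base))
    tabk <- do.call(contingency_table, as.list(base * k))
    r0 <- information_component(tab0)
    rk <- information_component(tabk)
    target <- log2(base[["O"]] / (base[["n_drug"]] * base[["n_event"]] / base[["N"]]))
    expect_lt(abs(rk$ic - target), abs(r0$ic - target))
    if (abs(r0$ic) > 0.1) expect_equal(sign(rk$ic), sign(r0$ic))
  }
})

test_that("comparative IC assigns overlap reports to the interest row by default", {
  # hand-built store: 6 interest, 5 comparator, 2 of them co-exposed
  ids <- sprintf("Q%02d", 1:9)
  reports <- tibble::tibble(report_id = ids)
  drugs <- tibble::tibble(
    report_id = c(ids[1:6], ids[5:9]),
    ingredient = c(rep("erenumab", 6), rep("sumatriptan", 5)),
    role = "suspected"
  )
  reactions <- tibble::tibble(
    report_id = ids,
    pt = c(rep("Raynaud's phenomenon", 2), rep("Headache", 7))
  )
  st <- report_store(reports, drugs, reactions, tiny_term_dict(),
                     tiny_drug_dict())
  keep <- comparative_ic(st, raynaud_pt_query(), cgrp_query(),
                         drug_query("atc_prefix", "N02CC"))
  expect_equal(keep$table$N, 9L)       # all reports in scope, cells disjoint
  expect_equal(keep$table$n_drug, 6L)  # co-exposed Q05, Q06 on interest row
  excl <- comparative_ic(st, raynaud_pt_query(), cgrp_query(),
                         drug_query("atc_prefix", "N02CC"),
                         overlap = "exclude")
  expect_equal(excl$table$N, 7L)
  expect_equal(excl$table$n_drug, 4L)
  # overlapping ingredient expansions are rejected
  expect_error(
    comparative_ic(st, raynaud_pt_query(), cgrp_query(),
                   drug_query("ingredient_set", "erenumab")),
    class = "icsignal_validation_error"
  )
})

test_that("comparative IC is ~0 with no differential reporting (null simulation)", {
  store <- generate_store(null_sim_config(seed = 555, n = 2000))$store
  res <- comparative_ic(store, raynaud_pt_query(),
                        drug_query("ingredient_set", "erenumab"),
                        drug_query("ingredient_set", "sumatriptan"))
  expect_lt(abs(res$ic), 0.8)
  expect_false(res$is_signal)
})

test_that("screen_all_pairs is complete and ranked by ic025", {
  store <- tiny_store()
  screen <- screen_all_pairs(
    store,
    list(N02CD = cgrp_query(),
         sumatriptan = drug_query("ingredient_set", "sumatriptan"),
         propranolol = drug_query("ingredient_set", "propranolol")),
    list(raynaud = raynaud_pt_query(),
         headache = term_query("PT", "Headache"))
  )
  expect_equal(nrow(screen), 6)
  expect_true(all(diff(screen$ic025) <= 0))
  # the zero-count pair is present, not dropped
  expect_true(any(screen$O == 0))
  # recomputation from cells matches
  i <- 1
  r <- information_component(
    contingency_table(screen$O[i], screen$n_drug[i], screen$n_event[i],
                      screen$N[i])
  )
  expect_equal(r$ic, screen$ic[i])
})

test_that("an injected association outranks null pairs in the screen", {
  cfg <- synthetic_config(
    n_reports = 20000, seed = 99,
    drug_marginals = c(erenumab = 0.05, sumatriptan = 0.5,
                       propranolol = 0.4, paracetamol = 0.35),
    event_marginals = c("Raynaud's phenomenon" = 0.005, "Headache" = 0.5,
                        "Nausea" = 0.4, "Fatigue" = 0.35),
    associations = list(list(drugs = "erenumab",
                             pt = "Raynaud's phenomenon", rho = 8))
  )
  sim <- generate_store(cfg)
  dq <- lapply(names(cfg$drug_marginals),
               function(i) drug_query("ingredient_set", i))
  names(dq) <- names(cfg$drug_marginals)
  eq <- lapply(names(cfg$event_marginals), function(p) term_query("PT", p))
  names(eq) <- names(cfg$event_marginals)
  screen <- screen_all_pairs(sim$store, dq, eq)
  expect_equal(screen$drug[1], "erenumab")
  expect_equal(screen$event[1], "Raynaud's phenomenon")
  # parameter recovery within 0.3 bits of the closed-form implied IC
  expect_lt(abs(screen$ic[1] - sim$truth$implied_ic), 0.3)
})
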
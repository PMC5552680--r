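test_that("JSON models load with validated structure", {
  f <- tempfile(fileext = ".json")
  writeLines('{
    "metabolites": ["a", "b"],
    "reactions": [
      {"id": "EX_a", "stoich": {"a": -1}, "lb": -5, "ub": 0, "exchange": true},
      {"id": "R1", "stoich": {"a": -1, "b": 1}, "lb": 0, "ub": 10},
      {"id": "EX_b", "stoich": {"b": -1}, "lb": 0, "ub": 10, "exchange": true}
    ],
    "atp": "b"
  }', f)
  m <- load_model(f)
  expect_equal(dim(m$S), c(2L, 3L))
  expect_equal(unname(m$S["a", "R1"]), -1)
  expect_equal(unname(exchange_map(m)[["a"]]), "EX_a")
})

test_that("model validation errors cite the offending reaction", {
  rx <- list(R1 = list(stoich = c(ghost = 1), lb = 0, ub = 1))
  expect_error(metabolic_model("a", rx, atp = "a"), "R1.*ghost")
  rx2 <- list(R1 = list(stoich = c(a = 1), lb = 5, ub = 1))
  expect_error(metabolic_model("a", rx2, atp = "a"), "lb <= ub")
  rx3 <- list(EX = list(stoich = c(a = 1, b = 1), lb = 0, ub = 1,
                        exchange = TRUE))
  expect_error(metabolic_model(c("a", "b"), rx3, atp = "a"),
               "exactly one")
  rx4 <- list(R1 = list(stoich = c(a = 1), lb = 0, ub = 1))
  expect_error(metabolic_model("a", rx4, atp = "zz"), "ATP species")
})

test_that("models round-trip through JSON and SBML", {
  m <- toy_core_model()
  fj <- tempfile(fileext = ".json")
  write_model(m, fj)
  mj <- load_model(fj)
  expect_equal(mj$S, m$S)
  expect_equal(mj$lb, m$lb)
  expect_equal(mj$ub, m$ub)
  expect_equal(mj$exchange, m$exchange)

  fs <- tempfile(fileext = ".xml")
  write_model_sbml(m, fs)
  ms <- read_model_sbml(fs, atp = "atp", inorganic = c("o2", "co2"))
  # identical stoichiometry up to column order
  expect_setequal(colnames(ms$S), colnames(m$S))
  expect_equal(ms$S[rownames(m$S), colnames(m$S)], m$S)
  expect_equal(ms$lb[names(m$lb)], m$lb)
  expect_equal(ms$ub[names(m$ub)], m$ub)
  expect_equal(ms$exchange[names(m$exchange)], m$exchange)
})

test_that("all-zero measured exchanges give the zero flux distribution", {
  m <- toy_core_model()
  fx <- fit_fluxes(m, c(glc = 0, lac = 0, leu = 0, ile = 0, val = 0))
  expect_true(all(fx$v == 0))
  expect_equal(fx$objective, 0)
})

test_that("the fermentation pathway flux matches the hand-computed LP", {
  m <- toy_core_model()
  fx <- fit_fluxes(m, c(glc = -1, lac = 2, leu = 0, ile = 0, val = 0))
  expect_equal(unname(fx$v["GLYC"]), 1, tolerance = 1e-9)
  expect_equal(unname(fx$v["LACOX"]), 0, tolerance = 1e-9)
  expect_equal(unname(fx$v["ATPM"]), 2, tolerance = 1e-9)
  # |EX_glc| + GLYC + |EX_lac| + ATPM = 1 + 1 + 2 + 2
  expect_equal(fx$objective, 6, tolerance = 1e-9)
  expect_lte(max(abs(m$S %*% fx$v)), 1e-9)
})

test_that("infeasible exchange sets are reported", {
  m <- toy_core_model()
  # more lactate out than glycolysis can make from the fixed glucose
  expect_error(fit_fluxes(m, c(glc = -1, lac = 3)), "no steady-state")
  expect_error(fit_fluxes(m, c(unobtainium = 1)), "no exchange")
})

test_that("pFBA picks the shorter of two parallel pathways", {
  rx <- list(
    EX_a = list(stoich = c(a = -1), lb = -10, ub = 0, exchange = TRUE),
    EX_b = list(stoich = c(b = -1), lb = 0, ub = 10, exchange = TRUE),
    direct = list(stoich = c(a = -1, b = 1), lb = 0, ub = 10),
    via1 = list(stoich = c(a = -1, c = 1), lb = 0, ub = 10),
    via2 = list(stoich = c(c = -1, b = 1), lb = 0, ub = 10))
  m <- metabolic_model(c("a", "b", "c", "atp"), c(rx, list(
    ATPM = list(stoich = c(atp = -1), lb = 0, ub = 10))), atp = "atp")
  fx <- fit_fluxes(m, c(a = -1, b = 1))
  expect_equal(unname(fx$v["direct"]), 1, tolerance = 1e-9)
  expect_equal(unname(fx$v["via1"]), 0)
  expect_equal(fx$objective, 3, tolerance = 1e-9)
})

test_that("reversible reactions are split correctly", {
  rx <- list(
    EX_a = list(stoich = c(a = -1), lb = -10, ub = 10, exchange = TRUE),
    EX_b = list(stoich = c(b = -1), lb = -10, ub = 10, exchange = TRUE),
    conv = list(stoich = c(a = -1, b = 1), lb = -10, ub = 10),
    ATPM = list(stoich = c(atp = -1), lb = 0, ub = 10))
  m <- metabolic_model(c("a", "b", "atp"), rx, atp = "atp")
  # force the backward direction: b in, a out
  fx <- fit_fluxes(m, c(a = 1, b = -1))
  expect_equal(unname(fx$v["conv"]), -1, tolerance = 1e-9)
  expect_equal(fx$objective, 3, tolerance = 1e-9)
})

test_that("fitted fluxes agree with an independent scipy LP on random profiles", {
  m <- toy_core_model()
  profiles <- simulate_uptake_profiles(10, seed = 31)
  fixed <- lapply(seq_len(nrow(profiles)), function(i) {
    pr <- unlist(profiles[i, c("glc", "lac", "leu", "ile", "val")])
    profile_to_fixed(m, pr)
  })
  ours <- vapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, , drop = FALSE]
    fx <- fit_fluxes(m, pr)
    expect_lte(max(abs(m$S %*% fx$v)), 1e-9)
    fx$objective
  }, numeric(1))
  theirs <- py_pfba_objectives(m, fixed)
  expect_equal(ours, theirs, tolerance = 1e-8)
  # and both match the hand-derived closed form for the toy network
  hand <- vapply(seq_len(nrow(profiles)), function(i)
    ref_toy_objective(-profiles$glc[i], profiles$lac[i], -profiles$leu[i],
                      -profiles$ile[i], -profiles$val[i]), numeric(1))
  expect_equal(ours, hand, tolerance = 1e-8)
})

test_that("total ATP production follows the positive-stoichiometry sum", {
  m <- toy_core_model()
  zero <- fit_fluxes(m, c(glc = 0, lac = 0, leu = 0, ile = 0, val = 0))
  expect_equal(total_atp(m, zero), 0)
  ferm <- fit_fluxes(m, c(glc = -1, lac = 2, leu = 0, ile = 0, val = 0))
  expect_equal(total_atp(m, ferm), 2, tolerance = 1e-9)
  # production equals consumption at steady state: the ATP row of S v is 0
  mixed <- fit_fluxes(m, c(glc = -1, lac = 1, leu = -0.1, ile = -0.05,
                           val = -0.02))
  arow <- m$S["atp", ]
  produced <- sum(pmax(0, arow * mixed$v))
  consumed <- -sum(pmin(0, arow * mixed$v))
  expect_equal(produced, consumed, tolerance = 1e-9)
  expect_equal(total_atp(m, mixed), produced)
})

test_that("substrate ATP yields match the authored stoichiometry", {
  m <- toy_core_model()
  expect_equal(substrate_atp_yield(m, "glc"), 30, tolerance = 1e-9)
  expect_equal(substrate_atp_yield(m, "leu"), 27, tolerance = 1e-9)
  expect_equal(substrate_atp_yield(m, "ile"), 32, tolerance = 1e-9)
  expect_equal(substrate_atp_yield(m, "val"), 24, tolerance = 1e-9)

  # fermentation-only bounds: oxygen closed leaves 2 ATP per glucose
  m2 <- m; m2$lb["EX_o2"] <- 0
  expect_equal(substrate_atp_yield(m2, "glc"), 2, tolerance = 1e-9)

  # closing the downstream Leu oxidation removes the pathway entirely
  m3 <- m; m3$ub["LEUOX"] <- 0
  expect_equal(substrate_atp_yield(m3, "leu"), 0)

  # doubling the ATP coefficient of the respiration lump doubles the
  # lactate yield
  m4 <- m; m4$S["atp", "LACOX"] <- 28
  expect_equal(substrate_atp_yield(m4, "lac"),
               2 * substrate_atp_yield(m, "lac"), tolerance = 1e-9)

  expect_error(substrate_atp_yield(m, "kic"), "no exchange")
})

test_that("metabolites without a consuming pathway yield zero ATP", {
  rx <- list(
    EX_a = list(stoich = c(a = -1), lb = -10, ub = 10, exchange = TRUE),
    ATPM = list(stoich = c(atp = -1), lb = 0, ub = 10))
  m <- metabolic_model(c("a", "atp"), rx, atp = "atp")
  expect_equal(substrate_atp_yield(m, "a"), 0)
})

test_that("uncapped energy-generating cycles are flagged as model defects", {
  rx <- list(
    EX_a = list(stoich = c(a = -1), lb = -1, ub = 0, exchange = TRUE),
    EX_e = list(stoich = c(e = -1), lb = 0, ub = Inf, exchange = TRUE),
    sink = list(stoich = c(a = -1, e = 1), lb = 0, ub = Inf),
    # futile loop making ATP from nothing, with no flux cap
    loop1 = list(stoich = c(c = -1, d = 1, atp = 1), lb = 0, ub = Inf),
    loop2 = list(stoich = c(d = -1, c = 1, atp = 1), lb = 0, ub = Inf),
    ATPM = list(stoich = c(atp = -1), lb = 0, ub = Inf))
  m <- metabolic_model(c("a", "e", "c", "d", "atp"), rx, atp = "atp")
  expect_error(substrate_atp_yield(m, "a"), "unbounded")
})

test_that("ATP attribution closed forms hold", {
  m <- toy_core_model()
  # pure fermentation: all ATP is lactate-linked
  pr <- c(glc = -1.5, lac = 3, leu = 0, ile = 0, val = 0)
  fx <- fit_fluxes(m, pr)
  bd <- atp_breakdown(m, fx, pr)
  expect_equal(bd$frac_lactate, 1, tolerance = 1e-6)
  expect_equal(bd$frac_other, 0, tolerance = 1e-6)
  expect_equal(bd$total_atp, 2 * 1.5, tolerance = 1e-9)
  # zero BCAA uptake zeroes the three amino-acid fractions
  expect_equal(bd$frac_leu + bd$frac_ile + bd$frac_val, 0)

  # fractions always sum to one
  profiles <- simulate_uptake_profiles(6, seed = 8)
  acc <- atp_accounting(m, profiles)
  expect_equal(acc$frac_lactate + acc$frac_leu + acc$frac_ile +
                 acc$frac_val + acc$frac_other, rep(1, 6),
               tolerance = 1e-6)
  expect_true(all(acc$frac_other >= 0 & acc$frac_other <= 1))

  # zero-flux distribution with claimed secretion is inconsistent
  fake <- structure(list(reaction_ids = m$rxns,
                         v = stats::setNames(numeric(length(m$rxns)),
                                             m$rxns),
                         objective = 0, cell_line = NA_character_),
                    class = "flux_distribution")
  expect_error(atp_breakdown(m, fake, c(glc = 0, lac = 1, leu = 0,
                                        ile = 0, val = 0)),
               "zero but sources")
  expect_error(atp_breakdown(m, fx, c(glc = -1, lac = -1, leu = 0,
                                      ile = 0, val = 0)),
               "secretion")
  expect_error(atp_breakdown(m, fx, c(glc = -1, lac = 1)), "lacks")
})

test_that("the BCAA ATP share rises monotonically along the sweep family", {
  m <- toy_core_model()
  sweep <- bcaa_sweep_profiles(n = 6)
  acc <- atp_accounting(m, sweep)
  bf <- acc$frac_leu + acc$frac_ile + acc$frac_val
  expect_true(all(diff(bf) > 0))
  expect_gte(max(bf) - min(bf), 0.4)
})
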
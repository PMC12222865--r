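test_that("FBA solves the linear chain and respects closed media", {
  m <- toy_chain_model()
  s <- fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 10, tolerance = 1e-9)
  # steady state holds at the optimum
  expect_lt(max(abs(stoich_matrix(m) %*% s$fluxes)), 1e-6)
  # closing the only uptake removes all growth
  closed <- set_medium(m, character(0))
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)
})

test_that("an objective pinned by bounds returns the pinned value", {
  m <- toy_chain_model()
  m$reactions$biomass$lb <- 3
  m$reactions$biomass$ub <- 3
  expect_equal(fba(m, maximize = "biomass")$objective_value, 3,
               tolerance = 1e-9)
})

test_that("scaling the biomass stoichiometry rescales the objective inversely", {
  m <- toy_chain_model()
  m2 <- m
  m2$reactions$biomass$stoich <- m$reactions$biomass$stoich * 2
  expect_equal(fba(m2)$objective_value, fba(m)$objective_value / 2,
               tolerance = 1e-9)
})

test_that("FBA matches an independent LP formulation on all toy fixtures", {
  skip_if_not_installed("boot")
  fixtures <- list(toy_chain_model(), toy_chain_model(n_steps = 3),
                   two_essential_model(), alt_carbon_model(),
                   no_requirement_model())
  sp <- crossfeed_spec(2, list(c("S1", "S2", "x"), c("S2", "S1", "y")))
  fixtures <- c(fixtures, make_crossfeeding_panel(sp)$models)
  for (m in fixtures) {
    mine <- fba(m)
    ref <- fba_oracle(m)
    expect_equal(mine$status, "optimal", info = m$id)
    expect_equal(mine$objective_value, ref$objective, tolerance = 1e-6,
                 info = m$id)
  }
})

test_that("exchange reactions are detected structurally", {
  m <- two_essential_model()
  ex <- exchange_reactions(m)
  expect_setequal(names(ex), c("a_e", "b_e"))
  expect_setequal(unname(ex), c("EX_a", "EX_b"))
  # an internal single-metabolite sink in the cytosol is not an exchange
  m$reactions$leak <- list(id = "leak", stoich = c(t_c = -1), lb = 0,
                           ub = 1000)
  expect_setequal(names(exchange_reactions(m)), c("a_e", "b_e"))
})

test_that("set_medium opens exactly the requested uptakes, idempotently", {
  m <- two_essential_model()
  m1 <- set_medium(m, "a_e", uptake_bound = 10)
  expect_equal(m1$reactions$EX_a$lb, -10)
  expect_equal(m1$reactions$EX_b$lb, 0)
  expect_identical(set_medium(m1, "a_e", uptake_bound = 10), m1)
  expect_error(set_medium(m, "nope_e"), "no exchange reaction")
})

test_that("predicted carbon-utilization width applies the organic rule", {
  mets <- data.frame(
    id = c("glc_e", "co2_e", "nh3_e", "ac_e", "etoh_e", "myst_e"),
    name = NA_character_, compartment = "e",
    formula = c("C6H12O6", "CO2", "NH3", "C2H3O2", "C2H6O", NA),
    stringsAsFactors = FALSE)
  mk <- function(ids) {
    rx <- lapply(ids, function(i) {
      list(id = paste0("EX_", i), stoich = stats::setNames(-1, i),
           lb = -10, ub = 1000)
    })
    rx[[length(rx) + 1]] <- list(id = "biomass",
                                 stoich = stats::setNames(-1, ids[1]),
                                 lb = 0, ub = 1000)
    metabolic_model("pw", mets[mets$id %in% ids, ], rx, "biomass")
  }
  expect_equal(predicted_width(mk(c("glc_e", "co2_e", "nh3_e"))), 1)
  expect_equal(predicted_width(mk(c("ac_e", "etoh_e"))), 2)
  expect_warning(w <- predicted_width(mk(c("glc_e", "myst_e"))),
                 "no formula")
  expect_equal(w, 1)
  # the permissive carbon rule still excludes the inorganic blocklist
  expect_equal(predicted_width(mk(c("glc_e", "co2_e", "nh3_e")),
                               rule = "carbon"), 1)
  m0 <- toy_chain_model()
  m0$reactions$EX_carbon <- NULL
  m0$reactions$TR_carbon <- NULL
  m0$metabolites <- m0$metabolites[m0$metabolites$id != "carbon_e", ]
  m0$reactions$GEN <- list(id = "GEN", stoich = c(m1 = 1), lb = 0, ub = 1000)
  expect_equal(predicted_width(m0), 0)
})

test_that("model validation pinpoints the offending element", {
  mets <- data.frame(id = "a_c", name = NA, compartment = "c",
                     formula = NA, stringsAsFactors = FALSE)
  expect_error(
    metabolic_model("bad", mets,
                    list(list(id = "r1", stoich = c(ghost = -1),
                              lb = 0, ub = 1)), "r1"),
    "unknown metabolite ghost")
  expect_error(
    metabolic_model("bad", mets,
                    list(list(id = "r1", stoich = c(a_c = -1),
                              lb = 2, ub = 1)), "r1"),
    "invalid bounds")
  expect_error(
    metabolic_model("bad", mets,
                    list(list(id = "r1", stoich = c(a_c = -1),
                              lb = 0, ub = 1)), "missing_obj"),
    "objective reaction not found")
})

test_that("models round-trip through JSON and SBML unchanged", {
  sp <- crossfeed_spec(2, list(c("S1", "S2", "x"), c("S2", "S1", "y")))
  m <- make_crossfeeding_panel(sp)$models$S1
  for (ext in c(".json", ".xml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_model(m, f)
    m2 <- read_model(f)
    S1 <- stoich_matrix(m)
    S2 <- stoich_matrix(m2)[rownames(S1), colnames(S1)]
    expect_equal(S1, S2, info = ext)
    expect_equal(m2$objective, m$objective, info = ext)
    expect_equal(vapply(m2$reactions[colnames(S1)], `[[`, 0, "lb"),
                 vapply(m$reactions[colnames(S1)], `[[`, 0, "lb"),
                 info = ext)
    expect_equal(vapply(m2$reactions[colnames(S1)], `[[`, 0, "ub"),
                 vapply(m$reactions[colnames(S1)], `[[`, 0, "ub"),
                 info = ext)
    # formulas survive the trip (needed for predicted widths)
    expect_equal(m2$metabolites$formula[match(m$metabolites$id,
                                              m2$metabolites$id)],
                 m$metabolites$formula, info = ext)
  }
})

test_that("bundled SBML fixture parses with exchanges and objective intact", {
  f <- system.file("extdata", "toy_chain_sbml.xml", package = "nichecom")
  m <- read_model(f)
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$objective, "R_biomass")
  ex <- exchange_reactions(m)
  expect_equal(unname(ex["M_glc_e"]), "R_EX_glc")
  expect_equal(fba(m)$objective_value, 5, tolerance = 1e-9)
})

test_that("SBML without an objective or with ghost species is rejected", {
  f <- system.file("extdata", "toy_chain_sbml.xml", package = "nichecom")
  txt <- readLines(f)
  noobj <- withr::local_tempfile(fileext = ".xml")
  obj_block <- grep("listOfObjectives", txt)
  writeLines(txt[-(obj_block[1]:obj_block[2])], noobj)
  expect_error(read_model(noobj), "no fbc objective")
  ghost <- withr::local_tempfile(fileext = ".xml")
  writeLines(gsub('species="M_glc_e"', 'species="M_ghost"',
                  txt, fixed = TRUE), ghost)
  expect_error(read_model(ghost), "unknown species")
})
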
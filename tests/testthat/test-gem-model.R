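test_that("molecular weights match atomic-weight sums and fail soft", {
  expect_equal(molecularWeight("H2O"), 18.015, tolerance = 0.01)
  expect_equal(molecularWeight("C6H12O6"), 180.156, tolerance = 0.01)
  # ATP at physiological protonation
  expect_equal(molecularWeight("C10H16N5O13P3"), 507.18, tolerance = 0.05)
  expect_true(is.na(molecularWeight("")))
  expect_true(is.na(molecularWeight(NA_character_)))
  # polymeric / repeat / unknown-element formulas are not computable
  expect_true(all(is.na(molecularWeight(c("RC6H5", "X2O", "*3C", "(CH2)n")))))
  # fractional counts (biomass pseudo-formulas) are accepted
  expect_equal(molecularWeight("C1.5H3"), 1.5 * 12.011 + 3 * 1.008,
               tolerance = 1e-9)
})

test_that("molecular weight is additive over disjoint element sets", {
  pairs <- list(c("C6H12O6", "N3P2"), c("H2O", "C2"), c("NaCl", "O2"),
                c("C10H16N5O13P3", "SeBr2"))
  for (p in pairs) {
    expect_equal(molecularWeight(paste0(p[1], p[2])),
                 molecularWeight(p[1]) + molecularWeight(p[2]),
                 tolerance = 1e-9)
  }
})

test_that("SBML writer/reader round-trips toy and random models", {
  for (gem in list(makeToyGEM("TOY6"), makeToyGEM("TOY6Z"),
                   makeRandomGEM(2, 3, 3, seed = 11))) {
    f <- withr::local_tempfile(fileext = ".xml")
    writeSBML(gem, f)
    back <- readSBML(f)
    expect_identical(metabolites(back)$id, metabolites(gem)$id)
    expect_identical(metabolites(back)$formula, metabolites(gem)$formula)
    expect_identical(metabolites(back)$charge, metabolites(gem)$charge)
    expect_identical(metabolites(back)$isBoundary, metabolites(gem)$isBoundary)
    expect_identical(reactions(back)$id, reactions(gem)$id)
    expect_equal(reactions(back)$lowerBound, reactions(gem)$lowerBound)
    expect_equal(reactions(back)$upperBound, reactions(gem)$upperBound)
    expect_equal(reactions(back)$objectiveCoefficient,
                 reactions(gem)$objectiveCoefficient)
    expect_identical(objectiveReaction(back), objectiveReaction(gem))
    expect_equal(stoichiometry(back), stoichiometry(gem))
  }
})

test_that("TOY6 fixture parses back with expected structure", {
  f <- withr::local_tempfile(fileext = ".xml")
  makeToyGEM("TOY6", file = f)
  gem <- readSBML(f)
  expect_equal(nrow(metabolites(gem)), 6)
  expect_equal(nrow(reactions(gem)), 6)
  expect_identical(objectiveReaction(gem), "BIO")
  expect_identical(compartments(gem), c(c = "cytosol"))
})

test_that("gzip-compressed SBML reads transparently", {
  f <- withr::local_tempfile(fileext = ".xml")
  fz <- withr::local_tempfile(fileext = ".xml.gz")
  makeToyGEM("TOY6", file = f)
  con <- gzfile(fz, "w")
  writeLines(readLines(f), con)
  close(con)
  gem <- readSBML(fz)
  expect_equal(nrow(reactions(gem)), 6)
  expect_identical(objectiveReaction(gem), "BIO")
})

test_that("legacy COBRA-dialect files resolve bounds, notes and objective", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(legacySBML(), f)
  gem <- readSBML(f)
  r <- reactions(gem)
  expect_equal(r$upperBound[r$id == "R_GLCup"], 8)
  expect_equal(r$lowerBound[r$id == "R_GLYC"], -1000)
  expect_identical(objectiveReaction(gem), "R_BIO")
  expect_identical(r$geneAssociation[r$id == "R_GLYC"], "(g1 and g2) or g3")
  m <- metabolites(gem)
  expect_identical(m$formula[m$id == "M_glc_c"], "C6H12O6")
  expect_identical(m$charge[m$id == "M_pyr_c"], -1L)
  expect_true(m$isBoundary[m$id == "M_glc_b"])
  # boundary species must not appear in the mass-balance rows
  expect_false("M_glc_b" %in% rownames(stoichiometricMatrix(gem)))
  expect_equal(objectiveValue(optimizeFlux(gem)), 8, tolerance = 1e-6)
})

test_that("reader rejects malformed and empty models with clear errors", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", f)
  expect_error(readSBML(f))
  writeLines(c("<?xml version=\"1.0\"?>",
               "<sbml><model id=\"m\"><listOfSpecies/></model></sbml>"), f)
  expect_error(readSBML(f), "no reactions")
  expect_error(readSBML(file.path(tempdir(), "does-not-exist.xml")),
               "not found")
})

test_that("a model without an fbc objective warns and refuses FBA", {
  f <- withr::local_tempfile(fileext = ".xml")
  gem <- makeToyGEM("TOY6")
  gem@reactions$objectiveCoefficient <- 0
  gem@objectiveReactionId <- character()
  writeSBML(gem, f)
  expect_warning(back <- readSBML(f), "no objective")
  expect_length(objectiveReaction(back), 0)
  expect_error(optimizeFlux(back), "no objective")
  # an explicit objective makes it solvable again
  expect_equal(objectiveValue(optimizeFlux(back, objective = "BIO")), 5,
               tolerance = 1e-6)
})

test_that("every stoichiometry key resolves to a parsed metabolite", {
  for (s in c(1, 7, 19)) {
    gem <- makeRandomGEM(1 + s %% 3, 2 + s %% 4, s %% 5, seed = s)
    ids <- metabolites(gem)$id
    for (st in stoichiometry(gem)) expect_true(all(names(st) %in% ids))
  }
})

test_that("cofactor tagging strips compartment suffixes and is idempotent", {
  gem <- makeToyGEM("TOY6")
  expect_equal(sum(metabolites(gem)$isCofactor), 2)
  expect_identical(metabolites(gem)$id[metabolites(gem)$isCofactor],
                   c("ATP", "ADP"))
  # idempotent
  expect_equal(sum(metabolites(tagCofactors(gem))$isCofactor), 2)
  # empty list clears the tagging
  expect_equal(sum(metabolites(tagCofactors(gem, character()))$isCofactor), 0)
  # suffix stripping over multiple compartments
  g2 <- GEM(compartments = c(c = "cytosol", m = "mitochondrion"),
            metabolites = data.frame(id = c("atp_c", "atp_m", "mal_c",
                                            "atpx_c")),
            reactions = data.frame(id = "r1"),
            stoichiometry = list(r1 = c(atp_c = -1, atp_m = 1)))
  g2 <- tagCofactors(g2, "atp")
  m <- metabolites(g2)
  expect_identical(m$id[m$isCofactor], c("atp_c", "atp_m"))
  # bracketed compartment suffix and BiGG species prefix
  expect_identical(metaboliteBaseId(c("M_atp_c", "atp[m]", "glc__D_c"),
                                    c("c", "m")),
                   c("atp", "atp", "glc__D"))
})

test_that("stoichiometric matrix reproduces the reaction stoichiometries", {
  gem <- makeToyGEM("TOY6")
  S <- stoichiometricMatrix(gem)
  expect_identical(dim(S), c(6L, 6L))
  expect_equal(S["B", "R2"], -1)
  expect_equal(S["ADP", "R2"], 1)
  for (rid in reactions(gem)$id) {
    st <- stoichiometry(gem)[[rid]]
    expect_equal(unname(S[names(st), rid]), unname(st))
  }
})
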
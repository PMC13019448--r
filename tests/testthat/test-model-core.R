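test_that("matrix assembly follows the sign convention and row ordering", {
  r <- two_species_records()
  sg <- assemble_matrices(r$dynamic, r$static, r$reactions, r$kinetics)
  expect_equal(sg$S[, "r1"], c(X1 = -1, X2 = 1))
  expect_equal(sg$G[, "r1"], c(X1 = 1, X2 = 0, E1 = 1))
  expect_identical(rownames(sg$G), c("X1", "X2", "E1"))

  # source reaction: positive column, all-zero G column permitted
  sg0 <- assemble_matrices(c("X1", "X2"), character(),
                           list(reaction_record("r0", products = c(X1 = 1))),
                           list(kinetics_record("r0")))
  expect_equal(sg0$S[, "r0"], c(X1 = 1, X2 = 0))
  expect_true(all(sg0$G[, "r0"] == 0))

  # non-unit coefficients enter with their multiplicity
  sg2 <- assemble_matrices("X1", character(),
                           list(reaction_record("r1", reactants = c(X1 = 2))),
                           list(kinetics_record("r1", c(X1 = 2))))
  expect_equal(sg2$S[1, 1], -2)
})

test_that("stoichiometry overrides replace the computed entry verbatim", {
  r <- two_species_records()
  sg <- assemble_matrices(r$dynamic, r$static, r$reactions, r$kinetics,
                          overrides = data.frame(species = "X2", reaction = "r1",
                                                 coefficient = 2))
  expect_equal(sg$S[, "r1"], c(X1 = -1, X2 = 2))
  # zero override: catalysis without mass flow
  sg0 <- assemble_matrices(r$dynamic, r$static, r$reactions, r$kinetics,
                           overrides = data.frame(species = "X1", reaction = "r1",
                                                  coefficient = 0))
  expect_equal(sg0$S["X1", "r1"], 0)
})

test_that("assembly rejects unknown names and duplicate kinetic orders", {
  r <- two_species_records()
  expect_error(
    assemble_matrices(r$dynamic, r$static,
                      list(reaction_record("r1", c(X9 = 1), c(X2 = 1))),
                      r$kinetics),
    "X9")
  expect_error(
    assemble_matrices(r$dynamic, r$static, r$reactions,
                      list(kinetics_record("r9", c(X1 = 1)))),
    "r9")
  expect_error(kinetics_record("r1", c(X1 = 1, X1 = 2)), "duplicate")
  expect_error(
    assemble_matrices(r$dynamic, r$static, r$reactions,
                      list(kinetics_record("r1", c(X1 = 1)),
                           kinetics_record("r1", c(E1 = 1)))),
    "duplicate")
})

test_that("assembly is insensitive to record order", {
  fx <- feedback_pathway_model()
  recs <- fx$model$records
  set.seed(11)
  perm_r <- sample(seq_along(recs$reactions))
  perm_k <- sample(seq_along(recs$kinetics))
  # species and reaction ordering is fixed by the name lists, so permuting
  # the record lists must not change the compiled matrices
  sg_perm <- assemble_matrices(fx$model$dynamic_species, fx$model$static_species,
                               recs$reactions[perm_r], recs$kinetics[perm_k])
  expect_identical(sg_perm$S[, fx$model$reaction_names], fx$model$S)
  expect_identical(sg_perm$G[, fx$model$reaction_names], fx$model$G)
})

test_that("unit-coefficient conversion reactions have zero net column sum", {
  fx <- feedback_pathway_model()
  # r1..r3: one reactant, one product, unit coefficients
  for (rx in c("r1", "r2", "r3")) {
    expect_equal(sum(fx$model$S[, rx]), 0)
  }
  # source r0 adds one molecule, sink r4 removes one
  expect_equal(sum(fx$model$S[, "r0"]), 1)
  expect_equal(sum(fx$model$S[, "r4"]), -1)
})

test_that("validate_model returns targeted diagnostics, not exceptions", {
  fx <- feedback_pathway_model()
  expect_length(validate_model(fx$model), 0)

  bad <- fx$model
  bad$alpha[2] <- -1
  d <- validate_model(bad)
  expect_match(d, "negative", all = FALSE)
  expect_match(d, "index 2", all = FALSE)

  bad2 <- fx$model
  bad2$S <- bad2$S[, 1:3]
  expect_match(validate_model(bad2), "dimensions", all = FALSE)

  bad3 <- fx$model
  bad3$xs["E1"] <- 0
  expect_match(validate_model(bad3), "static", all = FALSE)
})

test_that("classical reduction maps the two aggregate terms correctly", {
  m <- one_species_model(alpha = 2, beta = 1, g = 0, h = 1)
  cs <- classical_from_model(m)
  expect_equal(unname(cs$alpha), 2)
  expect_equal(unname(cs$beta), 1)
  expect_equal(cs$G[1, 1], 0)
  expect_equal(cs$H[1, 1], 1)
})

test_that("classical reduction rejects branched and zero-rate models", {
  # the branched pathway: C is consumed by both r3 and r4
  expect_error(classical_from_model(branched_pathway_model()),
               "not classically representable")
  # zero production rate constant: the log transform needs alpha > 0
  m0 <- one_species_model(alpha = 0, beta = 1)
  expect_error(classical_from_model(m0), "zero rate constant")
})

test_that("classical round-trip is the identity on the representable subclass", {
  for (seed in 1:5) {
    cs <- random_classical_ssystem(4, seed = seed)
    back <- classical_from_model(model_from_classical(cs))
    expect_equal(back$alpha, cs$alpha)
    expect_equal(back$beta, cs$beta)
    expect_equal(back$G, cs$G)
    expect_equal(back$H, cs$H)
    expect_equal(back$xs, cs$xs)
  }
})
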
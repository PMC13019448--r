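test_that("the feedback pathway fixture encodes the published constants", {
  fx <- feedback_pathway_model()
  m <- fx$model
  expect_length(m$dynamic_species, 5)
  expect_length(m$static_species, 3)
  expect_length(m$reaction_names, 6)
  expect_identical(m$G["X4", "r1"], -0.5)
  expect_identical(unname(m$alpha[c("r4", "r5", "r0")]), c(3, 0.1, 0))
  expect_identical(unname(m$alpha[c("r1", "r2", "r3")]), c(10, 10, 10))
  expect_identical(unname(m$xs), c(1, 1, 1))
  expect_identical(unname(m$x0), rep(0.1, 5))
  expect_length(validate_model(m), 0)
  # the input protocol: baseline 1, high pulse 10 on [5,15), medium 5 on [25,35)
  expect_equal(unname(bstkit:::input_vector(fx$input, 10, m)["X1"]), 10)
  expect_equal(unname(bstkit:::input_vector(fx$input, 30, m)["X1"]), 5)
  expect_equal(unname(bstkit:::input_vector(fx$input, 20, m)["X1"]), 1)
})

test_that("the branched pathway fixture is symmetric when the branch enzymes match", {
  m <- branched_pathway_model(E3 = 1, E4 = 1)
  expect_length(validate_model(m), 0)
  ss <- steadystate(m)
  expect_equal(unname(ss["D"]), unname(ss["E"]), tolerance = 1e-6)
  # with unit rate constants, flux conservation gives D = E3/(E3+E4) exactly
  ss2 <- steadystate(branched_pathway_model(E3 = 4, E4 = 1))
  expect_equal(unname(ss2["D"]), 4 / 5, tolerance = 1e-5)
  expect_equal(unname(ss2["E"]), 1 / 5, tolerance = 1e-5)
})

test_that("random models are reproducible, valid, and representable on request", {
  m1 <- random_model(3, 2, 4, seed = 42)
  m2 <- random_model(3, 2, 4, seed = 42)
  expect_identical(m1$S, m2$S)
  expect_identical(m1$G, m2$G)
  expect_identical(m1$alpha, m2$alpha)
  for (seed in 1:20) {
    m <- random_model(1 + seed %% 5, 1 + seed %% 3, 2 + seed %% 6, seed = seed)
    expect_length(validate_model(m), 0)
  }
  mr <- random_model(4, 1, seed = 3, representable = TRUE)
  expect_s3_class(classical_from_model(mr), "bst_classical")
})

test_that("shipped fixture files rebuild the programmatic fixtures bit-identically", {
  fx <- feedback_pathway_model()
  for (f in c("feedback.toml", "feedback.bst")) {
    m <- build_model(extdata(f))
    expect_identical(m$S, fx$model$S)
    expect_identical(m$G, fx$model$G)
    expect_identical(m$alpha, fx$model$alpha)
    expect_identical(m$x0, fx$model$x0)
    expect_identical(m$xs, fx$model$xs)
  }
  br <- build_model(extdata("branched.toml"))
  expect_identical(br$G, branched_pathway_model()$G)
})

test_that("the seven-parameter sensitivity problem is wired to the fixture", {
  g <- feedback_gsa_problem()
  expect_identical(g$pmap$names,
                   c("alpha_r0", "alpha_r1", "alpha_r2", "alpha_r3",
                     "alpha_r4", "alpha_r5", "g_X4_r1"))
  expect_equal(unname(g$lower), c(0.5, 5, 5, 5, 1.5, 0.05, -2))
  expect_equal(unname(g$upper), c(1.5, 15, 15, 15, 4.5, 0.15, 0))
  # the objective at nominal parameters is a finite positive exposure
  J <- g$f(g$nominal)
  expect_gt(J, 0)
  expect_true(is.finite(J))
})
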
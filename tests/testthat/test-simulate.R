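test_that("power-law rates follow the exponent matrix exactly", {
  # constant source: all-zero G column
  m0 <- model_from_records("X1", character(),
                           list(reaction_record("r0", products = c(X1 = 1))),
                           list(kinetics_record("r0")), alpha = c(r0 = 10))
  expect_equal(unname(rates(0, m0)), 10)

  # bilinear dependence on a dynamic and a static species
  r <- two_species_records()
  m <- model_from_records(r$dynamic, r$static, r$reactions, r$kinetics,
                          alpha = c(r1 = 10), xs = c(E1 = 1))
  expect_equal(unname(rates(c(2, 0), m)["r1"]), 20)

  # negative half-order feedback: alpha * 4^(-0.5) = 5
  fx <- feedback_pathway_model()
  rr <- rates(c(1, 0, 0, 4, 0), fx$model)
  expect_equal(unname(rr["r1"]), 10 * 4^(-0.5))

  expect_error(rates(c(NA, 0), m), "non-finite")
})

test_that("zero kinetic orders contribute exactly 1 even at zero concentration", {
  fx <- feedback_pathway_model()
  rr <- rates(rep(0, 5), fx$model)
  expect_identical(unname(rr["r0"]), 0)    # alpha 0
  # r4 depends only on X4 (floored at 1e-8), others contribute factor 1
  expect_equal(unname(rr["r4"]), 3 * (1e-8)^1)
})

test_that("mass-action limit: unit exponents on substrates give textbook rates", {
  m <- model_from_records(c("A", "B", "C"), character(),
                          list(reaction_record("r1", c(A = 1, B = 1), c(C = 1))),
                          list(kinetics_record("r1", c(A = 1, B = 1))),
                          alpha = c(r1 = 2.5))
  x <- c(A = 0.7, B = 1.3, C = 0.1)
  expect_identical(unname(rates(x, m)["r1"]), 2.5 * 0.7 * 1.3)
})

test_that("the right-hand side adds the external input to S r", {
  m <- one_species_model(alpha = 0, beta = 1, h = 1, x0 = 0)
  # dx/dt = u - x with baseline input 1
  expect_equal(unname(bst_rhs(0, 0.25, m, input = c(X1 = 1))), 0.75)
  # alpha all zero, no input: derivative zero
  m$alpha[] <- 0
  expect_equal(unname(bst_rhs(0, 0.5, m)), 0)

  # pulsed input contributes only to its channel, at pulse value
  fx <- feedback_pathway_model()
  f10 <- bst_rhs(10, rep(0.2, 5), fx$model, fx$input) -
    bst_rhs(10, rep(0.2, 5), fx$model, NULL)
  expect_equal(unname(f10), c(10, 0, 0, 0, 0))
  f20 <- bst_rhs(20, rep(0.2, 5), fx$model, fx$input) -
    bst_rhs(20, rep(0.2, 5), fx$model, NULL)
  expect_equal(unname(f20), c(1, 0, 0, 0, 0))  # back to baseline
})

test_that("input validation rejects unknown channels and overlapping pulses", {
  fx <- feedback_pathway_model()
  expect_error(evaluate(fx$model, c(0, 1), input = c(Z9 = 1)), "Z9")
  expect_error(pulse_schedule(c(X1 = 1),
                              data.frame(species = "X1", start = c(0, 5),
                                         stop = c(6, 10), value = c(1, 2))),
               "overlapping")
  expect_error(pulse_schedule(c(X1 = 1),
                              data.frame(species = "X1", start = 5, stop = 5,
                                         value = 1)),
               "start < stop")
})

test_that("integration reproduces the closed-form relaxation 1 - exp(-t)", {
  m <- one_species_model(alpha = 1, beta = 1, h = 1, x0 = 0)
  traj <- evaluate(m, c(0, 10))
  expect_lt(max(abs(traj$states[, 1] - (1 - exp(-traj$times)))), 1e-6)
  # zero dynamics: constant trajectory at x0
  mz <- one_species_model(alpha = 0, beta = 0, x0 = 0.3)
  trz <- evaluate(mz, c(0, 5))
  expect_true(all(trz$states == 0.3))
})

test_that("compiled and plain-R derivative paths agree", {
  fx <- feedback_pathway_model()
  t1 <- evaluate(fx$model, c(0, 20), fx$input)
  t2 <- evaluate(fx$model, c(0, 20), fx$input, compiled = FALSE)
  expect_equal(t1$states, t2$states, tolerance = 1e-7)
})

test_that("trajectories from non-negative starts stay non-negative", {
  fx <- feedback_pathway_model()
  traj <- evaluate(fx$model, c(0, 50), fx$input)
  expect_true(all(traj$states > -10 * 1e-10))
  br <- evaluate(branched_pathway_model(), c(0, 50))
  expect_true(all(br$states > -10 * 1e-10))
})

test_that("trajectory export writes a time + species CSV", {
  fx <- feedback_pathway_model()
  traj <- evaluate(fx$model, c(0, 1), save_times = seq(0, 1, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  got <- read.csv(path, check.names = FALSE)
  expect_identical(names(got), c("time", paste0("X", 1:5)))
  expect_equal(nrow(got), 3)
})

test_that("dynamic settling finds simple steady states with small residuals", {
  # dx/dt = 2 - x
  m <- one_species_model(alpha = 2, beta = 1, h = 1)
  ss <- steadystate(m)
  expect_equal(as.numeric(ss), 2, tolerance = 1e-6)
  expect_lt(attr(ss, "residual"), 10 * 1e-8)

  # one-species closed form (alpha/beta)^(1/(h-g)): alpha=4, beta=1, h=2
  m2 <- one_species_model(alpha = 4, beta = 1, g = 0, h = 2, x0 = 1)
  expect_equal(as.numeric(steadystate(m2)), 2, tolerance = 1e-6)

  # constant input enters the balance
  m3 <- one_species_model(alpha = 0, beta = 1, h = 1, x0 = 0.1)
  ss3 <- steadystate(m3, input = c(X1 = 3))
  expect_equal(as.numeric(ss3), 3, tolerance = 1e-6)
})

test_that("non-convergent systems raise a typed error carrying the last state", {
  # pure source, no sink: diverges linearly
  m <- model_from_records("X1", character(),
                          list(reaction_record("r0", products = c(X1 = 1))),
                          list(kinetics_record("r0")), alpha = c(r0 = 1))
  err <- tryCatch(steadystate(m, t_max = 100), bst_nonconvergence = function(e) e)
  expect_s3_class(err, "bst_nonconvergence")
  expect_true(is.numeric(err$state) && err$state > 50)
  expect_gt(err$residual, 0.5)
})

test_that("log-linear solve handles identity and closed-form cases", {
  # alpha = beta, G = 0, H = I: steady state is the unit vector
  cs <- classical_ssystem(alpha = c(3, 3), beta = c(3, 3),
                          G = matrix(0, 2, 2), H = diag(2))
  expect_equal(unname(solve_loglinear(cs)), c(1, 1))

  cs2 <- classical_ssystem(alpha = 4, beta = 1, G = matrix(0, 1, 1),
                           H = matrix(2, 1, 1))
  expect_equal(unname(solve_loglinear(cs2)), 2)

  # singular kinetic-order difference
  cs3 <- classical_ssystem(alpha = c(1, 2), beta = c(2, 1),
                           G = matrix(0, 2, 2),
                           H = matrix(c(1, 1, 1, 1), 2, 2))
  expect_error(solve_loglinear(cs3), "degenerate")
})

test_that("settling and the log-linear oracle agree on random classical systems", {
  for (seed in 1:10) {
    cs <- random_classical_ssystem(3 + seed %% 3, seed = seed)
    xa <- solve_loglinear(cs)
    xd <- steadystate(model_from_classical(cs))
    expect_lt(max(abs(xd - xa) / xa), 1e-5)
  }
})
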
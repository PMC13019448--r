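test_that("the exposure integral is exact on constant and linear trajectories", {
  # all rates zero: x(t) = 0.3, integral over [0, 20] = 6
  m <- one_species_model(alpha = 0, beta = 0, x0 = 0.3)
  expect_equal(performance_integral(m, c(0, 20), species = "X1"), 6,
               tolerance = 1e-9)
  # dx/dt = 1, x0 = 0: x(t) = t, integral = 200
  m2 <- model_from_records("X1", character(),
                           list(reaction_record("r0", products = c(X1 = 1))),
                           list(kinetics_record("r0")), alpha = c(r0 = 1))
  expect_equal(performance_integral(m2, c(0, 20), species = "X1"), 200,
               tolerance = 1e-6)
  expect_error(performance_integral(m2, c(0, 20), species = "Z"), "unknown species")
})

test_that("the unscrambled Sobol' sequence matches its reference values", {
  # first points of the standard sequence (radical inverse in base 2 for the
  # first coordinate; direction-number recursion beyond)
  p <- sobol_points(8, 3, scramble = FALSE)
  expect_equal(p[, 1], c(0, 1, 3, 1, 3, 7, 5, 1) / c(1, 2, 4, 4, 8, 8, 8, 8))
  expect_equal(p[1:4, 2], c(0, 0.5, 0.25, 0.75))
  expect_equal(p[1:4, 3], c(0, 0.5, 0.25, 0.75))
  expect_equal(p[5:8, 3], c(0.625, 0.125, 0.875, 0.375))
  # scrambled points remain equidistributed over dyadic halves
  ps <- sobol_points(256, 5, seed = 1)
  expect_true(all(abs(colMeans(ps) - 0.5) < 0.01))
})

test_that("Morris recovers constant effects for linear functions", {
  res <- morris(function(th) 3 * th[1] + 0 * th[2],
                lower = c(0, 0), upper = c(1, 1), r = 20, seed = 1)
  expect_equal(unname(res$mu_star[1]), 3, tolerance = 1e-10)
  expect_equal(unname(res$mu[1]), 3, tolerance = 1e-10)
  expect_equal(unname(res$sigma2[1]), 0, tolerance = 1e-10)
  expect_equal(unname(res$mu_star[2]), 0, tolerance = 1e-10)
  # mu* >= |mu| always
  expect_true(all(res$mu_star >= abs(res$mu) - 1e-12))
})

test_that("Morris flags interactions through the effect variance", {
  res <- morris(function(th) th[1] * th[2],
                lower = c(0, 0), upper = c(1, 1), r = 50, seed = 2)
  expect_gt(unname(res$sigma2[1]), 0.01)
})

test_that("Morris elementary effects are measured per unit of normalized span", {
  # f = theta1 on [0, 10]: d f / d(normalized theta) = 10
  res <- morris(function(th) th[1], lower = 0, upper = 10, r = 5, seed = 3)
  expect_equal(unname(res$mu_star[1]), 10, tolerance = 1e-10)
})

test_that("Sobol indices are analytic for additive functions", {
  # f = th1 + 2 th2, U(0,1): S1 = ST = (0.2, 0.8)
  res <- sobol(function(th) th[1] + 2 * th[2], lower = c(0, 0),
               upper = c(1, 1), N = 512, seed = 4, bootstrap = 50)
  expect_equal(unname(res$S1), c(0.2, 0.8), tolerance = 0.02)
  expect_equal(unname(res$ST), c(0.2, 0.8), tolerance = 0.02)
  # additive: S1 == ST per parameter
  expect_equal(res$S1, res$ST, tolerance = 0.02)
  # CI columns bracket the estimates
  expect_true(all(res$S1 >= res$S1_ci[, 1] - 1e-9 & res$S1 <= res$S1_ci[, 2] + 1e-9))
})

test_that("Sobol indices match the closed-form Ishigami decomposition", {
  truth <- ishigami_indices()
  res <- sobol(ishigami, lower = rep(-pi, 3), upper = rep(pi, 3),
               N = 4096, seed = 5, bootstrap = 0)
  expect_equal(unname(res$S1), truth$S1, tolerance = 0.02)
  expect_equal(unname(res$ST), truth$ST, tolerance = 0.02)
  # structural invariants at CI slack
  expect_lte(sum(res$S1), 1 + 0.05)
  expect_true(all(res$ST >= res$S1 - 0.05))
})

test_that("sensitivity summaries are invariant to scaling and shifts of f", {
  f <- function(th) th[1] + 2 * th[2]
  s1 <- sobol(f, c(0, 0), c(1, 1), N = 256, seed = 6, bootstrap = 0)
  s2 <- sobol(function(th) 5 * f(th), c(0, 0), c(1, 1), N = 256, seed = 6,
              bootstrap = 0)
  s3 <- sobol(function(th) f(th) + 100, c(0, 0), c(1, 1), N = 256, seed = 6,
              bootstrap = 0)
  expect_equal(s1$S1, s2$S1, tolerance = 1e-12)
  expect_equal(s1$ST, s2$ST, tolerance = 1e-12)
  expect_equal(s1$S1, s3$S1, tolerance = 1e-9)

  m1 <- morris(f, c(0, 0), c(1, 1), r = 10, seed = 7)
  m2 <- morris(function(th) f(th) + 100, c(0, 0), c(1, 1), r = 10, seed = 7)
  expect_equal(m1$mu, m2$mu, tolerance = 1e-9)
  expect_equal(m1$mu_star, m2$mu_star, tolerance = 1e-9)
  expect_equal(m1$sigma2, m2$sigma2, tolerance = 1e-9)
})

test_that("fixed seeds give bit-identical sensitivity results", {
  f <- function(th) th[1]^2 + th[2]
  a <- sobol(f, c(0, 0), c(1, 1), N = 128, seed = 8, bootstrap = 20)
  b <- sobol(f, c(0, 0), c(1, 1), N = 128, seed = 8, bootstrap = 20)
  expect_identical(a$S1, b$S1)
  expect_identical(a$ST, b$ST)
  expect_identical(a$S1_ci, b$S1_ci)
  ma <- morris(f, c(0, 0), c(1, 1), r = 10, seed = 9)
  mb <- morris(f, c(0, 0), c(1, 1), r = 10, seed = 9)
  expect_identical(ma$mu, mb$mu)
  expect_identical(ma$sigma2, mb$sigma2)
})

test_that("zero-variance outputs report zero indices with a warning", {
  expect_warning(res <- sobol(function(th) 1, c(0, 0), c(1, 1), N = 64,
                              seed = 10, bootstrap = 0),
                 "variance")
  expect_true(all(res$S1 == 0) && all(res$ST == 0))
  expect_true(res$zero_variance)
})

test_that("widespread evaluation failures abort the analysis", {
  f_bad <- function(th) if (th[1] > 0.2) stop("boom") else 1
  expect_error(sobol(f_bad, c(0, 0), c(1, 1), N = 64, seed = 11),
               "failed")
  expect_error(morris(f_bad, c(0, 0), c(1, 1), r = 10, seed = 11),
               "failed")
})

test_that("parameter maps modify copies, never the originals", {
  g <- feedback_gsa_problem()
  theta <- g$nominal
  theta["alpha_r4"] <- 99
  mi <- apply_parameters(g$model, g$input, g$pmap, theta)
  expect_equal(unname(mi$model$alpha["r4"]), 99)
  expect_equal(unname(g$model$alpha["r4"]), 3)  # original untouched
  # input gain rescales baseline and pulse values together
  theta2 <- g$nominal; theta2["alpha_r0"] <- 0.5
  mi2 <- apply_parameters(g$model, g$input, g$pmap, theta2)
  expect_equal(unname(mi2$input$baseline["X1"]), 0.5)
  expect_equal(mi2$input$pulses$value, c(5, 2.5))
  expect_error(parameter_map(g$model, list(list(kind = "alpha", reaction = "rX")),
                             0, 1), "rX")
})

test_that("sensitivity results export to CSV and JSON", {
  res <- morris(function(th) th[1], c(0, 0), c(1, 1), r = 4, seed = 12)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sensitivity(res, csv)
  write_sensitivity(res, js)
  got <- read.csv(csv)
  expect_identical(names(got), c("parameter", "mu", "mu_star", "sigma2"))
  expect_equal(nrow(got), 2)
  expect_length(jsonlite::fromJSON(js, simplifyVector = FALSE), 2)
})
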
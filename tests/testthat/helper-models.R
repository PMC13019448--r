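# Small builders used across test files.

# One-species generalized model: source with rate alpha (order g on X1) and
# sink with rate beta (order h on X1), dx/dt = alpha*x^g - beta*x^h.
one_species_model <- function(alpha, beta, g = 0, h = 1, x0 = 0) {
  deps_src <- if (g != 0) c(X1 = g) else NULL
  model_from_records(
    "X1", character(),
    list(reaction_record("src", products = c(X1 = 1)),
         reaction_record("snk", reactants = c(X1 = 1))),
    list(kinetics_record("src", deps_src),
         kinetics_record("snk", c(X1 = h))),
    alpha = c(src = alpha, snk = beta),
    x0 = c(X1 = x0))
}

# The worked two-species example: r1: X1 -> X2 with kinetics X1^1 E1^1.
two_species_records <- function() {
  list(dynamic = c("X1", "X2"), static = "E1",
       reactions = list(reaction_record("r1", c(X1 = 1), c(X2 = 1))),
       kinetics = list(kinetics_record("r1", c(X1 = 1, E1 = 1))))
}

extdata <- function(file) system.file("extdata", file, package = "bstkit")

# Ishigami test function and its analytic Sobol indices (the standard
# variance decomposition computed in closed form, independent of the
# estimators under test).
ishigami <- function(th, a = 7, b = 0.1) {
  sin(th[1]) + a * sin(th[2])^2 + b * th[3]^4 * sin(th[1])
}

ishigami_indices <- function(a = 7, b = 0.1) {
  V1 <- (1 + b * pi^4 / 5)^2 / 2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(S1 = c(V1, V2, 0) / V, ST = c(V1 + V13, V2, V13) / V)
}
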
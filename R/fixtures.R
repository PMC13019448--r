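# Example models: a five-species feedback-inhibited linear pathway driven by
# a pulsed input, a branched pathway with dual feedback, and seeded random
# model generators for property testing. Builders are deterministic.

#' Feedback-inhibited linear pathway with pulsed input
#'
#' Five dynamic species X1..X5: a precursor X1 is converted through X2 and X3
#' to the product X4, with a branch producing byproduct X5 from X3 (no
#' degradation, so X5 ratchets upward). Static enzymes E1, E2, E3 (all 1.0)
#' catalyze r1, r2, r3. The product X4 feedback-inhibits r1 with kinetic
#' order -0.5. Rate constants: alpha(r1) = alpha(r2) = alpha(r3) = 10,
#' alpha(r5) = 0.1, alpha(r4) = 3, and alpha(r0) = 0 — the source flux into
#' X1 is delivered instead through the external input channel u1(t):
#' baseline 1, a high pulse (10) on t in \[5, 15), and a medium pulse (5) on
#' t in \[25, 35). Initial conditions are 0.1 for all species (small and
#' strictly positive relative to responses of order 1-3).
#'
#' @param x0 Initial concentration used for all five species (default 0.1).
#' @return List with elements `model` (a [bst_model()]) and `input` (a
#'   [pulse_schedule()]).
#' @examples
#' fx <- feedback_pathway_model()
#' fx$model$G["X4", "r1"]  # -0.5
#' @export
feedback_pathway_model <- function(x0 = 0.1) {
  dyn <- paste0("X", 1:5)
  sta <- paste0("E", 1:3)
  reactions <- list(
    reaction_record("r0", products = c(X1 = 1)),
    reaction_record("r1", reactants = c(X1 = 1), products = c(X2 = 1)),
    reaction_record("r2", reactants = c(X2 = 1), products = c(X3 = 1)),
    reaction_record("r3", reactants = c(X3 = 1), products = c(X4 = 1)),
    reaction_record("r4", reactants = c(X4 = 1)),
    reaction_record("r5", reactants = c(X3 = 1), products = c(X5 = 1)))
  kinetics <- list(
    kinetics_record("r0"),
    kinetics_record("r1", c(X1 = 1, E1 = 1, X4 = -0.5)),
    kinetics_record("r2", c(X2 = 1, E2 = 1)),
    kinetics_record("r3", c(X3 = 1, E3 = 1)),
    kinetics_record("r4", c(X4 = 1)),
    kinetics_record("r5", c(X3 = 1)))
  model <- model_from_records(
    dyn, sta, reactions, kinetics,
    alpha = c(r0 = 0, r1 = 10, r2 = 10, r3 = 10, r4 = 3, r5 = 0.1),
    x0 = stats::setNames(rep(x0, 5), dyn),
    xs = c(E1 = 1, E2 = 1, E3 = 1),
    metadata = list(author = "bstkit", version = "1.0",
                    description = "feedback-inhibited linear pathway"))
  input <- pulse_schedule(
    baseline = c(X1 = 1),
    pulses = data.frame(species = "X1", start = c(5, 25), stop = c(15, 35),
                        value = c(10, 5)))
  list(model = model, input = input)
}

#' Branched pathway with dual feedback inhibition
#'
#' A source produces A, converted to B then C, where the pathway branches:
#' C -> D via r3 (catalyzed by enzyme E3) or C -> E via r4 (catalyzed by
#' E4); D and E are degraded first-order by r5 and r6. Two feedback loops:
#' E inhibits r1 and D inhibits r2, both with kinetic order -0.5 — the
#' topology of a biosynthetic branch point. Rate constants default to 1.0
#' for every reaction (the branch behavior of interest — flux
#' redistribution as E3 varies — is qualitative and does not depend on
#' their values).
#'
#' @param alpha Named rate constants (default: all 1).
#' @param E3,E4 Static branch enzyme levels.
#' @param x0 Initial concentration for all five dynamic species.
#' @return A [bst_model()].
#' @export
branched_pathway_model <- function(alpha = NULL, E3 = 1, E4 = 1, x0 = 0.1) {
  dyn <- c("A", "B", "C", "D", "E")
  sta <- c("E3", "E4")
  reactions <- list(
    reaction_record("r0", products = c(A = 1)),
    reaction_record("r1", reactants = c(A = 1), products = c(B = 1)),
    reaction_record("r2", reactants = c(B = 1), products = c(C = 1)),
    reaction_record("r3", reactants = c(C = 1), products = c(D = 1)),
    reaction_record("r4", reactants = c(C = 1), products = c(E = 1)),
    reaction_record("r5", reactants = c(D = 1)),
    reaction_record("r6", reactants = c(E = 1)))
  kinetics <- list(
    kinetics_record("r0"),
    kinetics_record("r1", c(A = 1, E = -0.5)),
    kinetics_record("r2", c(B = 1, D = -0.5)),
    kinetics_record("r3", c(C = 1, E3 = 1)),
    kinetics_record("r4", c(C = 1, E4 = 1)),
    kinetics_record("r5", c(D = 1)),
    kinetics_record("r6", c(E = 1)))
  a <- stats::setNames(rep(1, 7), paste0("r", 0:6))
  if (!is.null(alpha)) a[names(alpha)] <- alpha
  if (any(a <= 0)) stop("branched pathway rate constants must be positive", call. = FALSE)
  model_from_records(
    dyn, sta, reactions, kinetics,
    alpha = a,
    x0 = stats::setNames(rep(x0, 5), dyn),
    xs = c(E3 = E3, E4 = E4),
    metadata = list(author = "bstkit", version = "1.0",
                    description = "branched pathway with dual feedback"))
}

#' Seeded random model generator
#'
#' Generates a random but well-formed model for property tests: reactions
#' form a cycle through the dynamic species (so the reaction graph is
#' connected), each reaction depends on its substrate with a kinetic order
#' drawn from \[-1, 1\] and, with probability 1/2, on a random static
#' species; rate constants are drawn from \[0.5, 5\]. With
#' `representable = TRUE` the generator instead emits one producing and one
#' consuming reaction per species (`p` is then fixed at `2 n`), so
#' [classical_from_model()] always succeeds.
#'
#' @param n,m,p Numbers of dynamic species, static species, reactions.
#' @param seed Integer seed; the same seed reproduces the same model.
#' @param representable Generate a classically representable topology.
#' @return A validated [bst_model()].
#' @export
random_model <- function(n, m = 1L, p = max(2L, n), seed = 1L,
                         representable = FALSE) {
  stopifnot(n >= 1, m >= 1, p >= 1)
  set.seed(seed)
  dyn <- paste0("X", seq_len(n))
  sta <- paste0("E", seq_len(m))
  reactions <- list(); kinetics <- list(); alpha <- numeric(0)
  if (representable) {
    for (i in seq_len(n)) {
      sp <- dyn[i]
      rp <- paste0("prod_", sp); rd <- paste0("deg_", sp)
      reactions[[length(reactions) + 1L]] <- reaction_record(rp, products = stats::setNames(1, sp))
      reactions[[length(reactions) + 1L]] <- reaction_record(rd, reactants = stats::setNames(1, sp))
      src <- dyn[if (i == 1) n else i - 1]
      kinetics[[length(kinetics) + 1L]] <-
        kinetics_record(rp, stats::setNames(stats::runif(1, -1, 1), src))
      kinetics[[length(kinetics) + 1L]] <-
        kinetics_record(rd, stats::setNames(stats::runif(1, 0.5, 1), sp))
      alpha[rp] <- stats::runif(1, 0.5, 5); alpha[rd] <- stats::runif(1, 0.5, 5)
    }
  } else {
    for (k in seq_len(p)) {
      rn <- paste0("r", k)
      sub <- dyn[1 + (k - 1) %% n]
      prd <- dyn[1 + k %% n]
      reactions[[k]] <- if (identical(sub, prd))
        reaction_record(rn, reactants = stats::setNames(1, sub))
      else
        reaction_record(rn, reactants = stats::setNames(1, sub),
                        products = stats::setNames(1, prd))
      deps <- stats::setNames(stats::runif(1, -1, 1), sub)
      if (stats::runif(1) < 0.5) {
        es <- sample(sta, 1)
        deps[es] <- stats::runif(1, -1, 1)
      }
      kinetics[[k]] <- kinetics_record(rn, deps)
      alpha[rn] <- stats::runif(1, 0.5, 5)
    }
  }
  model_from_records(
    dyn, sta, reactions, kinetics,
    alpha = alpha,
    x0 = stats::setNames(stats::runif(n, 0.5, 2), dyn),
    xs = stats::setNames(stats::runif(m, 0.5, 2), sta))
}

#' Seeded random classical S-system
#'
#' Draws a well-conditioned classical S-system for cross-checking the
#' dynamic-settling steady state against the log-linear algebraic solution:
#' rate constants in \[0.5, 5\], self-consumption orders h_ii in
#' \[0.5, 1.5\], sparse off-diagonal production orders in \[-0.4, 0.4\]
#' (keeping A = G - H diagonally dominant, hence nonsingular, well
#' conditioned, and dynamically stable), and one static species with a
#' random order on each production term.
#'
#' @param n Number of dynamic species.
#' @param seed Integer seed.
#' @return A [classical_ssystem()].
#' @export
random_classical_ssystem <- function(n, seed = 1L) {
  set.seed(seed)
  dyn <- paste0("X", seq_len(n))
  G <- matrix(0, n, n + 1)
  H <- matrix(0, n, n + 1)
  for (i in seq_len(n)) {
    H[i, i] <- stats::runif(1, 0.5, 1.5)
    j <- sample(setdiff(seq_len(n), i), 1)
    if (n > 1) G[i, j] <- stats::runif(1, -0.4, 0.4)
    G[i, n + 1] <- stats::runif(1, -1, 1)
  }
  classical_ssystem(alpha = stats::runif(n, 0.5, 5), beta = stats::runif(n, 0.5, 5),
                    G = G, H = H, dynamic_species = dyn,
                    static_species = "E1", xs = c(E1 = stats::runif(1, 0.5, 2)))
}

#' The seven-parameter sensitivity problem for the feedback pathway
#'
#' Bundles the feedback pathway, its pulsed input, and the parameter map for
#' the canonical global sensitivity study of the time-integrated product
#' exposure J = integral of X4 over \[0, 20\] (the window containing the
#' first input pulse). The seven parameters are the rate constants of
#' r1..r5 at +/-50\% of their nominal values, the source gain on the input
#' channel u1 (labelled `alpha_r0`; the source flux enters through u(t), so
#' its magnitude is a gain on that channel, nominal 1, bounds \[0.5, 1.5\])
#' and the feedback kinetic order of X4 on r1, varied over \[-2, 0\].
#'
#' @param t_upper Upper limit of the exposure integral (default 20).
#' @param rtol,atol Integrator tolerances for objective evaluations.
#' @return List with `model`, `input`, `pmap` (a [parameter_map()]), `f`
#'   (the scalar objective for [morris()] / [sobol()]), `lower`, `upper`,
#'   and `nominal`.
#' @export
feedback_gsa_problem <- function(t_upper = 20, rtol = 1e-8, atol = 1e-10) {
  fx <- feedback_pathway_model()
  targets <- list(
    list(kind = "input_scale", species = "X1", name = "alpha_r0"),
    list(kind = "alpha", reaction = "r1"),
    list(kind = "alpha", reaction = "r2"),
    list(kind = "alpha", reaction = "r3"),
    list(kind = "alpha", reaction = "r4"),
    list(kind = "alpha", reaction = "r5"),
    list(kind = "kinetic_order", species = "X4", reaction = "r1"))
  nominal <- c(alpha_r0 = 1, alpha_r1 = 10, alpha_r2 = 10, alpha_r3 = 10,
               alpha_r4 = 3, alpha_r5 = 0.1, g_X4_r1 = -0.5)
  lower <- c(0.5 * nominal[1:6], g_X4_r1 = -2)
  upper <- c(1.5 * nominal[1:6], g_X4_r1 = 0)
  pmap <- parameter_map(fx$model, targets, lower, upper)
  f <- gsa_objective(fx$model, fx$input, pmap, species = "X4",
                     tspan = c(0, t_upper), t_upper = t_upper,
                     rtol = rtol, atol = atol)
  list(model = fx$model, input = fx$input, pmap = pmap, f = f,
       lower = pmap$lower, upper = pmap$upper, nominal = nominal)
}
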
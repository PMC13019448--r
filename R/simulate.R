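#' Power-law reaction rates
#'
#' Evaluates r_k = alpha_k * prod_j X_j^G\[j,k\] over the concatenated vector
#' of dynamic and static species concentrations. Concentrations are floored
#' at `eps` before exponentiation so that negative kinetic orders remain
#' finite near zero; species with a zero kinetic order contribute a factor of
#' exactly 1 even at zero concentration.
#'
#' @param x Numeric vector of dynamic species concentrations (length n).
#' @param model A [bst_model()].
#' @param eps Concentration floor used inside the power law (default 1e-8).
#'   The state itself is never clamped.
#' @return Named numeric vector of p reaction rates (all >= 0).
#' @examples
#' m <- model_from_records("X1", character(),
#'   list(reaction_record("r0", products = c(X1 = 1))),
#'   list(kinetics_record("r0")), alpha = c(r0 = 10))
#' rates(0, m)  # constant source: 10
#' @export
rates <- function(x, model, eps = 1e-8) {
  if (any(!is.finite(x)))
    stop("non-finite concentration passed to rates()", call. = FALSE)
  X <- pmax(c(as.numeric(x), model$xs), eps)
  r <- model$alpha * exp(drop(crossprod(model$G, log(X))))
  stats::setNames(r, model$reaction_names)
}

#' Model right-hand side
#'
#' The time derivative of the dynamic state, dx/dt = S r(x, xs) + u(t).
#'
#' @inheritParams rates
#' @param t Time (used only to evaluate a pulsed input).
#' @param input `NULL` (u = 0), a constant input vector, or a
#'   [pulse_schedule()].
#' @return Named numeric vector dx/dt of length n.
#' @export
bst_rhs <- function(t, x, model, input = NULL, eps = 1e-8) {
  u <- input_vector(input, t, model)
  drop(model$S %*% rates(x, model, eps)) + u
}

# Pack the model (and a constant input vector u) into the flat double vector
# consumed by the compiled derivative routine.
pack_model <- function(model, u, eps) {
  n <- length(model$dynamic_species); m <- length(model$static_species)
  p <- length(model$reaction_names)
  as.double(c(n, m, p, eps, model$S, model$G, model$alpha, model$xs, u))
}

# Integrate over one segment with constant input, returning the deSolve
# output matrix. Uses the compiled power-law rhs unless compiled = FALSE.
integrate_segment <- function(model, x, times, u, rtol, atol, eps, compiled) {
  if (compiled) {
    .Call("c_bst_set_model", pack_model(model, u, eps), PACKAGE = "bstkit")
    out <- deSolve::lsoda(y = as.numeric(x), times = times, func = "c_bst_derivs",
                          dllname = "bstkit", initfunc = NULL, parms = NULL,
                          rtol = rtol, atol = atol)
  } else {
    derivs <- function(t, y, parms) list(drop(model$S %*% rates(y, model, eps)) + u)
    out <- deSolve::lsoda(y = as.numeric(x), times = times, func = derivs,
                          parms = NULL, rtol = rtol, atol = atol)
  }
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0)
    stop(bst_numeric_error(sprintf(
      "ODE integration failed (istate = %d); last successful time %.6g",
      istate, out[nrow(out), 1])))
  if (any(!is.finite(out[, -1, drop = FALSE])))
    stop(bst_numeric_error("ODE integration produced non-finite states (blow-up)"))
  out
}

bst_numeric_error <- function(msg, ...) {
  structure(class = c("bst_numeric_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), ...))
}

#' Simulate the model dynamics
#'
#' Adaptive-step integration (lsoda: switches automatically between stiff and
#' non-stiff methods) of dx/dt = S r(x, xs) + u(t). When the input is a pulse
#' schedule the integration is restarted exactly at every pulse edge, so the
#' solver never steps across a discontinuity of u(t).
#'
#' @param model A [bst_model()].
#' @param tspan Numeric length-2 vector `(t0, tf)`, `t0 < tf`.
#' @param input `NULL`, a constant input vector, or a [pulse_schedule()].
#' @param save_times Times at which to record the state (default: 1001
#'   uniform points across `tspan`).
#' @param rtol,atol Integrator tolerances (defaults 1e-8 and 1e-10).
#' @param eps Concentration floor inside the power law.
#' @param compiled Use the compiled derivative routine (default `TRUE`; the
#'   plain-R path is retained as a reference implementation).
#' @return A `bst_trajectory`: list with `times` and a `|times| x n` state
#'   matrix `states` (columns named by species).
#' @examples
#' fx <- feedback_pathway_model()
#' traj <- evaluate(fx$model, c(0, 50), fx$input)
#' max(traj$states[, "X4"])
#' @export
evaluate <- function(model, tspan = c(0, 50), input = NULL, save_times = NULL,
                     rtol = 1e-8, atol = 1e-10, eps = 1e-8, compiled = TRUE) {
  stopifnot(length(tspan) == 2, tspan[1] < tspan[2])
  t0 <- tspan[1]; tf <- tspan[2]
  if (is.null(save_times)) save_times <- seq(t0, tf, length.out = 1001L)
  if (any(save_times < t0) || any(save_times > tf))
    stop("save_times must lie within tspan", call. = FALSE)
  save_times <- sort(unique(as.numeric(save_times)))
  input_vector(input, t0, model)  # validates channel names early
  breaks <- schedule_breaks(input, t0, tf)
  seg_edges <- unique(c(t0, breaks, tf))

  n <- length(model$dynamic_species)
  states <- matrix(NA_real_, length(save_times), n,
                   dimnames = list(NULL, model$dynamic_species))
  x <- model$x0
  if (length(save_times) && save_times[1] == t0) states[1, ] <- x
  for (s in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[s]; b <- seg_edges[s + 1L]
    idx <- which(save_times > a & save_times <= b)
    times <- unique(c(a, save_times[idx], b))
    u <- input_vector(input, (a + b) / 2, model)
    out <- integrate_segment(model, x, times, u, rtol, atol, eps, compiled)
    if (length(idx))
      states[idx, ] <- out[match(save_times[idx], out[, 1]), -1, drop = FALSE]
    x <- out[nrow(out), -1]
  }
  structure(list(times = save_times, states = states,
                 species = model$dynamic_species),
            class = "bst_trajectory")
}

#' @export
print.bst_trajectory <- function(x, ...) {
  cat(sprintf("<bst_trajectory> %d time points on [%g, %g], species: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.bst_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write a trajectory to CSV
#'
#' Header row is `time,<species...>`.
#'
#' @param traj A `bst_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Steady state by dynamic settling
#'
#' Integrates the ODE system forward in time (in geometrically growing
#' blocks) until the derivatives are sufficiently small:
#' `||dx/dt||_inf < tau_abs + tau_rel * ||x||_inf`. This is robust for
#' power-law systems where a direct algebraic solution is intractable; for
#' the classical subclass, [solve_loglinear()] gives the algebraic answer.
#'
#' @param model A [bst_model()].
#' @param input `NULL` or a constant input vector (named or length n).
#' @param x0 Optional starting state (default: the model's `x0`).
#' @param tau_abs,tau_rel Settling tolerances (defaults 1e-8, 1e-6).
#' @param t_max Give up after this much integration time (default 1e6).
#' @param rtol,atol,eps,compiled Passed to the integrator, see [evaluate()].
#' @return Named steady-state vector with attributes `residual`
#'   (`||S r + u||_inf` at the returned state) and `time` (settling time).
#'   If no steady state is reached by `t_max`, an error of class
#'   `bst_nonconvergence` is signalled carrying the last `state` and
#'   `residual` (sustained oscillation or divergence).
#' @examples
#' m <- model_from_records("X1", character(),
#'   list(reaction_record("r0", products = c(X1 = 1)),
#'        reaction_record("r1", reactants = c(X1 = 1))),
#'   list(kinetics_record("r0"), kinetics_record("r1", c(X1 = 1))),
#'   alpha = c(r0 = 2, r1 = 1))
#' steadystate(m)  # dx/dt = 2 - x  =>  x = 2
#' @export
steadystate <- function(model, input = NULL, x0 = NULL,
                        tau_abs = 1e-8, tau_rel = 1e-6, t_max = 1e6,
                        rtol = 1e-8, atol = 1e-10, eps = 1e-8, compiled = TRUE) {
  if (!is.null(input) && !is.numeric(input))
    stop("steadystate() takes a constant input vector (or NULL)", call. = FALSE)
  u <- input_vector(input, 0, model)
  x <- if (is.null(x0)) model$x0 else stats::setNames(as.numeric(x0), model$dynamic_species)
  t_done <- 0; span <- 10
  repeat {
    span <- min(span, t_max - t_done)
    out <- integrate_segment(model, x, c(0, span), u, rtol, atol, eps, compiled)
    x <- stats::setNames(out[nrow(out), -1], model$dynamic_species)
    t_done <- t_done + span
    f <- drop(model$S %*% rates(x, model, eps)) + u
    res <- max(abs(f))
    if (res < tau_abs + tau_rel * max(abs(x))) {
      attr(x, "residual") <- res
      attr(x, "time") <- t_done
      return(x)
    }
    if (t_done >= t_max)
      stop(structure(class = c("bst_nonconvergence", "bst_numeric_error",
                               "error", "condition"),
                     list(message = sprintf(
                       "no steady state by t = %g (residual %.3g): sustained oscillation or divergence",
                       t_max, res), call = sys.call(), state = x, residual = res)))
    span <- span * 5
  }
}

#' Algebraic steady state of a classical S-system
#'
#' At steady state the production and consumption terms balance, and taking
#' logarithms turns the power laws into the linear system A y = b with
#' A = (G - H) restricted to dynamic species columns, y = ln x, and
#' b_i = ln(beta_i / alpha_i) - sum over static species of (g - h) ln(xs).
#'
#' @param cs A [classical_ssystem()].
#' @return Named steady-state concentration vector exp(y).
#' @examples
#' cs <- classical_ssystem(alpha = 4, beta = 1,
#'                         G = matrix(0, 1, 1), H = matrix(2, 1, 1))
#' solve_loglinear(cs)  # (alpha/beta)^(1/(h-g)) = 2
#' @export
solve_loglinear <- function(cs) {
  stopifnot(inherits(cs, "bst_classical"))
  A <- cs$G - cs$H
  Ad <- A[, seq_len(cs$n), drop = FALSE]
  b <- log(cs$beta / cs$alpha)
  if (cs$m > 0) {
    As <- A[, cs$n + seq_len(cs$m), drop = FALSE]
    b <- b - drop(As %*% log(cs$xs))
  }
  if (rcond(Ad) < .Machine$double.eps * 100)
    stop("degenerate steady state: kinetic-order difference matrix (G - H) is singular",
         call. = FALSE)
  y <- solve(Ad, b)
  stats::setNames(exp(y), cs$dynamic_species)
}
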
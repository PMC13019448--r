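#' Map sensitivity parameters onto model quantities
#'
#' A parameter map names the model quantities that a sensitivity analysis
#' varies, together with finite bounds. Supported target kinds:
#' \describe{
#'   \item{`alpha`}{a reaction's rate constant (field `reaction`)}
#'   \item{`kinetic_order`}{one entry of G (fields `species`, `reaction`)}
#'   \item{`static_value`}{a static species concentration (field `species`)}
#'   \item{`initial`}{an initial condition (field `species`)}
#'   \item{`input_scale`}{a multiplicative gain on one channel of the
#'     external input u(t) (field `species`); used when a source flux is
#'     delivered through the input rather than through a reaction}
#' }
#'
#' @param model The model the targets must resolve in.
#' @param targets List of target descriptors, each a list with a `kind`
#'   field and the fields listed above. An optional `name` overrides the
#'   auto-generated parameter label.
#' @param lower,upper Numeric bounds, one per target (finite, lower < upper).
#' @return A `bst_parameter_map`.
#' @seealso [apply_parameters()], [gsa_objective()]
#' @export
parameter_map <- function(model, targets, lower, upper) {
  d <- length(targets)
  stopifnot(length(lower) == d, length(upper) == d,
            all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  nm <- character(d)
  for (i in seq_len(d)) {
    tg <- targets[[i]]
    kind <- tg$kind
    nm[i] <- switch(kind,
      alpha = {
        if (!(tg$reaction %in% model$reaction_names))
          stop(sprintf("parameter %d: unknown reaction '%s'", i, tg$reaction), call. = FALSE)
        paste0("alpha_", tg$reaction)
      },
      kinetic_order = {
        if (!(tg$species %in% rownames(model$G)))
          stop(sprintf("parameter %d: unknown species '%s'", i, tg$species), call. = FALSE)
        if (!(tg$reaction %in% model$reaction_names))
          stop(sprintf("parameter %d: unknown reaction '%s'", i, tg$reaction), call. = FALSE)
        paste0("g_", tg$species, "_", tg$reaction)
      },
      static_value = {
        if (!(tg$species %in% model$static_species))
          stop(sprintf("parameter %d: unknown static species '%s'", i, tg$species), call. = FALSE)
        paste0("xs_", tg$species)
      },
      initial = {
        if (!(tg$species %in% model$dynamic_species))
          stop(sprintf("parameter %d: unknown dynamic species '%s'", i, tg$species), call. = FALSE)
        paste0("x0_", tg$species)
      },
      input_scale = {
        if (!(tg$species %in% model$dynamic_species))
          stop(sprintf("parameter %d: unknown dynamic species '%s'", i, tg$species), call. = FALSE)
        paste0("u_", tg$species)
      },
      stop(sprintf("parameter %d: unknown kind '%s'", i, kind), call. = FALSE))
    if (!is.null(tg$name)) nm[i] <- tg$name
  }
  structure(list(targets = targets,
                 names = nm,
                 lower = stats::setNames(as.numeric(lower), nm),
                 upper = stats::setNames(as.numeric(upper), nm)),
            class = "bst_parameter_map")
}

#' Apply a parameter vector to a model and input
#'
#' Returns a modified deep copy; the original model and input are never
#' mutated, so evaluations are pure and may run in any order.
#'
#' @param model A [bst_model()].
#' @param input The input specification the simulation will use (may be
#'   `NULL` if no `input_scale` target is present).
#' @param pmap A [parameter_map()].
#' @param theta Numeric parameter vector (natural units, length = number of
#'   targets).
#' @return List with modified `model` and `input`.
#' @export
apply_parameters <- function(model, input, pmap, theta) {
  stopifnot(inherits(pmap, "bst_parameter_map"),
            length(theta) == length(pmap$targets))
  for (i in seq_along(pmap$targets)) {
    tg <- pmap$targets[[i]]
    v <- theta[i]
    switch(tg$kind,
      alpha = { model$alpha[tg$reaction] <- v },
      kinetic_order = { model$G[tg$species, tg$reaction] <- v },
      static_value = { model$xs[tg$species] <- v },
      initial = { model$x0[tg$species] <- v },
      input_scale = {
        if (is.null(input))
          stop("input_scale parameter requires a non-NULL input", call. = FALSE)
        input <- scale_input(input, tg$species, v)
      })
  }
  list(model = model, input = input)
}

#' Build a scalar sensitivity objective from a model
#'
#' Returns a function theta -> J suitable for [morris()] and [sobol()],
#' where J is the time-integrated concentration of one species
#' ([performance_integral()]) after applying theta through a parameter map.
#' If the ODE solve fails at an extreme parameter corner, the evaluation is
#' retried once with 10x tighter integrator tolerances before the failure is
#' propagated (the samplers then record the point as missing).
#'
#' @inheritParams apply_parameters
#' @param species Species whose exposure is integrated.
#' @param tspan Integration window.
#' @param t_upper Upper limit of the integral (default `tspan[2]`).
#' @param rtol,atol Integrator tolerances for the objective evaluations.
#' @return A function of a numeric parameter vector returning a scalar.
#' @export
gsa_objective <- function(model, input, pmap, species, tspan = c(0, 20),
                          t_upper = tspan[2], rtol = 1e-8, atol = 1e-10) {
  force(model); force(input); force(pmap)
  function(theta) {
    mi <- apply_parameters(model, input, pmap, theta)
    tryCatch(
      performance_integral(mi$model, tspan, mi$input, species, t_upper,
                           rtol = rtol, atol = atol),
      error = function(e)
        performance_integral(mi$model, tspan, mi$input, species, t_upper,
                             rtol = rtol / 10, atol = atol / 10))
  }
}
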
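#' Piecewise-constant pulsed input schedule
#'
#' Describes the external input u(t) of the model dynamics as a baseline value
#' per input channel (one channel per dynamic species) plus square pulses.
#' During a pulse the channel takes the pulse `value` (it replaces, not adds
#' to, the baseline); outside all pulses the channel sits at its baseline.
#' Pulses are half-open intervals `[start, stop)` and may not overlap within
#' a channel. Channels not mentioned have baseline 0.
#'
#' @param baseline Named numeric vector of baseline values by species.
#' @param pulses Data frame with columns `species`, `start`, `stop`, `value`
#'   (or `NULL` for a constant schedule).
#' @return An object of class `bst_schedule`.
#' @examples
#' pulse_schedule(c(X1 = 1),
#'                data.frame(species = "X1", start = c(5, 25),
#'                           stop = c(15, 35), value = c(10, 5)))
#' @export
pulse_schedule <- function(baseline = numeric(0), pulses = NULL) {
  if (length(baseline) && (is.null(names(baseline)) || any(!nzchar(names(baseline)))))
    stop("schedule baseline must be a named numeric vector", call. = FALSE)
  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses, stringsAsFactors = FALSE)
    need <- c("species", "start", "stop", "value")
    if (!all(need %in% names(pulses)))
      stop("pulses must have columns species, start, stop, value", call. = FALSE)
    if (any(pulses$start >= pulses$stop))
      stop("each pulse must have start < stop", call. = FALSE)
    for (sp in unique(pulses$species)) {
      pp <- pulses[pulses$species == sp, , drop = FALSE]
      pp <- pp[order(pp$start), , drop = FALSE]
      if (nrow(pp) > 1 && any(pp$start[-1] < pp$stop[-nrow(pp)]))
        stop(sprintf("overlapping pulses on channel '%s'", sp), call. = FALSE)
    }
  } else {
    pulses <- data.frame(species = character(0), start = numeric(0),
                         stop = numeric(0), value = numeric(0))
  }
  structure(list(baseline = baseline, pulses = pulses), class = "bst_schedule")
}

#' @export
print.bst_schedule <- function(x, ...) {
  cat("<bst_schedule>\n")
  if (length(x$baseline))
    cat("  baseline:", paste(sprintf("%s=%g", names(x$baseline), x$baseline),
                             collapse = ", "), "\n")
  if (nrow(x$pulses))
    for (i in seq_len(nrow(x$pulses)))
      cat(sprintf("  pulse: %s = %g on [%g, %g)\n", x$pulses$species[i],
                  x$pulses$value[i], x$pulses$start[i], x$pulses$stop[i]))
  invisible(x)
}

# Resolve an input specification (NULL, constant vector, or schedule) to the
# input vector u(t) of length n at a given time.
input_vector <- function(input, t, model) {
  n <- length(model$dynamic_species)
  u <- stats::setNames(rep(0, n), model$dynamic_species)
  if (is.null(input)) return(u)
  if (is.numeric(input)) {
    if (!is.null(names(input))) {
      bad <- setdiff(names(input), model$dynamic_species)
      if (length(bad))
        stop(sprintf("input names an unknown dynamic species '%s'", bad[1]), call. = FALSE)
      u[names(input)] <- input
    } else {
      if (length(input) != n)
        stop(sprintf("constant input has length %d but the model has %d dynamic species",
                     length(input), n), call. = FALSE)
      u[] <- input
    }
    return(u)
  }
  if (!inherits(input, "bst_schedule"))
    stop("input must be NULL, a numeric vector, or a pulse_schedule", call. = FALSE)
  bad <- setdiff(unique(c(names(input$baseline), input$pulses$species)),
                 model$dynamic_species)
  if (length(bad))
    stop(sprintf("input schedule names an unknown dynamic species '%s'", bad[1]), call. = FALSE)
  if (length(input$baseline)) u[names(input$baseline)] <- input$baseline
  pp <- input$pulses
  if (nrow(pp)) {
    active <- pp$start <= t & t < pp$stop
    if (any(active)) u[pp$species[active]] <- pp$value[active]
  }
  u
}

# All pulse edges that fall strictly inside (t0, tf); integration is
# restarted at each so the solver never steps across a discontinuity.
schedule_breaks <- function(input, t0, tf) {
  if (!inherits(input, "bst_schedule")) return(numeric(0))
  b <- sort(unique(c(input$pulses$start, input$pulses$stop)))
  b[b > t0 & b < tf]
}

#' Multiply one channel of an input by a scalar
#'
#' Scales both the baseline and every pulse value of one channel; used when a
#' sensitivity parameter acts as a gain on an external input (e.g. a source
#' flux delivered through u(t)).
#'
#' @param input A [pulse_schedule()] (or constant named vector).
#' @param species Channel (dynamic species) name.
#' @param factor Multiplicative factor.
#' @return The scaled input, same class as the input.
#' @export
scale_input <- function(input, species, factor) {
  if (is.numeric(input)) {
    if (!is.null(names(input)) && species %in% names(input))
      input[species] <- input[species] * factor
    return(input)
  }
  if (!inherits(input, "bst_schedule"))
    stop("input must be a numeric vector or a pulse_schedule", call. = FALSE)
  if (species %in% names(input$baseline))
    input$baseline[species] <- input$baseline[species] * factor
  sel <- input$pulses$species == species
  input$pulses$value[sel] <- input$pulses$value[sel] * factor
  input
}
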
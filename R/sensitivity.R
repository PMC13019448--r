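#' Time-integrated species exposure
#'
#' The scalar performance functional J = integral of one species'
#' concentration from `tspan[1]` to `t_upper`, computed by the trapezoidal
#' rule on a dense save grid (at least 2001 points). Used as the default
#' output for global sensitivity analysis (cumulative exposure to a
#' product).
#'
#' @param model A [bst_model()].
#' @param tspan Length-2 integration window; `t_upper` must lie inside it.
#' @param input `NULL`, constant vector, or [pulse_schedule()].
#' @param species Name of the dynamic species to integrate.
#' @param t_upper Upper integration limit (default `tspan[2]`).
#' @param n_points Save-grid size (floored at 2001).
#' @param ... Passed to [evaluate()] (tolerances etc.).
#' @return The scalar integral.
#' @export
performance_integral <- function(model, tspan, input = NULL, species,
                                 t_upper = tspan[2], n_points = 2001L, ...) {
  if (!(species %in% model$dynamic_species))
    stop(sprintf("unknown species '%s'", species), call. = FALSE)
  stopifnot(t_upper > tspan[1], t_upper <= tspan[2])
  grid <- seq(tspan[1], t_upper, length.out = max(as.integer(n_points), 2001L))
  traj <- evaluate(model, c(tspan[1], t_upper), input, save_times = grid, ...)
  y <- traj$states[, species]
  tt <- traj$times
  sum(diff(tt) * (y[-1] + y[-length(y)]) / 2)
}

map_to_bounds <- function(x01, lower, upper) {
  sweep(sweep(x01, 2, upper - lower, "*"), 2, lower, "+")
}

eval_points <- function(f, theta, retry = TRUE) {
  vals <- rep(NA_real_, nrow(theta))
  for (i in seq_len(nrow(theta))) {
    v <- tryCatch(f(theta[i, ]), error = function(e) NA_real_)
    if ((length(v) != 1L || !is.finite(v)) && retry)
      v <- tryCatch(f(theta[i, ]), error = function(e) NA_real_)
    vals[i] <- if (length(v) == 1L && is.finite(v)) v else NA_real_
  }
  vals
}

#' Morris elementary-effects screening
#'
#' Classic Morris trajectory design on a `levels`-level grid of the unit
#' hypercube with step Delta = levels / (2 (levels - 1)), mapped affinely to
#' the parameter bounds. Each of the `r` trajectories perturbs every
#' parameter exactly once (in random order and direction), yielding one
#' elementary effect per parameter per trajectory,
#' EE_k = (f(theta + Delta e_k * span) - f(theta)) / Delta. The summary
#' statistics are the signed mean mu, the mean absolute value mu* (the usual
#' screening statistic), and the variance sigma^2 (nonlinearity or
#' interaction) of the r effects.
#'
#' Model evaluations that fail or return a non-finite value are retried once
#' and then recorded as missing; the affected elementary effects are dropped.
#' More than 1\% missing evaluations aborts the analysis.
#'
#' @param f Function mapping a parameter vector (natural units) to a scalar.
#' @param lower,upper Numeric bounds per parameter (finite, lower < upper).
#' @param r Number of trajectories (>= 2; total cost r * (d + 1) evaluations).
#' @param levels Number of grid levels (even; default 4).
#' @param seed Optional integer seed; fixed seed gives bit-identical results.
#' @return A `bst_morris` object: per-parameter `mu`, `mu_star`, `sigma2`,
#'   plus `r`, `levels`, `seed`, and the count of failed evaluations.
#' @examples
#' res <- morris(function(th) 3 * th[1], lower = c(0, 0), upper = c(1, 1),
#'               r = 10, seed = 1)
#' res$mu_star  # c(3, 0)
#' @export
morris <- function(f, lower, upper, r = 500L, levels = 4L, seed = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper), r >= 2, levels %% 2 == 0)
  if (!is.null(seed)) set.seed(seed)
  delta <- levels / (2 * (levels - 1))
  span <- upper - lower
  start_levels <- (seq_len(levels / 2) - 1) / (levels - 1)  # grid points <= 1 - delta
  EE <- matrix(NA_real_, r, d)
  n_failed <- 0L; n_eval <- 0L
  for (tr in seq_len(r)) {
    x <- start_levels[sample.int(length(start_levels), d, replace = TRUE)]
    dir <- sample(c(-1, 1), d, replace = TRUE)
    out_of_box <- x + dir * delta > 1 | x + dir * delta < 0
    dir[out_of_box] <- -dir[out_of_box]
    ord <- sample.int(d)
    y0 <- eval_points(f, matrix(lower + x * span, 1))
    n_eval <- n_eval + 1L
    if (is.na(y0)) n_failed <- n_failed + 1L
    for (k in ord) {
      x[k] <- x[k] + dir[k] * delta
      y1 <- eval_points(f, matrix(lower + x * span, 1))
      n_eval <- n_eval + 1L
      if (is.na(y1)) n_failed <- n_failed + 1L
      if (!is.na(y0) && !is.na(y1)) EE[tr, k] <- (y1 - y0) / (delta * dir[k])
      y0 <- y1
    }
  }
  if (n_failed > 0.01 * n_eval)
    stop(bst_numeric_error(sprintf(
      "morris: %d of %d model evaluations failed (> 1%%)", n_failed, n_eval)))
  pn <- if (!is.null(names(lower))) names(lower) else paste0("theta", seq_len(d))
  structure(list(
    parameters = pn,
    mu = stats::setNames(colMeans(EE, na.rm = TRUE), pn),
    mu_star = stats::setNames(colMeans(abs(EE), na.rm = TRUE), pn),
    sigma2 = stats::setNames(apply(EE, 2, stats::var, na.rm = TRUE), pn),
    r = r, levels = levels, seed = seed, n_failed = n_failed
  ), class = "bst_morris")
}

#' @export
print.bst_morris <- function(x, ...) {
  cat(sprintf("<bst_morris> %d trajectories, %d levels\n", x$r, x$levels))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.bst_morris <- function(x, ...) {
  data.frame(parameter = x$parameters, mu = unname(x$mu),
             mu_star = unname(x$mu_star), sigma2 = unname(x$sigma2))
}

#' Sobol variance-based sensitivity indices
#'
#' Saltelli-design estimation of first-order (S1) and total-order (ST)
#' Sobol indices. Two N x d base matrices A and B are drawn from a scrambled
#' Sobol' low-discrepancy sequence (dimension 2d, split in half), plus the d
#' cross matrices A_B^(i) in which column i of A is replaced by column i of
#' B, for N (d + 2) model evaluations in total. S1 uses the Saltelli (2010)
#' estimator `mean(fB * (fAB_i - fA)) / V`; ST uses the Jansen estimator
#' `mean((fA - fAB_i)^2) / (2 V)`. 95\% confidence intervals come from a
#' bootstrap over sample rows.
#'
#' Failed or non-finite model evaluations are retried once, then the whole
#' sample row is dropped; more than 1\% missing rows aborts. If the output
#' variance is (numerically) zero all indices are reported as 0 with
#' `zero_variance = TRUE` and a warning.
#'
#' @inheritParams morris
#' @param N Base sample size (>= 64; a power of 2 is recommended for the
#'   low-discrepancy sequence).
#' @param bootstrap Number of bootstrap resamples for the CIs (default 200).
#' @param conf Confidence level (default 0.95).
#' @return A `bst_sobol` object: per-parameter `S1`, `ST`, CI matrices
#'   `S1_ci` and `ST_ci` (columns lower, upper), `N`, `seed`, and counts of
#'   dropped rows.
#' @examples
#' res <- sobol(function(th) th[1] + 2 * th[2], lower = c(0, 0),
#'              upper = c(1, 1), N = 256, seed = 1)
#' res$S1  # approx (0.2, 0.8)
#' @export
sobol <- function(f, lower, upper, N = 1024L, seed = NULL,
                  bootstrap = 200L, conf = 0.95) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper), N >= 64)
  if (!is.null(seed)) set.seed(seed)
  base <- sobol_points(N, 2L * d, scramble = TRUE)
  A <- map_to_bounds(base[, seq_len(d), drop = FALSE], lower, upper)
  B <- map_to_bounds(base[, d + seq_len(d), drop = FALSE], lower, upper)
  fA <- eval_points(f, A)
  fB <- eval_points(f, B)
  fAB <- matrix(NA_real_, N, d)
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    fAB[, i] <- eval_points(f, ABi)
  }
  ok <- is.finite(fA) & is.finite(fB) & apply(is.finite(fAB), 1, all)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.01 * N)
    stop(bst_numeric_error(sprintf(
      "sobol: %d of %d sample rows contained failed evaluations (> 1%%)",
      n_dropped, N)))
  fA <- fA[ok]; fB <- fB[ok]; fAB <- fAB[ok, , drop = FALSE]

  est <- function(idx) {
    a <- fA[idx]; b <- fB[idx]; ab <- fAB[idx, , drop = FALSE]
    mu0 <- mean(c(a, b))  # center the output: estimators are shift-invariant
    a <- a - mu0; b <- b - mu0; ab <- ab - mu0
    v <- stats::var(c(a, b))
    if (!is.finite(v) || v <= 0) return(list(S1 = rep(0, d), ST = rep(0, d), zero = TRUE))
    S1 <- colMeans(b * (ab - a)) / v
    ST <- colMeans((a - ab)^2) / (2 * v)
    list(S1 = S1, ST = ST, zero = FALSE)
  }
  point <- est(seq_along(fA))
  if (point$zero)
    warning("sobol: output variance is zero; all indices reported as 0")
  pn <- if (!is.null(names(lower))) names(lower) else paste0("theta", seq_len(d))

  S1_ci <- ST_ci <- matrix(NA_real_, d, 2, dimnames = list(pn, c("lower", "upper")))
  if (bootstrap > 0 && !point$zero) {
    bS1 <- bST <- matrix(NA_real_, bootstrap, d)
    for (b in seq_len(bootstrap)) {
      idx <- sample.int(length(fA), replace = TRUE)
      e <- est(idx)
      bS1[b, ] <- e$S1; bST[b, ] <- e$ST
    }
    qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    S1_ci[] <- t(apply(bS1, 2, stats::quantile, probs = qs, na.rm = TRUE))
    ST_ci[] <- t(apply(bST, 2, stats::quantile, probs = qs, na.rm = TRUE))
  }
  structure(list(
    parameters = pn,
    S1 = stats::setNames(point$S1, pn), ST = stats::setNames(point$ST, pn),
    S1_ci = S1_ci, ST_ci = ST_ci,
    N = N, d = d, seed = seed, bootstrap = bootstrap, conf = conf,
    zero_variance = point$zero, n_dropped = n_dropped
  ), class = "bst_sobol")
}

#' @export
print.bst_sobol <- function(x, ...) {
  cat(sprintf("<bst_sobol> base N = %d, %d parameters, %d bootstrap resamples\n",
              x$N, x$d, x$bootstrap))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.bst_sobol <- function(x, ...) {
  data.frame(parameter = x$parameters,
             S1 = unname(x$S1), S1_lower = x$S1_ci[, 1], S1_upper = x$S1_ci[, 2],
             ST = unname(x$ST), ST_lower = x$ST_ci[, 1], ST_upper = x$ST_ci[, 2],
             row.names = NULL)
}

#' Export a sensitivity result
#'
#' Writes a Morris or Sobol result as CSV (one row per parameter) or JSON,
#' chosen by the file extension.
#'
#' @param result A `bst_morris` or `bst_sobol` object.
#' @param path Output path ending in `.csv` or `.json`.
#' @export
write_sensitivity <- function(result, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(result)
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    stop(sprintf("unknown result extension '.%s' (use .csv or .json)", ext),
         call. = FALSE)
  }
  invisible(path)
}
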
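#' Reaction connectivity record
#'
#' A `reaction_record` states which species a reaction consumes and produces,
#' with positive stoichiometric coefficients on each side. Either side may be
#' empty, giving a constant source (no reactants) or a sink (no products).
#'
#' @param name Reaction name (non-empty string).
#' @param reactants Named numeric vector of reactant coefficients (all > 0),
#'   or `NULL` for a source reaction.
#' @param products Named numeric vector of product coefficients (all > 0),
#'   or `NULL` for a sink reaction.
#' @return An object of class `bst_reaction`.
#' @examples
#' reaction_record("r1", reactants = c(X1 = 1), products = c(X2 = 1))
#' reaction_record("r0", products = c(X1 = 1)) # source
#' @export
reaction_record <- function(name, reactants = NULL, products = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("reaction name must be a non-empty string", call. = FALSE)
  reactants <- check_side(reactants, name, "reactant")
  products <- check_side(products, name, "product")
  structure(list(name = name, reactants = reactants, products = products),
            class = "bst_reaction")
}

check_side <- function(side, name, what) {
  if (is.null(side) || length(side) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(side) || is.null(names(side)) || any(!nzchar(names(side))))
    stop(sprintf("reaction '%s': %s coefficients must be a named numeric vector", name, what),
         call. = FALSE)
  if (any(!is.finite(side)) || any(side <= 0))
    stop(sprintf("reaction '%s': %s coefficients must be finite and > 0", name, what),
         call. = FALSE)
  if (anyDuplicated(names(side)))
    stop(sprintf("reaction '%s': duplicate %s species", name, what), call. = FALSE)
  side
}

#' Kinetic dependency record
#'
#' A `kinetics_record` lists the species that appear in a reaction's power-law
#' rate law together with their kinetic orders (exponents). Positive orders
#' denote activation, negative orders inhibition. Orders are always explicit
#' here; the file readers supply the default order of 1 when a file omits one.
#'
#' @param reaction Name of the reaction the record applies to.
#' @param dependencies Named numeric vector mapping species names to finite
#'   kinetic orders. May be empty for a constant-rate reaction.
#' @return An object of class `bst_kinetics`.
#' @examples
#' kinetics_record("r1", c(X1 = 1, E1 = 1, X4 = -0.5))
#' @export
kinetics_record <- function(reaction, dependencies = NULL) {
  if (!is.character(reaction) || length(reaction) != 1L || !nzchar(reaction))
    stop("kinetics record: reaction name must be a non-empty string", call. = FALSE)
  if (is.null(dependencies) || length(dependencies) == 0L) {
    dependencies <- stats::setNames(numeric(0), character(0))
  } else {
    if (!is.numeric(dependencies) || is.null(names(dependencies)))
      stop(sprintf("kinetics record '%s': dependencies must be a named numeric vector", reaction),
           call. = FALSE)
    if (any(!is.finite(dependencies)))
      stop(sprintf("kinetics record '%s': kinetic orders must be finite", reaction), call. = FALSE)
    if (anyDuplicated(names(dependencies)))
      stop(sprintf("kinetics record '%s': duplicate kinetic order for species '%s'",
                   reaction, names(dependencies)[duplicated(names(dependencies))][1]),
           call. = FALSE)
  }
  structure(list(reaction = reaction, dependencies = dependencies),
            class = "bst_kinetics")
}

#' Assemble stoichiometric and kinetic-order matrices
#'
#' Compiles declarative reaction and kinetics records into the matrices of the
#' generalized S-system representation: the stoichiometric matrix `S` (n
#' dynamic species x p reactions, products positive, reactants negative) and
#' the kinetic-order matrix `G` ((n+m) species x p reactions). Rows of `G` are
#' ordered dynamic species first (in `dynamic_species` order), then static
#' species. Static species have `G` rows but no `S` rows. Explicit
#' stoichiometry overrides replace the computed `S` entry verbatim; a zero
#' override is allowed (a species can then shape a rate without mass flow).
#'
#' @param dynamic_species,static_species Character vectors of species names
#'   (disjoint, no duplicates).
#' @param reactions List of [reaction_record()] objects; their order fixes the
#'   column order of `S` and `G`.
#' @param kinetics List of [kinetics_record()] objects, at most one per
#'   reaction.
#' @param overrides Optional data frame with columns `species`, `reaction`,
#'   `coefficient` applied to `S` after assembly.
#' @return A list with elements `S` and `G` (both with dimnames).
#' @examples
#' sg <- assemble_matrices(
#'   c("X1", "X2"), "E1",
#'   list(reaction_record("r1", c(X1 = 1), c(X2 = 1))),
#'   list(kinetics_record("r1", c(X1 = 1, E1 = 1))))
#' sg$S  # column (-1, +1)
#' @export
assemble_matrices <- function(dynamic_species, static_species = character(),
                              reactions, kinetics = list(), overrides = NULL) {
  species <- c(dynamic_species, static_species)
  if (anyDuplicated(species))
    stop(sprintf("duplicate species name '%s'", species[duplicated(species)][1]), call. = FALSE)
  rnames <- vapply(reactions, function(r) r$name, character(1))
  if (anyDuplicated(rnames))
    stop(sprintf("duplicate reaction name '%s'", rnames[duplicated(rnames)][1]), call. = FALSE)
  n <- length(dynamic_species); m <- length(static_species); p <- length(reactions)

  S <- matrix(0, n, p, dimnames = list(dynamic_species, rnames))
  G <- matrix(0, n + m, p, dimnames = list(species, rnames))

  for (r in reactions) {
    for (side in c("reactants", "products")) {
      v <- r[[side]]
      bad <- setdiff(names(v), species)
      if (length(bad))
        stop(sprintf("reaction '%s': unknown species '%s'", r$name, bad[1]), call. = FALSE)
      stat <- intersect(names(v), static_species)
      dyn <- setdiff(names(v), static_species)
      sgn <- if (side == "reactants") -1 else 1
      if (length(dyn)) S[dyn, r$name] <- S[dyn, r$name] + sgn * v[dyn]
      # static species carry no mass balance: they appear only in G
      if (length(stat) && side == "reactants") {
        # permitted (e.g. enzyme written as a reactant), but contributes no S row
      }
    }
  }

  seen <- character(0)
  for (k in kinetics) {
    if (!(k$reaction %in% rnames))
      stop(sprintf("kinetics record references unknown reaction '%s'", k$reaction), call. = FALSE)
    if (k$reaction %in% seen)
      stop(sprintf("duplicate kinetics record for reaction '%s'", k$reaction), call. = FALSE)
    seen <- c(seen, k$reaction)
    bad <- setdiff(names(k$dependencies), species)
    if (length(bad))
      stop(sprintf("kinetics record '%s': unknown species '%s'", k$reaction, bad[1]), call. = FALSE)
    if (length(k$dependencies))
      G[names(k$dependencies), k$reaction] <- k$dependencies
  }

  if (!is.null(overrides) && nrow(as.data.frame(overrides))) {
    overrides <- as.data.frame(overrides, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(overrides))) {
      sp <- as.character(overrides$species[i]); rx <- as.character(overrides$reaction[i])
      if (!(sp %in% dynamic_species))
        stop(sprintf("stoichiometry override: unknown dynamic species '%s'", sp), call. = FALSE)
      if (!(rx %in% rnames))
        stop(sprintf("stoichiometry override: unknown reaction '%s'", rx), call. = FALSE)
      S[sp, rx] <- as.numeric(overrides$coefficient[i])
    }
  }
  list(S = S, G = G)
}

#' Construct a BST model
#'
#' The central container for a power-law (S-system) model in the generalized
#' matrix representation: dynamics dx/dt = S r(x, xs) + u(t), with reaction
#' rates r_k = alpha_k * prod_j X_j^G\[j,k\] over the concatenated vector of
#' dynamic and static species concentrations.
#'
#' @param dynamic_species Character vector of dynamic species names (length n).
#' @param static_species Character vector of static species names (length m).
#' @param S n x p stoichiometric matrix.
#' @param G (n+m) x p kinetic-order matrix, rows ordered dynamic then static.
#' @param alpha Length-p non-negative rate constants (named by reaction or not;
#'   names taken from `reaction_names`).
#' @param x0 Length-n non-negative initial concentrations.
#' @param xs Length-m strictly positive static species concentrations.
#' @param reaction_names Character vector of reaction names (length p).
#' @param records Optional list with elements `reactions`, `kinetics`,
#'   `overrides` retaining the declarative description the model was built
#'   from (kept by [model_from_records()] and the file readers so the model
#'   can be re-serialized to the text formats).
#' @param metadata Optional named list of free-form strings (author, version).
#' @return An object of class `bst_model`.
#' @seealso [model_from_records()], [validate_model()], [evaluate()]
#' @export
bst_model <- function(dynamic_species, static_species = character(),
                      S, G, alpha, x0, xs = numeric(0),
                      reaction_names = NULL, records = NULL, metadata = list()) {
  S <- as.matrix(S); G <- as.matrix(G)
  if (is.null(reaction_names)) {
    reaction_names <- colnames(S)
    if (is.null(reaction_names)) reaction_names <- paste0("r", seq_len(ncol(S)))
  }
  dimnames(S) <- list(dynamic_species, reaction_names)
  dimnames(G) <- list(c(dynamic_species, static_species), reaction_names)
  model <- structure(list(
    dynamic_species = as.character(dynamic_species),
    static_species = as.character(static_species),
    reaction_names = as.character(reaction_names),
    S = S, G = G,
    alpha = stats::setNames(as.numeric(alpha), reaction_names),
    x0 = stats::setNames(as.numeric(x0), dynamic_species),
    xs = stats::setNames(as.numeric(xs), static_species),
    records = records, metadata = metadata
  ), class = "bst_model")
  diags <- validate_model(model)
  if (length(diags))
    stop(paste(c("invalid model:", diags), collapse = "\n  "), call. = FALSE)
  model
}

#' Build a model from declarative records
#'
#' Convenience constructor used by the file readers and fixtures: assembles
#' `S` and `G` from records via [assemble_matrices()] and fills unspecified
#' initial conditions with 0 and unspecified static values with 1.
#'
#' @inheritParams assemble_matrices
#' @param alpha Named numeric vector of rate constants; must provide an entry
#'   for every reaction.
#' @param x0 Named numeric vector of initial conditions (missing species
#'   default to 0).
#' @param xs Named numeric vector of static species values (missing species
#'   default to 1).
#' @param metadata Optional named list of free-form strings.
#' @return A validated [bst_model()].
#' @export
model_from_records <- function(dynamic_species, static_species = character(),
                               reactions, kinetics = list(), overrides = NULL,
                               alpha, x0 = numeric(0), xs = numeric(0),
                               metadata = list()) {
  sg <- assemble_matrices(dynamic_species, static_species, reactions, kinetics, overrides)
  rnames <- colnames(sg$S)
  missing_a <- setdiff(rnames, names(alpha))
  if (length(missing_a))
    stop(sprintf("no rate constant (alpha) given for reaction '%s'", missing_a[1]), call. = FALSE)
  extra_a <- setdiff(names(alpha), rnames)
  if (length(extra_a))
    stop(sprintf("alpha given for unknown reaction '%s'", extra_a[1]), call. = FALSE)
  x0v <- stats::setNames(rep(0, length(dynamic_species)), dynamic_species)
  x0v[intersect(names(x0), dynamic_species)] <- x0[intersect(names(x0), dynamic_species)]
  bad_x0 <- setdiff(names(x0), dynamic_species)
  if (length(bad_x0))
    stop(sprintf("initial condition for unknown dynamic species '%s'", bad_x0[1]), call. = FALSE)
  xsv <- stats::setNames(rep(1, length(static_species)), static_species)
  xsv[intersect(names(xs), static_species)] <- xs[intersect(names(xs), static_species)]
  bad_xs <- setdiff(names(xs), static_species)
  if (length(bad_xs))
    stop(sprintf("static value for unknown static species '%s'", bad_xs[1]), call. = FALSE)
  bst_model(dynamic_species, static_species, sg$S, sg$G,
            alpha = alpha[rnames], x0 = x0v, xs = xsv,
            reaction_names = rnames,
            records = list(reactions = reactions, kinetics = kinetics,
                           overrides = overrides),
            metadata = metadata)
}

#' Validate a BST model
#'
#' Checks every structural invariant of the model container and returns a
#' character vector of human-readable diagnostics, one per violation. An
#' empty vector means the model is well formed. Diagnostics, not exceptions:
#' callers that want hard failure should `stop()` on a non-empty result.
#'
#' @param model A `bst_model` (possibly hand-edited).
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_model <- function(model) {
  d <- character(0)
  n <- length(model$dynamic_species); m <- length(model$static_species)
  p <- length(model$reaction_names)
  if (anyDuplicated(model$dynamic_species))
    d <- c(d, "duplicate dynamic species names")
  if (anyDuplicated(model$static_species))
    d <- c(d, "duplicate static species names")
  if (length(intersect(model$dynamic_species, model$static_species)))
    d <- c(d, "dynamic and static species lists are not disjoint")
  if (anyDuplicated(model$reaction_names))
    d <- c(d, "duplicate reaction names")
  if (!is.matrix(model$S) || !identical(dim(model$S), c(n, p)))
    d <- c(d, sprintf("S has dimensions %s, expected %d x %d",
                      paste(dim(model$S), collapse = " x "), n, p))
  if (!is.matrix(model$G) || !identical(dim(model$G), c(n + m, p)))
    d <- c(d, sprintf("G has dimensions %s, expected %d x %d",
                      paste(dim(model$G), collapse = " x "), n + m, p))
  if (length(model$alpha) != p) {
    d <- c(d, sprintf("alpha has length %d, expected %d", length(model$alpha), p))
  } else {
    neg <- which(!is.finite(model$alpha) | model$alpha < 0)
    if (length(neg))
      d <- c(d, sprintf("negative or non-finite rate constant at index %d (reaction '%s')",
                        neg[1], model$reaction_names[neg[1]]))
  }
  if (length(model$x0) != n) {
    d <- c(d, sprintf("x0 has length %d, expected %d", length(model$x0), n))
  } else {
    neg <- which(!is.finite(model$x0) | model$x0 < 0)
    if (length(neg))
      d <- c(d, sprintf("negative or non-finite initial condition at index %d (species '%s')",
                        neg[1], model$dynamic_species[neg[1]]))
  }
  if (length(model$xs) != m) {
    d <- c(d, sprintf("xs has length %d, expected %d", length(model$xs), m))
  } else if (m > 0) {
    bad <- which(!is.finite(model$xs) | model$xs <= 0)
    if (length(bad))
      d <- c(d, sprintf("non-positive static value at index %d (species '%s')",
                        bad[1], model$static_species[bad[1]]))
  }
  if (is.matrix(model$G) && any(!is.finite(model$G)))
    d <- c(d, "non-finite kinetic order in G")
  if (is.matrix(model$S) && any(!is.finite(model$S)))
    d <- c(d, "non-finite stoichiometric coefficient in S")
  d
}

#' @export
print.bst_model <- function(x, ...) {
  cat(sprintf("<bst_model> %d dynamic + %d static species, %d reactions\n",
              length(x$dynamic_species), length(x$static_species),
              length(x$reaction_names)))
  cat("  dynamic:", paste(x$dynamic_species, collapse = ", "), "\n")
  if (length(x$static_species))
    cat("  static: ", paste(sprintf("%s=%g", x$static_species, x$xs), collapse = ", "), "\n")
  cat("  alpha:  ", paste(sprintf("%s=%g", x$reaction_names, x$alpha), collapse = ", "), "\n")
  invisible(x)
}

#' Classical two-term S-system
#'
#' In the classical S-system each dynamic species X_i is governed by a single
#' aggregate production term and a single aggregate consumption term,
#' dX_i/dt = alpha_i * prod_j X_j^g_ij - beta_i * prod_j X_j^h_ij, with
#' alpha_i, beta_i > 0. Its steady state solves a linear system in log
#' coordinates (see [solve_loglinear()]).
#'
#' @param alpha,beta Length-n strictly positive rate-constant vectors.
#' @param G,H n x (n+m) kinetic-order matrices for production and consumption.
#' @param dynamic_species Names of the n dynamic species.
#' @param static_species,xs Names and (strictly positive) values of the m
#'   static species.
#' @return An object of class `bst_classical`.
#' @export
classical_ssystem <- function(alpha, beta, G, H, dynamic_species = NULL,
                              static_species = character(), xs = numeric(0)) {
  G <- as.matrix(G); H <- as.matrix(H)
  n <- length(alpha); m <- length(static_species)
  if (is.null(dynamic_species)) dynamic_species <- paste0("X", seq_len(n))
  if (length(beta) != n || nrow(G) != n || nrow(H) != n ||
      ncol(G) != n + m || ncol(H) != n + m || length(xs) != m)
    stop("classical S-system: inconsistent dimensions", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(!is.finite(beta)) || any(beta <= 0))
    stop("classical S-system requires strictly positive alpha and beta", call. = FALSE)
  if (m > 0 && any(xs <= 0))
    stop("classical S-system requires strictly positive static values", call. = FALSE)
  species <- c(dynamic_species, static_species)
  dimnames(G) <- dimnames(H) <- list(dynamic_species, species)
  structure(list(n = n, m = m,
                 dynamic_species = as.character(dynamic_species),
                 static_species = as.character(static_species),
                 alpha = stats::setNames(as.numeric(alpha), dynamic_species),
                 beta = stats::setNames(as.numeric(beta), dynamic_species),
                 G = G, H = H,
                 xs = stats::setNames(as.numeric(xs), static_species)),
            class = "bst_classical")
}

#' @export
print.bst_classical <- function(x, ...) {
  cat(sprintf("<bst_classical> %d dynamic + %d static species\n", x$n, x$m))
  invisible(x)
}

#' Reduce a generalized model to the classical S-system form
#'
#' A generalized model is classically representable when every dynamic
#' species has at most one producing reaction (positive stoichiometry) and at
#' most one consuming reaction (negative stoichiometry), each with
#' stoichiometric magnitude 1 and strictly positive rate constant: the two
#' reactions then map directly onto the aggregate production and consumption
#' terms of the classical form.
#'
#' @param model A `bst_model`.
#' @return A [classical_ssystem()] object.
#' @export
classical_from_model <- function(model) {
  n <- length(model$dynamic_species); m <- length(model$static_species)
  species <- c(model$dynamic_species, model$static_species)
  alpha_c <- beta_c <- numeric(n)
  Gc <- Hc <- matrix(0, n, n + m, dimnames = list(model$dynamic_species, species))
  for (i in seq_len(n)) {
    sp <- model$dynamic_species[i]
    srow <- model$S[i, ]
    prod_k <- which(srow > 0); cons_k <- which(srow < 0)
    if (length(prod_k) > 1 || length(cons_k) > 1)
      stop(sprintf("not classically representable: species '%s' has %d producing and %d consuming reactions",
                   sp, length(prod_k), length(cons_k)), call. = FALSE)
    if (length(prod_k) == 0 || length(cons_k) == 0)
      stop(sprintf("not classically representable: species '%s' lacks a producing or consuming reaction",
                   sp), call. = FALSE)
    if (abs(srow[prod_k]) != 1 || abs(srow[cons_k]) != 1)
      stop(sprintf("not classically representable: species '%s' has non-unit stoichiometry", sp),
           call. = FALSE)
    if (model$alpha[prod_k] <= 0 || model$alpha[cons_k] <= 0)
      stop(sprintf("not classically representable: species '%s' has a zero rate constant (classical form requires alpha_i, beta_i > 0)",
                   sp), call. = FALSE)
    alpha_c[i] <- model$alpha[prod_k]
    beta_c[i] <- model$alpha[cons_k]
    Gc[i, ] <- model$G[, prod_k]
    Hc[i, ] <- model$G[, cons_k]
  }
  classical_ssystem(alpha_c, beta_c, Gc, Hc,
                    dynamic_species = model$dynamic_species,
                    static_species = model$static_species, xs = model$xs)
}

#' Expand a classical S-system into a generalized model
#'
#' Builds a `bst_model` with one producing and one consuming reaction per
#' species (unit stoichiometry), named `prod_<species>` and `deg_<species>`.
#' [classical_from_model()] is the exact inverse on this subclass.
#'
#' @param cs A [classical_ssystem()].
#' @param x0 Optional named initial conditions (default: all 1).
#' @return A `bst_model`.
#' @export
model_from_classical <- function(cs, x0 = NULL) {
  species <- c(cs$dynamic_species, cs$static_species)
  reactions <- list(); kinetics <- list(); alpha <- numeric(0)
  for (i in seq_len(cs$n)) {
    sp <- cs$dynamic_species[i]
    rp <- paste0("prod_", sp); rd <- paste0("deg_", sp)
    reactions[[length(reactions) + 1L]] <-
      reaction_record(rp, products = stats::setNames(1, sp))
    reactions[[length(reactions) + 1L]] <-
      reaction_record(rd, reactants = stats::setNames(1, sp))
    gdep <- cs$G[i, ]; hdep <- cs$H[i, ]
    kinetics[[length(kinetics) + 1L]] <-
      kinetics_record(rp, gdep[gdep != 0])
    kinetics[[length(kinetics) + 1L]] <-
      kinetics_record(rd, hdep[hdep != 0])
    alpha[rp] <- cs$alpha[i]; alpha[rd] <- cs$beta[i]
  }
  if (is.null(x0)) x0 <- stats::setNames(rep(1, cs$n), cs$dynamic_species)
  model_from_records(cs$dynamic_species, cs$static_species,
                     reactions, kinetics,
                     alpha = alpha, x0 = x0, xs = cs$xs)
}
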
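# Record-string grammar shared by the TOML and BST text dialects.
#
# reaction:  "name::LHS --> RHS" where each side is "[]" (empty; source or
#            sink) or a "+"-separated list of terms "Species" or
#            "coef*Species" with coef > 0. The arrow "-->" is canonical; the
#            en-dash variant sometimes produced by document rendering is
#            accepted on input.
# kinetics:  "name::Species^order, Species, ..." — "^order" optional, the
#            file readers default it to 1 (mass-action-like).
# override:  "Species::reaction::coefficient".

trim <- function(x) gsub("^\\s+|\\s+$", "", x)

split2 <- function(s, sep, what, line = NULL) {
  at <- regexpr(sep, s, fixed = TRUE)
  if (at < 0)
    stop(sprintf("%s record '%s' is missing '%s'%s", what, s, sep, line_suffix(line)),
         call. = FALSE)
  c(substr(s, 1, at - 1), substr(s, at + nchar(sep), nchar(s)))
}

line_suffix <- function(line) if (is.null(line)) "" else sprintf(" (line %d)", line)

parse_side <- function(s, rec, line = NULL) {
  s <- trim(s)
  if (s == "[]" || s == "") return(NULL)
  terms <- trim(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tm in terms) {
    if (grepl("*", tm, fixed = TRUE)) {
      kv <- trim(strsplit(tm, "*", fixed = TRUE)[[1]])
      if (length(kv) != 2 || is.na(suppressWarnings(as.numeric(kv[1]))))
        stop(sprintf("cannot parse stoichiometric term '%s' in reaction record '%s'%s",
                     tm, rec, line_suffix(line)), call. = FALSE)
      out[kv[2]] <- as.numeric(kv[1])
    } else {
      if (!nzchar(tm))
        stop(sprintf("empty species term in reaction record '%s'%s", rec,
                     line_suffix(line)), call. = FALSE)
      out[tm] <- 1
    }
  }
  out
}

parse_reaction_string <- function(s, line = NULL) {
  parts <- split2(trim(s), "::", "reaction", line)
  name <- trim(parts[1])
  body <- gsub("–>", "-->", parts[2])  # accept en-dash arrow
  at <- regexpr("-->", body, fixed = TRUE)
  if (at < 0)
    stop(sprintf("reaction record '%s' has no '-->' arrow%s", s, line_suffix(line)),
         call. = FALSE)
  lhs <- substr(body, 1, at - 1)
  rhs <- substr(body, at + 3, nchar(body))
  reaction_record(name, reactants = parse_side(lhs, name, line),
                  products = parse_side(rhs, name, line))
}

parse_kinetics_string <- function(s, default_order = 1, line = NULL) {
  parts <- split2(trim(s), "::", "kinetics", line)
  name <- trim(parts[1])
  body <- trim(parts[2])
  deps <- numeric(0)
  if (nzchar(body) && body != "[]") {
    for (tm in trim(strsplit(body, ",", fixed = TRUE)[[1]])) {
      if (grepl("^", tm, fixed = TRUE)) {
        kv <- trim(strsplit(tm, "^", fixed = TRUE)[[1]])
        ord <- suppressWarnings(as.numeric(kv[2]))
        if (length(kv) != 2 || is.na(ord))
          stop(sprintf("cannot parse kinetic term '%s' in record '%s'%s",
                       tm, name, line_suffix(line)), call. = FALSE)
        deps[kv[1]] <- ord
      } else {
        if (!nzchar(tm))
          stop(sprintf("empty kinetic term in record '%s'%s", name, line_suffix(line)),
               call. = FALSE)
        deps[tm] <- default_order
      }
    }
  }
  kinetics_record(name, deps)
}

parse_override_string <- function(s, line = NULL) {
  parts <- trim(strsplit(trim(s), "::", fixed = TRUE)[[1]])
  coef <- suppressWarnings(as.numeric(parts[3]))
  if (length(parts) != 3 || is.na(coef))
    stop(sprintf("cannot parse stoichiometry override '%s' (expected species::reaction::coefficient)%s",
                 s, line_suffix(line)), call. = FALSE)
  data.frame(species = parts[1], reaction = parts[2], coefficient = coef,
             stringsAsFactors = FALSE)
}

#' Declarative model document
#'
#' The intermediate representation shared by the TOML and BST text readers:
#' species lists, record strings as they appeared in the file, and the
#' numeric tables. [document_to_model()] compiles it into a validated
#' [bst_model()].
#'
#' @param metadata Named list of free-form strings (e.g. author, version).
#' @param dynamic_species,static_species Character vectors.
#' @param reactions,kinetics,stoichiometry Character vectors of record
#'   strings in the dialect grammar.
#' @param alpha,initial,static_values Named numeric vectors.
#' @return A `bst_model_document`.
#' @export
model_document <- function(metadata = list(), dynamic_species = character(),
                           static_species = character(), reactions = character(),
                           kinetics = character(), stoichiometry = character(),
                           alpha = numeric(0), initial = numeric(0),
                           static_values = numeric(0)) {
  structure(list(metadata = metadata,
                 dynamic_species = as.character(dynamic_species),
                 static_species = as.character(static_species),
                 reactions = as.character(reactions),
                 kinetics = as.character(kinetics),
                 stoichiometry = as.character(stoichiometry),
                 alpha = alpha, initial = initial,
                 static_values = static_values),
            class = "bst_model_document")
}

#' Compile a model document into a model
#'
#' Parses the record strings, assembles the matrices, and validates the
#' result; any validation diagnostic is promoted to an error. Kinetic orders
#' omitted in a file default to 1.
#'
#' @param doc A [model_document()].
#' @return A validated [bst_model()].
#' @export
document_to_model <- function(doc) {
  reactions <- lapply(doc$reactions, parse_reaction_string)
  kinetics <- lapply(doc$kinetics, parse_kinetics_string, default_order = 1)
  overrides <- if (length(doc$stoichiometry)) {
    do.call(rbind, lapply(doc$stoichiometry, parse_override_string))
  } else NULL
  model_from_records(doc$dynamic_species, doc$static_species,
                     reactions, kinetics, overrides,
                     alpha = doc$alpha, x0 = doc$initial,
                     xs = doc$static_values, metadata = doc$metadata)
}

format_side <- function(v) {
  if (length(v) == 0) return("[]")
  paste(ifelse(v == 1, names(v), sprintf("%s*%s", num17(v), names(v))),
        collapse = " + ")
}

num17 <- function(x) sprintf("%.17g", x)

#' Turn a model back into a document
#'
#' Requires the model to retain its declarative records (models built from
#' files or [model_from_records()] do; hand-assembled matrix models do not).
#'
#' @param model A `bst_model` with records.
#' @return A [model_document()].
#' @export
model_to_document <- function(model) {
  if (is.null(model$records))
    stop("model does not retain declarative records; cannot re-serialize to a text dialect",
         call. = FALSE)
  reactions <- vapply(model$records$reactions, function(r)
    sprintf("%s::%s --> %s", r$name, format_side(r$reactants),
            format_side(r$products)), character(1))
  kinetics <- vapply(model$records$kinetics, function(k) {
    deps <- k$dependencies
    body <- if (length(deps) == 0) "[]" else
      paste(sprintf("%s^%s", names(deps), num17(deps)), collapse = ", ")
    sprintf("%s::%s", k$reaction, body)
  }, character(1))
  ov <- model$records$overrides
  stoich <- if (!is.null(ov) && nrow(as.data.frame(ov))) {
    ov <- as.data.frame(ov)
    sprintf("%s::%s::%s", ov$species, ov$reaction, num17(ov$coefficient))
  } else character(0)
  model_document(metadata = model$metadata,
                 dynamic_species = model$dynamic_species,
                 static_species = model$static_species,
                 reactions = reactions, kinetics = kinetics,
                 stoichiometry = stoich,
                 alpha = model$alpha, initial = model$x0,
                 static_values = model$xs)
}
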
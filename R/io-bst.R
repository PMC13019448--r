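# Reader and writer for the plain-text BST dialect.
#
# Sections are delimited by "#<name>::start" / "#<name>::end" markers; "//"
# comments run to end of line; blank lines are ignored. Recognized sections:
# dynamic, static, reactions, kinetics, stoichiometry, alpha, initial,
# staticvalues. Species sections hold one name per line; reactions /
# kinetics / stoichiometry hold record strings (same grammar as the TOML
# dialect); alpha / initial / staticvalues hold "name = value" lines.

#' Parse BST dialect text
#'
#' @param text Character vector of lines (or a single string with newlines).
#' @return A [model_document()].
#' @examples
#' parse_bst_text(c("#dynamic::start", "X1 // substrate", "#dynamic::end"))
#' @export
parse_bst_text <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  known <- c("dynamic", "static", "reactions", "kinetics", "stoichiometry",
             "alpha", "initial", "staticvalues")
  sections <- stats::setNames(vector("list", length(known)), known)
  lineno_of <- stats::setNames(vector("list", length(known)), known)
  current <- NULL; opened_at <- NA_integer_
  for (i in seq_along(lines)) {
    line <- trim(sub("//.*$", "", lines[i]))
    if (!nzchar(line)) next
    mk <- regmatches(line, regexec("^#([A-Za-z_]+)::(start|end)$", line))[[1]]
    if (length(mk)) {
      name <- mk[2]; which <- mk[3]
      if (!(name %in% known))
        stop(sprintf("unknown section '%s' at line %d", name, i), call. = FALSE)
      if (which == "start") {
        if (!is.null(current))
          stop(sprintf("section '%s' opened at line %d inside unterminated section '%s'",
                       name, i, current), call. = FALSE)
        current <- name; opened_at <- i
      } else {
        if (is.null(current) || current != name)
          stop(sprintf("'#%s::end' at line %d does not match an open section", name, i),
               call. = FALSE)
        current <- NULL
      }
      next
    }
    if (is.null(current))
      stop(sprintf("content outside any section at line %d: '%s'", i, line),
           call. = FALSE)
    sections[[current]] <- c(sections[[current]], line)
    lineno_of[[current]] <- c(lineno_of[[current]], i)
  }
  if (!is.null(current))
    stop(sprintf("section '%s' opened at line %d is missing '#%s::end'",
                 current, opened_at, current), call. = FALSE)

  parse_kv <- function(section) {
    ll <- sections[[section]]
    if (is.null(ll)) return(numeric(0))
    out <- numeric(0)
    for (j in seq_along(ll)) {
      eq <- regexpr("=", ll[j], fixed = TRUE)
      val <- suppressWarnings(as.numeric(trim(substr(ll[j], eq + 1, nchar(ll[j])))))
      if (eq < 0 || is.na(val))
        stop(sprintf("cannot parse '%s = value' record '%s' (line %d)",
                     section, ll[j], lineno_of[[section]][j]), call. = FALSE)
      out[trim(substr(ll[j], 1, eq - 1))] <- val
    }
    out
  }
  # validate record syntax early so errors carry the file line number
  for (j in seq_along(sections$reactions))
    parse_reaction_string(sections$reactions[j], line = lineno_of$reactions[j])
  for (j in seq_along(sections$kinetics))
    parse_kinetics_string(sections$kinetics[j], line = lineno_of$kinetics[j])
  for (j in seq_along(sections$stoichiometry))
    parse_override_string(sections$stoichiometry[j], line = lineno_of$stoichiometry[j])

  model_document(
    dynamic_species = sections$dynamic %||% character(0),
    static_species = sections$static %||% character(0),
    reactions = sections$reactions %||% character(0),
    kinetics = sections$kinetics %||% character(0),
    stoichiometry = sections$stoichiometry %||% character(0),
    alpha = parse_kv("alpha"),
    initial = parse_kv("initial"),
    static_values = parse_kv("staticvalues"))
}

#' Read a model from a BST dialect file
#'
#' @param path Path to a `.bst` file.
#' @param as_document Return the [model_document()] instead of the model.
#' @return A validated [bst_model()].
#' @export
read_model_bst <- function(path, as_document = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- parse_bst_text(readLines(path, warn = FALSE))
  if (as_document) doc else document_to_model(doc)
}

#' Write a model as a BST dialect file
#'
#' @param model A `bst_model` with records.
#' @param path Output path.
#' @export
write_model_bst <- function(model, path) {
  doc <- model_to_document(model)
  sec <- function(name, body) {
    if (length(body) == 0) return(character(0))
    c(sprintf("#%s::start", name), body, sprintf("#%s::end", name), "")
  }
  kv <- function(v) sprintf("%s = %s", names(v), num17(v))
  out <- c(sec("dynamic", doc$dynamic_species),
           sec("static", doc$static_species),
           sec("reactions", doc$reactions),
           sec("kinetics", doc$kinetics),
           sec("stoichiometry", doc$stoichiometry),
           sec("alpha", kv(doc$alpha)),
           sec("initial", kv(doc$initial)),
           sec("staticvalues", kv(doc$static_values)))
  writeLines(out, path)
  invisible(path)
}
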
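# Reader and writer for the TOML model dialect.
#
# Schema:
#   [metadata]            author = "...", version = "..."
#   [model]               dynamic_species = [ "X1", ... ]
#                         static_species  = [ "E1", ... ]
#                         reactions  = [ "r1::X1 --> X2", ... ]
#                         kinetics   = [ "r1::X1, E1, X4^-0.5", ... ]
#                         stoichiometry = [ "X2::r1::2.0", ... ]   (optional)
#   [model.alpha]         r1 = 10.0, ...    (one key per reaction)
#   [model.initial]       X1 = 0.1, ...     (missing species default to 0)
#   [model.static_values] E1 = 1.0, ...     (missing species default to 1)
#
# The parser covers exactly this subset of TOML: bare [section] headers,
# key = value lines with string / number / array-of-string values, arrays
# spanning several lines, and # comments.

strip_toml_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  in_str <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == '"') in_str <- !in_str
    if (chars[i] == "#" && !in_str) return(substr(line, 1, i - 1))
  }
  line
}

toml_scalar <- function(tok, lineno) {
  tok <- trim(tok)
  if (grepl('^".*"$', tok)) return(substr(tok, 2, nchar(tok) - 1))
  if (tok %in% c("true", "false")) return(tok == "true")
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num)) return(num)
  stop(sprintf("TOML parse error at line %d: cannot parse value '%s'", lineno, tok),
       call. = FALSE)
}

toml_array <- function(body, lineno) {
  inner <- trim(sub("^\\[", "", sub("\\]$", "", trim(body))))
  if (!nzchar(inner)) return(character(0))
  # split on commas outside quotes
  chars <- strsplit(inner, "", fixed = TRUE)[[1]]
  in_str <- FALSE; cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == '"') in_str <- !in_str
    if (chars[i] == "," && !in_str) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(chars))
  toks <- trim(mapply(function(s, e)
    if (s > e) "" else paste(chars[s:e], collapse = ""), starts, ends))
  toks <- toks[nzchar(toks)]
  vals <- lapply(toks, toml_scalar, lineno = lineno)
  if (all(vapply(vals, is.character, logical(1)))) return(unlist(vals))
  if (all(vapply(vals, is.numeric, logical(1)))) return(unlist(vals))
  stop(sprintf("TOML parse error at line %d: mixed-type array", lineno), call. = FALSE)
}

parse_toml_text <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  tables <- list()
  current <- NULL
  i <- 1L
  while (i <= length(lines)) {
    line <- trim(strip_toml_comment(lines[i]))
    if (!nzchar(line)) { i <- i + 1L; next }
    if (grepl("^\\[[^]]+\\]$", line)) {
      current <- trim(gsub("^\\[|\\]$", "", line))
      if (is.null(tables[[current]])) tables[[current]] <- list()
      i <- i + 1L; next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("TOML parse error at line %d: expected 'key = value', got '%s'",
                   i, line), call. = FALSE)
    if (is.null(current))
      stop(sprintf("TOML parse error at line %d: key outside any [section]", i),
           call. = FALSE)
    key <- trim(substr(line, 1, eq - 1))
    val <- trim(substr(line, eq + 1, nchar(line)))
    lineno <- i
    if (grepl("^\\[", val)) {
      # array, possibly spanning lines: accumulate until brackets balance
      depth_of <- function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        in_str <- FALSE; depth <- 0L
        for (c0 in ch) {
          if (c0 == '"') in_str <- !in_str
          if (!in_str && c0 == "[") depth <- depth + 1L
          if (!in_str && c0 == "]") depth <- depth - 1L
        }
        depth
      }
      while (depth_of(val) > 0L) {
        i <- i + 1L
        if (i > length(lines))
          stop(sprintf("TOML parse error: unterminated array starting at line %d",
                       lineno), call. = FALSE)
        val <- paste(val, trim(strip_toml_comment(lines[i])))
      }
      tables[[current]][[key]] <- toml_array(val, lineno)
    } else {
      tables[[current]][[key]] <- toml_scalar(val, lineno)
    }
    i <- i + 1L
  }
  tables
}

named_num <- function(tbl) {
  if (is.null(tbl) || length(tbl) == 0) return(numeric(0))
  vals <- vapply(tbl, function(v) as.numeric(v)[1], numeric(1))
  stats::setNames(vals, names(tbl))
}

#' Read a model from a TOML dialect file
#'
#' See the package vignette for the full schema. Kinetic orders omitted in
#' `kinetics` strings default to 1.
#'
#' @param path Path to a `.toml` file.
#' @param as_document Return the intermediate [model_document()] instead of
#'   the compiled model.
#' @return A validated [bst_model()] (or a `bst_model_document`).
#' @export
read_model_toml <- function(path, as_document = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tables <- parse_toml_text(readLines(path, warn = FALSE))
  mod <- tables[["model"]]
  if (is.null(mod)) stop("TOML model file has no [model] section", call. = FALSE)
  doc <- model_document(
    metadata = lapply(tables[["metadata"]] %||% list(), as.character),
    dynamic_species = as.character(mod$dynamic_species %||% character(0)),
    static_species = as.character(mod$static_species %||% character(0)),
    reactions = as.character(mod$reactions %||% character(0)),
    kinetics = as.character(mod$kinetics %||% character(0)),
    stoichiometry = as.character(mod$stoichiometry %||% character(0)),
    alpha = named_num(tables[["model.alpha"]]),
    initial = named_num(tables[["model.initial"]]),
    static_values = named_num(tables[["model.static_values"]]))
  if (as_document) doc else document_to_model(doc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toml_str_array <- function(x) {
  if (length(x) == 0) return("[]")
  paste0("[\n", paste(sprintf('    "%s",', x), collapse = "\n"), "\n]")
}

#' Write a model as a TOML dialect file
#'
#' The model must retain its declarative records (see [model_to_document()]).
#' Numbers are written with 17 significant digits so the file rebuilds a
#' bit-identical model.
#'
#' @param model A `bst_model` with records.
#' @param path Output path.
#' @export
write_model_toml <- function(model, path) {
  doc <- model_to_document(model)
  out <- c("[metadata]")
  meta <- doc$metadata
  if (length(meta))
    out <- c(out, sprintf('%s = "%s"', names(meta), unlist(meta)))
  else
    out <- c(out, 'author = "bstkit"', 'version = "1.0"')
  out <- c(out, "", "[model]",
           sprintf("dynamic_species = %s", toml_str_array(doc$dynamic_species)),
           sprintf("static_species = %s", toml_str_array(doc$static_species)),
           sprintf("reactions = %s", toml_str_array(doc$reactions)),
           sprintf("kinetics = %s", toml_str_array(doc$kinetics)))
  if (length(doc$stoichiometry))
    out <- c(out, sprintf("stoichiometry = %s", toml_str_array(doc$stoichiometry)))
  out <- c(out, "", "[model.alpha]",
           sprintf("%s = %s", names(doc$alpha), num17(doc$alpha)),
           "", "[model.initial]",
           sprintf("%s = %s", names(doc$initial), num17(doc$initial)))
  if (length(doc$static_values))
    out <- c(out, "", "[model.static_values]",
             sprintf("%s = %s", names(doc$static_values), num17(doc$static_values)))
  writeLines(out, path)
  invisible(path)
}
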
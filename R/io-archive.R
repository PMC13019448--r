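# Portable JSON model archive.
#
# A single JSON document with an explicit schema_version. Every floating-
# point number is serialized as a 17-significant-digit decimal string
# ("%.17g"), which round-trips IEEE binary64 values bit-exactly; the JSON
# layer itself never formats a double.

ARCHIVE_SCHEMA_VERSION <- 1L

archive_num <- function(x) as.list(sprintf("%.17g", as.numeric(x)))
unarchive_num <- function(x, nm = NULL) {
  v <- as.numeric(unlist(x))
  if (length(v) == 0) v <- numeric(0)
  if (!is.null(nm)) names(v) <- nm
  v
}

record_to_list <- function(r) {
  if (inherits(r, "bst_reaction")) {
    list(name = r$name,
         reactants = if (length(r$reactants)) as.list(stats::setNames(sprintf("%.17g", r$reactants), names(r$reactants))) else NULL,
         products = if (length(r$products)) as.list(stats::setNames(sprintf("%.17g", r$products), names(r$products))) else NULL)
  } else {
    list(reaction = r$reaction,
         dependencies = if (length(r$dependencies)) as.list(stats::setNames(sprintf("%.17g", r$dependencies), names(r$dependencies))) else NULL)
  }
}

list_to_named <- function(l) {
  if (is.null(l) || length(l) == 0) return(NULL)
  stats::setNames(as.numeric(unlist(l)), names(l))
}

#' Serialize a model to a JSON archive
#'
#' The archive is a portable plain-text document carrying a schema version;
#' [load_model()] reproduces the model field-for-field, floating-point
#' bit-exact.
#'
#' @param path Output path (conventionally `.json`).
#' @param model A valid [bst_model()].
#' @return The path, invisibly.
#' @export
save_model <- function(path, model) {
  diags <- validate_model(model)
  if (length(diags))
    stop(paste(c("refusing to save an invalid model:", diags), collapse = "\n  "),
         call. = FALSE)
  recs <- NULL
  if (!is.null(model$records)) {
    ov <- model$records$overrides
    recs <- list(
      reactions = lapply(model$records$reactions, record_to_list),
      kinetics = lapply(model$records$kinetics, record_to_list),
      overrides = if (!is.null(ov) && nrow(as.data.frame(ov))) {
        ov <- as.data.frame(ov)
        lapply(seq_len(nrow(ov)), function(i)
          list(species = as.character(ov$species[i]),
               reaction = as.character(ov$reaction[i]),
               coefficient = sprintf("%.17g", ov$coefficient[i])))
      } else NULL)
  }
  obj <- list(
    schema_version = ARCHIVE_SCHEMA_VERSION,
    format = "bstkit-model-archive",
    dynamic_species = as.list(model$dynamic_species),
    static_species = as.list(model$static_species),
    reaction_names = as.list(model$reaction_names),
    S = archive_num(model$S),
    G = archive_num(model$G),
    alpha = archive_num(model$alpha),
    x0 = archive_num(model$x0),
    xs = archive_num(model$xs),
    metadata = if (length(model$metadata)) model$metadata else NULL,
    records = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model from a JSON archive
#'
#' @param path Path written by [save_model()].
#' @return A validated [bst_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("corrupted model archive '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (!identical(obj$format, "bstkit-model-archive"))
    stop(sprintf("'%s' is not a bstkit model archive", path), call. = FALSE)
  ver <- as.integer(obj$schema_version)
  if (is.na(ver) || ver > ARCHIVE_SCHEMA_VERSION)
    stop(sprintf("model archive schema version %s is newer than the supported version %d",
                 obj$schema_version, ARCHIVE_SCHEMA_VERSION), call. = FALSE)
  dyn <- as.character(unlist(obj$dynamic_species))
  sta <- as.character(unlist(obj$static_species))
  rn <- as.character(unlist(obj$reaction_names))
  n <- length(dyn); m <- length(sta); p <- length(rn)
  recs <- NULL
  if (!is.null(obj$records)) {
    reactions <- lapply(obj$records$reactions, function(r)
      reaction_record(r$name, list_to_named(r$reactants), list_to_named(r$products)))
    kinetics <- lapply(obj$records$kinetics, function(k)
      kinetics_record(k$reaction, list_to_named(k$dependencies)))
    overrides <- if (!is.null(obj$records$overrides)) {
      do.call(rbind, lapply(obj$records$overrides, function(o)
        data.frame(species = o$species, reaction = o$reaction,
                   coefficient = as.numeric(o$coefficient),
                   stringsAsFactors = FALSE)))
    } else NULL
    recs <- list(reactions = reactions, kinetics = kinetics, overrides = overrides)
  }
  bst_model(dyn, sta,
            S = matrix(unarchive_num(obj$S), n, p),
            G = matrix(unarchive_num(obj$G), n + m, p),
            alpha = unarchive_num(obj$alpha),
            x0 = unarchive_num(obj$x0),
            xs = unarchive_num(obj$xs),
            reaction_names = rn, records = recs,
            metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}

#' Construct a model from a file
#'
#' Dispatches on the file extension: `.toml` (TOML dialect), `.bst`
#' (plain-text BST dialect), or `.json` (model archive). The result is
#' always validated; validation diagnostics are promoted to errors.
#'
#' @param path Path to a model file.
#' @return A validated [bst_model()].
#' @examples
#' path <- system.file("extdata", "feedback.toml", package = "bstkit")
#' build_model(path)
#' @export
build_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         toml = read_model_toml(path),
         bst = read_model_bst(path),
         json = load_model(path),
         stop(sprintf("unknown model file extension '.%s' (expected .toml, .bst, or .json)",
                      ext), call. = FALSE))
}
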
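#' Read a YAML run configuration
#'
#' A run configuration file has up to three blocks: `model` (arguments of
#' [rxn_config()]), `schema` (arguments of [rxn_schema()]) and `cv`
#' (`k`, `val_fraction`). Unknown keys are rejected so that typos fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (`rxn_config`), `schema`
#'   (`rxn_schema` or `NULL`) and `cv` (list or `NULL`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("model", "schema", "cv")
  extra <- setdiff(names(raw), known_top)
  if (length(extra) > 0L) {
    abort(paste0("Unknown configuration block(s): ",
                 paste(extra, collapse = ", ")),
          class = "rxngraph_config_error")
  }
  model_args <- raw$model %||% list()
  extra <- setdiff(names(model_args), names(formals(rxn_config)))
  if (length(extra) > 0L) {
    abort(paste0("Unknown model key(s): ", paste(extra, collapse = ", ")),
          class = "rxngraph_config_error")
  }
  schema <- NULL
  if (!is.null(raw$schema)) {
    extra <- setdiff(names(raw$schema), names(formals(rxn_schema)))
    if (length(extra) > 0L) {
      abort(paste0("Unknown schema key(s): ", paste(extra, collapse = ", ")),
            class = "rxngraph_config_error")
    }
    schema <- do.call(rxn_schema, raw$schema)
  }
  cv <- NULL
  if (!is.null(raw$cv)) {
    extra <- setdiff(names(raw$cv), c("k", "val_fraction"))
    if (length(extra) > 0L) {
      abort(paste0("Unknown cv key(s): ", paste(extra, collapse = ", ")),
            class = "rxngraph_config_error")
    }
    cv <- raw$cv
  }
  list(config = do.call(rxn_config, model_args), schema = schema, cv = cv)
}

#' Echo a run configuration to YAML
#'
#' Writes the fully resolved configuration (all defaults filled in) next to
#' a run's outputs so that the run can be reproduced from the echo and seed
#' alone.
#'
#' @param config An [rxn_config()].
#' @param schema An [rxn_schema()] or `NULL`.
#' @param cv Optional list with `k` and `val_fraction`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config_echo <- function(config, schema = NULL, cv = NULL, path) {
  out <- list(model = unclass(config))
  if (!is.null(schema)) out$schema <- unclass(schema)
  if (!is.null(cv)) out$cv <- cv
  yaml::write_yaml(out, path)
  invisible(path)
}
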
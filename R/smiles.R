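# SMILES handling sits on ChemmineOB (OpenBabel) for parsing and canonical
# ranking. Parsed structures are cached per canonical SMILES because datasets
# reuse a small substrate vocabulary thousands of times.

.smiles_cache <- new.env(parent = emptyenv())

#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to its canonical form so that different written
#' forms of the same molecule map to the same directed graph (and hence the
#' same learned embedding). Multi-fragment inputs (salts, mixtures written
#' with `.`) are reduced to their largest fragment with a warning, since the
#' encoder embeds a single connected component per reaction role.
#'
#' @param smiles A single SMILES string.
#' @return A single canonical SMILES string.
#' @examples
#' canonical_smiles("c1ccccc1N")
#' @export
canonical_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    abort("`smiles` must be a single non-empty string.", class = "rxngraph_parse_error")
  }
  smiles <- trimws(smiles)
  key <- paste0("can::", smiles)
  hit <- get0(key, envir = .smiles_cache)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  out <- trimws(out)
  if (!nzchar(out)) {
    abort(paste0("Could not parse SMILES: '", smiles, "'"),
          class = "rxngraph_parse_error")
  }
  if (grepl(".", out, fixed = TRUE)) {
    frags <- strsplit(out, ".", fixed = TRUE)[[1]]
    # heavy-atom count by stripping ring digits / bond symbols / brackets
    n_heavy <- vapply(frags, function(f) {
      nchar(gsub("[^A-Za-z]", "", gsub("H[0-9]*", "", f)))
    }, integer(1))
    keep <- frags[[which.max(n_heavy)]]
    warn(paste0("Multi-fragment SMILES '", smiles,
                "': keeping largest fragment '", keep, "'."))
    out <- canonical_smiles(keep)
  }
  assign(key, out, envir = .smiles_cache)
  out
}

# Parse a canonical SMILES into a ChemmineR SDF object (kekulized, 2D).
parse_smiles_sdf <- function(smiles_can) {
  key <- paste0("sdf::", smiles_can)
  hit <- get0(key, envir = .smiles_cache)
  if (!is.null(hit)) return(hit)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles_can)),
    error = function(e) NULL
  )
  if (is.null(sdfset) || length(sdfset) < 1L) {
    abort(paste0("Could not parse SMILES: '", smiles_can, "'"),
          class = "rxngraph_parse_error")
  }
  sdf <- sdfset[[1]]
  if (nrow(ChemmineR::atomblock(sdf)) < 1L) {
    abort(paste0("SMILES '", smiles_can, "' yields a molecule with no atoms."),
          class = "rxngraph_parse_error")
  }
  assign(key, sdf, envir = .smiles_cache)
  sdf
}

# Count of SMARTS matches per molecule SMILES (vectorized over smiles).
smarts_count <- function(smiles, smarts) {
  vapply(smiles, function(s) {
    sdf <- parse_smiles_sdf(canonical_smiles(s))
    sdfset <- methods::as(sdf, "SDFset")
    ChemmineR::cid(sdfset) <- "m1"
    as.integer(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = FALSE))
  }, integer(1), USE.NAMES = FALSE)
}
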
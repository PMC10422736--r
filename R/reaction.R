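# Reaction-level representation: per-component molecule embeddings are
# aggregated (sum or ordered concatenation) into one reaction vector;
# categorical components that have no sensible graph (catalysts, bases,
# inorganic reagents) are appended as one-hot blocks; a dense head with one
# hidden layer regresses the normalized outcome.

#' Declare the column schema of a reaction table
#'
#' A dataset is a data frame with one row per reaction. The schema names the
#' SMILES columns (in the fixed role order used for concatenation, e.g.
#' amine, bromide, product), any categorical columns encoded one-hot, and
#' the numeric outcome column.
#'
#' @param components Character vector of SMILES column names, in role order.
#' @param categorical Character vector of categorical column names (may be
#'   empty).
#' @param outcome Name of the numeric outcome column.
#' @return A list of class `rxn_schema`.
#' @examples
#' rxn_schema(c("amine", "bromide", "product"), outcome = "ratio")
#' @export
rxn_schema <- function(components, categorical = character(), outcome) {
  if (!is.character(components) || length(components) < 1L) {
    abort("`components` must name at least one SMILES column.")
  }
  if (!is.character(outcome) || length(outcome) != 1L) {
    abort("`outcome` must be a single column name.")
  }
  structure(list(components = components,
                 categorical = as.character(categorical),
                 outcome = outcome),
            class = "rxn_schema")
}

check_schema <- function(data, schema, need_outcome = TRUE) {
  cols <- c(schema$components, schema$categorical,
            if (need_outcome) schema$outcome)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rxngraph_schema_error")
  }
  invisible(TRUE)
}

#' One-hot encode a categorical value against a fixed vocabulary
#'
#' @param value A single category label.
#' @param vocabulary Character vector of known categories (built from
#'   training data).
#' @return A 0/1 vector of length `length(vocabulary)` with exactly one 1.
#' @examples
#' encode_onehot("b", c("a", "b", "c"))
#' @export
encode_onehot <- function(value, vocabulary) {
  i <- match(as.character(value), vocabulary)
  if (is.na(i)) {
    abort(paste0("Unknown category '", value, "'; known values: ",
                 paste(vocabulary, collapse = ", ")),
          class = "rxngraph_unknown_category")
  }
  v <- numeric(length(vocabulary))
  v[i] <- 1
  v
}

#' Aggregate component embeddings into a reaction vector
#'
#' @param molecule_vectors A list of equal-length numeric vectors (one per
#'   graph component, in role order) or a matrix with one row per component.
#' @param mode `"sum"` (elementwise sum, length `d`) or `"concat"` (ordered
#'   concatenation, length `d * n`).
#' @return A numeric reaction vector.
#' @examples
#' aggregate_reaction(list(1:3, 4:6), mode = "sum")     # length 3
#' aggregate_reaction(list(1:3, 4:6), mode = "concat")  # length 6
#' @export
aggregate_reaction <- function(molecule_vectors, mode = c("concat", "sum")) {
  mode <- match.arg(mode)
  if (is.matrix(molecule_vectors)) {
    molecule_vectors <- asplit(molecule_vectors, 1L)
  }
  if (length(molecule_vectors) == 0L) {
    abort("Need at least one component vector.")
  }
  lens <- lengths(molecule_vectors)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("Component vectors have mixed widths: %s.",
                  paste(unique(lens), collapse = ", ")),
          class = "rxngraph_shape_error")
  }
  vecs <- lapply(molecule_vectors, as.numeric)
  if (mode == "sum") Reduce(`+`, vecs) else unlist(vecs, use.names = FALSE)
}

#' Predict a normalized outcome from a reaction vector
#'
#' Applies the dense head (hidden layer with ReLU, then a linear unit) to a
#' reaction vector. Mostly useful for inspection; [predict.rxn_model()] runs
#' the full pipeline.
#'
#' @param reaction_vector Numeric vector of the head's input width.
#' @param head_params List with `W1`, `b1`, `W2`, `b2` (as in a fitted
#'   model's `$params`).
#' @return A single numeric prediction on the normalized outcome scale.
#' @export
predict_outcome <- function(reaction_vector, head_params) {
  if (length(reaction_vector) != nrow(head_params$W1)) {
    abort(sprintf("Reaction vector width %d does not match head input %d.",
                  length(reaction_vector), nrow(head_params$W1)),
          class = "rxngraph_shape_error")
  }
  drop(head_forward(matrix(reaction_vector, 1L), head_params)$yhat)
}

head_forward <- function(U, params) {
  A_pre <- addb(U %*% params$W1, params$b1)
  A <- relu(A_pre)
  yhat <- drop(A %*% params$W2) + params$b2
  list(U = U, A = A, yhat = yhat)
}

# dY: gradient w.r.t. predictions (length n). Returns head parameter
# gradients and the gradient w.r.t. the reaction-vector matrix U.
head_backward <- function(dY, fwd, params) {
  dA <- matrix(dY, ncol = 1L) %*% t(params$W2) # n x hh
  dA_pre <- dA * (fwd$A > 0)
  list(W1 = crossprod(fwd$U, dA_pre),
       b1 = colSums(dA_pre),
       W2 = crossprod(fwd$A, matrix(dY, ncol = 1L)),
       b2 = sum(dY),
       dU = dA_pre %*% t(params$W1))
}

# Build categorical vocabularies (one per categorical column) from training
# rows only.
build_vocab <- function(data, schema) {
  setNames(lapply(schema$categorical,
                  function(cl) sort(unique(as.character(data[[cl]])))),
           schema$categorical)
}

onehot_block <- function(data, vocab) {
  if (length(vocab) == 0L) return(matrix(0, nrow(data), 0L))
  do.call(cbind, lapply(names(vocab), function(cl) {
    t(vapply(as.character(data[[cl]]),
             encode_onehot, numeric(length(vocab[[cl]])),
             vocabulary = vocab[[cl]], USE.NAMES = FALSE))
  }))
}

# Reaction-vector width implied by config + schema + vocabularies.
reaction_width <- function(config, schema, vocab) {
  d <- config$hidden_size
  n <- length(schema$components)
  graph_part <- if (config$aggregation == "concat") d * n else d
  graph_part + sum(lengths(vocab))
}

# Assemble reaction vectors for `data` given molecule embeddings `emb`
# (rows indexed by canonical SMILES). comp_can: n x n_comp matrix of
# canonical SMILES per reaction/role.
assemble_reactions <- function(emb, comp_can, oh, config) {
  d <- ncol(emb)
  idx <- matrix(match(comp_can, rownames(emb)), nrow = nrow(comp_can))
  if (config$aggregation == "concat") {
    G <- do.call(cbind, lapply(seq_len(ncol(idx)), function(j) {
      emb[idx[, j], , drop = FALSE]
    }))
  } else {
    G <- Reduce(`+`, lapply(seq_len(ncol(idx)), function(j) {
      emb[idx[, j], , drop = FALSE]
    }))
  }
  list(U = cbind(G, oh), idx = idx, d = d)
}

# Push dU (gradient w.r.t. reaction vectors) back onto the unique-molecule
# embedding matrix.
disperse_dU <- function(dU, asm, config, n_unique) {
  d <- asm$d
  dEmb <- matrix(0, n_unique, d)
  for (j in seq_len(ncol(asm$idx))) {
    cols <- if (config$aggregation == "concat") (j - 1L) * d + seq_len(d) else
      seq_len(d)
    dEmb <- scatter_add(dEmb, asm$idx[, j], dU[, cols, drop = FALSE])
  }
  dEmb
}
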
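# Directed molecular graphs: each chemical bond contributes two opposed
# directed edges so the encoder can keep edge-wise hidden states. Atom and
# bond descriptors are encoded as fixed-width one-hot blocks.

ATOM_ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
ATOM_MASSES <- c(B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                 Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
                 I = 126.904)
ATOM_DEGREES <- 0:5
ATOM_CHARGES <- c(-2L, -1L, 0L, 1L, 2L)
ATOM_HCOUNTS <- 0:4
ATOM_HYBRID <- c("sp", "sp2", "sp3")
# element(+other) + degree + charge(+other) + chirality + Hcount(+other) +
# hybridization + aromatic flag + scaled mass
FA <- (length(ATOM_ELEMENTS) + 1L) + length(ATOM_DEGREES) +
  (length(ATOM_CHARGES) + 1L) + 3L + (length(ATOM_HCOUNTS) + 1L) +
  length(ATOM_HYBRID) + 1L + 1L
BOND_TYPES <- c("single", "double", "triple", "aromatic")
# bond type + conjugation + ring + stereo {none, wedge/annotated}
FB <- length(BOND_TYPES) + 1L + 1L + 2L

# default valences used to infer implicit hydrogen counts from kekulized
# bond orders (the SDF route stores hydrogens implicitly)
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, Br = 1, I = 1)

#' Number of atom and bond descriptor dimensions
#'
#' @return Named integer vector with elements `atom` (width of the atom
#'   feature vector) and `bond` (width of the bond feature vector).
#' @export
feature_widths <- function() c(atom = FA, bond = FB)

one_hot <- function(value, levels, other = TRUE) {
  v <- numeric(length(levels) + as.integer(other))
  i <- match(value, levels)
  if (is.na(i)) {
    if (other) v[length(v)] <- 1 else abort("Value outside one-hot vocabulary.")
  } else {
    v[i] <- 1
  }
  v
}

featurize_atom_row <- function(element, degree, charge, parity, n_h, hybrid,
                               aromatic) {
  mass <- if (element %in% names(ATOM_MASSES)) ATOM_MASSES[[element]] else 0
  c(one_hot(element, ATOM_ELEMENTS),
    one_hot(min(degree, 5L), ATOM_DEGREES, other = FALSE),
    one_hot(charge, ATOM_CHARGES),
    one_hot(parity, c(1L, 2L)),
    one_hot(n_h, ATOM_HCOUNTS),
    one_hot(hybrid, ATOM_HYBRID, other = FALSE),
    as.numeric(aromatic),
    mass / 100)
}

featurize_bond_row <- function(type, conjugated, in_ring, stereo) {
  c(one_hot(type, BOND_TYPES, other = FALSE),
    as.numeric(conjugated),
    as.numeric(in_ring),
    one_hot(if (stereo != 0) "annotated" else "none", c("none", "annotated"),
            other = FALSE))
}

mdl_charge <- function(code) {
  # MDL charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 radical, 5 -1, 6 -2, 7 -3
  unname(c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)[as.character(code)])
}

#' Build a directed molecular graph from a SMILES string
#'
#' Parses a SMILES string (canonicalizing it first, so every written form of
#' a molecule yields the same graph), perceives aromaticity and rings, and
#' returns the directed-graph representation used by the message-passing
#' encoder: every chemical bond becomes a pair of opposed directed edges with
#' identical bond features, and each directed edge knows the index of its
#' reverse. Hydrogens are implicit (encoded as an attached-H count feature,
#' not as graph nodes).
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol_graph`: a list with `smiles` (canonical
#'   form), `n_atoms`, `n_edges`, `elements`, `atom_features`
#'   (`n_atoms x feature_widths()["atom"]`), `edge_features`
#'   (`n_edges x feature_widths()["bond"]`), integer vectors `src`, `dst`,
#'   `rev` (directed-edge endpoints and reverse-edge index), and `atom_order`
#'   (canonical readout order).
#' @examples
#' g <- build_graph("c1ccccc1")
#' g$n_atoms  # 6
#' g$n_edges  # 12: six ring bonds, two directions each
#' @export
build_graph <- function(smiles) {
  can <- canonical_smiles(smiles)
  key <- paste0("graph::", can)
  hit <- get0(key, envir = .smiles_cache)
  if (!is.null(hit)) return(hit)
  sdf <- parse_smiles_sdf(can)
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  elements <- gsub("_.*$", "", rownames(ab))
  charges <- if ("C6" %in% colnames(ab)) mdl_charge(ab[, "C6"]) else
    integer(n)
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else
    integer(n)

  has_bonds <- nrow(bb) > 0L && any(bb[, 1] > 0)
  if (has_bonds) {
    from <- as.integer(bb[, 1]); to <- as.integer(bb[, 2])
    order_kek <- as.integer(bb[, 3])
    stereo <- as.integer(bb[, 4])
  } else {
    from <- to <- order_kek <- stereo <- integer(0)
  }
  nb <- length(from)
  if (any(c(from, to) > n)) {
    abort(paste0("Malformed bond table for SMILES '", can, "'"))
  }

  # aromatic perception: ChemmineR ring detection flags aromatic rings
  arom_atoms <- rep(FALSE, n)
  arom_bond <- rep(FALSE, nb)
  ring_bond <- rep(FALSE, nb)
  if (nb > 0L) {
    rn <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_sets <- lapply(rn$RINGS, function(r) as.integer(gsub(".*_", "", r)))
    arom_flag <- rn$AROMATIC
    for (i in seq_along(ring_sets)) {
      rs <- ring_sets[[i]]
      in_r <- from %in% rs & to %in% rs
      # bond must connect consecutive members of this ring, which for a
      # chordless ring equals both endpoints being members
      ring_bond <- ring_bond | in_r
      if (isTRUE(arom_flag[[i]])) {
        arom_atoms[rs] <- TRUE
        arom_bond <- arom_bond | in_r
      }
    }
  }

  deg <- tabulate(c(from, to), nbins = n)
  bond_order_sum <- rep(0, n)
  n_double <- rep(0L, n); n_triple <- rep(0L, n)
  if (nb > 0L) {
    for (b in seq_len(nb)) {
      o <- order_kek[b]
      bond_order_sum[from[b]] <- bond_order_sum[from[b]] + o
      bond_order_sum[to[b]] <- bond_order_sum[to[b]] + o
      if (o == 2L) {
        n_double[from[b]] <- n_double[from[b]] + 1L
        n_double[to[b]] <- n_double[to[b]] + 1L
      } else if (o == 3L) {
        n_triple[from[b]] <- n_triple[from[b]] + 1L
        n_triple[to[b]] <- n_triple[to[b]] + 1L
      }
    }
  }
  hybrid <- ifelse(n_triple > 0 | n_double >= 2, "sp",
                   ifelse(arom_atoms | n_double == 1, "sp2", "sp3"))
  val <- unname(DEFAULT_VALENCE[elements])
  val[is.na(val)] <- 0
  n_h <- pmax(0L, as.integer(round(val + charges - bond_order_sum)))

  atom_features <- t(vapply(seq_len(n), function(i) {
    featurize_atom_row(elements[i], deg[i], charges[i], parity[i], n_h[i],
                       hybrid[i], arom_atoms[i])
  }, numeric(FA)))

  # expand undirected bonds into directed edge pairs: edge 2b-1 is from->to,
  # edge 2b is to->from, so rev() is a fixed interleave
  src <- integer(2L * nb); dst <- integer(2L * nb); rev <- integer(2L * nb)
  edge_features <- matrix(0, 2L * nb, FB)
  sp2ish <- arom_atoms | n_double > 0 | n_triple > 0
  for (b in seq_len(nb)) {
    type <- if (arom_bond[b]) "aromatic" else
      c("single", "double", "triple")[min(order_kek[b], 3L)]
    conj <- arom_bond[b] || (sp2ish[from[b]] && sp2ish[to[b]])
    fv <- featurize_bond_row(type, conj, ring_bond[b], stereo[b])
    i1 <- 2L * b - 1L; i2 <- 2L * b
    src[i1] <- from[b]; dst[i1] <- to[b]
    src[i2] <- to[b]; dst[i2] <- from[b]
    rev[i1] <- i2; rev[i2] <- i1
    edge_features[i1, ] <- fv
    edge_features[i2, ] <- fv
  }

  g <- structure(list(
    smiles = can,
    n_atoms = n,
    n_edges = 2L * nb,
    elements = elements,
    atom_features = atom_features,
    edge_features = edge_features,
    src = src,
    dst = dst,
    rev = rev,
    atom_order = seq_len(n)
  ), class = "mol_graph")
  assign(key, g, envir = .smiles_cache)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", x$n_atoms, "  directed edges: ", x$n_edges, "\n", sep = "")
  invisible(x)
}

# Disjoint union of molecular graphs for batched encoding. Atom/edge indices
# are offset per molecule; `mol_of_atom` maps global atom rows back to the
# molecule they belong to.
batch_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, `[[`, integer(1), "n_atoms")
  n_edges <- vapply(graphs, `[[`, integer(1), "n_edges")
  atom_off <- cumsum(c(0L, head(n_atoms, -1L)))
  edge_off <- cumsum(c(0L, head(n_edges, -1L)))
  list(
    n_mols = length(graphs),
    n_atoms = sum(n_atoms),
    n_edges = sum(n_edges),
    atoms_per_mol = n_atoms,
    atom_features = do.call(rbind, lapply(graphs, `[[`, "atom_features")),
    edge_features = do.call(rbind, lapply(graphs, `[[`, "edge_features")),
    src = unlist(Map(function(g, o) g$src + o, graphs, atom_off)),
    dst = unlist(Map(function(g, o) g$dst + o, graphs, atom_off)),
    rev = unlist(Map(function(g, o) g$rev + o, graphs, edge_off)),
    mol_of_atom = rep.int(seq_along(graphs), n_atoms),
    # node_seq[[t]]: global atom index of the t-th atom (canonical order)
    # of every molecule with at least t atoms; used by the batched readout
    node_seq = {
      maxn <- max(n_atoms)
      lapply(seq_len(maxn), function(t) {
        keep <- which(n_atoms >= t)
        idx <- atom_off[keep] + vapply(graphs[keep],
                                       function(g) g$atom_order[t], integer(1))
        list(mols = keep, rows = idx)
      })
    }
  )
}
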
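# High-throughput-experimentation data reduction for C-N coupling plates:
# UV response of the product is normalized by an internal standard (IS) to a
# yield proxy, and reactions are grouped by the aromatic class (benzenoid vs
# pyridyl) of the amine and the bromide.

#' UV response ratio of product over internal standard
#'
#' Computes `ratio_UV = A_product * c / A_IS * 100%`, where `A_product` and
#' `A_IS` are the UV response areas (254 nm) of the product and of the
#' internal standard and `c` is the IS/product mole ratio at 100%
#' theoretical yield (0.0625 equivalents of
#' 4,4'-di-tert-butyl-1,1'-biphenyl in the reference protocol). With
#' `percent = FALSE` (default) the ratio is returned as a fraction in
#' `[0, 1]`-scale units, the form used for modelling; values above 1 are
#' retained with a warning rather than clipped.
#'
#' @param a_product Numeric vector of product response areas (>= 0).
#' @param a_is Numeric vector of internal-standard response areas (> 0).
#' @param c_eq Mole-ratio constant (default 0.0625).
#' @param percent If `TRUE`, return percent (0-100) instead of a fraction.
#' @return Numeric vector of UV ratios.
#' @examples
#' compute_ratio_uv(16, 1)                  # 1: the 100% point at c = 0.0625
#' compute_ratio_uv(1, 1, percent = TRUE)   # 6.25
#' @export
compute_ratio_uv <- function(a_product, a_is, c_eq = 0.0625, percent = FALSE) {
  if (any(!is.finite(a_is)) || any(a_is <= 0)) {
    abort("`a_is` must be a positive internal-standard signal.")
  }
  if (any(!is.finite(a_product)) || any(a_product < 0)) {
    abort("`a_product` must be non-negative.")
  }
  if (!is.numeric(c_eq) || c_eq <= 0) abort("`c_eq` must be positive.")
  r <- a_product * c_eq / a_is
  if (any(r > 1)) {
    warn(sprintf("%d ratio value(s) exceed 1 (100%%); retained unclipped.",
                 sum(r > 1)))
  }
  if (percent) r * 100 else r
}

# Classify the six-membered aromatic ring directly bearing `anchor` (a
# SMARTS fragment for the reactive group) as pyridine-type ("Py", ring
# nitrogen ortho/meta/para to the attachment) or benzene-type ("Ph").
classify_attached_ring <- function(smiles, anchor) {
  py_pats <- paste0(anchor, c("c1naaaa1", "c1anaaa1", "c1aanaa1"))
  ph_pat <- paste0(anchor, "c1ccccc1")
  vapply(smiles, function(s) {
    if (any(vapply(py_pats, function(p) smarts_count(s, p) > 0, logical(1)))) {
      "Py"
    } else if (smarts_count(s, ph_pat) > 0) {
      "Ph"
    } else {
      NA_character_
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Assign substrate-class groups G1-G4 to amine/bromide pairs
#'
#' Reactions between a primary aryl amine and an aryl bromide fall into four
#' quadrants by the aromatic class of the ring bearing the reactive group:
#' G1 = Ph-NH2 x Ph-Br, G2 = Ph-NH2 x Py-Br, G3 = Py-NH2 x Ph-Br,
#' G4 = Py-NH2 x Py-Br, where "Py" means that ring is a pyridine and "Ph" a
#' benzene (fused systems classify by the attached ring only).
#'
#' @param amine_smiles,bromide_smiles Character vectors (recycled to common
#'   length) of substrate SMILES; the amine must carry a primary amine on an
#'   aromatic ring and the bromide an aromatic bromide.
#' @return Character vector of `"G1".."G4"`.
#' @examples
#' assign_group("Nc1ccccc1", "Brc1ccccc1")  # G1
#' assign_group("Nc1ccncc1", "Brc1ccccc1")  # G3
#' @export
assign_group <- function(amine_smiles, bromide_smiles) {
  n <- max(length(amine_smiles), length(bromide_smiles))
  amine_smiles <- rep_len(amine_smiles, n)
  bromide_smiles <- rep_len(bromide_smiles, n)
  amine_cls <- classify_attached_ring(amine_smiles, "[NX3;H2]-")
  bromide_cls <- classify_attached_ring(bromide_smiles, "[Br]-")
  bad <- which(is.na(amine_cls) | is.na(bromide_cls))
  if (length(bad) > 0L) {
    abort(paste0("Unclassifiable substrate pair(s): ",
                 paste(sprintf("(%s, %s)", amine_smiles[bad],
                               bromide_smiles[bad])[seq_len(min(3, length(bad)))],
                       collapse = "; ")),
          class = "rxngraph_unclassifiable")
  }
  dplyr::case_when(
    amine_cls == "Ph" & bromide_cls == "Ph" ~ "G1",
    amine_cls == "Ph" & bromide_cls == "Py" ~ "G2",
    amine_cls == "Py" & bromide_cls == "Ph" ~ "G3",
    TRUE ~ "G4"
  )
}

#' Per-group counts and high-conversion fractions
#'
#' Summarizes grouped plate records: for each group, the number of reactions
#' and the fraction with a UV ratio at or above a threshold (default 0.5 on
#' the fractional scale).
#'
#' @param records Data frame with columns `group` and `ratio_uv` (fractions
#'   in `[0, 1]`).
#' @param threshold Ratio threshold (default 0.5).
#' @return A tibble with columns `group`, `n`, `n_at_least`,
#'   `fraction_at_least` (NA for empty groups).
#' @export
summarize_groups <- function(records, threshold = 0.5) {
  stopifnot(all(c("group", "ratio_uv") %in% names(records)))
  records |>
    dplyr::mutate(group = factor(.data$group,
                                 levels = c("G1", "G2", "G3", "G4"))) |>
    dplyr::group_by(.data$group, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_at_least = sum(.data$ratio_uv >= threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction_at_least = ifelse(.data$n > 0, .data$n_at_least / .data$n,
                                 NA_real_),
      group = as.character(.data$group)
    )
}

#' Reduce raw plate measurements to ratios and groups
#'
#' The one-call HTE reduction: computes the UV ratio from raw response areas
#' (unless a precomputed `ratio_uv` column is already present) and assigns
#' the G1-G4 substrate group.
#'
#' @param data Data frame with `amine_smiles`, `bromide_smiles` and either
#'   (`a_product`, `a_is`) or `ratio_uv`.
#' @param c_eq Mole-ratio constant for [compute_ratio_uv()].
#' @return The input as a tibble with `ratio_uv` (fraction) and `group`
#'   columns added.
#' @export
reduce_plate <- function(data, c_eq = 0.0625) {
  stopifnot(all(c("amine_smiles", "bromide_smiles") %in% names(data)))
  out <- tibble::as_tibble(data)
  if (!"ratio_uv" %in% names(out)) {
    if (!all(c("a_product", "a_is") %in% names(out))) {
      abort("Need either `ratio_uv` or both `a_product` and `a_is`.")
    }
    out$ratio_uv <- compute_ratio_uv(out$a_product, out$a_is, c_eq)
  }
  out$group <- assign_group(out$amine_smiles, out$bromide_smiles)
  out
}

#' Amine-by-bromide ratio matrix
#'
#' Arranges plate records as a matrix of UV ratios with one column per amine
#' ("A" ids) and one row per bromide ("B" ids); combinations never measured
#' (failed or discarded reactions) are `NA`.
#'
#' @param records Data frame with `amine_smiles`, `bromide_smiles`,
#'   `ratio_uv`.
#' @return A numeric matrix, rownames `B1..`, colnames `A1..`, with
#'   attributes `amine_smiles` and `bromide_smiles` giving the id-to-SMILES
#'   mapping.
#' @export
ratio_matrix <- function(records) {
  amines <- unique(records$amine_smiles)
  bromides <- unique(records$bromide_smiles)
  m <- matrix(NA_real_, length(bromides), length(amines),
              dimnames = list(paste0("B", seq_along(bromides)),
                              paste0("A", seq_along(amines))))
  i <- match(records$bromide_smiles, bromides)
  j <- match(records$amine_smiles, amines)
  m[cbind(i, j)] <- records$ratio_uv
  attr(m, "amine_smiles") <- amines
  attr(m, "bromide_smiles") <- bromides
  m
}

#' Heatmap of the amine-by-bromide ratio matrix
#'
#' @param records Data frame as for [ratio_matrix()].
#' @return A ggplot tile heatmap; unmeasured combinations are grey.
#' @export
plot_ratio_heatmap <- function(records) {
  m <- ratio_matrix(records)
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "ratio_uv",
                                              stringsAsFactors = FALSE))
  names(df)[1:2] <- c("bromide", "amine")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amine, y = .data$bromide,
                                   fill = .data$ratio_uv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80",
                                  name = "ratio_UV") +
    ggplot2::labs(x = "Amine", y = "Bromide") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Load a reduced HTE reaction table if present
#'
#' Reads a CSV of already-reduced coupling reactions (columns
#' `amine_smiles`, `bromide_smiles`, and `ratio_uv` or raw areas) such as a
#' published supplementary dataset, returning `NULL` when the file does not
#' exist so that analyses depending on external data can be skipped cleanly.
#'
#' @param path Path to the CSV file.
#' @return A reduced tibble (see [reduce_plate()]) or `NULL` if `path` is
#'   missing.
#' @export
load_plate_csv <- function(path) {
  if (!file.exists(path)) return(NULL)
  reduce_plate(utils::read.csv(path, stringsAsFactors = FALSE))
}
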
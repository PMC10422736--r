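# Seeded generator of C-N coupling reaction tables with known ground truth.
# It emulates the structure of an HTE campaign: a small vocabulary of
# substituted benzenoid and pyridyl amines and bromides (ortho/meta/para
# electron-donating and -withdrawing substituents), a smooth latent outcome
# in substituent space, and a heavily left-skewed observed distribution.

# aryl fragments written with the attachment (ipso) atom first, so an amine
# is "N" + fragment, a bromide "Br" + fragment, and the coupling product
# "N(" + fragA + ")" + fragB
AMINE_FRAGMENTS <- c(
  "c1ccccc1", "c1ccc(C)cc1", "c1cccc(OC)c1", "c1ccc(F)cc1",
  "c1cccc(C(F)(F)F)c1", "c1ccc(C#N)cc1",
  "c1ccccn1", "c1cccnc1", "c1ccncc1",
  "c1ccc(C)cn1", "c1cc(F)cnc1", "c1cc(OC)ccn1"
)
BROMIDE_FRAGMENTS <- c(
  "c1ccccc1", "c1ccc(C)cc1", "c1ccc(OC)cc1", "c1cccc(F)c1",
  "c1ccc(C(F)(F)F)cc1", "c1cc(C#N)ccc1",
  "c1ccccn1", "c1cccnc1", "c1ccncc1",
  "c1cc(C)ccn1", "c1ccc(F)cn1", "c1cc(C(F)(F)F)cnc1"
)

#' Generate a synthetic reaction dataset with known ground truth
#'
#' Samples amine/bromide pairs from a built-in vocabulary of substituted
#' benzenoid and pyridyl substrates, composes the coupling product SMILES,
#' and draws outcomes from a smooth latent model:
#' `truth = plogis(base + amine_effect + bromide_effect + interaction)^skew`,
#' with per-substrate effects drawn once from seeded normal distributions.
#' The observed outcome adds Gaussian noise and is clipped to `[0, 1]`. With
#' the default `skew = 3` roughly half of the outcomes fall below 0.2,
#' mimicking the strongly left-skewed conversion distributions of real
#' coupling campaigns; the median outcome decreases as `skew` grows.
#'
#' @param n Number of reactions.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param noise_sd Standard deviation of the observation noise (outcome
#'   units; default 0.05).
#' @param skew Power (>= 0) applied to the logistic latent value; larger
#'   values push outcomes toward 0.
#' @param effect_sd,interaction_sd,base Latent-model scales: SD of the
#'   per-substrate main effects, SD of the pairwise interaction, and the
#'   logistic intercept.
#' @param amine_fragments,bromide_fragments Optional custom vocabularies of
#'   aryl fragments written with the attachment atom first.
#' @return A tibble with columns `amine`, `bromide`, `product` (SMILES),
#'   `amine_id`, `bromide_id`, `ratio` (observed outcome in `[0, 1]`) and
#'   `ratio_true` (noiseless ground truth). The per-substrate effect tables
#'   are attached as attribute `"effects"`.
#' @examples
#' head(generate_reactions(10, seed = 1))
#' @export
generate_reactions <- function(n, seed = 1L, noise_sd = 0.05, skew = 3,
                               effect_sd = 1.0, interaction_sd = 0.3,
                               base = 0.3,
                               amine_fragments = AMINE_FRAGMENTS,
                               bromide_fragments = BROMIDE_FRAGMENTS) {
  if (!is_count(n)) abort("`n` must be a positive integer.")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.numeric(skew) || skew < 0) abort("`skew` must be >= 0.")
  if (length(amine_fragments) < 1L || length(bromide_fragments) < 1L) {
    abort("Substrate vocabularies must be non-empty.")
  }
  na <- length(amine_fragments)
  nb <- length(bromide_fragments)
  with_seed_local(seed, {
    amine_eff <- rnorm(na, 0, effect_sd)
    bromide_eff <- rnorm(nb, 0, effect_sd)
    inter <- matrix(rnorm(na * nb, 0, interaction_sd), na, nb)
    i <- sample.int(na, n, replace = TRUE)
    j <- sample.int(nb, n, replace = TRUE)
    truth <- stats::plogis(base + amine_eff[i] + bromide_eff[j] +
                             inter[cbind(i, j)])^skew
    ratio <- pmin(1, pmax(0, truth + rnorm(n, 0, noise_sd)))
    out <- tibble::tibble(
      amine = paste0("N", amine_fragments[i]),
      bromide = paste0("Br", bromide_fragments[j]),
      product = paste0("N(", amine_fragments[i], ")", bromide_fragments[j]),
      amine_id = paste0("A", i),
      bromide_id = paste0("B", j),
      ratio = ratio,
      ratio_true = truth
    )
    attr(out, "effects") <- list(
      amine = tibble::tibble(amine_id = paste0("A", seq_len(na)),
                             smiles = paste0("N", amine_fragments),
                             effect = amine_eff),
      bromide = tibble::tibble(bromide_id = paste0("B", seq_len(nb)),
                               smiles = paste0("Br", bromide_fragments),
                               effect = bromide_eff),
      interaction = inter,
      base = base, skew = skew, noise_sd = noise_sd
    )
    out
  })
}

#' Default schema for generated reaction tables
#'
#' @param include_product Whether the product SMILES participates as a third
#'   graph component.
#' @return An [rxn_schema()] for [generate_reactions()] output.
#' @export
synthetic_schema <- function(include_product = TRUE) {
  comps <- c("amine", "bromide", if (include_product) "product")
  rxn_schema(components = comps, outcome = "ratio")
}
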
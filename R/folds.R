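#' Build a k-fold cross-validation plan with inner validation splits
#'
#' Rows are partitioned into `k` disjoint test folds (cross-validation
#' without replacement, test sizes differing by at most one). For each fold
#' the remaining rows form the training portion, of which a fraction
#' (default 20%) is held out as a validation set for early stopping; the
#' rest is the gradient-update training set. The overall train:test ratio is
#' therefore 80:20 at `k = 5`.
#'
#' @param n Number of rows in the dataset.
#' @param k Number of folds (>= 2, <= n).
#' @param val_fraction Fraction of each fold's training portion held out for
#'   validation.
#' @param seed Integer seed; the plan is reproducible for a fixed seed.
#' @return A list of class `fold_plan` with `k`, `seed`, `val_fraction` and
#'   `folds`, a list of `k` lists each holding disjoint integer vectors
#'   `train`, `val`, `test`.
#' @examples
#' fp <- make_folds(100, k = 10, seed = 1)
#' lengths(fp$folds[[1]])
#' @export
make_folds <- function(n, k, val_fraction = 0.2, seed = 1L) {
  if (!is_count(n)) abort("`n` must be a positive integer.")
  if (!is_count(k) || k < 2L) abort("`k` must be an integer >= 2.")
  if (k > n) abort("`k` cannot exceed `n`.")
  if (!is.numeric(val_fraction) || val_fraction < 0 || val_fraction >= 1) {
    abort("`val_fraction` must be in [0, 1).")
  }
  seeds <- derive_seeds(seed, k + 1L)
  perm <- with_seed_local(seeds[[1]], sample.int(n))
  fold_id <- sort(rep_len(seq_len(k), n))
  folds <- lapply(seq_len(k), function(i) {
    test <- sort(perm[fold_id == i])
    pool <- sort(perm[fold_id != i])
    n_val <- floor(length(pool) * val_fraction)
    val <- if (n_val > 0L) {
      sort(with_seed_local(seeds[[i + 1L]], sample(pool, n_val)))
    } else integer(0)
    list(train = setdiff(pool, val), val = val, test = test)
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 val_fraction = val_fraction, folds = folds),
            class = "fold_plan")
}
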
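relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias row-vector to every row of a matrix
addb <- function(m, b) sweep(m, 2L, b, `+`)

# sum rows of `m` into an (n x ncol) matrix by integer group index in [1, n];
# groups with no rows get zeros. Workhorse for scatter-add in message passing.
rowsum_pad <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  if (nrow(m) > 0L) {
    s <- rowsum(m, group = idx)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

# scatter-add `a` into rows `idx` of `m` (idx may repeat)
scatter_add <- function(m, idx, a) {
  if (nrow(a) == 0L) return(m)
  s <- rowsum(a, group = idx)
  rows <- as.integer(rownames(s))
  m[rows, ] <- m[rows, , drop = FALSE] + s
  m
}

# derive independent child seeds from a master seed without disturbing the
# caller's RNG state more than once
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# run `expr` under a given seed, restoring the caller's RNG state afterwards
with_seed_local <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == trunc(x)
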
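# Independent reference implementation of the encoder: explicit nested
# loops over the edge list, no batching. Used to validate the vectorized
# forward pass on small graphs.

naive_encode <- function(g, P, depth, edge_message = "reverse",
                         node_aggregation = "sum") {
  d <- ncol(P$Wc)
  n <- g$n_atoms
  ne <- g$n_edges
  X <- g$atom_features
  relu0 <- function(x) pmax(x, 0)

  H0v <- matrix(0, n, d)
  for (v in seq_len(n)) {
    H0v[v, ] <- relu0(as.numeric(X[v, ] %*% P$Wi_n) + P$bi_n)
  }
  H0e <- matrix(0, ne, d)
  for (e in seq_len(ne)) {
    xin <- c(X[g$src[e], ], g$edge_features[e, ])
    H0e[e, ] <- relu0(as.numeric(xin %*% P$Wi_e) + P$bi_e)
  }

  pool <- function(He, v) {
    acc <- numeric(d)
    cnt <- 0L
    for (e in seq_len(ne)) {
      if (g$dst[e] == v) {
        acc <- acc + He[e, ]
        cnt <- cnt + 1L
      }
    }
    if (node_aggregation == "mean" && cnt > 0L) acc <- acc / cnt
    acc
  }

  Hv <- H0v
  He <- H0e
  for (k in seq_len(depth)) {
    Hv_new <- matrix(0, n, d)
    for (v in seq_len(n)) {
      m <- pool(He, v)
      Hv_new[v, ] <- relu0(as.numeric(c(Hv[v, ], m) %*% P$Wc) + P$bc)
    }
    He_new <- matrix(0, ne, d)
    for (e in seq_len(ne)) {
      other <- if (edge_message == "reverse") g$rev[e] else e
      me <- Hv_new[g$src[e], ] - He[other, ]
      He_new[e, ] <- relu0(H0e[e, ] + as.numeric(me %*% P$W))
    }
    Hv <- Hv_new
    He <- He_new
  }

  Hfin <- matrix(0, n, d)
  for (v in seq_len(n)) {
    m <- pool(He, v)
    Hfin[v, ] <- relu0(as.numeric(c(m, Hv[v, ], X[v, ]) %*% P$Wo) + P$bo)
  }

  naive_gru(Hfin[g$atom_order, , drop = FALSE], P)
}

# one-at-a-time GRU over the rows of M, returning the terminal hidden state
naive_gru <- function(M, P) {
  d <- ncol(P$Uz)
  h <- numeric(d)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in seq_len(nrow(M))) {
    x <- M[t, ]
    z <- sig(as.numeric(x %*% P$Wz) + as.numeric(h %*% P$Uz) + P$bz)
    r <- sig(as.numeric(x %*% P$Wr) + as.numeric(h %*% P$Ur) + P$br)
    g <- tanh(as.numeric(x %*% P$Wh) + as.numeric((r * h) %*% P$Uh) + P$bh)
    h <- (1 - z) * h + z * g
  }
  h
}
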
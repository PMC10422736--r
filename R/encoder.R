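# Communicative message-passing encoder. One molecule is a directed graph;
# K rounds of node/edge hidden-state updates are followed by a gated
# recurrent unit over the nodes (canonical order) whose terminal state is the
# molecule embedding. All molecules of a batch are encoded in one pass over
# the disjoint-union graph.
#
# Forward recursion, with d the hidden width:
#   h0(v)   = relu(x(v) Wi_n + bi_n)
#   h0(e)   = relu([x(src e), x(e)] Wi_e + bi_e)
#   m_k(v)  = sum over incoming edges e=(u,v) of h_{k-1}(e)
#   h_k(v)  = relu([h_{k-1}(v), m_k(v)] Wc + bc)            (communicative fn)
#   m_k(e)  = h_k(src e) - h_{k-1}(rev e)                   (or - h_{k-1}(e))
#   h_k(e)  = relu(h0(e) + m_k(e) W)
#   m(v)    = sum over incoming edges of h_K(e)
#   h(v)    = relu([m(v), h_K(v), x(v)] Wo + bo)
#   readout = GRU over h(v) in canonical atom order, terminal hidden state.

#' Model and optimizer configuration
#'
#' Collects every tunable of the reaction model in one validated list. The
#' defaults are the production settings: 300-dimensional molecule embeddings,
#' 3 message-passing rounds, reverse-edge message subtraction, summation as
#' the node-message aggregator, concatenation as the reaction-level
#' aggregation, a one-hidden-layer dense head, Adam with learning rate 1e-3,
#' batches of 32, up to 100 epochs with early-stopping patience 10.
#'
#' @param hidden_size Width `d` of all hidden states and of each molecule
#'   embedding (default 300).
#' @param depth Number of message-passing rounds `K` (default 3).
#' @param aggregation Reaction-level aggregation of component embeddings:
#'   `"concat"` (ordered concatenation, length `d` times the number of graph
#'   components) or `"sum"` (elementwise sum, length `d`).
#' @param node_aggregation How incoming edge states are pooled into a node
#'   message: `"sum"`, `"mean"` or `"max"`.
#' @param edge_message Which previous edge state is subtracted when forming
#'   the edge message: `"reverse"` (the opposed directed edge; default) or
#'   `"self"`.
#' @param head_hidden Width of the dense head's hidden layer; `NULL` means
#'   `hidden_size`.
#' @param learning_rate,batch_size,epochs,patience Adam step size, minibatch
#'   size, maximum epochs, and early-stopping patience (epochs without
#'   validation improvement).
#' @param seed Master seed controlling initialization, splits and shuffling.
#' @return A list of class `rxn_config`.
#' @examples
#' cfg <- rxn_config(hidden_size = 64, depth = 2, seed = 1)
#' @export
rxn_config <- function(hidden_size = 300L, depth = 3L,
                       aggregation = c("concat", "sum"),
                       node_aggregation = c("sum", "mean", "max"),
                       edge_message = c("reverse", "self"),
                       head_hidden = NULL,
                       learning_rate = 1e-3, batch_size = 32L,
                       epochs = 100L, patience = 10L, seed = 1L) {
  if (!is_count(hidden_size)) abort("`hidden_size` must be a positive integer.")
  if (!is_count(depth)) abort("`depth` must be a positive integer.")
  aggregation <- match.arg(aggregation)
  node_aggregation <- match.arg(node_aggregation)
  edge_message <- match.arg(edge_message)
  if (!is.null(head_hidden) && !is_count(head_hidden)) {
    abort("`head_hidden` must be NULL or a positive integer.")
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    abort("`learning_rate` must be positive.")
  }
  if (!is_count(batch_size)) abort("`batch_size` must be a positive integer.")
  if (!is_count(epochs)) abort("`epochs` must be a positive integer.")
  if (!is.numeric(patience) || patience < 0) abort("`patience` must be >= 0.")
  structure(list(
    hidden_size = as.integer(hidden_size), depth = as.integer(depth),
    aggregation = aggregation, node_aggregation = node_aggregation,
    edge_message = edge_message,
    head_hidden = as.integer(head_hidden %||% hidden_size),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "rxn_config")
}

xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Initialize encoder + head parameters. `head_input` is the reaction-vector
# width (depends on aggregation mode, number of graph components and one-hot
# vocabulary sizes), fixed by the dataset schema.
init_params <- function(config, head_input, fa = FA, fb = FB) {
  d <- config$hidden_size
  hh <- config$head_hidden
  with_seed_local(config$seed, {
    p <- list(
      Wi_n = xavier(fa, d), bi_n = numeric(d),
      Wi_e = xavier(fa + fb, d), bi_e = numeric(d),
      Wc = xavier(2L * d, d), bc = numeric(d),
      W = xavier(d, d),
      Wo = xavier(2L * d + fa, d), bo = numeric(d),
      Wz = xavier(d, d), Uz = xavier(d, d), bz = numeric(d),
      Wr = xavier(d, d), Ur = xavier(d, d), br = numeric(d),
      Wh = xavier(d, d), Uh = xavier(d, d), bh = numeric(d),
      W1 = xavier(head_input, hh), b1 = numeric(hh),
      W2 = xavier(hh, 1L), b2 = numeric(1L)
    )
    attr(p, "d") <- d
    attr(p, "head_input") <- as.integer(head_input)
    p
  })
}

check_widths <- function(bg, params) {
  fa <- ncol(bg$atom_features); fb <- ncol(bg$edge_features)
  if (fa != nrow(params$Wi_n)) {
    abort(sprintf("Atom feature width mismatch: expected %d, got %d.",
                  nrow(params$Wi_n), fa), class = "rxngraph_shape_error")
  }
  if (fa + fb != nrow(params$Wi_e)) {
    abort(sprintf("Edge feature width mismatch: expected %d, got %d.",
                  nrow(params$Wi_e) - nrow(params$Wi_n), fb),
          class = "rxngraph_shape_error")
  }
  invisible(TRUE)
}

# Pool incoming edge hidden states into per-node messages.
node_messages <- function(He, bg, mode) {
  n <- bg$n_atoms
  if (bg$n_edges == 0L) return(matrix(0, n, ncol(He)))
  if (mode == "sum") {
    rowsum_pad(He, bg$dst, n)
  } else if (mode == "mean") {
    s <- rowsum_pad(He, bg$dst, n)
    cnt <- tabulate(bg$dst, nbins = n)
    s / pmax(cnt, 1L)
  } else { # max; nodes without incoming edges get zeros
    out <- matrix(0, n, ncol(He))
    for (v in unique(bg$dst)) {
      rows <- which(bg$dst == v)
      out[v, ] <- do.call(pmax, c(lapply(rows, function(r) He[r, ]), list(0)))
    }
    out
  }
}

# Full forward pass over a batched graph. Returns molecule embeddings
# (n_mols x d) plus, when keep_cache, every intermediate needed by backward.
encoder_forward <- function(bg, params, config, keep_cache = FALSE) {
  check_widths(bg, params)
  d <- attr(params, "d")
  X <- bg$atom_features
  n <- bg$n_atoms; ne <- bg$n_edges
  Ein <- cbind(X[bg$src, , drop = FALSE], bg$edge_features)
  H0v <- relu(addb(X %*% params$Wi_n, params$bi_n))
  H0e <- relu(addb(Ein %*% params$Wi_e, params$bi_e))
  Hv <- H0v; He <- H0e
  steps <- vector("list", config$depth)
  for (k in seq_len(config$depth)) {
    Mv <- node_messages(He, bg, config$node_aggregation)
    Cin <- cbind(Hv, Mv)
    Hv_new <- relu(addb(Cin %*% params$Wc, params$bc))
    sub_idx <- if (config$edge_message == "reverse") bg$rev else seq_len(ne)
    Me <- Hv_new[bg$src, , drop = FALSE] - He[sub_idx, , drop = FALSE]
    He_new <- relu(H0e + Me %*% params$W)
    if (keep_cache) {
      steps[[k]] <- list(Hv_prev = Hv, He_prev = He, Cin = Cin,
                         Hv = Hv_new, Me = Me, He = He_new)
    }
    Hv <- Hv_new; He <- He_new
  }
  Mfin <- node_messages(He, bg, config$node_aggregation)
  Fin <- cbind(Mfin, Hv, X)
  Hfin <- relu(addb(Fin %*% params$Wo, params$bo))

  # batched GRU readout over canonical node sequences
  m <- bg$n_mols
  H <- matrix(0, m, d)
  Pz <- addb(Hfin %*% params$Wz, params$bz)
  Pr <- addb(Hfin %*% params$Wr, params$br)
  Ph <- addb(Hfin %*% params$Wh, params$bh)
  gru_steps <- vector("list", length(bg$node_seq))
  for (t in seq_along(bg$node_seq)) {
    ns <- bg$node_seq[[t]]
    hp <- H[ns$mols, , drop = FALSE]
    z <- sigmoid(Pz[ns$rows, , drop = FALSE] + hp %*% params$Uz)
    r <- sigmoid(Pr[ns$rows, , drop = FALSE] + hp %*% params$Ur)
    g <- tanh(Ph[ns$rows, , drop = FALSE] + (r * hp) %*% params$Uh)
    H[ns$mols, ] <- (1 - z) * hp + z * g
    if (keep_cache) gru_steps[[t]] <- list(hp = hp, z = z, r = r, g = g)
  }

  out <- list(embeddings = H)
  if (keep_cache) {
    out$cache <- list(bg = bg, X = X, Ein = Ein, H0v = H0v, H0e = H0e,
                      steps = steps, Mfin = Mfin, Fin = Fin, Hfin = Hfin,
                      gru_steps = gru_steps)
  }
  out
}

# Backward pass: dEmb is (n_mols x d) gradient of the loss w.r.t. molecule
# embeddings; returns a gradient list matching the encoder parameter names.
encoder_backward <- function(dEmb, cache, params, config) {
  bg <- cache$bg
  d <- attr(params, "d")
  if (!config$node_aggregation %in% c("sum", "mean")) {
    abort("Analytic gradients are implemented for node_aggregation 'sum' or 'mean'.")
  }
  # gradient of the node-message pooling: scatter the per-node gradient back
  # onto the incoming edges (divided by in-degree for mean pooling)
  indeg <- pmax(tabulate(bg$dst, nbins = bg$n_atoms), 1L)
  unpool <- function(dM) {
    if (bg$n_edges == 0L) return(matrix(0, 0L, d))
    if (config$node_aggregation == "mean") dM <- dM / indeg
    dM[bg$dst, , drop = FALSE]
  }
  g0 <- function(m) matrix(0, nrow(m), ncol(m))
  gr <- list(Wi_n = g0(params$Wi_n), bi_n = numeric(d),
             Wi_e = g0(params$Wi_e), bi_e = numeric(d),
             Wc = g0(params$Wc), bc = numeric(d),
             W = g0(params$W),
             Wo = g0(params$Wo), bo = numeric(d),
             Wz = g0(params$Wz), Uz = g0(params$Uz), bz = numeric(d),
             Wr = g0(params$Wr), Ur = g0(params$Ur), br = numeric(d),
             Wh = g0(params$Wh), Uh = g0(params$Uh), bh = numeric(d))

  # --- GRU backward (through time over node positions) ---
  Hfin <- cache$Hfin
  dHfin <- matrix(0, nrow(Hfin), d)
  dH <- dEmb
  for (t in rev(seq_along(bg$node_seq))) {
    ns <- bg$node_seq[[t]]
    st <- cache$gru_steps[[t]]
    dh <- dH[ns$mols, , drop = FALSE]
    dz <- dh * (st$g - st$hp)
    dg <- dh * st$z
    dhp <- dh * (1 - st$z)
    dg_pre <- dg * (1 - st$g^2)
    rh <- st$r * st$hp
    x <- Hfin[ns$rows, , drop = FALSE]
    gr$Wh <- gr$Wh + crossprod(x, dg_pre)
    gr$Uh <- gr$Uh + crossprod(rh, dg_pre)
    gr$bh <- gr$bh + colSums(dg_pre)
    dx <- dg_pre %*% t(params$Wh)
    drh <- dg_pre %*% t(params$Uh)
    dr <- drh * st$hp
    dhp <- dhp + drh * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    dr_pre <- dr * st$r * (1 - st$r)
    gr$Wz <- gr$Wz + crossprod(x, dz_pre)
    gr$Uz <- gr$Uz + crossprod(st$hp, dz_pre)
    gr$bz <- gr$bz + colSums(dz_pre)
    gr$Wr <- gr$Wr + crossprod(x, dr_pre)
    gr$Ur <- gr$Ur + crossprod(st$hp, dr_pre)
    gr$br <- gr$br + colSums(dr_pre)
    dx <- dx + dz_pre %*% t(params$Wz) + dr_pre %*% t(params$Wr)
    dhp <- dhp + dz_pre %*% t(params$Uz) + dr_pre %*% t(params$Ur)
    dHfin[ns$rows, ] <- dHfin[ns$rows, , drop = FALSE] + dx
    dH[ns$mols, ] <- dhp
  }

  # --- final communicative layer ---
  dFin_pre <- dHfin * (Hfin > 0)
  gr$Wo <- crossprod(cache$Fin, dFin_pre)
  gr$bo <- colSums(dFin_pre)
  dFin <- dFin_pre %*% t(params$Wo)
  dMfin <- dFin[, seq_len(d), drop = FALSE]
  dHv <- dFin[, d + seq_len(d), drop = FALSE]
  dHe <- unpool(dMfin)
  dH0e_acc <- matrix(0, bg$n_edges, d)

  # --- message-passing steps, reversed ---
  for (k in rev(seq_along(cache$steps))) {
    st <- cache$steps[[k]]
    # edge update: He = relu(H0e + Me W)
    dpre_e <- dHe * (st$He > 0)
    dH0e_acc <- dH0e_acc + dpre_e
    gr$W <- gr$W + crossprod(st$Me, dpre_e)
    dMe <- dpre_e %*% t(params$W)
    # Me = Hv[src,] - He_prev[sub_idx,]
    dHv <- dHv + rowsum_pad(dMe, bg$src, bg$n_atoms)
    sub_idx <- if (config$edge_message == "reverse") bg$rev else
      seq_len(bg$n_edges)
    dHe_prev <- matrix(0, bg$n_edges, d)
    dHe_prev <- scatter_add(dHe_prev, sub_idx, -dMe)
    # node update: Hv = relu([Hv_prev, Mv] Wc + bc)
    dpre_v <- dHv * (st$Hv > 0)
    gr$Wc <- gr$Wc + crossprod(st$Cin, dpre_v)
    gr$bc <- gr$bc + colSums(dpre_v)
    dCin <- dpre_v %*% t(params$Wc)
    dHv <- dCin[, seq_len(d), drop = FALSE]
    dMv <- dCin[, d + seq_len(d), drop = FALSE]
    dHe <- dHe_prev + unpool(dMv)
  }

  # --- input projections; H0e also feeds every step's edge update ---
  dH0e <- dHe + dH0e_acc
  dpre0v <- dHv * (cache$H0v > 0)
  gr$Wi_n <- crossprod(cache$X, dpre0v)
  gr$bi_n <- colSums(dpre0v)
  dpre0e <- dH0e * (cache$H0e > 0)
  gr$Wi_e <- crossprod(cache$Ein, dpre0e)
  gr$bi_e <- colSums(dpre0e)
  gr
}

#' Encode molecules as fixed-length embedding vectors
#'
#' Runs the full communicative message-passing encoder (graph construction,
#' K rounds of node/edge updates, GRU readout) on one or more SMILES strings.
#'
#' @param smiles Character vector of SMILES strings.
#' @param params Encoder parameters, e.g. from a fitted model's `$params` or
#'   [init_params()] via [rxn_config()].
#' @param config An [rxn_config()] matching `params`.
#' @return A numeric matrix with one row per molecule and `hidden_size`
#'   columns.
#' @examples
#' cfg <- rxn_config(hidden_size = 8, depth = 2, seed = 1)
#' p <- rxngraph:::init_params(cfg, head_input = 8)
#' dim(encode_molecules(c("CCO", "c1ccccc1"), p, cfg))
#' @export
encode_molecules <- function(smiles, params, config) {
  graphs <- lapply(smiles, build_graph)
  bg <- batch_graphs(graphs)
  emb <- encoder_forward(bg, params, config)$embeddings
  rownames(emb) <- vapply(graphs, `[[`, character(1), "smiles")
  emb
}

#' @rdname encode_molecules
#' @export
encode_molecule <- function(smiles, params, config) {
  drop(encode_molecules(smiles[1], params, config))
}
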
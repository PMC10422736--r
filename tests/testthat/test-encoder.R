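test_that("initial states have the contracted shapes, including edgeless graphs", {
  cfg <- tiny_config(d = 5L)
  p <- tiny_params(cfg)
  bg <- rxngraph:::batch_graphs(list(build_graph("C")))
  fwd <- rxngraph:::encoder_forward(bg, p, cfg, keep_cache = TRUE)
  expect_equal(dim(fwd$cache$H0v), c(1L, 5L))
  expect_equal(dim(fwd$cache$H0e), c(0L, 5L))
  expect_equal(dim(fwd$embeddings), c(1L, 5L))
})

test_that("encoding is deterministic and canonicalization-invariant", {
  cfg <- tiny_config(d = 8L, seed = 11L)
  p <- tiny_params(cfg)
  v1 <- encode_molecule("CCO", p, cfg)
  v2 <- encode_molecule("OCC", p, cfg)
  expect_identical(v1, v2)
  p_again <- tiny_params(cfg)
  expect_identical(p, p_again) # seeded init is bit-identical
  expect_identical(encode_molecule("CCO", p_again, cfg), v1)
  # distinct molecules map to distinct vectors under random params
  expect_false(isTRUE(all.equal(encode_molecule("CCN", p, cfg), v1)))
})

test_that("production width yields 300-dimensional molecule vectors", {
  cfg <- rxn_config(hidden_size = 300L, depth = 2L, seed = 1L)
  p <- tiny_params(cfg)
  v <- encode_molecule("Nc1ccccc1", p, cfg)
  expect_length(v, 300L)
})

test_that("node-message pooling matches an explicit loop over the edge list", {
  g <- build_graph("CCO") # 3-atom path
  bg <- rxngraph:::batch_graphs(list(g))
  set.seed(4)
  He <- matrix(rnorm(bg$n_edges * 3), bg$n_edges, 3)
  got <- rxngraph:::node_messages(He, bg, "sum")
  want <- matrix(0, bg$n_atoms, 3)
  for (e in seq_len(bg$n_edges)) {
    want[bg$dst[e], ] <- want[bg$dst[e], ] + He[e, ]
  }
  expect_equal(got, want)
  # single incoming edge passes through; zero states give zero messages
  one_in <- which(tabulate(bg$dst) == 1)
  if (length(one_in) > 0L) {
    v <- one_in[1]
    e <- which(bg$dst == v)
    expect_equal(got[v, ], He[e, ])
  }
  expect_equal(rxngraph:::node_messages(He * 0, bg, "sum"),
               matrix(0, bg$n_atoms, 3))
})

test_that("edge update reduces to ReLU of initial state when W is zero", {
  cfg <- tiny_config(d = 4L, depth = 3L)
  p <- tiny_params(cfg)
  p$W <- p$W * 0
  bg <- rxngraph:::batch_graphs(list(build_graph("CCO")))
  fwd <- rxngraph:::encoder_forward(bg, p, cfg, keep_cache = TRUE)
  for (st in fwd$cache$steps) {
    expect_equal(st$He, pmax(fwd$cache$H0e, 0))
  }
})

test_that("edge hidden states are non-negative at every step", {
  cfg <- tiny_config(d = 6L, depth = 3L)
  p <- tiny_params(cfg)
  bg <- rxngraph:::batch_graphs(lapply(c("Nc1ccccc1", "CC(=O)O"), build_graph))
  fwd <- rxngraph:::encoder_forward(bg, p, cfg, keep_cache = TRUE)
  for (st in fwd$cache$steps) {
    expect_true(all(st$He >= 0))
    expect_true(all(is.finite(st$He)))
  }
})

test_that("identity-selecting communicative weights pass the node state through", {
  d <- 4L
  cfg <- tiny_config(d = d, depth = 1L)
  p <- tiny_params(cfg)
  # select the first d coordinates (previous hidden state) of the 2d concat
  p$Wc <- rbind(diag(d), matrix(0, d, d))
  p$bc <- numeric(d)
  bg <- rxngraph:::batch_graphs(list(build_graph("CCO")))
  fwd <- rxngraph:::encoder_forward(bg, p, cfg, keep_cache = TRUE)
  # previous state is post-ReLU hence non-negative, so relu(identity) == identity
  expect_equal(fwd$cache$steps[[1]]$Hv, fwd$cache$H0v)
})

test_that("a hand-worked two-atom example reproduces the update equations", {
  # one bond, two directed edges; d = 2, all pieces set by hand
  g <- list(n_atoms = 2L, n_edges = 2L,
            atom_features = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
            edge_features = matrix(1, 2, 1),
            src = c(1L, 2L), dst = c(2L, 1L), rev = c(2L, 1L),
            atom_order = 1:2)
  bg <- rxngraph:::batch_graphs(list(g))
  cfg <- rxn_config(hidden_size = 2L, depth = 1L, seed = 1L)
  p <- rxngraph:::init_params(cfg, head_input = 2L, fa = 2L, fb = 1L)
  p$Wi_n <- matrix(c(1, 0, 0, 1), 2, 2); p$bi_n <- c(0, 0)
  p$Wi_e <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE); p$bi_e <- c(0, 0)
  p$Wc <- rbind(diag(2), diag(2)); p$bc <- c(0, 0)
  p$W <- diag(2)
  fwd <- rxngraph:::encoder_forward(bg, p, cfg, keep_cache = TRUE)
  # by hand: h0(v1)=(1,0), h0(v2)=(0,1)
  # h0(e12)=relu([1,0,1] Wi_e)=(2,1); h0(e21)=relu([0,1,1] Wi_e)=(1,2)
  expect_equal(fwd$cache$H0v, matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(fwd$cache$H0e, matrix(c(2, 1, 1, 2), 2, 2, byrow = TRUE))
  # m(v1)=h0(e21)=(1,2); h1(v1)=relu((1,0)+(1,2))=(2,2)
  # m(v2)=h0(e12)=(2,1); h1(v2)=relu((0,1)+(2,1))=(2,2)
  expect_equal(fwd$cache$steps[[1]]$Hv,
               matrix(c(2, 2, 2, 2), 2, 2, byrow = TRUE))
  # m(e12)=h1(v1)-h0(e21)=(1,0); h1(e12)=relu((2,1)+(1,0))=(3,1)
  # m(e21)=h1(v2)-h0(e12)=(0,1); h1(e21)=relu((1,2)+(0,1))=(1,3)
  expect_equal(fwd$cache$steps[[1]]$He,
               matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE))
})

test_that("per-node stages are permutation-equivariant before readout", {
  cfg <- tiny_config(d = 5L, depth = 2L)
  p <- tiny_params(cfg)
  g <- build_graph("CC(=O)N")
  perm <- c(3L, 1L, 4L, 2L)
  inv <- order(perm)
  gp <- list(n_atoms = g$n_atoms, n_edges = g$n_edges,
             atom_features = g$atom_features[perm, , drop = FALSE],
             edge_features = g$edge_features,
             src = inv[g$src], dst = inv[g$dst], rev = g$rev,
             atom_order = seq_len(g$n_atoms))
  f1 <- rxngraph:::encoder_forward(rxngraph:::batch_graphs(list(g)), p, cfg,
                                   keep_cache = TRUE)
  f2 <- rxngraph:::encoder_forward(rxngraph:::batch_graphs(list(gp)), p, cfg,
                                   keep_cache = TRUE)
  expect_equal(f2$cache$Hfin[inv, , drop = FALSE], f1$cache$Hfin,
               tolerance = 1e-12)
})

test_that("single-node readout equals one step of the recurrent unit", {
  cfg <- tiny_config(d = 6L, seed = 5L)
  p <- tiny_params(cfg)
  bg <- rxngraph:::batch_graphs(list(build_graph("C")))
  fwd <- rxngraph:::encoder_forward(bg, p, cfg, keep_cache = TRUE)
  want <- naive_gru(fwd$cache$Hfin, p)
  expect_equal(drop(fwd$embeddings), want, tolerance = 1e-12)
})

test_that("vectorized encoder matches the naive loop reference", {
  for (agg in c("sum", "mean")) {
    for (em in c("reverse", "self")) {
      cfg <- rxn_config(hidden_size = 4L, depth = 3L, seed = 13L,
                        node_aggregation = agg, edge_message = em)
      p <- tiny_params(cfg)
      for (s in small_molecules) {
        g <- build_graph(s)
        got <- encode_molecule(s, p, cfg)
        want <- naive_encode(g, p, cfg$depth, edge_message = em,
                             node_aggregation = agg)
        expect_equal(got, want, tolerance = 1e-6,
                     info = paste(s, agg, em))
      }
    }
  }
})

test_that("batched encoding equals molecule-by-molecule encoding", {
  cfg <- tiny_config(d = 7L, depth = 2L)
  p <- tiny_params(cfg)
  mols <- c("CCO", "c1ccccc1", "C", "NC(=O)c1cccnc1")
  batch <- encode_molecules(mols, p, cfg)
  for (i in seq_along(mols)) {
    expect_equal(unname(batch[i, ]), unname(encode_molecule(mols[i], p, cfg)),
                 tolerance = 1e-12, info = mols[i])
  }
})

test_that("embeddings stay finite across the drug-like fixture set", {
  cfg <- tiny_config(d = 8L, depth = 3L)
  p <- tiny_params(cfg)
  emb <- suppressWarnings(encode_molecules(fixture_smiles(), p, cfg))
  expect_true(all(is.finite(emb)))
  expect_equal(nrow(emb), 50L)
})

test_that("feature-width mismatches raise a shape error", {
  cfg <- tiny_config(d = 4L)
  p <- rxngraph:::init_params(cfg, head_input = 4L, fa = 3L, fb = 2L)
  bg <- rxngraph:::batch_graphs(list(build_graph("CC")))
  expect_error(rxngraph:::encoder_forward(bg, p, cfg),
               class = "rxngraph_shape_error")
})
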
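test_that("edge update is deterministic but direction-sensitive", {
  model <- tiny_model(seed = 4)
  p <- model$weights$layers[[1]]
  set.seed(1)
  h_a <- rnorm(model$embed_dim)
  h_b <- rnorm(model$embed_dim)
  expect_identical(edge_update(h_a, h_b, p), edge_update(h_a, h_b, p))
  expect_false(isTRUE(all.equal(edge_update(h_a, h_b, p),
                                edge_update(h_b, h_a, p))))
  expect_error(edge_update(h_a[-1], h_b, p), class = "qeqnet_dim_error")
})

test_that("a zero-initialized edge network returns its bias response", {
  model <- tiny_model(seed = 4)
  p <- model$weights$layers[[1]]
  p$edge$W1[] <- 0; p$edge$W2[] <- 0
  set.seed(2)
  out1 <- edge_update(rnorm(model$embed_dim), rnorm(model$embed_dim), p)
  out2 <- edge_update(rnorm(model$embed_dim), rnorm(model$embed_dim), p)
  expect_equal(out1, out2)  # input-independent: pure bias path
  expect_equal(out1, as.numeric(tanh(tanh(p$edge$b1) %*% p$edge$W2 + p$edge$b2)))
})

test_that("neighborhood aggregation is order-invariant and handles emptiness", {
  set.seed(3)
  E <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(aggregate_neighbors(E[2, , drop = FALSE], "sum"), E[2, ])
  x <- rnorm(4)
  expect_equal(aggregate_neighbors(rbind(x, -x), "sum"), numeric(4))
  perm <- sample(5)
  for (agg in c("sum", "mean")) {
    expect_equal(aggregate_neighbors(E, agg),
                 aggregate_neighbors(E[perm, ], agg))
  }
  expect_equal(aggregate_neighbors(matrix(numeric(0), 0, 4), "mean"), numeric(4))
})

test_that("node update is deterministic and shared across identical inputs", {
  model <- tiny_model(seed = 5)
  p <- model$weights$layers[[2]]
  set.seed(4)
  h <- rnorm(model$embed_dim); a <- rnorm(model$embed_dim)
  expect_identical(node_update(h, a, p), node_update(h, a, p))
  H <- rbind(h, h); A <- rbind(a, a)
  out <- node_update(H, A, p)
  expect_equal(out[1, ], out[2, ])
  # isolated node: zero aggregate still updates through the self path
  expect_true(all(is.finite(node_update(h, numeric(model$embed_dim), p))))
})

test_that("embeddings are permutation-equivariant", {
  model <- tiny_model(seed = 6, n_layers = 3)
  mols <- generate_toy_molecules(12, seed = 31)
  set.seed(7)
  for (m in mols) {
    n <- length(m$elements)
    perm <- sample(n)
    h <- embed_graph(build_graph(m, tiny_scheme), model)
    hp <- embed_graph(build_graph(permute_molecule(m, perm), tiny_scheme), model)
    expect_lt(max(abs(hp - h[perm, , drop = FALSE])), 1e-6)
  }
})

test_that("topologically equivalent atoms get identical embeddings", {
  model <- tiny_model(seed = 8)
  h <- embed_graph(build_graph(methane_mol(), tiny_scheme), model)
  for (i in 3:5) expect_lt(max(abs(h[i, ] - h[2, ])), 1e-6)
  ac <- parse_molecule("CC(=O)[O-]", "smiles")
  ho <- embed_graph(build_graph(ac, tiny_scheme), model)
  ox <- which(ac$elements == "O")
  expect_lt(max(abs(ho[ox[1], ] - ho[ox[2], ])), 1e-6)
})

test_that("K message-passing rounds have receptive field K", {
  K <- 2L
  model <- tiny_model(seed = 9, n_layers = K)
  # two carbon paths identical within radius K of atom 1; they differ at
  # atom 8 (distance 7), far beyond the receptive field
  a <- carbon_path(8)
  b <- carbon_path(8, swap_last_to = "O")
  ha <- embed_graph(build_graph(a, tiny_scheme), model)
  hb <- embed_graph(build_graph(b, tiny_scheme), model)
  expect_lt(max(abs(ha[1, ] - hb[1, ])), 1e-6)
  # while an edit inside the receptive field is felt
  c2 <- carbon_path(3, swap_last_to = "O")
  hc <- embed_graph(build_graph(carbon_path(3), tiny_scheme), model)
  hd <- embed_graph(build_graph(c2, tiny_scheme), model)
  expect_gt(max(abs(hc[1, ] - hd[1, ])), 1e-8)
})

test_that("batched embeddings equal concatenated per-molecule embeddings", {
  model <- tiny_model(seed = 10)
  mols <- generate_toy_molecules(6, seed = 41)
  graphs <- lapply(mols, build_graph, scheme = tiny_scheme)
  batch <- batch_graphs(graphs)
  hb <- embed_graph(batch, model)
  hs <- do.call(rbind, lapply(graphs, embed_graph, model = model))
  expect_lt(max(abs(hb - hs)), 1e-6)
  # batch independence: molecule 3 unmoved by different companions
  other <- batch_graphs(graphs[c(3, 1)])
  h3 <- embed_graph(other, model)[seq_len(graphs[[3]]$num_nodes), ]
  expect_lt(max(abs(h3 - embed_graph(graphs[[3]], model))), 1e-6)
})

test_that("readout heads give positive hardness and inherit symmetry", {
  model <- tiny_model(seed = 12)
  h <- embed_graph(build_graph(methane_mol(), tiny_scheme), model)
  es <- predict_e_s(h, model)
  expect_true(all(es$s > 0))
  expect_equal(es$e[2:5], rep(es$e[2], 4))
  expect_equal(es$s[2:5], rep(es$s[2], 4))
  expect_identical(predict_e_s(h, model), predict_e_s(h, model))
  expect_error(predict_e_s(h[, -1], model), class = "qeqnet_dim_error")
})

test_that("MEAN aggregation handles monatomic species", {
  he_scheme <- featurization_config(elements = c(QEQ_ELEMENTS, "He"))
  model <- charge_model(he_scheme, n_layers = 2, hidden = 8, embed_dim = 8,
                        agg = "mean", seed = 13)
  h <- embed_graph(build_graph(molecule("He", NULL), he_scheme), model)
  expect_true(all(is.finite(h)))
  expect_identical(nrow(h), 1L)
})
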
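# ---- small numeric helpers ----

addb <- function(M, b) {
  if (nrow(M) == 0L) return(M)
  M + matrix(b, nrow(M), length(b), byrow = TRUE)
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
softplus_inv <- function(y) log(expm1(y))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Segment-sum of matrix rows: rows of `M` grouped by integer `idx` into `n`
# output rows (groups absent from idx stay zero).
segment_rowsum <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  if (nrow(M) > 0L) {
    tmp <- rowsum(M, idx)
    out[as.integer(rownames(tmp)), ] <- tmp
  }
  out
}

# ---- model container ----

S_FLOOR <- 1e-6  # hard lower guard on hardness (strict convexity of QEq)

#' Create a charge model
#'
#' The learnable state of the method: an input projection from raw atom
#' features to the embedding space, `n_layers` rounds of message passing
#' (edge update, index-invariant neighborhood aggregation, node update — each
#' update a small feed-forward network with tanh activations), and a readout
#' head mapping final atom embeddings to electronegativity `e` and raw
#' hardness, the latter pushed through a softplus so hardness is strictly
#' positive. Weights use fan-in-scaled Gaussian initialization from the given
#' seed; the hardness bias starts at softplus^-1(1) so initial hardness is
#' near one.
#'
#' @param scheme A [featurization_config()]; its version is stamped into the
#'   model and checked on checkpoint load.
#' @param n_layers Number of message-passing rounds (K >= 1).
#' @param hidden Hidden width of the update networks.
#' @param embed_dim Dimension of node embeddings.
#' @param agg Neighborhood aggregation, `"sum"` or `"mean"` (both
#'   permutation-invariant; mean over an empty neighborhood is the zero
#'   vector so monatomic species are well-defined).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `qeq_model`.
#' @export
charge_model <- function(scheme = featurization_config(),
                         n_layers = 3L, hidden = 128L, embed_dim = 128L,
                         agg = c("sum", "mean"), seed = 1L) {
  agg <- match.arg(agg)
  stopifnot(n_layers >= 1, hidden >= 1, embed_dim >= 1)
  f <- scheme$n_features
  d <- as.integer(embed_dim)
  h <- as.integer(hidden)
  init_mat <- function(nin, nout) {
    matrix(rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
  }
  weights <- with_local_seed(seed, {
    list(
      input = list(W = init_mat(f, d), b = numeric(d)),
      layers = lapply(seq_len(n_layers), function(k) {
        list(
          edge = list(W1 = init_mat(2 * d, h), b1 = numeric(h),
                      W2 = init_mat(h, d), b2 = numeric(d)),
          node = list(W1 = init_mat(2 * d, h), b1 = numeric(h),
                      W2 = init_mat(h, d), b2 = numeric(d))
        )
      }),
      readout = list(W1 = init_mat(d, h), b1 = numeric(h),
                     W2 = init_mat(h, 2), b2 = c(0, softplus_inv(1)))
    )
  })
  structure(
    list(
      version = "qeqnet-model-1",
      scheme = scheme,
      n_layers = as.integer(n_layers),
      hidden = h,
      embed_dim = d,
      agg = agg,
      seed = as.integer(seed),
      weights = weights
    ),
    class = "qeq_model"
  )
}

#' @export
print.qeq_model <- function(x, ...) {
  cat("<qeq_model> K = ", x$n_layers, " layers, width ", x$hidden,
      ", embedding ", x$embed_dim, ", ", toupper(x$agg),
      " aggregation, features ", x$scheme$version,
      " (F = ", x$scheme$n_features, ")\n", sep = "")
  invisible(x)
}

# two-layer tanh MLP used by both update networks
mlp2 <- function(Z, p) tanh(addb(tanh(addb(Z %*% p$W1, p$b1)) %*% p$W2, p$b2))

# ---- exposed message-passing operations ----

#' Edge update
#'
#' Applies the edge-update network to the ordered pair of endpoint
#' embeddings of a directed edge. The function is deterministic but not
#' symmetric in its arguments: the message u -> v may differ from v -> u.
#'
#' @param h_u,h_v Embedding vectors (or matrices with matching row counts)
#'   of the source and destination nodes.
#' @param layer_params One element of `model$weights$layers`, or a list with
#'   an `edge` field of `W1`,`b1`,`W2`,`b2`.
#' @return The edge embedding (vector, or matrix for matrix input).
#' @export
edge_update <- function(h_u, h_v, layer_params) {
  p <- layer_params$edge %||% layer_params
  vec <- is.null(dim(h_u))
  if (vec) { h_u <- matrix(h_u, 1); h_v <- matrix(h_v, 1) }
  if (ncol(h_u) != ncol(h_v) || 2 * ncol(h_u) != nrow(p$W1)) {
    qeq_abort("embedding dimension does not match the edge network", "dim_error")
  }
  out <- mlp2(cbind(h_u, h_v), p)
  if (vec) out[1, ] else out
}

#' Aggregate incident-edge embeddings
#'
#' Pools the embeddings of the edges incident to a node with an
#' index-invariant operator, so any reordering of the incident-edge multiset
#' gives the same result. With no incident edges both operators return the
#' zero vector.
#'
#' @param edge_embeddings Matrix with one row per incident edge (possibly
#'   zero rows), or a single vector.
#' @param agg `"sum"` or `"mean"`.
#' @param dim Embedding dimension, required when `edge_embeddings` is empty.
#' @return The aggregated vector `a_v`.
#' @export
aggregate_neighbors <- function(edge_embeddings, agg = c("sum", "mean"),
                                dim = NULL) {
  agg <- match.arg(agg)
  if (is.null(dim(edge_embeddings))) {
    edge_embeddings <- matrix(edge_embeddings, nrow = length(edge_embeddings) > 0)
  }
  if (nrow(edge_embeddings) == 0L) {
    return(numeric(dim %||% ncol(edge_embeddings)))
  }
  if (agg == "sum") colSums(edge_embeddings) else colMeans(edge_embeddings)
}

#' Node update
#'
#' Applies the node-update network to the concatenation of a node's current
#' embedding and its aggregated neighborhood.
#'
#' @param h_v Current embedding (vector or matrix).
#' @param a_v Aggregated neighbor embedding, same shape.
#' @param layer_params One element of `model$weights$layers`, or a list with
#'   a `node` field.
#' @return The next-layer embedding.
#' @export
node_update <- function(h_v, a_v, layer_params) {
  p <- layer_params$node %||% layer_params
  vec <- is.null(dim(h_v))
  if (vec) { h_v <- matrix(h_v, 1); a_v <- matrix(a_v, 1) }
  if (ncol(h_v) != ncol(a_v) || 2 * ncol(h_v) != nrow(p$W1)) {
    qeq_abort("embedding dimension does not match the node network", "dim_error")
  }
  out <- mlp2(cbind(h_v, a_v), p)
  if (vec) out[1, ] else out
}

# ---- forward pass ----

as_batchlike <- function(graph) {
  if (inherits(graph, "qeq_graph_batch")) return(graph)
  if (!inherits(graph, "qeq_graph")) {
    qeq_abort("expected a qeq_graph or qeq_graph_batch", "dim_error")
  }
  list(
    node_features = graph$node_features,
    edges = graph$edges,
    segment_ids = rep(1L, graph$num_nodes),
    sizes = graph$num_nodes,
    Q = graph$Q,
    n_mol = 1L,
    names = graph$name,
    version = graph$version
  )
}

# Full forward pass. Returns embeddings, (e, s) and — when cache = TRUE —
# every intermediate needed by gnn_backward().
gnn_forward <- function(graph, model, cache = FALSE) {
  g <- as_batchlike(graph)
  X <- g$node_features
  if (ncol(X) != nrow(model$weights$input$W)) {
    qeq_abort(
      paste0("graph has ", ncol(X), " features but the model expects ",
             nrow(model$weights$input$W)),
      "dim_error"
    )
  }
  n <- nrow(X)
  src <- g$edges[, 1]
  dst <- g$edges[, 2]
  mean_agg <- model$agg == "mean"
  indeg <- tabulate(dst, nbins = n)
  # incidence operator for neighborhood aggregation, built once per pass
  agg_op <- if (length(dst) > 0L) {
    Matrix::sparseMatrix(i = dst, j = seq_along(dst), x = 1,
                         dims = c(n, length(dst)))
  }
  H <- addb(X %*% model$weights$input$W, model$weights$input$b)
  if (cache) {
    Hs <- vector("list", model$n_layers + 1L)
    Hs[[1]] <- H
    layer_cache <- vector("list", model$n_layers)
  }
  for (k in seq_len(model$n_layers)) {
    p <- model$weights$layers[[k]]
    Zin <- cbind(H[src, , drop = FALSE], H[dst, , drop = FALSE])
    T1 <- tanh(addb(Zin %*% p$edge$W1, p$edge$b1))
    Eemb <- tanh(addb(T1 %*% p$edge$W2, p$edge$b2))
    A <- if (is.null(agg_op)) matrix(0, n, ncol(Eemb))
         else as.matrix(agg_op %*% Eemb)
    if (mean_agg) A <- A / pmax(indeg, 1L)
    U <- cbind(H, A)
    T2 <- tanh(addb(U %*% p$node$W1, p$node$b1))
    Hnew <- tanh(addb(T2 %*% p$node$W2, p$node$b2))
    if (cache) {
      layer_cache[[k]] <- list(Zin = Zin, T1 = T1, Eemb = Eemb, U = U, T2 = T2)
      Hs[[k + 1L]] <- Hnew
    }
    H <- Hnew
  }
  if (any(!is.finite(H))) {
    qeq_abort("non-finite node embedding encountered", "numeric_error")
  }
  r <- model$weights$readout
  T3 <- tanh(addb(H %*% r$W1, r$b1))
  O <- addb(T3 %*% r$W2, r$b2)
  e <- O[, 1]
  s_raw <- O[, 2]
  s <- softplus(s_raw) + S_FLOOR
  if (any(!is.finite(e)) || any(!is.finite(s))) {
    qeq_abort("non-finite electronegativity/hardness output", "numeric_error")
  }
  out <- list(embeddings = H, e = e, s = s, graph = g)
  if (cache) {
    out$cache <- list(X = X, Hs = Hs, layers = layer_cache, T3 = T3,
                      s_raw = s_raw, src = src, dst = dst,
                      indeg = indeg, mean_agg = mean_agg)
  }
  out
}

#' Compute node embeddings
#'
#' Runs the configured number of message-passing rounds over a molecular
#' graph (or a block-diagonal batch) and returns the final per-atom
#' embeddings. Row order follows node order; for a batch, the result equals
#' the row-concatenation of the per-molecule embeddings because no message
#' crosses a molecule boundary.
#'
#' @param graph A [build_graph()] or [batch_graphs()] result.
#' @param model A [charge_model()].
#' @return An N x D numeric matrix.
#' @export
embed_graph <- function(graph, model) {
  gnn_forward(graph, model)$embeddings
}

#' Predict per-atom electronegativity and hardness
#'
#' Applies the readout head to node embeddings. Hardness is strictly
#' positive by construction (softplus plus a small floor), which makes the
#' downstream charge-equilibration objective strictly convex.
#'
#' @param embeddings N x D matrix from [embed_graph()].
#' @param model A [charge_model()].
#' @return A tibble with columns `e` (electronegativity) and `s` (hardness).
#' @export
predict_e_s <- function(embeddings, model) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, 1)
  if (any(!is.finite(embeddings))) {
    qeq_abort("non-finite embeddings", "numeric_error")
  }
  r <- model$weights$readout
  if (ncol(embeddings) != nrow(r$W1)) {
    qeq_abort("embedding dimension does not match the readout head", "dim_error")
  }
  T3 <- tanh(addb(embeddings %*% r$W1, r$b1))
  O <- addb(T3 %*% r$W2, r$b2)
  tibble(e = O[, 1], s = softplus(O[, 2]) + S_FLOOR)
}

# ---- backward pass ----

# Analytic gradients of a scalar loss w.r.t. every weight, given the loss
# gradients (de, ds) at the readout. Mirrors gnn_forward() exactly.
gnn_backward <- function(fwd, model, de, ds) {
  cc <- fwd$cache
  K <- model$n_layers
  r <- model$weights$readout
  HK <- fwd$embeddings
  dO <- cbind(de, ds * sigmoid(cc$s_raw))
  grads <- list(
    input = NULL, layers = vector("list", K),
    readout = list(W1 = NULL, b1 = NULL, W2 = crossprod(cc$T3, dO),
                   b2 = colSums(dO))
  )
  dT3 <- dO %*% t(r$W2)
  G3 <- dT3 * (1 - cc$T3^2)
  grads$readout$W1 <- crossprod(HK, G3)
  grads$readout$b1 <- colSums(G3)
  dH <- G3 %*% t(r$W1)
  d <- model$embed_dim
  for (k in rev(seq_len(K))) {
    p <- model$weights$layers[[k]]
    lc <- cc$layers[[k]]
    Hk <- cc$Hs[[k + 1L]]
    Hprev <- cc$Hs[[k]]
    G2 <- dH * (1 - Hk^2)
    g_node <- list(W2 = crossprod(lc$T2, G2), b2 = colSums(G2))
    dT2 <- G2 %*% t(p$node$W2)
    G1 <- dT2 * (1 - lc$T2^2)
    g_node$W1 <- crossprod(lc$U, G1)
    g_node$b1 <- colSums(G1)
    dU <- G1 %*% t(p$node$W1)
    dHprev <- dU[, seq_len(d), drop = FALSE]
    dA <- dU[, d + seq_len(d), drop = FALSE]
    if (nrow(lc$Zin) > 0L) {
      dEemb <- dA[cc$dst, , drop = FALSE]
      if (cc$mean_agg) dEemb <- dEemb / pmax(cc$indeg, 1L)[cc$dst]
      Ge2 <- dEemb * (1 - lc$Eemb^2)
      g_edge <- list(W2 = crossprod(lc$T1, Ge2), b2 = colSums(Ge2))
      dT1 <- Ge2 %*% t(p$edge$W2)
      Ge1 <- dT1 * (1 - lc$T1^2)
      g_edge$W1 <- crossprod(lc$Zin, Ge1)
      g_edge$b1 <- colSums(Ge1)
      dZin <- Ge1 %*% t(p$edge$W1)
      n <- nrow(Hprev)
      dHprev <- dHprev +
        segment_rowsum(dZin[, seq_len(d), drop = FALSE], cc$src, n) +
        segment_rowsum(dZin[, d + seq_len(d), drop = FALSE], cc$dst, n)
    } else {
      g_edge <- list(W1 = 0 * p$edge$W1, b1 = 0 * p$edge$b1,
                     W2 = 0 * p$edge$W2, b2 = 0 * p$edge$b2)
    }
    grads$layers[[k]] <- list(edge = g_edge[c("W1", "b1", "W2", "b2")],
                              node = g_node[c("W1", "b1", "W2", "b2")])
    dH <- dHprev
  }
  grads$input <- list(W = crossprod(cc$X, dH), b = colSums(dH))
  grads$readout <- grads$readout[c("W1", "b1", "W2", "b2")]
  grads[c("input", "layers", "readout")]  # same field order as model$weights
}
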
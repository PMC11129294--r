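#' Build a molecular graph
#'
#' Turns a molecule into the GNN substrate: a node-feature matrix plus a
#' directed edge list holding both directions of every bond (messages flow
#' both ways along each bond).
#'
#' @param mol A [molecule()].
#' @param scheme A [featurization_config()].
#' @return An object of class `qeq_graph`: list with `node_features`
#'   (N x F matrix), `edges` (E x 2 integer matrix of directed `src`,`dst`
#'   pairs, E = 2 x bond count), `num_nodes`, `Q` (total formal charge),
#'   `name`, and the scheme `version`.
#' @export
build_graph <- function(mol, scheme = featurization_config()) {
  feats <- featurize_atoms(mol, scheme)
  b <- mol$bonds
  edges <- if (nrow(b) == 0L) {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("src", "dst")))
  } else {
    e <- rbind(b, b[, c(2, 1), drop = FALSE])
    dimnames(e) <- list(NULL, c("src", "dst"))
    e
  }
  structure(
    list(
      node_features = feats,
      edges = edges,
      num_nodes = n_atoms(mol),
      Q = total_formal_charge(mol),
      name = mol$name,
      version = scheme$version
    ),
    class = "qeq_graph"
  )
}

#' @export
print.qeq_graph <- function(x, ...) {
  cat("<qeq_graph> ", x$num_nodes, " nodes, ", nrow(x$edges),
      " directed edges, F = ", ncol(x$node_features), ", Q = ", x$Q, "\n",
      sep = "")
  invisible(x)
}

#' Batch molecular graphs block-diagonally
#'
#' Concatenates graphs into one disconnected super-graph: node features are
#' stacked, edge indices are offset by cumulative node counts (so the
#' adjacency matrix is block-diagonal and no edge crosses a molecule
#' boundary), and a segment-id vector records which molecule each node
#' belongs to. One GNN pass over the batch then processes all molecules at
#' once; the charge-equilibration constraint is still applied per segment.
#'
#' @param graphs Non-empty list of [build_graph()] results.
#' @param charges Optional numeric vector of per-molecule total charges;
#'   defaults to each graph's own `Q`.
#' @return An object of class `qeq_graph_batch` with fields `node_features`,
#'   `edges`, `segment_ids` (1-based molecule index per node, nondecreasing),
#'   `sizes`, `Q` (per-molecule vector), `n_mol`, `names`.
#' @export
batch_graphs <- function(graphs, charges = NULL) {
  if (!is.list(graphs) || length(graphs) == 0L ||
      !all(vapply(graphs, inherits, logical(1), "qeq_graph"))) {
    qeq_abort("'graphs' must be a non-empty list of qeq_graph objects", "batch_error")
  }
  if (is.null(charges)) charges <- vapply(graphs, `[[`, numeric(1), "Q")
  if (length(charges) != length(graphs)) {
    qeq_abort("'charges' must have one entry per graph", "batch_error")
  }
  sizes <- vapply(graphs, `[[`, integer(1), "num_nodes")
  offsets <- cumsum(c(0L, head(sizes, -1L)))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    graphs[[k]]$edges + offsets[k]
  }))
  structure(
    list(
      node_features = do.call(rbind, lapply(graphs, `[[`, "node_features")),
      edges = edges,
      segment_ids = rep(seq_along(graphs), sizes),
      sizes = sizes,
      Q = as.numeric(charges),
      n_mol = length(graphs),
      names = vapply(graphs, `[[`, character(1), "name"),
      version = graphs[[1]]$version
    ),
    class = "qeq_graph_batch"
  )
}

#' @export
print.qeq_graph_batch <- function(x, ...) {
  cat("<qeq_graph_batch> ", x$n_mol, " molecules, ",
      sum(x$sizes), " nodes, ", nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' Split a batched per-node vector back into per-molecule vectors
#'
#' The inverse of the node concatenation performed by [batch_graphs()]:
#' element i of the result has the length of molecule i's atom count and the
#' concatenation of all elements reproduces the input exactly.
#'
#' @param batched A [batch_graphs()] result.
#' @param per_node_values Numeric vector with one entry per node of the batch.
#' @return A list of per-molecule numeric vectors, in input order.
#' @export
unbatch_node_values <- function(batched, per_node_values) {
  stopifnot(inherits(batched, "qeq_graph_batch"))
  if (length(per_node_values) != sum(batched$sizes)) {
    qeq_abort(
      paste0("per-node vector has length ", length(per_node_values),
             " but the batch has ", sum(batched$sizes), " nodes"),
      "dim_error"
    )
  }
  unname(split(per_node_values, batched$segment_ids))
}
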
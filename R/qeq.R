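#' Charging potential energy
#'
#' The second-order expansion of the charging potential that charge
#' equilibration minimizes: `sum_i (e_i q_i + s_i q_i^2)`, with
#' electronegativity `e_i` the first and hardness `s_i` (times 2) the second
#' derivative of the potential in the charge. Interatomic electrostatic
#' interactions are deliberately neglected, which is what makes the
#' constrained minimum available in closed form. Note the `s_i q_i^2`
#' convention (no 1/2 factor); comparisons with other QEq parameter sets must
#' account for it.
#'
#' @param e,s,q Equal-length numeric vectors: electronegativity, hardness and
#'   charge per atom.
#' @return The scalar energy.
#' @export
charging_energy <- function(e, s, q) {
  if (length(e) != length(s) || length(e) != length(q)) {
    qeq_abort("e, s and q must have equal length", "dim_error")
  }
  sum(e * q + s * q^2)
}

#' Solve charge equilibration in closed form
#'
#' Minimizes [charging_energy()] subject to `sum(q) = Q` via the Lagrange
#' multiplier solution
#' `q_i = (lambda - e_i) / (2 s_i)` with
#' `lambda = (Q + sum_j e_j/(2 s_j)) / sum_j 1/(2 s_j)`.
#' With all `s_i > 0` the objective is strictly convex, so this stationary
#' point is the unique constrained minimum; the multiplier `lambda` equals
#' the (uniform) value of `e_i + 2 s_i q_i` at the solution. The computation
#' is carried out in double precision and the charge sum matches `Q` to
#' 1e-8 or better.
#'
#' The sign convention follows from the objective as written: raising one
#' atom's electronegativity draws its charge down (more negative), never up.
#'
#' @param e Numeric vector of per-atom electronegativities (energy/charge).
#' @param s Numeric vector of per-atom hardnesses (energy/charge^2); every
#'   entry must exceed the positivity guard `1e-6`.
#' @param Q Total molecular charge (any real value is accepted; chemistry
#'   workflows pass the integer sum of formal charges).
#' @return An object of class `qeq_result`: list with `q` (charges),
#'   `Q`, `lambda`, and `energy` (objective value at `q`).
#' @export
qeq_solve <- function(e, s, Q) {
  n <- length(e)
  if (n == 0L) qeq_abort("empty molecule: no atoms to charge", "qeq_error")
  if (length(s) != n) qeq_abort("e and s must have equal length", "dim_error")
  if (any(!is.finite(e)) || any(!is.finite(s))) {
    qeq_abort("non-finite electronegativity/hardness", "numeric_error")
  }
  if (any(s <= S_FLOOR / 2)) {
    qeq_abort(
      paste0("hardness at atom ", which(s <= S_FLOOR / 2)[1],
             " is below the positivity guard; the QEq objective would not ",
             "have a bounded minimum"),
      "qeq_error"
    )
  }
  b <- 1 / (2 * s)
  lambda <- (Q + sum(e * b)) / sum(b)
  q <- (lambda - e) * b
  structure(
    list(q = q, Q = Q, lambda = lambda, energy = charging_energy(e, s, q)),
    class = "qeq_result"
  )
}

#' @export
print.qeq_result <- function(x, ...) {
  cat("<qeq_result> ", length(x$q), " atoms, Q = ", format(x$Q),
      ", lambda = ", format(x$lambda, digits = 6),
      ", energy = ", format(x$energy, digits = 6), "\n", sep = "")
  print(round(x$q, 6))
  invisible(x)
}

# Segment-wise QEq: one Lagrange multiplier per molecule of a batch, so each
# molecule's charges sum to its own Q. Returns q plus per-segment lambda.
qeq_solve_segments <- function(e, s, Q, segment_ids) {
  if (any(s <= S_FLOOR / 2)) {
    qeq_abort("hardness below the positivity guard in batch", "qeq_error")
  }
  b <- 1 / (2 * s)
  seg <- factor(segment_ids, levels = seq_along(Q))
  sum_eb <- as.numeric(rowsum(e * b, seg))
  sum_b <- as.numeric(rowsum(b, seg))
  lambda <- (Q + sum_eb) / sum_b
  q <- (lambda[segment_ids] - e) * b
  list(q = q, lambda = lambda)
}

# Gradient of a scalar loss through the closed-form QEq solution.
# Given gq = dL/dq (per atom), returns dL/de and dL/ds, segment-wise.
qeq_backward <- function(e, s, q, segment_ids, n_seg, gq) {
  b <- 1 / (2 * s)
  seg <- factor(segment_ids, levels = seq_len(n_seg))
  sum_b <- as.numeric(rowsum(b, seg))
  sum_gb <- as.numeric(rowsum(gq * b, seg))
  ratio <- (sum_gb / sum_b)[segment_ids]
  de <- b * (ratio - gq)
  # q_i = (lambda - e_i) b_i; dL/db_j = (lambda - e_j)(g_j - ratio_j)
  lambda_per_atom <- q / b + e
  db <- (lambda_per_atom - e) * (gq - ratio)
  ds <- db * (-2 * b^2)
  list(de = de, ds = ds)
}

#' Assign partial charges to molecules
#'
#' The end-to-end pipeline: featurize, embed with the message-passing
#' network, read out per-atom electronegativity/hardness, and solve the
#' per-molecule charge-equilibration problem. Molecules are processed as one
#' block-diagonal batch (one GNN pass), with the total-charge constraint
#' applied segment-wise so every molecule's charges sum to its own formal
#' charge exactly; the result is identical (to floating-point) to charging
#' each molecule alone.
#'
#' A molecule that fails (unparseable, out-of-vocabulary element, numerical
#' error) does not abort the rest: its atoms are omitted from the output and
#' its status row records the error message.
#'
#' @param mols A [molecule()] or a list of them. Character input is parsed as
#'   SMILES for convenience.
#' @param model A [charge_model()].
#' @return A tibble of class `qeq_charges`, one row per atom:
#'   `molecule` (index), `name`, `atom`, `element`, `charge`. Per-molecule
#'   metadata (atom count, Q, charge sum, energy, status) is available via
#'   [charge_summary()] / [glance()].
#' @examples
#' \donttest{
#' model <- charge_model(n_layers = 2, hidden = 16, embed_dim = 16, seed = 1)
#' assign_charges(c("C", "CC(=O)[O-]"), model)
#' }
#' @export
assign_charges <- function(mols, model) {
  stopifnot(inherits(model, "qeq_model"))
  if (inherits(mols, "qeq_mol")) mols <- list(mols)
  if (is.character(mols)) mols <- as.list(mols)
  if (!length(mols)) qeq_abort("no molecules supplied", "batch_error")
  prepared <- lapply(seq_along(mols), function(i) {
    tryCatch({
      m <- mols[[i]]
      if (is.character(m)) m <- parse_molecule(m, "smiles",
                                               vocabulary = model$scheme$elements)
      list(ok = TRUE, mol = m, graph = build_graph(m, model$scheme))
    }, qeqnet_error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  })
  ok <- vapply(prepared, `[[`, logical(1), "ok")
  status <- tibble(
    molecule = seq_along(mols),
    name = vapply(seq_along(mols), function(i) {
      if (ok[i]) prepared[[i]]$mol$name
      else if (is.character(mols[[i]])) mols[[i]]
      else if (inherits(mols[[i]], "qeq_mol")) mols[[i]]$name
      else ""
    }, character(1)),
    n_atoms = NA_integer_, Q = NA_real_, charge_sum = NA_real_,
    energy = NA_real_, status = ifelse(ok, "ok", "error"),
    message = vapply(prepared, function(p) p$message %||% "", character(1))
  )
  atoms <- tibble(molecule = integer(0), name = character(0),
                  atom = integer(0), element = character(0),
                  charge = numeric(0))
  if (any(ok)) {
    graphs <- lapply(prepared[ok], `[[`, "graph")
    batch <- batch_graphs(graphs)
    fwd <- gnn_forward(batch, model)
    sol <- qeq_solve_segments(fwd$e, fwd$s, batch$Q, batch$segment_ids)
    qs <- unbatch_node_values(batch, sol$q)
    es <- unbatch_node_values(batch, fwd$e)
    ss <- unbatch_node_values(batch, fwd$s)
    idx_ok <- which(ok)
    atoms <- bind_rows(lapply(seq_along(idx_ok), function(k) {
      i <- idx_ok[k]
      m <- prepared[[i]]$mol
      tibble(molecule = i, name = m$name, atom = seq_len(n_atoms(m)),
             element = m$elements, charge = qs[[k]])
    }))
    status$n_atoms[idx_ok] <- vapply(prepared[idx_ok],
                                     function(p) n_atoms(p$mol), integer(1))
    status$Q[idx_ok] <- batch$Q
    status$charge_sum[idx_ok] <- vapply(qs, sum, numeric(1))
    status$energy[idx_ok] <- vapply(seq_along(idx_ok), function(k) {
      charging_energy(es[[k]], ss[[k]], qs[[k]])
    }, numeric(1))
  }
  structure(atoms, status = status, class = c("qeq_charges", class(atoms)))
}

#' Per-molecule summary of a charge assignment
#'
#' @param x The tibble returned by [assign_charges()].
#' @return A tibble with one row per input molecule: `molecule`, `name`,
#'   `n_atoms`, `Q`, `charge_sum`, `energy`, `status`, `message`.
#' @export
charge_summary <- function(x) {
  stopifnot(inherits(x, "qeq_charges"))
  attr(x, "status")
}

#' @export
glance.qeq_charges <- function(x, ...) charge_summary(x)

#' @export
print.qeq_charges <- function(x, ...) {
  st <- charge_summary(x)
  cat("# Charge assignment: ", sum(st$status == "ok"), " of ", nrow(st),
      " molecules charged\n", sep = "")
  NextMethod()
}
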
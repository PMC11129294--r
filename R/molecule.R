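# Default bonding capacities of the neutral elements in the featurization
# vocabulary, used by the synthetic generator and by validity checks.
# Charged variants are handled as valence shifts (N+ gains one bond slot,
# O-/S- lose one).
ELEMENT_VALENCE <- c(
  H = 1L, C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

#' Construct a molecule
#'
#' A molecule is the chemical input of the charge model: a list of atoms
#' (element symbol plus integer formal charge) and a list of bonds between
#' them. Hydrogens are explicit atoms; the bond graph must be connected
#' (the total-charge constraint of charge equilibration is only meaningful
#' per covalently connected species). 3D coordinates, bond orders and
#' stereochemistry play no role: the model is deliberately geometry-agnostic.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Two-column integer matrix of 1-based atom index pairs, one row
#'   per (undirected) bond. May have zero rows for a monatomic species.
#' @param formal_charges Integer vector of per-atom formal charges (recycled
#'   from a scalar). Their sum is the total molecular charge Q.
#' @param name Text label used in error messages and output records.
#' @param aromatic Optional logical vector flagging atoms perceived as
#'   aromatic. Defaults to all-`FALSE` (correct for the acyclic molecules the
#'   synthetic generator builds; parsers fill it from toolkit perception).
#' @param validate Set to `FALSE` to skip the structural checks (internal use).
#'
#' @return An object of class `qeq_mol`.
#' @seealso [parse_molecule()], [total_formal_charge()]
#' @export
molecule <- function(elements, bonds, formal_charges = 0L, name = "",
                     aromatic = NULL, validate = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n == 0L) qeq_abort("a molecule must contain at least one atom", "mol_error")
  bonds <- bond_matrix(bonds)
  if (!length(formal_charges) %in% c(1L, n)) {
    qeq_abort("formal_charges must be a scalar or one value per atom", "mol_error")
  }
  formal_charges <- as.integer(rep_len(formal_charges, n))
  aromatic <- if (is.null(aromatic)) rep(FALSE, n) else rep_len(as.logical(aromatic), n)
  mol <- structure(
    list(
      elements = elements,
      bonds = bonds,
      formal_charges = formal_charges,
      aromatic = aromatic,
      in_ring = ring_membership(n, bonds),
      name = as.character(name)[1]
    ),
    class = "qeq_mol"
  )
  if (validate) validate_molecule(mol)
  mol
}

bond_matrix <- function(bonds) {
  if (is.null(bonds) || length(bonds) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2, dimnames = list(NULL, c("i", "j")))
  # store unordered pairs canonically (i < j)
  flip <- bonds[, 1] > bonds[, 2]
  bonds[flip, ] <- bonds[flip, c(2, 1)]
  bonds
}

validate_molecule <- function(mol) {
  n <- length(mol$elements)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    if (any(is.na(b)) || any(b < 1L) || any(b > n)) {
      qeq_abort("bond references an atom index outside 1..n_atoms", "mol_error")
    }
    if (any(b[, 1] == b[, 2])) qeq_abort("self-bond is not allowed", "mol_error")
    if (anyDuplicated(b)) qeq_abort("duplicate bond", "mol_error")
  }
  if (n > 1L) {
    g <- igraph::graph_from_edgelist(b, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (igraph::count_components(g) != 1L) {
      qeq_abort(
        paste0(
          "molecule '", mol$name, "' is disconnected (multi-fragment record); ",
          "the total-charge constraint is ambiguous across fragments"
        ),
        "fragment_error"
      )
    }
  }
  invisible(mol)
}

# An atom lies in a ring iff one of its incident bonds is not a bridge.
ring_membership <- function(n, bonds) {
  if (nrow(bonds) < 3L) return(rep(FALSE, n))
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  out <- rep(FALSE, n)
  out[unique(as.vector(bonds[cyc_edges, , drop = FALSE]))] <- TRUE
  out
}

#' Total molecular charge
#'
#' The sum of the integer formal charges: the target Q of the
#' charge-equilibration constraint (assigned partial charges must sum to it).
#'
#' @param mol A [molecule()].
#' @return An integer scalar.
#' @export
total_formal_charge <- function(mol) {
  stopifnot(inherits(mol, "qeq_mol"))
  sum(mol$formal_charges)
}

n_atoms <- function(mol) length(mol$elements)

#' @export
print.qeq_mol <- function(x, ...) {
  comp <- table(x$elements)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat(
    "<qeq_mol> ", if (nzchar(x$name)) paste0(x$name, " ") else "",
    formula, ": ", n_atoms(x), " atoms, ", nrow(x$bonds), " bonds, Q = ",
    total_formal_charge(x), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.qeq_mol <- function(x, ...) {
  paste0("<qeq_mol ", n_atoms(x), " atoms, Q=", total_formal_charge(x), ">")
}

#' Tabulate the atoms of a molecule
#'
#' @param x A [molecule()].
#' @param ... Unused.
#' @return A tibble with one row per atom: `atom` (index), `element`,
#'   `formal_charge`, `degree`, `in_ring`, `aromatic`.
#' @export
as_tibble.qeq_mol <- function(x, ...) {
  deg <- tabulate(as.vector(x$bonds), nbins = n_atoms(x))
  tibble(
    atom = seq_len(n_atoms(x)),
    element = x$elements,
    formal_charge = x$formal_charges,
    degree = deg,
    in_ring = x$in_ring,
    aromatic = x$aromatic
  )
}
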
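#' Featurization scheme
#'
#' Defines the resonance-independent per-atom feature vector: element one-hot
#' over a fixed vocabulary, total-degree one-hot, formal-charge one-hot,
#' ring-membership flag and aromaticity flag. All features derive from
#' connectivity only — never from a particular kekulé structure, conformer or
#' 3D geometry — so resonance-equivalent depictions of the same molecule give
#' identical features.
#'
#' To make the formal-charge block itself resonance-independent, atoms are
#' first grouped into topological equivalence classes by charge-blind
#' Weisfeiler-Lehman colour refinement (initial colour = element, degree,
#' ring, aromatic; `wl_rounds` refinement sweeps), and the formal-charge
#' one-hot is averaged within each class. A carboxylate's two oxygens thus
#' share a half-unit "delocalized" charge feature instead of one carrying
#' the full formal charge. The fixed round count keeps refinement linear in
#' molecule size.
#'
#' @param elements Element vocabulary (one-hot slots, in order).
#' @param max_degree Degrees 1..`max_degree` get one-hot slots; a degree-0
#'   (monatomic) atom has an all-zero degree block.
#' @param charge_range Two integers, the inclusive formal-charge one-hot range.
#' @param wl_rounds Number of Weisfeiler-Lehman refinement sweeps.
#' @param version Feature-scheme version tag; model checkpoints record it and
#'   loaders refuse a mismatch.
#' @return An object of class `qeq_featurization` with an `n_features` field.
#' @export
featurization_config <- function(elements = QEQ_ELEMENTS,
                                 max_degree = 6L,
                                 charge_range = c(-2L, 2L),
                                 wl_rounds = 8L,
                                 version = "qeqnet-feat-1") {
  stopifnot(length(elements) >= 1, max_degree >= 1,
            length(charge_range) == 2, charge_range[1] <= charge_range[2])
  charge_levels <- seq.int(charge_range[1], charge_range[2])
  structure(
    list(
      elements = as.character(elements),
      max_degree = as.integer(max_degree),
      charge_levels = as.integer(charge_levels),
      wl_rounds = as.integer(wl_rounds),
      version = version,
      n_features = length(elements) + max_degree + length(charge_levels) + 2L
    ),
    class = "qeq_featurization"
  )
}

#' @export
print.qeq_featurization <- function(x, ...) {
  cat("<qeq_featurization ", x$version, "> ", x$n_features, " features: ",
      length(x$elements), " elements + degree 1..", x$max_degree,
      " + charge ", min(x$charge_levels), "..", max(x$charge_levels),
      " + ring + aromatic\n", sep = "")
  invisible(x)
}

# Charge-blind Weisfeiler-Lehman colour refinement. Returns an integer class
# id per atom; atoms with the same id are topologically equivalent at the
# refinement depth (formal charges deliberately excluded from the colours).
wl_classes <- function(mol, rounds = 8L) {
  n <- n_atoms(mol)
  deg <- tabulate(as.vector(mol$bonds), nbins = n)
  col <- match(
    paste(mol$elements, deg, mol$in_ring, mol$aromatic),
    unique(paste(mol$elements, deg, mol$in_ring, mol$aromatic))
  )
  if (n == 1L || nrow(mol$bonds) == 0L) return(col)
  both <- rbind(mol$bonds, mol$bonds[, c(2, 1), drop = FALSE])
  src <- both[, 1]
  dst <- both[, 2]
  for (r in seq_len(rounds)) {
    # sorted neighbor-colour multiset per node, built fully vectorized
    o <- order(dst, col[src])
    segs <- split(col[src][o], dst[o])
    sig <- character(n)
    sig[as.integer(names(segs))] <- vapply(segs, paste, character(1),
                                           collapse = ",")
    full <- paste(col, sig, sep = "|")
    new_col <- match(full, unique(full))
    if (identical(new_col, col)) break
    col <- new_col
  }
  col
}

# Per-atom formal charge averaged over the atom's WL equivalence class —
# the "delocalized" charge used by featurization and by the synthetic EEM
# label generator alike.
delocalized_charges <- function(mol, rounds = 8L) {
  cls <- wl_classes(mol, rounds)
  stats::ave(as.numeric(mol$formal_charges), cls)
}

#' Compute per-atom features
#'
#' @param mol A [molecule()].
#' @param scheme A [featurization_config()].
#' @return A numeric matrix with one row per atom and
#'   `scheme$n_features` columns. Rows of topologically equivalent atoms are
#'   identical.
#' @export
featurize_atoms <- function(mol, scheme = featurization_config()) {
  stopifnot(inherits(mol, "qeq_mol"), inherits(scheme, "qeq_featurization"))
  n <- n_atoms(mol)
  unknown <- setdiff(unique(mol$elements), scheme$elements)
  if (length(unknown)) {
    qeq_abort(
      paste0("element(s) ", paste(unknown, collapse = ", "),
             " outside the featurization vocabulary"),
      "vocab_error"
    )
  }
  if (any(mol$formal_charges < min(scheme$charge_levels) |
          mol$formal_charges > max(scheme$charge_levels))) {
    qeq_abort("formal charge outside the featurization range", "vocab_error")
  }
  elem_block <- outer(mol$elements, scheme$elements, `==`) * 1
  deg <- tabulate(as.vector(mol$bonds), nbins = n)
  deg_block <- outer(deg, seq_len(scheme$max_degree), `==`) * 1
  # formal-charge one-hot, averaged over WL classes (see featurization_config)
  fc_block <- outer(mol$formal_charges, scheme$charge_levels, `==`) * 1
  cls <- wl_classes(mol, scheme$wl_rounds)
  for (j in seq_len(ncol(fc_block))) {
    fc_block[, j] <- stats::ave(fc_block[, j], cls)
  }
  out <- cbind(elem_block, deg_block, fc_block,
               as.numeric(mol$in_ring), as.numeric(mol$aromatic))
  colnames(out) <- c(
    paste0("el_", scheme$elements),
    paste0("deg_", seq_len(scheme$max_degree)),
    paste0("fc_", scheme$charge_levels),
    "ring", "aromatic"
  )
  out
}
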
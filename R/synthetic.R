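# cache for the shipped EEM table
.qeq_cache <- new.env(parent = emptyenv())

#' Synthetic electronegativity-equalization parameter table
#'
#' A fixed per-element table of electronegativity (`e0`), hardness (`s0`) and
#' a formal-charge adjustment slope (`de_per_charge`), shipped as a JSON data
#' file. The constants are hand-chosen to be chemically plausible
#' (electronegativity ordering F > O > N > C > H, positive hardness
#' everywhere) but are *synthetic*: they are the known ground truth for
#' generator-based experiments, not a fit to any quantum-chemical source.
#'
#' @param path Path to a table JSON file; defaults to the shipped one.
#' @return A tibble with columns `element`, `e0`, `s0`, `de_per_charge`.
#' @export
default_eem_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.qeq_cache$eem)) return(.qeq_cache$eem)
    path <- system.file("extdata", "eem_table_synthetic.json", package = "qeqnet")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble(
    element = raw$elements, e0 = raw$e0, s0 = raw$s0,
    de_per_charge = raw$de_per_charge
  )
  if (any(tab$s0 <= 0)) qeq_abort("EEM table hardness must be positive", "qeq_error")
  if (is.null(attr(path, "nocache"))) .qeq_cache$eem <- tab
  tab
}

#' Ground-truth charges from the EEM table
#'
#' Builds per-atom electronegativity and hardness by element lookup —
#' `e_i = e0 + de_per_charge * fc_i` with `fc_i` the atom's *delocalized*
#' formal charge (formal charge averaged over its topological equivalence
#' class, the same quantity the featurization encodes, so the labels are an
#' exact function of the model's input features) — and solves the
#' charge-equilibration problem for the molecule's total charge. Used as a
#' known, exactly reproducible label generator for training experiments.
#'
#' @param mol A [molecule()].
#' @param table An EEM table, by default [default_eem_table()].
#' @return Numeric vector of per-atom charges summing to the molecule's
#'   total formal charge (within 1e-8).
#' @export
eem_reference_charges <- function(mol, table = default_eem_table()) {
  stopifnot(inherits(mol, "qeq_mol"))
  idx <- match(mol$elements, table$element)
  if (anyNA(idx)) {
    qeq_abort(
      paste0("element(s) ", paste(unique(mol$elements[is.na(idx)]), collapse = ", "),
             " not covered by the EEM table"),
      "vocab_error"
    )
  }
  fc <- delocalized_charges(mol)
  e <- table$e0[idx] + table$de_per_charge[idx] * fc
  s <- table$s0[idx]
  qeq_solve(e, s, total_formal_charge(mol))$q
}

# element alphabet for random tree growth: neutral valences and draw weights
TOY_ALPHABET <- data.frame(
  element = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
  valence = c(4L, 3L, 2L, 2L, 3L, 1L, 1L, 1L, 1L),
  weight = c(8, 2, 2.5, 0.8, 0.3, 0.5, 0.5, 0.3, 0.2)
)

#' Generate random valence-valid toy molecules
#'
#' Draws connected molecules by random tree growth over a small heavy-atom
#' alphabet with valence bookkeeping, then completes every open valence with
#' an explicit hydrogen. Net charge is controlled by a requested distribution
#' over -2..+2 and realised by protonatable/deprotonatable sites (N gains a
#' bond slot and a +1 formal charge; O or S loses one and carries -1); a
#' fraction of the Q = -1 draws come out as monatomic halide ions and
#' one-heavy-atom draws yield diatomics such as H-Cl, so the size edge cases
#' are exercised. The generator is a pure function of `(n, seed, ...)`.
#'
#' Tree growth cannot create rings, so ring/aromatic features are exercised
#' by parsed molecules, not generated ones — a deliberate trade: validity is
#' guaranteed without a sanitization round-trip.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param max_heavy_atoms Upper bound on heavy-atom count per molecule.
#' @param charge_probs Named numeric vector of probabilities over net charges
#'   `"-2"`..`"2"` (normalized internally).
#' @return A list of `n` [molecule()] objects named `toy_0001`, ...
#' @export
generate_toy_molecules <- function(n, seed = 1L, max_heavy_atoms = 12L,
                                   charge_probs = c(`-2` = 0.05, `-1` = 0.2,
                                                    `0` = 0.5, `1` = 0.2,
                                                    `2` = 0.05)) {
  stopifnot(n >= 1, max_heavy_atoms >= 2)
  qs <- as.integer(names(charge_probs))
  stopifnot(all(qs %in% -2:2))
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      Q <- sample(qs, 1, prob = charge_probs)
      for (try in 1:50) {
        mol <- try_toy_molecule(Q, max_heavy_atoms, sprintf("toy_%04d", i))
        if (!is.null(mol)) return(mol)
      }
      qeq_abort("toy molecule generation failed to realise requested charge",
                "gen_error")
    })
  })
}

# One random draw; NULL when the requested net charge cannot be placed.
try_toy_molecule <- function(Q, max_heavy, name) {
  # monatomic halide ions for some of the -1 draws
  if (Q == -1L && runif(1) < 0.12) {
    el <- sample(c("F", "Cl", "Br", "I"), 1)
    return(molecule(el, NULL, -1L, name = name))
  }
  m <- sample(seq_len(max_heavy), 1)
  m <- max(m, abs(Q), if (abs(Q) == 2L) 2L else 1L)
  elems <- sample(TOY_ALPHABET$element, m, replace = TRUE,
                  prob = TOY_ALPHABET$weight)
  # guarantee enough charge-bearing sites
  if (Q > 0L && sum(elems == "N") < Q) {
    elems[sample(m, Q)] <- "N"
  }
  if (Q < 0L && sum(elems %in% c("O", "S")) < -Q) {
    elems[sample(m, -Q)] <- "O"
  }
  fv <- unname(ELEMENT_VALENCE[elems])
  bonds <- matrix(integer(0), ncol = 2)
  placed <- 1L
  for (t in seq_len(m)[-1]) {
    open <- which(fv[seq_len(placed)] > 0L)
    if (!length(open)) break
    parent <- if (length(open) == 1L) open else sample(open, 1)
    bonds <- rbind(bonds, c(parent, t))
    fv[parent] <- fv[parent] - 1L
    fv[t] <- fv[t] - 1L
    placed <- t
  }
  elems <- elems[seq_len(placed)]
  fv <- fv[seq_len(placed)]
  fc <- integer(placed)
  if (Q > 0L) {
    cand <- which(elems == "N" & fc == 0L)
    if (length(cand) < Q) return(NULL)
    pick <- if (length(cand) == 1L) cand else sample(cand, Q)
    fc[pick] <- 1L
    fv[pick] <- fv[pick] + 1L
  } else if (Q < 0L) {
    cand <- which(elems %in% c("O", "S") & fv > 0L)
    if (length(cand) < -Q) return(NULL)
    pick <- if (length(cand) == 1L) cand else sample(cand, -Q)
    fc[pick] <- -1L
    fv[pick] <- fv[pick] - 1L
  }
  # hydrogen completion
  nh <- sum(fv)
  if (nh > 0L) {
    h_idx <- placed + seq_len(nh)
    h_bonds <- cbind(rep(seq_len(placed), fv), h_idx)
    bonds <- rbind(bonds, h_bonds)
    elems <- c(elems, rep("H", nh))
    fc <- c(fc, integer(nh))
  }
  molecule(elems, bonds, fc, name = name)
}

#' Build a capped polyalanine-like chain
#'
#' Constructs an acetyl-capped chain of `n_residues` alanine-like residues
#' with an N-methyl amide cap — the classic capped-peptide series used for
#' size-scaling experiments. Each residue contributes 10 atoms (N, H, CA,
#' HA, CB, 3 x HB, C, O) and the two caps contribute 12, so the molecule has
#' `12 + 10 * n_residues` atoms; it is connected, acyclic, neutral and
#' valence-valid. The atom identities are a fixture template: the scaling
#' experiment needs size structure, not biochemistry.
#'
#' @param n_residues Number of residues (>= 1).
#' @return A [molecule()] named `chain_<n_residues>`.
#' @export
make_chain_graph <- function(n_residues) {
  stopifnot(n_residues >= 1)
  elems <- character(0)
  bonds <- matrix(integer(0), ncol = 2)
  add_atom <- function(el) {
    elems[[length(elems) + 1L]] <<- el
    length(elems)
  }
  add_bond <- function(i, j) bonds <<- rbind(bonds, c(i, j))
  # ACE cap: CH3-C(=O)-
  cm <- add_atom("C")
  for (k in 1:3) add_bond(cm, add_atom("H"))
  cc <- add_atom("C")
  add_bond(cm, cc)
  add_bond(cc, add_atom("O"))
  prev_c <- cc
  for (r in seq_len(n_residues)) {
    nn <- add_atom("N"); add_bond(prev_c, nn)
    add_bond(nn, add_atom("H"))
    ca <- add_atom("C"); add_bond(nn, ca)
    add_bond(ca, add_atom("H"))
    cb <- add_atom("C"); add_bond(ca, cb)
    for (k in 1:3) add_bond(cb, add_atom("H"))
    co <- add_atom("C"); add_bond(ca, co)
    add_bond(co, add_atom("O"))
    prev_c <- co
  }
  # NME cap: -NH-CH3
  nn <- add_atom("N"); add_bond(prev_c, nn)
  add_bond(nn, add_atom("H"))
  cm <- add_atom("C"); add_bond(nn, cm)
  for (k in 1:3) add_bond(cm, add_atom("H"))
  molecule(elems, bonds, 0L, name = paste0("chain_", n_residues))
}
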
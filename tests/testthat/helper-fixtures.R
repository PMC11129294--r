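# Shared fixtures: everything is built in code at test time.

tiny_scheme <- featurization_config()

tiny_model <- function(seed = 1L, n_layers = 2L, hidden = 8L, embed_dim = 8L,
                       agg = "sum") {
  charge_model(tiny_scheme, n_layers = n_layers, hidden = hidden,
               embed_dim = embed_dim, agg = agg, seed = seed)
}

# constructor-built methane: C(1) bonded to four H
methane_mol <- function() {
  molecule(c("C", "H", "H", "H", "H"),
           cbind(1L, 2:5), 0L, name = "methane")
}

water_mol <- function() {
  molecule(c("O", "H", "H"), rbind(c(1L, 2L), c(1L, 3L)), 0L, name = "water")
}

# unbranched carbon chain (no hydrogens; the constructor does not enforce
# valence, which makes radius-controlled edits easy)
carbon_path <- function(n, swap_last_to = NULL) {
  el <- rep("C", n)
  if (!is.null(swap_last_to)) el[n] <- swap_last_to
  molecule(el, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), 0L,
           name = paste0("path", n))
}

# apply an atom permutation: atom i of the result is atom perm[i] of mol
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  molecule(
    mol$elements[perm],
    matrix(inv[mol$bonds], ncol = 2),
    mol$formal_charges[perm],
    name = mol$name,
    aromatic = mol$aromatic[perm]
  )
}

# Independent QEq oracle: iterative equality-constrained minimization of the
# charging energy by eliminating the constraint (q_n = Q - sum of the rest)
# and running BFGS on the reduced problem.
oracle_qeq <- function(e, s, Q) {
  n <- length(e)
  if (n == 1L) return(Q)
  obj <- function(u) {
    q <- c(u, Q - sum(u))
    sum(e * q + s * q^2)
  }
  grad <- function(u) {
    q <- c(u, Q - sum(u))
    full <- e + 2 * s * q
    full[-n] - full[n]
  }
  fit <- stats::optim(rep(Q / n, n - 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  c(fit$par, Q - sum(fit$par))
}

random_qeq_instance <- function() {
  n <- sample(1:12, 1)
  list(e = runif(n, -5, 5), s = runif(n, 0.1, 10), Q = sample(-2:2, 1))
}

expect_abs_le <- function(x, tol) expect_lte(max(abs(x)), tol)
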
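# Electrotopological-state (E-state) descriptors. Atoms receive an
# intrinsic state I = ((2/N)^2 * delta_v + 1) / delta (N = principal quantum
# number, delta_v = valence electrons minus hydrogens, delta = heavy-atom
# degree), perturbed by every other atom through the topological distance:
# S_i = I_i + sum_j (I_i - I_j) / r_ij^2, r_ij = bonds(i,j) + 1.
# Atoms are binned into types by element, hydrogen count and bond pattern
# (on the kekulized graph, ring bonds marked); the descriptor vector is the
# per-type sum of S plus the per-type atom count over a fixed 55-type list,
# giving 110 features.

# Default 55-type list: element / hydrogen count / sorted bond pattern
# (bond order with "r" marking ring bonds). Covers the common atom
# environments of drug-like organic molecules; see the methods vignette.
.estate_default_types <- c(
  # carbon
  "C_H4_", "C_H3_1", "C_H2_1.1", "C_H1_1.1.1", "C_H0_1.1.1.1",
  "C_H2_2", "C_H1_1.2", "C_H0_1.1.2", "C_H1_3", "C_H0_1.3", "C_H0_2.2",
  "C_H2_1r.1r", "C_H1_1.1r.1r", "C_H1_1r.2r", "C_H0_1.1r.2r",
  "C_H0_1r.1r.2r", "C_H0_1r.1r.2", "C_H0_1.1.1r.1r", "C_H1_1r.1r.1r",
  "C_H0_1r.1r.1r.1r",
  # nitrogen
  "N_H2_1", "N_H1_1.1", "N_H0_1.1.1", "N_H1_2", "N_H0_1.2", "N_H0_3",
  "N_H1_1r.1r", "N_H0_1.1r.1r", "N_H0_1r.2r", "N_H0_1r.1r.2r",
  "N+1_H3_1", "N+1_H2_1.1", "N+1_H1_1.1.1", "N+1_H0_1.1.1.1",
  "N+1_H0_1.1.2", "N+1_H1_1r.2r",
  # oxygen
  "O_H1_1", "O_H0_2", "O_H0_1.1", "O_H0_1r.1r", "O-1_H0_1",
  # sulfur / selenium / phosphorus
  "S_H1_1", "S_H0_1.1", "S_H0_2", "S_H0_1r.1r", "S_H0_1.1.2",
  "S_H0_1.1.2.2", "Se_H0_1.1", "P_H0_1.1.1", "P_H0_1.1.1.2",
  # halogens and boron
  "F_H0_1", "Cl_H0_1", "Br_H0_1", "I_H0_1", "B_H0_1.1.1"
)

# Atom-type signature, e.g. "C_H1_1r.2r" = CH carbon with two ring bonds of
# order 1 and 2 (an aromatic CH on the kekulized graph).
estate_atom_types <- function(mol) {
  vapply(seq_len(mol$n_atoms), function(a) {
    o <- mol$adj_order[[a]]
    nb <- mol$adj[[a]]
    ring <- vapply(seq_along(nb), function(k) {
      any(mol$ring_bond & ((mol$bonds$i == a & mol$bonds$j == nb[k]) |
                           (mol$bonds$j == a & mol$bonds$i == nb[k])))
    }, logical(1))
    tok <- paste0(o, ifelse(ring, "r", ""))
    chg <- if (mol$charge[a] != 0) sprintf("%+d", mol$charge[a]) else ""
    paste0(mol$element[a], chg, "_H", mol$nh[a], "_",
           paste(sort(tok), collapse = "."))
  }, character(1))
}

estate_intrinsic <- function(mol) {
  z <- .valence_electrons[mol$element]
  n_q <- .quantum_n[mol$element]
  z[is.na(z)] <- 4; n_q[is.na(n_q)] <- 4
  dv <- pmax(z - mol$nh, 1)
  d <- pmax(mol$degree, 1) # lone heavy atoms (e.g. methane) treated as delta 1
  ((2 / n_q)^2 * dv + 1) / d
}

estate_values <- function(mol) {
  I <- estate_intrinsic(mol)
  if (mol$n_atoms == 1L) return(I)
  r <- mol_distances(mol) + 1
  diag(r) <- Inf
  I + rowSums(outer(I, I, "-") / r^2)
}

#' E-state descriptor names
#'
#' The default 110-feature list: for each of 55 atom types, the sum of
#' E-state values over atoms of that type (`Ssum_*`) and the atom count
#' (`Cnt_*`). The type list covers the common organic chemistry of
#' drug-like molecules; atoms falling outside the list contribute to no
#' feature (their columns would be structurally zero).
#'
#' @return Character vector of length 110.
#' @export
estate_feature_names <- function() {
  c(paste0("Ssum_", .estate_default_types), paste0("Cnt_", .estate_default_types))
}

estate_vector <- function(mol) {
  types <- estate_atom_types(mol)
  s <- estate_values(mol)
  out <- numeric(2L * length(.estate_default_types))
  idx <- match(types, .estate_default_types)
  for (a in seq_along(types)) {
    if (!is.na(idx[a])) {
      out[idx[a]] <- out[idx[a]] + s[a]
      out[length(.estate_default_types) + idx[a]] <-
        out[length(.estate_default_types) + idx[a]] + 1
    }
  }
  names(out) <- estate_feature_names()
  out
}
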
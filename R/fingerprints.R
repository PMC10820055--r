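# Fingerprint engines. Morgan (ECFP4) and path-based (Daylight dialect)
# fingerprints are computed on the package's own molecular graphs so that
# every bit can be traced back to the atoms that produced it (required for
# substructure interpretation). MACCS keys come from the OpenBabel backend.

.element_z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, As = 33, Se = 34, Br = 35, I = 53
)

.fp_lengths <- c(MACCS = 166L, DAYLIGHT = 2048L, ECFP4 = 1024L, ESTATE = 110L)

#' Descriptor family lengths
#'
#' @return Named integer vector of the fixed feature-vector length of each
#'   descriptor family (MACCS 166, DAYLIGHT 2048, ECFP4 1024, ESTATE 110).
#' @export
descriptor_lengths <- function() .fp_lengths

atom_z <- function(element) {
  z <- .element_z[element]
  z[is.na(z)] <- 0
  unname(z)
}

# Morgan algorithm with environment tracking. Returns a data frame of
# features: bit, center, radius, and a list-column of environment atoms.
morgan_features <- function(mol, radius = 2L, nbits = 1024L) {
  n <- mol$n_atoms
  inv <- vapply(seq_len(n), function(a) {
    hash_ints(c(atom_z(mol$element[a]), mol$degree[a], mol$nh[a],
                mol$charge[a] + 10, as.integer(mol$ring_atom[a]),
                sum(mol$adj_order[[a]])))
  }, numeric(1))
  feats <- list()
  env_sets <- character(0)
  emit <- function(id, center, r, atoms) {
    key <- paste0(sort(atoms), collapse = ",")
    if (key %in% env_sets) return()
    env_sets[[length(env_sets) + 1L]] <<- key
    feats[[length(feats) + 1L]] <<- list(
      id = id, bit = fold_bit(id, nbits), center = center, radius = r,
      atoms = sort(atoms))
  }
  env <- as.list(seq_len(n)) # atoms within radius r of each center
  for (a in seq_len(n)) emit(inv[a], a, 0L, a)
  r <- 0L
  while (r < radius) {
    r <- r + 1L
    new_inv <- numeric(n)
    new_env <- vector("list", n)
    for (a in seq_len(n)) {
      nbrs <- mol$adj[[a]]
      if (length(nbrs)) {
        ord <- order(mol$adj_order[[a]], inv[nbrs])
        pairs <- as.numeric(rbind(mol$adj_order[[a]][ord], inv[nbrs][ord]))
      } else pairs <- numeric(0)
      new_inv[a] <- hash_ints(c(r, inv[a], pairs))
      new_env[[a]] <- sort(unique(c(env[[a]], unlist(env[nbrs]))))
    }
    inv <- new_inv
    env <- new_env
    for (a in seq_len(n)) emit(inv[a], a, r, env[[a]])
  }
  if (!length(feats)) {
    return(data.frame(bit = integer(0), center = integer(0),
                      radius = integer(0)))
  }
  out <- data.frame(
    bit = vapply(feats, `[[`, numeric(1), "bit"),
    center = vapply(feats, `[[`, numeric(1), "center"),
    radius = vapply(feats, `[[`, numeric(1), "radius")
  )
  out$atoms <- lapply(feats, `[[`, "atoms")
  out
}

# Linear-path enumeration for the path-based (Daylight dialect) fingerprint:
# all simple paths of 1..max_bonds bonds, canonical direction, folded.
path_features <- function(mol, max_bonds = 7L, nbits = 2048L) {
  n <- mol$n_atoms
  seen <- new.env(hash = TRUE, parent = emptyenv())
  feats <- list()
  record <- function(atoms, orders) {
    key_f <- paste(atoms, collapse = ",")
    key_r <- paste(rev(atoms), collapse = ",")
    if (!is.null(seen[[key_f]]) || !is.null(seen[[key_r]])) return()
    assign(key_f, TRUE, envir = seen)
    z <- atom_z(mol$element[atoms])
    interleave <- function(zz, oo) {
      v <- numeric(length(zz) + length(oo))
      v[seq(1, length(v), by = 2)] <- zz
      if (length(oo)) v[seq(2, length(v) - 1, by = 2)] <- oo
      v
    }
    fwd <- interleave(z, orders)
    rev_ <- interleave(rev(z), rev(orders))
    lab <- if (paste(fwd, collapse = ".") <= paste(rev_, collapse = ".")) fwd else rev_
    id <- hash_ints(lab)
    feats[[length(feats) + 1L]] <<- list(
      bit = fold_bit(id, nbits), atoms = atoms, orders = orders)
  }
  walk <- function(path, orders) {
    a <- path[length(path)]
    for (k in seq_along(mol$adj[[a]])) {
      b <- mol$adj[[a]][k]
      if (b %in% path) next
      new_path <- c(path, b)
      new_orders <- c(orders, mol$adj_order[[a]][k])
      record(new_path, new_orders)
      if (length(new_orders) < max_bonds) walk(new_path, new_orders)
    }
  }
  for (a in seq_len(n)) walk(a, integer(0))
  if (!length(feats)) return(data.frame(bit = integer(0)))
  out <- data.frame(bit = vapply(feats, `[[`, numeric(1), "bit"))
  out$atoms <- lapply(feats, `[[`, "atoms")
  out$orders <- lapply(feats, `[[`, "orders")
  out
}

maccs_matrix <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparseable SMILES", call. = FALSE)
  m <- matrix(0, nrow = length(can), ncol = 166L)
  # bond-free (single-atom) molecules set no substructure keys and cannot be
  # round-tripped through ChemmineR's SDF container
  multi <- !grepl(.single_atom_re, can)
  if (any(multi)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(can[multi]))
    # ChemmineR warns about non-unique compound ids; ids are irrelevant here
    fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, "MACCS"))@fpma
    m[multi, ] <- fp[, seq_len(166L), drop = FALSE]
  }
  m
}

#' Compute a molecular fingerprint or descriptor vector
#'
#' Computes the fixed-length feature vector of one molecule for a descriptor
#' family: `"MACCS"` (166 substructure keys), `"DAYLIGHT"` (2048-bit hashed
#' path fingerprint, paths of 1-7 bonds), `"ECFP4"` (1024-bit Morgan
#' circular fingerprint of radius 2) or `"ESTATE"` (110 electrotopological-
#' state descriptors). Fingerprint families are binary; E-state is
#' real-valued. Input SMILES are canonicalized first, so the output does not
#' depend on atom ordering of the input string.
#'
#' @param smiles A single SMILES string.
#' @param family One of `"MACCS"`, `"DAYLIGHT"`, `"ECFP4"`, `"ESTATE"`.
#' @return Named numeric vector of the family's fixed length.
#' @examples
#' length(compute_fingerprint("c1ccccc1", "ECFP4"))  # 1024
#' @export
compute_fingerprint <- function(smiles, family = c("ECFP4", "DAYLIGHT",
                                                   "MACCS", "ESTATE")) {
  family <- match.arg(family)
  drop(fingerprint_matrix(smiles, family))
}

#' Compute a feature matrix for a set of molecules
#'
#' @param smiles Character vector of SMILES.
#' @param family Descriptor family, as in [compute_fingerprint()].
#' @return Numeric matrix, one row per molecule, with feature-id column
#'   names (`<FAMILY>_<bit>`).
#' @export
fingerprint_matrix <- function(smiles, family = c("ECFP4", "DAYLIGHT",
                                                  "MACCS", "ESTATE")) {
  family <- match.arg(family)
  nb <- .fp_lengths[[family]]
  if (family == "MACCS") {
    m <- maccs_matrix(smiles)
  } else if (family == "ESTATE") {
    m <- do.call(rbind, lapply(parse_mols(smiles), estate_vector))
  } else {
    mols <- parse_mols(smiles)
    m <- matrix(0, nrow = length(mols), ncol = nb)
    for (k in seq_along(mols)) {
      fe <- if (family == "ECFP4") morgan_features(mols[[k]], 2L, nb)
            else path_features(mols[[k]], 7L, nb)
      if (nrow(fe)) m[k, unique(fe$bit)] <- 1
    }
  }
  colnames(m) <- feature_ids(family)
  m
}

feature_ids <- function(family) {
  if (family == "ESTATE") return(estate_feature_names())
  paste0(family, "_", seq_len(.fp_lengths[[family]]))
}

#' Build a feature matrix from a compound table
#'
#' Data-frame-first front end over [fingerprint_matrix()]: takes a curated
#' compound tibble and returns a `qsar_features` object carrying the matrix,
#' the family and the per-column feature identities.
#'
#' @param data A data frame with a SMILES column.
#' @param family Descriptor family.
#' @param smiles_col Name of the SMILES column.
#' @return A `qsar_features` object (numeric matrix with `family` attribute;
#'   `tidy()` gives a long tibble of nonzero entries).
#' @export
featurize <- function(data, family = c("ECFP4", "DAYLIGHT", "MACCS", "ESTATE"),
                      smiles_col = "canonical_smiles") {
  family <- match.arg(family)
  stopifnot(smiles_col %in% names(data))
  m <- fingerprint_matrix(data[[smiles_col]], family)
  structure(m, family = family, class = c("qsar_features", "matrix", "array"))
}

#' @export
print.qsar_features <- function(x, ...) {
  cat("<qsar_features> ", attr(x, "family"), ": ", nrow(x), " compounds x ",
      ncol(x), " features\n", sep = "")
  invisible(x)
}

#' Map a fingerprint bit back to its substructure
#'
#' For an ECFP4 bit, returns the central atom and the atom environment of
#' radius at most 2 that hashed to the bit; for a DAYLIGHT bit, the linear
#' atom path(s). Errors if the bit is not set for the molecule.
#'
#' @param smiles A single SMILES string.
#' @param family `"ECFP4"` or `"DAYLIGHT"`.
#' @param bit_index Bit position (1-based) within the family's vector.
#' @return A `bit_substructure` object: list with `bit_index`, `family`,
#'   `matches` (tibble with `center`, `radius`, list-column `atoms`),
#'   `description` (element-path text) and the parsed `mol` (for plotting).
#' @export
explain_bit <- function(smiles, family = c("ECFP4", "DAYLIGHT"), bit_index) {
  family <- match.arg(family)
  stopifnot(length(smiles) == 1L, length(bit_index) == 1L)
  mol <- parse_mol(smiles)
  nb <- .fp_lengths[[family]]
  assert_that(bit_index >= 1 && bit_index <= nb,
              paste0("bit_index must be in 1..", nb))
  fe <- if (family == "ECFP4") morgan_features(mol, 2L, nb)
        else path_features(mol, 7L, nb)
  hit <- fe[fe$bit == bit_index, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("bit absent: bit ", bit_index, " (", family,
         ") is not set for this molecule", call. = FALSE)
  }
  matches <- tibble::tibble(
    center = if (family == "ECFP4") as.integer(hit$center) else NA_integer_,
    radius = if (family == "ECFP4") as.integer(hit$radius)
             else lengths(hit$atoms) - 1L,
    atoms = hit$atoms
  )
  desc <- vapply(hit$atoms, function(a) {
    paste(mol$element[a], collapse = "-")
  }, character(1))
  structure(list(bit_index = bit_index, family = family, matches = matches,
                 description = unique(desc), mol = mol),
            class = "bit_substructure")
}

#' @export
print.bit_substructure <- function(x, ...) {
  cat("<bit_substructure> ", x$family, " bit ", x$bit_index, " in ",
      x$mol$smiles, "\n  ", nrow(x$matches), " matching environment(s): ",
      paste(utils::head(x$description, 3), collapse = "; "), "\n", sep = "")
  invisible(x)
}
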
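#' Canonicalize SMILES strings
#'
#' Converts SMILES to their canonical form through the OpenBabel backend.
#' Unparseable entries are returned as `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input,
#'   with `NA` for strings the backend could not parse.
#' @examples
#' canonical_smiles(c("OCC", "CCO"))  # identical output
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ids <- paste0("m", seq_along(smiles))
  # OpenBabel aborts the input stream at the first unparseable record, so
  # convert in passes: everything echoed back is good; the first pending
  # record after an aborted pass is the bad one.
  pending <- which(!is.na(smiles) & nzchar(smiles))
  while (length(pending)) {
    input <- paste0(smiles[pending], " ", ids[pending], collapse = "\n")
    res <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(input, "\n"))
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got <- character(0)
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      can <- vapply(parts, `[`, character(1), 1L)
      id <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                          character(1)))
      keep <- !is.na(id) & id %in% ids[pending] & !is.na(can) & nzchar(can)
      out[match(id[keep], ids)] <- can[keep]
      got <- id[keep]
    }
    pending <- pending[!ids[pending] %in% got]
    if (length(pending)) pending <- pending[-1L] # first pending record failed
  }
  out
}

# Default valences for implicit-hydrogen assignment, charge-adjusted below.
.default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2, As = 3
)

# Principal quantum number per element (E-state intrinsic states).
.quantum_n <- c(
  B = 2, C = 2, N = 2, O = 2, F = 2,
  Si = 3, P = 3, S = 3, Cl = 3, As = 4, Se = 4, Br = 4, I = 5
)

# Valence electron counts.
.valence_electrons <- c(
  B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6,
  Cl = 7, As = 5, Se = 6, Br = 7, I = 7
)

# Old-style MDL charge codes in SDF atom blocks: 1..7 -> +3..-3 (4 = radical).
.mdl_charge <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)

#' Parse molecules into annotated molecular graphs
#'
#' Builds, for each SMILES, an internal graph representation (elements,
#' charges, kekulized bond orders, implicit hydrogen counts, ring membership,
#' 2D depiction coordinates) used by the fingerprint, descriptor and
#' scaffold code. Input SMILES are canonicalized first so the atom ordering
#' (and hence every downstream fingerprint) is independent of how the input
#' SMILES was written.
#'
#' @param smiles Character vector of SMILES.
#' @return A list of `mol` objects (see Details). Errors if any entry cannot
#'   be parsed.
#' @details A `mol` object is a list with elements `smiles` (canonical),
#'   `element`, `charge`, `nh` (implicit hydrogens), `degree` (heavy-atom
#'   neighbours), `bonds` (data frame `i`, `j`, `order`), `ring_atom`,
#'   `ring_bond` (logical), `adj`/`adj_order` (adjacency lists) and `coords`.
#' @export
parse_mols <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    bad <- smiles[is.na(can)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  single <- grepl(.single_atom_re, can)
  out <- vector("list", length(can))
  if (any(!single)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(can[!single]))
    out[!single] <- lapply(seq_len(sum(!single)),
                           function(k) .mol_from_sdf(sdf[[k]], can[!single][k]))
  }
  # ChemmineR cannot represent bond-free SDF records; build directly
  out[single] <- lapply(can[single], .mol_single_atom)
  out
}

.single_atom_re <- "^(\\[[A-Za-z][a-z]?H?[0-9]?[+-]?[0-9]?\\]|[A-Za-z][a-z]?)$"

.mol_single_atom <- function(can) {
  inner <- gsub("\\[|\\]", "", can)
  element <- regmatches(inner, regexpr("^[A-Za-z][a-z]?", inner))
  charge <- 0
  cm <- regmatches(inner, regexpr("[+-][0-9]?$", inner))
  if (length(cm) && nzchar(cm)) {
    mag <- sub("^[+-]", "", cm)
    charge <- (if (nzchar(mag)) as.numeric(mag) else 1) *
      (if (startsWith(cm, "-")) -1 else 1)
  }
  val <- unname(.default_valence[element])
  if (is.na(val)) val <- 0
  adj_val <- if (element == "C") val - abs(charge) else val + charge
  hm <- regmatches(inner, regexpr("H[0-9]?", inner))
  nh <- if (length(hm) && nzchar(hm)) {
    d <- sub("^H", "", hm); if (nzchar(d)) as.numeric(d) else 1
  } else max(0, adj_val)
  structure(list(
    smiles = can, n_atoms = 1L, element = element, charge = charge,
    nh = nh, degree = 0L,
    bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
    ring_atom = FALSE, ring_bond = logical(0),
    adj = list(integer(0)), adj_order = list(integer(0)),
    coords = matrix(0, 1, 2, dimnames = list(element, c("C1", "C2")))
  ), class = "mol")
}

#' @rdname parse_mols
#' @export
parse_mol <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  parse_mols(smiles)[[1L]]
}

.mol_from_sdf <- function(sdf, can) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  # x, y, z, massdiff, then the old-style charge code; single-atom SDFs can
  # come back with a truncated column set
  charge_code <- if ("C6" %in% colnames(ab)) as.character(ab[, "C6"])
                 else rep("0", nrow(ab))
  charge <- unname(ifelse(charge_code %in% names(.mdl_charge),
                          .mdl_charge[charge_code], 0))
  # explicit per-atom charges (M  CHG) override the atom-block code
  chg <- .mchg_from_sdf(sdf)
  if (!is.null(chg)) charge[chg$atom] <- chg$charge
  if (is.null(bb) || NROW(bb) == 0L || NCOL(bb) < 3L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  bosum <- numeric(n)
  for (r in seq_len(nrow(bonds))) {
    bosum[bonds$i[r]] <- bosum[bonds$i[r]] + bonds$order[r]
    bosum[bonds$j[r]] <- bosum[bonds$j[r]] + bonds$order[r]
  }
  val <- .default_valence[element]
  val[is.na(val)] <- 0
  adj_val <- ifelse(element == "C", val - abs(charge), val + charge)
  # hypervalent S/P: promote to the next valence shell when bonds exceed it
  hyper <- element %in% c("S", "P", "Se") & bosum > adj_val
  adj_val[hyper] <- ifelse(bosum[hyper] > adj_val[hyper] + 2,
                           adj_val[hyper] + 4, adj_val[hyper] + 2)
  nh <- pmax(0, adj_val - bosum)
  ring_bond <- .ring_bonds(n, bonds)
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) {
    ring_atom[unique(c(bonds$i[ring_bond], bonds$j[ring_bond]))] <- TRUE
  }
  adj <- vector("list", n)
  adj_order <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]; o <- bonds$order[r]
    adj[[i]] <- c(adj[[i]], j); adj_order[[i]] <- c(adj_order[[i]], o)
    adj[[j]] <- c(adj[[j]], i); adj_order[[j]] <- c(adj_order[[j]], o)
  }
  structure(list(
    smiles = can, n_atoms = n, element = element, charge = charge,
    nh = as.numeric(nh), degree = deg, bonds = bonds,
    ring_atom = ring_atom, ring_bond = ring_bond,
    adj = adj, adj_order = adj_order,
    coords = ab[, c("C1", "C2"), drop = FALSE]
  ), class = "mol")
}

.mchg_from_sdf <- function(sdf) {
  db <- tryCatch(ChemmineR::datablock(sdf), error = function(e) NULL)
  NULL # OpenBabel writes charges in the atom block; M CHG lines are not exposed
}

# bonds that lie on a cycle = non-bridge edges
.ring_bonds <- function(n, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(bonds))
  res[as.integer(br)] <- FALSE
  res
}

#' @export
print.mol <- function(x, ...) {
  cat("<mol> ", x$smiles, "  (", x$n_atoms, " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

# topological distance matrix (bonds between heavy atoms)
mol_distances <- function(mol) {
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j),
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$n_atoms) {
    g <- igraph::add_vertices(g, mol$n_atoms - igraph::vcount(g))
  }
  igraph::distances(g)
}

#' Count SMARTS pattern matches
#'
#' Thin wrapper over the OpenBabel SMARTS matcher; used for planted-
#' substructure ground truth and interpretation checks.
#'
#' @param smiles Character vector of SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of match counts per molecule.
#' @export
smarts_matches <- function(smiles, smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canonical_smiles(smiles)))
  unname(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE))
}
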
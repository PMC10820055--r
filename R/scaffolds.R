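#' @title Carbon scaffolds and scaffold-aware splitting
#' @name scaffolds
#' @description The carbon scaffold (cyclic skeleton) of a molecule is its
#'   ring systems plus the linkers connecting them, with every heteroatom
#'   replaced by carbon and every bond reduced to a single bond. Compounds
#'   sharing a carbon scaffold are near-analogs; splitting train/test by
#'   scaffold therefore tests generalization to new chemotypes.
NULL

#' Sentinel scaffold assigned to acyclic molecules
#' @export
ACYCLIC_SCAFFOLD <- "<acyclic>"

#' Extract the carbon scaffold (cyclic skeleton) of molecules
#'
#' Computes the Murcko framework (ring systems plus linkers, keeping atoms
#' multiply bonded to the framework, e.g. carbonyl oxygens on a linker),
#' replaces all heavy atoms by carbon, sets all bond orders to single, and
#' returns the canonical SMILES of the result. Acyclic molecules map to the
#' sentinel [ACYCLIC_SCAFFOLD]. The operation is idempotent.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES.
#' @examples
#' carbon_scaffold("c1ccncc1")   # "C1CCCCC1"
#' carbon_scaffold("Cc1ccccc1")  # "C1CCCCC1"
#' carbon_scaffold("CCCC")       # "<acyclic>"
#' @export
carbon_scaffold <- function(smiles) {
  out <- rep(ACYCLIC_SCAFFOLD, length(smiles))
  todo <- which(smiles != ACYCLIC_SCAFFOLD)
  if (!length(todo)) return(out)
  mols <- parse_mols(smiles[todo])
  skel <- lapply(mols, .skeleton_graph)
  nonempty <- !vapply(skel, is.null, logical(1))
  if (any(nonempty)) {
    sdf_txt <- vapply(skel[nonempty], .skeleton_sdf, character(1))
    res <- suppressWarnings(ChemmineOB::convertFormat(
      "SDF", "CAN", paste0(sdf_txt, collapse = "")))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    can <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
    assert_that(length(can) == sum(nonempty),
                "scaffold canonicalization dropped records")
    out[todo[nonempty]] <- can
  }
  out
}

# Ring-and-linker core: iteratively prune terminal side-chain atoms until
# only ring systems and the linkers between them remain. Keeping the core
# strictly to rings + linkers makes the operation idempotent. Returns NULL
# for acyclic molecules, else list(n, bonds).
.skeleton_graph <- function(mol) {
  if (!any(mol$ring_atom)) return(NULL)
  keep <- rep(TRUE, mol$n_atoms)
  repeat {
    b <- mol$bonds[keep[mol$bonds$i] & keep[mol$bonds$j], , drop = FALSE]
    d <- tabulate(c(b$i, b$j), nbins = mol$n_atoms)
    leaf <- keep & d <= 1 & !mol$ring_atom
    if (!any(leaf)) break
    keep[leaf] <- FALSE
  }
  idx <- which(keep)
  b <- mol$bonds[keep[mol$bonds$i] & keep[mol$bonds$j], , drop = FALSE]
  list(n = length(idx),
       bonds = data.frame(i = match(b$i, idx), j = match(b$j, idx)))
}

.skeleton_sdf <- function(sk) {
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", sk$n,
                    nrow(sk$bonds))
  atoms <- rep(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       0, 0, 0, "C"), sk$n)
  bonds <- sprintf("%3d%3d%3d  0  0  0  0", sk$bonds$i, sk$bonds$j, 1L)
  paste0(paste(c("scaffold", " scaffqsar", "", counts, atoms, bonds,
                 "M  END", "$$$$"), collapse = "\n"), "\n")
}

#' Scaffold census of a compound set
#'
#' Assigns every compound to exactly one carbon scaffold (acyclic compounds
#' to the sentinel group) and tabulates member counts, largest first.
#'
#' @param data Data frame of compounds with a SMILES column.
#' @param smiles_col Name of the SMILES column.
#' @return A tibble (`scaffold_smiles`, `n_members`, `member_indices`
#'   list-column of row indices into `data`), sorted by decreasing
#'   `n_members`.
#' @export
scaffold_census <- function(data, smiles_col = "canonical_smiles") {
  assert_that(nrow(data) > 0, "dataset must be non-empty")
  sc <- carbon_scaffold(data[[smiles_col]])
  grp <- split(seq_along(sc), sc)
  out <- tibble::tibble(
    scaffold_smiles = names(grp),
    n_members = unname(lengths(grp)),
    member_indices = unname(grp)
  )
  out <- out[order(-out$n_members, out$scaffold_smiles), ]
  tibble::as_tibble(out)
}

#' Scaffold-aware train/test split
#'
#' Splits compounds by carbon scaffold. Scaffolds with fewer than
#' `rare_threshold` members contribute exactly one randomly chosen member to
#' the training set, the rest to the test set; scaffolds with at least
#' `rare_threshold` members send `round(train_fraction * n)` (half-up)
#' random members to the training set and the remainder to the test set.
#' Setting `rare_to_train = FALSE` reverses the rare-scaffold direction (one
#' member to test, rest to train), since that reading keeps the training
#' share larger; the default follows the literal rule.
#'
#' @param data Data frame of compounds with a SMILES column.
#' @param seed Integer seed; the split is reproducible given the seed.
#' @param rare_threshold Minimum member count for the fractional rule.
#' @param train_fraction Training fraction for common scaffolds.
#' @param rare_to_train If `TRUE` (default) the single random member of a
#'   rare scaffold goes to the training set.
#' @param smiles_col Name of the SMILES column.
#' @return A `scaffold_split` object: list with `train_indices`,
#'   `test_indices`, `scaffold_assignment` tibble (`scaffold_smiles`,
#'   `n_members`, `n_train`, `n_test`) and `seed`. `tidy()` returns a
#'   per-compound tibble.
#' @export
scaffold_split <- function(data, seed, rare_threshold = 5L,
                           train_fraction = 0.8, rare_to_train = TRUE,
                           smiles_col = "canonical_smiles") {
  census <- scaffold_census(data, smiles_col = smiles_col)
  train <- integer(0)
  test <- integer(0)
  n_train <- integer(nrow(census))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (k in seq_len(nrow(census))) {
    members <- census$member_indices[[k]]
    n <- length(members)
    k_train <- if (n < rare_threshold) {
      if (rare_to_train) 1L else n - 1L
    } else {
      as.integer(round_half_up(train_fraction * n))
    }
    picked <- if (n == 1L) members else sample(members, k_train)
    train <- c(train, picked)
    test <- c(test, setdiff(members, picked))
    n_train[k] <- k_train
  }
  assignment <- tibble::tibble(
    scaffold_smiles = census$scaffold_smiles,
    n_members = census$n_members,
    n_train = n_train,
    n_test = census$n_members - n_train
  )
  structure(list(train_indices = sort(train), test_indices = sort(test),
                 scaffold_assignment = assignment, seed = as.integer(seed),
                 n = nrow(data)),
            class = "scaffold_split")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.scaffold_split <- function(x, ...) {
  cat("<scaffold_split> ", length(x$train_indices), " train / ",
      length(x$test_indices), " test over ",
      nrow(x$scaffold_assignment), " scaffolds (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Chemical-space PCA coordinates
#'
#' Principal component analysis of a feature matrix, for chemical-space
#' maps of training versus test compounds.
#'
#' @param features A numeric matrix or `qsar_features` object.
#' @param n_components Number of leading components to return.
#' @return A list with `coordinates` (tibble, one row per compound, columns
#'   `PC1`..), `explained_variance` (proportion per component,
#'   non-increasing) and the `prcomp` fit.
#' @export
chemspace_pca <- function(features, n_components = 2L) {
  m <- unclass(features)
  assert_that(nrow(m) >= n_components,
              "need at least n_components compounds")
  keep <- apply(m, 2, stats::sd) > 0
  assert_that(any(keep), "degenerate feature matrix: all columns constant")
  fit <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  coords <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(coordinates = coords, explained_variance = ev[seq_len(k)], fit = fit)
}
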
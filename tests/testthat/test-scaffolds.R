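test_that("carbon scaffolds match hand-derived skeletons", {
  fx <- scaffold_fixture()
  got <- carbon_scaffold(fx$smiles)
  expect_equal(got, canonical_smiles(fx$expected))
  # acyclic molecules collapse to the sentinel
  expect_equal(carbon_scaffold(c("CCCC", "CCO", "CC(C)C(=O)O")),
               rep(ACYCLIC_SCAFFOLD, 3))
})

test_that("carbon scaffold extraction is idempotent and all-carbon single-bond", {
  mols <- c(scaffold_fixture()$smiles, test_library()$smiles[1:20])
  sc <- carbon_scaffold(mols)
  expect_identical(carbon_scaffold(sc), sc)
  for (s in unique(sc[sc != ACYCLIC_SCAFFOLD])) {
    m <- parse_mol(s)
    expect_true(all(m$element == "C"))
    expect_true(all(m$bonds$order == 1L))
  }
})

test_that("scaffold census assigns every compound exactly once", {
  df <- tibble::tibble(canonical_smiles = c(
    "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",  # benzene skeleton x3
    "c1ccncc1", "c1ccccc1",                 # benzene skeleton x2 more
    "CCCC", "CCO",                          # acyclic x2
    "c1ccc2ccccc2c1"))                      # naphthalene x1
  cen <- scaffold_census(df)
  expect_equal(sum(cen$n_members), nrow(df))
  expect_equal(cen$n_members[1], 5L)
  expect_setequal(unlist(cen$member_indices), seq_len(nrow(df)))
  expect_true(ACYCLIC_SCAFFOLD %in% cen$scaffold_smiles)
  expect_true(all(diff(cen$n_members) <= 0))
  one <- scaffold_census(df[1, ])
  expect_equal(one$n_members, 1L)
})

test_that("split rule holds per scaffold for known multiplicities", {
  # five scaffold groups with member counts 10, 5, 3, 2, 4 (acyclic)
  df <- tibble::tibble(canonical_smiles = c(
    paste0(c("C", "CC", "CCC", "N", "O", "OC", "F", "Cl", "Br", "CN"),
           "c1ccccc1"),                                        # 10 benzene
    c("c1ccc(cc1)-c1ccccc1", "Cc1ccc(cc1)-c1ccccc1",
      "c1ccc(cc1)-c1ccncc1", "Oc1ccc(cc1)-c1ccccc1",
      "Nc1ccc(cc1)-c1ccccc1"),                                 # 5 biphenyl
    c("c1ccoc1", "c1ccsc1", "Cc1ccco1"),                       # 3 five-ring
    c("c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1"),                    # 2 naphthalene
    c("CCO", "CCC", "CCN", "CCCC")))                           # 4 acyclic
  for (seed in c(1, 99)) {
    sp <- scaffold_split(df, seed = seed)
    expect_partition(sp, nrow(df))
    a <- sp$scaffold_assignment
    expect_equal(a$n_train[a$n_members == 10], 8L)  # round(0.8*10)
    expect_equal(a$n_train[a$n_members == 5], 4L)   # round(0.8*5)
    expect_equal(a$n_train[a$n_members == 3], 1L)   # rare: one to train
    expect_equal(a$n_train[a$n_members == 2], 1L)
    expect_equal(a$n_train[a$n_members == 4], 1L)
    expect_equal(a$n_test, a$n_members - a$n_train)
  }
  # reversed rare direction
  sp_rev <- scaffold_split(df, seed = 1, rare_to_train = FALSE)
  a <- sp_rev$scaffold_assignment
  expect_equal(a$n_train[a$n_members == 3], 2L)
  expect_equal(a$n_train[a$n_members == 4], 3L)
})

test_that("splits are seed-reproducible and always partition", {
  lib <- test_library()[1:60, ]
  sp1 <- scaffold_split(lib, seed = 31, smiles_col = "smiles")
  sp2 <- scaffold_split(lib, seed = 31, smiles_col = "smiles")
  expect_identical(sp1$train_indices, sp2$train_indices)
  for (seed in 1:20) {
    sp <- scaffold_split(lib, seed = seed, smiles_col = "smiles")
    expect_partition(sp, nrow(lib))
    expect_identical(sp$scaffold_assignment$n_train,
                     sp1$scaffold_assignment$n_train)
  }
})

test_that("an all-rare library puts one compound per scaffold in train", {
  df <- tibble::tibble(canonical_smiles = c(
    "c1ccccc1", "Cc1ccccc1",            # 2 members
    "c1ccc2ccccc2c1",                   # 1
    "c1ccoc1", "Cc1ccco1", "c1ccsc1"))  # 3
  sp <- scaffold_split(df, seed = 3)
  expect_equal(length(sp$train_indices),
               nrow(sp$scaffold_assignment))
})

test_that("chemspace PCA has non-increasing variance and recovers planar data", {
  set.seed(9)
  # 30 points on a 2-D plane embedded in 10-D
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  pts <- matrix(rnorm(60), 30, 2) %*% t(basis)
  res <- chemspace_pca(pts, n_components = 2)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-8)
  ev_all <- res$fit$sdev^2
  expect_true(all(diff(ev_all) <= 1e-8))
  expect_error(chemspace_pca(matrix(1, 5, 4)), "degenerate")
  fm <- test_features("MACCS")
  res2 <- chemspace_pca(unclass(fm)[1:40, ])
  expect_equal(nrow(res2$coordinates), 40)
  expect_true(all(diff(res2$explained_variance) <= 1e-8))
})
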
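test_that("descriptor families have the published lengths and value types", {
  lens <- descriptor_lengths()
  expect_equal(unname(lens[c("MACCS", "DAYLIGHT", "ECFP4", "ESTATE")]),
               c(166L, 2048L, 1024L, 110L))
  for (fam in names(lens)) {
    v <- compute_fingerprint("CC(=O)Nc1ccc(O)cc1", fam)
    expect_length(v, lens[[fam]])
    expect_true(all(is.finite(v)))
    if (fam != "ESTATE") expect_true(all(v %in% c(0, 1)))
  }
  expect_length(compute_fingerprint("C", "MACCS"), 166L)
})

test_that("fingerprints are deterministic and invariant to input atom order", {
  pairs <- list(c("CCO", "OCC"),
                c("c1ccccc1", "C1=CC=CC=C1"),
                c("CC(=O)Nc1ccc(O)cc1", "Oc1ccc(NC(C)=O)cc1"))
  for (fam in c("ECFP4", "DAYLIGHT", "MACCS", "ESTATE")) {
    for (p in pairs) {
      expect_identical(compute_fingerprint(p[1], fam),
                       compute_fingerprint(p[2], fam))
    }
    expect_identical(compute_fingerprint("CN1CCCC1", fam),
                     compute_fingerprint("CN1CCCC1", fam))
  }
  expect_error(compute_fingerprint("xx((", "ECFP4"), "unparseable")
})

test_that("substructure-bearing and substructure-free analogs differ in ECFP4", {
  with_frag <- compute_fingerprint("c1ccc(NS(C)(=O)=O)cc1", "ECFP4")
  without <- compute_fingerprint("c1ccc(C)cc1", "ECFP4")
  expect_gt(sum(with_frag & !without), 0)
})

test_that("E-state values match hand computation for ethanol", {
  # intrinsic states: CH3 2, CH2 1.5, OH 6; perturbation over r = d + 1
  v <- compute_fingerprint("CCO", "ESTATE")
  s_ch3 <- 2 + (2 - 1.5) / 4 + (2 - 6) / 9
  s_ch2 <- 1.5 + (1.5 - 2) / 4 + (1.5 - 6) / 4
  s_oh <- 6 + (6 - 1.5) / 4 + (6 - 2) / 9
  expect_equal(unname(v["Ssum_C_H3_1"]), s_ch3)
  expect_equal(unname(v["Ssum_C_H2_1.1"]), s_ch2)
  expect_equal(unname(v["Ssum_O_H1_1"]), s_oh)
  expect_equal(unname(v["Cnt_O_H1_1"]), 1)
  expect_equal(sum(v[grep("^Cnt_", names(v))]), 3) # all atoms typed
})

test_that("E-state handles absent atom types and lone atoms", {
  v <- compute_fingerprint("C", "ESTATE")
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["Cnt_C_H4_"]), 1)
  expect_equal(sum(v[grep("^Cnt_", names(v))] > 0), 1)
  expect_equal(unname(compute_fingerprint("CCO", "ESTATE")["Cnt_F_H0_1"]), 0)
})

test_that("explain_bit maps ECFP4 bits to bounded environments", {
  fp <- compute_fingerprint("CC(=O)Nc1ccc(O)cc1", "ECFP4")
  bits <- which(fp == 1)
  for (b in bits[1:5]) {
    ex <- explain_bit("CC(=O)Nc1ccc(O)cc1", "ECFP4", b)
    expect_s3_class(ex, "bit_substructure")
    expect_true(all(ex$matches$radius <= 2))
    # environment atoms lie within the stated radius of the central atom
    mol <- ex$mol
    d <- scaffqsar:::mol_distances(mol)
    for (k in seq_len(nrow(ex$matches))) {
      ctr <- ex$matches$center[k]
      expect_true(all(d[ctr, ex$matches$atoms[[k]]] <= ex$matches$radius[k]))
    }
  }
  unset <- setdiff(seq_len(1024), bits)[1]
  expect_error(explain_bit("CC(=O)Nc1ccc(O)cc1", "ECFP4", unset),
               "bit absent")
})

test_that("explain_bit maps DAYLIGHT bits to linear paths without central atom", {
  smi <- "CCOc1ccccc1"
  fp <- compute_fingerprint(smi, "DAYLIGHT")
  b <- which(fp == 1)[3]
  ex <- explain_bit(smi, "DAYLIGHT", b)
  expect_true(all(is.na(ex$matches$center)))
  mol <- ex$mol
  for (k in seq_len(nrow(ex$matches))) {
    path <- ex$matches$atoms[[k]]
    expect_gte(length(path), 2)
    expect_lte(length(path), 8) # at most 7 bonds
    # consecutive path atoms are bonded
    for (i in seq_len(length(path) - 1)) {
      expect_true(path[i + 1] %in% mol$adj[[path[i]]])
    }
  }
})

test_that("planted-fragment characteristic bits trace back to fragment atoms", {
  # molecule with the methylsulfonamide head used by the generator
  smi <- "c1cc(C)ccc1NC(=O)Nc1ccc(NS(C)(=O)=O)cc1"
  plain <- "c1cc(C)ccc1NC(=O)Nc1ccc(CC)cc1"
  bits <- which(compute_fingerprint(smi, "ECFP4") == 1 &
                compute_fingerprint(plain, "ECFP4") == 0)
  expect_gt(length(bits), 0)
  found_s <- FALSE
  for (b in bits) {
    ex <- explain_bit(smi, "ECFP4", b)
    els <- unlist(lapply(ex$matches$atoms, function(a) ex$mol$element[a]))
    if ("S" %in% els) found_s <- TRUE
  }
  expect_true(found_s) # some distinguishing bit covers the sulfonamide S
})

test_that("featurize returns labelled matrices aligned with the input rows", {
  lib <- test_library()[1:15, ]
  fm <- featurize(lib, "ECFP4", smiles_col = "smiles")
  expect_s3_class(fm, "qsar_features")
  expect_equal(dim(fm), c(15L, 1024L))
  expect_equal(colnames(fm)[1], "ECFP4_1")
  expect_identical(unclass(fm)[3, ],
                   compute_fingerprint(lib$smiles[3], "ECFP4"))
})
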
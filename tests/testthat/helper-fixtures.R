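# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) {
    assign(name, expr, envir = .fixture_env)
  }
  .fixture_env[[name]]
}

# small mixed library for unit tests
test_library <- function() {
  fixture("lib120",
          generate_library(generator_config("Ki", n_compounds = 120,
                                            seed = 11)))
}

test_features <- function(family = "ECFP4") {
  fixture(paste0("fm120_", family),
          featurize(test_library(), family, smiles_col = "smiles"))
}

# planted-signal study conditions: one strong substructure effect
planted_config <- function() {
  generator_config(
    "Ki", n_compounds = 400,
    planted_effects = tibble::tibble(
      name = "methylsulfonamide", fragment = "NS(C)(=O)=O",
      smarts = "N[SX4](C)(=O)=O", effect = 1.0, prob = 0.5),
    noise_sd = 0.3, seed = 101)
}

planted_library <- function() {
  fixture("planted_lib", generate_library(planted_config()))
}

planted_features <- function() {
  fixture("planted_fm",
          unclass(featurize(planted_library(), "ECFP4",
                            smiles_col = "smiles")))
}

# RFE-RF selection on the planted library (shared by several checks)
planted_selection <- function() {
  fixture("planted_sel",
          rfe_rf(planted_features(), planted_library()$p_activity,
                 step = 32L, num_trees = 200L, min_features = 2L,
                 seed = 11))
}

expect_partition <- function(split, n) {
  expect_setequal(c(split$train_indices, split$test_indices), seq_len(n))
  expect_length(intersect(split$train_indices, split$test_indices), 0)
}

# Hand-derived carbon scaffolds: expected skeletons are written directly as
# all-carbon single-bond structures and compared after canonicalization.
scaffold_fixture <- function() {
  tibble::tribble(
    ~smiles,                         ~expected,
    "c1ccccc1",                      "C1CCCCC1",          # benzene
    "c1ccncc1",                      "C1CCCCC1",          # pyridine
    "Cc1ccccc1",                     "C1CCCCC1",          # toluene
    "Oc1ccccc1",                     "C1CCCCC1",          # phenol
    "COc1ccccc1",                    "C1CCCCC1",          # anisole
    "C1CCCCC1",                      "C1CCCCC1",          # cyclohexane
    "C1=CCCCC1",                     "C1CCCCC1",          # cyclohexene
    "c1ccoc1",                       "C1CCCC1",           # furan
    "c1ccsc1",                       "C1CCCC1",           # thiophene
    "c1cc[nH]c1",                    "C1CCCC1",           # pyrrole
    "c1ccc2ccccc2c1",                "C1CCC2CCCCC2C1",    # naphthalene
    "c1ccc2[nH]ccc2c1",              "C1CCC2CCCC2C1",     # indole
    "c1ccc(cc1)-c1ccccc1",           "C1CCCCC1C1CCCCC1",  # biphenyl
    "c1ccc(Cc2ccccc2)cc1",           "C(C1CCCCC1)C1CCCCC1",    # diphenylmethane
    "O=C(Nc1ccccc1)c1ccccc1",        "C(CC1CCCCC1)C1CCCCC1",   # benzanilide
    "NC(=O)Nc1ccccc1",               "C1CCCCC1",          # phenylurea side chain
    "C=Cc1ccccc1",                   "C1CCCCC1",          # styrene
    "c1ccc(cc1)-c1ccncc1",           "C1CCCCC1C1CCCCC1",  # 4-phenylpyridine
    "Cn1cnc2c1c(=O)n(C)c(=O)n2C",    "C1CCC2CCCC2C1",     # caffeine (purine core)
    "O=S(=O)(N)c1ccccc1",            "C1CCCCC1"           # benzenesulfonamide
  )
}

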
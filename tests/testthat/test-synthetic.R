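test_that("generator presets emulate the endpoint sizes and ranges", {
  presets <- list(Ki = c(661L, 5.76, 10.00), IC50 = c(1894L, 4.04, 9.40),
                  EC50 = c(367L, 3.95, 8.72))
  for (ep in names(presets)) {
    cfg <- generator_config(ep)
    expect_equal(cfg$n_compounds, presets[[ep]][1])
    expect_equal(cfg$activity_range, presets[[ep]][2:3])
  }
  # scaled-down draws respect the configured activity bounds
  for (ep in c("Ki", "EC50")) {
    lib <- generate_library(generator_config(ep, n_compounds = 60, seed = 2))
    rng <- generator_config(ep)$activity_range
    expect_true(all(lib$p_activity >= rng[1] & lib$p_activity <= rng[2]))
  }
})

test_that("libraries are reproducible, unique, and flag-consistent", {
  cfg <- generator_config("Ki", n_compounds = 80, seed = 19)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(as.data.frame(lib1), as.data.frame(lib2))
  expect_false(anyDuplicated(lib1$smiles) > 0)
  # flags agree with SMARTS matching on the emitted SMILES
  pe <- cfg$planted_effects
  for (k in seq_len(nrow(pe))) {
    expect_identical(lib1[[paste0("has_", pe$name[k])]],
                     smarts_matches(lib1$smiles, pe$smarts[k]) > 0)
  }
})

test_that("noiseless activity equals baseline plus planted effects", {
  cfg <- generator_config("Ki", n_compounds = 60, noise_sd = 0, seed = 23)
  lib <- generate_library(cfg)
  pe <- cfg$planted_effects
  expected <- cfg$baseline +
    as.numeric(as.matrix(lib[paste0("has_", pe$name)]) %*% pe$effect)
  expect_equal(lib$p_noiseless, expected)
  expect_equal(lib$p_activity,
               pmin(pmax(expected, cfg$activity_range[1]),
                    cfg$activity_range[2]))
  # single planted effect of +1.0: flagged-group difference is exactly 1
  cfg1 <- generator_config("Ki", n_compounds = 60, noise_sd = 0,
                           planted_effects = tibble::tibble(
                             name = "methylsulfonamide",
                             fragment = "NS(C)(=O)=O",
                             smarts = "N[SX4](C)(=O)=O",
                             effect = 1.0, prob = 0.4),
                           seed = 29)
  lib1 <- generate_library(cfg1)
  expect_equal(
    mean(lib1$p_noiseless[lib1$has_methylsulfonamide]) -
      mean(lib1$p_noiseless[!lib1$has_methylsulfonamide]), 1.0)
})

test_that("the scaffold census mixes common and rare groups", {
  lib <- generate_library(generator_config("Ki", n_compounds = 200,
                                           seed = 31))
  cen <- scaffold_census(lib, smiles_col = "smiles")
  expect_true(any(cen$n_members >= 5))
  expect_true(any(cen$n_members < 5))
  # census has at least as many groups as distinct template skeletons drawn
  cfg <- attr(lib, "config")
  templates <- c(cfg$scaffold_templates,
                 cfg$rare_templates)[unique(lib$template_id)]
  t_scaff <- unique(carbon_scaffold(sprintf(templates, "C", "C", "C")))
  expect_gte(nrow(cen), length(t_scaff))
})

test_that("duplicate expansion round-trips through curation", {
  lib <- test_library()[1:50, ]
  rec0 <- add_duplicates(lib, fraction = 0, jitter = 0, seed = 2)
  expect_equal(nrow(rec0), 50)
  cur <- curate_activities(rec0)
  expect_equal(nrow(cur), 50)
  expect_equal(sort(cur$canonical_smiles), sort(canonical_smiles(lib$smiles)))
  expect_equal(cur$p_activity[match(lib$smiles, cur$canonical_smiles)],
               lib$p_activity, tolerance = 1e-9)
  # jitter above 0.5 forces the duplicated pair's range above 1 -> discarded
  rec1 <- add_duplicates(lib, fraction = 0.2, jitter = 0.8, seed = 2)
  cur1 <- curate_activities(rec1)
  expect_equal(curation_report(cur1)$discarded_inconsistent, 10L)
  expect_equal(nrow(cur1), 40L)
  # jitter below 0.5 keeps every compound, merged to its mean
  rec2 <- add_duplicates(lib, fraction = 0.2, jitter = 0.3, seed = 2)
  cur2 <- curate_activities(rec2)
  expect_equal(nrow(cur2), 50L)
})
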
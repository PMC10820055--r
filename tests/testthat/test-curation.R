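test_that("negative log molar conversion matches closed forms", {
  expect_equal(to_negative_log_molar(1, "nM"), 9)
  expect_equal(to_negative_log_molar(10, "uM"), 5)
  expect_equal(to_negative_log_molar(0.001, "M"), 3)
  expect_equal(to_negative_log_molar(c(100, 50), c("nM", "uM")),
               c(7, -log10(50e-6)))
  expect_error(to_negative_log_molar(0, "nM"), "positive")
  expect_error(to_negative_log_molar(-3, "M"), "positive")
  expect_error(to_negative_log_molar(1, "mg/mL"), "unconvertible")
})

test_that("negative log molar is strictly decreasing in value", {
  v <- sort(10^runif(25, -3, 3))
  p <- to_negative_log_molar(v, "uM")
  expect_true(all(diff(p) < 0))
})

test_that("salt stripping keeps the largest organic fragment", {
  expect_equal(strip_salts_and_metals("CCO.[Na+].[Cl-]"),
               canonical_smiles("CCO"))
  expect_equal(strip_salts_and_metals("c1ccccc1"),
               canonical_smiles("c1ccccc1"))
  # metal-only input has no organic fragment left
  expect_true(is.na(strip_salts_and_metals("[Na+].[Cl-]")))
  # larger organic fragment wins regardless of order
  expect_equal(strip_salts_and_metals("CC(=O)O.c1ccccc1CCN"),
               canonical_smiles("c1ccccc1CCN"))
  expect_error(strip_salts_and_metals("not-a-smiles"), "unparseable")
})

test_that("activity-table screening drops and counts bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    SMILES = c("CCO", "CCN", "CCC", "CCCC", "CC"),
    type = c("IC50", "IC50", NA, "potency", "IC50"),
    val = c(100, NA, 50, 50, 10),
    units = c("nM", "nM", "nM", "nM", "mg/mL")
  ), path, row.names = FALSE)
  rec <- parse_activity_table(path, column_map = c(
    smiles = "SMILES", endpoint = "type", value = "val", unit = "units"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$smiles, "CCO")
  log <- attr(rec, "drop_log")
  expect_equal(unname(log["missing_endpoint"]), 2L)
  expect_equal(unname(log["missing_value"]), 1L)
  expect_equal(unname(log["unconvertible_unit"]), 1L)
  expect_error(parse_activity_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("deduplication applies the one-log-unit rule", {
  rec <- tibble::tibble(
    canonical_smiles = c("CCO", "CCO", "CCN", "CCN", "CCC"),
    endpoint = "Ki",
    p_activity = c(8.0, 8.6, 6.0, 7.5, 7.2)
  )
  out <- deduplicate(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$p_activity[out$canonical_smiles == "CCO"], 8.3)
  expect_equal(out$p_activity[out$canonical_smiles == "CCC"], 7.2)
  expect_false("CCN" %in% out$canonical_smiles)
  expect_equal(attr(out, "n_discarded"), 1L)
  # boundary: range exactly 1 is kept (inclusive rule)
  keep <- deduplicate(tibble::tibble(
    canonical_smiles = "CCO", endpoint = "Ki", p_activity = c(7, 8)))
  expect_equal(keep$p_activity, 7.5)
})

test_that("retained group means stay within group bounds and output is unique", {
  set.seed(42)
  rec <- tibble::tibble(
    canonical_smiles = sample(paste0("C", 1:8, "CO"), 60, replace = TRUE),
    endpoint = sample(c("Ki", "IC50"), 60, replace = TRUE),
    p_activity = runif(60, 4, 9)
  )
  rec$canonical_smiles <- paste0("CC(C)", substr(rec$canonical_smiles, 1, 2))
  out <- deduplicate(rec)
  expect_false(any(duplicated(out[c("canonical_smiles", "endpoint")])))
  for (k in seq_len(nrow(out))) {
    grp <- rec$p_activity[rec$canonical_smiles == out$canonical_smiles[k] &
                          rec$endpoint == out$endpoint[k]]
    expect_gte(out$p_activity[k], min(grp))
    expect_lte(out$p_activity[k], max(grp))
  }
})

test_that("curation is idempotent on its own output", {
  lib <- test_library()[1:40, ]
  rec <- add_duplicates(lib, fraction = 0.3, jitter = 0.2, seed = 5)
  cur <- curate_activities(rec)
  rec2 <- tibble::tibble(
    smiles = cur$canonical_smiles, endpoint = cur$endpoint,
    value = 10^(9 - cur$p_activity), unit = "nM")
  cur2 <- curate_activities(rec2)
  expect_equal(nrow(cur2), nrow(cur))
  expect_equal(sort(cur2$canonical_smiles), sort(cur$canonical_smiles))
  expect_equal(cur2$p_activity[order(cur2$canonical_smiles)],
               cur$p_activity[order(cur$canonical_smiles)],
               tolerance = 1e-10)
  expect_equal(curation_report(cur2)$discarded_inconsistent, 0L)
})
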
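#' Convert an activity value to its negative log molar form
#'
#' Converts a measured activity (Ki, IC50 or EC50) in nM, uM or M to molar
#' units and returns the negative base-10 logarithm (pKi / pIC50 / pEC50).
#'
#' @param value Positive numeric vector of activity values.
#' @param unit Character vector of units, one of `"nM"`, `"uM"` (also
#'   accepted: `"µM"`), `"M"`. Recycled against `value`.
#' @return Numeric vector of p-activities.
#' @examples
#' to_negative_log_molar(1, "nM")    # 9
#' to_negative_log_molar(10, "uM")   # 5
#' @export
to_negative_log_molar <- function(value, unit) {
  if (any(!is.finite(value) | value <= 0)) {
    stop("activity values must be positive and finite", call. = FALSE)
  }
  f <- unit_to_molar_factor(unit)
  if (anyNA(f)) {
    stop("unconvertible unit(s): ",
         paste(unique(unit[is.na(f)]), collapse = ", "), call. = FALSE)
  }
  -log10(value * f)
}

unit_to_molar_factor <- function(unit) {
  u <- tolower(trimws(unit))
  u[u == "µm"] <- "um"
  unname(c(nm = 1e-9, um = 1e-6, m = 1)[u])
}

#' Strip salts and metal counter-ions from SMILES
#'
#' Keeps the largest organic fragment of each input: the fragment with the
#' most heavy atoms that contains at least one carbon. Ties are broken toward
#' the lexicographically smallest canonical SMILES so the result is
#' deterministic. Inputs with no organic fragment (bare salts/metals) return
#' `NA`.
#'
#' @param smiles Character vector of SMILES (possibly multi-component).
#' @return Character vector of canonical parent SMILES; `NA` where no
#'   organic fragment exists. Errors on unparseable SMILES.
#' @examples
#' strip_salts_and_metals("CCO.[Na+].[Cl-]")  # "CCO"
#' @export
strip_salts_and_metals <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[is.na(can)], 5), collapse = ", "),
         call. = FALSE)
  }
  vapply(can, function(s) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (length(frags) == 1L) {
      if (!grepl("[Cc]", gsub("Cl|Ca|Cd|Co|Cr|Cu|Cs", "", frags))) return(NA_character_)
      return(s)
    }
    cf <- canonical_smiles(frags)
    info <- lapply(parse_mols(cf), function(m) {
      c(n = m$n_atoms, org = as.integer(any(m$element == "C")))
    })
    n <- vapply(info, `[[`, numeric(1), "n")
    org <- vapply(info, `[[`, numeric(1), "org") == 1
    if (!any(org)) return(NA_character_)
    cand <- cf[org & n == max(n[org])]
    sort(cand)[1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Read a raw activity table
#'
#' Reads a CSV of raw activity measurements and applies the first curation
#' step: rows without a recognized endpoint, without a positive numeric
#' activity value, or with a unit that cannot be converted to molar are
#' dropped and counted per reason.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Named character vector mapping the canonical record
#'   fields `smiles`, `endpoint`, `value`, `unit` (optionally `source_id`)
#'   to column names in the file.
#' @return A tibble of activity records (`smiles`, `endpoint`, `value`,
#'   `unit`, `source_id`) with a `drop_log` attribute: a named integer vector
#'   of dropped-row counts per reason code.
#' @export
parse_activity_table <- function(path,
                                 column_map = c(smiles = "smiles",
                                                endpoint = "endpoint",
                                                value = "value",
                                                unit = "unit")) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("smiles", "endpoint", "value", "unit")
  assert_that(all(need %in% names(column_map)),
              "column_map must map smiles, endpoint, value, unit")
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  assert_that(length(missing_cols) == 0,
              paste0("columns absent from file: ",
                     paste(missing_cols, collapse = ", ")))
  df <- tibble::tibble(
    smiles = as.character(raw[[column_map[["smiles"]]]]),
    endpoint = as.character(raw[[column_map[["endpoint"]]]]),
    value = suppressWarnings(as.numeric(raw[[column_map[["value"]]]])),
    unit = as.character(raw[[column_map[["unit"]]]]),
    source_id = if ("source_id" %in% names(column_map) &&
                    column_map[["source_id"]] %in% names(raw)) {
      as.character(raw[[column_map[["source_id"]]]])
    } else NA_character_
  )
  screen_activity_records(df)
}

#' @rdname parse_activity_table
#' @param records A data frame with columns `smiles`, `endpoint`, `value`,
#'   `unit` (and optionally `source_id`).
#' @export
screen_activity_records <- function(records) {
  df <- tibble::as_tibble(records)
  if (!"source_id" %in% names(df)) df$source_id <- NA_character_
  drop_log <- c(missing_endpoint = 0L, missing_value = 0L,
                unconvertible_unit = 0L)
  bad_ep <- is.na(df$endpoint) | !df$endpoint %in% c("Ki", "IC50", "EC50")
  drop_log[["missing_endpoint"]] <- sum(bad_ep)
  df <- df[!bad_ep, ]
  bad_val <- is.na(df$value) | !is.finite(df$value) | df$value <= 0
  drop_log[["missing_value"]] <- sum(bad_val)
  df <- df[!bad_val, ]
  bad_unit <- is.na(unit_to_molar_factor(df$unit))
  drop_log[["unconvertible_unit"]] <- sum(bad_unit)
  df <- df[!bad_unit, ]
  attr(df, "drop_log") <- drop_log
  df
}

#' Merge replicate measurements into one compound record
#'
#' Groups records by `(canonical_smiles, endpoint)`. If the spread of the
#' p-activities within a group is at most 1 log unit the group collapses to
#' its arithmetic mean; otherwise the compound is discarded as inconsistent.
#'
#' @param records A data frame with columns `canonical_smiles`, `endpoint`,
#'   `p_activity`.
#' @return A tibble with one row per retained `(canonical_smiles, endpoint)`
#'   and a `n_discarded` attribute counting discarded compounds.
#' @export
deduplicate <- function(records) {
  df <- tibble::as_tibble(records)
  stopifnot(all(c("canonical_smiles", "endpoint", "p_activity") %in% names(df)))
  assert_that(all(is.finite(df$p_activity)), "p_activity must be finite")
  grouped <- df |>
    dplyr::group_by(.data$canonical_smiles, .data$endpoint) |>
    dplyr::summarise(
      spread = max(.data$p_activity) - min(.data$p_activity),
      p_activity = mean(.data$p_activity),
      n_measurements = dplyr::n(),
      .groups = "drop"
    )
  keep <- grouped$spread <= 1.0
  out <- grouped[keep, c("canonical_smiles", "endpoint", "p_activity",
                         "n_measurements")]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Curate a raw activity table end to end
#'
#' Applies the full four-step curation: (1) drop rows without a clear
#' endpoint/value/convertible unit, (2) convert values to molar and take the
#' negative log10, (3) merge or discard replicate measurements by the
#' 1-log-unit rule, (4) strip salt and metal ions, keeping the largest
#' organic fragment. Salt stripping happens before de-duplication so that
#' salt forms of the same parent merge.
#'
#' @param records A data frame of raw records (`smiles`, `endpoint`,
#'   `value`, `unit`, optional `source_id`), e.g. from
#'   [parse_activity_table()] or [add_duplicates()].
#' @return A tibble of curated compounds (`canonical_smiles`, `endpoint`,
#'   `p_activity`, `n_measurements`) with a `curation_report` attribute.
#' @seealso [curation_report()]
#' @export
curate_activities <- function(records) {
  df <- screen_activity_records(records)
  report <- as.list(attr(df, "drop_log"))
  report$n_input <- nrow(tibble::as_tibble(records))
  can <- canonical_smiles(df$smiles)
  report$unparseable_smiles <- sum(is.na(can))
  df <- df[!is.na(can), ]
  parent <- strip_salts_and_metals(df$smiles)
  report$no_organic_fragment <- sum(is.na(parent))
  df <- df[!is.na(parent), ]
  parent <- parent[!is.na(parent)]
  curated <- tibble::tibble(
    canonical_smiles = parent,
    endpoint = df$endpoint,
    p_activity = to_negative_log_molar(df$value, df$unit)
  ) |> deduplicate()
  report$discarded_inconsistent <- attr(curated, "n_discarded")
  report$n_output <- nrow(curated)
  attr(curated, "curation_report") <- report
  curated
}

#' @rdname curate_activities
#' @param x A curated tibble returned by [curate_activities()].
#' @export
curation_report <- function(x) attr(x, "curation_report")
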
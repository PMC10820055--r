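# Synthetic molecule libraries with planted structure-activity signal.
# Compounds are assembled as scaffold template x R-group decoration;
# activity is a baseline plus additive substructure effects plus Gaussian
# noise, clipped to the endpoint's activity range. Everything downstream
# (curation, descriptors, scaffold split, selection, modelling,
# interpretation) can therefore be checked against known ground truth.

# Two-ring templates over a range of linker lengths plus assorted ring
# systems give a census of structurally distinct carbon scaffolds; the
# trailing block of templates is sampled rarely (to below the rare-scaffold
# threshold) to emulate the long tail of a real scaffold census.
.common_templates <- c(
  "c1cc(%2$s)ccc1NC(=O)Nc1cc(%3$s)cc(%1$s)c1",   # phenyl-urea-phenyl neck
  "c1cc(%2$s)ccc1CNC(=O)c1cc(%3$s)cc(%1$s)c1",   # benzamide with methylene
  "c1cc(%2$s)ccc1NC(=O)c1cc(%3$s)cc(%1$s)c1",    # benzanilide
  "c1cc(%2$s)ccc1CCNC(=O)c1cc(%3$s)cc(%1$s)c1",  # ethylene-linked amide
  "C1CC(%2$s)CCC1NC(=O)Nc1cc(%3$s)cc(%1$s)c1",   # cyclohexyl urea
  "c1cc(%2$s)cc2cc(N(C%3$s)C(=O)C%1$s)ccc12",    # naphthalene amide
  "c1cc(%2$s)ccc1N(C%3$s)c1ccc(%1$s)cc1",        # diphenylamine
  "C1CC(%2$s)CCC1c1cc(%3$s)cc(%1$s)c1"           # cyclohexyl-phenyl
)

.rare_template_set <- function() {
  ringsA <- c("c1cc(%2$s)ccc1", "C1CC(%2$s)CC1", "C1CC(%2$s)CCCC1",
              "c1cc(%2$s)cc2ccccc12", "c1cc(%2$s)sc1")
  linkers <- c("CC", "CCC", "CCCC", "NC(=O)CC")
  unlist(lapply(ringsA, function(a) {
    vapply(linkers, function(l) paste0(a, l, "c1cc(%3$s)cc(%1$s)c1"),
           character(1))
  }), use.names = FALSE)
}

.plain_decorations <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N",
                        "N(C)C", "F", "Cl", "Br", "C(F)(F)F", "C#N", "CO",
                        "CCO", "C(C)(C)C", "OC(C)C", "OC(F)F", "CN", "CCN",
                        "C(C)O", "SC", "C(=O)C", "C(=O)OC", "CCCC")

# Planted substructure effects: fragment inserted as a decoration, the
# SMARTS that defines ground-truth presence, the additive activity effect
# (p-units) and the sampling probability of the fragment.
default_planted_effects <- function() {
  tibble::tibble(
    name = c("methylsulfonamide", "trifluoroacetamide"),
    fragment = c("NS(C)(=O)=O", "NC(=O)C(F)(F)F"),
    smarts = c("N[SX4](C)(=O)=O", "[NX3]C(=O)C(F)(F)F"),
    effect = c(1.0, 0.3),
    prob = c(0.45, 0.20)
  )
}

.endpoint_presets <- list(
  Ki   = list(n_compounds = 661L,  activity_range = c(5.76, 10.00)),
  IC50 = list(n_compounds = 1894L, activity_range = c(4.04, 9.40)),
  EC50 = list(n_compounds = 367L,  activity_range = c(3.95, 8.72))
)

#' Configuration for the synthetic library generator
#'
#' Defaults emulate the published study conditions per endpoint: library
#' sizes 661 (Ki), 1894 (IC50), 367 (EC50); p-activity ranges [5.76, 10.00],
#' [4.04, 9.40] and [3.95, 8.72] respectively; a scaffold census mixing
#' common (>= 5 members) and rare (< 5 members) carbon scaffolds; and two
#' planted substructure effects (+1.0 and +0.3 p-units) over a Gaussian
#' noise floor.
#'
#' @param endpoint `"Ki"`, `"IC50"` or `"EC50"`.
#' @param n_compounds Library size; defaults to the endpoint preset.
#' @param activity_range Length-2 numeric, low < high; endpoint preset by
#'   default.
#' @param scaffold_templates Character vector of `sprintf` templates with
#'   one `%s` decoration slot, sampled with Zipf-like weights.
#' @param rare_templates Templates reserved for the rare tail of the
#'   scaffold census.
#' @param rare_fraction Fraction of compounds spread thinly (at most
#'   `rare_threshold - 1` per template) over `rare_templates`.
#' @param decorations Plain (effect-free) R-group SMILES fragments.
#' @param planted_effects Tibble with columns `name`, `fragment`, `smarts`,
#'   `effect`, `prob`; see [default_planted_effects()].
#' @param noise_sd Gaussian noise standard deviation in p-units.
#' @param baseline Noiseless activity of an effect-free compound; defaults
#'   to 20% above the low end of `activity_range`.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(endpoint = c("Ki", "IC50", "EC50"),
                             n_compounds = NULL, activity_range = NULL,
                             scaffold_templates = .common_templates,
                             rare_templates = .rare_template_set(),
                             rare_fraction = 0.10,
                             decorations = .plain_decorations,
                             planted_effects = default_planted_effects(),
                             noise_sd = 0.3, baseline = NULL, seed = 1L) {
  endpoint <- match.arg(endpoint)
  preset <- .endpoint_presets[[endpoint]]
  n_compounds <- as.integer(n_compounds %||% preset$n_compounds)
  activity_range <- activity_range %||% preset$activity_range
  assert_that(n_compounds >= 1, "n_compounds must be >= 1")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(activity_range[1] < activity_range[2],
              "activity_range must satisfy low < high")
  baseline <- baseline %||%
    (activity_range[1] + 0.2 * diff(activity_range))
  structure(list(
    endpoint = endpoint, n_compounds = n_compounds,
    activity_range = activity_range,
    scaffold_templates = scaffold_templates,
    rare_templates = rare_templates, rare_fraction = rare_fraction,
    decorations = decorations, planted_effects = planted_effects,
    noise_sd = noise_sd, baseline = baseline, seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate a synthetic molecule library
#'
#' Assembles `n_compounds` molecules (template + sampled decoration),
#' assigns activities `baseline + sum(effect * presence) + N(0, noise_sd)`
#' clipped to the activity range, and records per-compound ground truth.
#' Substructure presence flags are computed by SMARTS matching on the
#' emitted structures, so incidental occurrences of a planted substructure
#' count as present. Fully reproducible under the config seed.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_library` tibble: `compound_id`, `smiles`
#'   (canonical), `endpoint`, `p_activity`, `p_noiseless`, `template_id`,
#'   plus one logical `has_<name>` column per planted effect. The config is
#'   attached as attribute `config`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_compounds
  n_rare <- min(floor(config$rare_fraction * n),
                4L * length(config$rare_templates))
  n_common <- n - n_rare
  pe <- config$planted_effects
  assert_that(sum(pe$prob) <= 1, "planted-effect probabilities exceed 1")
  zipf <- (1 / seq_along(config$scaffold_templates)^1.2)
  rare_pool <- if (n_rare > 0) {
    rep_len(rep(config$rare_templates, each = 4L), n_rare)
  } else character(0)
  # assemble template x decoration combinations, resampling any structure
  # that canonicalizes onto one already emitted (compounds are unique)
  draw_batch <- function(m, templates) {
    tdraw <- if (is.null(templates)) {
      sample(config$scaffold_templates, m, replace = TRUE,
             prob = zipf / sum(zipf))
    } else templates
    frag_draw <- stats::runif(m)
    frag_idx <- findInterval(frag_draw, c(0, cumsum(pe$prob)),
                             left.open = TRUE)
    frag_idx[frag_idx > nrow(pe)] <- 0L
    dec1 <- ifelse(frag_idx > 0, pe$fragment[pmax(frag_idx, 1)],
                   sample(config$decorations, m, replace = TRUE))
    dec2 <- sample(config$decorations, m, replace = TRUE)
    dec3 <- sample(config$decorations, m, replace = TRUE)
    raw <- sprintf(tdraw, dec1, dec2, dec3)
    can <- canonical_smiles(raw)
    if (anyNA(can)) {
      bad <- unique(raw[is.na(can)])
      stop("uncombinable template/decoration pair(s): ",
           paste(utils::head(bad, 3), collapse = "; "), call. = FALSE)
    }
    tibble::tibble(smiles = can, template = tdraw)
  }
  collect <- function(m, templates = NULL, seen = character(0)) {
    out <- NULL
    pending_templates <- templates
    tries <- 0L
    while (m > 0) {
      tries <- tries + 1L
      assert_that(tries <= 50L,
                  "generator failed to produce enough unique structures")
      batch <- draw_batch(m, pending_templates)
      keep <- !duplicated(batch$smiles) & !batch$smiles %in% seen
      batch <- batch[keep, ]
      seen <- c(seen, batch$smiles)
      out <- dplyr::bind_rows(out, batch)
      if (!is.null(pending_templates)) {
        pending_templates <- pending_templates[!keep]
      }
      m <- m - nrow(batch)
    }
    out
  }
  common <- collect(n_common)
  rare <- if (n_rare > 0) collect(n_rare, templates = rare_pool,
                                  seen = common$smiles) else NULL
  lib <- dplyr::bind_rows(common, rare)
  can <- lib$smiles
  flags <- vapply(seq_len(nrow(pe)), function(k) {
    smarts_matches(can, pe$smarts[k]) > 0
  }, logical(n))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = n)
  p_noiseless <- config$baseline + as.numeric(flags %*% pe$effect)
  noise <- stats::rnorm(n, 0, config$noise_sd)
  p_activity <- pmin(pmax(p_noiseless + noise, config$activity_range[1]),
                     config$activity_range[2])
  out <- tibble::tibble(
    compound_id = sprintf("SYN%05d", seq_len(n)),
    smiles = can,
    endpoint = config$endpoint,
    p_activity = p_activity,
    p_noiseless = p_noiseless,
    template_id = match(lib$template, c(config$scaffold_templates,
                                        config$rare_templates))
  )
  colnames(flags) <- paste0("has_", pe$name)
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(flags)))
  attr(out, "config") <- config
  class(out) <- c("synthetic_library", class(out))
  out
}

#' Expand a library into raw unit-bearing activity records
#'
#' Converts each library compound into one or more raw measurement records
#' (random nM / uM units), optionally duplicating a fraction of compounds
#' with symmetric p-activity jitter to exercise the curation rules: with
#' `jitter = 0` curation recovers the library exactly; a jitter above 0.5
#' forces the duplicated compound's p-activity range above 1 so curation
#' discards it.
#'
#' @param library A `synthetic_library` (or any tibble with `smiles`,
#'   `endpoint`, `p_activity`).
#' @param fraction Fraction of compounds receiving duplicate measurements.
#' @param jitter Half-spread of the duplicate pair: duplicates are emitted
#'   at `p_activity +/- jitter`.
#' @param seed Integer seed.
#' @return A tibble of raw records (`smiles`, `endpoint`, `value`, `unit`,
#'   `source_id`) consumable by [curate_activities()].
#' @export
add_duplicates <- function(library, fraction = 0, jitter = 0, seed = 1L) {
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  base <- tibble::tibble(
    smiles = library$smiles,
    endpoint = library$endpoint,
    p = library$p_activity,
    source_id = paste0("rec", seq_len(nrow(library)))
  )
  n_dup <- round(fraction * nrow(base))
  extra <- NULL
  if (n_dup > 0) {
    pick <- sample(nrow(base), n_dup)
    extra <- dplyr::bind_rows(
      dplyr::mutate(base[pick, ], p = .data$p + jitter,
                    source_id = paste0(.data$source_id, "_dupA")),
      dplyr::mutate(base[pick, ], p = .data$p - jitter,
                    source_id = paste0(.data$source_id, "_dupB"))
    )
  }
  all_rec <- dplyr::bind_rows(base, extra)
  unit <- sample(c("nM", "uM"), nrow(all_rec), replace = TRUE)
  value <- ifelse(unit == "nM", 10^(9 - all_rec$p), 10^(6 - all_rec$p))
  tibble::tibble(
    smiles = all_rec$smiles, endpoint = all_rec$endpoint,
    value = value, unit = unit, source_id = all_rec$source_id
  )
}

#' Bits perfectly correlated with a planted flag
#'
#' Utility for ground-truth checks: returns the feature columns whose
#' presence pattern across the library equals the planted-substructure
#' flag, i.e. the fingerprint bits characteristic of the planted fragment.
#'
#' @param features Feature matrix.
#' @param flag Logical vector over rows.
#' @return Character vector of feature ids.
#' @export
characteristic_bits <- function(features, flag) {
  m <- as.matrix(features) > 0
  colnames(m)[apply(m, 2, function(col) all(col == flag))]
}
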
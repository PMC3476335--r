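#' Parse a database name per Ensembl naming conventions
#'
#' Four productions are recognised, disambiguated by the literal
#' `collection` token, the type keyword and the number of trailing numeric
#' tokens:
#'
#' * `<species>_<type>_<schema>_<build>` — Ensembl-main single species;
#' * `<species>_<type>_<egver>_<schema>_<build>` — EnsemblGenomes single
#'   species (three trailing tokens, the first two numeric);
#' * `<stem>_collection_<type>_<egver>_<schema>_<build>` — multi-species
#'   collection;
#' * `ensembl_compara[_<division>_<egver>]_<schema>` — compara (no species).
#'
#' When two trailing integers could be read either way they are read as
#' `<schema>_<build>`. Names matching no production are classified
#' `db_type = "other"` and are later ignored by the catalog (not an error).
#'
#' @param name Database name (one string).
#' @return One-row tibble with columns `raw_name`, `db_type`,
#'   `species_token`, `is_collection`, `eg_version`, `division`,
#'   `schema_release`, `build_token`.
#' @examples
#' parse_database_name("testus_exemplaris_core_65_2")
#' parse_database_name("escherichia_shigella_collection_core_14_66_1")
#' parse_database_name("ensembl_compara_66")
#' @export
parse_database_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  other <- tibble(
    raw_name = name, db_type = "other", species_token = NA_character_,
    is_collection = FALSE, eg_version = NA_integer_, division = NA_character_,
    schema_release = NA_integer_, build_token = NA_character_)

  # compara: ensembl_compara[_<division>_<egver>]_<schema>
  m <- regmatches(name, regexec(
    "^ensembl_compara(?:_([a-z][a-z_]*?)_([0-9]+))?_([0-9]+)$", name))[[1]]
  if (length(m)) {
    return(tibble(
      raw_name = name, db_type = "compara", species_token = NA_character_,
      is_collection = FALSE,
      eg_version = if (nzchar(m[[3]])) as.integer(m[[3]]) else NA_integer_,
      division = if (nzchar(m[[2]])) m[[2]] else NA_character_,
      schema_release = as.integer(m[[4]]), build_token = NA_character_))
  }

  # collection: <stem>_collection_<type>_<egver>_<schema>_<build>
  m <- regmatches(name, regexec(
    "^([a-z0-9_]+)_collection_(core|variation)_([0-9]+)_([0-9]+)_([A-Za-z0-9]+)$",
    name))[[1]]
  if (length(m)) {
    return(tibble(
      raw_name = name, db_type = m[[3]], species_token = m[[2]],
      is_collection = TRUE, eg_version = as.integer(m[[4]]),
      division = NA_character_,
      schema_release = as.integer(m[[5]]), build_token = m[[6]]))
  }

  # single species with EG version: three trailing tokens, first two numeric
  m <- regmatches(name, regexec(
    "^([a-z0-9_]+?)_(core|variation)_([0-9]+)_([0-9]+)_([A-Za-z0-9]+)$",
    name))[[1]]
  if (length(m)) {
    return(tibble(
      raw_name = name, db_type = m[[3]], species_token = m[[2]],
      is_collection = FALSE, eg_version = as.integer(m[[4]]),
      division = NA_character_,
      schema_release = as.integer(m[[5]]), build_token = m[[6]]))
  }

  # plain: <species>_<type>_<schema>_<build>
  m <- regmatches(name, regexec(
    "^([a-z0-9_]+?)_(core|variation)_([0-9]+)_([A-Za-z0-9]+)$", name))[[1]]
  if (length(m)) {
    return(tibble(
      raw_name = name, db_type = m[[3]], species_token = m[[2]],
      is_collection = FALSE, eg_version = NA_integer_,
      division = NA_character_,
      schema_release = as.integer(m[[4]]), build_token = m[[5]]))
  }

  other
}

#' Parse many database names
#' @param names Character vector of database names.
#' @return Tibble with one row per name (see [parse_database_name()]).
#' @export
parse_database_names <- function(names) {
  purrr::map_dfr(names, parse_database_name)
}

#' Reconstruct a database name from its parsed descriptor
#'
#' Inverse of [parse_database_name()] for every recognised production.
#'
#' @param desc One-row descriptor tibble.
#' @return The database name string.
#' @export
reconstruct_database_name <- function(desc) {
  stopifnot(nrow(desc) == 1)
  if (desc$db_type == "other") return(desc$raw_name)
  if (desc$db_type == "compara") {
    mid <- if (!is.na(desc$division)) {
      paste0("_", desc$division, "_", desc$eg_version)
    } else ""
    return(paste0("ensembl_compara", mid, "_", desc$schema_release))
  }
  parts <- c(
    desc$species_token,
    if (desc$is_collection) "collection",
    desc$db_type,
    if (!is.na(desc$eg_version)) desc$eg_version,
    desc$schema_release,
    desc$build_token)
  paste(parts, collapse = "_")
}
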
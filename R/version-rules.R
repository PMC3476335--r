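#' Version-aware mapping configuration
#'
#' An Ensembl-style datasource evolves its relational schema between
#' releases; the same logical query (say, "gene by stable id") needs
#' different SQL before and after a migration. The package keeps all SQL in
#' named template sets ("mapping sets") and uses a small declarative rules
#' file to decide which set serves which schema release. Releases outside
#' every rule interval are *unsupported*: the package refuses to guess.
#'
#' The rules grammar is one rule per line:
#' `"<db_type>.<min>-<max?>=<mapping_set_id>"` where `db_type` is one of
#' `core`, `variation`, `compara`; an empty `max` means open-ended.
#' `#` comments and blank lines are ignored.
#'
#' @name version-rules
NULL

DB_TYPES <- c("core", "variation", "compara")

# The canonical query catalogue, partitioned by database type. After import
# resolution every mapping set must cover the catalogue of its type.
QUERY_CATALOGUE <- list(
  core = c(
    "coord_systems.all", "seq_regions.by_coord_system", "seq_region.by_name",
    "assembly.components_of", "sequence.of_region",
    "genes.by_region", "gene.by_stable_id",
    "transcripts.of_gene", "exons.of_transcript", "translation.of_transcript"
  ),
  variation = "variation.features_by_region",
  compara = "compara.homologues_by_stable_id"
)

#' Canonical query catalogue
#'
#' @param db_type Optional database type; if given, only that type's
#'   query-names are returned.
#' @return Character vector of query-names.
#' @export
query_catalogue <- function(db_type = NULL) {
  if (is.null(db_type)) return(unlist(QUERY_CATALOGUE, use.names = FALSE))
  stopifnot(db_type %in% DB_TYPES)
  QUERY_CATALOGUE[[db_type]]
}

#' Load version-mapping rules
#'
#' @param path Path to a properties-style rules file.
#' @param text Rules text, as an alternative to `path`.
#' @return A tibble with columns `db_type`, `min_release`, `max_release`
#'   (`NA` for an open upper bound) and `mapping_set_id`.
#' @examples
#' read_version_rules(text = "core.51-64=57\ncore.65-=65")
#' @export
read_version_rules <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  raw <- lines
  lines <- trimws(sub("#.*$", "", lines))
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec(
      "^(core|variation|compara)\\.([0-9]+)-([0-9]*)=([A-Za-z0-9_]+)$", ln))[[1]]
    if (length(m) == 0) {
      rw_abort("parse_error",
               paste0("malformed rule at line ", i, ": '", raw[[i]], "'"))
    }
    min_r <- as.integer(m[[3]])
    max_r <- if (nzchar(m[[4]])) as.integer(m[[4]]) else NA_integer_
    if (!is.na(max_r) && min_r > max_r) {
      rw_abort("parse_error", paste0(
        "invalid interval at line ", i, ": min release ", min_r,
        " exceeds max release ", max_r))
    }
    rules[[length(rules) + 1]] <- tibble(
      db_type = m[[2]], min_release = min_r, max_release = max_r,
      mapping_set_id = m[[5]])
  }
  out <- if (length(rules)) bind_rows(rules) else
    tibble(db_type = character(), min_release = integer(),
           max_release = integer(), mapping_set_id = character())
  validate_version_rules(out)
  out
}

# Intervals of one db_type must be pairwise disjoint.
validate_version_rules <- function(rules) {
  for (ty in unique(rules$db_type)) {
    r <- rules[rules$db_type == ty, ]
    if (nrow(r) < 2) next
    r <- r[order(r$min_release), ]
    hi <- ifelse(is.na(r$max_release), Inf, r$max_release)
    if (any(r$min_release[-1] <= hi[-nrow(r)])) {
      rw_abort("config_error",
               paste0("overlapping release intervals for db_type '", ty, "'"))
    }
  }
  invisible(rules)
}

#' Resolve the mapping set for a schema release
#'
#' @param rules Rules tibble from [read_version_rules()].
#' @param db_type One of `"core"`, `"variation"`, `"compara"`.
#' @param release Integer schema release.
#' @return The mapping-set id (a string), or `NA_character_` when the
#'   release falls outside every declared interval (unsupported — the
#'   configuration never guesses).
#' @examples
#' rules <- read_version_rules(default_rules_path())
#' resolve_mapping_set(rules, "core", 60)      # "57"
#' resolve_mapping_set(rules, "variation", 61) # NA: unsupported
#' @export
resolve_mapping_set <- function(rules, db_type, release) {
  stopifnot(db_type %in% DB_TYPES, length(release) == 1)
  release <- as.integer(release)
  r <- rules[rules$db_type == db_type, ]
  hi <- ifelse(is.na(r$max_release), Inf, r$max_release)
  hit <- which(r$min_release <= release & release <= hi)
  if (length(hit) == 0) return(NA_character_)
  r$mapping_set_id[[hit]]
}

# Highest release any rule declares for a db_type (Inf if open-ended).
max_declared_release <- function(rules, db_type) {
  r <- rules[rules$db_type == db_type, ]
  if (nrow(r) == 0) return(-Inf)
  max(ifelse(is.na(r$max_release), Inf, r$max_release))
}
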
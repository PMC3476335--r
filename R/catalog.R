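#' Datasource catalog (registry)
#'
#' The catalog plays the registry role: it parses database names per the
#' Ensembl naming conventions, keeps only databases whose schema release
#' resolves to a mapping set under the version rules (unknown releases are
#' excluded, never guessed at), indexes species by name and alias, and
#' answers "latest release" queries so that calls without an explicit
#' release default to the most recent known version.
#'
#' @name datasource-catalog
NULL

#' Build a catalog from database names
#'
#' @param names Character vector of database names (for file-backed
#'   databases, the file names without extension).
#' @param rules Version rules from [read_version_rules()].
#' @param paths Optional named character vector mapping each name to its
#'   SQLite file path; required for any data access, optional for pure
#'   name/registration logic.
#' @param sets Mapping sets from [read_mapping_sets()]; defaults to the
#'   shipped template tree.
#' @return A `genome_catalog` object.
#' @export
build_catalog <- function(names, rules, paths = NULL,
                          sets = read_mapping_sets()) {
  parsed <- parse_database_names(names)
  entries <- list(); exclusions <- list()
  exclude <- function(name, reason) {
    message("catalog: excluding ", name, " (", reason, ")")
    tibble(name = name, reason = reason)
  }
  for (i in seq_len(nrow(parsed))) {
    d <- parsed[i, ]
    if (d$db_type == "other") {
      exclusions[[length(exclusions) + 1]] <-
        exclude(d$raw_name, "unrecognized name")
      next
    }
    set_id <- resolve_mapping_set(rules, d$db_type, d$schema_release)
    if (is.na(set_id)) {
      reason <- if (d$schema_release > max_declared_release(rules, d$db_type))
        paste0("release ", d$schema_release,
               " post-dates the configured mappings")
      else
        paste0("no mapping set configured for ", d$db_type, " release ",
               d$schema_release)
      exclusions[[length(exclusions) + 1]] <- exclude(d$raw_name, reason)
      next
    }
    entries[[length(entries) + 1]] <- mutate(d, mapping_set_id = set_id)
  }
  entries <- if (length(entries)) bind_rows(entries) else
    mutate(parsed[0, ], mapping_set_id = character(0))

  # several builds of one (species, type, release): keep the
  # lexicographically greatest build token
  if (nrow(entries) > 1) {
    key <- paste(entries$species_token, entries$db_type,
                 entries$schema_release)
    keep <- rep(TRUE, nrow(entries))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      winner <- idx[order(entries$build_token[idx])][length(idx)]
      for (j in setdiff(idx, winner)) {
        keep[[j]] <- FALSE
        exclusions[[length(exclusions) + 1]] <- exclude(
          entries$raw_name[[j]],
          paste0("shadowed by build ", entries$build_token[[winner]]))
      }
    }
    entries <- entries[keep, ]
  }

  cat_env <- new.env(parent = emptyenv())
  cat_env$entries <- entries
  cat_env$exclusions <- if (length(exclusions)) bind_rows(exclusions) else
    tibble(name = character(), reason = character())
  cat_env$rules <- rules
  cat_env$sets <- sets
  cat_env$paths <- paths
  cat_env$handles <- new.env(parent = emptyenv())
  cat_env$species <- NULL     # built lazily (collections need a meta read)
  class(cat_env) <- "genome_catalog"
  cat_env
}

#' Build a catalog from a directory of fixture databases
#'
#' Every `*.sqlite` file is offered to [build_catalog()] under its base
#' name.
#'
#' @param dir Directory holding `<database_name>.sqlite` files.
#' @param rules_path Version-rules file; defaults to the shipped rules.
#' @inheritParams build_catalog
#' @return A `genome_catalog` object.
#' @export
catalog_from_dir <- function(dir, rules_path = default_rules_path(),
                             sets = read_mapping_sets()) {
  files <- sort(list.files(dir, pattern = "\\.sqlite$", full.names = TRUE))
  names <- sub("\\.sqlite$", "", basename(files))
  build_catalog(names, read_version_rules(rules_path),
                paths = stats::setNames(files, names), sets = sets)
}

#' Registered databases
#' @param catalog A `genome_catalog`.
#' @return Tibble of registered database descriptors with their mapping set.
#' @export
catalog_entries <- function(catalog) catalog$entries

#' Databases excluded at registration, with reasons
#' @param catalog A `genome_catalog`.
#' @return Tibble with columns `name` and `reason`.
#' @export
catalog_exclusions <- function(catalog) catalog$exclusions

#' @export
print.genome_catalog <- function(x, ...) {
  cat("<genome_catalog> ", nrow(x$entries), " database(s), ",
      nrow(x$exclusions), " excluded\n", sep = "")
  print(x$entries[, c("raw_name", "db_type", "schema_release",
                      "mapping_set_id")])
  invisible(x)
}

entry_path <- function(catalog, raw_name) {
  if (is.null(catalog$paths) || !raw_name %in% names(catalog$paths)) {
    rw_abort("not_available_error",
             paste0("no file path registered for database ", raw_name))
  }
  catalog$paths[[raw_name]]
}

# Species index: one record per species of every registered core database.
# Collection members are only knowable from the database meta table, so the
# index is built on first use (and needs paths for collection entries).
species_index <- function(catalog) {
  if (!is.null(catalog$species)) return(catalog$species)
  records <- list()
  add <- function(canonical, aliases, collection) {
    rec <- records[[canonical]]
    if (is.null(rec)) {
      rec <- list(canonical_name = canonical, aliases = character(0),
                  collection_member = collection)
    }
    rec$aliases <- sort(unique(c(rec$aliases, tolower(canonical),
                                 tolower(aliases))))
    records[[canonical]] <<- rec
  }
  cores <- catalog$entries[catalog$entries$db_type == "core", ]
  for (i in seq_len(nrow(cores))) {
    d <- cores[i, ]
    has_path <- !is.null(catalog$paths) &&
      d$raw_name %in% names(catalog$paths)
    if (d$is_collection) {
      if (!has_path) next  # members unknowable without the meta table
      meta <- read_species_meta(catalog$paths[[d$raw_name]])
      for (sp in unique(meta$name)) {
        add(sp, meta$alias[meta$name == sp], collection = TRUE)
      }
    } else {
      aliases <- character(0)
      if (has_path) {
        meta <- read_species_meta(catalog$paths[[d$raw_name]])
        aliases <- meta$alias
      }
      add(d$species_token, aliases, collection = FALSE)
    }
  }
  catalog$species <- records
  records
}

# Direct meta read at the catalog layer (species discovery precedes any
# versioned query; the query catalogue itself has no meta entry).
read_species_meta <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  meta <- DBI::dbGetQuery(con, paste0(
    "SELECT species_id, meta_key, meta_value FROM meta ",
    "WHERE meta_key IN ('species.db_name', 'species.alias') ",
    "ORDER BY meta_id"))
  names_by_sid <- meta[meta$meta_key == "species.db_name", ]
  out <- list()
  for (i in seq_len(nrow(names_by_sid))) {
    sid <- names_by_sid$species_id[[i]]
    nm <- names_by_sid$meta_value[[i]]
    als <- meta$meta_value[meta$meta_key == "species.alias" &
                             meta$species_id == sid]
    out[[length(out) + 1]] <- tibble(
      species_id = sid, name = nm,
      alias = if (length(als)) list(c(nm, als)) else list(nm))
  }
  res <- bind_rows(out)
  tibble(species_id = rep(res$species_id, lengths(res$alias)),
         name = rep(res$name, lengths(res$alias)),
         alias = unlist(res$alias))
}

#' Look up a species by name or alias
#'
#' Case-insensitive exact alias match.
#'
#' @param catalog A `genome_catalog`.
#' @param alias Species name or registered alias.
#' @return A species record (list with `canonical_name`, `aliases`,
#'   `collection_member`), or `NULL` when no species matches.
#' @export
find_species <- function(catalog, alias) {
  idx <- species_index(catalog)
  key <- tolower(alias)
  hits <- purrr::keep(idx, function(rec) key %in% rec$aliases)
  if (length(hits) == 0) return(NULL)
  if (length(hits) > 1) {
    rw_abort("lookup_error", paste0(
      "alias '", alias, "' is ambiguous; candidates: ",
      paste(vapply(hits, `[[`, "", "canonical_name"), collapse = ", ")))
  }
  hits[[1]]
}

#' All species known to the catalog
#' @param catalog A `genome_catalog`.
#' @return Tibble with `canonical_name`, `collection_member` and a
#'   list-column `aliases`.
#' @export
catalog_species <- function(catalog) {
  idx <- species_index(catalog)
  purrr::map_dfr(idx, function(rec) tibble(
    canonical_name = rec$canonical_name,
    collection_member = rec$collection_member,
    aliases = list(rec$aliases)))
}

# Entries serving a species: its own databases plus, for collection
# members, the collection database that carries them.
entries_for_species <- function(catalog, species_name, db_type) {
  e <- catalog$entries[catalog$entries$db_type == db_type, ]
  if (nrow(e) == 0) return(e)
  direct <- !is.na(e$species_token) & e$species_token == species_name &
    !e$is_collection
  via_collection <- rep(FALSE, nrow(e))
  for (i in which(e$is_collection)) {
    if (is.null(catalog$paths) || !e$raw_name[[i]] %in% names(catalog$paths))
      next
    meta <- read_species_meta(catalog$paths[[e$raw_name[[i]]]])
    via_collection[[i]] <- species_name %in% meta$name
  }
  e[direct | via_collection, ]
}

#' Most recent registered release for a species and database type
#'
#' @param catalog A `genome_catalog`.
#' @param species Species name, alias, or record from [find_species()].
#' @param db_type `"core"`, `"variation"` or `"compara"`.
#' @return Integer release.
#' @export
latest_release <- function(catalog, species, db_type) {
  if (db_type == "compara") {
    e <- catalog$entries[catalog$entries$db_type == "compara", ]
    if (nrow(e) == 0) {
      rw_abort("not_available_error", "no compara database registered")
    }
    return(max(e$schema_release))
  }
  rec <- as_species_record(catalog, species)
  e <- entries_for_species(catalog, rec$canonical_name, db_type)
  if (nrow(e) == 0) {
    rw_abort("not_available_error", paste0(
      "no ", db_type, " database registered for ", rec$canonical_name))
  }
  max(e$schema_release)
}

as_species_record <- function(catalog, species) {
  if (is.list(species) && !is.null(species$canonical_name)) return(species)
  rec <- find_species(catalog, species)
  if (is.null(rec)) {
    rw_abort("not_found_error", paste0("unknown species '", species, "'"))
  }
  rec
}
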
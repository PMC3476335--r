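#' Version-aware data access
#'
#' [open_database()] binds a registered database to the query-template set
#' its schema release resolves to; every subsequent operation runs only
#' catalogued, named-parameter templates through the bound handle. Handles
#' are shared: re-opening the same (species, type, release) returns the
#' same object, so per-query execution counters (see [query_counts()])
#' observe all access to that database — which is how the package's lazy
#' loading is made testable: listing genes never touches transcript or
#' sequence queries; those run on first explicit access.
#'
#' @name annotation-access
NULL

#' Open a bound database
#'
#' @param catalog A `genome_catalog`.
#' @param species Species name/alias/record; `NULL` for compara.
#' @param db_type `"core"`, `"variation"` or `"compara"`.
#' @param release Integer schema release, or `NULL` for the most recent
#'   registered release ([latest_release()]).
#' @return A `bound_database` handle.
#' @export
open_database <- function(catalog, species, db_type, release = NULL) {
  species_name <- if (is.null(species)) NA_character_ else
    as_species_record(catalog, species)$canonical_name
  if (is.null(release)) {
    release <- latest_release(catalog, species, db_type)
  }
  release <- as.integer(release)
  key <- paste(species_name, db_type, release, sep = "|")
  if (!is.null(catalog$handles[[key]])) return(catalog$handles[[key]])

  e <- if (db_type == "compara") {
    catalog$entries[catalog$entries$db_type == "compara" &
                      catalog$entries$schema_release == release, ]
  } else {
    es <- entries_for_species(catalog, species_name, db_type)
    es[es$schema_release == release, ]
  }
  if (nrow(e) == 0) {
    avail <- if (db_type == "compara") {
      catalog$entries$schema_release[catalog$entries$db_type == "compara"]
    } else {
      entries_for_species(catalog, species_name, db_type)$schema_release
    }
    hint <- if (length(avail)) {
      paste0("; nearest available release: ",
             avail[which.min(abs(avail - release))])
    } else ""
    rw_abort("not_available_error", paste0(
      "no ", db_type, " database at release ", release,
      if (!is.na(species_name)) paste0(" for ", species_name), hint))
  }
  e <- e[1, ]
  templates <- effective_templates(catalog$sets, e$mapping_set_id, db_type)

  db <- new.env(parent = emptyenv())
  db$descriptor <- e
  db$catalog <- catalog
  db$species <- species_name
  db$mapping_set_id <- e$mapping_set_id
  db$templates <- templates
  db$path <- entry_path(catalog, e$raw_name)
  db$con <- NULL                       # connection opened on first query
  db$species_id <- NA_integer_
  db$counters <- new.env(parent = emptyenv())
  db$cache <- new.env(parent = emptyenv())
  class(db) <- "bound_database"
  catalog$handles[[key]] <- db
  db
}

#' @export
print.bound_database <- function(x, ...) {
  cat("<bound_database> ", x$descriptor$raw_name, " (mapping set ",
      x$mapping_set_id, ")\n", sep = "")
  invisible(x)
}

db_connection <- function(db) {
  if (is.null(db$con)) {
    db$con <- DBI::dbConnect(RSQLite::SQLite(), db$path)
    reg.finalizer(db, function(e) {
      if (!is.null(e$con)) try(DBI::dbDisconnect(e$con), silent = TRUE)
    })
  }
  db$con
}

# species_id of the bound species within this database (collections hold
# several); a direct meta read, performed once per handle.
db_species_id <- function(db) {
  if (!is.na(db$species_id)) return(db$species_id)
  sid <- 1L
  if (!is.na(db$species)) {
    meta <- read_species_meta(db$path)
    hit <- meta$species_id[meta$name == db$species]
    if (length(hit)) sid <- as.integer(hit[[1]])
  }
  db$species_id <- sid
  sid
}

#' Execute a catalogued query against a bound database
#'
#' The only path by which SQL reaches the database: `name` must be a
#' query-name of the bound mapping set, and each execution increments the
#' handle's per-query counter.
#'
#' @param db A `bound_database`.
#' @param name Query-name from the canonical catalogue.
#' @param params Named list of template parameters.
#' @return Result tibble.
#' @export
db_query <- function(db, name, params = list()) {
  sql <- if (name %in% names(db$templates)) db$templates[[name]] else NULL
  if (is.null(sql)) {
    rw_abort("config_error", paste0(
      "query '", name, "' is not in the mapping set bound to ",
      db$descriptor$raw_name))
  }
  n <- db$counters[[name]]
  db$counters[[name]] <- if (is.null(n)) 1L else n + 1L
  if (getOption("releasewise.trace", FALSE)) {
    message("query: ", name, " @ ", db$descriptor$raw_name)
  }
  as_tibble(DBI::dbGetQuery(db_connection(db), sql, params = params))
}

#' Per-query execution counts of a handle
#'
#' @param db A `bound_database`.
#' @return Named integer vector (query-name to count); names with no
#'   executions are absent.
#' @export
query_counts <- function(db) {
  nms <- ls(db$counters)
  stats::setNames(vapply(nms, function(n) db$counters[[n]], integer(1)), nms)
}

#' Coordinate systems of a core database
#'
#' Scoped to the bound species (multi-species collections share tables,
#' separated by `species_id`), ordered by rank.
#'
#' @param db A core `bound_database`.
#' @return Tibble with `coord_system_id`, `name`, `version`, `rank`,
#'   `sequence_level`.
#' @export
coordinate_systems <- function(db) {
  cached <- db$cache$coord_systems
  if (!is.null(cached)) return(cached)
  res <- db_query(db, "coord_systems.all",
                  list(species_id = db_species_id(db)))
  if (nrow(res) == 0) {
    rw_abort("data_integrity_error", paste0(
      "core database ", db$descriptor$raw_name,
      " defines no coordinate systems"))
  }
  out <- tibble(
    coord_system_id = as.integer(res$coord_system_id),
    name = res$name, version = res$version, rank = as.integer(res$rank),
    sequence_level = grepl("sequence_level", res$attrib %||% ""))
  db$cache$coord_systems <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Region row by name (species-scoped); not-found error when absent.
region_by_name <- function(db, region_name) {
  res <- db_query(db, "seq_region.by_name",
                  list(name = region_name, species_id = db_species_id(db)))
  if (nrow(res) == 0) {
    rw_abort("not_found_error", paste0(
      "unknown region '", region_name, "' in ", db$descriptor$raw_name))
  }
  res[1, ]
}

# All regions of this species, indexed by seq_region_id; cached per handle.
regions_index <- function(db) {
  cached <- db$cache$regions
  if (!is.null(cached)) return(cached)
  cs <- coordinate_systems(db)
  out <- purrr::map_dfr(cs$coord_system_id, function(id) {
    r <- db_query(db, "seq_regions.by_coord_system",
                  list(coord_system_id = id))
    mutate(r, coord_system_id = as.integer(id))
  })
  out <- dplyr::left_join(
    out,
    cs[, c("coord_system_id", "rank", "sequence_level")],
    by = "coord_system_id")
  db$cache$regions <- out
  out
}

#' Genes overlapping a region interval
#'
#' Overlap is closed-interval (`gene_end >= start` and `gene_start <= end`).
#' The result carries each gene's mapping onto the region; transcripts and
#' sequence are *not* loaded — they are fetched on first access through
#' [transcripts_of_gene()] / [fetch_sequence()].
#'
#' @param db A core `bound_database`.
#' @param region_name Region (e.g. chromosome) name.
#' @param start,end Query interval, 1-based closed.
#' @return Tibble of genes (`stable_id`, `biotype`, `display_name`,
#'   `region`, `start`, `end`, `strand`, `region_length`) ordered by start;
#'   the queried region row is attached as attribute `"region"`.
#' @export
genes_in_region <- function(db, region_name, start, end) {
  region <- region_by_name(db, region_name)
  assert_valid_location(location(region_name, start, end, 1L, region$length))
  res <- db_query(db, "genes.by_region",
                  list(seq_region_id = region$seq_region_id,
                       start = as.integer(start), end = as.integer(end)))
  out <- gene_rows(res)
  attr(out, "region") <- region
  out
}

gene_rows <- function(res) {
  tibble(
    stable_id = res$stable_id, biotype = res$biotype,
    display_name = res$display_label, region = res$region_name,
    start = as.integer(res$seq_region_start),
    end = as.integer(res$seq_region_end),
    strand = as.integer(res$seq_region_strand),
    region_length = as.integer(res$region_length))
}

#' Fetch one gene by stable identifier
#'
#' Dialect-transparent: the bound mapping set decides whether the stable id
#' lives in a separate table (pre-65 layouts) or on the gene table itself.
#'
#' @param db A core `bound_database`.
#' @param stable_id Gene stable identifier.
#' @return One-row gene tibble (see [genes_in_region()]).
#' @export
gene_by_stable_id <- function(db, stable_id) {
  res <- db_query(db, "gene.by_stable_id", list(stable_id = stable_id))
  if (nrow(res) == 0) {
    rw_abort("not_found_error", paste0(
      "no gene '", stable_id, "' in ", db$descriptor$raw_name))
  }
  gene_rows(res[1, ])
}

#' A gene's coordinates across all registered releases
#'
#' The through-time query: one row per registered core release in which the
#' stable id exists, ascending by release. Releases lacking the id are
#' skipped with a message.
#'
#' @param catalog A `genome_catalog`.
#' @param species Species name/alias/record.
#' @param stable_id Gene stable identifier.
#' @return Tibble with `release`, `region`, `start`, `end`, `strand`.
#' @export
gene_across_releases <- function(catalog, species, stable_id) {
  rec <- as_species_record(catalog, species)
  releases <- sort(unique(
    entries_for_species(catalog, rec$canonical_name, "core")$schema_release))
  if (length(releases) == 0) {
    rw_abort("not_available_error",
             paste0("no core database registered for ", rec$canonical_name))
  }
  rows <- purrr::map(releases, function(r) {
    db <- open_database(catalog, rec, "core", r)
    g <- tryCatch(gene_by_stable_id(db, stable_id),
                  rw_not_found_error = function(e) NULL)
    if (is.null(g)) {
      message("gene-history: ", stable_id, " absent from release ", r)
      return(NULL)
    }
    tibble(release = as.integer(r), region = g$region, start = g$start,
           end = g$end, strand = g$strand)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    rw_abort("not_found_error", paste0(
      "gene '", stable_id, "' found in no registered release"))
  }
  out
}

#' Transcripts of a gene
#'
#' @param db A core `bound_database`.
#' @param gene_stable_id Gene stable identifier.
#' @return Tibble of transcripts (`stable_id`, `region`, `start`, `end`,
#'   `strand`, `region_length`).
#' @export
transcripts_of_gene <- function(db, gene_stable_id) {
  res <- db_query(db, "transcripts.of_gene",
                  list(gene_stable_id = gene_stable_id))
  tibble(
    stable_id = res$stable_id, region = res$region_name,
    start = as.integer(res$seq_region_start),
    end = as.integer(res$seq_region_end),
    strand = as.integer(res$seq_region_strand),
    region_length = as.integer(res$region_length))
}

#' Exons of a transcript, in transcription order
#'
#' @param db A core `bound_database`.
#' @param transcript_stable_id Transcript stable identifier.
#' @return Tibble of exons ordered by rank (ascending coordinates on the
#'   forward strand, descending on the reverse).
#' @export
exons_of_transcript <- function(db, transcript_stable_id) {
  res <- db_query(db, "exons.of_transcript",
                  list(transcript_stable_id = transcript_stable_id))
  tibble(
    stable_id = res$stable_id, region = res$region_name,
    start = as.integer(res$seq_region_start),
    end = as.integer(res$seq_region_end),
    strand = as.integer(res$seq_region_strand),
    region_length = as.integer(res$region_length),
    rank = as.integer(res$rank))
}

#' Translation record of a transcript
#'
#' @param db A core `bound_database`.
#' @param transcript_stable_id Transcript stable identifier.
#' @return One-row tibble (`stable_id`, `seq_start`, `seq_end`,
#'   `start_exon`, `end_exon`), or `NULL` for a non-coding transcript.
#' @export
translation_of_transcript <- function(db, transcript_stable_id) {
  res <- db_query(db, "translation.of_transcript",
                  list(transcript_stable_id = transcript_stable_id))
  if (nrow(res) == 0) return(NULL)
  as_tibble(res[1, ])
}

#' Variants overlapping a region interval
#'
#' Cross-schema: the region identifier is resolved through the same-release
#' core database, then the variation database is queried by that shared
#' identifier (no cross-database SQL).
#'
#' @param catalog A `genome_catalog`.
#' @param species Species name/alias/record.
#' @param release Integer release; both a core and a variation database
#'   must be registered at it.
#' @param region_name Region name.
#' @param start,end Query interval, 1-based closed.
#' @return Tibble with `name`, `allele_string`, `region`, `start`, `end`,
#'   `strand`.
#' @export
variants_in_region <- function(catalog, species, release, region_name,
                               start, end) {
  core <- open_database(catalog, species, "core", release)
  vardb <- open_database(catalog, species, "variation", release)
  region <- region_by_name(core, region_name)
  assert_valid_location(location(region_name, start, end, 1L, region$length))
  res <- db_query(vardb, "variation.features_by_region",
                  list(seq_region_id = region$seq_region_id,
                       start = as.integer(start), end = as.integer(end)))
  tibble(
    name = res$variation_name, allele_string = res$allele_string,
    region = region_name,
    start = as.integer(res$seq_region_start),
    end = as.integer(res$seq_region_end),
    strand = as.integer(res$seq_region_strand))
}

#' Homologues of a gene from the compara database
#'
#' @param catalog A `genome_catalog`.
#' @param stable_id Source gene stable identifier.
#' @param release Integer release; `NULL` for the most recent registered
#'   compara database.
#' @param target_species Optional species-name filter on the hits.
#' @return Tibble with `source_stable_id`, `target_stable_id`,
#'   `target_species`, `target_region`, `target_start`, `target_end`,
#'   `homology_type` — enough to re-query the hit against its core schema.
#' @export
homologues_of <- function(catalog, stable_id, release = NULL,
                          target_species = NULL) {
  db <- open_database(catalog, NULL, "compara", release)
  res <- db_query(db, "compara.homologues_by_stable_id",
                  list(stable_id = stable_id))
  out <- tibble(
    source_stable_id = res$source_stable_id,
    target_stable_id = res$target_stable_id,
    target_species = res$target_species_name,
    target_region = res$target_region_name,
    target_start = as.integer(res$target_start),
    target_end = as.integer(res$target_end),
    homology_type = res$homology_type)
  if (!is.null(target_species)) {
    out <- out[out$target_species == target_species, ]
  }
  out
}
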
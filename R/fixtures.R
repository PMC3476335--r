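#' Miniature fixture databases
#'
#' The fixture forge writes small single-file SQLite databases that emulate
#' Ensembl-style core, variation and compara schemas in each supported
#' dialect, with identical logical content encodable in the pre- and
#' post-migration core layouts ("57": separate `*_stable_id` tables; "65":
#' stable ids merged into the feature tables). Files are deterministic:
#' fixed row order, no timestamps, so repeated builds are byte-identical.
#'
#' @name fixture-forge
NULL

#' Construct fixture content
#'
#' A validated in-memory description of one database's logical content.
#' All coordinate fields are 1-based closed intervals.
#'
#' @param db_type `"core"`, `"variation"` or `"compara"`.
#' @param schema_release Integer release written to the `meta` table.
#' @param species Tibble `(species_id, name, aliases)` where `aliases` is a
#'   list-column of character vectors.
#' @param coord_systems Tibble `(coord_system_id, species_id, name, version,
#'   rank, sequence_level)`.
#' @param seq_regions Tibble `(seq_region_id, coord_system_id, name, length)`.
#' @param dna Tibble `(seq_region_id, sequence)` for sequence-level regions.
#' @param assembly Tibble `(asm_seq_region_id, asm_start, asm_end,
#'   cmp_seq_region_id, cmp_start, cmp_end, ori)`.
#' @param genes,transcripts,exons,exon_transcript,translations Annotation
#'   tables (see the reference fixture for the expected columns).
#' @param variants Tibble `(variation_feature_id, name, allele_string,
#'   seq_region_id, start, end, strand)`.
#' @param homologies Tibble `(source_stable_id, source_species, source_region,
#'   source_start, source_end, target_stable_id, target_species,
#'   target_region, target_start, target_end, homology_type)`.
#' @return A `fixture_content` list.
#' @export
fixture_content <- function(db_type, schema_release,
                            species = NULL, coord_systems = NULL,
                            seq_regions = NULL, dna = NULL, assembly = NULL,
                            genes = NULL, transcripts = NULL, exons = NULL,
                            exon_transcript = NULL, translations = NULL,
                            variants = NULL, homologies = NULL) {
  content <- structure(list(
    db_type = db_type, schema_release = as.integer(schema_release),
    species = species, coord_systems = coord_systems,
    seq_regions = seq_regions, dna = dna, assembly = assembly,
    genes = genes, transcripts = transcripts, exons = exons,
    exon_transcript = exon_transcript, translations = translations,
    variants = variants, homologies = homologies),
    class = "fixture_content")
  validate_fixture_content(content)
  content
}

n0 <- function(x) if (is.null(x)) 0L else nrow(x)

validate_fixture_content <- function(content) {
  fail <- function(msg) rw_abort("input_error",
                                 paste0("inconsistent fixture content: ", msg))
  sr <- content$seq_regions
  if (!is.null(content$dna) && n0(content$dna)) {
    m <- match(content$dna$seq_region_id, sr$seq_region_id)
    if (anyNA(m)) fail("dna references unknown seq_region")
    if (any(nchar(content$dna$sequence) != sr$length[m])) {
      fail("dna length differs from seq_region length")
    }
  }
  if (!is.null(content$assembly) && n0(content$assembly)) {
    a <- content$assembly
    if (any((a$asm_end - a$asm_start) != (a$cmp_end - a$cmp_start))) {
      fail("assembly block spans differ between asm and cmp sides")
    }
    if (!all(c(a$asm_seq_region_id, a$cmp_seq_region_id) %in%
             sr$seq_region_id)) {
      fail("assembly block references unknown seq_region")
    }
    for (rid in unique(a$asm_seq_region_id)) {
      r <- a[a$asm_seq_region_id == rid, ]
      r <- r[order(r$asm_start), ]
      if (nrow(r) > 1 && any(r$asm_start[-1] <= r$asm_end[-nrow(r)])) {
        fail("overlapping assembly blocks on one assembled region")
      }
    }
  }
  check_feats <- function(tab, what) {
    if (is.null(tab) || !n0(tab)) return(invisible())
    m <- match(tab$seq_region_id, sr$seq_region_id)
    if (anyNA(m)) fail(paste0(what, " on unknown seq_region"))
    if (any(tab$start < 1 | tab$end > sr$length[m] | tab$start > tab$end)) {
      fail(paste0(what, " location outside its region"))
    }
  }
  check_feats(content$genes, "gene")
  check_feats(content$transcripts, "transcript")
  check_feats(content$exons, "exon")
  check_feats(content$variants, "variant")
  invisible(content)
}

FIXTURE_DIALECTS <- c("57", "65", "62-variation", "compara")

dialect_db_type <- function(dialect) {
  switch(dialect, "57" = "core", "65" = "core",
         "62-variation" = "variation", "compara" = "compara",
         rw_abort("input_error", paste0("unknown dialect '", dialect, "'")))
}

#' Build a fixture database file
#'
#' @param content A [fixture_content()] object.
#' @param dialect One of `"57"`, `"65"` (core layouts), `"62-variation"`,
#'   `"compara"`.
#' @param out_path File path to write (overwritten if present).
#' @return `out_path`, invisibly.
#' @export
build_fixture <- function(content, dialect, out_path) {
  if (dialect_db_type(dialect) != content$db_type) {
    rw_abort("input_error", paste0(
      "content of db_type '", content$db_type,
      "' cannot be encoded in dialect '", dialect, "'"))
  }
  validate_fixture_content(content)
  if (file.exists(out_path)) unlink(out_path)
  con <- DBI::dbConnect(RSQLite::SQLite(), out_path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA page_size = 4096")
  DBI::dbBegin(con)
  write_meta(con, content)
  if (content$db_type == "core") write_core_tables(con, content, dialect)
  if (content$db_type == "variation") write_variation_tables(con, content)
  if (content$db_type == "compara") write_compara_tables(con, content)
  DBI::dbCommit(con)
  invisible(out_path)
}

exec_rows <- function(con, sql, rows) {
  # one INSERT per row in fixed order keeps files bit-stable
  for (i in seq_len(nrow(rows))) {
    DBI::dbExecute(con, sql, params = as.list(rows[i, ]))
  }
}

write_meta <- function(con, content) {
  DBI::dbExecute(con, paste0(
    "CREATE TABLE meta (meta_id INTEGER PRIMARY KEY, species_id INTEGER, ",
    "meta_key TEXT NOT NULL, meta_value TEXT NOT NULL)"))
  rows <- list(list(species_id = NA_integer_, meta_key = "schema_version",
                    meta_value = as.character(content$schema_release)))
  if (!is.null(content$species)) {
    sp <- content$species[order(content$species$species_id), ]
    for (i in seq_len(nrow(sp))) {
      rows[[length(rows) + 1]] <- list(
        species_id = sp$species_id[[i]], meta_key = "species.db_name",
        meta_value = sp$name[[i]])
      for (al in sort(setdiff(sp$aliases[[i]], sp$name[[i]]))) {
        rows[[length(rows) + 1]] <- list(
          species_id = sp$species_id[[i]], meta_key = "species.alias",
          meta_value = al)
      }
    }
  }
  for (k in seq_along(rows)) {
    DBI::dbExecute(con, paste0(
      "INSERT INTO meta (meta_id, species_id, meta_key, meta_value) ",
      "VALUES (:id, :sid, :k, :v)"),
      params = list(id = k, sid = rows[[k]]$species_id,
                    k = rows[[k]]$meta_key, v = rows[[k]]$meta_value))
  }
}

write_core_tables <- function(con, content, dialect) {
  merged <- identical(dialect, "65")

  DBI::dbExecute(con, paste0(
    "CREATE TABLE coord_system (coord_system_id INTEGER PRIMARY KEY, ",
    "species_id INTEGER NOT NULL, name TEXT NOT NULL, version TEXT, ",
    "rank INTEGER NOT NULL, attrib TEXT)"))
  cs <- content$coord_systems[order(content$coord_systems$coord_system_id), ]
  for (i in seq_len(nrow(cs))) {
    attrib <- paste(c("default_version",
                      if (isTRUE(cs$sequence_level[[i]])) "sequence_level"),
                    collapse = ",")
    DBI::dbExecute(con, paste0(
      "INSERT INTO coord_system VALUES (:a, :b, :c, :d, :e, :f)"),
      params = list(a = cs$coord_system_id[[i]], b = cs$species_id[[i]],
                    c = cs$name[[i]], d = cs$version[[i]],
                    e = cs$rank[[i]], f = attrib))
  }

  DBI::dbExecute(con, paste0(
    "CREATE TABLE seq_region (seq_region_id INTEGER PRIMARY KEY, ",
    "name TEXT NOT NULL, coord_system_id INTEGER NOT NULL, ",
    "length INTEGER NOT NULL)"))
  sr <- content$seq_regions[order(content$seq_regions$seq_region_id), ]
  exec_rows(con, "INSERT INTO seq_region VALUES (:seq_region_id, :name, :coord_system_id, :length)",
            sr[, c("seq_region_id", "name", "coord_system_id", "length")])

  DBI::dbExecute(con, paste0(
    "CREATE TABLE assembly (asm_seq_region_id INTEGER NOT NULL, ",
    "cmp_seq_region_id INTEGER NOT NULL, asm_start INTEGER NOT NULL, ",
    "asm_end INTEGER NOT NULL, cmp_start INTEGER NOT NULL, ",
    "cmp_end INTEGER NOT NULL, ori INTEGER NOT NULL)"))
  if (n0(content$assembly)) {
    a <- content$assembly[order(content$assembly$asm_seq_region_id,
                                content$assembly$asm_start), ]
    exec_rows(con, paste0(
      "INSERT INTO assembly VALUES (:asm_seq_region_id, :cmp_seq_region_id, ",
      ":asm_start, :asm_end, :cmp_start, :cmp_end, :ori)"),
      a[, c("asm_seq_region_id", "cmp_seq_region_id", "asm_start",
            "asm_end", "cmp_start", "cmp_end", "ori")])
  }

  DBI::dbExecute(con, paste0(
    "CREATE TABLE dna (seq_region_id INTEGER PRIMARY KEY, ",
    "sequence TEXT NOT NULL)"))
  if (n0(content$dna)) {
    d <- content$dna[order(content$dna$seq_region_id), ]
    exec_rows(con, "INSERT INTO dna VALUES (:seq_region_id, :sequence)",
              d[, c("seq_region_id", "sequence")])
  }

  stable_col <- if (merged) ", stable_id TEXT NOT NULL" else ""
  DBI::dbExecute(con, paste0(
    "CREATE TABLE gene (gene_id INTEGER PRIMARY KEY, biotype TEXT NOT NULL, ",
    "display_label TEXT, seq_region_id INTEGER NOT NULL, ",
    "seq_region_start INTEGER NOT NULL, seq_region_end INTEGER NOT NULL, ",
    "seq_region_strand INTEGER NOT NULL", stable_col, ")"))
  DBI::dbExecute(con, paste0(
    "CREATE TABLE transcript (transcript_id INTEGER PRIMARY KEY, ",
    "gene_id INTEGER NOT NULL, seq_region_id INTEGER NOT NULL, ",
    "seq_region_start INTEGER NOT NULL, seq_region_end INTEGER NOT NULL, ",
    "seq_region_strand INTEGER NOT NULL", stable_col, ")"))
  DBI::dbExecute(con, paste0(
    "CREATE TABLE exon (exon_id INTEGER PRIMARY KEY, ",
    "seq_region_id INTEGER NOT NULL, seq_region_start INTEGER NOT NULL, ",
    "seq_region_end INTEGER NOT NULL, seq_region_strand INTEGER NOT NULL",
    stable_col, ")"))
  DBI::dbExecute(con, paste0(
    "CREATE TABLE exon_transcript (exon_id INTEGER NOT NULL, ",
    "transcript_id INTEGER NOT NULL, rank INTEGER NOT NULL)"))
  DBI::dbExecute(con, paste0(
    "CREATE TABLE translation (translation_id INTEGER PRIMARY KEY, ",
    "transcript_id INTEGER NOT NULL, seq_start INTEGER NOT NULL, ",
    "start_exon_id INTEGER NOT NULL, seq_end INTEGER NOT NULL, ",
    "end_exon_id INTEGER NOT NULL", stable_col, ")"))
  if (!merged) {
    for (t in c("gene", "transcript", "exon", "translation")) {
      DBI::dbExecute(con, paste0(
        "CREATE TABLE ", t, "_stable_id (", t, "_id INTEGER PRIMARY KEY, ",
        "stable_id TEXT NOT NULL)"))
    }
  }

  ins_feat <- function(tab, table, id_col, cols) {
    if (!n0(tab)) return(invisible())
    tab <- tab[order(tab[[id_col]]), ]
    main_cols <- c(id_col, cols)
    if (merged) main_cols <- c(main_cols, "stable_id")
    ph <- paste0(":", main_cols, collapse = ", ")
    exec_rows(con, paste0("INSERT INTO ", table, " VALUES (", ph, ")"),
              tab[, main_cols])
    if (!merged) {
      exec_rows(con, paste0("INSERT INTO ", table, "_stable_id VALUES (:",
                            id_col, ", :stable_id)"),
                tab[, c(id_col, "stable_id")])
    }
  }
  g <- content$genes
  if (n0(g)) {
    g <- dplyr::rename(g, seq_region_start = "start", seq_region_end = "end",
                       seq_region_strand = "strand")
  }
  ins_feat(g, "gene", "gene_id",
           c("biotype", "display_label", "seq_region_id",
             "seq_region_start", "seq_region_end", "seq_region_strand"))
  tr <- content$transcripts
  if (n0(tr)) {
    tr <- dplyr::rename(tr, seq_region_start = "start",
                        seq_region_end = "end", seq_region_strand = "strand")
  }
  ins_feat(tr, "transcript", "transcript_id",
           c("gene_id", "seq_region_id", "seq_region_start",
             "seq_region_end", "seq_region_strand"))
  ex <- content$exons
  if (n0(ex)) {
    ex <- dplyr::rename(ex, seq_region_start = "start",
                        seq_region_end = "end", seq_region_strand = "strand")
  }
  ins_feat(ex, "exon", "exon_id",
           c("seq_region_id", "seq_region_start", "seq_region_end",
             "seq_region_strand"))
  if (n0(content$exon_transcript)) {
    et <- content$exon_transcript[order(content$exon_transcript$transcript_id,
                                        content$exon_transcript$rank), ]
    exec_rows(con, "INSERT INTO exon_transcript VALUES (:exon_id, :transcript_id, :rank)",
              et[, c("exon_id", "transcript_id", "rank")])
  }
  ins_feat(content$translations, "translation", "translation_id",
           c("transcript_id", "seq_start", "start_exon_id", "seq_end",
             "end_exon_id"))
}

write_variation_tables <- function(con, content) {
  DBI::dbExecute(con, paste0(
    "CREATE TABLE variation_feature (variation_feature_id INTEGER PRIMARY ",
    "KEY, seq_region_id INTEGER NOT NULL, seq_region_start INTEGER NOT ",
    "NULL, seq_region_end INTEGER NOT NULL, seq_region_strand INTEGER NOT ",
    "NULL, variation_name TEXT NOT NULL, allele_string TEXT NOT NULL)"))
  if (n0(content$variants)) {
    v <- content$variants[order(content$variants$variation_feature_id), ]
    exec_rows(con, paste0(
      "INSERT INTO variation_feature VALUES (:variation_feature_id, ",
      ":seq_region_id, :start, :end, :strand, :name, :allele_string)"),
      v[, c("variation_feature_id", "seq_region_id", "start", "end",
            "strand", "name", "allele_string")])
  }
}

write_compara_tables <- function(con, content) {
  DBI::dbExecute(con, paste0(
    "CREATE TABLE genome_db (genome_db_id INTEGER PRIMARY KEY, ",
    "name TEXT NOT NULL)"))
  DBI::dbExecute(con, paste0(
    "CREATE TABLE member (member_id INTEGER PRIMARY KEY, ",
    "stable_id TEXT NOT NULL, genome_db_id INTEGER NOT NULL, ",
    "chr_name TEXT NOT NULL, chr_start INTEGER NOT NULL, ",
    "chr_end INTEGER NOT NULL)"))
  DBI::dbExecute(con, paste0(
    "CREATE TABLE homology (homology_id INTEGER PRIMARY KEY, ",
    "description TEXT NOT NULL)"))
  DBI::dbExecute(con, paste0(
    "CREATE TABLE homology_member (homology_id INTEGER NOT NULL, ",
    "member_id INTEGER NOT NULL)"))
  h <- content$homologies
  if (!n0(h)) return(invisible())
  species <- sort(unique(c(h$source_species, h$target_species)))
  for (i in seq_along(species)) {
    DBI::dbExecute(con, "INSERT INTO genome_db VALUES (:a, :b)",
                   params = list(a = i, b = species[[i]]))
  }
  members <- unique(bind_rows(
    tibble(stable_id = h$source_stable_id, species = h$source_species,
           chr_name = h$source_region, chr_start = h$source_start,
           chr_end = h$source_end),
    tibble(stable_id = h$target_stable_id, species = h$target_species,
           chr_name = h$target_region, chr_start = h$target_start,
           chr_end = h$target_end)))
  members <- members[order(members$stable_id), ]
  for (i in seq_len(nrow(members))) {
    DBI::dbExecute(con, "INSERT INTO member VALUES (:a, :b, :c, :d, :e, :f)",
                   params = list(a = i, b = members$stable_id[[i]],
                                 c = match(members$species[[i]], species),
                                 d = members$chr_name[[i]],
                                 e = members$chr_start[[i]],
                                 f = members$chr_end[[i]]))
  }
  for (i in seq_len(nrow(h))) {
    DBI::dbExecute(con, "INSERT INTO homology VALUES (:a, :b)",
                   params = list(a = i, b = h$homology_type[[i]]))
    DBI::dbExecute(con, "INSERT INTO homology_member VALUES (:a, :b)",
                   params = list(a = i,
                                 b = match(h$source_stable_id[[i]],
                                           members$stable_id)))
    DBI::dbExecute(con, "INSERT INTO homology_member VALUES (:a, :b)",
                   params = list(a = i,
                                 b = match(h$target_stable_id[[i]],
                                           members$stable_id)))
  }
  invisible()
}
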
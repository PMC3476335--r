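#' Read mapping sets from a template tree
#'
#' A mapping set is a directory `<root>/<id>/<db_type>/` holding one `.sql`
#' file per query-name plus an `imports.properties` manifest whose single
#' `imports=` line names the sets (comma separated, same db_type) whose
#' templates are inherited before this set's own files override them. This
#' is how a schema migration is absorbed: the post-migration set imports the
#' older one and replaces only the queries the migration touched.
#'
#' @param root Root directory of the template tree; defaults to the tree
#'   shipped with the package.
#' @return A named list of mapping sets keyed `"<db_type>/<id>"`, each a
#'   list with `id`, `db_type`, `imports` and `templates` (named character
#'   vector of SQL text).
#' @export
read_mapping_sets <- function(root = default_templates_path()) {
  sets <- list()
  for (id in sort(list.dirs(root, recursive = FALSE, full.names = FALSE))) {
    for (ty in sort(list.dirs(file.path(root, id),
                              recursive = FALSE, full.names = FALSE))) {
      dir <- file.path(root, id, ty)
      manifest <- file.path(dir, "imports.properties")
      imports <- character(0)
      if (file.exists(manifest)) {
        props <- read_properties(manifest)
        if (!is.null(props["imports"]) && !is.na(props["imports"]) &&
            nzchar(props[["imports"]])) {
          imports <- trimws(strsplit(props[["imports"]], ",")[[1]])
        }
      }
      files <- sort(list.files(dir, pattern = "\\.sql$"))
      templates <- vapply(
        files,
        function(f) paste(readLines(file.path(dir, f), warn = FALSE),
                          collapse = "\n"),
        character(1))
      names(templates) <- sub("\\.sql$", "", files)
      sets[[paste0(ty, "/", id)]] <- list(
        id = id, db_type = ty, imports = imports, templates = templates)
    }
  }
  sets
}

#' Resolve the effective templates of a mapping set
#'
#' Applies imported sets in manifest order, then the set's own templates
#' override by query-name. The result must cover the full query catalogue
#' for the set's database type.
#'
#' @param sets Mapping sets from [read_mapping_sets()].
#' @param id Mapping-set id (e.g. `"65"`).
#' @param db_type Database type of the set.
#' @return Named character vector: query-name to SQL text.
#' @export
effective_templates <- function(sets, id, db_type) {
  merged <- resolve_set(sets, id, db_type, active = character(0))
  catalogue <- query_catalogue(db_type)
  missing <- setdiff(catalogue, names(merged))
  if (length(missing)) {
    rw_abort("config_error", paste0(
      "mapping set '", db_type, "/", id, "' is incomplete after import ",
      "resolution; missing query-names: ", paste(missing, collapse = ", ")))
  }
  merged[catalogue]
}

resolve_set <- function(sets, id, db_type, active) {
  key <- paste0(db_type, "/", id)
  if (key %in% active) {
    rw_abort("config_error",
             paste0("import cycle involving mapping set '", key, "'"))
  }
  set <- sets[[key]]
  if (is.null(set)) {
    rw_abort("config_error", paste0("unknown mapping set '", key, "'"))
  }
  merged <- character(0)
  for (imp in set$imports) {
    inherited <- resolve_set(sets, imp, db_type, c(active, key))
    merged[names(inherited)] <- inherited
  }
  merged[names(set$templates)] <- set$templates
  merged
}
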
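# Shared fixtures and independent oracles.
# The reference databases are built once per test run; tests that need
# clean query counters open a fresh catalog over the same files.

.rw_test_env <- new.env()

ref_dir <- function() {
  if (is.null(.rw_test_env$dir)) {
    dir <- file.path(tempdir(), "releasewise-ref")
    suppressMessages(reference_fixture(dir))
    .rw_test_env$dir <- dir
  }
  .rw_test_env$dir
}

ref_catalog <- function() {
  if (is.null(.rw_test_env$catalog)) {
    .rw_test_env$catalog <- suppressMessages(catalog_from_dir(ref_dir()))
  }
  .rw_test_env$catalog
}

# new handle registry (and hence zeroed query counters) over the same files
fresh_ref_catalog <- function() {
  suppressMessages(catalog_from_dir(ref_dir()))
}

ref_rules <- function() read_version_rules(default_rules_path())

# --- independent per-base projection oracle ------------------------------
# Maps every base of the query separately through block arithmetic, then
# groups maximal runs. Deliberately naive; project_location() must agree.

oracle_base <- function(p, blocks, strand = 1L) {
  hit <- blocks[blocks$asm_start <= p & blocks$asm_end >= p, ]
  if (nrow(hit) == 0) return(NULL)
  b <- hit[1, ]
  pos <- if (b$ori == 1L) b$cmp_start + (p - b$asm_start) else
    b$cmp_end - (p - b$asm_start)
  list(region = as.character(b$cmp_region), pos = as.integer(pos),
       strand = as.integer(strand * b$ori))
}

oracle_project <- function(start, end, blocks, strand = 1L) {
  maps <- lapply(start:end, oracle_base, blocks = blocks, strand = strand)
  segs <- list()
  push <- function(s) segs[[length(segs) + 1]] <<- s
  cur <- NULL
  for (m in maps) {
    if (is.null(m)) {
      if (!is.null(cur) && cur$kind == "GAP") {
        cur$length <- cur$length + 1L
      } else {
        if (!is.null(cur)) push(cur)
        cur <- list(kind = "GAP", region = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_integer_, length = 1L)
      }
    } else {
      dir <- if (m$strand == strand) 1L else -1L
      extends <- !is.null(cur) && cur$kind == "MAPPED" &&
        identical(cur$region, m$region) && cur$strand == m$strand &&
        m$pos == cur$last + dir
      if (extends) {
        cur$start <- min(cur$start, m$pos); cur$end <- max(cur$end, m$pos)
        cur$last <- m$pos; cur$length <- cur$length + 1L
      } else {
        if (!is.null(cur)) push(cur)
        cur <- list(kind = "MAPPED", region = m$region, start = m$pos,
                    end = m$pos, strand = m$strand, length = 1L,
                    last = m$pos)
      }
    }
  }
  if (!is.null(cur)) push(cur)
  dplyr::bind_rows(lapply(segs, function(s) tibble::tibble(
    kind = s$kind, cmp_region = s$region, start = s$start, end = s$end,
    strand = s$strand, length = s$length)))
}

# blocks of one assembled region from fixture content, with component names
content_blocks <- function(content, asm_name) {
  sr <- content$seq_regions
  asm_id <- sr$seq_region_id[sr$name == asm_name]
  a <- content$assembly[content$assembly$asm_seq_region_id == asm_id, ]
  tibble::tibble(
    asm_start = a$asm_start, asm_end = a$asm_end,
    cmp_region = sr$name[match(a$cmp_seq_region_id, sr$seq_region_id)],
    cmp_start = a$cmp_start, cmp_end = a$cmp_end, ori = a$ori)
}

# per-base sequence oracle over fixture content: resolves every chromosome
# base down to the sequence level (through any number of assembly levels)
oracle_sequence <- function(content, region_name, start, end) {
  sr <- content$seq_regions
  seq_level_ids <- sr$seq_region_id[
    sr$coord_system_id == max(content$coord_systems$coord_system_id)]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  base_at <- function(rid, p, strand) {
    if (rid %in% seq_level_ids) {
      s <- content$dna$sequence[content$dna$seq_region_id == rid]
      ch <- substr(s, p, p)
      return(if (strand == -1L) comp[[ch]] else ch)
    }
    a <- content$assembly[content$assembly$asm_seq_region_id == rid &
                            content$assembly$asm_start <= p &
                            content$assembly$asm_end >= p, ]
    if (nrow(a) == 0) return("N")
    b <- a[1, ]
    pos <- if (b$ori == 1L) b$cmp_start + (p - b$asm_start) else
      b$cmp_end - (p - b$asm_start)
    base_at(b$cmp_seq_region_id, pos, strand * b$ori)
  }
  rid <- sr$seq_region_id[sr$name == region_name]
  paste(vapply(start:end, function(p) base_at(rid, p, 1L), character(1)),
        collapse = "")
}

# two equal-content core databases, one per dialect, in their own catalog
dialect_pair_catalog <- function() {
  if (is.null(.rw_test_env$pair)) {
    dir <- file.path(tempdir(), "releasewise-pair")
    dir.create(dir, showWarnings = FALSE)
    build_fixture(releasewise:::ref_core_content(60L, 2L), "57",
                  file.path(dir, "testus_exemplaris_core_60_1.sqlite"))
    build_fixture(releasewise:::ref_core_content(66L, 2L), "65",
                  file.path(dir, "testus_exemplaris_core_66_1.sqlite"))
    .rw_test_env$pair <- dir
  }
  suppressMessages(catalog_from_dir(.rw_test_env$pair))
}

# length-safe random draw from a candidate vector (sample() reinterprets a
# single integer as 1:n)
pick1 <- function(x) x[sample.int(length(x), 1)]
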
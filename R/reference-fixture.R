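#' Reference fixture content and databases
#'
#' The canonical miniature genome used throughout the package's tests and
#' examples: a 20-base chromosome `chr1` assembled from contig `ctgA`
#' (bases 1-10, forward) and contig `ctgB` (bases 13-20, reverse, with a
#' 2-base gap at 11-12); a protein-coding gene `G1` with one
#' transcript/exon and a full-exon translation; a non-coding reverse-strand
#' gene `G2`; one SNP; one cross-species orthologue. Two core releases are
#' emitted in the two core dialects — the gene model shifts by one base
#' between them, giving the through-release history something to show.
#'
#' @name reference-fixture
NULL

ref_species <- function() {
  tibble(species_id = 1L, name = "testus_exemplaris",
         aliases = list(c("testus_exemplaris", "test")))
}

ref_core_content <- function(release, g1_start) {
  g1_end <- g1_start + 8L
  fixture_content(
    db_type = "core", schema_release = release,
    species = ref_species(),
    coord_systems = tibble(
      coord_system_id = c(1L, 2L), species_id = 1L,
      name = c("chromosome", "contig"), version = c("TEST1", NA),
      rank = c(1L, 2L), sequence_level = c(FALSE, TRUE)),
    seq_regions = tibble(
      seq_region_id = c(101L, 102L, 103L), coord_system_id = c(1L, 2L, 2L),
      name = c("chr1", "ctgA", "ctgB"), length = c(20L, 10L, 8L)),
    dna = tibble(seq_region_id = c(102L, 103L),
                 sequence = c("AATGAAATAG", "AAAACCCC")),
    assembly = tibble(
      asm_seq_region_id = 101L, asm_start = c(1L, 13L),
      asm_end = c(10L, 20L), cmp_seq_region_id = c(102L, 103L),
      cmp_start = c(1L, 1L), cmp_end = c(10L, 8L), ori = c(1L, -1L)),
    genes = tibble(
      gene_id = c(1L, 2L),
      stable_id = c("TESTG00000000001", "TESTG00000000002"),
      biotype = c("protein_coding", "lincRNA"),
      display_label = c("G1", "G2"),
      seq_region_id = 101L, start = c(g1_start, 14L),
      end = c(g1_end, 19L), strand = c(1L, -1L)),
    transcripts = tibble(
      transcript_id = c(1L, 2L), gene_id = c(1L, 2L),
      stable_id = c("TESTT00000000001", "TESTT00000000002"),
      seq_region_id = 101L, start = c(g1_start, 14L),
      end = c(g1_end, 19L), strand = c(1L, -1L)),
    exons = tibble(
      exon_id = c(1L, 2L),
      stable_id = c("TESTE00000000001", "TESTE00000000002"),
      seq_region_id = 101L, start = c(g1_start, 14L),
      end = c(g1_end, 19L), strand = c(1L, -1L)),
    exon_transcript = tibble(exon_id = c(1L, 2L),
                             transcript_id = c(1L, 2L), rank = 1L),
    translations = tibble(
      translation_id = 1L, transcript_id = 1L,
      stable_id = "TESTP00000000001", seq_start = 1L, start_exon_id = 1L,
      seq_end = 9L, end_exon_id = 1L))
}

ref_variation_content <- function(release = 66L) {
  fixture_content(
    db_type = "variation", schema_release = release,
    species = ref_species(),
    seq_regions = tibble(seq_region_id = 101L, coord_system_id = 1L,
                         name = "chr1", length = 20L),
    variants = tibble(
      variation_feature_id = 1L, name = "rs0000001", allele_string = "A/G",
      seq_region_id = 101L, start = 5L, end = 5L, strand = 1L))
}

ref_compara_content <- function(release = 66L) {
  fixture_content(
    db_type = "compara", schema_release = release,
    homologies = tibble(
      source_stable_id = "TESTG00000000001",
      source_species = "testus_exemplaris", source_region = "chr1",
      source_start = 2L, source_end = 10L,
      target_stable_id = "OTHERG00000000005",
      target_species = "alius_speciesus", target_region = "chr2",
      target_start = 100L, target_end = 200L,
      homology_type = "ortholog_one2one"))
}

#' Build the reference fixture databases
#'
#' Emits six database files: registrable core releases 60 (dialect "57")
#' and 66 (dialect "65"), variation and compara at 66, plus core releases
#' 49 and 70 which straddle the configured support window and exist only to
#' exercise registry exclusion.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, keyed by database name.
#' @export
reference_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    list(name = "testus_exemplaris_core_60_1",
         content = ref_core_content(60L, 2L), dialect = "57"),
    list(name = "testus_exemplaris_core_66_2",
         content = ref_core_content(66L, 3L), dialect = "65"),
    list(name = "testus_exemplaris_core_49_1",
         content = ref_core_content(49L, 2L), dialect = "57"),
    list(name = "testus_exemplaris_core_70_3",
         content = ref_core_content(70L, 3L), dialect = "65"),
    list(name = "testus_exemplaris_variation_66_2",
         content = ref_variation_content(66L), dialect = "62-variation"),
    list(name = "ensembl_compara_66",
         content = ref_compara_content(66L), dialect = "compara"))
  paths <- vapply(specs, function(s) {
    p <- file.path(dir, paste0(s$name, ".sqlite"))
    build_fixture(s$content, s$dialect, p)
    p
  }, character(1))
  stats::setNames(paths, vapply(specs, `[[`, "", "name"))
}

#' Generate a random assembly fixture
#'
#' Drives the projection property tests: a chromosome assembled from
#' non-overlapping blocks with random orientations and random gaps,
#' optionally through an intermediate supercontig level, with random DNA on
#' the sequence-level regions. Reproducible for a given seed; every block
#' satisfies the assembly invariants.
#'
#' @param seed Integer seed.
#' @param n_regions Number of component regions at the top level.
#' @param max_len Rough upper bound on component lengths.
#' @param levels 1 (chromosome to contigs) or 2 (chromosome to supercontigs
#'   to contigs).
#' @return A core [fixture_content()] with assembly and dna tables only.
#' @export
random_assembly <- function(seed, n_regions, max_len, levels = 1L) {
  stopifnot(n_regions >= 1, max_len >= 4, levels %in% c(1L, 2L))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)

  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  next_id <- 200L
  regions <- list(); dna <- list(); blocks <- list()
  add_region <- function(name, cs_id, len) {
    next_id <<- next_id + 1L
    regions[[length(regions) + 1]] <<- tibble(
      seq_region_id = next_id, coord_system_id = cs_id,
      name = name, length = as.integer(len))
    next_id
  }

  # lay blocks left to right on an assembled region; each component is a
  # fresh region with a random internal offset and orientation
  lay_blocks <- function(n, piece_max, cmp_cs, cmp_prefix) {
    pos <- 1L; out <- list(); comps <- list()
    for (i in seq_len(n)) {
      gap <- sample(0:3, 1)
      len <- sample(2:max(3, piece_max), 1)
      a1 <- pos + gap; a2 <- a1 + len - 1L
      off <- sample(0:3, 1)
      c1 <- 1L + off; c2 <- c1 + len - 1L
      cmp_len <- c2 + sample(0:2, 1)
      id <- add_region(paste0(cmp_prefix, i), cmp_cs, cmp_len)
      out[[i]] <- tibble(
        asm_start = as.integer(a1), asm_end = as.integer(a2),
        cmp_seq_region_id = id, cmp_start = as.integer(c1),
        cmp_end = as.integer(c2), ori = sample(c(1L, -1L), 1))
      comps[[i]] <- list(id = id, len = cmp_len)
      pos <- a2 + 1L
    }
    list(blocks = bind_rows(out), comps = comps,
         total = pos - 1L + sample(0:3, 1))
  }

  seq_cs <- if (levels == 2L) 3L else 2L
  piece_max <- max(4L, as.integer(max_len / n_regions))

  if (levels == 1L) {
    laid <- lay_blocks(n_regions, piece_max, seq_cs, "ctg")
    chr_id <- add_region("chr1", 1L, max(laid$total, max(laid$blocks$asm_end)))
    blocks[[1]] <- mutate(laid$blocks, asm_seq_region_id = chr_id)
    for (cm in laid$comps) {
      dna[[length(dna) + 1]] <- tibble(seq_region_id = cm$id,
                                       sequence = rand_dna(cm$len))
    }
  } else {
    laid <- lay_blocks(n_regions, piece_max, 2L, "sct")
    chr_id <- add_region("chr1", 1L, max(laid$total, max(laid$blocks$asm_end)))
    blocks[[1]] <- mutate(laid$blocks, asm_seq_region_id = chr_id)
    for (k in seq_along(laid$comps)) {
      sct <- laid$comps[[k]]
      sub <- lay_blocks(sample(1:2, 1), max(4L, sct$len), seq_cs,
                        paste0("ctg", k, "_"))
      sub_blocks <- mutate(sub$blocks, asm_seq_region_id = sct$id)
      # clip sub-blocks to the supercontig's declared length
      keep <- sub_blocks$asm_end <= sct$len
      blocks[[length(blocks) + 1]] <- sub_blocks[keep, ]
      for (j in which(keep)) {
        cm <- sub$comps[[j]]
        dna[[length(dna) + 1]] <- tibble(seq_region_id = cm$id,
                                         sequence = rand_dna(cm$len))
      }
    }
  }

  cs <- tibble(
    coord_system_id = seq_len(seq_cs), species_id = 1L,
    name = c("chromosome", if (levels == 2L) "supercontig", "contig"),
    version = c("RND1", rep(NA_character_, seq_cs - 1L)),
    rank = seq_len(seq_cs),
    sequence_level = seq_len(seq_cs) == seq_cs)
  regions <- bind_rows(regions)
  dna <- bind_rows(dna)
  if (nrow(dna) == 0) {
    dna <- tibble(seq_region_id = integer(0), sequence = character(0))
  }
  dna <- dna[dna$seq_region_id %in% regions$seq_region_id, ]
  all_blocks <- bind_rows(blocks)

  fixture_content(
    db_type = "core", schema_release = 66L, species = ref_species(),
    coord_systems = cs, seq_regions = regions, dna = dna,
    assembly = all_blocks[, c("asm_seq_region_id", "asm_start", "asm_end",
                              "cmp_seq_region_id", "cmp_start", "cmp_end",
                              "ori")])
}
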
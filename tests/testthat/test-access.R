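test_that("open_database defaults to the latest release and binds its dialect", {
  cat_ <- ref_catalog()
  db <- open_database(cat_, "testus_exemplaris", "core")
  expect_equal(db$descriptor$schema_release, 66L)
  expect_equal(db$mapping_set_id, "65")
  db60 <- open_database(cat_, "testus_exemplaris", "core", 60)
  expect_equal(db60$mapping_set_id, "57")
  err <- expect_error(
    open_database(cat_, "testus_exemplaris", "variation", 60),
    class = "rw_not_available_error")
  expect_match(conditionMessage(err), "66")  # names the nearest release
  expect_error(open_database(cat_, "ignotus_specius", "core"),
               class = "rw_not_found_error")
})

test_that("default-release access equals explicit latest-release access", {
  cat_ <- ref_catalog()
  dflt <- open_database(cat_, "test", "core")
  expl <- open_database(cat_, "test", "core",
                        latest_release(cat_, "test", "core"))
  expect_identical(dflt, expl)  # one shared handle
  expect_identical(genes_in_region(dflt, "chr1", 1, 20),
                   genes_in_region(expl, "chr1", 1, 20))
})

test_that("region gene queries use closed-interval overlap", {
  db <- open_database(ref_catalog(), "test", "core", 66)
  g <- genes_in_region(db, "chr1", 1, 20)
  expect_equal(g$stable_id, c("TESTG00000000001", "TESTG00000000002"))
  expect_equal(g$start, c(3L, 14L))
  expect_equal(g$end, c(11L, 19L))
  expect_equal(g$strand, c(1L, -1L))
  expect_equal(nrow(genes_in_region(db, "chr1", 12, 13)), 0)
  both <- genes_in_region(db, "chr1", 11, 14)  # 1-base overlaps at 11 and 14
  expect_equal(both$stable_id, c("TESTG00000000001", "TESTG00000000002"))
  expect_error(genes_in_region(db, "chrUnknown", 1, 10),
               class = "rw_not_found_error")
})

test_that("stable-id lookup is dialect-transparent across releases", {
  cat_ <- ref_catalog()
  g60 <- gene_by_stable_id(open_database(cat_, "test", "core", 60),
                           "TESTG00000000001")
  expect_equal(c(g60$start, g60$end, g60$strand), c(2L, 10L, 1L))
  g66 <- gene_by_stable_id(open_database(cat_, "test", "core", 66),
                           "TESTG00000000001")
  expect_equal(c(g66$start, g66$end, g66$strand), c(3L, 11L, 1L))
  expect_error(
    gene_by_stable_id(open_database(cat_, "test", "core", 66),
                      "TESTG99999999999"),
    class = "rw_not_found_error")
})

test_that("gene history walks ascending releases and skips absences", {
  cat_ <- ref_catalog()
  h <- gene_across_releases(cat_, "test", "TESTG00000000001")
  expect_equal(h$release, c(60L, 66L))
  expect_equal(h$start, c(2L, 3L))
  expect_equal(h$end, c(10L, 11L))
  expect_equal(h$region, c("chr1", "chr1"))
  expect_error(gene_across_releases(cat_, "test", "TESTG99999999999"),
               class = "rw_not_found_error")
})

test_that("a gene present in only one release yields a one-row history", {
  dir <- withr::local_tempdir()
  c60 <- releasewise:::ref_core_content(60L, 2L)
  c66 <- releasewise:::ref_core_content(66L, 3L)
  extra <- tibble::tibble(
    gene_id = 3L, stable_id = "TESTG00000000003", biotype = "protein_coding",
    display_label = "G3", seq_region_id = 101L, start = 1L, end = 4L,
    strand = 1L)
  c66$genes <- dplyr::bind_rows(c66$genes, extra)
  build_fixture(c60, "57",
                file.path(dir, "testus_exemplaris_core_60_1.sqlite"))
  build_fixture(c66, "65",
                file.path(dir, "testus_exemplaris_core_66_2.sqlite"))
  cat_ <- suppressMessages(catalog_from_dir(dir))
  h <- suppressMessages(
    gene_across_releases(cat_, "test", "TESTG00000000003"))
  expect_equal(h$release, 66L)
})

test_that("variant retrieval crosses schemas via the shared region id", {
  cat_ <- ref_catalog()
  v <- variants_in_region(cat_, "test", 66, "chr1", 1, 10)
  expect_equal(v$name, "rs0000001")
  expect_equal(v$allele_string, "A/G")
  expect_equal(c(v$start, v$end), c(5L, 5L))
  expect_equal(nrow(variants_in_region(cat_, "test", 66, "chr1", 6, 20)), 0)
  expect_error(variants_in_region(cat_, "test", 60, "chr1", 1, 10),
               class = "rw_not_available_error")
})

test_that("homology hits carry enough to re-query the target core schema", {
  cat_ <- ref_catalog()
  h <- homologues_of(cat_, "TESTG00000000001")
  expect_equal(h$target_stable_id, "OTHERG00000000005")
  expect_equal(h$target_species, "alius_speciesus")
  expect_equal(h$target_region, "chr2")
  expect_equal(c(h$target_start, h$target_end), c(100L, 200L))
  expect_equal(h$homology_type, "ortholog_one2one")
  expect_true(h$target_start <= h$target_end)
  expect_equal(nrow(homologues_of(cat_, "TESTG00000000001",
                                  target_species = "alius_speciesus")), 1)
  expect_equal(nrow(homologues_of(cat_, "TESTG00000000001",
                                  target_species = "missingus")), 0)
})

test_that("coordinate systems are species-scoped and rank-ordered", {
  db <- open_database(ref_catalog(), "test", "core", 66)
  cs <- coordinate_systems(db)
  expect_equal(cs$name, c("chromosome", "contig"))
  expect_equal(cs$rank, c(1L, 2L))
  expect_equal(cs$sequence_level, c(FALSE, TRUE))

  # two-species collection: each species sees only its own systems
  dir <- withr::local_tempdir()
  content <- fixture_content(
    db_type = "core", schema_release = 66L,
    species = tibble::tibble(
      species_id = c(1L, 2L),
      name = c("escherichia_coli", "shigella_flexneri"),
      aliases = list(c("escherichia_coli", "ecoli"), "shigella_flexneri")),
    coord_systems = tibble::tibble(
      coord_system_id = c(1L, 2L), species_id = c(1L, 2L),
      name = c("chromosome", "plasmid_chromosome"),
      version = c("B1", "B2"), rank = c(1L, 1L), sequence_level = TRUE),
    seq_regions = tibble::tibble(
      seq_region_id = c(1L, 2L), coord_system_id = c(1L, 2L),
      name = c("Chromosome", "Chr"), length = c(8L, 6L)),
    dna = tibble::tibble(seq_region_id = c(1L, 2L),
                         sequence = c("ACGTACGT", "GGGCCC")))
  nm <- "escherichia_shigella_collection_core_14_66_1"
  build_fixture(content, "65", file.path(dir, paste0(nm, ".sqlite")))
  cat2 <- suppressMessages(catalog_from_dir(dir))
  rec <- find_species(cat2, "ecoli")
  expect_true(rec$collection_member)
  db1 <- open_database(cat2, "escherichia_coli", "core", 66)
  db2 <- open_database(cat2, "shigella_flexneri", "core", 66)
  expect_equal(coordinate_systems(db1)$name, "chromosome")
  expect_equal(coordinate_systems(db2)$name, "plasmid_chromosome")
  expect_identical(fetch_sequence(db2, "Chr", 1, 6), "GGGCCC")

  # a core database without coordinate systems is corrupt
  bad <- fixture_content(
    db_type = "core", schema_release = 66L,
    species = releasewise:::ref_species(),
    coord_systems = tibble::tibble(
      coord_system_id = 1L, species_id = 2L, name = "chromosome",
      version = NA_character_, rank = 1L, sequence_level = TRUE),
    seq_regions = tibble::tibble(
      seq_region_id = 1L, coord_system_id = 1L, name = "chr1", length = 4L),
    dna = tibble::tibble(seq_region_id = 1L, sequence = "ACGT"))
  nm2 <- "testus_exemplaris_core_66_1"
  dir2 <- withr::local_tempdir()
  build_fixture(bad, "65", file.path(dir2, paste0(nm2, ".sqlite")))
  cat3 <- suppressMessages(catalog_from_dir(dir2))
  db3 <- open_database(cat3, "testus_exemplaris", "core", 66)
  expect_error(coordinate_systems(db3), class = "rw_data_integrity_error")
})

test_that("child and sequence queries run only on first explicit access", {
  cat_ <- fresh_ref_catalog()
  db <- open_database(cat_, "test", "core", 66)
  genes <- genes_in_region(db, "chr1", 1, 20)
  counts <- query_counts(db)
  expect_false("transcripts.of_gene" %in% names(counts))
  expect_false("sequence.of_region" %in% names(counts))
  expect_equal(counts[["genes.by_region"]], 1L)

  transcripts_of_gene(db, genes$stable_id[[1]])
  expect_equal(query_counts(db)[["transcripts.of_gene"]], 1L)
  expect_false("sequence.of_region" %in% names(query_counts(db)))

  fetch_sequence(db, "chr1", 1, 5)
  expect_equal(query_counts(db)[["sequence.of_region"]], 1L)
})

test_that("repeated opens share one handle, and all queries are catalogued", {
  cat_ <- fresh_ref_catalog()
  a <- open_database(cat_, "test", "core", 60)
  b <- open_database(cat_, "Testus_Exemplaris", "core", 60)
  expect_identical(a, b)
  genes_in_region(a, "chr1", 1, 20)
  expect_equal(query_counts(b)[["genes.by_region"]], 1L)

  # exercise the full surface, then check template provenance
  fetch_sequence(a, "chr1", 1, 20)
  splice_transcript(a, "TESTT00000000001")
  translate_cds(a, "TESTT00000000001")
  variants_in_region(cat_, "test", 66, "chr1", 1, 10)
  homologues_of(cat_, "TESTG00000000001")
  coordinate_systems(a)
  for (key in ls(cat_$handles)) {
    db <- cat_$handles[[key]]
    expect_true(all(names(query_counts(db)) %in% query_catalogue()),
                info = key)
  }
  expect_error(db_query(a, "meta.everything"), class = "rw_config_error")
})
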
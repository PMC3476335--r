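test_that("chromosome sequence is stitched from components with N gaps", {
  db <- open_database(ref_catalog(), "test", "core", 60)
  expect_identical(fetch_sequence(db, "chr1", 1, 20),
                   "AATGAAATAGNNGGGGTTTT")
  expect_identical(fetch_sequence(db, "chr1", 13, 20), "GGGGTTTT")
  expect_identical(fetch_sequence(db, "ctgA", 1, 10), "AATGAAATAG")
  expect_identical(fetch_sequence(db, "chr1", 11, 12), "NN")
  expect_error(fetch_sequence(db, "chr9", 1, 5),
               class = "rw_not_found_error")
  expect_error(fetch_sequence(db, "chr1", 15, 25),
               class = "rw_input_error")
})

test_that("minus-strand fetch equals the reverse complement, 100 intervals", {
  db <- open_database(ref_catalog(), "test", "core", 60)
  set.seed(11)
  for (k in 1:100) {
    a <- sample(1:20, 1); b <- pick1(a:20)
    fwd <- fetch_sequence(db, "chr1", a, b, strand = 1L)
    rev <- fetch_sequence(db, "chr1", a, b, strand = -1L)
    expect_identical(rev, reverse_complement(fwd))
  }
})

test_that("stitching through two assembly levels matches the per-base oracle", {
  dir <- withr::local_tempdir()
  for (seed in c(5, 17, 23, 31)) {
    content <- random_assembly(seed, 3, 40, levels = 2L)
    nm <- sprintf("testus_exemplaris_core_66_%d", seed)
    build_fixture(content, "65", file.path(dir, paste0(nm, ".sqlite")))
  }
  # also a single-level case through the database path
  one <- random_assembly(63, 4, 40, levels = 1L)
  build_fixture(one, "65",
                file.path(dir, "testus_exemplaris_core_66_63.sqlite"))
  cat_ <- suppressMessages(catalog_from_dir(dir))
  # the catalog keeps the greatest build; open the others directly per name
  for (seed in c(5, 17, 23, 31, 63)) {
    nm <- sprintf("testus_exemplaris_core_66_%d", seed)
    sub <- suppressMessages(build_catalog(
      nm, ref_rules(),
      paths = stats::setNames(file.path(dir, paste0(nm, ".sqlite")), nm)))
    db <- open_database(sub, "test", "core", 66)
    content <- if (seed == 63) one else random_assembly(seed, 3, 40, levels = 2L)
    chr_len <- content$seq_regions$length[content$seq_regions$name == "chr1"]
    expect_identical(fetch_sequence(db, "chr1", 1, chr_len),
                     oracle_sequence(content, "chr1", 1, chr_len),
                     info = paste("seed", seed))
  }
})

test_that("transcripts splice on their own strand", {
  db <- open_database(ref_catalog(), "test", "core", 60)
  expect_identical(splice_transcript(db, "TESTT00000000001"), "ATGAAATAG")
  expect_identical(splice_transcript(db, "TESTT00000000002"), "AAACCC")
  expect_error(splice_transcript(db, "TESTT99999999999"),
               class = "rw_input_error")
})

test_that("a multi-exon transcript concatenates exon pieces in rank order", {
  dir <- withr::local_tempdir()
  content <- releasewise:::ref_core_content(60L, 2L)
  content$transcripts <- tibble::tibble(
    transcript_id = 1L, gene_id = 1L, stable_id = "TESTT00000000001",
    seq_region_id = 101L, start = 2L, end = 10L, strand = 1L)
  content$exons <- tibble::tibble(
    exon_id = c(1L, 3L), stable_id = c("TESTE00000000001",
                                       "TESTE00000000003"),
    seq_region_id = 101L, start = c(2L, 8L), end = c(4L, 10L), strand = 1L)
  content$exon_transcript <- tibble::tibble(
    exon_id = c(1L, 3L), transcript_id = 1L, rank = c(1L, 2L))
  content$genes <- content$genes[1, ]
  content$translations <- NULL
  nm <- "testus_exemplaris_core_60_9"
  build_fixture(content, "57", file.path(dir, paste0(nm, ".sqlite")))
  cat_ <- suppressMessages(catalog_from_dir(dir))
  db <- open_database(cat_, "test", "core", 60)
  expect_identical(splice_transcript(db, "TESTT00000000001"), "ATGTAG")
})

test_that("translation applies the standard code and strips the stop", {
  db <- open_database(ref_catalog(), "test", "core", 60)
  expect_identical(translate_cds(db, "TESTT00000000001"), "MK")
  expect_error(translate_cds(db, "TESTT00000000002"),
               class = "rw_not_coding_error")
})

test_that("CDS length and internal stops are data-integrity errors", {
  expect_identical(releasewise:::translate_cds_string("ATGAAATAG"), "MK")
  expect_identical(releasewise:::translate_cds_string("ATG"), "M")
  expect_error(releasewise:::translate_cds_string("ATGA"),
               class = "rw_data_integrity_error")
  expect_error(releasewise:::translate_cds_string("ATGTAGAAATAG"),
               class = "rw_data_integrity_error")

  # through the access layer: a translation spanning a frame-breaking CDS
  dir <- withr::local_tempdir()
  content <- releasewise:::ref_core_content(60L, 2L)
  content$translations$seq_end <- 4L  # CDS "ATGA": length 4
  nm <- "testus_exemplaris_core_60_8"
  build_fixture(content, "57", file.path(dir, paste0(nm, ".sqlite")))
  cat_ <- suppressMessages(catalog_from_dir(dir))
  db <- open_database(cat_, "test", "core", 60)
  expect_error(translate_cds(db, "TESTT00000000001"),
               class = "rw_data_integrity_error")
})
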
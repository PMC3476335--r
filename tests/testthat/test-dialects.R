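test_that("identical content in the two core dialects answers identically", {
  cat_ <- dialect_pair_catalog()
  db57 <- open_database(cat_, "test", "core", 60)  # separate stable_id tables
  db65 <- open_database(cat_, "test", "core", 66)  # merged layout
  expect_equal(db57$mapping_set_id, "57")
  expect_equal(db65$mapping_set_id, "65")

  strip <- function(x) { attributes(x)["region"] <- NULL; x }
  expect_identical(coordinate_systems(db57), coordinate_systems(db65))
  g57 <- genes_in_region(db57, "chr1", 1, 20)
  g65 <- genes_in_region(db65, "chr1", 1, 20)
  expect_identical(as.data.frame(g57), as.data.frame(g65))
  expect_identical(gene_by_stable_id(db57, "TESTG00000000001"),
                   gene_by_stable_id(db65, "TESTG00000000001"))
  expect_identical(transcripts_of_gene(db57, "TESTG00000000001"),
                   transcripts_of_gene(db65, "TESTG00000000001"))
  expect_identical(exons_of_transcript(db57, "TESTT00000000001"),
                   exons_of_transcript(db65, "TESTT00000000001"))
  expect_identical(translation_of_transcript(db57, "TESTT00000000001"),
                   translation_of_transcript(db65, "TESTT00000000001"))
  expect_identical(fetch_sequence(db57, "chr1", 1, 20),
                   fetch_sequence(db65, "chr1", 1, 20))
  expect_identical(splice_transcript(db57, "TESTT00000000001"),
                   splice_transcript(db65, "TESTT00000000001"))
  expect_identical(translate_cds(db57, "TESTT00000000001"),
                   translate_cds(db65, "TESTT00000000001"))

  # exports are byte-identical across dialects
  expect_identical(export_gff3(db57, g57), export_gff3(db65, g65))
  expect_identical(
    export_fasta("chr1", fetch_sequence(db57, "chr1", 1, 20)),
    export_fasta("chr1", fetch_sequence(db65, "chr1", 1, 20)))
})

test_that("dialect 57 files keep stable ids in side tables; 65 merges them", {
  dir <- withr::local_tempdir()
  p57 <- file.path(dir, "a57.sqlite"); p65 <- file.path(dir, "a65.sqlite")
  build_fixture(releasewise:::ref_core_content(60L, 2L), "57", p57)
  build_fixture(releasewise:::ref_core_content(66L, 2L), "65", p65)

  con57 <- DBI::dbConnect(RSQLite::SQLite(), p57)
  con65 <- DBI::dbConnect(RSQLite::SQLite(), p65)
  on.exit({ DBI::dbDisconnect(con57); DBI::dbDisconnect(con65) })

  side_tables <- c("gene_stable_id", "transcript_stable_id",
                   "exon_stable_id", "translation_stable_id")
  expect_true(all(side_tables %in% DBI::dbListTables(con57)))
  expect_false(any(side_tables %in% DBI::dbListTables(con65)))
  for (t in c("gene", "transcript", "exon", "translation")) {
    expect_false("stable_id" %in% DBI::dbListFields(con57, t), info = t)
    expect_true("stable_id" %in% DBI::dbListFields(con65, t), info = t)
  }
})

test_that("fixture builds are byte-identical across repeated runs", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "one.sqlite"); p2 <- file.path(dir, "two.sqlite")
  content <- releasewise:::ref_core_content(66L, 3L)
  build_fixture(content, "65", p1)
  Sys.sleep(0.1)
  build_fixture(content, "65", p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # the compara and variation writers too
  v1 <- file.path(dir, "v1.sqlite"); v2 <- file.path(dir, "v2.sqlite")
  build_fixture(releasewise:::ref_variation_content(), "62-variation", v1)
  build_fixture(releasewise:::ref_variation_content(), "62-variation", v2)
  expect_identical(readBin(v1, "raw", file.size(v1)),
                   readBin(v2, "raw", file.size(v2)))
})

test_that("content/dialect mismatches are input errors", {
  expect_error(
    build_fixture(releasewise:::ref_variation_content(), "57",
                  tempfile(fileext = ".sqlite")),
    class = "rw_input_error")
  expect_error(
    build_fixture(releasewise:::ref_core_content(60L, 2L), "62-variation",
                  tempfile(fileext = ".sqlite")),
    class = "rw_input_error")
  expect_error(
    build_fixture(releasewise:::ref_core_content(60L, 2L), "58",
                  tempfile(fileext = ".sqlite")),
    class = "rw_input_error")
})

test_that("internally inconsistent fixture content is rejected", {
  content <- releasewise:::ref_core_content(60L, 2L)
  content$dna$sequence[[1]] <- "ACGT"  # length 4 vs declared 10
  expect_error(build_fixture(content, "57", tempfile(fileext = ".sqlite")),
               class = "rw_input_error")
  content2 <- releasewise:::ref_core_content(60L, 2L)
  content2$genes$end[[1]] <- 99L
  expect_error(build_fixture(content2, "57", tempfile(fileext = ".sqlite")),
               class = "rw_input_error")
})
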
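#' Stitch genomic sequence for a location
#'
#' DNA is stored only at the sequence-level coordinate system. For a region
#' at any higher level the query interval is projected through the assembly
#' relation — recursively, since components may themselves be assembled —
#' and only the required substrings of sequence-level components are read
#' (lazy: nothing is fetched until this call, and never more than the
#' projected ranges). Minus-orientation segments are reverse-complemented,
#' gaps fill with `N`, and a minus-strand query reverse-complements the
#' final concatenation.
#'
#' @param db A core `bound_database`.
#' @param region_name Region name at any coordinate-system level.
#' @param start,end Interval on that region, 1-based closed.
#' @param strand Query strand, `+1` or `-1`.
#' @return DNA string of length `end - start + 1`.
#' @export
fetch_sequence <- function(db, region_name, start, end, strand = 1L) {
  region <- region_by_name(db, region_name)
  loc <- location(region_name, start, end, strand, region$length)
  assert_valid_location(loc)
  ridx <- regions_index(db)
  n_levels <- length(unique(ridx$coord_system_id))
  seq <- fetch_forward(db, ridx, as.integer(region$seq_region_id),
                       as.integer(start), as.integer(end),
                       depth = n_levels)
  if (strand == -1L) seq <- reverse_complement(seq)
  seq
}

fetch_forward <- function(db, ridx, seq_region_id, start, end, depth) {
  if (depth < 0) {
    rw_abort("data_integrity_error",
             "cyclic assembly: projection exceeded the coordinate-system depth")
  }
  row <- ridx[ridx$seq_region_id == seq_region_id, ]
  if (nrow(row) == 0) {
    rw_abort("not_found_error",
             paste0("unknown seq_region_id ", seq_region_id))
  }
  if (isTRUE(row$sequence_level[[1]])) {
    res <- db_query(db, "sequence.of_region",
                    list(seq_region_id = seq_region_id,
                         start = start, length = end - start + 1L))
    if (nrow(res) == 0 || is.na(res$sequence[[1]])) {
      rw_abort("data_integrity_error", paste0(
        "sequence-level region ", row$name[[1]], " has no stored dna"))
    }
    return(toupper(res$sequence[[1]]))
  }
  blocks <- db_query(db, "assembly.components_of",
                     list(asm_seq_region_id = seq_region_id,
                          start = start, end = end))
  segs <- project_location(
    start, end,
    tibble(asm_start = as.integer(blocks$asm_start),
           asm_end = as.integer(blocks$asm_end),
           cmp_region = as.character(blocks$cmp_seq_region_id),
           cmp_start = as.integer(blocks$cmp_start),
           cmp_end = as.integer(blocks$cmp_end),
           ori = as.integer(blocks$ori)))
  pieces <- purrr::map_chr(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    if (s$kind == "GAP") return(strrep("N", s$length))
    piece <- fetch_forward(db, ridx, as.integer(s$cmp_region),
                           s$start, s$end, depth - 1L)
    if (s$strand == -1L) piece <- reverse_complement(piece)
    piece
  })
  paste(pieces, collapse = "")
}

#' Spliced (cDNA) sequence of a transcript
#'
#' Exons are fetched in transcription order, each on the transcript strand,
#' and concatenated.
#'
#' @param db A core `bound_database`.
#' @param transcript_stable_id Transcript stable identifier.
#' @return The spliced DNA string.
#' @export
splice_transcript <- function(db, transcript_stable_id) {
  exons <- exons_of_transcript(db, transcript_stable_id)
  if (nrow(exons) == 0) {
    rw_abort("input_error", paste0(
      "transcript '", transcript_stable_id, "' has no exons"))
  }
  pieces <- purrr::map_chr(seq_len(nrow(exons)), function(i) {
    e <- exons[i, ]
    fetch_sequence(db, e$region, e$start, e$end, e$strand)
  })
  paste(pieces, collapse = "")
}

#' Translate the coding sequence of a transcript
#'
#' The CDS is cut from the spliced sequence using the translation record's
#' start/end exons and 1-based offsets within them, then translated with
#' the standard nuclear genetic code; the trailing stop codon is removed.
#'
#' @param db A core `bound_database`.
#' @param transcript_stable_id Transcript stable identifier.
#' @return Peptide string.
#' @export
translate_cds <- function(db, transcript_stable_id) {
  tl <- translation_of_transcript(db, transcript_stable_id)
  if (is.null(tl)) {
    rw_abort("not_coding_error", paste0(
      "transcript '", transcript_stable_id, "' has no translation"))
  }
  exons <- exons_of_transcript(db, transcript_stable_id)
  widths <- exons$end - exons$start + 1L
  offset_before <- cumsum(c(0L, widths))[seq_len(nrow(exons))]
  i_start <- match(tl$start_exon, exons$stable_id)
  i_end <- match(tl$end_exon, exons$stable_id)
  if (is.na(i_start) || is.na(i_end)) {
    rw_abort("data_integrity_error", paste0(
      "translation of '", transcript_stable_id,
      "' references exons outside the transcript"))
  }
  cdna <- splice_transcript(db, transcript_stable_id)
  cds_start <- offset_before[[i_start]] + tl$seq_start
  cds_end <- offset_before[[i_end]] + tl$seq_end
  if (cds_start < 1 || cds_end > nchar(cdna) || cds_start > cds_end) {
    rw_abort("data_integrity_error", paste0(
      "translation offsets of '", transcript_stable_id,
      "' fall outside the spliced sequence"))
  }
  translate_cds_string(substr(cdna, cds_start, cds_end))
}
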